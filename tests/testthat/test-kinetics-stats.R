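test_that("cumulative dwell distribution counts events per location", {
  sch <- acquisition_schedule()
  tab <- table_from_dwells(
    list(
      "5i3" = list(c(10), c(60, 60)),
      "no_RNA" = list()
    ),
    n_locations = 50, schedule = sch
  )
  d <- cumulative_dwell_distribution(tab, "5i3", grid = c(0, 50, 61))
  expect_equal(d$value, c(3 / 50, 2 / 50, 0))
  expect_equal(d$n_locations, 50L)

  # empty construct: identically zero
  d0 <- cumulative_dwell_distribution(tab, "no_RNA", grid = c(0, 50, 61))
  expect_true(all(d0$value == 0))

  # non-increasing for arbitrary tables
  set.seed(14)
  dwells <- replicate(30, rexp(rpois(1, 3), 1 / 30), simplify = FALSE)
  tab2 <- table_from_dwells(list(a = dwells), 30, sch)
  d2 <- cumulative_dwell_distribution(tab2, "a")
  expect_true(all(diff(d2$value) <= 0))

  expect_error(cumulative_dwell_distribution(tab, "nope"), "not present")
})

test_that("specific binding frequency is the intercept difference", {
  sch <- plain_schedule(2400)
  tab <- table_from_dwells(
    list(
      rna = replicate(50, NULL, simplify = FALSE),
      no_RNA = replicate(50, NULL, simplify = FALSE)
    ),
    n_locations = 50, schedule = sch
  )
  # install counts directly: 45 events on RNA (0.90/loc), 5 on controls (0.10)
  set.seed(15)
  tab <- table_from_dwells(
    list(
      rna = lapply(1:50, function(i) if (i <= 45) 10 else NULL),
      no_RNA = lapply(1:50, function(i) if (i <= 5) 10 else NULL)
    ),
    n_locations = 50, schedule = sch
  )
  d_rna <- cumulative_dwell_distribution(tab, "rna")
  d_ctl <- cumulative_dwell_distribution(tab, "no_RNA")
  fr <- specific_binding_frequency(d_rna, d_ctl, B = 200, seed = 1)
  expect_equal(fr$f_specific, 0.80)
  fr_s <- specific_binding_frequency(d_rna, d_ctl, per_second = TRUE, B = 200, seed = 1)
  expect_equal(fr_s$f_specific, 0.80 / 2400, tolerance = 1e-12)

  # identical distributions: zero
  fr0 <- specific_binding_frequency(d_rna, d_rna, B = 200, seed = 1)
  expect_equal(fr0$f_specific, 0)

  d_bad <- cumulative_dwell_distribution(tab, "no_RNA", grid = c(0, 1))
  expect_error(specific_binding_frequency(d_rna, d_bad), "grid")
})

test_that("duration classes partition the total frequency", {
  sch <- acquisition_schedule()
  tab <- table_from_dwells(
    list(
      "5i3" = list(c(10), c(60, 60)),
      "no_RNA" = list()
    ),
    n_locations = 50, schedule = sch
  )
  cl <- frequency_by_duration_class(tab, "5i3", threshold = 50, B = 200, seed = 2)
  expect_equal(cl$short$f_specific, 0.02)
  expect_equal(cl$long$f_specific, 0.04)

  # all dwells short: long class empty
  tab2 <- table_from_dwells(list(a = list(c(10, 10)), no_RNA = list()), 10, sch)
  cl2 <- frequency_by_duration_class(tab2, "a", B = 200, seed = 2)
  expect_equal(cl2$long$f_specific, 0)

  # classes sum to the all-events frequency on random tables
  set.seed(16)
  dwells <- replicate(20, rexp(rpois(1, 4), 1 / 40), simplify = FALSE)
  ctl <- replicate(20, rexp(rpois(1, 1), 1 / 5), simplify = FALSE)
  tab3 <- table_from_dwells(list(a = dwells, no_RNA = ctl), 20, sch)
  cl3 <- frequency_by_duration_class(tab3, "a", B = 100, seed = 3)
  fr3 <- specific_binding_frequency(
    cumulative_dwell_distribution(tab3, "a"),
    cumulative_dwell_distribution(tab3, "no_RNA"),
    B = 100, seed = 3
  )
  expect_equal(cl3$short$f_specific + cl3$long$f_specific, fr3$f_specific)
})

test_that("the specific-occupancy formula matches hand arithmetic", {
  expect_equal(specific_occupancy(0.5, 0.2), 0.375)
  expect_equal(specific_occupancy(0.3, 0.3), 0) # background-only
  expect_equal(specific_occupancy(0.42, 0), 0.42) # no background
  expect_error(specific_occupancy(0.5, 1), "f_c = 1")
})

test_that("occupancy from a table averages bound fractions over locations", {
  # one RNA location bound for the whole observation: occupancy 1
  sch <- plain_schedule(100)
  iv <- tibble::tibble(
    location_id = "r1", start_s = 0, end_s = 100, dwell_s = 100,
    left_censored = TRUE, right_censored = TRUE, label = "U2", construct = "rna"
  )
  locs <- tibble::tibble(
    location_id = c("r1", "c1", "c2"),
    construct = c("rna", "no_RNA", "no_RNA"),
    n_frames_observed = 100L
  )
  tab <- intervals_table(iv, locs, sch)
  expect_warning(
    occ <- occupancy_from_table(tab, "rna", B = 50, seed = 1),
    "fewer than 2"
  )
  expect_equal(occ$specific_occupancy, 1)

  # all-empty table: occupancy 0
  tab0 <- intervals_table(iv[0, ], locs, sch)
  occ0 <- suppressWarnings(occupancy_from_table(tab0, "rna", B = 50, seed = 1))
  expect_equal(occ0$specific_occupancy, 0)
})

test_that("occupancy estimator matches the renewal-theory prediction", {
  # occupancy ~ labeling * k*tau / (1 + k*tau) for a single-exponential dwell
  sch <- acquisition_schedule()
  k <- 5e-3
  tau <- 30
  lf <- 0.5
  p <- kinetic_params("U2",
    k_assoc_specific = k,
    dwell_mixture = data.frame(weight = 1, mean_s = tau),
    k_assoc_nonspecific = 0, labeling_fraction = lf,
    bleach_rate = 0, frac_active = 1
  )
  ests <- vapply(1:50, function(r) {
    lay <- single_construct_layout(40, 5, seed = 600 + r)
    panel <- simulate_panel(lay, p, sch, seed = 600 + r)
    tab <- panel_intervals(panel)
    occupancy_from_table(tab, "5i3", B = 50, seed = r)$specific_occupancy
  }, numeric(1))
  pred <- lf * k * tau / (1 + k * tau)
  sem <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - pred), 3 * sem + 0.005)
})

test_that("occupancy is invariant to location relabeling and interval order", {
  sch <- acquisition_schedule()
  set.seed(17)
  dwells <- replicate(20, rexp(rpois(1, 3), 1 / 40), simplify = FALSE)
  ctl <- replicate(20, rexp(rpois(1, 1), 1 / 4), simplify = FALSE)
  tab <- table_from_dwells(list(a = dwells, no_RNA = ctl), 20, sch)
  occ1 <- occupancy_from_table(tab, "a", B = 100, seed = 5)

  shuf <- tab
  perm <- sample(nrow(shuf$intervals))
  shuf$intervals <- shuf$intervals[perm, ]
  relabel <- function(x) sub("^a_", "zz_", x)
  shuf$intervals$location_id <- relabel(shuf$intervals$location_id)
  shuf$locations$location_id <- relabel(shuf$locations$location_id)
  shuf$locations <- shuf$locations[sample(nrow(shuf$locations)), ]
  tab2 <- intervals_table(shuf$intervals, shuf$locations, sch)
  occ2 <- occupancy_from_table(tab2, "a", B = 100, seed = 5)
  expect_equal(occ2$f_m, occ1$f_m)
  expect_equal(occ2$specific_occupancy, occ1$specific_occupancy)
})

test_that("bootstrap SE is deterministic and matches closed forms", {
  x <- rep(2.5, 30)
  expect_equal(bootstrap_se(x, B = 200, seed = 1)$se, 0) # identical locations

  set.seed(18)
  y <- rnorm(100)
  b1 <- bootstrap_se(y, B = 2000, seed = 7)
  b2 <- bootstrap_se(y, B = 2000, seed = 7)
  expect_identical(b1$se, b2$se)
  expect_lt(abs(b1$se - 1 / sqrt(100)) / (1 / sqrt(100)), 0.2)

  expect_error(bootstrap_se(3, B = 10, seed = 1), "at least 2")
})

test_that("table bootstrap resamples locations, not intervals", {
  sch <- acquisition_schedule()
  set.seed(19)
  dwells <- replicate(25, rexp(rpois(1, 2), 1 / 30), simplify = FALSE)
  tab <- table_from_dwells(list(a = dwells), 25, sch)
  stat <- function(t) nrow(t$intervals) / nrow(t$locations)
  b <- bootstrap_se(tab, statistic = stat, B = 300, seed = 3)
  expect_equal(b$estimate, stat(tab))
  # resampled tables keep the location count fixed
  expect_true(all(is.finite(b$samples)))
  direct <- bootstrap_se(
    as.numeric(cumulative_dwell_distribution(tab, "a")$counts),
    B = 300, seed = 3
  )
  expect_lt(abs(b$se - direct$se) / direct$se, 0.3)
})

test_that("first-binding times flag never-bound locations as censored", {
  sch <- acquisition_schedule()
  tab <- table_from_dwells(
    list(a = list(c(10, 20), NULL, c(5))),
    n_locations = 5, schedule = sch
  )
  fb <- first_binding_times(tab, "a")
  expect_equal(nrow(fb), 5L)
  expect_equal(sum(!fb$observed), 5L - 2L)
  expect_true(all(fb$time_s[!fb$observed] == 2400))
  expect_equal(fb$time_s[fb$location_id == "a_001"], 0)
})

test_that("first-binding fit recovers a known exponential rate", {
  set.seed(20)
  k <- 0.01
  t_end <- 2400
  raw <- rexp(500, k)
  fb <- tibble::tibble(
    location_id = sprintf("l%03d", 1:500),
    time_s = pmin(raw, t_end),
    observed = raw < t_end
  )
  fit <- fit_first_binding(fb)
  expect_true(fit$converged)
  expect_lt(abs(fit$k_f - k), 3 * fit$k_f_se + 1e-4)
  expect_gt(fit$A_f, 0.9)

  # cross-check the pure-exponential rate against survreg
  if (requireNamespace("survival", quietly = TRUE)) {
    sv <- survival::survreg(
      survival::Surv(fb$time_s, fb$observed) ~ 1,
      dist = "exponential"
    )
    expect_equal(fit$k_f, exp(-unname(coef(sv))), tolerance = 0.1)
  }
})

test_that("background events leave the specific first-binding rate unbiased", {
  set.seed(21)
  k_f <- 2e-3
  k_bg <- 5e-4
  t_end <- 2400
  errs <- vapply(1:50, function(r) {
    first_spec <- rexp(100, k_f)
    first_bg <- rexp(100, k_bg)
    t_rna <- pmin(first_spec, first_bg)
    ctrl <- rexp(100, k_bg)
    fit <- fit_first_binding(
      tibble::tibble(
        location_id = as.character(1:100),
        time_s = pmin(t_rna, t_end), observed = t_rna < t_end
      ),
      control = tibble::tibble(
        location_id = as.character(1:100),
        time_s = pmin(ctrl, t_end), observed = ctrl < t_end
      )
    )
    (fit$k_f - k_f) / ifelse(is.na(fit$k_f_se) || fit$k_f_se == 0, 1, fit$k_f_se)
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 3), 0.9)

  # degenerate data: all censored
  expect_warning(
    fit0 <- fit_first_binding(tibble::tibble(
      location_id = as.character(1:20), time_s = rep(2400, 20),
      observed = rep(FALSE, 20)
    )),
    "amplitude"
  )
  expect_equal(fit0$A_f, 0)
})

test_that("synergy ratio arithmetic and additivity null behave as defined", {
  sch <- plain_schedule(2400)
  tab <- table_from_dwells(
    list(
      "5i3e5" = lapply(1:10, function(i) if (i <= 4) 10 else NULL),
      "5i3eX" = lapply(1:10, function(i) if (i <= 1) 10 else NULL),
      "Xi3e5" = lapply(1:10, function(i) if (i <= 1) 10 else NULL),
      no_RNA = list()
    ),
    n_locations = 10, schedule = sch
  )
  sr <- synergy_ratio(tab, B = 200, seed = 1)
  expect_equal(sr$R, 0.4 / 0.2) # f = (0.4, 0.1, 0.1) -> R = 2

  # f_both = f_up + f_down: R = 1 exactly
  tab2 <- table_from_dwells(
    list(
      "5i3e5" = lapply(1:10, function(i) if (i <= 2) 10 else NULL),
      "5i3eX" = lapply(1:10, function(i) if (i <= 1) 10 else NULL),
      "Xi3e5" = lapply(1:10, function(i) if (i <= 1) 10 else NULL),
      no_RNA = list()
    ),
    n_locations = 10, schedule = sch
  )
  expect_equal(synergy_ratio(tab2, B = 200, seed = 1)$R, 1)

  # non-positive denominator: undefined
  tab3 <- table_from_dwells(
    list(
      "5i3e5" = list(c(10)), "5i3eX" = list(), "Xi3e5" = list(),
      no_RNA = list()
    ),
    n_locations = 10, schedule = sch
  )
  expect_error(synergy_ratio(tab3, B = 100, seed = 1), "denominator|undefined|<= 0")
})

test_that("intron retention conditions on exon-dye survival", {
  sch <- acquisition_schedule()
  tl <- tibble::tibble(
    molecule_id = sprintf("m%02d", 1:13),
    exon_loss_s = c(rep(Inf, 10), 100, 500, 1200), # 3 molecules excluded
    intron_lost_s = c(rep(Inf, 8), 900, 1500, Inf, Inf, 200)
  )
  curve <- intron_retention_curve(tl, sch, times = c(0, 1000, 2400))
  expect_equal(attr(curve, "n_conditioned"), 10L)
  expect_equal(curve$fraction_remaining[1], 1)
  expect_equal(curve$fraction_remaining[3], 0.8) # 2 of 10 lost by the end
  expect_true(all(diff(curve$fraction_remaining) <= 0))

  # no losses: curve identically 1
  tl2 <- tibble::tibble(exon_loss_s = rep(Inf, 5), intron_lost_s = rep(Inf, 5))
  c2 <- intron_retention_curve(tl2, sch)
  expect_true(all(c2$fraction_remaining == 1))

  tl3 <- tibble::tibble(exon_loss_s = 10, intron_lost_s = Inf)
  expect_error(intron_retention_curve(tl3, sch), "exon")
})

test_that("rastergrams sort latest-first with never-bound rows on top", {
  sch <- acquisition_schedule()
  set.seed(22)
  dwells <- c(
    lapply(1:20, function(i) c(5)), # bound
    replicate(30, NULL, simplify = FALSE) # never bound
  )
  tab <- table_from_dwells(list(a = sample(dwells)), 50, sch)
  ras <- build_rastergram(tab, "a")
  expect_equal(ras$percent_bound, 40)
  expect_equal(ras$percent_bound_se, 100 * sqrt(0.4 * 0.6 / 50), tolerance = 1e-9)
  never <- !ras$rows$observed
  expect_true(all(which(never) < min(which(!never)))) # never-bound block first
  bound_times <- ras$rows$time_s[!never]
  expect_true(all(diff(bound_times) <= 0)) # latest to earliest

  # row order is invariant under input shuffling (ties broken by id)
  shuf <- tab
  shuf$intervals <- shuf$intervals[sample(nrow(shuf$intervals)), ]
  shuf$locations <- shuf$locations[sample(nrow(shuf$locations)), ]
  tabs <- intervals_table(shuf$intervals, shuf$locations, sch)
  ras2 <- build_rastergram(tabs, "a")
  expect_identical(ras2$rows$location_id, ras$rows$location_id)
})

test_that("frequency/occupancy ratio is invariant to labeling fraction", {
  sch <- acquisition_schedule()
  ratio_at <- function(lf, seeds) {
    p <- kinetic_params("U2",
      k_assoc_specific = 3e-3, labeling_fraction = lf,
      k_assoc_nonspecific = 0, bleach_rate = 0, frac_active = 1
    )
    vals <- vapply(seeds, function(s) {
      lay <- single_construct_layout(40, 5, seed = s)
      panel <- simulate_panel(lay, p, sch, seed = s)
      tab <- panel_intervals(panel)
      fr <- specific_binding_frequency(
        cumulative_dwell_distribution(tab, "5i3"),
        cumulative_dwell_distribution(tab, "no_RNA"),
        per_second = TRUE, B = 50, seed = s
      )
      occ <- occupancy_from_table(tab, "5i3", B = 50, seed = s)
      fr$f_specific / occ$specific_occupancy
    }, numeric(1))
    mean(vals)
  }
  r_low <- ratio_at(0.3, 700 + 1:12)
  r_high <- ratio_at(0.6, 800 + 1:12)
  expect_lt(abs(r_high / r_low - 1), 0.25)
})
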