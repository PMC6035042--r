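test_that("slide layouts are deterministic and respect density bounds", {
  lay1 <- build_slide_layout(panel_cross_intron_exon(),
    counts = c(50, 50),
    n_controls = 50, seed = 7
  )
  lay2 <- build_slide_layout(panel_cross_intron_exon(),
    counts = c(50, 50),
    n_controls = 50, seed = 7
  )
  expect_equal(nrow(lay1), 150L)
  expect_false(anyDuplicated(lay1$location_id) > 0)
  expect_identical(lay1$x_um, lay2$x_um)
  expect_identical(lay1$y_um, lay2$y_um)

  # 10,000 spots on 100x100 um is density 1.0, above the 0.5 upper bound
  expect_error(
    build_slide_layout(panel_cross_intron_exon(),
      counts = c(5000, 5000),
      seed = 1
    ),
    "density"
  )

  # density-driven sizing: 0.3 spots/um^2 on 100x100 um -> 3,000 locations
  lay3 <- build_slide_layout(list(construct_spec("a", upstream_5ss = TRUE)),
    density = 0.3, n_controls = 0, seed = 2
  )
  expect_equal(nrow(lay3), 3000L)

  # minimum separation holds between all pairs
  d <- as.matrix(dist(cbind(lay1$x_um, lay1$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), 0.5)
})

test_that("zero association rates produce empty timelines and zero statistics", {
  sch <- acquisition_schedule()
  p0 <- kinetic_params("U2",
    k_assoc_specific = 0, k_assoc_nonspecific = 0,
    frac_active = 1
  )
  cs <- panel_cross_intron_exon()[["5i3"]]
  tl <- simulate_location_timeline(cs, p0, sch, seed = 1)
  expect_equal(nrow(tl), 0L)

  lay <- single_construct_layout(10, 10, seed = 3)
  panel <- simulate_panel(lay, p0, sch, seed = 3)
  expect_equal(nrow(panel$truth), 0L)
  tab <- panel_intervals(panel)
  d <- cumulative_dwell_distribution(tab, "5i3")
  expect_true(all(d$value == 0))
  expect_equal(occupancy_from_table(tab, "5i3", B = 50, seed = 1)$specific_occupancy, 0)
})

test_that("labeling_fraction 0 marks every event unlabeled and invisible", {
  sch <- acquisition_schedule()
  p <- bare_params(k = 0.01)
  p$labeling_fraction <- 0
  cs <- panel_cross_intron_exon()[["5i3"]]
  tl <- simulate_location_timeline(cs, p, sch, seed = 5)
  expect_gt(nrow(tl), 0)
  expect_true(all(!tl$labeled))
  expect_true(all(is.na(tl$visible_until_s)))
  tr <- discretize_timeline(tl, sch)
  expect_true(all(!tr$present, na.rm = TRUE))
})

test_that("event counts match the renewal-theory expectation", {
  # k = 0.01/s association, 20 s mean dwell: one binding cycle averages
  # 100 + 20 = 120 s, so ~20 events are expected in 2,400 s.
  sch <- acquisition_schedule()
  p <- bare_params(k = 0.01, mean_dwell = 20)
  cs <- panel_cross_intron_exon()[["5i3"]]
  n_rep <- 400
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(simulate_location_timeline(cs, p, sch, seed = 10000 + i))
  }, numeric(1))
  sem <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 2400 / 120), 3 * sem + 0.2)
})

test_that("discretization follows the half-frame-overlap rule", {
  sch <- plain_schedule(20)
  # event spanning 10.0-13.0 s covers frames 11-13 (1-based) fully
  tr <- discretize_timeline(timeline_of(list(c(10, 13))), sch)
  expect_identical(which(tr$present), 11:13)

  # 0.4 s sliver in one frame: below half-frame overlap, invisible
  tr2 <- discretize_timeline(timeline_of(list(c(5.1, 5.5))), sch)
  expect_true(all(!tr2$present))

  # an event confined to a red-interleave frame yields no present frames
  sch_red <- acquisition_schedule(1, 4, 1, 10)
  tr3 <- discretize_timeline(timeline_of(list(c(4.1, 4.9))), sch_red)
  expect_true(all(!tr3$present, na.rm = TRUE))

  # empty timeline: all-absent, red frames flagged missing
  tr4 <- discretize_timeline(timeline_of(list()), sch_red)
  expect_true(all(!tr4$present, na.rm = TRUE))
  expect_identical(which(is.na(tr4$present)), c(5L, 10L))
})

test_that("simulated dwell times converge to the configured mixture", {
  sch <- acquisition_schedule()
  p <- kinetic_params("U2",
    k_assoc_specific = 0.02,
    dwell_mixture = data.frame(weight = c(0.7, 0.3), mean_s = c(5, 60)),
    k_assoc_nonspecific = 0, labeling_fraction = 1,
    bleach_rate = 0, frac_active = 1
  )
  lay <- single_construct_layout(60, 2, seed = 9)
  panel <- simulate_panel(lay, p, sch, seed = 9)
  dw <- panel$truth[panel$truth$specific & panel$truth$departure_s < 2400, ]
  dwell <- dw$departure_s - dw$arrival_s
  expect_gt(length(dwell), 300)
  mix_cdf <- function(q) 1 - (0.7 * exp(-q / 5) + 0.3 * exp(-q / 60))
  ks <- suppressWarnings(stats::ks.test(dwell, mix_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("visible event count scales linearly with labeling fraction", {
  sch <- acquisition_schedule()
  cs <- panel_cross_intron_exon()[["5i3"]]
  visible_events <- function(lf, seeds) {
    p <- bare_params(k = 0.01)
    p$labeling_fraction <- lf
    sum(vapply(seeds, function(s) {
      tl <- simulate_location_timeline(cs, p, sch, seed = s)
      sum(tl$labeled)
    }, numeric(1)))
  }
  n1 <- visible_events(0.25, 1:150)
  n2 <- visible_events(0.50, 151:300)
  expect_gt(n1, 500)
  expect_lt(abs(n2 / n1 - 2), 0.25)
})

test_that("no-RNA locations behave identically regardless of the RNA panel", {
  sch <- acquisition_schedule()
  ctrl_counts <- function(constructs, seeds) {
    unlist(lapply(seeds, function(s) {
      lay <- build_slide_layout(constructs,
        counts = rep(5, length(constructs)),
        n_controls = 10, seed = s
      )
      p <- kinetic_params("U2", k_assoc_nonspecific = 5e-4)
      panel <- simulate_panel(lay, p, sch, seed = s)
      tab <- panel_intervals(panel)
      cumulative_dwell_distribution(tab, "no_RNA")$counts
    }))
  }
  a <- ctrl_counts(panel_cross_intron_exon(), 1:20)
  b <- ctrl_counts(panel_double_5ss(), 101:120)
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
})

test_that("panel simulation is deterministic and controls stay nonspecific", {
  sch <- acquisition_schedule()
  lay <- single_construct_layout(10, 10, seed = 4)
  p <- kinetic_params("U2")
  p1 <- simulate_panel(lay, p, sch, seed = 21)
  p2 <- simulate_panel(lay, p, sch, seed = 21)
  expect_identical(p1$presence, p2$presence)
  expect_equal(p1$truth, p2$truth)
  ctrl <- p1$truth[grepl("^no_RNA", p1$truth$location_id), ]
  expect_true(all(!ctrl$specific))
})

test_that("U2 event counts rank with functional 5'SS content", {
  sch <- acquisition_schedule()
  lay <- build_slide_layout(panel_double_5ss(),
    counts = rep(60, 4),
    n_controls = 60, seed = 31
  )
  p <- kinetic_params("U2",
    k_assoc_specific = 2e-3, synergy_factor = 3,
    labeling_fraction = 1, frac_active = 1
  )
  panel <- simulate_panel(lay, p, sch, seed = 31)
  counts <- table(factor(panel$truth$construct[panel$truth$specific],
    levels = c("5i3e5", "5i3eX", "Xi3e5", "Xi3eX")
  ))
  expect_gt(counts[["5i3e5"]], counts[["5i3eX"]])
  expect_gt(counts[["5i3e5"]], counts[["Xi3e5"]])
  expect_equal(counts[["Xi3eX"]], 0L) # no 5'SS: specific binding impossible
})

test_that("intron-loss fractions follow the closed-form survival model", {
  sch <- acquisition_schedule()
  # lag 600 s then rate 1/600: P(lost by 2,400) = 1 - exp(-1800/600) = 0.950
  tl <- simulate_intron_loss_panel(10000,
    lag_s = 600, loss_rate = 1 / 600,
    intron_bleach_rate = 0, exon_loss_rate = 0,
    atp = TRUE, schedule = sch, seed = 8
  )
  frac_lost <- mean(tl$intron_lost_s <= 2400)
  expect_lt(abs(frac_lost - (1 - exp(-1800 / 600))), 3 * sqrt(0.95 * 0.05 / 10000))

  # no ATP: only bleaching can remove the intron dye (~1% by design default)
  tl0 <- simulate_intron_loss_panel(10000,
    atp = FALSE, intron_bleach_rate = 4.6e-6,
    exon_loss_rate = 0, schedule = sch, seed = 9
  )
  expect_lt(abs(mean(tl0$intron_lost_s <= 2400) - (1 - exp(-4.6e-6 * 2400))), 0.005)

  # zero rate and infinite lag: nothing is ever lost
  tl1 <- simulate_intron_loss_panel(100,
    loss_rate = 0, intron_bleach_rate = 0,
    exon_loss_rate = 0, schedule = sch, seed = 10
  )
  expect_true(all(is.infinite(tl1$intron_lost_s)))
})
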