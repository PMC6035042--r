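test_that("sliding average reproduces hand-computed values", {
  tr <- intensity_trace(rep(3.5, 21))
  out <- sliding_average(tr, 5)
  expect_equal(out$value, rep(3.5, 21)) # constant in, constant out

  imp <- intensity_trace(c(rep(0, 10), 1, rep(0, 10)))
  out <- sliding_average(imp, 5)
  expect_equal(out$value[9:13], rep(0.2, 5))
  expect_equal(out$value[c(8, 14)], c(0, 0))

  expect_identical(sliding_average(imp, 1), imp)
  expect_error(sliding_average(imp, 4), "odd")
  expect_error(sliding_average(intensity_trace(1:3), 5), "larger than trace")
})

test_that("sliding average is linear and skips missing frames", {
  set.seed(11)
  sch <- acquisition_schedule(1, 10, 1, 44)
  a <- intensity_trace(rnorm(44), sch)
  b <- intensity_trace(rnorm(44), sch)
  lin <- intensity_trace(2 * a$value - 3 * b$value, sch)
  lhs <- sliding_average(lin, 5)$value
  rhs <- 2 * sliding_average(a, 5)$value - 3 * sliding_average(b, 5)$value
  expect_equal(lhs, rhs)
  expect_identical(sliding_average(a, 5)$missing, a$missing)
})

test_that("hysteresis thresholding follows the two-level rule", {
  below <- intensity_trace(c(10, 20, 5, 0, 15))
  expect_true(all(!threshold_trace(below, 500, 400)$present))

  clean <- intensity_trace(c(0, 1000, 1000, 0, 1000, 0))
  expect_identical(
    threshold_trace(clean, 500, 500)$present,
    c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  )

  # flicker to 450 stays on with off-level 400 (single on-period of 3 frames)
  flick <- intensity_trace(c(0, 600, 450, 600, 0))
  expect_identical(
    threshold_trace(flick, 500, 400)$present,
    c(FALSE, TRUE, TRUE, TRUE, FALSE)
  )

  expect_error(threshold_trace(clean, 400, 500))
})

test_that("interval extraction sets dwells and censor flags correctly", {
  sch <- plain_schedule(6)
  iv <- extract_intervals(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE), sch)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$dwell_s, 3)
  expect_equal(iv$start_s, 1)
  expect_equal(iv$end_s, 4)
  expect_false(iv$left_censored)
  expect_false(iv$right_censored)

  # presence through the final frame is right-censored
  iv2 <- extract_intervals(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE), sch)
  expect_true(iv2$right_censored)
  expect_false(iv2$left_censored)
  iv3 <- extract_intervals(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), sch)
  expect_true(iv3$left_censored)

  expect_equal(nrow(extract_intervals(rep(FALSE, 6), sch)), 0L)
})

test_that("runs separated only by red-interleave gaps are merged", {
  # 99 green + 1 red per cycle: frame 100 is red
  sch <- acquisition_schedule(1, 99, 1, 200)
  present <- rep(FALSE, 200)
  present[c(98, 99, 101, 102)] <- TRUE
  present[is_red_frame(sch)] <- NA
  iv <- extract_intervals(present, sch)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$dwell_s, 5)
  expect_equal(iv$start_s, 97)
  expect_equal(iv$end_s, 102)
})

test_that("threshold + extraction recovers simulated ground truth exactly", {
  # last frame green so both routes agree on right-censoring at the boundary
  sch <- acquisition_schedule(1, 100, 1, 301)
  p <- kinetic_params("U2",
    k_assoc_specific = 0.01, k_assoc_nonspecific = 1e-3,
    labeling_fraction = 0.8, frac_active = 1
  )
  for (rep in 1:20) {
    lay <- single_construct_layout(8, 2, seed = 400 + rep)
    panel <- simulate_panel(lay, p, sch, seed = 400 + rep)
    for (i in seq_len(nrow(panel$presence))) {
      id <- rownames(panel$presence)[i]
      truth_presence <- oracle_presence(panel$truth, id, sch)
      expect_identical(panel$presence[i, ], truth_presence)

      # noiseless two-level intensity trace -> hysteresis -> same intervals
      vals <- ifelse(is.na(panel$presence[i, ]), 0, panel$presence[i, ] * 1000)
      tr <- intensity_trace(vals, sch, location_id = id)
      direct <- extract_intervals(panel$presence[i, ], sch, location_id = id)
      via_threshold <- extract_intervals(threshold_trace(tr, 500, 500))
      expect_equal(via_threshold[names(direct)], direct)
    }
  }
})

test_that("right-censored intervals never outnumber locations", {
  sch <- acquisition_schedule()
  lay <- single_construct_layout(30, 10, seed = 77)
  panel <- simulate_panel(lay, kinetic_params("U1"), sch, seed = 77)
  tab <- panel_intervals(panel)
  expect_lte(sum(tab$intervals$right_censored), nrow(tab$locations))
})

test_that("CSV interval tables round-trip losslessly", {
  sch <- acquisition_schedule()
  set.seed(12)
  dwells <- replicate(40, sample(1:30, sample(0:4, 1)), simplify = FALSE)
  tab <- table_from_dwells(list("5i3" = dwells, "no_RNA" = dwells[1:10]),
    n_locations = 40, schedule = sch
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(tab, path)
  tab2 <- read_intervals(path)
  expect_equal(tab2$intervals, tab$intervals)
  expect_equal(tab2$locations, tab$locations)
  expect_equal(unclass(tab2$schedule), unclass(tab$schedule))
})

test_that("empty tables and malformed files are handled explicitly", {
  sch <- acquisition_schedule()
  empty <- intervals_table(
    tibble::tibble(
      location_id = character(), start_s = numeric(), end_s = numeric(),
      dwell_s = numeric(), left_censored = logical(),
      right_censored = logical(), label = character(), construct = character()
    ),
    tibble::tibble(
      location_id = "a", construct = "no_RNA",
      n_frames_observed = 100L
    ),
    sch
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(empty, path)
  back <- read_intervals(path)
  expect_equal(nrow(back$intervals), 0L)
  expect_equal(nrow(back$locations), 1L)

  # corrupt an interval so end < start: the parser names the line
  lines <- readLines(path)
  lines <- c(lines, "interval,a,no_RNA,50,10,FALSE,FALSE,U2,")
  writeLines(lines, path)
  expect_error(read_intervals(path), "line 5")
})

test_that("MAT containers written by the package round-trip exactly", {
  sch <- acquisition_schedule()
  set.seed(13)
  dwells <- replicate(15, sample(1:40, sample(0:3, 1)), simplify = FALSE)
  tab <- table_from_dwells(list("5i3e5" = dwells, "no_RNA" = dwells[1:5]),
    n_locations = 15, schedule = sch
  )
  path <- withr::local_tempfile(fileext = ".mat")
  write_imscroll_intervals(tab, path)
  tab2 <- read_imscroll_intervals(path)
  expect_equal(tab2$intervals, tab$intervals)
  expect_equal(tab2$locations, tab$locations)
  expect_equal(unclass(tab2$schedule), unclass(tab$schedule))
})

test_that("empty and unreadable MAT containers behave as documented", {
  path <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(), path)
  tab <- read_imscroll_intervals(path)
  expect_equal(nrow(tab$intervals), 0L)
  expect_equal(nrow(tab$locations), 0L)

  bad <- withr::local_tempfile(fileext = ".mat")
  writeBin(as.raw(sample(0:255, 400, replace = TRUE)), bad)
  expect_error(read_imscroll_intervals(bad), "unsupported format")
})

test_that("foreign interval layouts are mapped heuristically with a warning", {
  path <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(
    IntervalList = cbind(
      aoi = c(1, 1, 2),
      start = c(2, 8, 1),
      stop = c(5, 9, 4)
    ),
    AOIClassNames = c("rna", "rna")
  ), path)
  expect_warning(tab <- read_imscroll_intervals(path), "heuristically")
  expect_equal(nrow(tab$intervals), 3L)
  expect_equal(nrow(tab$locations), 2L)
  expect_equal(tab$intervals$start_s, c(1, 7, 0))
})
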