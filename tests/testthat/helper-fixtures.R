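# Shared fixture builders. Everything is generated in code at test time.

# A plain schedule with n one-second green frames and no red interleave.
plain_schedule <- function(n) {
  acquisition_schedule(
    frame_duration = 1, green_block_length = n,
    red_interleave_length = 0, total_duration = n
  )
}

# Hand-build an intervals table from dwells: `dwells` is a named list
# (construct -> list of per-location dwell vectors); every construct gets
# `n_locations` locations (trailing ones event-free). Intervals are laid
# head-to-tail with 1 s gaps from t = 0.
table_from_dwells <- function(dwells, n_locations, schedule) {
  iv <- list()
  locs <- list()
  for (cs in names(dwells)) {
    per_loc <- dwells[[cs]]
    ids <- sprintf("%s_%03d", cs, seq_len(n_locations))
    locs[[cs]] <- tibble::tibble(
      location_id = ids, construct = cs,
      n_frames_observed = schedule$n_frames - sum(is_red_frame(schedule))
    )
    for (i in seq_along(per_loc)) {
      d <- per_loc[[i]]
      if (length(d) == 0) next
      starts <- cumsum(c(0, head(d, -1) + 1))
      iv[[paste(cs, i)]] <- tibble::tibble(
        location_id = ids[i],
        start_s = starts, end_s = starts + d, dwell_s = d,
        left_censored = FALSE, right_censored = FALSE,
        label = "U2", construct = cs
      )
    }
  }
  intervals_table(
    dplyr::bind_rows(iv), dplyr::bind_rows(locs), schedule
  )
}

# Minimal hand-made ground-truth timeline for discretization tests.
timeline_of <- function(events, location_id = "loc") {
  tl <- tibble::tibble(
    arrival_s = vapply(events, `[[`, numeric(1), 1),
    departure_s = vapply(events, `[[`, numeric(1), 2),
    labeled = TRUE,
    specific = TRUE,
    bleached_at_s = NA_real_,
    visible_until_s = vapply(events, `[[`, numeric(1), 2)
  )
  attr(tl, "location_id") <- location_id
  class(tl) <- c("true_timeline", class(tl))
  tl
}

# Kinetic parameters with every stochastic complication switched off except
# what a test turns back on.
bare_params <- function(k = 0.01, mean_dwell = 20, ...) {
  kinetic_params("U2",
    k_assoc_specific = k,
    dwell_mixture = data.frame(weight = 1, mean_s = mean_dwell),
    k_assoc_nonspecific = 0,
    labeling_fraction = 1,
    bleach_rate = 0,
    frac_active = 1,
    ...
  )
}

single_construct_layout <- function(n_rna = 50, n_ctrl = 50, seed = 1,
                                    name = "5i3") {
  cs <- construct_spec(name,
    upstream_5ss = TRUE, downstream_5ss = FALSE,
    bs_3ss = TRUE, spliceable = TRUE
  )
  build_slide_layout(list(cs),
    counts = n_rna, n_controls = n_ctrl,
    seed = seed
  )
}

# Independent frame-level rediscretization of a panel's ground truth,
# written without reusing the package's frame helpers: a frame is present
# iff some labeled visible event overlaps >= half of it; red frames NA;
# runs separated only by red frames merge.
oracle_presence <- function(truth, location_id, schedule) {
  n <- schedule$n_frames
  fd <- schedule$frame_duration
  cyc <- schedule$green_block_length + schedule$red_interleave_length
  red <- ((seq_len(n) - 1) %% cyc) >= schedule$green_block_length
  present <- rep(FALSE, n)
  ev <- truth[truth$location_id == location_id & !is.na(truth$visible_until_s), , drop = FALSE]
  for (f in seq_len(n)) {
    lo <- (f - 1) * fd
    hi <- f * fd
    for (j in seq_len(nrow(ev))) {
      ov <- min(ev$visible_until_s[j], hi) - max(ev$arrival_s[j], lo)
      if (ov >= fd / 2) {
        present[f] <- TRUE
        break
      }
    }
  }
  present[red] <- NA
  present
}
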