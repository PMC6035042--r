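#' Simulate the ground-truth binding timeline of one surface location
#'
#' Binding is modeled as the superposition of two independent alternating
#' renewal processes:
#' * *specific* binding at the rate returned by
#'   [resolve_association_rate()] (zero at no-RNA locations and at locations
#'   not competent to bind), with dwell times from the configured exponential
#'   mixture;
#' * *nonspecific* surface binding at `k_assoc_nonspecific` with short
#'   exponential dwells, present at every location.
#'
#' In each process, exponential waiting times separate the departure of one
#' molecule and the arrival of the next (memoryless association; the site is
#' blocked while occupied). Each event is independently dye-labeled with
#' probability `labeling_fraction`; a labeled fluorophore photobleaches after
#' an exponential amount of cumulative green-excitation exposure, truncating
#' its *visible* dwell without ending the underlying binding event.
#'
#' @param construct A [construct_spec()].
#' @param params A [kinetic_params()].
#' @param schedule An [acquisition_schedule()].
#' @param seed Integer seed (optional).
#' @param active Optional logical overriding the Bernoulli(`frac_active`) draw
#'   for specific-binding competence (used by [simulate_panel()] so the draw
#'   is part of the per-location stream).
#'
#' @return A `true_timeline`: tibble with one row per binding event and
#'   columns `arrival_s`, `departure_s`, `labeled`, `specific`,
#'   `bleached_at_s` (NA if the dye survives) and `visible_until_s`
#'   (= min(departure, bleach); NA for unlabeled events).
#' @export
simulate_location_timeline <- function(construct, params, schedule,
                                       seed = NULL, active = NULL) {
  stopifnot(
    inherits(construct, "construct_spec"),
    inherits(params, "kinetic_params"),
    inherits(schedule, "cosmos_schedule")
  )
  if (!is.null(seed)) set.seed(seed)
  if (is.null(active)) active <- stats::runif(1) < params$frac_active

  rate_spec <- if (active) resolve_association_rate(construct, params) else 0

  spec <- renewal_events(
    rate_spec, schedule$total_duration,
    function(n) sample_dwell_mixture(params, n)
  )
  nonspec <- renewal_events(
    params$k_assoc_nonspecific, schedule$total_duration,
    function(n) stats::rexp(n, rate = 1 / params$nonspecific_mean_dwell)
  )
  ev <- rbind(
    cbind(spec, specific = rep(TRUE, nrow(spec))),
    cbind(nonspec, specific = rep(FALSE, nrow(nonspec)))
  )
  ev <- ev[order(ev$arrival_s), , drop = FALSE]
  n <- nrow(ev)

  labeled <- stats::runif(n) < params$labeling_fraction
  bleached_at <- rep(NA_real_, n)
  if (n > 0 && params$bleach_rate > 0) {
    budget <- stats::rexp(n, rate = params$bleach_rate)
    for (i in which(labeled)) {
      b <- green_to_wall(schedule, ev$arrival_s[i], budget[i])
      if (b < ev$departure_s[i]) bleached_at[i] <- b
    }
  }
  visible_until <- ifelse(labeled, pmin(ev$departure_s,
    ifelse(is.na(bleached_at), Inf, bleached_at)
  ), NA_real_)

  out <- tibble::tibble(
    arrival_s = ev$arrival_s,
    departure_s = ev$departure_s,
    labeled = labeled,
    specific = ev$specific,
    bleached_at_s = bleached_at,
    visible_until_s = visible_until
  )
  attr(out, "construct") <- construct$name
  attr(out, "active") <- active
  class(out) <- c("true_timeline", class(out))
  out
}

# Alternating-renewal event generator on [0, total): exponential waits at
# `rate` between departure and next arrival, dwells drawn by `dwell_fun`.
# Departures are censored at `total`.
renewal_events <- function(rate, total, dwell_fun) {
  arrivals <- numeric(0)
  dwells <- numeric(0)
  if (rate > 0) {
    t <- 0
    repeat {
      t <- t + stats::rexp(1, rate)
      if (t >= total) break
      d <- dwell_fun(1L)
      arrivals <- c(arrivals, t)
      dwells <- c(dwells, d)
      t <- t + d
      if (t >= total) break
    }
  }
  data.frame(
    arrival_s = arrivals,
    departure_s = pmin(arrivals + dwells, total)
  )
}

#' Discretize a ground-truth timeline onto the frame schedule
#'
#' A frame is marked *present* iff a labeled, not-yet-bleached event overlaps
#' at least 50% of that frame's exposure window. Red-interleave frames carry
#' no green data and are marked `NA` (missing), never absent.
#'
#' @param timeline A `true_timeline` from [simulate_location_timeline()].
#' @param schedule The [acquisition_schedule()] used to record it.
#' @return A `presence_trace` (see [presence_trace()]): logical vector with
#'   `NA` at red frames.
#' @export
discretize_timeline <- function(timeline, schedule) {
  stopifnot(inherits(schedule, "cosmos_schedule"))
  present <- rep(FALSE, schedule$n_frames)
  vis <- timeline[!is.na(timeline$visible_until_s) &
    timeline$visible_until_s > timeline$arrival_s, , drop = FALSE]
  for (i in seq_len(nrow(vis))) {
    idx <- frames_covered(vis$arrival_s[i], vis$visible_until_s[i], schedule)
    present[idx] <- TRUE
  }
  present[is_red_frame(schedule)] <- NA
  presence_trace(present, schedule,
    location_id = attr(timeline, "location_id") %||% "loc"
  )
}

# Frame indices (1-based) whose exposure window overlaps [a, b) by at least
# half a frame duration.
frames_covered <- function(a, b, schedule) {
  fd <- schedule$frame_duration
  i0 <- max(1L, floor(a / fd) + 1L)
  i1 <- min(schedule$n_frames, ceiling(b / fd))
  if (i1 < i0) {
    return(integer(0))
  }
  idx <- i0:i1
  starts <- (idx - 1) * fd
  overlap <- pmin(b, starts + fd) - pmax(a, starts)
  idx[overlap >= fd / 2]
}

#' Simulate a full slide panel
#'
#' Simulates one binding timeline per location of a [build_slide_layout()]
#' layout and discretizes each onto the frame schedule. Per-location random
#' streams are derived by hashing the master seed with the location id, so
#' results do not depend on iteration order and individual locations can be
#' re-simulated in isolation.
#'
#' @param layout A `slide_layout`.
#' @param params A [kinetic_params()].
#' @param schedule An [acquisition_schedule()].
#' @param seed Master integer seed.
#'
#' @return A `cosmos_panel`: list with `presence` (locations x frames logical
#'   matrix, `NA` at red frames), `layout`, `truth` (ground-truth event table
#'   with per-event visible frame counts), `params`, `schedule`, `seed`.
#' @export
simulate_panel <- function(layout, params, schedule, seed = 1L) {
  stopifnot(inherits(layout, "slide_layout"))
  constructs <- attr(layout, "constructs")
  n_loc <- nrow(layout)
  presence <- matrix(NA, nrow = n_loc, ncol = schedule$n_frames)
  rownames(presence) <- layout$location_id
  truth_list <- vector("list", n_loc)
  active <- logical(n_loc)

  for (i in seq_len(n_loc)) {
    id <- layout$location_id[i]
    cs <- constructs[[layout$construct[i]]]
    tl <- simulate_location_timeline(cs, params, schedule,
      seed = location_seed(seed, id)
    )
    attr(tl, "location_id") <- id
    tr <- discretize_timeline(tl, schedule)
    presence[i, ] <- tr$present
    active[i] <- attr(tl, "active")
    if (nrow(tl) > 0) {
      # visible frames counted on the green schedule only
      red <- is_red_frame(schedule)
      tl$n_visible_frames <- vapply(seq_len(nrow(tl)), function(j) {
        if (is.na(tl$visible_until_s[j])) {
          return(0L)
        }
        idx <- frames_covered(tl$arrival_s[j], tl$visible_until_s[j], schedule)
        sum(!red[idx])
      }, integer(1))
      truth_list[[i]] <- tibble::tibble(
        location_id = id, construct = layout$construct[i], tl
      )
    }
  }
  truth <- dplyr::bind_rows(truth_list)
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(
      location_id = character(), construct = character(),
      arrival_s = numeric(), departure_s = numeric(), labeled = logical(),
      specific = logical(), bleached_at_s = numeric(),
      visible_until_s = numeric(), n_visible_frames = integer()
    )
  }
  structure(
    list(
      presence = presence,
      layout = layout,
      truth = truth,
      active = stats::setNames(active, layout$location_id),
      params = params,
      schedule = schedule,
      seed = seed
    ),
    class = "cosmos_panel"
  )
}

#' @export
print.cosmos_panel <- function(x, ...) {
  cat(sprintf(
    "<cosmos_panel> %d locations x %d frames (%s), %d ground-truth events\n",
    nrow(x$presence), ncol(x$presence), x$params$subcomplex, nrow(x$truth)
  ))
  print(table(x$layout$construct))
  invisible(x)
}

# Deterministic per-location seed: polynomial hash of the location id seeded
# by the master seed, kept strictly below 2^31 (R integers are 32-bit).
location_seed <- function(master_seed, location_id) {
  h <- (as.numeric(master_seed) * 2654435761) %% 2147483647
  for (b in utf8ToInt(location_id)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

#' Simulate an intron-loss (single-molecule splicing) panel
#'
#' Emulates the two-color splicing assay: each tethered pre-mRNA carries an
#' exon dye and an intron dye; intron release by the spliceosome removes the
#' intron dye. Intron loss times are drawn as `lag + Exponential(loss_rate)`
#' when ATP is present (no loss otherwise); intron-dye photobleaching and
#' exon-dye loss (bleaching/degradation) are sampled independently so the
#' retention estimator's conditioning on exon-dye survival can be tested.
#'
#' Defaults emulate a 2,400 s experiment in which roughly 18% of molecules
#' release their intron with ATP versus about 1% apparent loss (bleaching
#' only) without ATP.
#'
#' @param n_molecules Number of molecules.
#' @param lag_s Lag before first-order intron release becomes possible (s).
#' @param loss_rate First-order intron release rate after the lag (1/s).
#' @param intron_bleach_rate Intron-dye photobleaching rate (1/s).
#' @param exon_loss_rate Exon-dye loss rate (bleaching + degradation, 1/s).
#' @param atp Is ATP present (splicing possible)?
#' @param schedule An [acquisition_schedule()] (its `total_duration` bounds
#'   the observation).
#' @param seed Integer seed.
#'
#' @return A `splicing_timelines` tibble with per-molecule loss times
#'   (`Inf` when the event never happens within the observation window is
#'   encoded as a time beyond `total_duration`).
#' @export
simulate_intron_loss_panel <- function(n_molecules,
                                       lag_s = 600,
                                       loss_rate = 1.1e-4,
                                       intron_bleach_rate = 4.6e-6,
                                       exon_loss_rate = 5e-5,
                                       atp = TRUE,
                                       schedule = acquisition_schedule(),
                                       seed = NULL) {
  stopifnot(
    n_molecules >= 1, lag_s >= 0, loss_rate >= 0,
    intron_bleach_rate >= 0, exon_loss_rate >= 0
  )
  if (!is.null(seed)) set.seed(seed)
  n <- n_molecules
  splice <- if (atp && loss_rate > 0) {
    lag_s + stats::rexp(n, loss_rate)
  } else {
    rep(Inf, n)
  }
  ibleach <- if (intron_bleach_rate > 0) stats::rexp(n, intron_bleach_rate) else rep(Inf, n)
  exon <- if (exon_loss_rate > 0) stats::rexp(n, exon_loss_rate) else rep(Inf, n)
  out <- tibble::tibble(
    molecule_id = sprintf("mol_%05d", seq_len(n)),
    atp = atp,
    splice_loss_s = splice,
    intron_bleach_s = ibleach,
    exon_loss_s = exon,
    intron_lost_s = pmin(splice, ibleach)
  )
  attr(out, "schedule") <- schedule
  class(out) <- c("splicing_timelines", class(out))
  out
}
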