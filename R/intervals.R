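#' Extract censor-flagged binding intervals from a presence trace
#'
#' Maximal runs of present frames become intervals. Runs separated *only* by
#' missing frames (red-interleave gaps) are merged into a single interval, so
#' the alternating-excitation schedule never artificially splits a binding
#' event. Intervals are closed on the left and open on the right, in seconds:
#' an interval covering frames `i..j` runs from the start of frame `i` to the
#' end of frame `j`, so `dwell = end - start`.
#'
#' An interval is `right_censored` when it touches the end of the observation
#' (its true dwell exceeds the observed span) and `left_censored` when it
#' touches the start.
#'
#' @param trace A [presence_trace()], or a logical vector (`NA` = missing)
#'   together with `schedule`.
#' @param schedule An [acquisition_schedule()]; taken from the trace when
#'   omitted.
#' @param location_id,label Metadata attached to each interval row.
#' @return Tibble with columns `location_id`, `start_s`, `end_s`, `dwell_s`,
#'   `left_censored`, `right_censored`, `label`.
#' @export
#' @examples
#' sch <- acquisition_schedule(1, 6, 0, 6)
#' tr <- presence_trace(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE), sch)
#' extract_intervals(tr) # one 3 s interval, uncensored
extract_intervals <- function(trace, schedule = NULL, location_id = NULL,
                              label = NA_character_) {
  if (inherits(trace, "presence_trace")) {
    present <- trace$present
    schedule <- schedule %||% trace$schedule
    location_id <- location_id %||% trace$location_id
  } else {
    present <- as.logical(trace)
    if (is.null(schedule)) stop("schedule required for a bare logical vector", call. = FALSE)
    location_id <- location_id %||% "loc"
  }
  stopifnot(inherits(schedule, "cosmos_schedule"), length(present) == schedule$n_frames)
  fd <- schedule$frame_duration
  n <- length(present)

  empty <- tibble::tibble(
    location_id = character(), start_s = numeric(), end_s = numeric(),
    dwell_s = numeric(), left_censored = logical(), right_censored = logical(),
    label = character()
  )
  if (!any(present, na.rm = TRUE)) {
    return(empty)
  }

  # encode frames as 0 = absent, 1 = present, 2 = missing, then merge
  # present-runs separated only by missing-runs
  code <- ifelse(is.na(present), 2L, as.integer(present))
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(code = r$values, start = starts, end = ends)

  iv_start <- integer(0)
  iv_end <- integer(0)
  open_start <- NA_integer_
  open_end <- NA_integer_
  for (k in seq_len(nrow(runs))) {
    v <- runs$code[k]
    if (v == 1L) {
      if (is.na(open_start)) open_start <- runs$start[k]
      open_end <- runs$end[k]
    } else if (v == 0L) {
      if (!is.na(open_start)) {
        iv_start <- c(iv_start, open_start)
        iv_end <- c(iv_end, open_end)
        open_start <- NA_integer_
      }
    }
    # v == 2 (missing): keep the run open (bridge)
  }
  if (!is.na(open_start)) {
    iv_start <- c(iv_start, open_start)
    iv_end <- c(iv_end, open_end)
  }

  # censoring: an interval touches the boundary if only missing frames (or
  # nothing) separate it from the trace edge
  first_obs <- which(code != 2L)[1]
  last_obs <- max(which(code != 2L))
  left_c <- vapply(iv_start, function(s) s <= first_obs, logical(1))
  right_c <- vapply(iv_end, function(e) e >= last_obs, logical(1))

  tibble::tibble(
    location_id = location_id,
    start_s = (iv_start - 1L) * fd,
    end_s = iv_end * fd,
    dwell_s = (iv_end - iv_start + 1L) * fd,
    left_censored = left_c,
    right_censored = right_c,
    label = label
  )
}

#' Assemble an intervals table
#'
#' An `intervals_table` bundles the binding intervals of an experiment with
#' per-location metadata (construct, number of observed green frames) and the
#' acquisition schedule. Every location appears in the metadata even when it
#' produced no intervals, which is essential for unbiased per-location
#' frequencies.
#'
#' @param intervals Tibble of intervals as produced by [extract_intervals()]
#'   (must include a `construct` column or one is joined from `locations`).
#' @param locations Tibble with columns `location_id`, `construct`,
#'   `n_frames_observed`; `observed_s` is derived from the schedule if
#'   absent.
#' @param schedule The [acquisition_schedule()].
#' @return An `intervals_table` object.
#' @export
intervals_table <- function(intervals, locations, schedule) {
  stopifnot(
    inherits(schedule, "cosmos_schedule"),
    all(c("location_id", "construct", "n_frames_observed") %in% names(locations))
  )
  locations <- tibble::as_tibble(locations)
  if (!"observed_s" %in% names(locations)) {
    locations$observed_s <- locations$n_frames_observed * schedule$frame_duration
  }
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) > 0) {
    if (any(intervals$end_s <= intervals$start_s)) {
      stop("intervals must have end_s > start_s", call. = FALSE)
    }
    unknown <- setdiff(intervals$location_id, locations$location_id)
    if (length(unknown)) {
      stop(
        "intervals reference locations missing from metadata: ",
        paste(utils::head(unknown, 5), collapse = ", "),
        call. = FALSE
      )
    }
    if (!"construct" %in% names(intervals)) {
      intervals <- dplyr::left_join(
        intervals,
        locations[, c("location_id", "construct")],
        by = "location_id"
      )
    }
    intervals <- dplyr::arrange(intervals, .data$location_id, .data$start_s)
    # per-location non-overlap
    bad <- intervals |>
      dplyr::group_by(.data$location_id) |>
      dplyr::summarise(
        overlap = any(.data$start_s[-1] < .data$end_s[-dplyr::n()]),
        .groups = "drop"
      )
    if (any(bad$overlap, na.rm = TRUE)) {
      stop("intervals overlap within a location", call. = FALSE)
    }
  } else if (!"construct" %in% names(intervals)) {
    intervals$construct <- character(0)
  }
  structure(
    list(intervals = intervals, locations = locations, schedule = schedule),
    class = "intervals_table"
  )
}

#' @export
print.intervals_table <- function(x, ...) {
  cat(sprintf(
    "<intervals_table> %d intervals over %d locations (%s)\n",
    nrow(x$intervals), nrow(x$locations),
    paste(names(table(x$locations$construct)), collapse = ", ")
  ))
  invisible(x)
}

#' Convert a simulated panel to an intervals table
#'
#' Runs [extract_intervals()] over every discretized location trace of a
#' [simulate_panel()] result. This is the noiseless, trace-level entry point
#' into the statistics layer; the image-level pipeline produces the same
#' structure via [colocalize_locations()].
#'
#' @param panel A `cosmos_panel`.
#' @param label Channel / subcomplex label stored with each interval
#'   (defaults to the simulated subcomplex).
#' @return An [intervals_table()].
#' @export
panel_intervals <- function(panel, label = NULL) {
  stopifnot(inherits(panel, "cosmos_panel"))
  label <- label %||% panel$params$subcomplex
  construct_map <- stats::setNames(panel$layout$construct, panel$layout$location_id)
  intervals_from_presence(panel$presence, construct_map, panel$schedule, label)
}

#' Build an intervals table from a presence matrix
#'
#' Shared back-end for the trace-level ([panel_intervals()]) and image-level
#' ([colocalize_locations()]) pipelines: runs [extract_intervals()] over each
#' row of a `locations x frames` logical matrix (`NA` = missing frame).
#'
#' @param presence Logical matrix with locations in rows (rownames are
#'   location ids) and frames in columns.
#' @param construct_map Named character vector mapping location id to
#'   construct name.
#' @param schedule The [acquisition_schedule()].
#' @param label Channel / subcomplex label for the intervals.
#' @return An [intervals_table()].
#' @export
intervals_from_presence <- function(presence, construct_map, schedule,
                                    label = NA_character_) {
  stopifnot(is.matrix(presence), !is.null(rownames(presence)))
  ids <- rownames(presence)
  stopifnot(all(ids %in% names(construct_map)))
  iv <- dplyr::bind_rows(lapply(seq_len(nrow(presence)), function(i) {
    extract_intervals(presence[i, ],
      schedule = schedule,
      location_id = ids[i], label = label
    )
  }))
  n_obs <- rowSums(!is.na(presence))
  locations <- tibble::tibble(
    location_id = ids,
    construct = as.character(construct_map[ids]),
    n_frames_observed = as.integer(n_obs)
  )
  intervals_table(iv, locations, schedule)
}

#' Read and write interval tables as CSV
#'
#' The package's documented plain-text dialect: a CSV whose first two lines
#' are `#`-prefixed metadata (format tag and the acquisition schedule),
#' followed by a single table with a `record_type` column distinguishing
#' `location` metadata rows from `interval` rows. The round trip
#' `read_intervals(write_intervals(x))` is lossless. Column semantics are
#' documented in `system.file("extdata", "intervals-schema.yaml",
#' package = "cosmoskit")`.
#'
#' @param table An [intervals_table()].
#' @param path File path.
#' @return `write_intervals` returns `path` invisibly; `read_intervals`
#'   returns an [intervals_table()].
#' @export
write_intervals <- function(table, path) {
  stopifnot(inherits(table, "intervals_table"))
  sch <- table$schedule
  header <- c(
    "# cosmoskit-intervals v1",
    sprintf(
      "# schedule: frame_duration=%g;green_block_length=%d;red_interleave_length=%d;total_duration=%g",
      sch$frame_duration, sch$green_block_length,
      sch$red_interleave_length, sch$total_duration
    )
  )
  loc <- table$locations
  loc_rows <- data.frame(
    record_type = "location",
    location_id = loc$location_id,
    construct = loc$construct,
    start_s = NA_real_, end_s = NA_real_,
    left_censored = NA, right_censored = NA,
    label = NA_character_,
    n_frames_observed = loc$n_frames_observed,
    stringsAsFactors = FALSE
  )
  iv <- table$intervals
  iv_rows <- data.frame(
    record_type = character(0), location_id = character(0),
    construct = character(0), start_s = numeric(0), end_s = numeric(0),
    left_censored = logical(0), right_censored = logical(0),
    label = character(0), n_frames_observed = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(iv) > 0) {
    iv_rows <- data.frame(
      record_type = "interval",
      location_id = iv$location_id,
      construct = iv$construct,
      start_s = iv$start_s, end_s = iv$end_s,
      left_censored = iv$left_censored, right_censored = iv$right_censored,
      label = as.character(iv$label),
      n_frames_observed = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(rbind(loc_rows, iv_rows), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "# cosmoskit-intervals")) {
    stop("not a cosmoskit intervals file: ", path, call. = FALSE)
  }
  m <- regmatches(lines[2], regexec(
    "frame_duration=([0-9.eE+-]+);green_block_length=([0-9]+);red_interleave_length=([0-9]+);total_duration=([0-9.eE+-]+)",
    lines[2]
  ))[[1]]
  if (length(m) != 5) stop("malformed schedule header at line 2 of ", path, call. = FALSE)
  sch <- acquisition_schedule(
    frame_duration = as.numeric(m[2]),
    green_block_length = as.integer(m[3]),
    red_interleave_length = as.integer(m[4]),
    total_duration = as.numeric(m[5])
  )
  df <- utils::read.csv(textConnection(lines[-(1:2)]), stringsAsFactors = FALSE)
  needed <- c(
    "record_type", "location_id", "construct", "start_s", "end_s",
    "left_censored", "right_censored", "label", "n_frames_observed"
  )
  if (!all(needed %in% names(df))) {
    stop("malformed header at line 3 of ", path, call. = FALSE)
  }
  # data lines start at file line 4 (two comments + header)
  df$.line <- seq_len(nrow(df)) + 3L
  locs <- df[df$record_type == "location", , drop = FALSE]
  ivs <- df[df$record_type == "interval", , drop = FALSE]
  if (nrow(ivs) > 0) {
    bad <- which(!(ivs$end_s > ivs$start_s))
    if (length(bad)) {
      stop(sprintf(
        "line %d: interval has end_s <= start_s", ivs$.line[bad[1]]
      ), call. = FALSE)
    }
  }
  intervals <- tibble::tibble(
    location_id = ivs$location_id,
    start_s = as.numeric(ivs$start_s),
    end_s = as.numeric(ivs$end_s),
    dwell_s = as.numeric(ivs$end_s) - as.numeric(ivs$start_s),
    left_censored = as.logical(ivs$left_censored),
    right_censored = as.logical(ivs$right_censored),
    label = as.character(ivs$label),
    construct = ivs$construct
  )
  locations <- tibble::tibble(
    location_id = locs$location_id,
    construct = locs$construct,
    n_frames_observed = as.integer(locs$n_frames_observed)
  )
  intervals_table(intervals, locations, sch)
}
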