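#' Write an intervals table as a MAT-container in the documented layout
#'
#' Serializes an [intervals_table()] to a MAT v5 file holding a single
#' struct variable `Intervals` with fields:
#' * `CumulativeIntervalArray` — one row per interval, columns
#'   `[aoi, start_frame, end_frame, start_s, end_s, left_censored,
#'   right_censored]`, `aoi` being the 1-based index into the location list;
#' * `LocationIDs`, `AOIClasses` — cell arrays of location ids and construct
#'   names, one entry per location;
#' * `Labels` — cell array of channel labels, one per interval;
#' * `FramesObserved` — observed green frames per location;
#' * `Schedule` — `[frame_duration, green_block_length,
#'   red_interleave_length, total_duration]`.
#'
#' @param table An [intervals_table()].
#' @param path Output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_imscroll_intervals <- function(table, path) {
  stopifnot(inherits(table, "intervals_table"))
  loc <- table$locations
  iv <- table$intervals
  sch <- table$schedule
  fd <- sch$frame_duration
  aoi <- match(iv$location_id, loc$location_id)
  cia <- cbind(
    aoi = aoi,
    start_frame = iv$start_s / fd + 1,
    end_frame = iv$end_s / fd,
    start_s = iv$start_s,
    end_s = iv$end_s,
    left_censored = as.numeric(iv$left_censored),
    right_censored = as.numeric(iv$right_censored)
  )
  if (nrow(iv) == 0) cia <- matrix(numeric(0), nrow = 0, ncol = 7)
  write_mat5(
    list(Intervals = list(
      CumulativeIntervalArray = cia,
      LocationIDs = loc$location_id,
      AOIClasses = loc$construct,
      Labels = if (nrow(iv)) as.character(iv$label) else character(0),
      FramesObserved = as.numeric(loc$n_frames_observed),
      Schedule = c(
        fd, sch$green_block_length,
        sch$red_interleave_length, sch$total_duration
      )
    )),
    path
  )
}

#' Best-effort reader for single-molecule 'intervals' MAT containers
#'
#' Reads binding-interval containers of the kind deposited with
#' single-molecule colocalization studies (MAT v5 files produced by the
#' imscroll analysis software). Files written by
#' [write_imscroll_intervals()] round-trip exactly. For foreign files the
#' reader maps what it can recognize: a numeric interval array (field name
#' containing `interval`, one row per interval with an AOI index and
#' start/end columns) and, where present, per-AOI class labels. Unknown
#' fields are ignored with a warning; containers in which no interval data
#' can be identified raise an unsupported-format error rather than silently
#' returning partial data.
#'
#' @param path Path to a `.mat` intervals container.
#' @param frame_duration Fallback frame duration (s) for foreign files that
#'   record frames but no schedule.
#' @return An [intervals_table()].
#' @export
read_imscroll_intervals <- function(path, frame_duration = 1) {
  vars <- read_mat5(path)
  if (length(vars) == 0) {
    return(intervals_table(
      tibble::tibble(
        location_id = character(), start_s = numeric(), end_s = numeric(),
        dwell_s = numeric(), left_censored = logical(),
        right_censored = logical(), label = character(),
        construct = character()
      ),
      tibble::tibble(
        location_id = character(), construct = character(),
        n_frames_observed = integer()
      ),
      acquisition_schedule()
    ))
  }

  # exact path: our own layout
  if (!is.null(vars$Intervals) && is.list(vars$Intervals) &&
    !is.null(vars$Intervals$CumulativeIntervalArray) &&
    !is.null(vars$Intervals$LocationIDs)) {
    s <- vars$Intervals
    sched_v <- as.numeric(s$Schedule)
    sch <- acquisition_schedule(sched_v[1], sched_v[2], sched_v[3], sched_v[4])
    cia <- s$CumulativeIntervalArray
    if (length(cia) == 0) cia <- matrix(numeric(0), nrow = 0, ncol = 7)
    loc_ids <- as.character(unlist(s$LocationIDs))
    classes <- as.character(unlist(s$AOIClasses))
    labels <- as.character(unlist(s$Labels))
    n_iv <- nrow(cia)
    intervals <- tibble::tibble(
      location_id = loc_ids[cia[, 1]],
      start_s = cia[, 4],
      end_s = cia[, 5],
      dwell_s = cia[, 5] - cia[, 4],
      left_censored = cia[, 6] != 0,
      right_censored = cia[, 7] != 0,
      label = if (n_iv > 0 && length(labels) == n_iv) labels else rep(NA_character_, n_iv),
      construct = classes[cia[, 1]]
    )
    locations <- tibble::tibble(
      location_id = loc_ids,
      construct = classes,
      n_frames_observed = as.integer(round(as.numeric(s$FramesObserved)))
    )
    return(intervals_table(intervals, locations, sch))
  }

  # heuristic path for foreign containers
  hit <- find_interval_array(vars)
  if (is.null(hit)) {
    stop("unsupported format: no recognizable interval data in ", path, call. = FALSE)
  }
  mat <- hit$matrix
  warning(
    "foreign intervals container: interpreting field '", hit$field,
    "' heuristically; other fields ignored"
  )
  cols <- guess_interval_columns(mat)
  aoi <- as.integer(mat[, cols$aoi])
  start_f <- mat[, cols$start]
  end_f <- mat[, cols$end]
  n_loc <- max(aoi)
  loc_ids <- sprintf("aoi_%04d", seq_len(n_loc))
  classes <- hit$classes %||% rep("unknown", n_loc)
  if (length(classes) < n_loc) classes <- rep(classes, length.out = n_loc)
  t_end <- max(end_f) * frame_duration
  sch <- acquisition_schedule(
    frame_duration = frame_duration,
    green_block_length = as.integer(ceiling(t_end / frame_duration)),
    red_interleave_length = 0,
    total_duration = ceiling(t_end / frame_duration) * frame_duration
  )
  intervals <- tibble::tibble(
    location_id = loc_ids[aoi],
    start_s = (start_f - 1) * frame_duration,
    end_s = end_f * frame_duration,
    dwell_s = (end_f - start_f + 1) * frame_duration,
    left_censored = start_f <= 1,
    right_censored = end_f >= max(end_f),
    label = NA_character_,
    construct = classes[aoi]
  )
  locations <- tibble::tibble(
    location_id = loc_ids,
    construct = classes,
    n_frames_observed = sch$n_frames
  )
  intervals_table(intervals, locations, sch)
}

# Walk the parsed MAT variables for a numeric matrix that looks like an
# interval list: field name mentioning 'interval', >= 3 columns, and a
# column of small positive integers usable as an AOI index.
find_interval_array <- function(vars, prefix = "") {
  for (nm in names(vars)) {
    v <- vars[[nm]]
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.numeric(v) && is.matrix(v) && ncol(v) >= 3 &&
      grepl("interval", nm, ignore.case = TRUE)) {
      classes <- NULL
      cls_field <- grep("class", names(vars), ignore.case = TRUE, value = TRUE)
      if (length(cls_field)) classes <- as.character(unlist(vars[[cls_field[1]]]))
      return(list(matrix = v, field = full, classes = classes))
    }
    if (is.list(v) && !is.null(names(v))) {
      hit <- find_interval_array(v, full)
      if (!is.null(hit)) {
        return(hit)
      }
    }
  }
  NULL
}

# Heuristic column roles: AOI = first column of positive integers with
# repeats; start/end = first pair of later columns with end >= start.
guess_interval_columns <- function(mat) {
  is_index <- apply(mat, 2, function(x) {
    all(x > 0) && all(abs(x - round(x)) < 1e-9) && any(duplicated(x))
  })
  aoi <- which(is_index)[1]
  if (is.na(aoi)) aoi <- 1L
  others <- setdiff(seq_len(ncol(mat)), aoi)
  for (i in seq_along(others)) {
    for (j in seq_along(others)) {
      if (i == j) next
      a <- others[i]
      b <- others[j]
      if (all(mat[, b] >= mat[, a]) && all(mat[, a] >= 0)) {
        return(list(aoi = aoi, start = a, end = b))
      }
    }
  }
  stop("unsupported format: could not identify start/end columns", call. = FALSE)
}
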