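#' Bootstrap standard error over surface locations
#'
#' Resamples the independent experimental units — surface locations, never
#' individual binding events — with replacement `B` times, recomputes the
#' statistic on each resample, and reports the standard deviation of the
#' resampled statistics as the standard error, together with a percentile
#' confidence interval. The default of 2,000 resamples matches standard
#' practice for these experiments.
#'
#' Two interfaces are provided:
#' * `bootstrap_se(x)` where `x` is a numeric vector of one value per
#'   location (e.g. per-location event counts) and `statistic` maps such a
#'   vector to a number;
#' * `bootstrap_se(table, statistic = f)` where `table` is an
#'   [intervals_table()] and `statistic` maps a resampled table to a number
#'   (locations are resampled; each drawn location keeps all its intervals).
#'
#' @param x Numeric vector of per-location values, or an [intervals_table()].
#' @param statistic Function of a resample returning a single number
#'   (default: `mean` for vectors).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed; results are deterministic under a fixed seed.
#' @param conf_level Level for the percentile interval.
#' @param ... Passed to methods.
#'
#' @return List with `se`, `ci` (percentile), `estimate`, and the vector of
#'   resampled statistics (`samples`).
#' @export
#' @examples
#' set.seed(1)
#' bootstrap_se(rnorm(100), B = 500, seed = 2)$se # close to 1/sqrt(100)
bootstrap_se <- function(x, ...) UseMethod("bootstrap_se")

#' @rdname bootstrap_se
#' @export
bootstrap_se.numeric <- function(x, statistic = mean, B = 2000, seed = 1L,
                                 conf_level = 0.95, ...) {
  n <- length(x)
  if (n < 2) stop("need at least 2 locations to bootstrap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  samples <- apply(idx, 1, function(i) statistic(x[i]))
  finish_boot(samples, statistic(x), conf_level)
}

#' @rdname bootstrap_se
#' @export
bootstrap_se.intervals_table <- function(x, statistic, B = 2000, seed = 1L,
                                         conf_level = 0.95, ...) {
  stopifnot(is.function(statistic))
  n <- nrow(x$locations)
  if (n < 2) stop("need at least 2 locations to bootstrap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  samples <- vapply(seq_len(B), function(b) {
    statistic(resample_locations(x))
  }, numeric(1))
  finish_boot(samples, statistic(x), conf_level)
}

finish_boot <- function(samples, estimate, conf_level) {
  alpha <- (1 - conf_level) / 2
  list(
    se = stats::sd(samples),
    ci = stats::quantile(samples, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE),
    estimate = estimate,
    samples = samples
  )
}

# Resample the locations of an intervals table with replacement; intervals
# travel with their location, and resampled duplicates get distinct ids so
# per-location statistics keep the right denominators.
resample_locations <- function(table) {
  n <- nrow(table$locations)
  pick <- sample.int(n, n, replace = TRUE)
  loc <- table$locations[pick, , drop = FALSE]
  new_ids <- sprintf("%s*%d", loc$location_id, seq_len(n))
  iv_by_loc <- split(
    seq_len(nrow(table$intervals)),
    factor(table$intervals$location_id, levels = table$locations$location_id)
  )
  rows <- iv_by_loc[loc$location_id]
  reps <- lengths(rows)
  iv <- table$intervals[unlist(rows, use.names = FALSE), , drop = FALSE]
  iv$location_id <- rep(new_ids, reps)
  loc$location_id <- new_ids
  structure(
    list(intervals = iv, locations = loc, schedule = table$schedule),
    class = "intervals_table"
  )
}
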