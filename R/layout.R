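#' Lay out RNA molecules and no-RNA control locations on a slide surface
#'
#' Places the requested number of molecules of each construct, plus
#' non-overlapping no-RNA control locations, uniformly at random in a
#' rectangular field of view, enforcing a minimum separation so that
#' locations remain individually resolvable. The realized density of
#' fluorescent (RNA) spots is validated against `density_bounds`.
#'
#' Either give explicit per-construct `counts`, or a target spot `density`
#' (spots/um^2) which is split evenly across the constructs.
#'
#' @param constructs List of [construct_spec()] objects (controls are added
#'   automatically; do not include `no_RNA` here).
#' @param counts Integer vector of molecule counts, one per construct.
#' @param n_controls Number of no-RNA control locations (default: 25% of the
#'   RNA locations, at least 10).
#' @param field_size_um Field of view as `c(width, height)` in micrometers.
#' @param density_bounds Allowed range of RNA spot density (spots/um^2).
#' @param density Optional target RNA spot density; used when `counts` is
#'   missing.
#' @param min_separation_um Minimum center-to-center distance between any two
#'   locations.
#' @param seed Integer seed; layouts are reproducible under a fixed seed.
#'
#' @return A `slide_layout`: a tibble with columns `location_id`, `construct`,
#'   `x_um`, `y_um`, carrying the field size and density as attributes.
#' @export
#' @examples
#' lay <- build_slide_layout(panel_cross_intron_exon(),
#'   counts = c(50, 50),
#'   n_controls = 50, seed = 7
#' )
#' nrow(lay) # 150
build_slide_layout <- function(constructs,
                               counts = NULL,
                               n_controls = NULL,
                               field_size_um = c(100, 100),
                               density_bounds = c(0, 0.5),
                               density = NULL,
                               min_separation_um = 0.5,
                               seed = 1L) {
  stopifnot(is.list(constructs), length(constructs) >= 1)
  lapply(constructs, function(cs) stopifnot(inherits(cs, "construct_spec")))
  names(constructs) <- vapply(constructs, `[[`, character(1), "name")
  if (anyDuplicated(names(constructs))) {
    stop("construct names must be unique within a panel", call. = FALSE)
  }
  if ("no_RNA" %in% names(constructs)) {
    stop("do not include 'no_RNA' in constructs; controls are added via n_controls",
      call. = FALSE
    )
  }
  area <- prod(field_size_um)
  if (is.null(counts)) {
    if (is.null(density)) stop("give either counts or density", call. = FALSE)
    total <- round(density * area)
    counts <- rep(floor(total / length(constructs)), length(constructs))
    counts[seq_len(total - sum(counts))] <- counts[seq_len(total - sum(counts))] + 1L
  }
  stopifnot(length(counts) == length(constructs), all(counts > 0))
  n_rna <- sum(counts)
  realized_density <- n_rna / area
  if (realized_density < density_bounds[1] || realized_density > density_bounds[2]) {
    stop(sprintf(
      "requested RNA spot density %.3g /um^2 outside allowed bounds [%g, %g]",
      realized_density, density_bounds[1], density_bounds[2]
    ), call. = FALSE)
  }
  if (is.null(n_controls)) n_controls <- max(10L, round(0.25 * n_rna))
  n_total <- n_rna + n_controls

  if (!is.null(seed)) set.seed(seed)
  xy <- sample_separated_points(n_total, field_size_um, min_separation_um)

  construct <- c(rep(names(constructs), counts), rep("no_RNA", n_controls))
  idx <- stats::ave(seq_along(construct), construct, FUN = seq_along)
  location_id <- sprintf("%s_%04d", construct, idx)

  layout <- tibble::tibble(
    location_id = location_id,
    construct = construct,
    x_um = xy[, 1],
    y_um = xy[, 2]
  )
  attr(layout, "field_size_um") <- field_size_um
  attr(layout, "density_um2") <- realized_density
  attr(layout, "constructs") <- c(constructs, list(no_RNA = no_rna_spec()))
  class(layout) <- c("slide_layout", class(layout))
  layout
}

# Uniform points in a rectangle with a hard minimum-separation constraint,
# via grid-bucketed rejection resampling.
sample_separated_points <- function(n, field, min_sep) {
  pts <- cbind(stats::runif(n, 0, field[1]), stats::runif(n, 0, field[2]))
  if (min_sep <= 0 || n < 2) {
    return(pts)
  }
  cell <- min_sep
  for (pass in 1:200) {
    key <- paste(floor(pts[, 1] / cell), floor(pts[, 2] / cell))
    bad <- rep(FALSE, n)
    # check each point against points in its own and neighboring buckets
    buckets <- split(seq_len(n), key)
    bx <- floor(pts[, 1] / cell)
    by <- floor(pts[, 2] / cell)
    for (i in seq_len(n)) {
      if (bad[i]) next
      nb <- unlist(buckets[paste(
        rep(bx[i] + (-1:1), each = 3),
        rep(by[i] + (-1:1), times = 3)
      )], use.names = FALSE)
      nb <- nb[nb != i & !bad[nb]]
      if (length(nb)) {
        d2 <- (pts[nb, 1] - pts[i, 1])^2 + (pts[nb, 2] - pts[i, 2])^2
        bad[nb[d2 < min_sep^2]] <- TRUE
      }
    }
    if (!any(bad)) {
      return(pts)
    }
    pts[bad, ] <- cbind(
      stats::runif(sum(bad), 0, field[1]),
      stats::runif(sum(bad), 0, field[2])
    )
  }
  stop("could not place locations with the requested minimum separation; reduce density",
    call. = FALSE
  )
}
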