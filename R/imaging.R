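# Image-level layer: forward rendering of synthetic TIRF movies and
# recovery of binding by spot detection, drift correction, and channel
# registration. Coordinates are 0-based, pixel-center convention:
# x runs along columns, y along rows, and the center of the top-left pixel
# is (0, 0).

#' Render a synthetic two-channel TIRF image stack from a simulated panel
#'
#' Forward model for testing the detection pipeline: every visible
#' fluorophore is rendered as a symmetric 2-D Gaussian (integrated over
#' pixels, so the summed signal equals the amplitude), on a constant
#' background, with Poisson shot noise and additive Gaussian read noise.
#' Bright, persistent fiducial beads are added for drift estimation, and an
#' optional stage-drift trajectory translates everything. Binding spots are
#' rendered only in green-excitation frames; fiducials appear in every
#' frame.
#'
#' @param panel A `cosmos_panel` from [simulate_panel()] (its layout must fit
#'   in the field of view at the given pixel size).
#' @param pixel_size_um Pixel size in micrometers.
#' @param psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @param amplitude Photons per frame per visible fluorophore.
#' @param background Background photons per pixel per frame.
#' @param read_noise_sd SD of additive Gaussian read noise (photons).
#' @param drift_px Per-frame drift: either `c(dx, dy)` per frame (linear
#'   drift) or an `n_frames x 2` matrix of offsets; `NULL` for none.
#' @param fiducials Tibble with `x_px`, `y_px`, `amplitude`, or an integer
#'   number of beads to place on a margin-respecting grid.
#' @param seed Integer seed; stacks are identical under identical seeds.
#' @param noise Set `FALSE` for a noise-free stack.
#'
#' @return An `image_stack`: list with `frames` (array `ny x nx x n_frames`),
#'   `channel` per frame, `pixel_size_um`, `fiducials_px`, `drift_px`,
#'   `schedule`, and the true spot positions in pixels (`locations_px`).
#' @export
render_image_stack <- function(panel,
                               pixel_size_um = 0.16,
                               psf_sigma_px = 1.2,
                               amplitude = 400,
                               background = 100,
                               read_noise_sd = 2,
                               drift_px = NULL,
                               fiducials = 4L,
                               seed = 1L,
                               noise = TRUE) {
  stopifnot(inherits(panel, "cosmos_panel"))
  layout <- panel$layout
  sched <- panel$schedule
  n_frames <- sched$n_frames
  field <- attr(layout, "field_size_um")
  nx <- as.integer(ceiling(field[1] / pixel_size_um))
  ny <- as.integer(ceiling(field[2] / pixel_size_um))

  loc_px <- tibble::tibble(
    location_id = layout$location_id,
    construct = layout$construct,
    x_px = layout$x_um / pixel_size_um,
    y_px = layout$y_um / pixel_size_um
  )
  if (is.numeric(fiducials) && length(fiducials) == 1) {
    # beads go on the field perimeter so they never shadow RNA locations
    k <- as.integer(fiducials)
    margin <- 4
    corners <- cbind(
      c(margin, nx - 1 - margin, margin, nx - 1 - margin),
      c(margin, ny - 1 - margin, ny - 1 - margin, margin)
    )
    sel <- ((seq_len(max(k, 0)) - 1L) %% 4L) + 1L
    fiducials <- tibble::tibble(
      x_px = corners[sel, 1], y_px = corners[sel, 2],
      amplitude = rep(6 * amplitude, k)
    )
  }
  if (is.null(drift_px)) {
    drift <- matrix(0, n_frames, 2)
  } else if (is.matrix(drift_px)) {
    stopifnot(nrow(drift_px) == n_frames, ncol(drift_px) == 2)
    drift <- drift_px
  } else {
    drift <- cbind((seq_len(n_frames) - 1) * drift_px[1],
      (seq_len(n_frames) - 1) * drift_px[2]
    )
  }

  if (!is.null(seed)) set.seed(seed)
  red <- is_red_frame(sched)
  frames <- array(0, dim = c(ny, nx, n_frames))
  for (f in seq_len(n_frames)) {
    img <- matrix(background, ny, nx)
    if (!red[f]) {
      on <- which(!is.na(panel$presence[, f]) & panel$presence[, f])
      for (i in on) {
        img <- add_gaussian_spot(
          img, loc_px$x_px[i] + drift[f, 1],
          loc_px$y_px[i] + drift[f, 2], amplitude, psf_sigma_px
        )
      }
    }
    for (j in seq_len(nrow(fiducials))) {
      img <- add_gaussian_spot(
        img, fiducials$x_px[j] + drift[f, 1],
        fiducials$y_px[j] + drift[f, 2], fiducials$amplitude[j], psf_sigma_px
      )
    }
    if (noise) {
      img <- matrix(
        stats::rpois(length(img), lambda = img) +
          stats::rnorm(length(img), sd = read_noise_sd),
        ny, nx
      )
    }
    frames[, , f] <- img
  }
  structure(
    list(
      frames = frames,
      channel = ifelse(red, "red", "green"),
      pixel_size_um = pixel_size_um,
      psf_sigma_px = psf_sigma_px,
      fiducials_px = fiducials,
      drift_px = drift,
      locations_px = loc_px,
      schedule = sched
    ),
    class = "image_stack"
  )
}

# Add an integrated symmetric Gaussian of total intensity `amp` at sub-pixel
# position (x, y) (0-based pixel centers).
add_gaussian_spot <- function(img, x, y, amp, sigma) {
  ny <- nrow(img)
  nx <- ncol(img)
  r <- ceiling(4 * sigma) + 1L
  cx <- round(x)
  cy <- round(y)
  xs <- max(0, cx - r):min(nx - 1, cx + r)
  ys <- max(0, cy - r):min(ny - 1, cy + r)
  if (length(xs) == 0 || length(ys) == 0) {
    return(img)
  }
  gx <- stats::pnorm(xs + 0.5, x, sigma) - stats::pnorm(xs - 0.5, x, sigma)
  gy <- stats::pnorm(ys + 0.5, y, sigma) - stats::pnorm(ys - 0.5, y, sigma)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp * (gy %o% gx)
  img
}

#' Detect fluorescent spots in a single image
#'
#' Matched-filter detection: the image (minus its median background) is
#' correlated with a unit-L2-norm Gaussian kernel matched to the PSF, local
#' maxima of the filtered image above `threshold_sigma` robust noise SDs are
#' taken as detections, and positions are refined to sub-pixel precision by
#' intensity-weighted centroid in a window around each maximum. Because the
#' kernel has unit L2 norm, white noise keeps its SD through the filter and
#' `threshold_sigma` has the usual Gaussian tail interpretation.
#'
#' @param image Numeric matrix (one frame).
#' @param threshold_sigma Detection threshold in noise SDs.
#' @param psf_sigma_px PSF sigma in pixels.
#' @return Tibble with `x_px`, `y_px` (0-based), `amplitude` (background
#'   subtracted, summed over the refinement window), `background`,
#'   `filter_snr`.
#' @export
detect_spots <- function(image, threshold_sigma = 5, psf_sigma_px = 1.2) {
  stopifnot(is.matrix(image))
  bg <- stats::median(image)
  noise <- stats::mad(image)
  if (noise == 0) noise <- stats::sd(image)
  if (is.na(noise) || noise == 0) noise <- 1e-12
  filt <- gaussian_filter_l2(image - bg, psf_sigma_px)
  r <- ceiling(2 * psf_sigma_px) + 1L
  maxima <- local_maxima(filt, threshold = threshold_sigma * noise, border = r)
  if (nrow(maxima) == 0) {
    return(tibble::tibble(
      x_px = numeric(0), y_px = numeric(0), amplitude = numeric(0),
      background = numeric(0), filter_snr = numeric(0)
    ))
  }
  out <- lapply(seq_len(nrow(maxima)), function(k) {
    i <- maxima$row[k]
    j <- maxima$col[k]
    ys <- max(1, i - r):min(nrow(image), i + r)
    xs <- max(1, j - r):min(ncol(image), j + r)
    w <- pmax(image[ys, xs, drop = FALSE] - bg, 0)
    tot <- sum(w)
    if (tot <= 0) {
      cx <- j - 1
      cy <- i - 1
    } else {
      cx <- sum(t(w) * (xs - 1)) / tot
      cy <- sum(w * (ys - 1)) / tot
    }
    c(cx, cy, tot, maxima$value[k] / noise)
  })
  out <- do.call(rbind, out)
  tibble::tibble(
    x_px = out[, 1], y_px = out[, 2], amplitude = out[, 3],
    background = bg, filter_snr = out[, 4]
  )
}

# Separable Gaussian correlation with a unit-L2-norm kernel ("same" size,
# truncated at the borders).
gaussian_filter_l2 <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sqrt(sum(g^2))
  conv_rows <- band_matrix(nrow(img), g)
  conv_cols <- band_matrix(ncol(img), g)
  conv_rows %*% img %*% t(conv_cols)
}

band_matrix <- function(n, g) {
  r <- (length(g) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (k in -r:r) {
    idx <- seq_len(n)
    j <- idx + k
    ok <- j >= 1 & j <= n
    m[cbind(idx[ok], j[ok])] <- g[k + r + 1L]
  }
  m
}

local_maxima <- function(img, threshold, border = 2L) {
  ny <- nrow(img)
  nx <- ncol(img)
  rows <- (border + 1L):(ny - border)
  cols <- (border + 1L):(nx - border)
  core <- img[rows, cols, drop = FALSE]
  is_max <- core >= threshold
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (core >= img[rows + di, cols + dj, drop = FALSE])
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  tibble::tibble(
    row = rows[idx[, 1]],
    col = cols[idx[, 2]],
    value = core[idx]
  )
}

#' Detect spots across a stack with sliding-window frame averaging
#'
#' Averages each green frame with its neighboring green frames (centered
#' window, red-interleave frames skipped) before running [detect_spots()],
#' the standard noise-suppression step before spot picking.
#'
#' @param stack An `image_stack`.
#' @param window Odd number of green frames to average.
#' @param frames Which frame indices to process (default: all green frames).
#' @inheritParams detect_spots
#' @return Tibble of detections with a `frame` column.
#' @export
detect_spots_stack <- function(stack, threshold_sigma = 5, window = 5L,
                               frames = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  green <- which(stack$channel == "green")
  if (is.null(frames)) frames <- green
  frames <- intersect(frames, green)
  half <- as.integer(window) %/% 2L
  pos <- match(frames, green)
  out <- lapply(seq_along(frames), function(k) {
    p <- pos[k]
    sel <- green[max(1, p - half):min(length(green), p + half)]
    avg <- apply(stack$frames[, , sel, drop = FALSE], c(1, 2), mean)
    det <- detect_spots(avg, threshold_sigma, stack$psf_sigma_px)
    if (nrow(det) > 0) det$frame <- frames[k]
    det
  })
  dplyr::bind_rows(out)
}

#' Track fiducial beads through a stack of detections
#'
#' Associates each frame's detections with the known approximate fiducial
#' positions (nearest detection within `radius_px`).
#'
#' @param spots Detections tibble with `frame`, `x_px`, `y_px`.
#' @param fiducials_px Tibble with `x_px`, `y_px` (approximate positions).
#' @param radius_px Association radius in pixels.
#' @return Tibble with `frame`, `fiducial_id`, `x_px`, `y_px`.
#' @export
track_fiducials <- function(spots, fiducials_px, radius_px = 4) {
  out <- list()
  for (j in seq_len(nrow(fiducials_px))) {
    d2 <- (spots$x_px - fiducials_px$x_px[j])^2 +
      (spots$y_px - fiducials_px$y_px[j])^2
    near <- spots[d2 <= radius_px^2, , drop = FALSE]
    near_d2 <- d2[d2 <= radius_px^2]
    if (nrow(near) == 0) next
    best <- near |>
      dplyr::mutate(.d2 = near_d2) |>
      dplyr::group_by(.data$frame) |>
      dplyr::slice_min(.data$.d2, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    out[[j]] <- tibble::tibble(
      frame = best$frame, fiducial_id = j,
      x_px = best$x_px, y_px = best$y_px
    )
  }
  dplyr::bind_rows(out)
}

#' Estimate the stage-drift trajectory from fiducial tracks
#'
#' Per-frame mean displacement of the fiducials relative to the reference
#' (first tracked) frame, linearly interpolated over frames in which no
#' fiducial was tracked. The offset at the reference frame is (0, 0) by
#' construction, and with several fiducials sharing the same drift the
#' average equals any single track.
#'
#' @param tracks Tibble from [track_fiducials()] (needs `frame`,
#'   `fiducial_id`, `x_px`, `y_px`).
#' @param n_frames Total number of frames for the interpolated trajectory.
#' @return A `drift_trajectory` tibble with `frame`, `dx_px`, `dy_px`.
#' @export
estimate_drift <- function(tracks, n_frames = max(tracks$frame)) {
  if (is.null(tracks) || nrow(tracks) == 0) {
    stop("no fiducial tracks available for drift estimation", call. = FALSE)
  }
  ref_frame <- min(tracks$frame)
  refs <- tracks |>
    dplyr::group_by(.data$fiducial_id) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tr <- dplyr::left_join(tracks, refs[, c("fiducial_id", "x_px", "y_px")],
    by = "fiducial_id", suffix = c("", "_ref")
  )
  per_frame <- tr |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      dx_px = mean(.data$x_px - .data$x_px_ref),
      dy_px = mean(.data$y_px - .data$y_px_ref),
      .groups = "drop"
    )
  frames <- seq_len(n_frames)
  dx <- stats::approx(per_frame$frame, per_frame$dx_px, xout = frames, rule = 2)$y
  dy <- stats::approx(per_frame$frame, per_frame$dy_px, xout = frames, rule = 2)$y
  # anchor exactly at the reference frame
  dx <- dx - dx[ref_frame]
  dy <- dy - dy[ref_frame]
  out <- tibble::tibble(frame = frames, dx_px = dx, dy_px = dy)
  class(out) <- c("drift_trajectory", class(out))
  out
}

#' Fit an affine mapping between the two excitation channels
#'
#' Least-squares affine transform (2x2 matrix plus offset) taking green-
#' channel coordinates to red-channel coordinates, from matched bead
#' positions observed in both channels.
#'
#' @param green_xy,red_xy Matrices (or data frames) of matched positions,
#'   columns x and y; at least 3 non-collinear pairs.
#' @return A `channel_mapping`: list with `A` (2x2), `b` (length 2), and
#'   `residual_rms` in pixels.
#' @export
fit_channel_mapping <- function(green_xy, red_xy) {
  g <- as.matrix(green_xy)
  r <- as.matrix(red_xy)
  stopifnot(ncol(g) == 2, ncol(r) == 2, nrow(g) == nrow(r))
  if (nrow(g) < 3) stop("need at least 3 bead pairs", call. = FALSE)
  X <- cbind(1, g)
  if (qr(X)$rank < 3) {
    stop("bead positions are collinear; affine mapping is not identifiable", call. = FALSE)
  }
  coef <- qr.solve(X, r) # 3 x 2: row 1 = offset, rows 2:3 = linear part
  A <- t(coef[2:3, , drop = FALSE])
  b <- as.numeric(coef[1, ])
  if (abs(det(A)) < 1e-12) {
    stop("fitted channel mapping is not invertible", call. = FALSE)
  }
  fitted <- X %*% coef
  res <- r - fitted
  structure(
    list(A = A, b = b, residual_rms = sqrt(mean(rowSums(res^2)))),
    class = "channel_mapping"
  )
}

#' Apply a channel mapping to coordinates
#' @param mapping A `channel_mapping`.
#' @param xy Matrix of coordinates (columns x, y).
#' @return Mapped coordinates.
#' @export
apply_channel_mapping <- function(mapping, xy) {
  xy <- as.matrix(xy)
  t(mapping$A %*% t(xy) + mapping$b)
}

#' Colocalize detected spots with reference locations
#'
#' A reference location is *bound* in a frame iff at least one detected spot
#' (after drift correction) lies within `radius_px`; when several locations
#' compete for one spot, the nearest location wins. The default radius of
#' 1.5 PSF sigmas matches the localization precision of the detector.
#'
#' @param spots Detections tibble with `frame`, `x_px`, `y_px`.
#' @param locations_px Tibble with `location_id`, `x_px`, `y_px` (reference,
#'   drift-free coordinates).
#' @param schedule The [acquisition_schedule()]; red-interleave frames are
#'   reported as missing (`NA`).
#' @param radius_px Colocalization radius in pixels.
#' @param drift A `drift_trajectory` to subtract from spot positions, or
#'   `NULL`.
#' @param frames Frames actually processed (default: green frames); frames
#'   outside this set are `NA` in the output.
#' @return Logical matrix `locations x frames` (`NA` = no data).
#' @export
colocalize_locations <- function(spots, locations_px, schedule,
                                 radius_px = 1.8, drift = NULL,
                                 frames = NULL) {
  stopifnot(inherits(schedule, "cosmos_schedule"))
  green <- which(!is_red_frame(schedule))
  if (is.null(frames)) frames <- green
  n_loc <- nrow(locations_px)
  presence <- matrix(NA, n_loc, schedule$n_frames)
  rownames(presence) <- locations_px$location_id
  presence[, frames] <- FALSE
  if (!is.null(drift)) {
    d <- drift[match(spots$frame, drift$frame), , drop = FALSE]
    spots$x_px <- spots$x_px - d$dx_px
    spots$y_px <- spots$y_px - d$dy_px
  }
  spots <- spots[spots$frame %in% frames, , drop = FALSE]
  for (f in unique(spots$frame)) {
    sp <- spots[spots$frame == f, , drop = FALSE]
    if (nrow(sp) == 0) next
    d2 <- outer(sp$x_px, locations_px$x_px, "-")^2 +
      outer(sp$y_px, locations_px$y_px, "-")^2
    nearest <- apply(d2, 1, which.min)
    within <- d2[cbind(seq_len(nrow(sp)), nearest)] <= radius_px^2
    presence[unique(nearest[within]), f] <- TRUE
  }
  presence
}
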