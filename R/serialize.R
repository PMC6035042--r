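#' Serialize a simulated panel to plain-text artifacts
#'
#' `write_panel_csv()` writes the layout, ground-truth event table, and
#' discretized presence traces of a [simulate_panel()] result as three CSV
#' files (`layout.csv`, `truth.csv`, `traces.csv`; traces in long run-length
#' form). `write_panel_container()` stores the same content, plus the
#' schedule and kinetic parameters, in one hierarchical JSON container that
#' `read_panel_container()` restores losslessly (presence traces are
#' run-length encoded; `NA` runs mark red-interleave frames).
#'
#' @param panel A `cosmos_panel`.
#' @param dir Output directory for the CSV bundle.
#' @param path Output path for the JSON container.
#' @return The directory or path, invisibly.
#' @export
write_panel_csv <- function(panel, dir) {
  stopifnot(inherits(panel, "cosmos_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(panel$layout),
    file.path(dir, "layout.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(panel$truth),
    file.path(dir, "truth.csv"),
    row.names = FALSE
  )
  rle_rows <- lapply(seq_len(nrow(panel$presence)), function(i) {
    r <- rle(encode_presence(panel$presence[i, ]))
    data.frame(
      location_id = rownames(panel$presence)[i],
      state = r$values, length = r$lengths
    )
  })
  utils::write.csv(do.call(rbind, rle_rows),
    file.path(dir, "traces.csv"),
    row.names = FALSE
  )
  invisible(dir)
}

encode_presence <- function(p) {
  ifelse(is.na(p), "missing", ifelse(p, "present", "absent"))
}

decode_presence <- function(state, length) {
  v <- rep(state, length)
  ifelse(v == "missing", NA, v == "present")
}

#' @rdname write_panel_csv
#' @export
write_panel_container <- function(panel, path) {
  stopifnot(inherits(panel, "cosmos_panel"))
  traces <- lapply(seq_len(nrow(panel$presence)), function(i) {
    r <- rle(encode_presence(panel$presence[i, ]))
    list(
      location_id = rownames(panel$presence)[i],
      state = r$values, length = r$lengths
    )
  })
  obj <- list(
    format = "cosmoskit-panel v1",
    seed = panel$seed,
    schedule = panel$schedule[c(
      "frame_duration", "green_block_length",
      "red_interleave_length", "total_duration"
    )],
    params = c(
      list(subcomplex = panel$params$subcomplex),
      panel$params[c(
        "k_assoc_specific", "k_assoc_nonspecific",
        "nonspecific_mean_dwell", "labeling_fraction", "bleach_rate",
        "synergy_factor", "frac_active"
      )],
      list(dwell_mixture = panel$params$dwell_mixture)
    ),
    layout = list(
      location_id = panel$layout$location_id,
      construct = panel$layout$construct,
      x_um = panel$layout$x_um,
      y_um = panel$layout$y_um,
      field_size_um = attr(panel$layout, "field_size_um"),
      constructs = lapply(attr(panel$layout, "constructs"), unclass)
    ),
    active = as.list(panel$active),
    truth = as.list(panel$truth),
    traces = traces
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "cosmoskit-panel v1")) {
    stop("not a cosmoskit panel container: ", path, call. = FALSE)
  }
  schedule <- acquisition_schedule(
    obj$schedule$frame_duration, obj$schedule$green_block_length,
    obj$schedule$red_interleave_length, obj$schedule$total_duration
  )
  params <- kinetic_params(
    subcomplex = obj$params$subcomplex,
    k_assoc_specific = obj$params$k_assoc_specific,
    dwell_mixture = as.data.frame(obj$params$dwell_mixture),
    k_assoc_nonspecific = obj$params$k_assoc_nonspecific,
    nonspecific_mean_dwell = obj$params$nonspecific_mean_dwell,
    labeling_fraction = obj$params$labeling_fraction,
    bleach_rate = obj$params$bleach_rate,
    synergy_factor = obj$params$synergy_factor,
    frac_active = obj$params$frac_active
  )
  layout <- tibble::tibble(
    location_id = obj$layout$location_id,
    construct = obj$layout$construct,
    x_um = obj$layout$x_um,
    y_um = obj$layout$y_um
  )
  attr(layout, "field_size_um") <- obj$layout$field_size_um
  attr(layout, "constructs") <- lapply(obj$layout$constructs, function(cs) {
    construct_spec(cs$name,
      upstream_5ss = isTRUE(cs$upstream_5ss),
      downstream_5ss = isTRUE(cs$downstream_5ss),
      bs_3ss = isTRUE(cs$bs_3ss),
      spliceable = isTRUE(cs$spliceable)
    )
  })
  class(layout) <- c("slide_layout", class(layout))
  tr <- obj$traces
  presence <- t(vapply(seq_len(nrow(layout)), function(i) {
    decode_presence(tr$state[[i]], tr$length[[i]])
  }, logical(schedule$n_frames)))
  rownames(presence) <- tr$location_id
  presence <- presence[layout$location_id, , drop = FALSE]
  col <- function(x, as) as(unlist(x) %||% vector(mode(as(logical(0))), 0))
  truth <- tibble::tibble(
    location_id = col(obj$truth$location_id, as.character),
    construct = col(obj$truth$construct, as.character),
    arrival_s = col(obj$truth$arrival_s, as.numeric),
    departure_s = col(obj$truth$departure_s, as.numeric),
    labeled = col(obj$truth$labeled, as.logical),
    specific = col(obj$truth$specific, as.logical),
    bleached_at_s = as.numeric(vapply(
      obj$truth$bleached_at_s %||% list(),
      function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)
    )),
    visible_until_s = as.numeric(vapply(
      obj$truth$visible_until_s %||% list(),
      function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1)
    )),
    n_visible_frames = col(obj$truth$n_visible_frames, as.integer)
  )
  structure(
    list(
      presence = presence,
      layout = layout,
      truth = truth,
      active = stats::setNames(unlist(obj$active), names(obj$active)),
      params = params,
      schedule = schedule,
      seed = obj$seed
    ),
    class = "cosmos_panel"
  )
}
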