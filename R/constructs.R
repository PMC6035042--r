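#' Define an RNA construct by its functional splice-site elements
#'
#' A construct is an abstract flag set: which 5' splice sites (upstream of the
#' branch site across the intron, downstream across the exon) are functional,
#' whether the branch site / polypyrimidine tract / 3'SS block is intact, and
#' whether the RNA can complete splicing (release its intron). Sequence-level
#' detail is deliberately out of scope; the flags are what the binding
#' kinetics respond to.
#'
#' The name `"no_RNA"` is reserved for control surface locations and must
#' carry all-false flags (see [no_rna_spec()]).
#'
#' @param name Short unique label, e.g. `"5i3e5"`.
#' @param upstream_5ss Is the 5'SS upstream of the intron functional?
#' @param downstream_5ss Is the 5'SS across the downstream exon functional?
#' @param bs_3ss Is the branch site / polypyrimidine tract / 3'SS intact?
#' @param spliceable Can the construct release its intron (cross-intron
#'   geometry with all required elements)?
#'
#' @return An object of class `construct_spec`.
#' @export
#' @examples
#' construct_spec("5i3", upstream_5ss = TRUE, downstream_5ss = FALSE)
construct_spec <- function(name,
                           upstream_5ss = FALSE,
                           downstream_5ss = FALSE,
                           bs_3ss = TRUE,
                           spliceable = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  flags <- c(upstream_5ss, downstream_5ss, bs_3ss, spliceable)
  stopifnot(is.logical(flags), !anyNA(flags))
  if (name == "no_RNA" && any(flags)) {
    stop("'no_RNA' is reserved for control locations and must have all flags FALSE",
      call. = FALSE
    )
  }
  structure(
    list(
      name = name,
      upstream_5ss = upstream_5ss,
      downstream_5ss = downstream_5ss,
      bs_3ss = bs_3ss,
      spliceable = spliceable
    ),
    class = "construct_spec"
  )
}

#' Reserved construct for no-RNA control locations
#' @return A `construct_spec` named `"no_RNA"` with all flags FALSE.
#' @export
no_rna_spec <- function() {
  construct_spec("no_RNA",
    upstream_5ss = FALSE, downstream_5ss = FALSE,
    bs_3ss = FALSE, spliceable = FALSE
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  cat(sprintf(
    "<construct_spec> %s  [5'SS up:%s down:%s  BS/3'SS:%s  spliceable:%s]\n",
    x$name, x$upstream_5ss, x$downstream_5ss, x$bs_3ss, x$spliceable
  ))
  invisible(x)
}

#' Standard construct panels
#'
#' `panel_cross_intron_exon()` returns the single-intron / single-exon pair:
#' a cross-intron substrate (`5i3`: one upstream 5'SS, intact 3'SS block,
#' spliceable) and a cross-exon substrate (`3e5`: the same elements in
#' swapped order, so the only 5'SS sits across the exon and the RNA cannot
#' splice).
#'
#' `panel_double_5ss()` returns the four-construct panel used to probe 5'SS
#' synergy: both flanking 5'SS functional (`5i3e5`), upstream only (`5i3eX`),
#' downstream only (`Xi3e5`), or neither (`Xi3eX`). All four retain an intact
#' branch site / 3'SS block.
#'
#' @return A named list of [construct_spec()] objects.
#' @export
panel_cross_intron_exon <- function() {
  list(
    `5i3` = construct_spec("5i3",
      upstream_5ss = TRUE, downstream_5ss = FALSE,
      bs_3ss = TRUE, spliceable = TRUE
    ),
    `3e5` = construct_spec("3e5",
      upstream_5ss = FALSE, downstream_5ss = TRUE,
      bs_3ss = TRUE, spliceable = FALSE
    )
  )
}

#' @rdname panel_cross_intron_exon
#' @export
panel_double_5ss <- function() {
  list(
    `5i3e5` = construct_spec("5i3e5",
      upstream_5ss = TRUE, downstream_5ss = TRUE,
      bs_3ss = TRUE, spliceable = TRUE
    ),
    `5i3eX` = construct_spec("5i3eX",
      upstream_5ss = TRUE, downstream_5ss = FALSE,
      bs_3ss = TRUE, spliceable = TRUE
    ),
    `Xi3e5` = construct_spec("Xi3e5",
      upstream_5ss = FALSE, downstream_5ss = TRUE,
      bs_3ss = TRUE, spliceable = FALSE
    ),
    `Xi3eX` = construct_spec("Xi3eX",
      upstream_5ss = FALSE, downstream_5ss = FALSE,
      bs_3ss = TRUE, spliceable = FALSE
    )
  )
}

#' Ground-truth kinetic parameters for the simulator
#'
#' Houses the mechanistic quantities the analysis pipeline estimates. Rates
#' are per surface location per second; dwell times are drawn from an
#' exponential mixture with a short-lived (seconds) and a long-lived (tens of
#' seconds and longer) class. A fluorophore survives an exponentially
#' distributed amount of *green-excitation exposure* before photobleaching.
#'
#' `k_assoc_specific` is the sequence-specific association rate contributed by
#' a single functional 5' splice site; [resolve_association_rate()] maps a
#' construct's flags (and the `synergy_factor`) to the realized rate.
#'
#' @param subcomplex Which labeled subcomplex the parameters describe:
#'   `"U1"`, `"U2"`, or `"U5"`.
#' @param k_assoc_specific Specific association rate per functional 5'SS
#'   (events/location/s).
#' @param dwell_mixture Data frame with columns `weight` and `mean_s`; weights
#'   must sum to 1.
#' @param k_assoc_nonspecific Nonspecific (surface) binding rate, identical at
#'   all locations including no-RNA controls (events/location/s).
#' @param nonspecific_mean_dwell Mean dwell of nonspecific events (s).
#' @param labeling_fraction Probability that a given subcomplex copy carries a
#'   dye. Only labeled events are visible.
#' @param bleach_rate Photobleaching rate per second of green exposure.
#' @param synergy_factor Multiplier on the U2/U5 association rate when both
#'   flanking 5'SS are functional.
#' @param frac_active Fraction of RNA locations competent for specific
#'   binding.
#'
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(subcomplex = c("U2", "U1", "U5"),
                           k_assoc_specific = NULL,
                           dwell_mixture = NULL,
                           k_assoc_nonspecific = 2e-4,
                           nonspecific_mean_dwell = 2.5,
                           labeling_fraction = NULL,
                           bleach_rate = 2e-4,
                           synergy_factor = 3,
                           frac_active = 0.75) {
  subcomplex <- match.arg(subcomplex)
  defaults <- list(
    # Association rates and mixtures: U1 sampling is fast and short-lived-
    # dominated; U2/U5 are progressively slower. Labeling fractions follow the
    # measured fractions of dye-carrying subcomplex pools (30%, 60%, 50%).
    U1 = list(k = 4e-3, mix = data.frame(weight = c(0.8, 0.2), mean_s = c(3, 90)), lab = 0.30),
    U2 = list(k = 5e-4, mix = data.frame(weight = c(0.7, 0.3), mean_s = c(5, 60)), lab = 0.60),
    U5 = list(k = 3e-4, mix = data.frame(weight = c(0.7, 0.3), mean_s = c(5, 60)), lab = 0.50)
  )[[subcomplex]]
  if (is.null(k_assoc_specific)) k_assoc_specific <- defaults$k
  if (is.null(dwell_mixture)) dwell_mixture <- defaults$mix
  if (is.null(labeling_fraction)) labeling_fraction <- defaults$lab

  dwell_mixture <- as.data.frame(dwell_mixture)
  stopifnot(
    all(c("weight", "mean_s") %in% names(dwell_mixture)),
    nrow(dwell_mixture) >= 1,
    all(dwell_mixture$weight >= 0),
    all(dwell_mixture$mean_s > 0)
  )
  if (abs(sum(dwell_mixture$weight) - 1) > 1e-8) {
    stop("dwell_mixture weights must sum to 1", call. = FALSE)
  }
  stopifnot(
    k_assoc_specific >= 0, is.finite(k_assoc_specific),
    k_assoc_nonspecific >= 0, is.finite(k_assoc_nonspecific),
    nonspecific_mean_dwell > 0,
    labeling_fraction >= 0, labeling_fraction <= 1,
    bleach_rate >= 0,
    synergy_factor >= 0,
    frac_active >= 0, frac_active <= 1
  )
  structure(
    list(
      subcomplex = subcomplex,
      k_assoc_specific = k_assoc_specific,
      dwell_mixture = dwell_mixture,
      k_assoc_nonspecific = k_assoc_nonspecific,
      nonspecific_mean_dwell = nonspecific_mean_dwell,
      labeling_fraction = labeling_fraction,
      bleach_rate = bleach_rate,
      synergy_factor = synergy_factor,
      frac_active = frac_active
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> %s: k_spec=%g /s/site, k_ns=%g /s, labeling=%g, bleach=%g /green-s, synergy=%g, active=%g\n",
    x$subcomplex, x$k_assoc_specific, x$k_assoc_nonspecific,
    x$labeling_fraction, x$bleach_rate, x$synergy_factor, x$frac_active
  ))
  print(x$dwell_mixture, row.names = FALSE)
  invisible(x)
}

#' Resolve the specific association rate for a construct
#'
#' Encodes how splice-site elements gate recruitment of each subcomplex:
#' * U1 binds functional 5' splice sites directly; its rate is
#'   `k_assoc_specific` times the number of functional 5'SS.
#' * U2 (and U5, which requires the same pre-spliceosome) binds the branch
#'   site / 3'SS region only when that block is intact *and* at least one
#'   flanking 5'SS is functional; each functional 5'SS contributes
#'   `k_assoc_specific`, and when both flanking sites are present the summed
#'   rate is additionally multiplied by `synergy_factor`. With equal
#'   single-site rates the frequency ratio
#'   `f_both / (f_up + f_down)` therefore recovers `synergy_factor`.
#'
#' @param construct A [construct_spec()].
#' @param params A [kinetic_params()].
#' @return Specific association rate (events/location/s).
#' @export
#' @examples
#' p <- kinetic_params("U2", synergy_factor = 3)
#' both <- construct_spec("both", upstream_5ss = TRUE, downstream_5ss = TRUE)
#' resolve_association_rate(both, p) / p$k_assoc_specific # 6 = 2 sites x synergy 3
resolve_association_rate <- function(construct, params) {
  stopifnot(inherits(construct, "construct_spec"), inherits(params, "kinetic_params"))
  n_sites <- sum(construct$upstream_5ss, construct$downstream_5ss)
  if (params$subcomplex == "U1") {
    return(params$k_assoc_specific * n_sites)
  }
  # U2 / U5: need intact BS/3'SS and at least one functional 5'SS
  if (!construct$bs_3ss || n_sites == 0L) {
    return(0)
  }
  rate <- params$k_assoc_specific * n_sites
  if (n_sites == 2L) rate <- rate * params$synergy_factor
  rate
}

# Mean of the dwell mixture (s).
mixture_mean_dwell <- function(params) {
  sum(params$dwell_mixture$weight * params$dwell_mixture$mean_s)
}

# Draw n dwell times from the exponential mixture.
sample_dwell_mixture <- function(params, n) {
  if (n == 0L) {
    return(numeric(0))
  }
  comp <- sample.int(nrow(params$dwell_mixture),
    size = n, replace = TRUE,
    prob = params$dwell_mixture$weight
  )
  stats::rexp(n, rate = 1 / params$dwell_mixture$mean_s[comp])
}

# Mixture survival function P(dwell >= t), vectorized over t.
mixture_survival <- function(params, t) {
  w <- params$dwell_mixture$weight
  m <- params$dwell_mixture$mean_s
  vapply(t, function(ti) sum(w * exp(-ti / m)), numeric(1))
}
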