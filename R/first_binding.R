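#' Times to first binding event per location
#'
#' For every location of the construct, the start time of its earliest
#' interval; locations that never bind are censored at the end of their
#' observation window. These right-censored observations must be kept — the
#' fraction of never-binding molecules is exactly what the amplitude of the
#' first-binding model estimates.
#'
#' @param table An [intervals_table()].
#' @param construct Construct name.
#' @return Tibble with columns `location_id`, `time_s`, `observed`.
#' @export
first_binding_times <- function(table, construct) {
  stopifnot(inherits(table, "intervals_table"))
  loc <- table$locations[table$locations$construct == construct, , drop = FALSE]
  if (nrow(loc) == 0) {
    stop("construct not present in table: ", construct, call. = FALSE)
  }
  iv <- table$intervals[table$intervals$location_id %in% loc$location_id, , drop = FALSE]
  first <- as.numeric(tapply(
    iv$start_s, factor(iv$location_id, levels = loc$location_id),
    min,
    default = NA_real_
  ))
  t_end <- table$schedule$total_duration
  tibble::tibble(
    location_id = loc$location_id,
    time_s = unname(ifelse(is.na(first), t_end, first)),
    observed = !is.na(first)
  )
}

#' Fit the background-corrected single-exponential first-binding model
#'
#' Models the cumulative fraction of locations that have shown a first event
#' by time `t` as
#' \deqn{P(t) = A_f (1 - e^{-(k_f + k_{bg}) t}) + (1 - A_f)(1 - e^{-k_{bg} t})}
#' where `A_f` is the fraction of locations competent for specific binding,
#' `k_f` the specific first-binding rate, and `k_bg` the background
#' (nonspecific) event rate. `k_bg` is estimated first from the control
#' locations as a censored single-exponential maximum-likelihood rate
#' (`events / total observed waiting time`) and held fixed; `A_f` and `k_f`
#' are then fit by maximum likelihood in which censored locations contribute
#' survival terms `1 - P(t)`.
#'
#' @param times Tibble from [first_binding_times()] for the RNA construct, or
#'   a numeric vector of times with `observed` given separately.
#' @param observed Logical vector when `times` is numeric.
#' @param control Tibble from [first_binding_times()] for the control
#'   locations, or `NULL` to fix `k_bg = 0`.
#'
#' @return A `first_binding_fit`: list with `A_f`, `k_f`, `k_bg`, standard
#'   errors from the observed information, log-likelihood and convergence
#'   diagnostics.
#' @export
fit_first_binding <- function(times, observed = NULL, control = NULL) {
  if (is.data.frame(times)) {
    observed <- times$observed
    times <- times$time_s
  }
  stopifnot(length(times) == length(observed), all(times > 0))
  if (length(times) < 10) {
    stop("need at least 10 locations to fit the first-binding model", call. = FALSE)
  }

  k_bg <- 0
  if (!is.null(control)) {
    if (is.data.frame(control)) {
      k_bg <- censored_exponential_rate(control$time_s, control$observed)
    } else {
      stop("control must be a first_binding_times() tibble or NULL", call. = FALSE)
    }
  }

  if (!any(observed)) {
    warning("no first-binding events observed; amplitude fixed at 0")
    return(structure(
      list(
        A_f = 0, k_f = 0, k_bg = k_bg, A_f_se = NA_real_, k_f_se = NA_real_,
        loglik = 0, converged = TRUE, n = length(times), n_observed = 0
      ),
      class = "first_binding_fit"
    ))
  }

  nll <- function(par) {
    A <- stats::plogis(par[1])
    kf <- exp(par[2])
    ktot <- kf + k_bg
    dens <- A * ktot * exp(-ktot * times) + (1 - A) * k_bg * exp(-k_bg * times)
    surv <- A * exp(-ktot * times) + (1 - A) * exp(-k_bg * times)
    ll <- sum(log(pmax(dens[observed], 1e-300))) +
      sum(log(pmax(surv[!observed], 1e-300)))
    -ll
  }
  p_bound <- mean(observed)
  start <- c(stats::qlogis(min(max(p_bound, 0.05), 0.95)),
    log(max(1 / mean(times[observed]), 1e-6)))
  fit <- stats::optim(start, nll, method = "BFGS", hessian = TRUE)

  A_hat <- stats::plogis(fit$par[1])
  k_hat <- exp(fit$par[2])
  ses <- c(NA_real_, NA_real_)
  vc <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(vc, "try-error") && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
    # delta method back to the natural scale
    ses <- sqrt(diag(vc)) * c(A_hat * (1 - A_hat), k_hat)
  } else {
    # the full Hessian degenerates when A_f saturates; fall back to the
    # per-parameter observed information
    h <- diag(fit$hessian)
    if (is.finite(h[2]) && h[2] > 0) ses[2] <- k_hat / sqrt(h[2])
    if (is.finite(h[1]) && h[1] > 0) ses[1] <- A_hat * (1 - A_hat) / sqrt(h[1])
  }
  structure(
    list(
      A_f = A_hat, k_f = k_hat, k_bg = k_bg,
      A_f_se = ses[1], k_f_se = ses[2],
      loglik = -fit$value, converged = fit$convergence == 0,
      n = length(times), n_observed = sum(observed)
    ),
    class = "first_binding_fit"
  )
}

#' @export
print.first_binding_fit <- function(x, ...) {
  cat(sprintf(
    "<first_binding_fit> A_f=%.3g ± %.2g, k_f=%.3g ± %.2g /s, k_bg=%.3g /s (n=%d, %d bound)\n",
    x$A_f, x$A_f_se, x$k_f, x$k_f_se, x$k_bg, x$n, x$n_observed
  ))
  invisible(x)
}

# Censored-exponential MLE: rate = events / total observed waiting time.
censored_exponential_rate <- function(times, observed) {
  if (sum(times) <= 0 || !any(observed)) {
    return(0)
  }
  sum(observed) / sum(times)
}
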