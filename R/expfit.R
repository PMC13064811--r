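#' Amplitude-weighted time constant
#'
#' The weighted time constant of a double-exponential relaxation,
#' \code{tau_w = (tau_f * A_f + tau_s * A_s) / (A_f + A_s)}. Amplitudes of a
#' single relaxation share sign; \code{tau_w} always lies between the two
#' time constants.
#'
#' @param tau_fast,tau_slow time constants, s (> 0).
#' @param a_fast,a_slow component amplitudes, pA (same sign, nonzero sum).
#' @return weighted time constant, s.
#' @examples
#' weighted_tau(0.1, 3, 0.5, 1) # 0.2
#' @export
weighted_tau <- function(tau_fast, a_fast, tau_slow, a_slow) {
  if (any(c(tau_fast, tau_slow) <= 0)) stop("time constants must be positive")
  if (a_fast * a_slow < 0) stop("amplitudes of one relaxation must share sign")
  if (a_fast + a_slow == 0) stop("degenerate fit: zero total amplitude")
  (tau_fast * a_fast + tau_slow * a_slow) / (a_fast + a_slow)
}

# Small-sample-corrected Akaike information criterion for an nls fit.
aicc <- function(fit, n) {
  k <- length(stats::coef(fit)) + 1  # + residual variance
  aic <- stats::AIC(fit)
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

# One- or two-component exponential fit on (t, y), t starting at 0.
# Returns the nls fit or NULL on failure.
fit_exp_n <- function(t, y, n_comp) {
  span <- max(t)
  y_end <- mean(y[t >= 0.9 * span])
  a0 <- y[1] - y_end
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  if (n_comp == 1) {
    st <- list(A1 = a0, ltau1 = log(span / 5), off = y_end)
    fml <- y ~ off + A1 * exp(-t / exp(ltau1))
  } else {
    st <- list(A1 = 0.6 * a0, ltau1 = log(span / 20),
               A2 = 0.4 * a0, ltau2 = log(span / 3), off = y_end)
    fml <- y ~ off + A1 * exp(-t / exp(ltau1)) + A2 * exp(-t / exp(ltau2))
  }
  tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y), start = st,
                      control = ctrl),
    error = function(e) NULL
  )
}

#' Exponential decomposition of a trace segment
#'
#' Least-squares fit of \code{offset + sum_i A_i exp(-t/tau_i)} to the
#' current within a named epoch. The component count (1 or 2) is chosen by
#' small-sample-corrected AIC, with the second component accepted only when
#' \code{tau_slow / tau_fast >= 2} and both amplitude fractions are at least
#' 5%; otherwise the single-exponential fit is kept. The weighted time
#' constant (amplitude-weighted mean of the two taus) is reported; for a
#' single component it equals that component's tau.
#'
#' @param trace a [current_trace()], or a data.frame with columns
#'   \code{time_s} and \code{current_pA} (then \code{window} is ignored).
#' @param window epoch name delimiting the fitted segment.
#' @param max_components 1 or 2.
#' @param start_offset_s time after epoch start at which the fit begins
#'   (default 0).
#' @return object of class \code{"exp_fit"}: list with \code{tau_fast},
#'   \code{tau_slow}, \code{a_fast}, \code{a_slow}, \code{tau_w},
#'   \code{n_components}, \code{offset}, \code{rss}, \code{converged},
#'   \code{short_window} (TRUE when the window is shorter than 3 fitted
#'   tau_fast ... a reliability flag), and \code{window}.
#' @export
fit_exponential <- function(trace, window = NULL, max_components = 2,
                            start_offset_s = 0) {
  if (inherits(trace, "current_trace")) {
    if (is.null(window)) stop("window (epoch name) required for a trace")
    ep <- get_epoch(trace, window)
    sel <- epoch_window(trace, ep) &
      trace$time >= ep$start_s + start_offset_s
    t <- trace$time[sel]
    y <- trace$current[sel]
  } else {
    t <- trace$time_s
    y <- trace$current_pA
    window <- window %||% "segment"
  }
  if (length(t) < 20) stop("fit window must contain at least 20 samples")
  t <- t - t[1]
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * (1 + abs(mean(y)))) {
    stop("degenerate fit: no relaxation in window (flat signal)")
  }
  if (!max_components %in% c(1, 2)) stop("max_components must be 1 or 2")

  f1 <- fit_exp_n(t, y, 1)
  if (is.null(f1)) stop("fit failure: single-exponential fit did not converge")
  use2 <- FALSE
  f2 <- NULL
  if (max_components == 2) {
    f2 <- fit_exp_n(t, y, 2)
    if (!is.null(f2)) {
      cf <- stats::coef(f2)
      taus <- exp(cf[c("ltau1", "ltau2")])
      amps <- cf[c("A1", "A2")]
      fr <- abs(amps) / sum(abs(amps))
      same_sign <- amps[1] * amps[2] > 0
      sep <- max(taus) / min(taus)
      use2 <- same_sign && sep >= 2 && all(fr >= 0.05) &&
        aicc(f2, length(t)) < aicc(f1, length(t))
    }
  }
  if (use2) {
    cf <- stats::coef(f2)
    ord <- order(exp(cf[c("ltau1", "ltau2")]))
    taus <- exp(cf[c("ltau1", "ltau2")])[ord]
    amps <- unname(cf[c("A1", "A2")][ord])
    res <- list(tau_fast = unname(taus[1]), tau_slow = unname(taus[2]),
                a_fast = amps[1], a_slow = amps[2],
                tau_w = unname(weighted_tau(taus[1], amps[1],
                                            taus[2], amps[2])),
                n_components = 2L, offset = unname(cf["off"]),
                rss = sum(stats::residuals(f2)^2), converged = TRUE)
  } else {
    cf <- stats::coef(f1)
    tau <- unname(exp(cf["ltau1"]))
    amp <- unname(cf["A1"])
    if (abs(amp) < 1e-9 * (1 + abs(cf["off"]))) {
      stop("degenerate fit: vanishing relaxation amplitude")
    }
    res <- list(tau_fast = tau, tau_slow = tau,
                a_fast = amp, a_slow = 0,
                tau_w = tau, n_components = 1L, offset = unname(cf["off"]),
                rss = sum(stats::residuals(f1)^2), converged = TRUE)
  }
  res$short_window <- max(t) < 3 * res$tau_fast
  res$window <- window
  class(res) <- "exp_fit"
  res
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("Exponential fit (%s): %d component(s)\n",
              x$window, x$n_components))
  if (x$n_components == 2) {
    cat(sprintf("  tau_fast = %.4g s (A = %.4g pA)\n", x$tau_fast, x$a_fast))
    cat(sprintf("  tau_slow = %.4g s (A = %.4g pA)\n", x$tau_slow, x$a_slow))
  }
  cat(sprintf("  tau_w = %.4g s, offset = %.4g pA, rss = %.4g\n",
              x$tau_w, x$offset, x$rss))
  if (isTRUE(x$short_window)) {
    cat("  warning: window shorter than 3 x tau_fast\n")
  }
  invisible(x)
}

#' @export
coef.exp_fit <- function(object, ...) {
  c(tau_fast = object$tau_fast, tau_slow = object$tau_slow,
    a_fast = object$a_fast, a_slow = object$a_slow,
    tau_w = object$tau_w, offset = object$offset)
}

#' MK-801 (or other blocker) onset kinetics
#'
#' Fits the current decay during the blocker epoch with [fit_exponential()].
#' The current is first normalized to the mean of the 100 ms preceding
#' blocker onset, so the fitted relaxation starts near 1. This is the
#' tau_w-MK-801 measurement.
#'
#' @param trace a [current_trace()] with a "blocker" epoch applied during a
#'   steady agonist response.
#' @param blocker_epoch epoch name (default "blocker").
#' @param max_components 1 or 2.
#' @param start_offset_s skip this much time after blocker onset before
#'   fitting (e.g. to exclude the solution-exchange ramp); default 0.
#' @return an \code{"exp_fit"} (amplitudes in normalized units).
#' @export
blocker_onset_tau <- function(trace, blocker_epoch = "blocker",
                              max_components = 2, start_offset_s = 0) {
  stopifnot(inherits(trace, "current_trace"))
  ep <- get_epoch(trace, blocker_epoch)
  pre <- trace$time < ep$start_s & trace$time >= ep$start_s - 0.1
  if (!any(pre)) stop("no pre-blocker baseline available for normalization")
  ref <- mean(trace$current[pre])
  if (abs(ref) < 1e-12) stop("degenerate fit: no steady current to block")
  sel <- epoch_window(trace, ep) &
    trace$time >= ep$start_s + start_offset_s
  seg <- data.frame(time_s = trace$time[sel],
                    current_pA = trace$current[sel] / ref)
  if (stats::sd(seg$current_pA) < 1e-6) {
    stop("degenerate fit: no decay during blocker epoch")
  }
  fit <- fit_exponential(seg, window = blocker_epoch,
                         max_components = max_components)
  fit
}

#' Memantine onset and offset time constants
#'
#' Onset: exponential fit of the decay during the blocker epoch (normalized
#' to the pre-blocker steady current). Offset: exponential fit of the
#' recovery after blocker removal during continued agonist. If no wash
#' segment follows the blocker epoch, \code{tau_off} is \code{NA} and the
#' result is flagged partial.
#'
#' @param trace a [current_trace()].
#' @param blocker_epoch epoch name (default "blocker").
#' @param min_wash_s minimum post-blocker span required for the offset fit, s.
#' @return list with \code{tau_on}, \code{tau_off} (s; \code{NA} when
#'   unavailable), the two \code{"exp_fit"} objects (\code{on_fit},
#'   \code{off_fit}) and \code{partial} flag.
#' @export
memantine_kinetics <- function(trace, blocker_epoch = "blocker",
                               min_wash_s = 0.25) {
  stopifnot(inherits(trace, "current_trace"))
  on_fit <- blocker_onset_tau(trace, blocker_epoch)
  ep <- get_epoch(trace, blocker_epoch)
  t_end <- trace$time[length(trace$time)]
  # recovery fitted over any agonist time remaining after blocker removal
  ag <- tryCatch(get_epoch(trace, "agonist"), error = function(e) NULL)
  wash_end <- if (!is.null(ag)) min(ag$end_s, t_end) else t_end
  if (wash_end - ep$end_s < min_wash_s) {
    return(list(tau_on = on_fit$tau_w, tau_off = NA_real_,
                on_fit = on_fit, off_fit = NULL, partial = TRUE))
  }
  sel <- trace$time >= ep$end_s & trace$time <= wash_end
  seg <- data.frame(time_s = trace$time[sel],
                    current_pA = trace$current[sel])
  off_fit <- fit_exponential(seg, window = "wash")
  list(tau_on = on_fit$tau_w, tau_off = off_fit$tau_w,
       on_fit = on_fit, off_fit = off_fit, partial = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
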