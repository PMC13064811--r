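#' Estimate NMDAR open probability from MK-801 blocking kinetics
#'
#' Implements the kinetic-model-based estimation of microscopic open
#' probability. The procedure, per cell:
#' \enumerate{
#'   \item From the agonist response, measure the peak current, steady-state
#'     current and the desensitization-onset time constant \code{tau_d}
#'     (single-exponential fit from the peak).
#'   \item Fit the opening rate \code{ko} by simulating the
#'     D <-> C <-> O -> B scheme from the pre-blocker steady state and
#'     matching the normalized open-state decay \code{O(t)/O(0)} to the
#'     observed current decay during the blocker epoch, normalized to the
#'     mean current over the 100 ms before blocker onset. Desensitization and
#'     resensitization rates are tied to the measured steady-state/peak ratio
#'     and \code{tau_d} through the scheme's own steady-state relations at
#'     each candidate \code{ko} (see Details).
#'   \item Report \code{Po = ko / (ko + kc)}.
#' }
#'
#' @details
#' The measured ratio \code{R = Imax/Ipeak} reflects the equilibrium of the
#' full D <-> C <-> O subsystem relative to the pre-desensitization
#' quasi-equilibrium peak, so \code{R = (1 + ko/kc) / (1 + ko/kc + kd/kr)}.
#' Given a candidate \code{ko} the ratio is inverted for \code{kd/kr}, and
#' \code{kd + kr = 1/tau_d} fixes both rates. The peak used for \code{R} is
#' the fitted desensitization exponential extrapolated back to the moment the
#' agonist concentration is established (epoch start plus the
#' solution-exchange time constant), which removes the attenuation caused by
#' finite solution exchange. \code{ko} is searched deterministically on a
#' log scale over \[1e-2, 1e4\] 1/s (decade-spaced scan, then golden-section
#' refinement).
#'
#' @param trace a [current_trace()] with "agonist" and "blocker" epochs.
#' @param kc closing rate, 1/s (default 250).
#' @param kb blocking rate, 1/(uM s) (default 25, MK-801).
#' @param blocker_conc blocker concentration, uM; taken from the blocker
#'   epoch's \code{conc_um} when present, else this argument (default 1).
#' @param exchange_tau solution-exchange time constant of the application
#'   system, s (default 0.017).
#' @param n_fit_points maximum number of (decimated) samples used in the
#'   least-squares objective.
#' @return object of class \code{"po_fit"} with elements \code{po},
#'   \code{ko_hat}, \code{residual_norm} (RSS of the normalized decay fit),
#'   \code{converged}, \code{boundary} (TRUE when \code{ko} hit the search
#'   bound), \code{desens} (extent, kd, kr, tau_d at the fitted \code{ko}),
#'   \code{kc}, \code{kb_eff}, and the fitted decay (\code{t}, \code{obs},
#'   \code{fitted}).
#' @examples
#' \donttest{
#' tr <- generate_trace(po = 0.066, seed = 1)
#' fit <- estimate_po(tr)
#' fit$po
#' }
#' @export
estimate_po <- function(trace, kc = 250, kb = 25, blocker_conc = 1,
                        exchange_tau = 0.017, n_fit_points = 400) {
  stopifnot(inherits(trace, "current_trace"))
  if (kc <= 0 || kb <= 0) stop("kc and kb must be positive")
  bl <- get_epoch(trace, "blocker")
  if (!is.null(bl$conc_um) && !is.na(bl$conc_um)) blocker_conc <- bl$conc_um
  if (blocker_conc <= 0) stop("no block to fit: blocker concentration is zero")
  kb_eff <- kb * blocker_conc

  des <- measure_desensitization(trace, exchange_tau = exchange_tau,
                                 until_s = bl$start_s)

  # observed normalized decay during the blocker epoch
  pre <- trace$time < bl$start_s & trace$time >= bl$start_s - 0.1
  ref <- mean(trace$current[pre])
  if (abs(ref) < 1e-9) stop("no steady pre-blocker current to normalize by")
  sel <- epoch_window(trace, bl)
  t_obs <- trace$time[sel] - bl$start_s
  y_obs <- trace$current[sel] / ref
  if (stats::sd(y_obs) < 1e-7) stop("no block to fit: flat blocker epoch")
  keep <- unique(round(seq(1, length(t_obs),
                           length.out = min(n_fit_points, length(t_obs)))))
  t_fit <- t_obs[keep]
  y_fit <- y_obs[keep]
  if (t_fit[1] <= 0) {
    t_fit[1] <- min(1e-6, t_fit[2] / 2)
  }

  obj <- function(log10_ko) {
    ko <- 10^log10_ko
    sch <- scheme_at_ko(ko, kc, kb_eff, des)
    sim <- simulate_blocker_onset(sch, t_fit, exchange_tau = exchange_tau)
    o0 <- steady_state_unblocked(sch)[["o"]]
    sum((y_fit - sim$O / o0)^2)
  }

  lo <- -2; hi <- 4
  grid <- seq(lo, hi, by = 0.5)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(obj, interval = bracket, tol = 1e-6)
  ko_hat <- 10^opt$minimum
  boundary <- opt$minimum <= lo + 1e-3 || opt$minimum >= hi - 1e-3

  sch <- scheme_at_ko(ko_hat, kc, kb_eff, des)
  sim <- simulate_blocker_onset(sch, t_fit, exchange_tau = exchange_tau)
  fitted <- sim$O / steady_state_unblocked(sch)[["o"]]

  structure(list(
    po = po_from_ko(ko_hat, kc),
    ko_hat = ko_hat,
    residual_norm = opt$objective,
    converged = is.finite(opt$objective) && !boundary,
    boundary = boundary,
    desens = list(extent_D = sch$kd * des$tau_d,
                  kd = sch$kd, kr = sch$kr, tau_d = des$tau_d,
                  i_peak = des$i_peak, i_max = des$i_max),
    kc = kc, kb_eff = kb_eff, exchange_tau = exchange_tau,
    decay = data.frame(t = t_fit, obs = y_fit, fitted = fitted)
  ), class = "po_fit")
}

#' Measure desensitization observables from an agonist response
#'
#' Peak and steady-state currents plus the single-exponential
#' desensitization time constant, as consumed by [estimate_po()]. The
#' exponential fit starts a few exchange time constants after the measured
#' peak (where the solution-exchange convolution has died away) and the peak
#' is the fitted exponential extrapolated back to agonist establishment,
#' undoing the attenuation caused by finite solution exchange.
#'
#' @param trace a [current_trace()] with an "agonist" epoch.
#' @param exchange_tau solution-exchange time constant, s.
#' @param until_s truncate the fitted segment at this absolute time (use the
#'   blocker onset to keep the segment block-free).
#' @return list with \code{i_peak}, \code{i_max} (baseline-subtracted, pA),
#'   \code{tau_d} (s; \code{NA} when no measurable desensitization),
#'   \code{ratio} (= |i_max| / |i_peak|), \code{baseline} and \code{t_peak}.
#' @export
measure_desensitization <- function(trace, exchange_tau, until_s = Inf) {
  ps <- measure_peak_steady(trace)
  ag <- get_epoch(trace, "agonist")
  seg_end <- min(until_s, ag$end_s)
  # start the exponential fit after the solution-exchange convolution has
  # died away, so tau_d is uncontaminated; extrapolate amplitudes back
  t_start <- ps$t_peak + 4 * exchange_tau
  sel <- trace$time >= t_start & trace$time <= seg_end
  i_peak <- ps$i_peak
  i_max <- ps$i_max
  tau_d <- NA_real_
  ratio <- abs(i_max) / abs(i_peak)
  if (ratio < 0.98 && sum(sel) >= 20) {
    t_s <- trace$time[sel][1]
    seg <- data.frame(time_s = trace$time[sel],
                      current_pA = trace$current[sel] - ps$baseline)
    fit <- tryCatch(fit_exponential(seg, window = "desensitization",
                                    max_components = 1),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      tau_d <- fit$tau_w
      # extrapolate the fitted exponential back to agonist establishment
      # (epoch start plus the exchange group delay)
      t_ref <- ag$start_s + exchange_tau
      a_back <- fit$a_fast * exp((t_s - t_ref) / tau_d)
      i_peak_c <- fit$offset + a_back
      if (abs(i_peak_c) >= abs(i_max)) i_peak <- i_peak_c
      i_max <- fit$offset
    }
  }
  list(i_peak = i_peak, i_max = i_max, tau_d = tau_d,
       ratio = abs(i_max) / abs(i_peak), baseline = ps$baseline,
       t_peak = ps$t_peak)
}

# Scheme with kd, kr tied to the measured desensitization observables at a
# candidate ko. Two measured quantities pin the two free rates:
#   * steady/peak ratio R = (1 + ko/kc) / (1 + ko/kc + kd/kr)
#     (equilibrium of D <-> C <-> O over the C <-> O quasi-equilibrium peak),
#   * observed relaxation rate s = 1/tau_d, the slow eigenvalue of the
#     D <-> C <-> O system: s^2 - s (kr + kd + ko + kc)
#     + (kr kc + kr ko + kd kc) = 0.
# Solving with q = kd/kr fixed by R gives kr in closed form.
scheme_at_ko <- function(ko, kc, kb_eff, des) {
  r <- ko / kc
  if (is.na(des$tau_d) || des$ratio >= 0.98) {
    kd <- 0
    kr <- 1
  } else {
    q <- (1 + r) * (1 - des$ratio) / des$ratio  # kd / kr
    s <- 1 / des$tau_d
    denom <- kc + ko + q * kc - s * (1 + q)
    if (denom <= 0) {
      # relaxation faster than the gating step allows; fall back to the
      # slow-desensitization limit kd + kr = s
      kr <- s / (1 + q)
    } else {
      kr <- s * (ko + kc - s) / denom
    }
    kd <- q * kr
  }
  gating_scheme(kd = kd, kr = kr, ko = ko, kc = kc, kb = kb_eff,
                blocker_conc = 1)
}

#' @export
print.po_fit <- function(x, ...) {
  cat("Open-probability estimate from blocking kinetics\n")
  cat(sprintf("  Po = %.4f  (ko = %.4g /s, kc = %g /s)\n",
              x$po, x$ko_hat, x$kc))
  cat(sprintf("  desensitization extent D = %.3f, tau_d = %.4g s\n",
              x$desens$extent_D, x$desens$tau_d))
  cat(sprintf("  residual norm %.4g; converged: %s%s\n", x$residual_norm,
              x$converged, if (x$boundary) " (ko at search bound)" else ""))
  invisible(x)
}

#' @export
summary.po_fit <- function(object, ...) {
  cat("Kinetic-scheme fit of MK-801 blocking onset\n")
  print(object)
  cat(sprintf("  kd = %.4g /s, kr = %.4g /s, kb' = %g /s\n",
              object$desens$kd, object$desens$kr, object$kb_eff))
  cat(sprintf("  fitted over %d points spanning %.3g s\n",
              nrow(object$decay), max(object$decay$t)))
  invisible(object)
}

#' @export
coef.po_fit <- function(object, ...) {
  c(po = object$po, ko = object$ko_hat, kc = object$kc,
    kd = object$desens$kd, kr = object$desens$kr)
}

#' @export
predict.po_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) return(object$decay$fitted)
  sch <- gating_scheme(kd = object$desens$kd, kr = object$desens$kr,
                       ko = object$ko_hat, kc = object$kc,
                       kb = object$kb_eff, blocker_conc = 1)
  sim <- simulate_blocker_onset(sch, t, exchange_tau = object$exchange_tau)
  sim$O / steady_state_unblocked(sch)[["o"]]
}

#' @export
residuals.po_fit <- function(object, ...) {
  object$decay$obs - object$decay$fitted
}

#' @export
plot.po_fit <- function(x, ...) {
  plot(x$decay$t, x$decay$obs, pch = ".", col = "grey40",
       xlab = "time from blocker onset (s)",
       ylab = "normalized current", ...)
  graphics::lines(x$decay$t, x$decay$fitted, col = "red", lwd = 2)
  graphics::legend("topright", bty = "n",
                   legend = sprintf("Po = %.3f", x$po))
  invisible(x)
}

#' Po recovery validation over a grid of true values
#'
#' Generates synthetic recordings at each requested open probability (via
#' [generate_trace()]), runs [estimate_po()] on each, and tabulates the
#' median recovered Po and relative error. Deterministic given \code{seed}.
#'
#' @param po_grid true open probabilities, fractions in (0, 0.5].
#' @param noise_sigma recording noise sd as a fraction of the peak current.
#' @param n_reps replicates per grid point (>= 1).
#' @param seed integer seed.
#' @param ... further arguments passed to [generate_trace()].
#' @return data.frame with columns \code{true_po}, \code{median_po},
#'   \code{median_rel_error}, \code{n}.
#' @export
po_recovery_report <- function(po_grid, noise_sigma = 0.02, n_reps = 10,
                               seed = 1, ...) {
  if (length(po_grid) == 0) stop("po_grid must be non-empty")
  if (any(po_grid <= 0 | po_grid > 0.5)) {
    stop("po_grid values must lie in (0, 0.5]")
  }
  rows <- lapply(seq_along(po_grid), function(i) {
    po <- po_grid[i]
    est <- vapply(seq_len(n_reps), function(r) {
      tr <- generate_trace(po = po, noise_sigma = noise_sigma,
                           seed = seed + 1000L * i + r, ...)
      estimate_po(tr)$po
    }, numeric(1))
    data.frame(true_po = po, median_po = stats::median(est),
               median_rel_error = stats::median(abs(est - po) / po),
               n = n_reps)
  })
  do.call(rbind, rows)
}
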