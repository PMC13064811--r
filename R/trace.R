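#' Whole-cell current trace with application epochs
#'
#' Bundles a uniformly sampled current recording with named solution
#' application windows (epochs). Epochs carry the applied solution
#' (\code{"agonist"}, \code{"blocker"}, \code{"wash"}) and optional
#' concentration; the same solution may not have overlapping windows.
#'
#' @param time time points, s, uniformly sampled and strictly increasing.
#' @param current current, pA (inward currents negative).
#' @param epochs data.frame with columns \code{name}, \code{start_s},
#'   \code{end_s}, \code{solution} and optionally \code{conc_um}.
#' @param sampling_rate sampling rate, Hz; inferred from \code{time} when
#'   missing.
#' @param meta optional list of annotations (e.g. generator ground truth).
#' @return object of class \code{"current_trace"}.
#' @export
current_trace <- function(time, current, epochs, sampling_rate = NULL,
                          meta = list()) {
  if (length(time) != length(current) || length(time) < 2) {
    stop("time and current must have equal length >= 2")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) stop("time must be uniformly sampled")
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  req <- c("name", "start_s", "end_s", "solution")
  if (!is.data.frame(epochs) || !all(req %in% names(epochs))) {
    stop("epochs must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (any(epochs$end_s <= epochs$start_s)) {
    stop("each epoch must have end_s > start_s")
  }
  if (any(epochs$start_s < time[1] - 1e-9) ||
      any(epochs$end_s > time[length(time)] + 1e-9)) {
    stop("epochs must lie within the recorded time span")
  }
  for (sol in unique(epochs$solution)) {
    e <- epochs[epochs$solution == sol, , drop = FALSE]
    e <- e[order(e$start_s), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)] - 1e-9)) {
      stop("overlapping epochs for solution '", sol, "'")
    }
  }
  structure(list(time = time, current = current, epochs = epochs,
                 sampling_rate = sampling_rate, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples at %.6g Hz, %.3f-%.3f s\n",
              length(x$time), x$sampling_rate, x$time[1],
              x$time[length(x$time)]))
  cat(sprintf("  current range [%.4g, %.4g] pA\n",
              min(x$current), max(x$current)))
  for (i in seq_len(nrow(x$epochs))) {
    e <- x$epochs[i, ]
    cat(sprintf("  epoch %-10s %s  %.3f-%.3f s%s\n", e$name,
                e$solution, e$start_s, e$end_s,
                if (!is.null(e$conc_um) && !is.na(e$conc_um))
                  sprintf("  %g uM", e$conc_um) else ""))
  }
  invisible(x)
}

# Epoch lookup; errors with a missing-epoch message when absent.
get_epoch <- function(trace, name) {
  idx <- which(trace$epochs$name == name)
  if (length(idx) == 0) stop("missing epoch '", name, "' in trace")
  trace$epochs[idx[1], , drop = FALSE]
}

# Logical index of samples within [start, end].
epoch_window <- function(trace, epoch) {
  trace$time >= epoch$start_s - 1e-12 & trace$time <= epoch$end_s + 1e-12
}

# Centered moving mean used to suppress single-sample noise spikes before
# peak detection; width in seconds.
moving_mean <- function(x, width_s, sampling_rate) {
  k <- max(1L, round(width_s * sampling_rate))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= length(x)) return(rep(mean(x), length(x)))
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Peak and steady-state current of an agonist response
#'
#' Baseline (mean of the 200 ms preceding the epoch, or the available
#' pre-epoch span) is subtracted; the peak is the extremum of the 2-ms
#' moving-mean-smoothed current within the epoch, and the steady state is the
#' mean over the final 10% of the epoch (at least 100 ms). Sign convention:
#' inward currents are negative and comparisons use magnitudes.
#'
#' @param trace a [current_trace()].
#' @param agonist_epoch epoch name (default "agonist").
#' @return list with \code{i_peak}, \code{i_max}, \code{t_peak} (s),
#'   \code{baseline} (pA) and \code{below_noise} flag (peak indistinguishable
#'   from baseline noise).
#' @export
measure_peak_steady <- function(trace, agonist_epoch = "agonist") {
  stopifnot(inherits(trace, "current_trace"))
  ep <- get_epoch(trace, agonist_epoch)
  win <- epoch_window(trace, ep)
  if (sum(win) < 100) stop("agonist epoch too short for peak/steady analysis")
  pre <- trace$time < ep$start_s & trace$time >= ep$start_s - 0.2
  baseline <- if (any(pre)) mean(trace$current[pre]) else 0
  base_sd <- if (sum(pre) > 2) stats::sd(trace$current[pre]) else 0
  i <- trace$current[win] - baseline
  sm <- moving_mean(i, 0.002, trace$sampling_rate)
  pk_idx <- which.max(abs(sm))
  i_peak <- sm[pk_idx]
  t_all <- trace$time[win]
  steady_len <- max(0.1, 0.1 * (ep$end_s - ep$start_s))
  steady <- t_all >= ep$end_s - steady_len
  i_max <- mean(i[steady])
  if (abs(i_max) > abs(i_peak)) i_peak <- i_max  # monotone-rise traces
  list(i_peak = i_peak, i_max = i_max, t_peak = t_all[pk_idx],
       baseline = baseline,
       below_noise = abs(i_peak) < 3 * base_sd)
}
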