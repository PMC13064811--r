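#' Dose-response series
#'
#' A set of (concentration, normalized response) pairs for either agonist
#' activation or antagonist inhibition.
#'
#' @param concentrations concentrations, uM; strictly positive and unique.
#' @param responses normalized current responses (dimensionless).
#' @param response_type "activation" or "inhibition".
#' @return object of class \code{"dose_response_series"}.
#' @export
dose_response_series <- function(concentrations, responses,
                                 response_type = c("activation",
                                                   "inhibition")) {
  response_type <- match.arg(response_type)
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length")
  }
  if (length(concentrations) < 4) {
    stop("at least 4 concentration points are required")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (anyDuplicated(concentrations)) stop("concentrations must be unique")
  structure(list(concentrations = concentrations, responses = responses,
                 response_type = response_type),
            class = "dose_response_series")
}

# Hill curves of activation / inhibition.
hill_response <- function(conc, half, h, i_max = 1,
                          type = c("activation", "inhibition")) {
  type <- match.arg(type)
  switch(type,
         activation = i_max / (1 + (half / conc)^h),
         inhibition = 1 / (1 + (conc / half)^h))
}

# Shared Hill fitting engine on log-concentration.
fit_hill_engine <- function(series, type) {
  conc <- series$concentrations
  y <- series$responses
  if (stats::sd(y) < 1e-12) stop("degenerate fit: responses are constant")
  lc <- log(conc)
  half0 <- exp(mean(lc))  # geometric mean of tested concentrations
  if (type == "activation") {
    st <- list(lhalf = log(half0), h = 1, imax = max(y))
    fml <- y ~ imax / (1 + exp(h * (lhalf - lc)))
  } else {
    st <- list(lhalf = log(half0), h = 1)
    fml <- y ~ 1 / (1 + exp(h * (lc - lhalf)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(lc = lc, y = y), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  half <- exp(cf[["lhalf"]])
  if (cf[["h"]] <= 0) stop("fit failure: nonpositive Hill coefficient")
  extrapolated <- half < min(conc) * 0.1 || half > max(conc) * 10
  structure(list(
    ec50_or_ic50 = half,
    hill_h = cf[["h"]],
    i_max = if (type == "activation") cf[["imax"]] else 1,
    se = c(ec50_or_ic50 = unname(half * se["lhalf"]),
           hill_h = unname(se["h"]),
           i_max = if (type == "activation") unname(se["imax"]) else 0),
    response_type = type,
    extrapolated = extrapolated,
    rss = sum(stats::residuals(fit)^2),
    data = data.frame(conc_um = conc, response = y)
  ), class = "hill_fit")
}

#' Fit an agonist concentration-response (Hill) curve
#'
#' Least-squares fit of \code{I = Imax / (1 + (EC50/[A])^h)} on
#' log-concentration. \code{Imax} is free; at \code{[A] = EC50} the fitted
#' curve equals \code{Imax / 2} by construction.
#'
#' @param series a [dose_response_series()] with
#'   \code{response_type = "activation"}.
#' @return object of class \code{"hill_fit"} with \code{ec50_or_ic50} (uM),
#'   \code{hill_h}, \code{i_max}, standard errors (\code{se}),
#'   \code{extrapolated} flag (EC50 outside tested range x \[0.1, 10\]) and
#'   the data.
#' @examples
#' s <- generate_dose_response(5.27, 1.20, response_type = "activation")
#' fit_hill(s)
#' @export
fit_hill <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (series$response_type != "activation") {
    stop("fit_hill expects an activation series; see fit_inhibition()")
  }
  fit_hill_engine(series, "activation")
}

#' Fit an antagonist inhibition curve
#'
#' Least-squares fit of \code{I = 1 / (1 + ([ant]/IC50)^h)} on
#' log-concentration; the amplitude is fixed at 1 (responses must be
#' normalized to the uninhibited current). The fitted curve equals 0.5 at
#' \code{[ant] = IC50}.
#'
#' @param series a [dose_response_series()] with
#'   \code{response_type = "inhibition"}.
#' @return a \code{"hill_fit"} (see [fit_hill()]); \code{ec50_or_ic50} is
#'   the IC50.
#' @examples
#' s <- generate_dose_response(1.34, 1.04, response_type = "inhibition")
#' fit_inhibition(s)
#' @export
fit_inhibition <- function(series) {
  stopifnot(inherits(series, "dose_response_series"))
  if (series$response_type != "inhibition") {
    stop("fit_inhibition expects an inhibition series; see fit_hill()")
  }
  fit_hill_engine(series, "inhibition")
}

#' @export
print.hill_fit <- function(x, ...) {
  lab <- if (x$response_type == "activation") "EC50" else "IC50"
  cat(sprintf("Hill %s fit: %s = %.4g uM (se %.3g), h = %.3g (se %.3g)\n",
              x$response_type, lab, x$ec50_or_ic50, x$se["ec50_or_ic50"],
              x$hill_h, x$se["hill_h"]))
  if (x$response_type == "activation") {
    cat(sprintf("  Imax = %.4g (se %.3g)\n", x$i_max, x$se["i_max"]))
  }
  if (x$extrapolated) cat("  note: half-maximal concentration extrapolated",
                          "beyond tested range\n")
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50_or_ic50 = object$ec50_or_ic50, hill_h = object$hill_h,
    i_max = object$i_max)
}

#' @export
predict.hill_fit <- function(object, concentrations = NULL, ...) {
  conc <- concentrations %||% object$data$conc_um
  hill_response(conc, object$ec50_or_ic50, object$hill_h, object$i_max,
                object$response_type)
}

#' @export
plot.hill_fit <- function(x, ...) {
  conc <- x$data$conc_um
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 200))
  plot(conc, x$data$response, log = "x",
       xlab = "concentration (uM)", ylab = "normalized response", ...)
  graphics::lines(grid, predict(x, grid), col = "red")
  invisible(x)
}

#' Normalize raw currents to a reference
#'
#' Elementwise division by the reference magnitude; order and sign are
#' preserved.
#'
#' @param raw_currents currents, pA.
#' @param reference nonzero reference current, pA.
#' @return normalized responses.
#' @export
normalize_series <- function(raw_currents, reference) {
  if (length(reference) != 1 || !is.finite(reference) || reference == 0) {
    stop("reference must be a single nonzero current")
  }
  raw_currents / abs(reference)
}

#' Per-cell dose-response fits with parameter averaging
#'
#' Fits each cell's series separately and reports mean and SEM of the fitted
#' parameters across cells (the convention of per-cell fits with n = cells).
#' Pooled fitting of all points at once is available with
#' \code{pooled = TRUE}.
#'
#' @param data data.frame with columns \code{conc_um}, \code{response} and
#'   \code{cell_id}.
#' @param response_type "activation" or "inhibition".
#' @param pooled fit all points in a single series instead.
#' @return for per-cell mode, a list with \code{per_cell} (data.frame of
#'   parameters per cell) and \code{summary} (mean, sem, n per parameter);
#'   for pooled mode, a single \code{"hill_fit"}.
#' @export
fit_dose_response_by_cell <- function(data,
                                      response_type = c("activation",
                                                        "inhibition"),
                                      pooled = FALSE) {
  response_type <- match.arg(response_type)
  req <- c("conc_um", "response")
  if (!all(req %in% names(data))) {
    stop("data must have columns conc_um and response")
  }
  fit1 <- function(d, allow_dup = FALSE) {
    if (allow_dup) {
      # pooled points may repeat concentrations across cells; fit directly
      s <- list(concentrations = d$conc_um, responses = d$response,
                response_type = response_type)
      return(fit_hill_engine(s, response_type))
    }
    s <- dose_response_series(d$conc_um, d$response, response_type)
    if (response_type == "activation") fit_hill(s) else fit_inhibition(s)
  }
  if (pooled || is.null(data$cell_id)) {
    return(fit1(data, allow_dup = pooled))
  }
  cells <- split(data, data$cell_id)
  per_cell <- do.call(rbind, lapply(names(cells), function(id) {
    f <- fit1(cells[[id]])
    data.frame(cell_id = id, ec50_or_ic50 = f$ec50_or_ic50,
               hill_h = f$hill_h, i_max = f$i_max)
  }))
  n <- nrow(per_cell)
  summ <- data.frame(
    parameter = c("ec50_or_ic50", "hill_h", "i_max"),
    mean = c(mean(per_cell$ec50_or_ic50), mean(per_cell$hill_h),
             mean(per_cell$i_max)),
    sem = c(stats::sd(per_cell$ec50_or_ic50), stats::sd(per_cell$hill_h),
            stats::sd(per_cell$i_max)) / sqrt(n),
    n = n)
  list(per_cell = per_cell, summary = summ)
}
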