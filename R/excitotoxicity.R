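#' Two-component Gaussian mixture fit of nuclear areas
#'
#' Maximum-likelihood fit of a univariate two-component Gaussian mixture to
#' nuclear cross-section areas by expectation-maximization, emulating the
#' histogram-based separation of pyknotic (condensed, smaller) and
#' nonpyknotic nuclei in excitotoxicity assays. Initialization splits the
#' sample at its median; additional restarts perturb the split quantile with
#' seeds derived deterministically from \code{seed}, and the best
#' log-likelihood wins. Components are reported in ascending mean order, so
#' component 1 is the pyknotic one.
#'
#' @param sample a [generate_nuclei()] result, or any list with an
#'   \code{areas} vector (positive, n >= 50).
#' @param seed integer seed controlling the restart sequence.
#' @param n_restarts number of EM restarts (default 10).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return object of class \code{"pyknosis_fit"}: list with \code{means},
#'   \code{sds}, \code{weights} (ascending-mean order), \code{loglik},
#'   \code{n_iter}, \code{converged}.
#' @examples
#' s <- generate_nuclei(n = 500, seed = 7)
#' fit_two_gaussian(s, seed = 7)
#' @export
fit_two_gaussian <- function(sample, seed = 1, n_restarts = 10,
                             max_iter = 500, tol = 1e-8) {
  areas <- if (is.list(sample)) sample$areas else sample
  if (length(areas) < 50) {
    stop("insufficient data: at least 50 nuclei required for a mixture fit")
  }
  if (any(areas <= 0)) stop("areas must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))
  qs <- c(0.5, stats::runif(n_restarts - 1, 0.2, 0.8))
  best <- NULL
  for (q in qs) {
    fit <- em_two_gaussian(areas, split_q = q, max_iter = max_iter,
                           tol = tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("degenerate fit: EM failed for all restarts")
  ord <- order(best$means)
  structure(list(means = best$means[ord], sds = best$sds[ord],
                 weights = best$weights[ord], loglik = best$loglik,
                 n_iter = best$n_iter, converged = best$converged),
            class = "pyknosis_fit")
}

# Single EM run from a quantile-split initialization. Returns NULL when the
# run degenerates (vanishing variance) even after regularized retry.
em_two_gaussian <- function(x, split_q, max_iter, tol) {
  n <- length(x)
  var_floor <- (1e-3 * stats::sd(x))^2
  cut <- stats::quantile(x, split_q)
  g <- x <= cut
  if (!any(g) || all(g)) g <- x <= stats::median(x)
  mu <- c(mean(x[g]), mean(x[!g]))
  s2 <- c(stats::var(x[g]), stats::var(x[!g]))
  s2[!is.finite(s2) | s2 < var_floor] <- stats::var(x) / 4
  w <- c(mean(g), mean(!g))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    r1 <- d1 / tot
    ll <- sum(log(tot))
    n1 <- sum(r1)
    if (n1 < 2 || n - n1 < 2) return(NULL)
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / (n - n1))
    s2 <- c(sum(r1 * (x - mu[1])^2) / n1,
            sum((1 - r1) * (x - mu[2])^2) / (n - n1))
    s2 <- pmax(s2, var_floor)  # regularize vanishing variance
    w <- c(n1 / n, 1 - n1 / n)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(means = mu, sds = sqrt(s2), weights = w, loglik = ll,
       n_iter = it, converged = converged)
}

#' @export
print.pyknosis_fit <- function(x, ...) {
  cat("Two-Gaussian nuclear-area mixture\n")
  cat(sprintf("  pyknotic:    mean %.2f um^2, sd %.2f, weight %.3f\n",
              x$means[1], x$sds[1], x$weights[1]))
  cat(sprintf("  nonpyknotic: mean %.2f um^2, sd %.2f, weight %.3f\n",
              x$means[2], x$sds[2], x$weights[2]))
  cat(sprintf("  loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' @export
coef.pyknosis_fit <- function(object, ...) {
  c(mean_pyknotic = object$means[1], mean_nonpyknotic = object$means[2],
    sd_pyknotic = object$sds[1], sd_nonpyknotic = object$sds[2],
    weight_pyknotic = object$weights[1])
}

#' Posterior probabilities of mixture membership
#'
#' @param fit a \code{"pyknosis_fit"}.
#' @param areas nuclear areas, um^2.
#' @return matrix with columns \code{pyknotic}, \code{nonpyknotic}; rows sum
#'   to 1.
#' @export
posterior_pyknotic <- function(fit, areas) {
  stopifnot(inherits(fit, "pyknosis_fit"))
  d1 <- fit$weights[1] * stats::dnorm(areas, fit$means[1], fit$sds[1])
  d2 <- fit$weights[2] * stats::dnorm(areas, fit$means[2], fit$sds[2])
  p <- cbind(pyknotic = d1 / (d1 + d2), nonpyknotic = d2 / (d1 + d2))
  # areas far into either tail can underflow both densities; resolve by mean
  deg <- !is.finite(p[, 1])
  if (any(deg)) {
    p[deg, 1] <- as.numeric(abs(areas[deg] - fit$means[1]) / fit$sds[1] <
                              abs(areas[deg] - fit$means[2]) / fit$sds[2])
    p[deg, 2] <- 1 - p[deg, 1]
  }
  p
}

#' Classify nuclei and compute the pyknotic fraction
#'
#' Each nucleus is assigned to the mixture component with the higher
#' posterior probability; the pyknotic component is the smaller-mean one.
#' Exact posterior ties are assigned nonpyknotic (conservative toward
#' survival). The pyknotic fraction is the pyknotic count over the total.
#'
#' @param fit a \code{"pyknosis_fit"} (mixture parameters).
#' @param areas nuclear areas, um^2 (defaults to the areas of \code{sample}
#'   when given instead).
#' @return list with \code{labels} (character), \code{pyknotic_fraction},
#'   \code{posterior} (matrix), \code{n}.
#' @examples
#' s <- generate_nuclei(n = 500, seed = 7)
#' f <- fit_two_gaussian(s, seed = 7)
#' classify_nuclei(f, s$areas)$pyknotic_fraction
#' @export
classify_nuclei <- function(fit, areas) {
  stopifnot(inherits(fit, "pyknosis_fit"))
  if (is.list(areas)) areas <- areas$areas
  p <- posterior_pyknotic(fit, areas)
  labels <- unname(ifelse(p[, "pyknotic"] > 0.5, "pyknotic", "nonpyknotic"))
  list(labels = labels,
       pyknotic_fraction = mean(labels == "pyknotic"),
       posterior = p, n = length(areas))
}

#' Pooled-model pyknosis analysis across conditions
#'
#' Fits the mixture on areas pooled across all conditions (control plus
#' treatments), then classifies each condition against the pooled model and
#' reports per-condition pyknotic fractions. Per-condition fitting is
#' available with \code{pool = FALSE}.
#'
#' @param data data.frame with columns \code{area_um2} and \code{condition}.
#' @param seed integer seed for the mixture fit(s).
#' @param pool fit one pooled model (default) or one model per condition.
#' @return list with \code{fit} (pooled; or named list of fits) and
#'   \code{fractions} (data.frame condition, pyknotic_fraction, n).
#' @export
pyknosis_by_condition <- function(data, seed = 1, pool = TRUE) {
  req <- c("area_um2", "condition")
  if (!all(req %in% names(data))) {
    stop("data must have columns area_um2 and condition")
  }
  conds <- split(data$area_um2, data$condition)
  if (pool) {
    fit <- fit_two_gaussian(list(areas = data$area_um2), seed = seed)
    fr <- lapply(names(conds), function(cd) {
      cl <- classify_nuclei(fit, conds[[cd]])
      data.frame(condition = cd, pyknotic_fraction = cl$pyknotic_fraction,
                 n = cl$n)
    })
    list(fit = fit, fractions = do.call(rbind, fr))
  } else {
    fits <- lapply(conds, function(a)
      fit_two_gaussian(list(areas = a), seed = seed))
    fr <- lapply(names(conds), function(cd) {
      cl <- classify_nuclei(fits[[cd]], conds[[cd]])
      data.frame(condition = cd, pyknotic_fraction = cl$pyknotic_fraction,
                 n = cl$n)
    })
    list(fit = fits, fractions = do.call(rbind, fr))
  }
}
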