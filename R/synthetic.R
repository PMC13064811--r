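#' Recording protocol for synthetic whole-cell traces
#'
#' Describes the application schedule and acquisition settings used by
#' [generate_trace()]: a sustained agonist application with a blocker
#' coapplication window, first-order solution exchange, additive Gaussian
#' recording noise, and 5 kHz digitization.
#'
#' @param agonist c(start, end) of the agonist application, s.
#' @param blocker c(start, end) of the blocker coapplication, s (must lie
#'   within the agonist window; NULL for no blocker).
#' @param blocker_conc blocker concentration, uM.
#' @param exchange_tau solution-exchange time constant, s. Default 0.017
#'   (midpoint of the 15-20 ms range typical of fast application systems).
#' @param noise_sigma recording noise sd as a fraction of the peak current.
#' @param sampling_rate digitization rate, Hz (default 5000).
#' @param t_end recording end, s (default: 0.3 s past the agonist end).
#' @param seed integer seed used by the generator.
#' @return object of class \code{"trace_protocol"}.
#' @export
trace_protocol <- function(agonist = c(0.3, 11.5), blocker = c(3.3, 11.5),
                           blocker_conc = 1, exchange_tau = 0.017,
                           noise_sigma = 0.02, sampling_rate = 5000,
                           t_end = NULL, seed = 1) {
  if (length(agonist) != 2 || diff(agonist) <= 0) {
    stop("agonist must be c(start, end) with end > start")
  }
  if (!is.null(blocker)) {
    if (length(blocker) != 2 || diff(blocker) <= 0) {
      stop("blocker must be c(start, end) with end > start")
    }
    if (blocker[1] < agonist[1]) {
      stop("blocker application must start within the agonist application")
    }
  }
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative")
  if (exchange_tau < 0) stop("exchange_tau must be nonnegative")
  if (exchange_tau < 0.010 || exchange_tau > 0.030) {
    warning("exchange_tau outside the typical 10-30 ms range")
  }
  if (is.null(t_end)) {
    t_end <- max(agonist[2], if (is.null(blocker)) 0 else blocker[2]) + 0.3
  }
  structure(list(agonist = agonist, blocker = blocker,
                 blocker_conc = blocker_conc, exchange_tau = exchange_tau,
                 noise_sigma = noise_sigma, sampling_rate = sampling_rate,
                 t_end = t_end, seed = seed),
            class = "trace_protocol")
}

# Filtered square pulse: first-order low-pass response to a unit step on at
# t0, off at t1 (vectorized, analytic).
filtered_pulse <- function(t, t0, t1, tau) {
  if (tau <= 0) return(as.numeric(t >= t0 & t < t1))
  a <- numeric(length(t))
  on <- t >= t0 & t < t1
  a[on] <- 1 - exp(-(t[on] - t0) / tau)
  a_end <- 1 - exp(-(t1 - t0) / tau)
  off <- t >= t1
  a[off] <- a_end * exp(-(t[off] - t1) / tau)
  a
}

#' Generate a synthetic whole-cell current trace
#'
#' Forward model combining the D <-> C <-> O -> B gating scheme with
#' first-order solution exchange and additive Gaussian recording noise.
#' The agonist drive (filtered 0/1 waveform) multiplies the liganded-state
#' transitions (opening and desensitization); the filtered blocker waveform
#' multiplies the blocking rate. Occupancies start fully in the closed state.
#' The current is scaled so the ideal (pre-desensitization) peak equals
#' \code{peak_scale}; noise sd is \code{noise_sigma * |peak_scale|}.
#'
#' @param po true open probability; converted to \code{ko = kc po/(1-po)}.
#' @param extent_D desensitization extent used for \code{kd, kr}.
#' @param tau_d desensitization time constant, s.
#' @param kc,kb closing and blocking rates (defaults 250 1/s, 25 1/(uM s)).
#' @param scheme optional [gating_scheme()]; overrides \code{po},
#'   \code{extent_D}, \code{tau_d}, \code{kc}, \code{kb}.
#' @param protocol a [trace_protocol()].
#' @param peak_scale ideal peak current, pA (inward negative).
#' @param noise_sigma overrides the protocol's noise fraction when non-NULL.
#' @param seed overrides the protocol's seed when non-NULL.
#' @return a [current_trace()] whose \code{meta} records the generating
#'   ground truth (\code{true_po}, \code{extent_D}, \code{tau_d}, rates,
#'   \code{peak_scale}, \code{noise_sigma}, \code{seed}).
#' @examples
#' tr <- generate_trace(po = 0.066, seed = 42)
#' tr$meta$true_po
#' @export
generate_trace <- function(po = 0.066, extent_D = 0.4, tau_d = 0.5,
                           kc = 250, kb = 25, scheme = NULL,
                           protocol = trace_protocol(), peak_scale = -500,
                           noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(protocol, "trace_protocol"))
  if (is.null(scheme)) {
    if (po <= 0 || po >= 1) stop("po must lie in (0, 1)")
    ko <- kc * po / (1 - po)
    kd <- if (extent_D > 0) extent_D / tau_d else 0
    kr <- if (extent_D > 0) (1 - extent_D) / tau_d else 1
    scheme <- gating_scheme(kd = kd, kr = kr, ko = ko, kc = kc, kb = kb,
                            blocker_conc = protocol$blocker_conc %||% 0)
  }
  if (is.null(noise_sigma)) noise_sigma <- protocol$noise_sigma
  if (is.null(seed)) seed <- protocol$seed
  dt <- 1 / protocol$sampling_rate
  t <- seq(0, protocol$t_end, by = dt)
  te <- protocol$exchange_tau
  ag <- protocol$agonist
  bl <- protocol$blocker
  has_blocker <- !is.null(bl) && scheme$kb_eff > 0

  a_fun <- function(s) filtered_pulse(s, ag[1], ag[2], te)
  b_fun <- if (has_blocker) {
    function(s) filtered_pulse(s, bl[1], bl[2], te)
  } else {
    function(s) 0
  }
  rhs <- function(s, x, p) {
    a <- a_fun(s)
    kbe <- scheme$kb_eff * b_fun(s)
    d <- x[1]; cc <- x[2]; o <- x[3]; b <- x[4]
    list(c(-scheme$kr * d + scheme$kd * a * cc,
           scheme$kr * d - (scheme$kd * a + scheme$ko * a) * cc +
             scheme$kc * o,
           scheme$ko * a * cc - (scheme$kc + kbe) * o + scheme$ku * b,
           kbe * o - scheme$ku * b))
  }
  sol <- deSolve::lsoda(y = c(0, 1, 0, 0), times = t, func = rhs,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  o_t <- sol[, 4]
  true_po <- po_from_ko(scheme$ko, scheme$kc)
  scale <- peak_scale / true_po  # ideal quasi-equilibrium peak = peak_scale
  current <- scale * o_t
  if (noise_sigma > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    current <- current + stats::rnorm(length(t),
                                      sd = noise_sigma * abs(peak_scale))
  }
  epochs <- data.frame(name = "agonist", start_s = ag[1], end_s = ag[2],
                       solution = "agonist", conc_um = NA_real_)
  if (has_blocker) {
    epochs <- rbind(epochs, data.frame(
      name = "blocker", start_s = bl[1], end_s = bl[2],
      solution = "blocker", conc_um = scheme$blocker_conc))
  }
  current_trace(
    time = t, current = current, epochs = epochs,
    sampling_rate = protocol$sampling_rate,
    meta = list(true_po = true_po,
                extent_D = if (scheme$kd > 0)
                  scheme$kd / (scheme$kd + scheme$kr) else 0,
                tau_d = if (scheme$kd > 0) 1 / (scheme$kd + scheme$kr)
                        else NA_real_,
                scheme = scheme, peak_scale = peak_scale,
                noise_sigma = noise_sigma, seed = seed,
                noiseless = scale * o_t)
  )
}

#' Generate a synthetic reversible-blocker (memantine-like) trace
#'
#' Phenomenological forward model of a reversible open-channel blocker
#' applied during a steady agonist response: during the blocker epoch the
#' current relaxes exponentially at \code{on_rate} toward
#' \code{(1 - block_extent)} of the steady current, and after removal it
#' recovers at \code{off_rate}. Application edges are smoothed by the
#' protocol's solution-exchange filter.
#'
#' @param on_rate onset relaxation rate during block, 1/s.
#' @param off_rate recovery rate after removal, 1/s.
#' @param block_extent steady-state blocked fraction in (0, 1\].
#' @param protocol a [trace_protocol()] whose blocker window ends before the
#'   agonist window (so a wash-in-agonist segment exists).
#' @param peak_scale steady agonist current, pA.
#' @param noise_sigma,seed override the protocol values when non-NULL.
#' @return a [current_trace()] with ground truth in \code{meta}.
#' @export
generate_reversible_block_trace <- function(on_rate = 2, off_rate = 1.25,
                                            block_extent = 0.8,
                                            protocol = trace_protocol(
                                              agonist = c(0.3, 12),
                                              blocker = c(2, 6)),
                                            peak_scale = -500,
                                            noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(protocol, "trace_protocol"))
  if (on_rate <= 0 || off_rate <= 0) stop("rates must be positive")
  if (block_extent <= 0 || block_extent > 1) {
    stop("block_extent must lie in (0, 1]")
  }
  if (is.null(protocol$blocker)) stop("protocol must include a blocker epoch")
  if (is.null(noise_sigma)) noise_sigma <- protocol$noise_sigma
  if (is.null(seed)) seed <- protocol$seed
  dt <- 1 / protocol$sampling_rate
  t <- seq(0, protocol$t_end, by = dt)
  ag <- protocol$agonist; bl <- protocol$blocker; te <- protocol$exchange_tau
  a <- filtered_pulse(t, ag[1], ag[2], te)
  blocked <- numeric(length(t))
  on <- t >= bl[1] & t < bl[2]
  blocked[on] <- block_extent * (1 - exp(-(t[on] - bl[1]) * on_rate))
  b_end <- block_extent * (1 - exp(-(bl[2] - bl[1]) * on_rate))
  off <- t >= bl[2]
  blocked[off] <- b_end * exp(-(t[off] - bl[2]) * off_rate)
  current <- peak_scale * a * (1 - blocked)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    current <- current + stats::rnorm(length(t),
                                      sd = noise_sigma * abs(peak_scale))
  }
  epochs <- data.frame(
    name = c("agonist", "blocker"),
    start_s = c(ag[1], bl[1]), end_s = c(ag[2], bl[2]),
    solution = c("agonist", "blocker"),
    conc_um = c(NA_real_, protocol$blocker_conc))
  current_trace(time = t, current = current, epochs = epochs,
                sampling_rate = protocol$sampling_rate,
                meta = list(on_rate = on_rate, off_rate = off_rate,
                            block_extent = block_extent, seed = seed))
}

#' Generate a synthetic dose-response series
#'
#' Responses follow the Hill activation curve
#' \code{I = Imax / (1 + (EC50/[A])^h)} or the inhibition curve
#' \code{I = 1 / (1 + ([ant]/IC50)^h)}, with multiplicative Gaussian noise.
#'
#' @param ec50_or_ic50 half-maximal concentration, uM.
#' @param hill_h Hill coefficient.
#' @param i_max maximal response (activation only; inhibition is unit-scaled).
#' @param response_type "activation" or "inhibition".
#' @param concentrations tested concentrations, uM (positive, unique).
#' @param noise_sigma multiplicative noise sd (fraction of each response).
#' @param seed integer seed.
#' @return object of class \code{"dose_response_series"} (see
#'   [dose_response_series()]) with ground truth in \code{meta}.
#' @export
generate_dose_response <- function(ec50_or_ic50, hill_h, i_max = 1,
                                   response_type = c("activation",
                                                     "inhibition"),
                                   concentrations =
                                     ec50_or_ic50 * 10^seq(-1.5, 1.5, 0.5),
                                   noise_sigma = 0, seed = 1) {
  response_type <- match.arg(response_type)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  resp <- hill_response(concentrations, ec50_or_ic50, hill_h, i_max,
                        response_type)
  if (noise_sigma > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    resp <- resp * (1 + stats::rnorm(length(resp), sd = noise_sigma))
  }
  out <- dose_response_series(concentrations, resp, response_type)
  out$meta <- list(ec50_or_ic50 = ec50_or_ic50, hill_h = hill_h,
                   i_max = i_max, noise_sigma = noise_sigma, seed = seed)
  out
}

#' Generate a synthetic nuclear-area sample
#'
#' Areas are drawn from a two-component Gaussian mixture (pyknotic =
#' smaller-mean component), truncated at positive values. Ground-truth
#' component labels are retained for recovery testing.
#'
#' @param means component means, um^2 (length 2).
#' @param sds component sds, um^2 (length 2).
#' @param weights mixing weights summing to 1 (first = pyknotic).
#' @param n sample size.
#' @param condition condition label.
#' @param seed integer seed.
#' @return object of class \code{"nuclei_sample"}: list with \code{areas},
#'   \code{condition}, \code{true_labels} and \code{meta}.
#' @export
generate_nuclei <- function(means = c(40, 90), sds = c(8, 15),
                            weights = c(0.3, 0.7), n = 2000,
                            condition = "synthetic", seed = 1) {
  if (length(means) != 2 || length(sds) != 2 || length(weights) != 2) {
    stop("means, sds, weights must each have length 2")
  }
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    stop("weights must be nonnegative and sum to 1")
  }
  if (any(sds <= 0)) stop("sds must be positive")
  if (n < 1) stop("n must be at least 1")
  set.seed(as.integer(seed %% .Machine$integer.max))
  comp <- sample.int(2, n, replace = TRUE, prob = weights)
  areas <- stats::rnorm(n, means[comp], sds[comp])
  while (any(areas <= 0)) {  # truncate at positive area
    bad <- areas <= 0
    areas[bad] <- stats::rnorm(sum(bad), means[comp[bad]], sds[comp[bad]])
  }
  structure(list(areas = areas, condition = condition,
                 true_labels = ifelse(comp == which.min(means),
                                      "pyknotic", "nonpyknotic"),
                 meta = list(means = means, sds = sds, weights = weights,
                             seed = seed)),
            class = "nuclei_sample")
}

# Disk mask helper for image generators.
disk_mask <- function(nrow, ncol, center, radius) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  cl <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (r - center[1])^2 + (cl - center[2])^2 <= radius^2
}

#' Generate a synthetic two-channel image with a marker subregion
#'
#' Produces a reporter-channel raster whose mean intensity inside a
#' marker-defined blob (e.g. a Golgi region) is \code{inside_outside_ratio}
#' times the mean outside it (within the cell), a marker-channel raster, and
#' the cell mask. A uniform background plus Gaussian noise is added, so
#' downstream ratio metrics must background-subtract.
#'
#' @param size image dimensions c(rows, cols).
#' @param pixel_um pixel size, um.
#' @param inside_outside_ratio target in/out mean-intensity ratio (> 0).
#' @param marker_radius_frac marker blob radius as a fraction of the cell
#'   radius (must be < 1).
#' @param base_intensity mean reporter intensity outside the marker region.
#' @param background uniform background level added everywhere.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param seed integer seed.
#' @return list with matrices \code{signal}, \code{marker}, logical
#'   \code{cell_mask}, \code{marker_mask}, \code{pixel_um} and \code{meta}
#'   (ground truth).
#' @export
generate_two_channel_image <- function(size = c(96, 96), pixel_um = 0.2,
                                       inside_outside_ratio = 3,
                                       marker_radius_frac = 0.35,
                                       base_intensity = 100,
                                       background = 20, noise_sigma = 2,
                                       seed = 1) {
  if (inside_outside_ratio <= 0) stop("inside_outside_ratio must be positive")
  if (marker_radius_frac >= 1) stop("marker region must be smaller than cell")
  set.seed(as.integer(seed %% .Machine$integer.max))
  cell_r <- 0.4 * min(size)
  center <- size / 2
  cell <- disk_mask(size[1], size[2], center, cell_r)
  marker_center <- center + c(0.3, 0.2) * cell_r
  marker <- disk_mask(size[1], size[2], marker_center,
                      marker_radius_frac * cell_r) & cell
  signal <- matrix(background, size[1], size[2])
  signal[cell] <- background + base_intensity
  signal[marker] <- background + base_intensity * inside_outside_ratio
  marker_ch <- matrix(background, size[1], size[2])
  marker_ch[marker] <- background + 150
  if (noise_sigma > 0) {
    signal <- signal + matrix(stats::rnorm(prod(size), sd = noise_sigma),
                              size[1], size[2])
    marker_ch <- marker_ch + matrix(stats::rnorm(prod(size),
                                                 sd = noise_sigma),
                                    size[1], size[2])
  }
  signal[signal < 0] <- 0
  marker_ch[marker_ch < 0] <- 0
  list(signal = signal, marker = marker_ch, cell_mask = cell,
       marker_mask = marker, pixel_um = pixel_um,
       meta = list(inside_outside_ratio = inside_outside_ratio,
                   base_intensity = base_intensity, background = background,
                   noise_sigma = noise_sigma, seed = seed))
}

#' Generate a synthetic surface/total labeling image pair
#'
#' The total-channel raster carries the full receptor pool within the cell;
#' the surface-channel raster is \code{surface_fraction} times the total
#' signal, plus background and noise.
#'
#' @param size image dimensions c(rows, cols).
#' @param surface_fraction true surface/total signal ratio.
#' @param base_intensity mean total intensity within the cell.
#' @param background uniform background level.
#' @param noise_sigma additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list with matrices \code{surface}, \code{total}, logical
#'   \code{cell_mask} and \code{meta}.
#' @export
generate_surface_total_image <- function(size = c(96, 96),
                                         surface_fraction = 0.4,
                                         base_intensity = 100,
                                         background = 20, noise_sigma = 2,
                                         seed = 1) {
  if (surface_fraction < 0) stop("surface_fraction must be nonnegative")
  set.seed(as.integer(seed %% .Machine$integer.max))
  cell <- disk_mask(size[1], size[2], size / 2, 0.4 * min(size))
  total <- matrix(background, size[1], size[2])
  # mild intensity gradient so the pair is not trivially uniform
  grad <- matrix(seq(0.8, 1.2, length.out = size[2]), size[1], size[2],
                 byrow = TRUE)
  total[cell] <- background + (base_intensity * grad)[cell]
  surface <- matrix(background, size[1], size[2])
  surface[cell] <- background + surface_fraction * (base_intensity * grad)[cell]
  if (noise_sigma > 0) {
    total <- total + matrix(stats::rnorm(prod(size), sd = noise_sigma),
                            size[1], size[2])
    surface <- surface + matrix(stats::rnorm(prod(size), sd = noise_sigma),
                                size[1], size[2])
  }
  total[total < 0] <- 0
  surface[surface < 0] <- 0
  list(surface = surface, total = total, cell_mask = cell,
       meta = list(surface_fraction = surface_fraction,
                   background = background, noise_sigma = noise_sigma,
                   seed = seed))
}
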