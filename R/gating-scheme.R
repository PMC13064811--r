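#' Four-state gating scheme for an NMDAR with an open-channel blocker
#'
#' Constructs the kinetic scheme D <-> C <-> O -> B used throughout the
#' package: a desensitized state \code{D}, the fully liganded closed state
#' \code{C}, the open state \code{O}, and the blocker-occupied state \code{B}.
#' Ligand-binding steps are omitted; the agonist is assumed saturating, so the
#' scheme is time-homogeneous during a constant-concentration epoch. Block by
#' MK-801 is treated as irreversible on the experimental timescale
#' (\code{ku = 0}); a nonzero unblocking rate \code{ku} covers reversible
#' open-channel blockers such as memantine.
#'
#' @param kd desensitization rate C -> D, 1/s.
#' @param kr resensitization rate D -> C, 1/s.
#' @param ko opening rate C -> O, 1/s.
#' @param kc closing rate O -> C, 1/s. Fixed at 250 by convention; the
#'   microscopic open probability is \code{ko / (ko + kc)}.
#' @param kb blocking rate of the open channel, 1/(uM s). Default 25,
#'   the established MK-801 value.
#' @param blocker_conc blocker concentration, uM.
#' @param ku unblocking rate B -> O, 1/s. Default 0 (irreversible block).
#'
#' @return An object of class \code{"gating_scheme"}: a list with the rate
#'   constants above plus \code{kb_eff = kb * blocker_conc} (the
#'   pseudo-first-order blocking rate, 1/s).
#'
#' @examples
#' sch <- gating_scheme(kd = 1, kr = 1, ko = 17.66)
#' po_from_ko(sch$ko, sch$kc)
#' @export
gating_scheme <- function(kd, kr, ko, kc = 250, kb = 25, blocker_conc = 0,
                          ku = 0) {
  rates <- c(kd = kd, kr = kr, ko = ko, kc = kc, kb = kb,
             blocker_conc = blocker_conc, ku = ku)
  if (any(!is.finite(rates))) {
    stop("all rate constants and concentrations must be finite numbers")
  }
  if (any(rates < 0)) {
    stop("rate constants and concentrations must be nonnegative")
  }
  if (kc <= 0) {
    stop("closing rate kc must be strictly positive")
  }
  structure(
    list(kd = kd, kr = kr, ko = ko, kc = kc, kb = kb,
         blocker_conc = blocker_conc, ku = ku,
         kb_eff = kb * blocker_conc),
    class = "gating_scheme"
  )
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("Gating scheme  D <-> C <-> O -> B\n")
  cat(sprintf("  kd = %g /s, kr = %g /s (desensitization / resensitization)\n",
              x$kd, x$kr))
  cat(sprintf("  ko = %g /s, kc = %g /s (opening / closing)\n", x$ko, x$kc))
  cat(sprintf("  kb = %g /uM/s x [blocker] = %g uM  =>  kb' = %g /s\n",
              x$kb, x$blocker_conc, x$kb_eff))
  if (x$ku > 0) cat(sprintf("  ku = %g /s (reversible block)\n", x$ku))
  cat(sprintf("  microscopic Po = ko/(ko+kc) = %.4f\n",
              po_from_ko(x$ko, x$kc)))
  invisible(x)
}

#' Generator matrix of the gating scheme
#'
#' Returns the 4x4 matrix \code{A} such that the state occupancies
#' \code{x = (d, c, o, b)} obey \code{dx/dt = A x}. An explicit
#' pseudo-first-order blocking rate can be supplied to override
#' \code{scheme$kb_eff} (used for time-varying blocker concentration).
#'
#' @param scheme a [gating_scheme()].
#' @param kb_eff optional pseudo-first-order blocking rate, 1/s.
#' @return numeric 4x4 matrix with rows/columns named D, C, O, B.
#' @export
rate_matrix <- function(scheme, kb_eff = scheme$kb_eff) {
  stopifnot(inherits(scheme, "gating_scheme"))
  kd <- scheme$kd; kr <- scheme$kr; ko <- scheme$ko; kc <- scheme$kc
  ku <- scheme$ku
  matrix(
    c(-kr,        kd,            0,             0,
       kr, -(kd + ko),          kc,             0,
        0,         ko, -(kc + kb_eff),         ku,
        0,          0,       kb_eff,          -ku),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("D", "C", "O", "B"), c("D", "C", "O", "B"))
  )
}

#' Steady state of the unblocked D <-> C <-> O subsystem
#'
#' Equilibrium occupancies with no blocker present, used as the initial
#' condition for blocker-onset simulations (the cell is equilibrated in
#' agonist before the blocker is coapplied). Detailed balance on the linear
#' chain gives occupancies proportional to \code{(kd/kr, 1, ko/kc)}.
#'
#' @param scheme a [gating_scheme()].
#' @return named numeric state vector (d, c, o, b) summing to 1, with b = 0.
#' @export
steady_state_unblocked <- function(scheme) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (scheme$kr <= 0 && scheme$kd > 0) {
    stop("kr = 0 with kd > 0: all occupancy absorbs into D, no steady state")
  }
  d <- if (scheme$kd > 0) scheme$kd / scheme$kr else 0
  o <- scheme$ko / scheme$kc
  x <- c(d = d, c = 1, o = o, b = 0)
  x / sum(x)
}

#' Microscopic open probability from opening and closing rates
#'
#' \code{Po = ko / (ko + kc)}: the equilibrium open fraction of the C <-> O
#' gating step. Reported as a fraction in \[0, 1); multiply by 100 for the
#' percentage convention.
#'
#' @param ko opening rate, 1/s (>= 0).
#' @param kc closing rate, 1/s (> 0).
#' @return open probability, dimensionless fraction.
#' @examples
#' po_from_ko(250, 250)   # 0.5
#' po_from_ko(17.66, 250) # ~0.066
#' @export
po_from_ko <- function(ko, kc) {
  if (any(kc <= 0)) stop("closing rate kc must be strictly positive")
  if (any(ko < 0)) stop("opening rate ko must be nonnegative")
  ko / (ko + kc)
}

#' Desensitization extent and rate constants from peak and steady state
#'
#' From the peak current \code{Ipeak}, the steady-state current \code{Imax}
#' and the desensitization-onset time constant \code{tau_d}, computes the
#' desensitization extent \code{D = 1 - Imax/Ipeak} and the rate constants
#' \code{kd = D / tau_d}, \code{kr = (1 - D) / tau_d}. These satisfy
#' \code{kd + kr = 1 / tau_d} identically. Comparisons use magnitudes, so
#' inward (negative) currents may be passed directly.
#'
#' @param i_peak peak current, pA.
#' @param i_max steady-state current, pA (same sign as \code{i_peak}).
#' @param tau_d desensitization-onset time constant, s.
#' @return list with elements \code{extent_D}, \code{kd}, \code{kr},
#'   \code{tau_d}, \code{i_peak}, \code{i_max}.
#' @examples
#' desensitization_params(i_peak = -2, i_max = -1, tau_d = 0.5)
#' @export
desensitization_params <- function(i_peak, i_max, tau_d) {
  if (!is.finite(tau_d) || tau_d <= 0) {
    stop("tau_d must be a positive time constant")
  }
  if (abs(i_max) > abs(i_peak)) {
    stop("inconsistent trace: |i_max| exceeds |i_peak|")
  }
  if (abs(i_peak) == 0) stop("i_peak must be nonzero")
  extent <- 1 - abs(i_max) / abs(i_peak)
  list(extent_D = extent,
       kd = extent / tau_d,
       kr = (1 - extent) / tau_d,
       tau_d = tau_d,
       i_peak = i_peak,
       i_max = i_max)
}
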