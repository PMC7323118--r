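#' Bending-energy profiles
#'
#' A `bending_profile` represents the effective bending energy per bending
#' site, \eqn{E(\theta)}, of a semiflexible polymer as a function of the bend
#' angle \eqn{\theta} (the angle between successive segment directions;
#' \eqn{\theta = 0} is straight).  Angles are in radians and energies in units
#' of \eqn{k_BT} at 300 K throughout; profiles carry no temperature.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{quartic}{\eqn{E(\theta) = c_2\theta^2 + c_3\theta^3 + c_4\theta^4},
#'     the functional form used for empirical per-base-pair DNA bending
#'     energies inferred from protein-DNA complex structures.}
#'   \item{harmonic}{\eqn{E(\theta) = \tfrac{1}{2} L_p \theta^2}, the
#'     worm-like-chain (WLC) energy per bending site with the persistence
#'     length \eqn{L_p} expressed dimensionlessly in bending sites (base
#'     pairs for DNA).}
#'   \item{tabulated}{a strictly increasing table of (angle, energy) knots,
#'     interpolated with the monotone (Fritsch-Carlson) piecewise cubic so the
#'     derivative is continuous and free of spurious oscillation.}
#' }
#'
#' @param c2,c3,c4 quartic coefficients in kT/rad^2, kT/rad^3, kT/rad^4.
#' @param Lp persistence length in bending sites (bp for DNA); must be > 0.
#' @param theta,energy knot vectors for a tabulated profile; `theta` strictly
#'   increasing, radians; `energy` in kT.
#' @param domain numeric length-2, the angular domain `[theta_min, theta_max]`
#'   in radians on which the profile may be evaluated.
#' @return an object of class `bending_profile`.
#' @examples
#' p <- quartic_profile(203.1, -552.7, 416.8)
#' profile_energy(p, 0.1)
#' profile_slope(p, 0.1)
#' @name bending_profile
NULL

new_bending_profile <- function(kind, domain, ...) {
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2])
  structure(list(kind = kind, domain = as.numeric(domain), ...),
            class = c(paste0(kind, "_profile"), "bending_profile"))
}

#' @rdname bending_profile
#' @export
quartic_profile <- function(c2, c3, c4, domain = c(0, 1.2)) {
  co <- c(c2 = c2, c3 = c3, c4 = c4)
  if (!all(is.finite(co)))
    stop("quartic coefficients must be finite numbers", call. = FALSE)
  new_bending_profile("quartic", domain, c2 = c2, c3 = c3, c4 = c4)
}

#' @rdname bending_profile
#' @export
harmonic_profile <- function(Lp, domain = c(0, pi)) {
  if (!is.finite(Lp) || Lp <= 0)
    stop("persistence length Lp must be a positive finite number", call. = FALSE)
  new_bending_profile("harmonic", domain, Lp = Lp)
}

#' @rdname bending_profile
#' @export
tabulated_profile <- function(theta, energy) {
  if (length(theta) < 4L)
    stop("tabulated profile needs at least 4 knots", call. = FALSE)
  if (length(theta) != length(energy))
    stop("theta and energy must have equal length", call. = FALSE)
  if (!all(is.finite(theta)) || !all(is.finite(energy)))
    stop("tabulated knots must be finite", call. = FALSE)
  if (any(diff(theta) <= 0)) {
    bad <- which(diff(theta) <= 0)[1] + 1L
    stop("tabulated angles must be strictly increasing (violated at row ",
         bad, ")", call. = FALSE)
  }
  fun <- stats::splinefun(theta, energy, method = "monoH.FC")
  new_bending_profile("tabulated", range(theta),
                      theta = as.numeric(theta), energy = as.numeric(energy),
                      interpolant = fun)
}

#' Empirical DNA bending-energy profile
#'
#' The per-base-pair effective bending energy of double-stranded DNA inferred
#' from the distribution of bend angles in a large set of experimental
#' protein-DNA complex structures,
#' \eqn{E(\theta) = 203.1\theta^2 - 552.7\theta^3 + 416.8\theta^4} (kT,
#' \eqn{\theta} in radians).  Its non-convex region gives rise to the
#' two-state (kinked) bending regime analysed by the ECH model.
#'
#' @param domain angular domain in radians; the default covers the convex
#'   hull region (upper tangent near 0.62 rad) with margin while excluding
#'   the unphysical large-angle tail.
#' @return a quartic `bending_profile`.
#' @export
dna_quartic_profile <- function(domain = c(0, 1.2)) {
  quartic_profile(203.1, -552.7, 416.8, domain = domain)
}

check_in_domain <- function(profile, theta) {
  d <- profile$domain
  if (any(theta < d[1]))
    stop(sprintf("angle %.6g rad below profile domain lower bound %.6g rad",
                 min(theta), d[1]), call. = FALSE)
  if (any(theta > d[2]))
    stop(sprintf("angle %.6g rad above profile domain upper bound %.6g rad",
                 max(theta), d[2]), call. = FALSE)
  invisible(TRUE)
}

#' Evaluate a bending-energy profile
#'
#' @param profile a `bending_profile`.
#' @param theta bend angle(s), radians, within the profile domain.
#' @return energy (kT), vectorised over `theta`.
#' @export
profile_energy <- function(profile, theta) {
  UseMethod("profile_energy")
}

#' @export
profile_energy.quartic_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  theta^2 * (profile$c2 + theta * (profile$c3 + theta * profile$c4))
}

#' @export
profile_energy.harmonic_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  0.5 * profile$Lp * theta^2
}

#' @export
profile_energy.tabulated_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  profile$interpolant(theta)
}

#' Derivative of a bending-energy profile
#'
#' Exact analytic derivative for the quartic and harmonic kinds; the
#' interpolant's derivative for tabulated profiles.
#'
#' @inheritParams profile_energy
#' @return dE/d\eqn{\theta} (kT/rad), vectorised over `theta`.
#' @export
profile_slope <- function(profile, theta) {
  UseMethod("profile_slope")
}

#' @export
profile_slope.quartic_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  theta * (2 * profile$c2 + theta * (3 * profile$c3 + theta * 4 * profile$c4))
}

#' @export
profile_slope.harmonic_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  profile$Lp * theta
}

#' @export
profile_slope.tabulated_profile <- function(profile, theta) {
  check_in_domain(profile, theta)
  profile$interpolant(theta, deriv = 1)
}

#' @export
print.bending_profile <- function(x, ...) {
  cat("<bending_profile:", x$kind, ">\n")
  cat("  domain: [", format(x$domain[1]), ",", format(x$domain[2]), "] rad\n")
  switch(x$kind,
    quartic = cat(sprintf("  E(theta) = %g th^2 + %g th^3 + %g th^4  (kT)\n",
                          x$c2, x$c3, x$c4)),
    harmonic = cat(sprintf("  E(theta) = 0.5 * %g * th^2  (kT), Lp = %g sites\n",
                           x$Lp, x$Lp)),
    tabulated = cat("  knots:", length(x$theta), "\n"))
  invisible(x)
}

# Internal: encode a profile for the C++ kernels.
# quartic -> kind 0, params (c2, c3, c4); harmonic -> kind 1, params (Lp);
# tabulated -> kind 2 with a dense equispaced lookup table (linear interp in
# C++) built from the monotone-cubic interpolant.
profile_for_kernel <- function(profile, theta_max = pi, n_table = 4096L) {
  if (inherits(profile, "quartic_profile")) {
    list(kind = 0L, params = c(profile$c2, profile$c3, profile$c4),
         tab_x = numeric(0), tab_y = numeric(0))
  } else if (inherits(profile, "harmonic_profile")) {
    list(kind = 1L, params = profile$Lp, tab_x = numeric(0), tab_y = numeric(0))
  } else {
    lo <- profile$domain[1]
    hi <- min(profile$domain[2], theta_max)
    x <- seq(lo, hi, length.out = n_table)
    list(kind = 2L, params = numeric(0), tab_x = x, tab_y = profile$interpolant(x))
  }
}
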