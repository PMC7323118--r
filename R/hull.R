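#' Double-tangent (convex hull) construction for a bending-energy profile
#'
#' A non-convex bending-energy profile \eqn{E(\theta)} admits a common-tangent
#' line touching it at two angles \eqn{\theta_a < \theta_b} and lying strictly
#' below the curve in between: the lower convex hull of the profile.  The
#' construction is the bending analogue of the double-tangent rule of
#' phase-coexistence thermodynamics: between \eqn{\theta_a} and
#' \eqn{\theta_b} the minimum-energy chain phase-separates into weakly bent
#' sites at \eqn{\theta_a} and strongly bent ("kinked") sites at
#' \eqn{\theta_b}, and its per-site energy follows the hull line with slope
#' \eqn{\lambda} (the Lagrange multiplier of the constrained minimisation).
#'
#' The finder samples the profile on a uniform grid, builds the discrete
#' lower convex hull by monotone chain, uses the hull edge that skips
#' interior samples to bracket the tangency pair, and refines the bracket
#' with a damped Newton iteration on the tangency system
#' \eqn{E'(a) = E'(b) = (E(b)-E(a))/(b-a)}.
#'
#' @param profile a [bending_profile][quartic_profile].
#' @param domain angular search interval in radians; defaults to the profile
#'   domain.
#' @param tol tangency residual tolerance, kT/rad.
#' @param grid_n number of grid samples used for bracketing.
#' @return an object of class `hull_result` with fields `theta_a`, `theta_b`
#'   (radians), `lambda` (common slope, kT/rad), `E_a`, `E_b` (kT), or `NULL`
#'   if the profile is convex on the domain (no double tangent exists).
#' @examples
#' find_double_tangent(dna_quartic_profile())   # theta_a ~ 2.2 deg, theta_b ~ 35.8 deg
#' find_double_tangent(harmonic_profile(150))   # NULL: convex everywhere
#' @export
find_double_tangent <- function(profile, domain = profile$domain,
                                tol = 1e-10, grid_n = 4001L) {
  stopifnot(length(domain) == 2L, domain[1] < domain[2])
  x <- seq(domain[1], domain[2], length.out = grid_n)
  y <- profile_energy(profile, x)

  hull_idx <- lower_hull_indices(x, y)
  gaps <- diff(hull_idx)
  long <- which(gaps > 1L)          # hull edges skipping interior samples
  if (length(long) == 0L) return(NULL)
  # Cluster long edges separated by at most two elementary edges (a sample
  # sitting numerically on the chord splits one region in two), then drop
  # clusters that are sub-resolution ripple rather than genuine
  # non-convexity: spanning <= 5 samples, or with the profile dipping less
  # than depth_tol below the chord (interpolated tabulated profiles carry
  # ripple of this size).
  cl_id <- cumsum(c(1L, diff(long) > 3L))
  clusters <- split(long, cl_id)
  span <- vapply(clusters, function(e)
    hull_idx[max(e) + 1L] - hull_idx[min(e)], integer(1))
  depth_tol <- max(1e-5 * diff(range(y)), 1e-9)
  depth <- vapply(clusters, function(e) {
    i <- hull_idx[min(e)]; j <- hull_idx[max(e) + 1L]
    mid <- (i + 1):(j - 1)
    chord <- y[i] + (x[mid] - x[i]) / (x[j] - x[i]) * (y[j] - y[i])
    max(y[mid] - chord)
  }, numeric(1))
  clusters <- clusters[span > 5L & depth > depth_tol]
  if (length(clusters) == 0L) return(NULL)
  if (length(clusters) > 1L)
    stop("profile has multiple non-convex regions; only a single ",
         "double-tangent segment is supported", call. = FALSE)

  i <- hull_idx[min(clusters[[1]])]
  j <- hull_idx[max(clusters[[1]]) + 1L]
  if (i == 1L || j == grid_n)
    stop("hull-truncated-by-domain: the double-tangent segment touches the ",
         "search domain boundary; widen `domain`", call. = FALSE)

  ab <- refine_tangency(profile, x[i], x[j], domain, tol)
  a <- ab[1]; b <- ab[2]
  Ea <- profile_energy(profile, a)
  Eb <- profile_energy(profile, b)
  structure(list(theta_a = a, theta_b = b,
                 lambda = (Eb - Ea) / (b - a), E_a = Ea, E_b = Eb),
            class = "hull_result")
}

# Monotone-chain lower convex hull of points already sorted by x.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      # pop while the last turn is not strictly convex (cross product <= 0)
      cr <- (x[h[k]] - x[h[k - 1L]]) * (y[i] - y[h[k - 1L]]) -
            (y[h[k]] - y[h[k - 1L]]) * (x[i] - x[h[k - 1L]])
      if (cr <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

# Damped Newton on F(a,b) = (E'(a) - s, E'(b) - s), s = (E(b)-E(a))/(b-a),
# with a numerically differenced Jacobian of profile_slope.
refine_tangency <- function(profile, a, b, domain, tol) {
  fres <- function(p) {
    s <- (profile_energy(profile, p[2]) - profile_energy(profile, p[1])) /
      (p[2] - p[1])
    c(profile_slope(profile, p[1]) - s, profile_slope(profile, p[2]) - s)
  }
  p <- c(a, b)
  h0 <- 1e-7 * (domain[2] - domain[1])
  for (iter in 1:100) {
    f <- fres(p)
    if (max(abs(f)) < tol) break
    J <- matrix(0, 2, 2)
    for (k in 1:2) {
      dp <- p
      dm <- p
      dp[k] <- min(dp[k] + h0, domain[2])
      dm[k] <- max(dm[k] - h0, domain[1])
      J[, k] <- (fres(dp) - fres(dm)) / (dp[k] - dm[k])
    }
    step <- tryCatch(solve(J, f), error = function(e) f * 0)
    damp <- 1
    repeat {
      q <- p - damp * step
      ok <- q[1] > domain[1] && q[2] < domain[2] && q[1] < q[2]
      if (ok && max(abs(fres(q))) <= max(abs(f))) break
      damp <- damp / 2
      if (damp < 1e-8) { q <- p; break }
    }
    if (identical(q, p)) break
    p <- q
  }
  p
}

#' @export
print.hull_result <- function(x, ...) {
  cat("<hull_result>\n")
  cat(sprintf("  theta_a = %.6f rad (%.2f deg), E_a = %.4f kT\n",
              x$theta_a, x$theta_a * 180 / pi, x$E_a))
  cat(sprintf("  theta_b = %.6f rad (%.2f deg), E_b = %.4f kT\n",
              x$theta_b, x$theta_b * 180 / pi, x$E_b))
  cat(sprintf("  common slope lambda = %.4f kT/rad\n", x$lambda))
  invisible(x)
}

#' Hull-line (phase-coexistence) energy
#'
#' Per-site energy on the common-tangent segment: the linear interpolation
#' between the tangency points, the energy of the two-state mixture of weak
#' and strong bends at average angle `theta_bar`.
#'
#' @param profile the bending profile the hull was computed from.
#' @param hull a `hull_result` from [find_double_tangent()].
#' @param theta_bar average bend angle(s), radians, in
#'   `[theta_a, theta_b]`.
#' @return energy in kT.
#' @export
hull_energy <- function(profile, hull, theta_bar) {
  if (any(theta_bar < hull$theta_a) || any(theta_bar > hull$theta_b))
    stop("theta_bar outside [theta_a, theta_b]; use profile_energy() for ",
         "angles outside the hull segment", call. = FALSE)
  hull$E_a + (theta_bar - hull$theta_a) /
    (hull$theta_b - hull$theta_a) * (hull$E_b - hull$E_a)
}

#' Fraction of strongly bent sites in the two-state regime
#'
#' In the coexistence region the lever rule gives the fraction of sites bent
#' through the strong angle \eqn{\theta_b}:
#' \eqn{p = (\bar\theta - \theta_a)/(\theta_b - \theta_a)}.
#'
#' @param theta_bar average bend angle, radians.
#' @param theta_a,theta_b hull tangency angles, radians.
#' @return fraction in `[0, 1]`, vectorised over `theta_bar`.
#' @export
strong_fraction <- function(theta_bar, theta_a, theta_b) {
  stopifnot(theta_a < theta_b)
  if (any(theta_bar < theta_a) || any(theta_bar > theta_b))
    stop("theta_bar outside [theta_a, theta_b]", call. = FALSE)
  (theta_bar - theta_a) / (theta_b - theta_a)
}

#' ECH model and its piecewise per-site energy
#'
#' The energy convex hull (ECH) model keeps the harmonic worm-like-chain
#' energy for weak average bends and switches to the linear hull-line energy
#' beyond the hull onset angle \eqn{\theta_a}:
#' \deqn{E(\bar\theta) = \tfrac12 L_p \bar\theta^2
#'   \quad (\bar\theta \le \theta_a), \qquad
#'   E(\bar\theta) = L_p \theta_a (\bar\theta - \theta_a/2)
#'   \quad (\theta_a < \bar\theta < \theta_b).}
#' Both value and first derivative are continuous at \eqn{\theta_a}.  The
#' extreme regime \eqn{\bar\theta \ge \theta_b} (loops shorter than about
#' 10 bp for DNA) is outside the model's validity and is rejected.
#'
#' @param Lp persistence length in bending sites (bp).
#' @param theta_a hull onset angle, radians.
#' @param theta_b optional upper validity bound, radians (`Inf` to disable).
#' @return `ech_model()` returns an object of class `ech_model`;
#'   `ech_energy()` the per-site energy in kT.
#' @examples
#' m <- ech_model(Lp = 150, theta_a = 2.2 * pi / 180)
#' ech_energy(m, 0.3)
#' @export
ech_model <- function(Lp, theta_a, theta_b = Inf) {
  stopifnot(is.finite(Lp), Lp > 0, is.finite(theta_a), theta_a > 0,
            theta_b > theta_a)
  structure(list(Lp = Lp, theta_a = theta_a, theta_b = theta_b),
            class = "ech_model")
}

#' @rdname ech_model
#' @param model an `ech_model`.
#' @param theta_bar average bend angle(s), radians, `0 <= theta_bar < theta_b`.
#' @export
ech_energy <- function(model, theta_bar) {
  stopifnot(inherits(model, "ech_model"))
  if (any(theta_bar < 0))
    stop("theta_bar must be non-negative", call. = FALSE)
  if (any(theta_bar >= model$theta_b))
    stop("theta_bar >= theta_b: the uniform re-entrant strong-bending ",
         "regime is outside the ECH model's validity", call. = FALSE)
  Lp <- model$Lp
  ta <- model$theta_a
  ifelse(theta_bar <= ta,
         0.5 * Lp * theta_bar^2,
         Lp * ta * (theta_bar - 0.5 * ta))
}

#' Minimum bending energy of a chain with a fixed total bend
#'
#' Minimises \eqn{\sum_i E(\theta_i)} over the per-site bend angles of an
#' `N`-site chain subject to the constraint \eqn{\sum_i \theta_i = \alpha}.
#' For a convex profile the optimum is uniform bending,
#' \eqn{\theta_i = \alpha/N}.  For a profile with a double-tangent segment
#' and \eqn{\theta_a < \alpha/N < \theta_b}, the optimum is the two-state
#' assignment: `m` sites near the strong angle \eqn{\theta_b} and the rest
#' near \eqn{\theta_a}.  Because `m` must be an integer, both
#' \eqn{\lfloor pN \rfloor} and \eqn{\lceil pN \rceil} strong sites are
#' completed (the weak angle adjusting to honour the exact sum constraint)
#' and the lower total kept; the uniform assignment is also compared.
#'
#' @param profile a bending profile.
#' @param N number of bending sites (>= 2).
#' @param alpha total bend, radians (\eqn{2\pi} for a closed loop).
#' @param hull optional precomputed `hull_result`; computed if missing.
#' @return list with `energy_per_site` (kT), `angles` (length-`N` radians,
#'   summing to `alpha`), and `uniform` (logical: was uniform bending
#'   optimal).
#' @export
constrained_minimum <- function(profile, N, alpha, hull = NULL) {
  stopifnot(N >= 2, alpha >= 0)
  tb <- alpha / N
  check_in_domain(profile, tb)   # infeasible alpha -> domain error
  if (is.null(hull))
    hull <- tryCatch(find_double_tangent(profile), error = function(e) NULL)

  uniform <- list(energy_per_site = profile_energy(profile, tb),
                  angles = rep(tb, N), uniform = TRUE)
  if (is.null(hull) || tb <= hull$theta_a || tb >= hull$theta_b)
    return(uniform)

  p <- strong_fraction(tb, hull$theta_a, hull$theta_b)
  best <- uniform
  for (m in unique(c(floor(p * N), ceiling(p * N)))) {
    if (m < 1 || m >= N) next
    tw <- (alpha - m * hull$theta_b) / (N - m)   # weak angle honouring the sum
    if (tw < profile$domain[1] || tw > profile$domain[2]) next
    etot <- m * profile_energy(profile, hull$theta_b) +
      (N - m) * profile_energy(profile, tw)
    if (etot / N < best$energy_per_site) {
      best <- list(energy_per_site = etot / N,
                   angles = c(rep(hull$theta_b, m), rep(tw, N - m)),
                   uniform = FALSE)
    }
  }
  best
}
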