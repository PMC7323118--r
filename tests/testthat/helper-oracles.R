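# Independent oracles used across the suite.  These deliberately avoid the
# package's own solver paths: the hull oracle is a brute-force discrete
# lower-hull scan, the constrained-minimum oracle a dynamic program over a
# discretised angle grid, and the open-chain oracle draws i.i.d. angles from
# the exact single-site Boltzmann density.

# Discrete lower convex hull of E sampled on a dense grid; returns the grid
# chord that skips interior samples (the double-tangent bracket), or NULL if
# every hull edge is elementary (convex profile).
brute_hull_oracle <- function(profile, domain = profile$domain, n = 1e5) {
  x <- seq(domain[1], domain[2], length.out = n)
  y <- profile_energy(profile, x)
  h <- integer(n); k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      cr <- (x[h[k]] - x[h[k - 1L]]) * (y[i] - y[h[k - 1L]]) -
            (y[h[k]] - y[h[k - 1L]]) * (x[i] - x[h[k - 1L]])
      if (cr <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    h[k] <- i
  }
  h <- h[seq_len(k)]
  gaps <- diff(h)
  long <- which(gaps > 1L)
  if (length(long) == 0L) return(NULL)
  long <- long[which.max(gaps[long])]
  list(theta_a = x[h[long]], theta_b = x[h[long + 1L]])
}

# Dynamic-programming minimisation of sum(E(theta_i)) subject to
# sum(theta_i) = alpha, with angles restricted to a uniform grid.  Exact on
# the grid; per-site energies accurate to O(step^2).
dp_constrained_oracle <- function(profile, N, alpha, grid_n = 241L) {
  dom <- profile$domain
  step <- (dom[2] - dom[1]) / (grid_n - 1)
  E <- profile_energy(profile, dom[1] + step * (0:(grid_n - 1)))
  S <- round(alpha / step)        # target sum in grid units
  f <- rep(Inf, S + 1)            # f[s+1]: min energy of sites so far summing s
  f[1] <- 0
  for (n in seq_len(N)) {
    g <- rep(Inf, S + 1)
    for (k in 0:(grid_n - 1)) {
      if (k > S) break
      idx <- (k + 1):(S + 1)
      cand <- f[idx - k] + E[k + 1]
      g[idx] <- pmin(g[idx], cand)
    }
    f <- g
  }
  f[S + 1] / N
}

# i.i.d. bend angles of an unconstrained open chain at 300 K: inverse-CDF
# samples from the density proportional to sin(theta) * exp(-E(theta)).
open_chain_angle_oracle <- function(profile, n, seed, theta_max = pi) {
  set.seed(seed)
  th <- seq(1e-6, theta_max, length.out = 20001)
  E <- if (inherits(profile, "harmonic_profile")) 0.5 * profile$Lp * th^2
       else th^2 * (profile$c2 + th * (profile$c3 + th * profile$c4))
  w <- sin(th) * exp(-(E - min(E)))
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)   # flat high-energy tail
  stats::approx(cdf[keep], th[keep], xout = stats::runif(n), rule = 2)$y
}

paper_profile <- function() dna_quartic_profile()
deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

# Random non-convex quartic with its hull inside (0, 1.1); used by the
# hull-oracle equivalence checks.
random_nonconvex_quartic <- function() {
  repeat {
    c2 <- runif(1, 50, 400)
    c3 <- -runif(1, 2.5, 4.5) * c2
    c4 <- runif(1, 1.1, 2.2) * abs(c3)
    if (9 * c3^2 <= 32 * c2 * c4) next       # convexity discriminant
    q <- quartic_profile(c2, c3, c4, domain = c(0, 1.2))
    h <- tryCatch(find_double_tangent(q), error = function(e) NULL)
    if (!is.null(h) && h$theta_b < 1.1) return(q)
  }
}
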