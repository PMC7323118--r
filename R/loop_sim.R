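#' Closed bead-chain (ring) construction
#'
#' Builds a planar regular `N`-gon of beads with side `b`, the unstrained
#' starting conformation for closed-loop simulations: every bend angle is
#' exactly `2*pi/N` and the total curvature is `2*pi`.
#'
#' @param N bead count (one bead per bending site / base pair), >= 3.
#' @param b bond length in Angstrom (3.3 A: base-pair rise of B-DNA).
#' @return an object of class `ring_chain`: list with `N`, `coords`
#'   (`N x 3`, Angstrom), `b`, `topology = "ring"`.
#' @export
build_regular_loop <- function(N, b = 3.3) {
  if (N < 3) stop("a ring needs at least 3 beads", call. = FALSE)
  R <- b / (2 * sin(pi / N))
  phi <- 2 * pi * (seq_len(N) - 1) / N
  coords <- cbind(R * cos(phi), R * sin(phi), 0)
  structure(list(N = as.integer(N), coords = coords, b = b, topology = "ring"),
            class = "ring_chain")
}

#' Bend angles of a bead chain
#'
#' Angle at each bending site between the incoming and outgoing bond vectors
#' (0 = straight, radians in `[0, pi]`).  Ring chains have `N` angles (with
#' wraparound), open chains `N - 2` interior angles.
#'
#' @param chain a `ring_chain`, or any list with `coords` and `topology`.
#' @return numeric vector of angles, radians.
#' @export
bend_angles <- function(chain) {
  ring <- identical(chain$topology, "ring")
  .bend_angles_cpp(chain$coords, ring)
}

#' Metropolis Monte-Carlo sampling of a closed loop
#'
#' Samples a closed bead chain with virtually inextensible bonds (stiff
#' harmonic springs) and the supplied per-site bending potential, using
#' single-bead Gaussian displacement moves with the step size auto-tuned
#' during burn-in towards ~40 % acceptance.  No further bead-bead
#' interactions or geometric constraints are imposed.  Energies are in kT at
#' 300 K; the Metropolis weight at temperature `T` uses `beta = 300/T`.
#'
#' For a non-convex bending potential this sampler reproduces the two-state
#' bending phenomenology: loops whose average angle `2*pi/N` lies inside the
#' hull region develop a bimodal bend-angle distribution with peaks near the
#' two tangency angles, while large loops remain unimodal.
#'
#' @param chain a `ring_chain` starting conformation.
#' @param profile a [bending_profile][quartic_profile]; analytic kinds are
#'   evaluated by their formula at any angle, tabulated kinds by their
#'   interpolant (clamped outside the table).
#' @param T temperature, K.
#' @param sweeps number of MC sweeps (one sweep = `N` single-bead attempts).
#' @param seed integer RNG seed (trajectories are bit-reproducible).
#' @param burn_frac fraction of sweeps discarded as burn-in.
#' @param thin record one snapshot every `thin` post-burn-in sweeps.
#' @param bond_k bond stiffness, kT/A^2.
#' @param step0 initial displacement scale, Angstrom.
#' @param record_coords store snapshot coordinates (needed for trajectory
#'   output; angles and energies are always stored).
#' @return an object of class `loop_ensemble`: `angles` (frames x N,
#'   radians), `bend_energy` and `total_energy` per frame (kT), `coords`
#'   (list of frame matrices or `NULL`), `final` (`ring_chain`),
#'   `acceptance`, `energy_drift_max`, `seed`, `T`.
#' @export
mc_sample <- function(chain, profile, T = 300, sweeps = 10000L,
                      seed = 1L, burn_frac = 0.1, thin = 10L,
                      bond_k = 100, step0 = 0.3, record_coords = FALSE) {
  stopifnot(inherits(chain, "ring_chain"))
  if (sweeps <= 0) stop("sweeps must be positive", call. = FALSE)
  set.seed(seed)
  pr <- profile_for_kernel(profile)
  res <- .mc_ring_cpp(chain$coords, pr, beta = 300 / T,
                      sweeps = as.integer(sweeps), burn_frac = burn_frac,
                      thin = as.integer(thin), step0 = step0,
                      bond_k = bond_k, bond_b = chain$b,
                      record_coords = record_coords, check_every = 1000L)
  if (res$acceptance < 0.05 || res$acceptance > 0.95)
    warning(sprintf("MC acceptance rate %.2f outside (0.05, 0.95) after tuning",
                    res$acceptance))
  coords <- NULL
  if (record_coords && res$n_frames > 0) {
    coords <- lapply(seq_len(res$n_frames), function(f) {
      off <- (f - 1) * chain$N * 3
      matrix(res$coords_flat[off + seq_len(chain$N * 3)],
             ncol = 3, byrow = TRUE)
    })
  }
  structure(list(
    angles = res$angles[seq_len(res$n_frames), , drop = FALSE],
    bend_energy = res$bend_energy[seq_len(res$n_frames)],
    total_energy = res$total_energy[seq_len(res$n_frames)],
    coords = coords,
    final = structure(list(N = chain$N, coords = res$final_coords,
                           b = chain$b, topology = "ring"),
                      class = "ring_chain"),
    acceptance = res$acceptance, step = res$step,
    energy_drift_max = res$energy_drift_max,
    seed = seed, T = T, N = chain$N, b = chain$b),
    class = "loop_ensemble")
}

#' Energy minimisation of a closed loop
#'
#' Relaxes a ring conformation to a local minimum of the total energy
#' (stiff bonds plus bending potential) with the FIRE inertial relaxation
#' scheme, stopping when the max-norm gradient falls below `tol` (kT/A).
#' Starting from a thermal snapshot this yields the zero-temperature
#' conformation of the sampled basin: a uniform ring below the hull onset,
#' or a kinked ring whose per-site energy falls on the hull line inside the
#' two-state region.
#'
#' @inheritParams mc_sample
#' @param tol gradient max-norm convergence tolerance, kT/A.
#' @param max_iter iteration cap; non-convergence raises an error carrying
#'   the last state.
#' @return list with `chain` (minimised `ring_chain`), `energy_per_site`
#'   (bending energy per site, kT), `angles` (radians), `total_energy`,
#'   `iterations`.
#' @export
minimize_loop <- function(chain, profile, bond_k = 100, tol = 1e-6,
                          max_iter = 500000L) {
  stopifnot(inherits(chain, "ring_chain"))
  res <- withCallingHandlers(
    .minimize_ring_cpp(chain$coords, profile_for_kernel(profile),
                       bond_k = bond_k, bond_b = chain$b,
                       tol = tol, max_iter = as.integer(max_iter)),
    warning = function(w) invokeRestart("muffleWarning"))
  out_chain <- structure(list(N = chain$N, coords = res$coords, b = chain$b,
                              topology = "ring"), class = "ring_chain")
  if (!res$converged) {
    e <- simpleError(sprintf(
      "minimization did not converge in %d iterations", max_iter))
    e$last_state <- out_chain
    stop(e)
  }
  list(chain = out_chain,
       energy_per_site = res$angle_energy / chain$N,
       angles = bend_angles(out_chain),
       total_energy = res$energy,
       iterations = res$iterations)
}

#' Simulated-annealing minimisation of a closed loop
#'
#' Cools a ring through a staged Monte-Carlo temperature schedule and then
#' relaxes the final conformation with [minimize_loop()].  Annealing lets
#' the kink count equilibrate at each stage, so the result approaches the
#' global two-state optimum (the hull line) rather than freezing in the
#' kink excess of a single thermal snapshot, which plain descent does.
#'
#' @inheritParams mc_sample
#' @param T_schedule decreasing temperatures, K.
#' @param sweeps_per_T MC sweeps at each stage.
#' @param ... passed to [minimize_loop()].
#' @return as [minimize_loop()].
#' @export
anneal_loop <- function(chain, profile, T_schedule = c(300, 150, 60, 20, 5),
                        sweeps_per_T = 4000L, seed = 1L, bond_k = 100, ...) {
  cur <- chain
  for (i in seq_along(T_schedule)) {
    # burn_frac 0.5 so the step size re-tunes to the stage temperature
    ens <- suppressWarnings(
      mc_sample(cur, profile, T = T_schedule[i], sweeps = sweeps_per_T,
                seed = seed + i, burn_frac = 0.5, thin = sweeps_per_T,
                bond_k = bond_k))
    cur <- ens$final
  }
  minimize_loop(cur, profile, bond_k = bond_k, ...)
}

#' Weak/strong bending-state occupancy of an ensemble
#'
#' Classifies every sampled bend angle as weakly or strongly bent relative
#' to a boundary angle and returns the two fractions.  The default boundary,
#' the midpoint `(theta_a + theta_b)/2` of the hull segment, lies in the
#' depleted valley between the bimodal peaks.
#'
#' @param ensemble a `loop_ensemble` from [mc_sample()], or any object with
#'   an `angles` matrix, or a bare numeric vector/matrix of angles.
#' @param hull a `hull_result` (used for the default boundary).
#' @param boundary classification angle, radians; overrides `hull`.
#' @return named numeric vector `c(weak = ..., strong = ...)`, summing to 1.
#' @export
angle_occupancy <- function(ensemble, hull = NULL, boundary = NULL) {
  ang <- if (is.numeric(ensemble)) ensemble else ensemble$angles
  if (length(ang) == 0) stop("empty ensemble", call. = FALSE)
  if (is.null(boundary)) {
    if (is.null(hull))
      stop("supply either a hull_result or an explicit boundary", call. = FALSE)
    boundary <- (hull$theta_a + hull$theta_b) / 2
  }
  strong <- mean(ang >= boundary)
  c(weak = 1 - strong, strong = strong)
}

#' Histogram of sampled bend angles
#'
#' Fixed-width binning of an ensemble's bend angles (default 0.5 degree bins
#' on 0-60 degrees), returned as a density over angle in radians.
#'
#' @inheritParams angle_occupancy
#' @param bin_deg bin width, degrees.
#' @param range_deg histogram range, degrees.
#' @return `data.frame` with `center_rad`, `center_deg`, `density`.
#' @export
angle_histogram <- function(ensemble, bin_deg = 0.5, range_deg = c(0, 60)) {
  ang <- if (is.numeric(ensemble)) ensemble else ensemble$angles
  deg <- as.vector(ang) * 180 / pi
  breaks <- seq(range_deg[1], range_deg[2], by = bin_deg)
  deg <- deg[deg >= range_deg[1] & deg <= range_deg[2]]
  h <- graphics::hist(deg, breaks = breaks, plot = FALSE)
  data.frame(center_rad = h$mids * pi / 180, center_deg = h$mids,
             density = h$density * 180 / pi)
}

#' Count modes of a smoothed bend-angle histogram
#'
#' Used to classify ensembles as unimodal (weak bending only) or bimodal
#' (two-state coexistence of weakly and strongly bent sites).
#'
#' Applies a fixed moving-average smoothing to the binned angle density and
#' counts local maxima whose topographic prominence (height above the
#' highest saddle separating the peak from higher terrain) exceeds a fixed
#' fraction of the global maximum.  Prominence, unlike a bare height floor,
#' rejects ripple in the depleted valley between genuine modes.
#'
#' @inheritParams angle_histogram
#' @param smooth moving-average window, bins (odd).
#' @param min_prom minimum peak prominence relative to the global maximum.
#' @return list with `n_modes` and `modes_deg` (peak locations, degrees).
#' @export
histogram_modes <- function(ensemble, bin_deg = 0.5, range_deg = c(0, 60),
                            smooth = 9L, min_prom = 0.02) {
  h <- angle_histogram(ensemble, bin_deg, range_deg)
  d <- stats::filter(h$density, rep(1 / smooth, smooth), sides = 2)
  d[is.na(d)] <- 0
  d <- as.numeric(d)
  n <- length(d)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (d[i] > d[i - 1] && d[i] >= d[i + 1]) {
      j <- i
      while (j < n - 1L && d[j + 1] == d[j]) j <- j + 1L   # plateau
      if (d[j + 1] < d[i]) peaks <- c(peaks, as.integer(round((i + j) / 2)))
      i <- j + 1L
    }
    i <- i + 1L
  }
  prominence <- vapply(peaks, function(i) {
    lhs <- d[1:i]
    rhs <- d[i:n]
    sad_l <- if (any(lhs > d[i])) min(d[max(which(lhs > d[i])):i]) else 0
    sad_r <- if (any(rhs > d[i]))
      min(d[i:(i - 1 + min(which(rhs > d[i])))]) else 0
    d[i] - max(sad_l, sad_r)
  }, numeric(1))
  peaks <- peaks[prominence >= min_prom * max(d)]
  list(n_modes = length(peaks), modes_deg = h$center_deg[peaks])
}
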