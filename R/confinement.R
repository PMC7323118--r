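#' Electrostatically confined chain ("protein-DNA complex" toy model)
#'
#' An open chain of `N` charged beads (charge `qs`, default -1) with stiff
#' bonds and a per-site bending potential is attracted to a positive charge
#' `Q` carried by an impenetrable core (sphere or cylinder of radius `R` at
#' the origin); two impenetrable walls at `z = +-gap/2` suppress
#' out-of-plane bending.  The confinement strength is `|Q/qs|`.  Under
#' strong confinement the chain is pressed onto a uniformly curved path on
#' the core surface and its mean bending energy follows the bare profile
#' `E(theta)`; under weak confinement the chain is free to trade uniform
#' bending for localized kinks and its energy per bead approaches the
#' convex hull of `E(theta)`.
#'
#' Electrostatics are unscreened Coulomb in kT units,
#' `E = q_i q_j l_B / r`, with the Bjerrum length `l_B = 7.1` A (water,
#' 300 K); an absolute dielectric calibration is not attempted since the
#' crossover depends only on the ordering of confinement strengths.
#'
#' @param N bead count (20 for the minimal model; 147 for the
#'   nucleosome-geometry variant).
#' @param profile a [bending_profile][quartic_profile].
#' @param Q core charge, atomic units (> 0 attracts the `qs = -1` beads).
#' @param R core radius, Angstrom.
#' @param qs bead charge, atomic units.
#' @param core `"sphere"` or `"cylinder"` (axis along z).
#' @param gap wall separation, Angstrom (0 disables the walls).
#' @param b bond length, Angstrom.
#' @param lB Bjerrum length, Angstrom.
#' @param nonbonded enable bead-bead Coulomb plus soft-core repulsion
#'   (nucleosome variant); off for the minimal model, whose bead charges
#'   interact only with the core.
#' @return an object of class `confined_system`.
#' @export
confined_system <- function(N = 20, profile = dna_quartic_profile(),
                            Q = 100, R = 15, qs = -1,
                            core = c("sphere", "cylinder"), gap = 10,
                            b = 3.3, lB = 7.1, nonbonded = FALSE) {
  core <- match.arg(core)
  if (Q < 0) stop("core charge Q must be >= 0", call. = FALSE)
  stopifnot(N >= 3, R > 0, b > 0)
  structure(list(N = as.integer(N), profile = profile, Q = Q, R = R, qs = qs,
                 core = core, gap = gap, b = b, lB = lB,
                 nonbonded = nonbonded),
            class = "confined_system")
}

# Starting conformation: chain wrapped on a circle just outside the core,
# at z = 0, clamped to at most ~0.9 turns so the geometry stays feasible.
# With no core attraction (Q = 0) nothing favours wrapping, so the chain
# starts straight on a tangent line instead.
confined_start <- function(sys) {
  if (sys$Q == 0) {
    xs <- (seq_len(sys$N) - (sys$N + 1) / 2) * sys$b
    return(cbind(xs, rep(sys$R + 2, sys$N), rep(0, sys$N)))
  }
  r0 <- sys$R + 1.5
  dphi <- 2 * asin(sys$b / (2 * r0))
  if ((sys$N - 1) * dphi > 1.8 * pi) {
    # long chain relative to core: spiral out slightly in z if walls allow
    dz <- if (sys$gap > 0) 0.8 * sys$gap / sys$N else sys$b / 4
    phi <- (seq_len(sys$N) - 1) * dphi
    z <- (seq_len(sys$N) - 1 - (sys$N - 1) / 2) * dz
    coords <- cbind(r0 * cos(phi), r0 * sin(phi), z)
  } else {
    phi <- (seq_len(sys$N) - 1) * dphi
    coords <- cbind(r0 * cos(phi), r0 * sin(phi), 0)
  }
  coords
}

#' Sample a confined chain at equilibrium
#'
#' Metropolis Monte-Carlo for a [confined_system()]: single-bead Gaussian
#' moves, step auto-tuned during burn-in, moves that penetrate the core or
#' the walls rejected outright (a steep inverse-power surface repulsion
#' keeps accepted beads off the contact surfaces).
#'
#' The reported average bend angle `theta_bar` is taken over interior
#' bending sites whose bead lies within `contact_cut` of the core surface
#' (default `1.5 * b` beyond `R`), i.e. over the wrapped part of the chain.
#'
#' @param sys a `confined_system`.
#' @param T temperature, K.
#' @param sweeps MC sweeps (one sweep = `N` single-bead attempts).
#' @param seed integer RNG seed.
#' @param burn_frac,thin,step0 sampler controls as in [mc_sample()].
#' @param bond_k bond stiffness, kT/A^2.
#' @param contact_cut contact-shell thickness beyond `R`, Angstrom.
#' @param n_detach,detach_off,k_detach outward flat-bottom restraint on the
#'   trailing `n_detach` beads (used by [unwrap_energy()]): beads are pushed
#'   outside `R + detach_off` with stiffness `k_detach` (kT/A^2).
#' @param record_coords store snapshot coordinates.
#' @return an object of class `confined_ensemble` with per-frame `angles`
#'   (interior sites), `radii` (bead distances from the core axis/centre),
#'   `bend_energy`, `total_energy`, and the summaries `theta_bar` (mean
#'   contact-site bend angle, radians) and `energy_per_bead` (mean bending
#'   energy per contact site, kT).
#' @export
simulate_confined <- function(sys, T = 300, sweeps = 20000L, seed = 1L,
                              burn_frac = 0.2, thin = 10L, step0 = 0.3,
                              bond_k = 100, contact_cut = 1.5 * sys$b,
                              n_detach = 0L, detach_off = 25,
                              k_detach = 5, record_coords = FALSE) {
  stopifnot(inherits(sys, "confined_system"))
  if (sweeps <= 0) stop("sweeps must be positive", call. = FALSE)
  set.seed(seed)
  res <- .mc_confined_cpp(
    confined_start(sys), profile_for_kernel(sys$profile), beta = 300 / T,
    sweeps = as.integer(sweeps), burn_frac = burn_frac,
    thin = as.integer(thin), step0 = step0,
    bond_k = bond_k, bond_b = sys$b,
    qs = sys$qs, Q = sys$Q, lB = sys$lB, R = sys$R, gap = sys$gap,
    core = if (sys$core == "sphere") 0L else 1L,
    nonbonded = sys$nonbonded, sigma = sys$b,
    n_detach = as.integer(n_detach), detach_off = detach_off,
    k_detach = k_detach, record_coords = record_coords)

  nf <- res$n_frames
  ang <- res$angles[seq_len(nf), , drop = FALSE]
  rad <- res$radii[seq_len(nf), , drop = FALSE]
  # site i (angle column i) corresponds to bead i+1; contact = bead on core
  site_rad <- rad[, 2:(sys$N - 1), drop = FALSE]
  contact <- site_rad <= sys$R + contact_cut
  pe <- profile_energy_unbounded(sys$profile, ang)
  any_contact <- any(contact)
  theta_bar <- if (any_contact) mean(ang[contact]) else mean(ang)
  e_bead <- if (any_contact) mean(pe[contact]) else mean(pe)

  coords <- NULL
  if (record_coords && nf > 0) {
    coords <- lapply(seq_len(nf), function(f) {
      off <- (f - 1) * sys$N * 3
      matrix(res$coords_flat[off + seq_len(sys$N * 3)], ncol = 3, byrow = TRUE)
    })
  }
  structure(list(
    system = sys, angles = ang, radii = rad,
    bend_energy = res$bend_energy[seq_len(nf)],
    total_energy = res$total_energy[seq_len(nf)],
    contact = contact, theta_bar = theta_bar, energy_per_bead = e_bead,
    coords = coords,
    final = list(N = sys$N, coords = res$final_coords, b = sys$b,
                 topology = "open"),
    acceptance = res$acceptance, seed = seed, T = T),
    class = "confined_ensemble")
}

# profile_energy without the domain check: MC angles can exceed an analytic
# profile's nominal domain; analytic kinds extend by their formula, tabulated
# kinds clamp (matching the C++ kernel).
profile_energy_unbounded <- function(profile, theta) {
  if (inherits(profile, "quartic_profile")) {
    e <- theta^2 * (profile$c2 + theta * (profile$c3 + theta * profile$c4))
  } else if (inherits(profile, "harmonic_profile")) {
    e <- 0.5 * profile$Lp * theta^2
  } else {
    th <- pmin(pmax(theta, profile$domain[1]), profile$domain[2])
    e <- profile$interpolant(th)
  }
  if (is.matrix(theta)) e <- matrix(e, nrow = nrow(theta))
  e
}

#' Confinement-strength sweep
#'
#' Runs [simulate_confined()] over grids of core charge and radius and
#' collects the (confinement strength, radius, mean contact angle, energy
#' per bead) table describing the crossover between hull-following (weak
#' confinement) and profile-following (strong confinement) behaviour.
#'
#' @param sys template `confined_system` (its `Q` and `R` are overridden).
#' @param Q_values,R_values non-empty grids.
#' @inheritParams simulate_confined
#' @return `data.frame` with columns `Q_ratio` (|Q/qs|), `R`, `theta_bar`
#'   (radians), `energy_per_bead` (kT), `acceptance`.
#' @export
confinement_sweep <- function(sys, Q_values, R_values, T = 300,
                              sweeps = 20000L, seed = 1L, ...) {
  if (length(Q_values) == 0 || length(R_values) == 0)
    stop("empty parameter grid", call. = FALSE)
  grid <- expand.grid(Q = Q_values, R = R_values)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- sys
    s$Q <- grid$Q[i]
    s$R <- grid$R[i]
    sim <- simulate_confined(s, T = T, sweeps = sweeps,
                             seed = seed + i - 1L, ...)
    data.frame(Q_ratio = abs(grid$Q[i] / sys$qs), R = grid$R[i],
               theta_bar = sim$theta_bar,
               energy_per_bead = sim$energy_per_bead,
               acceptance = sim$acceptance)
  })
  do.call(rbind, rows)
}

#' Energy cost of unwrapping a chain segment from the core
#'
#' Estimates the cost of pulling a trailing segment of the chain off the
#' core as the difference of mean physical energies (bonds, bending,
#' electrostatics, surface repulsion; the restraint bias excluded) between
#' a fully wrapped simulation and one in which the segment is restrained
#' outside `R + detach_off`.  This is a mean-energy estimate at the level
#' of a qualitative binding analysis, not a free-energy calculation.
#'
#' @param sys a `confined_system` (nucleosome variant: cylinder core,
#'   `N = 147`, `nonbonded = TRUE`).
#' @param detached number of trailing beads pulled away (bp); 0 returns 0.
#' @inheritParams simulate_confined
#' @return energy cost in kT.
#' @export
unwrap_energy <- function(sys, detached, T = 300, sweeps = 20000L, seed = 1L,
                          detach_off = 25, ...) {
  stopifnot(detached >= 0, detached < sys$N)
  if (detached == 0) return(0)
  full <- simulate_confined(sys, T = T, sweeps = sweeps, seed = seed, ...)
  det <- simulate_confined(sys, T = T, sweeps = sweeps, seed = seed,
                           n_detach = as.integer(detached),
                           detach_off = detach_off, ...)
  # subtract the restraint bias recorded inside total_energy of `det`
  bias <- restraint_bias(det, detached, detach_off)
  mean(det$total_energy - bias) - mean(full$total_energy)
}

restraint_bias <- function(ensemble, detached, detach_off, k_detach = 5) {
  sys <- ensemble$system
  rr <- sys$R + detach_off
  idx <- (sys$N - detached + 1):sys$N
  r <- ensemble$radii[, idx, drop = FALSE]
  pen <- pmax(rr - r, 0)
  rowSums(0.5 * k_detach * pen^2)
}
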