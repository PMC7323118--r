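test_that("regular loops are exact N-gons with total curvature 2*pi", {
  hexa <- build_regular_loop(6, b = 3.3)
  expect_equal(bend_angles(hexa), rep(pi / 3, 6), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(hexa$coords^2)), rep(3.3, 6), tolerance = 1e-12)
  sq <- build_regular_loop(4)
  expect_equal(bend_angles(sq), rep(pi / 2, 4), tolerance = 1e-12)
  for (N in c(3, 7, 50, 311))
    expect_equal(sum(bend_angles(build_regular_loop(N))), 2 * pi,
                 tolerance = 1e-9)
  expect_error(build_regular_loop(2), "at least 3")
})

test_that("bend angles handle open chains, collinear and right-angle triples", {
  open3 <- function(coords) list(coords = coords, topology = "open")
  expect_equal(bend_angles(open3(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))),
               0, tolerance = 1e-12)
  expect_equal(bend_angles(open3(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))),
               pi / 2, tolerance = 1e-12)
  expect_error(bend_angles(open3(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)))),
               "degenerate")
})

test_that("MC trajectories are seed-deterministic", {
  p <- paper_profile()
  ring <- build_regular_loop(30)
  e1 <- mc_sample(ring, p, sweeps = 500, seed = 123)
  e2 <- mc_sample(ring, p, sweeps = 500, seed = 123)
  expect_identical(e1$angles, e2$angles)
  expect_identical(e1$bend_energy, e2$bend_energy)
  e3 <- mc_sample(ring, p, sweeps = 500, seed = 124)
  expect_false(identical(e1$angles, e3$angles))
})

test_that("sampled ensembles keep exact energy bookkeeping and geometry", {
  p <- paper_profile()
  ens <- mc_sample(build_regular_loop(40), p, sweeps = 3000, seed = 5,
                   record_coords = TRUE)
  # incremental MC energy vs periodic full recomputation
  expect_lt(ens$energy_drift_max, 1e-6)
  # stored bending energies equal the profile re-applied to stored angles
  recomputed <- rowSums(matrix(
    echbend:::profile_energy_unbounded(p, ens$angles),
    nrow = nrow(ens$angles)))
  expect_equal(ens$bend_energy, recomputed, tolerance = 1e-9)
  # stored angles equal angles recomputed from stored coordinates
  a_re <- t(vapply(ens$coords, function(m)
    bend_angles(list(coords = m, topology = "ring")),
    numeric(40)))
  expect_equal(unname(ens$angles), unname(a_re), tolerance = 1e-9)
  # stiff-bond regime: thermal bond fluctuations at the harmonic scale
  # sqrt(kT/k) = 0.1 A, and within 1% of b once thermal noise is removed
  bl <- unlist(lapply(ens$coords, function(m) {
    d <- m[c(2:40, 1), ] - m
    sqrt(rowSums(d^2))
  }))
  expect_lt(sqrt(mean((bl - 3.3)^2)), 0.15)
  mn <- minimize_loop(ens$final, p)
  dmin <- mn$chain$coords[c(2:40, 1), ] - mn$chain$coords
  expect_true(all(abs(sqrt(rowSums(dmin^2)) / 3.3 - 1) < 0.01))
  # Fenchel: total curvature of every closed frame at least 2*pi
  expect_true(all(rowSums(ens$angles) >= 2 * pi - 1e-9))
  expect_gt(ens$acceptance, 0.05)
  expect_lt(ens$acceptance, 0.95)
})

test_that("non-convex bending gives bimodal angle statistics, convex unimodal", {
  p <- paper_profile()
  h <- find_double_tangent(p)
  ens60 <- mc_sample(build_regular_loop(60), p, sweeps = 12000, seed = 7)
  m60 <- histogram_modes(ens60)
  expect_equal(m60$n_modes, 2)
  expect_lt(abs(min(m60$modes_deg) - deg(h$theta_a)), 3)
  expect_lt(abs(max(m60$modes_deg) - deg(h$theta_b)), 3)

  ens_h <- mc_sample(build_regular_loop(100), harmonic_profile(150),
                     sweeps = 4000, seed = 8)
  expect_equal(histogram_modes(ens_h)$n_modes, 1)
  expect_true(all(rowSums(ens_h$angles) >= 2 * pi - 1e-9))

  # large loop: average angle below theta_a, single weak-bending mode
  ens300 <- mc_sample(build_regular_loop(300), p, sweeps = 4000, seed = 9)
  m300 <- histogram_modes(ens300)
  expect_equal(m300$n_modes, 1)
  # single thermal mode deep in the weak-bending basin, far below theta_b
  expect_lt(m300$modes_deg, 8)
})

test_that("minimisation recovers the uniform ring for convex potentials", {
  hp <- harmonic_profile(150)
  ring <- build_regular_loop(100)
  set.seed(42)
  noisy <- ring
  noisy$coords <- ring$coords + matrix(rnorm(300, 0, 0.4), ncol = 3)
  mn <- minimize_loop(noisy, hp)
  expect_equal(mn$energy_per_site, 0.5 * 150 * (2 * pi / 100)^2,
               tolerance = 1e-3)
  expect_equal(mn$angles, rep(2 * pi / 100, 100), tolerance = 1e-2)
})

test_that("annealed minima track the hull line inside the two-state region", {
  p <- paper_profile()
  h <- find_double_tangent(p)
  mn <- anneal_loop(build_regular_loop(60), p, sweeps_per_T = 2500, seed = 3)
  hl <- hull_energy(p, h, 2 * pi / 60)
  expect_lt(abs(mn$energy_per_site / hl - 1), 0.1)
  expect_lt(mn$energy_per_site, profile_energy(p, 2 * pi / 60))
  # below the hull onset the minimized ring is uniform at E(2*pi/N)
  mn400 <- minimize_loop(build_regular_loop(400), p)
  expect_equal(mn400$energy_per_site, profile_energy(p, 2 * pi / 400),
               tolerance = 1e-6)
})

test_that("occupancy classification obeys its boundary and the lever rule", {
  expect_equal(angle_occupancy(c(0.1, 0.2, 0.15), boundary = 0.3),
               c(weak = 1, strong = 0))
  expect_equal(angle_occupancy(c(0.4, 0.5), boundary = 0.3),
               c(weak = 0, strong = 1))
  p <- paper_profile()
  h <- find_double_tangent(p)
  mn <- anneal_loop(build_regular_loop(60), p, sweeps_per_T = 2500, seed = 3)
  occ <- angle_occupancy(mn$angles, h)
  p_theory <- strong_fraction(2 * pi / 60, h$theta_a, h$theta_b)
  expect_lt(abs(occ["strong"] - p_theory), 0.05)
  expect_equal(sum(occ), 1)
})
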