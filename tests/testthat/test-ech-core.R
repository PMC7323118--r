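test_that("double tangent of the DNA quartic matches the brute-force hull", {
  p <- paper_profile()
  h <- find_double_tangent(p)
  expect_s3_class(h, "hull_result")
  # published endpoints to one decimal in degrees
  expect_equal(round(deg(h$theta_a), 1), 2.2)
  expect_equal(round(deg(h$theta_b), 1), 35.8)
  # tangency residuals at solver tolerance
  s <- (h$E_b - h$E_a) / (h$theta_b - h$theta_a)
  expect_lt(abs(profile_slope(p, h$theta_a) - s), 1e-8)
  expect_lt(abs(profile_slope(p, h$theta_b) - s), 1e-8)
  expect_equal(h$lambda, s)
  # independent brute-force discrete hull oracle
  o <- brute_hull_oracle(p)
  expect_lt(abs(h$theta_a - o$theta_a), 1e-3)
  expect_lt(abs(h$theta_b - o$theta_b), 1e-3)
})

test_that("convex profiles yield no double tangent", {
  expect_null(find_double_tangent(harmonic_profile(150)))
  expect_null(find_double_tangent(quartic_profile(75, 0, 0)))
})

test_that("a hull segment touching the domain boundary is reported", {
  p <- paper_profile()
  expect_error(find_double_tangent(p, domain = c(0, 0.5)),
               "hull-truncated-by-domain")
})

test_that("hull endpoints are invariant under uniform profile rescaling", {
  p <- paper_profile()
  h0 <- find_double_tangent(p)
  for (lam in c(0.1, 3, 10)) {
    ps <- quartic_profile(lam * 203.1, lam * -552.7, lam * 416.8)
    hs <- find_double_tangent(ps)
    expect_equal(hs$theta_a, h0$theta_a, tolerance = 1e-8)
    expect_equal(hs$theta_b, h0$theta_b, tolerance = 1e-8)
    expect_equal(hs$lambda, lam * h0$lambda, tolerance = 1e-6)
  }
})

test_that("the hull line lies strictly below the profile between tangencies", {
  p <- paper_profile()
  h <- find_double_tangent(p)
  th <- seq(h$theta_a, h$theta_b, length.out = 1000)
  gap <- profile_energy(p, th) - hull_energy(p, h, th)
  expect_true(all(gap >= -1e-9))
  expect_true(all(gap[-c(1, 1000)] > 0))
  expect_lt(abs(gap[1]), 1e-9)
  expect_lt(abs(gap[1000]), 1e-9)
})

test_that("hull_energy interpolates the tangency endpoints and rejects outside", {
  p <- paper_profile()
  h <- find_double_tangent(p)
  expect_equal(hull_energy(p, h, h$theta_a), h$E_a)
  expect_equal(hull_energy(p, h, h$theta_b), h$E_b)
  # compare mid-segment value with the brute-force oracle chord
  o <- brute_hull_oracle(p)
  chord <- function(th) {
    ya <- profile_energy(p, o$theta_a); yb <- profile_energy(p, o$theta_b)
    ya + (th - o$theta_a) / (o$theta_b - o$theta_a) * (yb - ya)
  }
  expect_equal(hull_energy(p, h, 0.3), chord(0.3), tolerance = 1e-2)
  expect_error(hull_energy(p, h, 0.01), "outside")
  expect_error(hull_energy(p, h, 0.7), "outside")
})

test_that("strong_fraction follows the lever rule", {
  ta <- 0.04; tb <- 0.6
  expect_equal(strong_fraction(ta, ta, tb), 0)
  expect_equal(strong_fraction(tb, ta, tb), 1)
  expect_equal(strong_fraction((ta + tb) / 2, ta, tb), 0.5)
  expect_error(strong_fraction(0.7, ta, tb), "outside")
})

test_that("ECH piecewise energy is smooth at theta_a and rejects theta_b", {
  ta <- 0.0383972
  m <- ech_model(Lp = 150, theta_a = ta, theta_b = 0.6249)
  expect_equal(ech_energy(m, 0.02), 0.5 * 150 * 0.02^2)
  # continuity of value and derivative across theta_a
  eps <- 1e-7
  expect_lt(abs(ech_energy(m, ta - eps) - ech_energy(m, ta + eps)), 1e-5)
  d_lo <- (ech_energy(m, ta) - ech_energy(m, ta - eps)) / eps
  d_hi <- (ech_energy(m, ta + eps) - ech_energy(m, ta)) / eps
  expect_equal(d_lo, d_hi, tolerance = 1e-5)
  expect_equal(ech_energy(m, ta), 0.5 * 150 * ta^2, tolerance = 1e-12)
  # linear branch: 150 * 0.0383972 * (0.3 - 0.0191986)
  expect_equal(ech_energy(m, 0.3), 1.61734, tolerance = 1e-4)
  expect_error(ech_energy(m, 0.63), "theta_b")
})

test_that("convex profiles are stable against symmetric angle perturbation", {
  # E(th+d) + E(th-d) >= 2 E(th) for convex, reversed in the concave region
  h <- harmonic_profile(150)
  p <- paper_profile()
  for (d in c(0.01, 0.05, 0.1)) {
    expect_gte(profile_energy(h, 0.3 + d) + profile_energy(h, 0.3 - d),
               2 * profile_energy(h, 0.3))
    expect_lt(profile_energy(p, 0.25 + d) + profile_energy(p, 0.25 - d),
              2 * profile_energy(p, 0.25))
  }
})

test_that("constrained minimum is uniform for convex, two-state inside hull", {
  h150 <- harmonic_profile(150)
  cm <- constrained_minimum(h150, 100, 2 * pi)
  expect_true(cm$uniform)
  expect_equal(cm$energy_per_site, 0.5 * 150 * (2 * pi / 100)^2,
               tolerance = 1e-12)
  expect_equal(sum(cm$angles), 2 * pi)

  p <- paper_profile()
  hull <- find_double_tangent(p)
  cm60 <- constrained_minimum(p, 60, 2 * pi, hull = hull)
  expect_false(cm60$uniform)
  expect_equal(sum(cm60$angles), 2 * pi, tolerance = 1e-9)
  expect_lte(cm60$energy_per_site, profile_energy(p, 2 * pi / 60))
  # continuum hull value and the DP oracle agree with the two-state optimum
  expect_equal(cm60$energy_per_site, hull_energy(p, hull, 2 * pi / 60),
               tolerance = 0.01)
  expect_equal(cm60$energy_per_site, dp_constrained_oracle(p, 60, 2 * pi),
               tolerance = 0.01)

  # below the hull onset the uniform ring is optimal
  cm400 <- constrained_minimum(p, 400, 2 * pi, hull = hull)
  expect_true(cm400$uniform)
  expect_equal(cm400$energy_per_site, profile_energy(p, 2 * pi / 400),
               tolerance = 1e-12)
  expect_equal(cm400$energy_per_site, 0.048, tolerance = 1e-3)
})

test_that("constrained minimum never exceeds the uniform-bending energy", {
  p <- paper_profile()
  hull <- find_double_tangent(p)
  for (N in c(15, 30, 60, 120, 250, 500)) {
    cm <- constrained_minimum(p, N, 2 * pi, hull = hull)
    expect_lte(cm$energy_per_site, profile_energy(p, 2 * pi / N) + 1e-12)
    expect_equal(sum(cm$angles), 2 * pi, tolerance = 1e-9)
  }
})
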