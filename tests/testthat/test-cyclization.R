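theta_a_dna <- 2.2 * pi / 180

test_that("loop energies follow the WLC and ECH closed forms", {
  expect_equal(loop_energy(150, "wlc", Lp = 150), 2 * pi^2, tolerance = 1e-12)
  # 50-bp ECH loop: 150 * theta_a * (2*pi - 25 * theta_a)
  expect_equal(loop_energy(50, "ech", Lp = 150, theta_a = theta_a_dna),
               30.6597, tolerance = 1e-4)
  # branch continuity at L = 2*pi/theta_a
  Lc <- 2 * pi / theta_a_dna
  expect_equal(loop_energy(Lc, "ech", Lp = 150, theta_a = theta_a_dna),
               loop_energy(Lc, "wlc", Lp = 150), tolerance = 1e-9)
  expect_equal(loop_energy(Lc, "wlc", Lp = 150), 18.0946, tolerance = 1e-4)
  expect_error(loop_energy(8, "ech", Lp = 150, theta_a = theta_a_dna,
                           theta_b = 35.8 * pi / 180), "validity")
  expect_error(loop_energy(50, "ech", Lp = 150), "theta_a")
})

test_that("ECH loop energy is bounded by WLC and both decrease with length", {
  tb <- 35.8 * pi / 180
  L <- seq(2 * pi / tb + 1, 2 * pi / theta_a_dna - 1, length.out = 200)
  ech <- loop_energy(L, "ech", Lp = 150, theta_a = theta_a_dna)
  wlc <- loop_energy(L, "wlc", Lp = 150)
  expect_true(all(ech <= wlc + 1e-12))
  expect_true(all(diff(ech) < 0))
  expect_true(all(diff(wlc) < 0))
})

test_that("the j-factor closed form evaluates and modulates correctly", {
  # direct hand evaluation: 150^-3 * exp(-2*pi^2 + 150/600)
  expect_equal(jfactor(150, "wlc", Lp = 150, k = 1),
               150^-3 * exp(-2 * pi^2 + 0.25), tolerance = 1e-12)
  expect_equal(jfactor(150, "wlc", Lp = 150, k = 1), 1.01782e-15,
               tolerance = 1e-5)
  # at integer helical repeats the cosine factor is 1: curve touches envelope
  expect_equal(jfactor(50, "ech", Lp = 150, theta_a = theta_a_dna,
                       modulation = "cosine", h = 10),
               jfactor(50, "ech", Lp = 150, theta_a = theta_a_dna),
               tolerance = 1e-12)
  # half-integer repeats are clamped at the positivity floor
  j_half <- jfactor(55, "ech", Lp = 150, theta_a = theta_a_dna,
                    modulation = "cosine", h = 10)
  expect_gt(j_half, 0)
  expect_equal(j_half / jfactor(55, "ech", Lp = 150, theta_a = theta_a_dna),
               1e-3, tolerance = 1e-6)
})

test_that("j-factor ratios are prefactor-free and antisymmetric", {
  r1 <- jfactor_ratio(40, 50, "ech", Lp = 150, theta_a = theta_a_dna)
  j1 <- jfactor(40, "ech", Lp = 150, theta_a = theta_a_dna, k = 1e3)
  j2 <- jfactor(50, "ech", Lp = 150, theta_a = theta_a_dna, k = 1e3)
  expect_equal(r1, j1 / j2, tolerance = 1e-12)
  expect_equal(r1 * jfactor_ratio(50, 40, "ech", Lp = 150,
                                  theta_a = theta_a_dna), 1,
               tolerance = 1e-12)
  expect_equal(jfactor_ratio(80, 80, "wlc", Lp = 150), 1)
})

test_that("published j-factor ratios are reproduced to three digits", {
  expect_equal(signif(jfactor_ratio(40, 50, "ech", Lp = 150,
                                    theta_a = theta_a_dna), 3), 0.993)
  expect_equal(signif(jfactor_ratio(40, 50, "wlc", Lp = 150), 3), 1.12e-6)
  expect_equal(signif(jfactor_ratio(71, 101, "ech", Lp = 150,
                                    theta_a = theta_a_dna), 3), 0.201)
})

test_that("the envelope minimum matches its closed form and a numeric argmin", {
  Lmin <- envelope_minimum(150, theta_a_dna)
  expect_equal(Lmin, 44.546, tolerance = 1e-4)
  expect_equal(round(Lmin), 45)
  # theta_a -> 0: the formula degenerates to 20 Lp
  expect_equal(envelope_minimum(150, 0), 3000)
  expect_equal(envelope_minimum(150, 1.5 * pi / 180), 94.21, tolerance = 1e-3)
  # numeric argmin of the unmodulated envelope on a 0.01-bp grid
  L <- seq(20, 120, by = 0.01)
  j <- jfactor(L, "ech", Lp = 150, theta_a = theta_a_dna)
  expect_lt(abs(L[which.min(j)] - Lmin), 0.011)
})

test_that("prefactor calibration recovers known k values", {
  # exact one-point inversion
  j1 <- jfactor(100, "ech", Lp = 150, theta_a = theta_a_dna, k = 2.5)
  expect_equal(fit_k(100, j1, "ech", Lp = 150, theta_a = theta_a_dna), 2.5,
               tolerance = 1e-12)
  # noiseless multi-point round trip
  L <- c(60, 90, 120, 150, 180)
  j <- jfactor(L, "ech", Lp = 150, theta_a = theta_a_dna, k = 0.07)
  expect_equal(fit_k(L, j, "ech", Lp = 150, theta_a = theta_a_dna), 0.07,
               tolerance = 1e-12)
  # lognormal multiplicative noise, sigma = 0.1, n = 50
  set.seed(99)
  L <- round(seq(60, 200, length.out = 50))
  jn <- jfactor(L, "ech", Lp = 150, theta_a = theta_a_dna, k = 0.07) *
    rlnorm(50, 0, 0.1)
  expect_equal(fit_k(L, jn, "ech", Lp = 150, theta_a = theta_a_dna), 0.07,
               tolerance = 0.05)
  expect_error(fit_k(numeric(0), numeric(0), "wlc"), "no calibration")
  expect_error(fit_k(100, -1, "wlc"), "positive")
})
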