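# linear-response Marcus parameters, rates, detailed balance, lifetimes

test_that("linear response: zero variance gives lambda 0 and G = <E>", {
  le <- simulate_energy_series(15582, 0, 10, seed = 1, "LE")
  ct <- simulate_energy_series(20656, 0, 10, seed = 2, "CT")
  mp <- linear_response(le, ct, T = 300)
  expect_equal(mp$lambda_LE, 0)
  expect_equal(mp$G_LE, 15582)
  expect_equal(mp$G_CT, 20656)
  expect_equal(mp$deltaG, 20656 - 15582)
})

test_that("lambda follows sigma^2 / (2 kB T) with kB T(300) = 208.51 cm-1", {
  # hand value: sigma 500 -> lambda = 250000 / (2 * 208.5104) = 599.49
  x <- c(-500, 500) / sqrt(2)  # sample variance exactly 500^2
  le <- structure(list(state_label = "LE", values = 20000 + x, seed = 0L),
                  class = "energy_series")
  ct <- structure(list(state_label = "CT", values = 25000 + x, seed = 0L),
                  class = "energy_series")
  mp <- linear_response(le, ct, T = 300)
  expect_equal(mp$lambda_LE, 500^2 / (2 * 0.6950348 * 300), tolerance = 1e-12)
  expect_equal(mp$lambda_LE, 599.5, tolerance = 1e-3)
  # paired identical fluctuations: gap variance zero
  expect_equal(mp$lambda_eff, 0)
})

test_that("lambda estimates are unbiased on synthetic Gaussian data", {
  kT <- 0.6950348 * 300
  lam_true <- 1500^2 / (2 * kT)
  est <- vapply(1:100, function(s) {
    le <- simulate_energy_series(15600, 700, 200, seed = s, "LE")
    ct <- simulate_energy_series(20700, 1500, 200, seed = 10000 + s, "CT")
    linear_response(le, ct, T = 300)$lambda_CT
  }, numeric(1L))
  # chi-square sampling error of a variance: relative SE ~ sqrt(2/(n-1))
  expect_equal(median(est), lam_true, tolerance = 0.03 * lam_true)
  le <- simulate_energy_series(0, 1, 10, seed = 1)
  ct <- simulate_energy_series(0, 1, 12, seed = 2)
  expect_error(linear_response(le, ct), "paired")
})

test_that("Marcus rate reproduces the activationless closed form", {
  # k = (2 pi / hbar) V^2 / sqrt(4 pi lambda kB T), hand-evaluated
  hbar <- 5.3088e-12; kT <- 0.6950348 * 300
  k_hand <- (2 * pi / hbar) * 100^2 / sqrt(4 * pi * 2000 * kT)
  expect_equal(marcus_rate(100, -2000, 2000, 300), k_hand,
               tolerance = 1e-10 * k_hand)
  expect_equal(k_hand, 5.17e12, tolerance = 0.01 * 5.17e12)
  expect_equal(marcus_rate(0, -500, 1000), 0)
  # V-squared law
  expect_equal(marcus_rate(200, -500, 1500), 4 * marcus_rate(100, -500, 1500),
               tolerance = 1e-12)
  expect_error(marcus_rate(100, 0, -5), "lam")
})

test_that("rate is maximized at deltaG = -lambda over a grid", {
  lam <- 1800
  dg <- seq(-5000, 3000, by = 50)
  k <- marcus_rate(150, dg, lam, 300)
  expect_equal(dg[which.max(k)], -lam)
})

test_that("detailed balance closes the LE/CT pair", {
  expect_equal(back_rate(1e10, 0), 1e10)
  kT <- 0.6950348 * 300
  expect_equal(back_rate(1e10, kT * log(10)), 1e11, tolerance = 1e-4 * 1e11)
  # two-state equilibrium reproduces the Boltzmann ratio
  dg <- 350
  kf <- 2e9; kb <- back_rate(kf, dg)
  expect_equal(kf / kb, exp(-dg / kT), tolerance = 1e-12)
})

test_that("lifetime limits match closed forms", {
  # isolated chromophore
  expect_equal(excitation_lifetime(kinetic_scheme(k_cs = 0, k_back = 0)),
               1e12 / 2.5e8, tolerance = 1e-9)
  # irreversible sink: k_rec -> infinity, tau = 1/(k_intr + p k_cs)
  s <- kinetic_scheme(k_cs = 52.8e9, k_back = 0, k_rec = 1e20)
  expect_equal(excitation_lifetime(s), 1e12 / (0.25e9 + 52.8e9 / 8),
               tolerance = 1e-6 * 146)
  expect_equal(excitation_lifetime(s), 146, tolerance = 1)
})

test_that("closed-form lifetime matches numerical master-equation integration", {
  skip_if_not_installed("deSolve")
  schemes <- list(
    kinetic_scheme(k_cs = 5e10, deltaG = -800),
    kinetic_scheme(k_cs = 2e9, deltaG = 400, k_intr = 5e8),
    kinetic_scheme(k_cs = 1e11, k_back = 0, k_rec = 5e10))
  for (s in schemes) {
    A <- rbind(c(-(s$k_intr + s$p_quencher * s$k_cs), s$k_back),
               c(s$p_quencher * s$k_cs, -(s$k_back + s$k_rec)))
    # augmented system: y3 accumulates the survival integral
    deriv <- function(t, y, parms)
      list(c(as.numeric(A %*% y[1:2]), y[1] + y[2]))
    t_end <- 200e-9   # ~50 intrinsic lifetimes: residual survival negligible
    sol <- deSolve::lsoda(c(1, 0, 0), c(0, t_end), deriv, NULL,
                          rtol = 1e-10, atol = 1e-14)
    tau_num <- unname(sol[nrow(sol), 4L]) * 1e12
    expect_equal(excitation_lifetime(s), tau_num, tolerance = 1e-6)
  }
})

test_that("lifetime is monotone in k_cs and in deltaG with detailed balance", {
  taus_k <- vapply(c(1e9, 5e9, 2e10, 1e11), function(k)
    excitation_lifetime(kinetic_scheme(k_cs = k, deltaG = -500)), numeric(1L))
  expect_true(all(diff(taus_k) < 0))
  taus_g <- vapply(seq(-2000, 2000, by = 500), function(dg)
    excitation_lifetime(kinetic_scheme(k_cs = 3e10, deltaG = dg)), numeric(1L))
  expect_true(all(diff(taus_g) >= 0))
})

test_that("rate table evaluates the cluster-by-set Cartesian grid", {
  tab <- rate_table(c(CL2 = 292), list(ref = list(lambda = 2000,
                                                  deltaG = -500)))
  expect_identical(nrow(tab), 1L)
  # equal (lambda, dG): rate ratio is the coupling ratio squared
  tab2 <- rate_table(c(CL2 = 292, CL5 = 199),
                     list(ref = list(lambda = 2000, deltaG = -500)))
  expect_equal(tab2$kcs_per_s[1L] / tab2$kcs_per_s[2L], (292 / 199)^2,
               tolerance = 1e-10)
  # doubling lambda changes rate per the closed form
  tab3 <- rate_table(c(A = 100), list(s1 = list(lambda = 1500, deltaG = -300),
                                      s2 = list(lambda = 3000, deltaG = -300)))
  kT <- 0.6950348 * 300; hbar <- 5.3088e-12
  khand <- function(lam) (2 * pi / hbar) * 1e4 / sqrt(4 * pi * lam * kT) *
    exp(-(-300 + lam)^2 / (4 * lam * kT))
  expect_equal(tab3$kcs_per_s, c(khand(1500), khand(3000)),
               tolerance = 1e-10)
})
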