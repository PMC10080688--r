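# synthetic-data generators: exact enumeration oracle, Monte Carlo titration,
# Gaussian energy series, boosted sampling, toy pigment pairs

test_that("exact_titration reproduces Henderson-Hasselbalch for one site", {
  m <- site_model("E1", "GLU", pKa_int = 5)
  expect_equal(exact_titration(m, 5)[["E1"]], 0.5, tolerance = 1e-14)
  expect_equal(exact_titration(m, 7)[["E1"]], 1 / (1 + 100), tolerance = 1e-14)
  # full-curve identity at machine precision
  for (ph in seq(2, 9, by = 0.5)) {
    hh <- 1 / (1 + 10^(ph - 5))
    expect_equal(exact_titration(m, ph)[["E1"]], hh, tolerance = 1e-14)
  }
})

test_that("exact_titration factorizes over uncoupled sites", {
  m3 <- site_model(c("A", "B", "C"), c("GLU", "ASP", "GLU"),
                   pKa_int = c(4.5, 5.5, 7.0))
  f <- exact_titration(m3, 5.8)
  singles <- vapply(c(A = 4.5, B = 5.5, C = 7.0), function(pk)
    1 / (1 + 10^(5.8 - pk)), numeric(1L))
  expect_equal(unname(f), unname(singles), tolerance = 1e-12)
})

test_that("positive coupling suppresses joint deprotonation", {
  w2 <- site_model(c("A", "B"), "GLU", pKa_int = c(5, 5),
                   couplings = data.frame(site_a = "A", site_b = "B", w = 2))
  w0 <- site_model(c("A", "B"), "GLU", pKa_int = c(5, 5))
  # at the midpoint, penalising the DD state raises the protonated fraction
  expect_gt(exact_titration(w2, 5)[["A"]], exact_titration(w0, 5)[["A"]])
  # and the MC sampler agrees with the enumeration oracle
  tr <- simulate_coupled_titration(w2, 5, 40000, seed = 11)
  f_mc <- colMeans(tr$states)
  f_ex <- exact_titration(w2, 5)
  expect_equal(unname(f_mc), unname(f_ex), tolerance = 0.02)
})

test_that("Monte Carlo titration matches enumeration within 3 SE for small models", {
  m <- site_model(c("A", "B", "C"), "GLU", pKa_int = c(4.8, 5.4, 6.1),
                  couplings = data.frame(site_a = c("A", "B"),
                                         site_b = c("B", "C"),
                                         w = c(1.5, -1.0)))
  n <- 30000
  ok <- 0L
  for (s in 1:20) {
    tr <- simulate_coupled_titration(m, 5.5, n, seed = 500 + s)
    f_mc <- colMeans(tr$states)
    f_ex <- exact_titration(m, 5.5)
    # effective SE from batch means (autocorrelated chain)
    se <- vapply(seq_along(f_mc), function(j) {
      bm <- colMeans(matrix(tr$states[, j], nrow = 500))
      sd(bm) / sqrt(length(bm))
    }, numeric(1L))
    if (all(abs(f_mc - f_ex) < 3 * pmax(se, 1e-3))) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("generators are bit-reproducible under a fixed seed", {
  m <- site_model(c("A", "B"), "GLU", pKa_int = c(5, 6))
  t1 <- simulate_coupled_titration(m, 5.5, 500, seed = 42)
  t2 <- simulate_coupled_titration(m, 5.5, 500, seed = 42)
  expect_identical(t1$states, t2$states)
  e1 <- simulate_energy_series(20656, 326, 50, seed = 7, "CT")
  e2 <- simulate_energy_series(20656, 326, 50, seed = 7, "CT")
  expect_identical(e1$values, e2$values)
  b1 <- simulate_biased_samples(function(x) x^2, function(x) 0 * x + 1,
                                1000, seed = 3)
  b2 <- simulate_biased_samples(function(x) x^2, function(x) 0 * x + 1,
                                1000, seed = 3)
  expect_identical(b1$cv, b2$cv)
})

test_that("trajectory respects n_frames = 1 and argument errors", {
  m <- site_model("A", "GLU")
  tr <- simulate_coupled_titration(m, 5, 1, seed = 1, init = c(0))
  expect_identical(nrow(tr$states), 1L)
  expect_identical(as.integer(tr$states[1L, ]), 0L)
  expect_error(simulate_coupled_titration(m, 5, 0, seed = 1), "n_frames")
  expect_error(site_model(c("A", "B"), "GLU",
                          couplings = data.frame(site_a = "A", site_b = "Z",
                                                 w = 1)),
               "unknown site")
  expect_error(exact_titration(site_model(paste0("S", 1:21), "GLU"), 5),
               "20 sites")
})

test_that("energy series have the requested moments", {
  e0 <- simulate_energy_series(20656, 0, 10, seed = 1, "CT")
  expect_true(all(e0$values == 20656))
  e <- simulate_energy_series(0, 1, 1e5, seed = 2)
  expect_equal(sd(e$values), 1, tolerance = 0.01)
  expect_equal(mean(e$values), 0, tolerance = 0.02)
  expect_error(simulate_energy_series(0, 1, 1, seed = 1), "n must be")
  expect_error(simulate_energy_series(0, -1, 10, seed = 1), "sd")
})

test_that("boosted sampling reduces to the unbiased density for flat boosts", {
  Fq <- function(x) 2 * x^2            # harmonic, kcal/mol
  b0 <- simulate_biased_samples(Fq, function(x) 0 * x, 5e4, seed = 5)
  bc <- simulate_biased_samples(Fq, function(x) 0 * x + 3, 5e4, seed = 5)
  # constant boost shifts nothing: same seed, same draws
  expect_equal(b0$cv, bc$cv, tolerance = 1e-12)
  # harmonic F at 300 K: sd = sqrt(kT / (2a))
  kT <- phys_constants()$kB_kcal * 300
  expect_equal(sd(b0$cv), sqrt(kT / 4), tolerance = 0.02)
  expect_error(simulate_biased_samples(Fq, function(x) -1 + 0 * x, 100,
                                       seed = 1), "boost")
})

test_that("toy pigment pairs have the declared geometry and detect clashes", {
  pt <- data.frame(atom = "X", x = 0, y = 0, z = 0, q = 1)
  pair <- make_toy_pigment_pair(10, charge_pattern = pt)
  expect_equal(pair$B$atoms$x - pair$A$atoms$x, 10)
  expect_error(make_toy_pigment_pair(0.2, charge_pattern = pt), "verlap")
  # mirror symmetry: swapping the sets leaves the coupling unchanged
  dp <- data.frame(atom = c("P", "M"), x = 0, y = c(0.5, -0.5), z = 0,
                   q = c(0.3, -0.3))
  pr <- make_toy_pigment_pair(12, charge_pattern = dp)
  expect_equal(as.numeric(tresp_coupling(pr$A, pr$B)),
               as.numeric(tresp_coupling(pr$B, pr$A)), tolerance = 1e-12)
})
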