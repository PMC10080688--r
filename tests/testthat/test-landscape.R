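# tICA, density clustering, boosted-PMF reweighting, stratified sampling,
# representative frames

test_that("tICA identifies the slow mode of a two-timescale system", {
  x_slow <- ar1_series(20000, exp(-1 / 100), seed = 1)
  x_fast <- ar1_series(20000, exp(-1 / 2), seed = 2)
  X <- cbind(slow = x_slow, fast = x_fast)
  tm <- fit_tica(X, lag = 50)
  v <- tm$components[, 1L]
  expect_gt(abs(v["slow"]) / sqrt(sum(v^2)), 0.99)
  # slow eigenvalue near exp(-lag/tau), fast one near zero
  expect_equal(tm$eigenvalues[1L], exp(-50 / 100), tolerance = 0.1)
  expect_lt(abs(tm$eigenvalues[2L]), 0.1)
})

test_that("tICA matches a dense generalized-eigensolver oracle to 1e-8", {
  set.seed(77)
  X <- matrix(rnorm(3000 * 10), ncol = 10)
  # induce correlations and unequal scales
  X <- X %*% matrix(rnorm(100, sd = 1), 10) + 0.1 * X
  colnames(X) <- paste0("f", 1:10)
  tm <- fit_tica(X, lag = 5, n_dims = 10)
  lam_r <- tm$ridge * sum(diag(tm$C0)) / 10
  C0r <- tm$C0 + diag(lam_r, 10)
  # oracle: non-symmetric dense solve of C0r^-1 Ct
  ev <- eigen(solve(C0r) %*% tm$Ct)
  expect_lt(max(abs(sort(Re(ev$values), decreasing = TRUE) -
                      tm$eigenvalues)), 1e-8)
  # eigenvector directions agree up to sign (compare unit cosines)
  ord <- order(Re(ev$values), decreasing = TRUE)
  for (k in 1:3) {
    a <- tm$components[, k]; b <- Re(ev$vectors[, ord[k]])
    expect_gt(abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)), 1 - 1e-8)
  }
  # symmetrized eigenvalues are real and bounded by 1
  expect_true(all(tm$eigenvalues <= 1 + 1e-10))
})

test_that("tICA eigenvalues are invariant under invertible feature maps", {
  set.seed(11)
  x <- ar1_series(8000, 0.95, seed = 3)
  y <- ar1_series(8000, 0.5, seed = 4)
  X <- cbind(a = x, b = y)
  A <- matrix(c(2, 0.5, -1, 1.5), 2L)   # invertible re-parameterization
  Y <- X %*% A
  colnames(Y) <- c("u", "v")
  e1 <- fit_tica(X, lag = 20, ridge = 1e-12)$eigenvalues
  e2 <- fit_tica(Y, lag = 20, ridge = 1e-12)$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("projection honors the schema, centering and linearity", {
  set.seed(12)
  X <- cbind(p = rnorm(500), q = rnorm(500))
  tm <- fit_tica(X, lag = 2)
  # training projections have unit variance in the C0 metric (per component)
  P <- predict(tm, X)
  expect_equal(apply(P, 2L, var), c(tIC1 = 1, tIC2 = 1), tolerance = 0.05)
  # replicated means project to zero
  M <- matrix(tm$means, 10, 2, byrow = TRUE, dimnames = list(NULL, c("p", "q")))
  expect_true(all(abs(predict(tm, M)) < 1e-12))
  bad <- X; colnames(bad) <- c("q", "p")
  expect_error(predict(tm, bad), "feature names")
})

test_that("density clustering separates blobs and rejects uniform noise", {
  set.seed(21)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  X <- rbind(blob(0, 0, 500), blob(10, 10, 500))
  truth <- rep(1:2, each = 500)
  cs <- cluster_density(X, min_cluster_size = 25)
  expect_identical(cs$n_clusters, 2L)
  tab <- table(cs$labels[cs$labels > 0], truth[cs$labels > 0])
  expect_gte(sum(apply(tab, 1L, max)) / 1000, 0.99)
  # pure uniform noise: no density mode survives
  U <- cbind(runif(400), runif(400))
  expect_warning(cu <- cluster_density(U, min_cluster_size = 40),
                 "noise")
  expect_identical(cu$n_clusters, 0L)
  expect_true(all(cu$labels == -1L))
})

test_that("cluster composition bookkeeping tracks provenance fractions", {
  set.seed(22)
  X <- rbind(cbind(rnorm(200, 0, 0.05), rnorm(200, 0, 0.05)),
             cbind(rnorm(100, 5, 0.05), rnorm(100, 5, 0.05)))
  pms <- c(rep(c("PPD", "DPP"), c(180, 20)), rep("PDP", 100))
  cs <- cluster_density(X, min_cluster_size = 20, pms = pms)
  expect_identical(cs$n_clusters, 2L)
  # identify the mixed blob by its membership
  mixed <- as.character(cs$labels[1L])
  comp <- cs$composition[[mixed]]
  expect_equal(unname(comp["PPD"]), 0.9, tolerance = 0.02)
  expect_equal(unname(comp["DPP"]), 0.1, tolerance = 0.02)
})

test_that("partitions are stable under frame permutation (label-free)", {
  set.seed(23)
  X <- rbind(cbind(rnorm(300), rnorm(300)),
             cbind(rnorm(300, 8), rnorm(300, 8)),
             cbind(rnorm(200, -8), rnorm(200, 6)))
  cs1 <- cluster_density(X, min_cluster_size = 30)
  perm <- sample(nrow(X))
  cs2 <- cluster_density(X[perm, ], min_cluster_size = 30)
  # same partition up to label permutation: every cluster maps 1:1
  l1 <- cs1$labels[perm]; l2 <- cs2$labels
  tab <- table(l1, l2)
  expect_equal(sum(apply(tab, 1L, max)), nrow(X))
})

test_that("cumulant reweighting recovers a double-well PMF from boosted samples", {
  kT <- phys_constants()$kB_kcal * 300
  Fw <- function(x) 3 * (x^2 - 1)^2            # ~5 kT barrier
  boost <- function(x) 0.9 * pmax(3.2 - Fw(x), 0)   # well-filling
  bs <- simulate_biased_samples(Fw, boost, n = 2e5, seed = 3,
                                cv_range = c(-1.5, 1.5))
  pm <- reweight_pmf(bs$cv, bs$boost, bins = 50, T = 300)
  mid <- pmf_midpoints(pm)[[1L]]
  truth <- Fw(mid); truth <- truth - min(truth[pm$reliable])
  expect_lt(max(abs(pm$F[pm$reliable] - truth[pm$reliable])), 0.5 * kT)
})

test_that("zero and constant boosts reduce to the plain histogram PMF", {
  set.seed(9)
  x <- rnorm(5e4)
  pm0 <- reweight_pmf(x, rep(0, 5e4), bins = 40)
  # independent histogram construction
  kT <- phys_constants()$kB_kcal * 300
  cnt <- tabulate(findInterval(x, pm0$edges[[1L]], rightmost.closed = TRUE,
                               all.inside = TRUE), 40)
  h <- -kT * log(cnt / length(x))
  h <- h - min(h[pm0$reliable])
  expect_equal(as.numeric(pm0$F[pm0$reliable]), h[pm0$reliable],
               tolerance = 1e-12)
  # constant boost cancels in normalization
  pmc <- reweight_pmf(x, rep(7.5, 5e4), bins = 40)
  expect_equal(as.numeric(pmc$F[pmc$reliable]),
               as.numeric(pm0$F[pm0$reliable]), tolerance = 1e-10)
  expect_error(reweight_pmf(x, rep(0, 10)), "aligned")
})

test_that("stratified sampling preserves composition by largest remainder", {
  mk_cs <- function(pms) {
    structure(list(labels = rep(1L, length(pms)), sizes = c(`1` = length(pms)),
                   composition = NULL, pms = pms, n_clusters = 1L),
              class = "cluster_set")
  }
  s <- stratified_sample(mk_cs(rep(c("PPD", "DPP"), c(90, 10))), 30, seed = 1)
  tab <- table(rep(c("PPD", "DPP"), c(90, 10))[s[["1"]]])
  expect_identical(as.integer(tab[c("PPD", "DPP")]), c(27L, 3L))
  s3 <- stratified_sample(mk_cs(rep(c("A", "B", "C"), c(50, 30, 20))), 30,
                          seed = 2)
  tab3 <- table(rep(c("A", "B", "C"), c(50, 30, 20))[s3[["1"]]])
  expect_identical(as.integer(tab3[c("A", "B", "C")]), c(15L, 9L, 6L))
  # single-stratum cluster: all samples from it, without replacement
  s1 <- stratified_sample(mk_cs(rep("PDP", 60)), 30, seed = 3)
  expect_length(s1[["1"]], 30L)
  expect_false(anyDuplicated(s1[["1"]]) > 0)
  # allocation exceeding a stratum falls back to replacement with a warning
  suppressWarnings(
    expect_warning(stratified_sample(mk_cs(rep(c("A", "B"), c(2, 98))), 200,
                                     seed = 4), "replacement"))
})

test_that("representative frames minimize distance to the cluster mean", {
  pr <- rbind(c(-1, 0), c(0, 0.01), c(1, 0))
  cs <- structure(list(labels = rep(1L, 3), sizes = c(`1` = 3L),
                       composition = NULL, pms = NULL, n_clusters = 1L),
                  class = "cluster_set")
  expect_identical(unname(representative_frame(cs, pr)), 2L)
  # singleton cluster returns its only frame
  cs1 <- structure(list(labels = c(-1L, 1L), sizes = c(`1` = 1L),
                        composition = NULL, pms = NULL, n_clusters = 1L),
                   class = "cluster_set")
  expect_identical(unname(representative_frame(cs1, rbind(c(5, 5), c(0, 0)))),
                   2L)
  # Gaussian blob: chosen frame within the 10th percentile of distances
  set.seed(6)
  G <- cbind(rnorm(1000), rnorm(1000))
  csg <- structure(list(labels = rep(1L, 1000), sizes = c(`1` = 1000L),
                        composition = NULL, pms = NULL, n_clusters = 1L),
                   class = "cluster_set")
  idx <- representative_frame(csg, G)
  d <- sqrt(rowSums(sweep(G, 2L, colMeans(G))^2))
  expect_lte(d[idx], quantile(d, 0.1))
})
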