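# fixtures built in code for the test suite

# sample a discrete Markov chain with transition matrix P (row-stochastic)
sample_markov_chain <- function(P, n, seed, init = 1L) {
  set.seed(seed)
  k <- nrow(P)
  x <- integer(n)
  x[1L] <- init
  u <- runif(n)
  cum <- t(apply(P, 1L, cumsum))
  for (t in 2:n) x[t] <- findInterval(u[t], cum[x[t - 1L], ]) + 1L
  x
}

# stationary AR(1) series with marginal sd 1 and autocorrelation phi
ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - phi^2)), phi, "recursive"))
}

# ideal transition-dipole coupling between two charge sets (oracle form)
dipole_coupling_oracle <- function(A, B) {
  Ke <- 116140
  mu_a <- colSums(A$atoms$q * as.matrix(A$atoms[, c("x", "y", "z")]))
  mu_b <- colSums(B$atoms$q * as.matrix(B$atoms[, c("x", "y", "z")]))
  com <- function(S) colMeans(as.matrix(S$atoms[, c("x", "y", "z")]))
  r <- com(B) - com(A)
  rn <- sqrt(sum(r^2)); rh <- r / rn
  Ke * (sum(mu_a * mu_b) - 3 * sum(mu_a * rh) * sum(mu_b * rh)) / rn^3
}

# wrap a binary vector into a single-site protonation trajectory
as_traj <- function(x, pH = 7, site = "S1", dt_ps = 100) {
  structure(list(pH = pH, dt_ps = dt_ps, sites = site,
                 states = matrix(as.integer(x), ncol = 1L,
                                 dimnames = list(NULL, site)),
                 seed = 0L),
            class = "protonation_trajectory")
}

# wrap labels into a microstate series
as_mseries <- function(labels, site_order, pH = 7) {
  structure(list(labels = labels, site_order = site_order, pH = pH),
            class = "microstate_series")
}
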