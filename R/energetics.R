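# Marcus analysis: linear-response reorganization energies and driving
# forces from vertical-energy fluctuations, nonadiabatic charge-separation
# rates, and the coarse-grained excitation-lifetime model of the complex.

#' Linear-response Marcus parameters from vertical-energy samples
#'
#' For each electronic state X the reorganization energy is estimated from
#' the energy-gap fluctuations, \eqn{\lambda_X = \sigma_X^2 / (2 k_B T)},
#' and the free energy as \eqn{G_X = \langle E_X \rangle - \lambda_X}
#' (linear response, Gaussian statistics). The driving force is
#' \eqn{\Delta G = G_{CT} - G_{LE}}. An effective reorganization energy for
#' the LE-to-CT process is estimated from the variance of the paired
#' vertical gap \eqn{\Delta E = E_{CT} - E_{LE}} by the same relation.
#'
#' @param series_LE,series_CT `energy_series` objects (cm^-1, >= 2 samples
#'   each). The gap statistics require equal lengths (paired samples).
#' @param T Temperature, K.
#' @param paired If `TRUE` (default), compute `sigma2_gap`/`lambda_eff`
#'   from paired samples; an error is raised if the series lengths differ.
#' @return A `marcus_parameters`: list with `E_LE_mean`, `E_CT_mean`,
#'   `sigma2_LE`, `sigma2_CT`, `sigma2_gap`, `lambda_LE`, `lambda_CT`,
#'   `lambda_eff`, `G_LE`, `G_CT`, `deltaG` (all cm^-1 or cm^-2), `T`.
#' @export
linear_response <- function(series_LE, series_CT, T = 300, paired = TRUE) {
  stopifnot(inherits(series_LE, "energy_series"),
            inherits(series_CT, "energy_series"))
  le <- series_LE$values; ct <- series_CT$values
  if (length(le) < 2L || length(ct) < 2L) stop("need >= 2 samples per series")
  kT <- .kB_cm1 * T
  s2_le <- stats::var(le); s2_ct <- stats::var(ct)
  lam_le <- s2_le / (2 * kT); lam_ct <- s2_ct / (2 * kT)
  g_le <- mean(le) - lam_le; g_ct <- mean(ct) - lam_ct
  s2_gap <- lam_eff <- NA_real_
  if (paired) {
    if (length(le) != length(ct))
      stop("gap statistics need paired series of equal length")
    s2_gap <- stats::var(ct - le)
    lam_eff <- s2_gap / (2 * kT)
  }
  structure(list(E_LE_mean = mean(le), E_CT_mean = mean(ct),
                 sigma2_LE = s2_le, sigma2_CT = s2_ct, sigma2_gap = s2_gap,
                 lambda_LE = lam_le, lambda_CT = lam_ct, lambda_eff = lam_eff,
                 G_LE = g_le, G_CT = g_ct, deltaG = g_ct - g_le, T = T),
            class = "marcus_parameters")
}

#' @export
print.marcus_parameters <- function(x, ...) {
  cat(sprintf(paste0("marcus_parameters (T = %g K):\n",
                     "  <E_LE> = %.0f, <E_CT> = %.0f cm-1\n",
                     "  lambda_LE = %.0f, lambda_CT = %.0f, lambda_eff = %s cm-1\n",
                     "  deltaG = %.0f cm-1\n"),
              x$T, x$E_LE_mean, x$E_CT_mean, x$lambda_LE, x$lambda_CT,
              format(x$lambda_eff, digits = 4), x$deltaG))
  invisible(x)
}

#' Nonadiabatic Marcus charge-separation rate
#'
#' High-temperature nonadiabatic Marcus rate
#' \deqn{k = \frac{2\pi}{\hbar} V^2 (4\pi\lambda k_B T)^{-1/2}
#'       \exp\!\left(-\frac{(\Delta G + \lambda)^2}{4\lambda k_B T}\right)}
#' with all energetic quantities in cm^-1 and
#' \eqn{\hbar = 5.3088\times 10^{-12}} cm^-1 s.
#'
#' @param V Electronic coupling, cm^-1 (vectorized).
#' @param deltaG Driving force, cm^-1.
#' @param lam Reorganization energy, cm^-1 (> 0).
#' @param T Temperature, K (> 0).
#' @return Rate, s^-1.
#' @examples
#' marcus_rate(V = 100, deltaG = -2000, lam = 2000, T = 300)  # activationless
#' @export
marcus_rate <- function(V, deltaG, lam, T = 300) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(T <= 0)) stop("T must be > 0")
  kT <- .kB_cm1 * T
  (2 * pi / .hbar_cm1_s) * V^2 / sqrt(4 * pi * lam * kT) *
    exp(-(deltaG + lam)^2 / (4 * lam * kT))
}

#' Detailed-balance back-transfer rate
#'
#' Closes the reversible LE/CT pair by detailed balance:
#' \eqn{k_{back} = k_{cs} \exp(\Delta G / k_B T)} with
#' \eqn{\Delta G = G_{CT} - G_{LE}}, so an uphill forward step implies
#' `k_back > k_cs`.
#'
#' @param k_cs Forward rate, s^-1.
#' @param deltaG Driving force, cm^-1.
#' @param T Temperature, K.
#' @return Back rate, s^-1.
#' @export
back_rate <- function(k_cs, deltaG, T = 300) {
  if (any(T <= 0)) stop("T must be > 0")
  k_cs * exp(deltaG / (.kB_cm1 * T))
}

#' Define the coarse-grained kinetic scheme of the complex
#'
#' A pool of `n_pool` chlorophylls in fast excitonic equilibrium (equal
#' weights by default) feeds the charge-transfer state through the quencher
#' chlorophyll, which carries an equilibrium excited-state weight
#' `p_quencher`; the CT state recombines to the ground state and can
#' back-transfer. Intrinsic (fluorescence + intersystem) decay acts on the
#' excited manifold.
#'
#' @param k_cs Charge-separation rate of the quenching pair, s^-1.
#' @param n_pool Number of pool chlorophylls (default 8).
#' @param p_quencher Equilibrium weight of the quencher (default `1/n_pool`,
#'   isoenergetic fast equilibrium; pass Boltzmann weights for nonuniform
#'   site energies).
#' @param k_rec CT recombination rate, s^-1 (default `(10 ps)^-1`).
#' @param k_intr Intrinsic decay of the excited manifold, s^-1 (default
#'   `(4 ns)^-1`, a typical chlorophyll a fluorescence decay).
#' @param k_back Back-transfer rate, s^-1; `NULL` (default) leaves it to be
#'   set from detailed balance by [excitation_lifetime()], 0 gives the
#'   irreversible scheme.
#' @param deltaG Driving force used for detailed balance when `k_back` is
#'   `NULL`, cm^-1.
#' @param T Temperature, K.
#' @return A `kinetic_scheme`.
#' @export
kinetic_scheme <- function(k_cs, n_pool = 8L, p_quencher = 1 / n_pool,
                           k_rec = 1e11, k_intr = 2.5e8, k_back = NULL,
                           deltaG = 0, T = 300) {
  if (is.null(k_back)) k_back <- back_rate(k_cs, deltaG, T)
  rates <- c(k_cs = k_cs, k_rec = k_rec, k_intr = k_intr, k_back = k_back)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (p_quencher < 0 || p_quencher > 1) stop("p_quencher must be in [0, 1]")
  structure(list(n_pool = n_pool, p_quencher = p_quencher, k_cs = k_cs,
                 k_back = k_back, k_rec = k_rec, k_intr = k_intr, T = T),
            class = "kinetic_scheme")
}

# 2x2 rate matrix of the scheme acting on (excited manifold, CT)
.scheme_matrix <- function(s) {
  matrix(c(-(s$k_intr + s$p_quencher * s$k_cs), s$k_back,
           s$p_quencher * s$k_cs, -(s$k_back + s$k_rec)),
         2L, 2L, byrow = TRUE)
}

#' Mean excitation lifetime of the complex
#'
#' Solves the two-state master equation (excited manifold, CT state) in
#' closed form: with rate matrix A and initial condition all population in
#' the excited manifold (excitation equally partitioned over the pool),
#' the time integral of the total survival probability is
#' \eqn{\tau = \mathbf{1}^\top (-A)^{-1} p_0}.
#'
#' @param scheme A [kinetic_scheme()].
#' @return Mean lifetime, ps.
#' @examples
#' # isolated-chromophore limit: tau = 1/k_intr = 4000 ps
#' excitation_lifetime(kinetic_scheme(k_cs = 0, k_back = 0))
#' @export
excitation_lifetime <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  A <- .scheme_matrix(scheme)
  if (all(abs(A) < .Machine$double.xmin))
    stop("all rates zero: survival integral diverges")
  tau_s <- sum(solve(-A, c(1, 0)))
  tau_s * 1e12
}

#' Rate and lifetime table over clusters and reorganization-energy sets
#'
#' Cartesian evaluation of the Marcus rate and the coarse-grained lifetime
#' for each cluster coupling and each named (lambda, deltaG) set, mirroring
#' the layout rates-per-cluster-per-set tables are reported in.
#'
#' @param couplings Named numeric vector of per-cluster couplings V, cm^-1.
#' @param lambda_sets Named list; each element a list/vector with `lambda`
#'   and `deltaG` (cm^-1).
#' @param T Temperature, K.
#' @param ... Passed to [kinetic_scheme()] (e.g. `n_pool`, `k_intr`,
#'   `k_rec`, `k_back = 0` for the irreversible scheme).
#' @return Data frame with columns `cluster`, `set`, `V_cm1`, `lambda_cm1`,
#'   `dG_cm1`, `kcs_per_s`, `tau_ps`.
#' @export
rate_table <- function(couplings, lambda_sets, T = 300, ...) {
  stopifnot(length(couplings) >= 1L, length(lambda_sets) >= 1L)
  rows <- list()
  for (set_name in names(lambda_sets)) {
    set <- lambda_sets[[set_name]]
    lam <- as.numeric(set[["lambda"]]); dg <- as.numeric(set[["deltaG"]])
    for (cl in names(couplings)) {
      k <- marcus_rate(couplings[[cl]], dg, lam, T)
      sch <- kinetic_scheme(k_cs = k, deltaG = dg, T = T, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, set = set_name, V_cm1 = couplings[[cl]],
        lambda_cm1 = lam, dG_cm1 = dg, kcs_per_s = k,
        tau_ps = excitation_lifetime(sch))
    }
  }
  do.call(rbind, rows)
}
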