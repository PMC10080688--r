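# Synthetic-data generators: every input the pipeline consumes can be produced
# here with known ground truth, standing in for constant-pH MD, Gaussian
# accelerated MD and QM/MM outputs that are not desk-reproducible.

#' Define a set of coupled titratable sites
#'
#' Builds the generative model for coupled acid titration: each site has an
#' intrinsic pKa and, optionally, pairwise Ising-like couplings in pH units
#' that penalise (w > 0) or favour (w < 0) joint deprotonation of a pair.
#' The dimensionless microstate energy (in units of kT ln 10) is
#' \deqn{E(s) = \sum_i (1-s_i)(pKa_i - pH) + \sum_{i<j} w_{ij} (1-s_i)(1-s_j)}
#' with \eqn{s_i = 1} for a protonated site (the "P" label). The one-site,
#' zero-coupling case reduces exactly to Henderson-Hasselbalch.
#'
#' @param site_id Character vector of site labels, e.g. `c("E114","E227")`.
#' @param residue_class Character vector, `"GLU"` or `"ASP"` per site.
#' @param pKa_int Numeric vector of intrinsic pKa values (pH units). Defaults
#'   to the water reference values: Glu 4.3, Asp 3.9.
#' @param couplings `NULL`, or a data frame with columns `site_a`, `site_b`,
#'   `w` giving the symmetric pair interaction applied when both sites are
#'   deprotonated (pH units, dimensionless in the scaled energy).
#' @return An object of class `site_model`.
#' @seealso [exact_titration()], [simulate_coupled_titration()]
#' @export
site_model <- function(site_id, residue_class, pKa_int = NULL, couplings = NULL) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("duplicated site_id")
  residue_class <- match.arg(toupper(residue_class), c("GLU", "ASP"),
                             several.ok = TRUE)
  residue_class <- rep_len(residue_class, length(site_id))
  if (is.null(pKa_int)) {
    pKa_int <- ifelse(residue_class == "GLU", 4.3, 3.9)
  }
  pKa_int <- rep_len(as.numeric(pKa_int), length(site_id))
  if (!all(is.finite(pKa_int))) stop("pKa_int must be finite")
  n <- length(site_id)
  W <- matrix(0, n, n, dimnames = list(site_id, site_id))
  if (!is.null(couplings) && nrow(as.data.frame(couplings)) > 0L) {
    couplings <- as.data.frame(couplings)
    stopifnot(all(c("site_a", "site_b", "w") %in% names(couplings)))
    bad <- setdiff(c(couplings$site_a, couplings$site_b), site_id)
    if (length(bad) > 0L)
      stop("couplings reference unknown site(s): ", paste(bad, collapse = ", "))
    for (k in seq_len(nrow(couplings))) {
      i <- couplings$site_a[k]; j <- couplings$site_b[k]
      if (i == j) stop("self-coupling not allowed: ", i)
      W[i, j] <- W[i, j] + couplings$w[k]
      W[j, i] <- W[j, i] + couplings$w[k]
    }
  }
  structure(list(site_id = site_id, residue_class = residue_class,
                 pKa_int = stats::setNames(pKa_int, site_id), W = W),
            class = "site_model")
}

# scaled microstate energy E(s)/ (kT ln10) for binary state vector s (1 = P)
.microstate_energy <- function(model, s, pH) {
  d <- 1 - s  # deprotonation indicator
  sum(d * (model$pKa_int - pH)) + 0.5 * drop(d %*% model$W %*% d)
}

#' Exact per-site protonated fractions by exhaustive enumeration
#'
#' Boltzmann average over all 2^N protonation microstates of the coupled-site
#' energy model; serves as the analytic ground truth against which the Monte
#' Carlo generator and the Hill fits are validated.
#'
#' @param model A [site_model()].
#' @param pH Solution pH.
#' @return Named numeric vector of protonated fractions, one per site.
#' @examples
#' m <- site_model("E1", "GLU", pKa_int = 5)
#' exact_titration(m, 5)   # 0.5
#' exact_titration(m, 7)   # 1/(1 + 10^2)
#' @export
exact_titration <- function(model, pH) {
  stopifnot(inherits(model, "site_model"))
  n <- length(model$site_id)
  if (n > 20L) stop("exact enumeration limited to 20 sites (2^N states)")
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  colnames(states) <- model$site_id
  logw <- apply(states, 1L, function(s) -.microstate_energy(model, s, pH))
  logw <- logw - max(logw)
  w <- 10^logw
  drop(crossprod(states, w)) / sum(w)
}

#' Simulate a coupled constant-pH protonation trajectory
#'
#' Metropolis Monte Carlo over binary protonation microstates at a fixed pH:
#' each frame one randomly chosen site attempts a flip, mirroring the periodic
#' single-exchange attempts of discrete constant-pH MD. The chain of visited
#' states (including rejected-move frames) is returned.
#'
#' @param model A [site_model()].
#' @param pH Solution pH.
#' @param n_frames Number of frames to record (>= 1).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param dt_ps Time between recorded frames, ps (metadata only).
#' @param init Optional initial 0/1 state vector (default: all protonated).
#' @return An object of class `protonation_trajectory`: list with `pH`,
#'   `dt_ps`, `sites`, `states` (frames x sites 0/1 matrix), `seed`.
#' @export
simulate_coupled_titration <- function(model, pH, n_frames, seed,
                                       dt_ps = 100, init = NULL) {
  stopifnot(inherits(model, "site_model"))
  if (n_frames < 1L) stop("n_frames must be >= 1")
  n <- length(model$site_id)
  s <- if (is.null(init)) rep(1, n) else as.numeric(init)
  stopifnot(length(s) == n, all(s %in% c(0, 1)))
  states <- matrix(0L, n_frames, n, dimnames = list(NULL, model$site_id))
  ln10 <- log(10)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  pick <- sample.int(n, n_frames, replace = TRUE)
  u <- stats::runif(n_frames)
  states[1L, ] <- s                     # frame 1 is the initial state
  for (t in seq_len(n_frames)[-1L]) {
    i <- pick[t]
    d <- 1 - s[i]                       # deprotonation indicator before flip
    # energy change for flipping site i, in units of kT ln10
    dE <- ((1 - d) - d) *
      ((model$pKa_int[i] - pH) + sum(model$W[i, ] * (1 - s)))
    if (u[t] < exp(-ln10 * dE)) s[i] <- 1 - s[i]
    states[t, ] <- s
  }
  structure(list(pH = pH, dt_ps = dt_ps, sites = model$site_id,
                 states = states, seed = as.integer(seed)),
            class = "protonation_trajectory")
}

#' @export
print.protonation_trajectory <- function(x, ...) {
  cat("protonation_trajectory:", nrow(x$states), "frames,",
      length(x$sites), "site(s), pH", x$pH, "\n")
  invisible(x)
}

#' Simulate Gaussian vertical-energy samples for an electronic state
#'
#' I.i.d. Gaussian draws emulating the vertical energies of a locally excited
#' (LE) or charge-transfer (CT) state sampled over an MD ensemble; Gaussian
#' statistics are the premise of the linear-response treatment downstream.
#'
#' @param mean,sd Mean and standard deviation, cm^-1 (`sd >= 0`).
#' @param n Number of samples (>= 2).
#' @param seed Integer seed.
#' @param state_label `"LE"` or `"CT"`.
#' @return An object of class `energy_series`: list with `state_label`,
#'   `values` (cm^-1) and `seed`.
#' @export
simulate_energy_series <- function(mean, sd, n, seed, state_label = "LE") {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  restore <- .with_seed(seed)
  on.exit(restore())
  values <- stats::rnorm(n, mean, sd)
  structure(list(state_label = match.arg(state_label, c("LE", "CT")),
                 values = values, seed = as.integer(seed)),
            class = "energy_series")
}

#' Draw boosted samples from a known free-energy surface
#'
#' Generates collective-variable samples from the biased density
#' \eqn{p^*(x) \propto \exp(-\beta (F(x) + \Delta V(x)))} where the boost
#' \eqn{\Delta V \ge 0} fills the wells of the reference surface, emulating
#' Gaussian accelerated MD output together with the per-frame boost record
#' needed for cumulant reweighting.
#'
#' @param truth_pmf Function of the collective variable returning the
#'   reference free energy F, kcal/mol, or a two-column data frame `(cv, F)`
#'   interpolated linearly.
#' @param boost_rule Function returning the boost DV(cv) >= 0, kcal/mol.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param cv_range Length-2 numeric support of the collective variable.
#' @param T Temperature, K.
#' @param grid_size Resolution of the discretised support used for sampling.
#' @return An object of class `biased_sample`: list with `cv`, `boost`
#'   (per-frame DV, kcal/mol), `truth_pmf` (function) and `T`.
#' @export
simulate_biased_samples <- function(truth_pmf, boost_rule, n, seed,
                                    cv_range = c(-2, 2), T = 300,
                                    grid_size = 4096L) {
  if (is.data.frame(truth_pmf)) {
    tab <- truth_pmf
    truth_pmf <- stats::approxfun(tab[[1L]], tab[[2L]], rule = 2L)
  }
  stopifnot(is.function(truth_pmf), is.function(boost_rule), n >= 1L)
  grid <- seq(cv_range[1L], cv_range[2L], length.out = grid_size)
  dv <- boost_rule(grid)
  if (any(dv < -1e-12)) stop("boost_rule must be >= 0 everywhere sampled")
  dv <- pmax(dv, 0)
  beta <- 1 / (.kB_kcal * T)
  logp <- -beta * (truth_pmf(grid) + dv)
  p <- exp(logp - max(logp))
  restore <- .with_seed(seed)
  on.exit(restore())
  idx <- sample.int(grid_size, n, replace = TRUE, prob = p)
  h <- diff(cv_range) / (grid_size - 1L)
  cv <- grid[idx] + stats::runif(n, -h / 2, h / 2)
  structure(list(cv = cv, boost = pmax(boost_rule(cv), 0),
                 truth_pmf = truth_pmf, T = T),
            class = "biased_sample")
}

#' Build a rigid toy pigment pair with transition charges
#'
#' Places two copies of a local charge pattern at a given separation and
#' relative orientation, producing a pair of transition-charge sets usable by
#' the TrEsp coupling routine, with closed-form limits (bare Coulomb for point
#' charges, ideal dipole-dipole at large separation) available as oracles.
#'
#' @param separation Centre-to-centre distance along the x axis, Angstrom (> 0).
#' @param orientation Length-3 numeric of Euler angles (radians, applied as
#'   rotations about z, y, x in that order) for the second copy, or a 3x3
#'   rotation matrix.
#' @param charge_pattern Data frame with columns `atom`, `x`, `y`, `z`, `q`
#'   giving the local geometry (Angstrom) and transition charges (e).
#' @param state_label Electronic-state label stored on both sets.
#' @return List of two [transition_charge_set()] objects `A` and `B`.
#' @export
make_toy_pigment_pair <- function(separation, orientation = c(0, 0, 0),
                                  charge_pattern, state_label = "toy") {
  if (separation <= 0) stop("separation must be > 0")
  cp <- as.data.frame(charge_pattern)
  stopifnot(all(c("atom", "x", "y", "z", "q") %in% names(cp)))
  R <- if (is.matrix(orientation)) orientation else .euler_zyx(orientation)
  xyzA <- as.matrix(cp[, c("x", "y", "z")])
  xyzB <- xyzA %*% t(R)
  xyzB[, 1L] <- xyzB[, 1L] + separation
  A <- transition_charge_set("pigA", data.frame(atom = cp$atom, xyzA, q = cp$q),
                             state_label)
  B <- transition_charge_set("pigB",
                             data.frame(atom = cp$atom,
                                        stats::setNames(as.data.frame(xyzB),
                                                        c("x", "y", "z")),
                                        q = cp$q),
                             state_label)
  dmin <- min(.cross_distances(A$atoms, B$atoms))
  if (dmin < 0.5)
    stop(sprintf("overlapping atoms between sets (min distance %.3f A)", dmin))
  list(A = A, B = B)
}

#' Simulate boosted conformational feature matrices per protonation microstate
#'
#' Emulates enhanced-sampling output for a set of protonation microstates:
#' each microstate samples AR(1) features around a microstate-specific
#' conformational centre (so different microstates occupy distinct basins, as
#' seen for the C-terminal helix rearrangements), together with a Gaussian
#' per-frame boost-potential record.
#'
#' @param centers Numeric matrix (microstates x features) of basin centres;
#'   rownames are the microstate labels, colnames the feature names.
#' @param n_frames Frames per microstate per replica.
#' @param n_replicas Replicas per microstate.
#' @param seed Integer seed.
#' @param ar_phi AR(1) coefficient of the feature dynamics.
#' @param sd Marginal feature standard deviation.
#' @param boost_mean,boost_sd Mean and sd of the per-frame boost, kcal/mol
#'   (defaults 26.0 and 6.8, typical of well-tempered dual-boost runs);
#'   draws are truncated at zero.
#' @param dt_ps Time between frames, ps (provenance metadata).
#' @return List with `X` (frames x features matrix), `pms`, `replica`,
#'   `time_ps` (per-frame provenance) and `boost` (kcal/mol).
#' @export
simulate_gamd_features <- function(centers, n_frames, n_replicas = 2L, seed,
                                   ar_phi = 0.9, sd = 1, boost_mean = 26,
                                   boost_sd = 6.8, dt_ps = 100) {
  centers <- as.matrix(centers)
  stopifnot(!is.null(rownames(centers)), n_frames >= 2L)
  restore <- .with_seed(seed)
  on.exit(restore())
  p <- ncol(centers)
  eps_sd <- sd * sqrt(1 - ar_phi^2)
  out <- list()
  for (ms in rownames(centers)) {
    for (r in seq_len(n_replicas)) {
      X <- matrix(0, n_frames, p)
      X[1L, ] <- stats::rnorm(p, 0, sd)
      for (t in 2:n_frames)
        X[t, ] <- ar_phi * X[t - 1L, ] + stats::rnorm(p, 0, eps_sd)
      X <- sweep(X, 2L, centers[ms, ], "+")
      out[[length(out) + 1L]] <- list(
        X = X, pms = rep(ms, n_frames), replica = rep(r, n_frames),
        time_ps = seq_len(n_frames) * dt_ps,
        boost = pmax(stats::rnorm(n_frames, boost_mean, boost_sd), 0))
    }
  }
  X <- do.call(rbind, lapply(out, `[[`, "X"))
  colnames(X) <- colnames(centers)
  list(X = X,
       pms = unlist(lapply(out, `[[`, "pms")),
       replica = unlist(lapply(out, `[[`, "replica")),
       time_ps = unlist(lapply(out, `[[`, "time_ps")),
       boost = unlist(lapply(out, `[[`, "boost")))
}

# rotation matrix from Euler angles (z, then y, then x)
.euler_zyx <- function(ang) {
  cz <- cos(ang[1L]); sz <- sin(ang[1L])
  cy <- cos(ang[2L]); sy <- sin(ang[2L])
  cx <- cos(ang[3L]); sx <- sin(ang[3L])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  Rx %*% Ry %*% Rz
}

# all pairwise distances between two atom tables (rows: atoms with x,y,z)
.cross_distances <- function(a, b) {
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  sqrt(pmax(d2, 0))
}

# set the RNG seed locally; returns a restore function
.with_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
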