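# Titration analysis: protonation fractions, Hill fits, blocked-bootstrap
# pKa errors, and classification of pH-sensor candidates.

#' Protonated fraction of one site along a trajectory
#'
#' @param traj A `protonation_trajectory`.
#' @param site_id Site label present in the trajectory.
#' @return Mean of the binary occupancy column, in `[0, 1]`.
#' @export
protonation_fraction <- function(traj, site_id) {
  stopifnot(inherits(traj, "protonation_trajectory"))
  if (!site_id %in% traj$sites) stop("unknown site: ", site_id)
  mean(traj$states[, site_id])
}

#' Assemble a titration curve for one site across pH values
#'
#' @param trajs List of `protonation_trajectory` objects (one or more replicas
#'   per pH are averaged; replicas are recognised by equal `pH`).
#' @param site_id Site label.
#' @param err Optional per-point errors (same order as the sorted unique pH).
#' @return A `titration_curve`: data frame with columns `pH`, `frac`, `err`,
#'   `n_frames`, ordered by strictly increasing pH.
#' @export
titration_curve <- function(trajs, site_id, err = NULL) {
  stopifnot(length(trajs) >= 1L)
  ph <- vapply(trajs, `[[`, numeric(1L), "pH")
  ph_u <- sort(unique(ph))
  frac <- nfr <- numeric(length(ph_u))
  for (k in seq_along(ph_u)) {
    idx <- which(ph == ph_u[k])
    cols <- unlist(lapply(trajs[idx], function(tr) {
      if (!site_id %in% tr$sites) stop("unknown site: ", site_id)
      tr$states[, site_id]
    }))
    frac[k] <- mean(cols)
    nfr[k] <- length(cols)
  }
  if (is.null(err)) err <- rep(NA_real_, length(ph_u))
  out <- data.frame(pH = ph_u, frac = frac, err = err, n_frames = nfr)
  class(out) <- c("titration_curve", "data.frame")
  attr(out, "site_id") <- site_id
  out
}

#' Hill fit of a titration curve
#'
#' Least-squares fit of the protonated fraction to the Hill form
#' \deqn{f(pH) = 1 / (1 + 10^{\,n\,(pH - pKa)})}
#' (decreasing with pH, `n > 0`), by bounded optimisation with
#' `n` in (0, 10], `pKa` in \[0, 14\]; the initial guess places pKa at the
#' half-maximum crossing with `n = 1`. Degenerate (flat) or nonmonotonic
#' curves — the signature of strongly coupled sites — return
#' `converged = FALSE` rather than an error.
#'
#' @param curve A [titration_curve()] or data frame with `pH` and `frac`
#'   columns (optionally `err`).
#' @param nonmono_tol Absolute slack added to the 2-sigma pooled-error
#'   threshold of the nonmonotonicity test.
#' @return A `hill_fit`: list with `pKa`, `n_hill`, `pKa_err`, `n_err`
#'   (NA until bootstrapped), `converged`, `rss`.
#' @export
fit_hill <- function(curve, nonmono_tol = 1e-6) {
  ph <- curve$pH; f <- curve$frac
  keep <- is.finite(ph) & is.finite(f)
  ph <- ph[keep]; f <- f[keep]
  if (length(ph) < 3L) stop("need >= 3 usable pH points")
  if (is.unsorted(ph, strictly = TRUE)) stop("pH values must be strictly increasing")
  err <- if ("err" %in% names(curve)) curve$err[keep] else rep(NA_real_, length(ph))
  err[!is.finite(err)] <- 0
  bad <- FALSE
  # flat curve: pKa unidentifiable
  if (diff(range(f)) < 0.05) bad <- TRUE
  # nonmonotonic beyond 2x pooled point error ("up-and-down" coupled case)
  inc <- diff(f)
  pooled <- sqrt(err[-length(err)]^2 + err[-1L]^2)
  if (any(inc > 2 * pooled + nonmono_tol)) bad <- TRUE
  if (bad) {
    return(structure(list(pKa = NA_real_, n_hill = NA_real_,
                          pKa_err = NA_real_, n_err = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "hill_fit"))
  }
  # initial pKa: pH of the half-maximum crossing (linear interpolation)
  pka0 <- tryCatch(stats::approx(f, ph, xout = 0.5, ties = "ordered")$y,
                   error = function(e) NA_real_)
  if (!is.finite(pka0)) pka0 <- ph[which.min(abs(f - 0.5))]
  obj <- function(p) sum((f - 1 / (1 + 10^(p[2L] * (ph - p[1L]))))^2)
  opt <- tryCatch(
    stats::optim(c(pka0, 1), obj, method = "L-BFGS-B",
                 lower = c(0, 1e-3), upper = c(14, 10),
                 control = list(factr = 10, pgtol = 1e-12, maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) {
    return(structure(list(pKa = NA_real_, n_hill = NA_real_,
                          pKa_err = NA_real_, n_err = NA_real_,
                          converged = FALSE, rss = NA_real_),
                     class = "hill_fit"))
  }
  structure(list(pKa = opt$par[1L], n_hill = opt$par[2L],
                 pKa_err = NA_real_, n_err = NA_real_,
                 converged = opt$convergence == 0L, rss = opt$value),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("hill_fit: pKa = %.3f +/- %s, n = %.3f +/- %s\n", x$pKa,
                format(x$pKa_err, digits = 3), x$n_hill,
                format(x$n_err, digits = 3)))
  else cat("hill_fit: not converged (flat or nonmonotonic curve)\n")
  invisible(x)
}

#' Hill fit with blocked-bootstrap errors
#'
#' Resamples whole contiguous blocks with replacement within each pH
#' trajectory (correcting for autocorrelation in the occupancy series),
#' recomputes the protonated fractions and refits the Hill equation per
#' replicate. Reported errors are two times the standard deviation over
#' replicates, following the common 2-SE convention for titration fits.
#'
#' @param trajs List of `protonation_trajectory` objects covering several pH
#'   values (replicas allowed).
#' @param site_id Site label.
#' @param block_length Block length in frames (>= 1, <= shortest trajectory).
#' @param n_boot Number of bootstrap replicates (>= 2; 1000 typical).
#' @param seed Integer seed.
#' @return A `hill_fit` whose `pKa_err` and `n_err` are filled in; the point
#'   estimates come from the full-data fit. The per-point curve errors
#'   (2 x SD of the bootstrapped fractions) are attached as attribute
#'   `"curve"`.
#' @export
blocked_bootstrap_pka <- function(trajs, site_id, block_length = 100L,
                                  n_boot = 1000L, seed = 1L) {
  if (n_boot < 2L) stop("n_boot must be >= 2")
  nmin <- min(vapply(trajs, function(tr) nrow(tr$states), integer(1L)))
  if (block_length < 1L || block_length > nmin)
    stop("block_length must be in [1, shortest trajectory]")
  cols <- lapply(trajs, function(tr) {
    if (!site_id %in% tr$sites) stop("unknown site: ", site_id)
    tr$states[, site_id]
  })
  ph <- vapply(trajs, `[[`, numeric(1L), "pH")
  ph_u <- sort(unique(ph))
  restore <- .with_seed(seed)
  on.exit(restore())
  boot_frac <- matrix(NA_real_, n_boot, length(ph_u))
  est <- matrix(NA_real_, n_boot, 2L)
  for (b in seq_len(n_boot)) {
    frac <- vapply(seq_along(ph_u), function(k) {
      idx <- which(ph == ph_u[k])
      mean(unlist(lapply(idx, function(i) .resample_blocks(cols[[i]], block_length))))
    }, numeric(1L))
    boot_frac[b, ] <- frac
    fit <- fit_hill(data.frame(pH = ph_u, frac = frac))
    if (fit$converged) est[b, ] <- c(fit$pKa, fit$n_hill)
  }
  point_err <- 2 * apply(boot_frac, 2L, stats::sd)
  curve <- titration_curve(trajs, site_id, err = point_err)
  fit <- fit_hill(curve)
  ok <- stats::complete.cases(est)
  if (sum(ok) >= 2L) {
    fit$pKa_err <- 2 * stats::sd(est[ok, 1L])
    fit$n_err <- 2 * stats::sd(est[ok, 2L])
  }
  attr(fit, "curve") <- curve
  fit
}

.resample_blocks <- function(x, block_length) {
  n <- length(x)
  n_blocks <- ceiling(n / block_length)
  starts <- sample.int(n - block_length + 1L, n_blocks, replace = TRUE)
  idx <- rep(starts, each = block_length) + seq_len(block_length) - 1L
  x[idx[seq_len(n)]]
}

#' Classify a residue as a lumenal pH-sensor candidate
#'
#' A residue is a sensor candidate when its fitted pKa is upshifted by more
#' than one pH unit from the water reference of its class (Glu 4.3, Asp 3.9),
#' so that it can respond to lumen acidification around pH 5.5-6; a
#' non-converged fit (flat or up-and-down curve) indicates a strongly coupled
#' site whose pKa is undefined.
#'
#' @param fit A [fit_hill()] result.
#' @param residue_class `"GLU"` or `"ASP"`.
#' @param reference Named reference pKa values in water.
#' @param shift_threshold Minimum upshift, pH units.
#' @return One of `"sensor_candidate"`, `"non_sensor"`,
#'   `"coupled_undetermined"`.
#' @export
classify_sensor <- function(fit, residue_class,
                            reference = c(GLU = 4.3, ASP = 3.9),
                            shift_threshold = 1.0) {
  residue_class <- match.arg(toupper(residue_class), names(reference))
  if (!isTRUE(fit$converged)) return("coupled_undetermined")
  if (fit$pKa - reference[[residue_class]] > shift_threshold) "sensor_candidate"
  else "non_sensor"
}
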