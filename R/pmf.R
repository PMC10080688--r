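# Free-energy reweighting of boosted (accelerated-MD) samples by cumulant
# expansion of the exponential-boost average to the second order.

#' Reweight a boosted sample into a free-energy surface
#'
#' Histograms the projections on a uniform grid and recovers the unbiased
#' free energy per bin from the second-order cumulant expansion of the boost
#' reweighting factor,
#' \deqn{F = -k_B T\,[\ln p_{biased} + \beta\langle\Delta V\rangle_{bin}
#'       + \beta^2 \sigma^2_{\Delta V, bin}/2] + C,}
#' with the constant chosen so the minimum over reliable bins is zero. The
#' expansion is exact (up to sampling) when the boost is Gaussian within
#' each bin. Bins with fewer than `n_min` frames are flagged unreliable.
#'
#' @param projections Numeric vector or matrix with 1 or 2 columns
#'   (collective-variable values per frame).
#' @param boost Per-frame boost potential, kcal/mol (>= 0), aligned with
#'   `projections`; use zeros for unbiased data.
#' @param bins Number of uniform bins per dimension (default 50).
#' @param T Temperature, K.
#' @param n_min Minimum frames for a reliable bin (default 10).
#' @return A `pmf2d`: list with `edges` (list of per-dimension bin edges),
#'   `F` (kcal/mol, min-shifted to 0 over reliable bins; NA where empty),
#'   `counts`, `reliable` (logical), `T`.
#' @export
reweight_pmf <- function(projections, boost, bins = 50L, T = 300,
                         n_min = 10L) {
  X <- as.matrix(projections)
  ndim <- ncol(X)
  if (!ndim %in% c(1L, 2L)) stop("projections must have 1 or 2 columns")
  n <- nrow(X)
  if (length(boost) != n) stop("boost not aligned with projections")
  if (n == 0L) stop("no frames to reweight")
  if (any(boost < -1e-12)) stop("boost must be >= 0")
  beta <- 1 / (.kB_kcal * T)
  edges <- lapply(seq_len(ndim), function(d) {
    r <- range(X[, d])
    if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
    seq(r[1L], r[2L], length.out = bins + 1L)
  })
  bin_of <- function(x, e) {
    b <- findInterval(x, e, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), length(e) - 1L)
  }
  ib <- bin_of(X[, 1L], edges[[1L]])
  cell <- if (ndim == 2L) (bin_of(X[, 2L], edges[[2L]]) - 1L) * bins + ib else ib
  ncell <- if (ndim == 2L) bins * bins else bins
  counts <- tabulate(cell, nbins = ncell)
  sum_dv <- rowsum(boost, cell)
  sum_dv2 <- rowsum(boost^2, cell)
  mean_dv <- var_dv <- numeric(ncell)
  occ <- as.integer(rownames(sum_dv))
  mean_dv[occ] <- sum_dv[, 1L] / counts[occ]
  var_dv[occ] <- pmax(sum_dv2[, 1L] / counts[occ] - mean_dv[occ]^2, 0)
  Fv <- rep(NA_real_, ncell)
  occ_any <- counts > 0L
  Fv[occ_any] <- -(1 / beta) * (log(counts[occ_any] / n) +
                                  beta * mean_dv[occ_any] +
                                  beta^2 * var_dv[occ_any] / 2)
  reliable <- counts >= n_min
  if (!any(reliable)) stop("no bin reaches n_min frames")
  Fv <- Fv - min(Fv[reliable])
  shape <- if (ndim == 2L) c(bins, bins) else bins
  structure(list(edges = edges,
                 F = array(Fv, dim = shape),
                 counts = array(counts, dim = shape),
                 reliable = array(reliable, dim = shape),
                 T = T, n_min = n_min),
            class = "pmf2d")
}

#' Bin midpoints of a reweighted surface
#'
#' @param pmf A `pmf2d`.
#' @return List of per-dimension midpoint vectors.
#' @export
pmf_midpoints <- function(pmf) {
  lapply(pmf$edges, function(e) (e[-1L] + e[-length(e)]) / 2)
}
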