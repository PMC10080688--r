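# Geometric observables of the quenching site: chlorin-fixed reference
# frame, in-plane center-of-mass displacement, covariance coverage ellipse,
# and bond-length alternation of the conjugated carotenoid chain.

#' Build a chlorin-fixed reference frame
#'
#' Orthonormal frame anchored on a chlorophyll: origin at the Mg ion, z
#' normal to the least-squares plane of the four ring nitrogens (sign fixed
#' right-handed with respect to the nitrogen input order), x along the
#' in-plane projection of a designated N-to-N direction, y completing the
#' right-handed set.
#'
#' @param mg Length-3 Mg position, Angstrom.
#' @param ring_atoms 4 x 3 matrix of nitrogen positions.
#' @param x_pair Indices of the nitrogens defining the x direction
#'   (first -> second; default nitrogen 1 to nitrogen 3).
#' @return A `chlorin_frame`: list with `origin`, `x_axis`, `y_axis`,
#'   `z_axis` (orthonormal to 1e-8), `x_pair`.
#' @export
build_chlorin_frame <- function(mg, ring_atoms, x_pair = c(1L, 3L)) {
  mg <- as.numeric(mg)
  N <- as.matrix(ring_atoms)
  stopifnot(length(mg) == 3L, nrow(N) == 4L, ncol(N) == 3L)
  ctr <- colMeans(N)
  Nc <- sweep(N, 2L, ctr)
  sv <- svd(Nc)
  if (sv$d[2L] < 1e-8 * sv$d[1L]) stop("ring nitrogens are collinear")
  z <- sv$v[, 3L]
  # right-handed with respect to atom order N1, N2, N3
  hand <- .cross3(N[2L, ] - N[1L, ], N[3L, ] - N[1L, ])
  if (sum(hand * z) < 0) z <- -z
  dirx <- N[x_pair[2L], ] - N[x_pair[1L], ]
  xin <- dirx - sum(dirx * z) * z
  if (sqrt(sum(xin^2)) < 1e-10) stop("x_pair direction is normal to the ring plane")
  x <- xin / sqrt(sum(xin^2))
  y <- .cross3(z, x)
  structure(list(origin = mg, x_axis = x, y_axis = y, z_axis = z,
                 x_pair = x_pair),
            class = "chlorin_frame")
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' In-plane center-of-mass displacement in a chlorin frame
#'
#' Mass-weighted centroid of a set of atoms (e.g. the carotenoid isoprenoid
#' chain) expressed in the chlorin frame; returns the in-plane (x, y)
#' components, invariant under global rigid motion applied to both atoms
#' and frame.
#'
#' @param positions n x 3 matrix of atom positions, Angstrom.
#' @param masses Positive atomic masses (recycled if length 1).
#' @param frame A [build_chlorin_frame()] result.
#' @return Named numeric `c(x, y)`, Angstrom.
#' @export
com_displacement <- function(positions, masses, frame) {
  P <- as.matrix(positions)
  if (nrow(P) == 0L) stop("empty atom set")
  masses <- rep_len(as.numeric(masses), nrow(P))
  if (any(masses <= 0)) stop("masses must be > 0")
  com <- colSums(P * masses) / sum(masses)
  r <- com - frame$origin
  c(x = sum(r * frame$x_axis), y = sum(r * frame$y_axis))
}

#' Covariance ellipse enclosing a given fraction of 2-D data
#'
#' Mean-centered covariance ellipse scaled by the chi-square (2 dof)
#' quantile at the requested coverage; for Gaussian data the ellipse
#' encloses the nominal fraction of points asymptotically.
#'
#' @param points n x 2 matrix (n >= 3).
#' @param coverage Fraction in (0, 1) (default 0.40).
#' @return List with `center`, `semi_axes` (descending), `orientation`
#'   (radians of the major axis), `cov`, `coverage`, `degenerate` flag.
#' @export
coverage_ellipse <- function(points, coverage = 0.40) {
  P <- as.matrix(points)
  stopifnot(ncol(P) == 2L)
  if (nrow(P) < 3L) stop("need >= 3 points")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  ctr <- colMeans(P)
  S <- stats::cov(P)
  e <- eigen(S, symmetric = TRUE)
  degenerate <- e$values[2L] < 1e-12 * max(e$values[1L], 1e-300)
  c2 <- stats::qchisq(coverage, df = 2L)
  list(center = ctr,
       semi_axes = sqrt(pmax(c2 * e$values, 0)),
       orientation = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
       cov = S, coverage = coverage, degenerate = degenerate)
}

#' Fraction of points inside a coverage ellipse
#'
#' Mahalanobis containment check; the empirical counterpart of the nominal
#' coverage.
#'
#' @param ellipse A [coverage_ellipse()] result.
#' @param points n x 2 matrix.
#' @return Fraction of `points` inside the ellipse.
#' @export
ellipse_containment <- function(ellipse, points) {
  P <- sweep(as.matrix(points), 2L, ellipse$center)
  md2 <- rowSums((P %*% solve(ellipse$cov)) * P)
  mean(md2 <= stats::qchisq(ellipse$coverage, df = 2L))
}

#' Define a conjugated chain for bond-length alternation
#'
#' @param positions Ordered n x 3 matrix of the conjugated-chain atoms
#'   (n >= 4), Angstrom.
#' @param pattern Character vector of length n-1 with entries `"single"` or
#'   `"double"` per consecutive bond (alternation starting from the first
#'   bond by default).
#' @return A `conjugated_chain`.
#' @export
conjugated_chain <- function(positions,
                             pattern = rep_len(c("double", "single"),
                                               nrow(as.matrix(positions)) - 1L)) {
  P <- as.matrix(positions)
  if (nrow(P) < 4L) stop("need >= 4 atoms")
  if (length(pattern) != nrow(P) - 1L)
    stop("pattern length must equal number of bonds (atoms - 1)")
  pattern <- match.arg(pattern, c("single", "double"), several.ok = TRUE)
  structure(list(positions = P, pattern = pattern),
            class = "conjugated_chain")
}

#' Bond-length alternation of a conjugated chain
#'
#' Mean single-bond length minus mean double-bond length along the chain --
#' a proxy for pi-delocalization and hence for the carotenoid excitation
#' energy.
#'
#' @param chain A [conjugated_chain()].
#' @return BLA, Angstrom.
#' @export
bla <- function(chain) {
  stopifnot(inherits(chain, "conjugated_chain"))
  P <- chain$positions
  d <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  s <- chain$pattern == "single"
  if (!any(s) || all(s)) stop("pattern needs at least one single and one double bond")
  mean(d[s]) - mean(d[!s])
}
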