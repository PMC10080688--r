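# TrEsp excitonic couplings: Coulomb interaction of atom-centered transition
# charges between two pigments, with the empirical rescaling used to map the
# vacuum point-charge interaction onto screened reference couplings.

#' Construct a transition-charge set for one pigment state
#'
#' @param pigment_id Pigment label, e.g. `"Lut"` or `"a612"`.
#' @param atoms Data frame with columns `atom`, `x`, `y`, `z` (Angstrom) and
#'   `q` (transition charge, e); at least one atom, finite positions.
#' @param state_label Electronic-state label, e.g. `"S1"` or `"Qy"`.
#' @return A `transition_charge_set`.
#' @export
transition_charge_set <- function(pigment_id, atoms, state_label = "") {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("atom", "x", "y", "z", "q") %in% names(atoms)),
            nrow(atoms) >= 1L)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z", "q")]))))
    stop("non-finite positions or charges")
  structure(list(pigment_id = pigment_id, atoms = atoms,
                 state_label = state_label),
            class = "transition_charge_set")
}

#' @export
print.transition_charge_set <- function(x, ...) {
  cat(sprintf("transition_charge_set %s(%s): %d atoms, total q = %.4f e\n",
              x$pigment_id, x$state_label, nrow(x$atoms), sum(x$atoms$q)))
  invisible(x)
}

#' TrEsp excitonic coupling between two transition-charge sets
#'
#' Raw Coulomb double sum
#' \deqn{V_{raw} = K_e \sum_{i \in A}\sum_{j \in B} q_i q_j / r_{ij}}
#' with `K_e = 116140` cm^-1 Angstrom e^-2 (vacuum). The reported value
#' applies the empirical rescale factor; by the default `"divide"`
#' convention `V = V_raw / rescale` (attenuation, screening implicitly
#' absorbed in the factor), with `"multiply"` available. The result is
#' symmetric in the two sets.
#'
#' @param A,B `transition_charge_set` objects.
#' @param rescale Positive rescale factor (1 = raw; 3.7 used for the
#'   Lut/Chl pair to be comparable with reference work).
#' @param convention `"divide"` (default) or `"multiply"`.
#' @return Coupling V, cm^-1, with attributes `raw` and `convention`.
#' @export
tresp_coupling <- function(A, B, rescale = 1, convention = c("divide", "multiply")) {
  stopifnot(inherits(A, "transition_charge_set"),
            inherits(B, "transition_charge_set"))
  convention <- match.arg(convention)
  if (rescale <= 0) stop("rescale must be > 0")
  R <- .cross_distances(A$atoms, B$atoms)
  if (any(R < 0.5)) {
    idx <- which(R < 0.5, arr.ind = TRUE)[1L, ]
    stop(sprintf("atom clash between %s atom %d and %s atom %d (r = %.3f A)",
                 A$pigment_id, idx[1L], B$pigment_id, idx[2L], R[idx[1L], idx[2L]]))
  }
  v_raw <- .Ke_cm1_A_e2 * sum(outer(A$atoms$q, B$atoms$q) / R)
  v <- if (convention == "divide") v_raw / rescale else v_raw * rescale
  structure(v, raw = v_raw, convention = convention)
}

#' Per-frame TrEsp couplings with ensemble statistics
#'
#' @param frames List of frames, each a list with elements `A` and `B`
#'   (`transition_charge_set` objects), e.g. from [make_toy_pigment_pair()].
#' @param rescale,convention Passed to [tresp_coupling()].
#' @param conf Confidence level for the t-based interval (default 0.95).
#' @return List with `V` (per-frame couplings, cm^-1), `mean`, `ci`
#'   (length-2), `sd`, `n`.
#' @export
ensemble_couplings <- function(frames, rescale = 1,
                               convention = c("divide", "multiply"),
                               conf = 0.95) {
  stopifnot(length(frames) >= 1L)
  convention <- match.arg(convention)
  V <- vapply(frames, function(fr)
    as.numeric(tresp_coupling(fr$A, fr$B, rescale, convention)), numeric(1L))
  m <- mean(V); n <- length(V)
  s <- if (n > 1L) stats::sd(V) else 0
  half <- if (n > 1L) stats::qt(1 - (1 - conf) / 2, n - 1L) * s / sqrt(n) else 0
  list(V = V, mean = m, ci = c(m - half, m + half), sd = s, n = n)
}

#' Transition dipole of a charge set
#'
#' \eqn{\mu = \sum_i q_i r_i} (e Angstrom); with zero net charge this is
#' origin-independent and drives the far-field limit of the TrEsp coupling.
#'
#' @param A A `transition_charge_set`.
#' @return Length-3 numeric dipole, e Angstrom.
#' @export
transition_dipole <- function(A) {
  stopifnot(inherits(A, "transition_charge_set"))
  colSums(A$atoms$q * as.matrix(A$atoms[, c("x", "y", "z")]))
}
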