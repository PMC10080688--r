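# Protonation-microstate analysis: P/D encoding of coupled triads, windowed
# fraction coupling, and Markov transition networks over microstates.

#' Encode a protonation trajectory into microstate labels
#'
#' Each frame becomes a k-letter string over the alphabet P (protonated) /
#' D (deprotonated) in the declared site order, e.g. `"PDP"` for the
#' E114/E227/E233 triad with the middle site deprotonated.
#'
#' @param traj A `protonation_trajectory`.
#' @param triad Ordered character vector of sites (any k >= 1).
#' @return A `microstate_series`: list with `labels` (character per frame),
#'   `site_order`, `pH`.
#' @export
encode_microstates <- function(traj, triad) {
  stopifnot(inherits(traj, "protonation_trajectory"))
  missing <- setdiff(triad, traj$sites)
  if (length(missing) > 0L)
    stop("site(s) not in trajectory: ", paste(missing, collapse = ", "))
  m <- traj$states[, triad, drop = FALSE]
  letters_m <- matrix(c("D", "P")[m + 1L], nrow = nrow(m))
  labels <- do.call(paste0, as.data.frame(letters_m))
  structure(list(labels = labels, site_order = triad, pH = traj$pH),
            class = "microstate_series")
}

#' Decode microstate labels back to a binary occupancy matrix
#'
#' Inverse of [encode_microstates()]; used for round-trip checks.
#'
#' @param series A `microstate_series`.
#' @return Integer 0/1 matrix, frames x sites (1 = P).
#' @export
decode_microstates <- function(series) {
  stopifnot(inherits(series, "microstate_series"))
  k <- length(series$site_order)
  chars <- matrix(unlist(strsplit(series$labels, "", fixed = TRUE)),
                  ncol = k, byrow = TRUE)
  m <- matrix(as.integer(chars == "P"), ncol = k)
  colnames(m) <- series$site_order
  m
}

#' Nonoverlapping windowed protonation fractions
#'
#' Means over consecutive nonoverlapping windows of the binary occupancy
#' (e.g. 10-ns windows); a final partial window is dropped.
#'
#' @param traj A `protonation_trajectory`.
#' @param site_id Site label.
#' @param window Window length in frames (>= 1, <= trajectory length).
#' @return Numeric vector of per-window means.
#' @export
windowed_fractions <- function(traj, site_id, window) {
  stopifnot(inherits(traj, "protonation_trajectory"))
  if (!site_id %in% traj$sites) stop("unknown site: ", site_id)
  x <- traj$states[, site_id]
  if (window < 1L) stop("window must be >= 1")
  if (window > length(x)) stop("window longer than trajectory")
  nw <- length(x) %/% window
  colMeans(matrix(x[seq_len(nw * window)], nrow = window))
}

#' Classify the protonation coupling of a site pair
#'
#' Pearson correlation of two windowed protonation-fraction series: a
#' positive correlation means the pair is simultaneously neutral or charged,
#' a negative correlation a proton-sharing charged/neutral alternation.
#'
#' @param fracA,fracB Equal-length numeric series (length >= 3).
#' @param threshold Classification threshold on `|r|` (default 0.3).
#' @return List with `direction` (`"positive"`, `"negative"`,
#'   `"undetermined"`), `r`, and `r_defined` (FALSE for zero-variance input).
#' @export
correlation_coupling <- function(fracA, fracB, threshold = 0.3) {
  if (length(fracA) != length(fracB)) stop("series lengths differ")
  if (length(fracA) < 3L) stop("need >= 3 windows")
  if (stats::sd(fracA) == 0 || stats::sd(fracB) == 0)
    return(list(direction = "undetermined", r = NA_real_, r_defined = FALSE))
  r <- stats::cor(fracA, fracB)
  dir <- if (r > threshold) "positive" else if (r < -threshold) "negative"
  else "undetermined"
  list(direction = dir, r = r, r_defined = TRUE)
}

#' Estimate the Markov transition network over protonation microstates
#'
#' Counts transitions at a fixed lag over all sliding frame pairs, row-
#' normalizes into a transition matrix, and reports empirical state
#' populations. The full P/D alphabet over the declared sites is retained:
#' never-visited states keep a self-transition of 1 and population 0.
#'
#' @param series A `microstate_series`, or a list of them (independent
#'   replicas at the same pH; counts are merged before normalization).
#' @param lag Lag in frames (>= 1, < series length).
#' @return A `microstate_network`: list with `states`, `T` (row-stochastic),
#'   `counts`, `populations`, `lag`, `pH`.
#' @export
estimate_network <- function(series, lag = 1L) {
  if (inherits(series, "microstate_series")) series <- list(series)
  stopifnot(length(series) >= 1L, lag >= 1L)
  site_order <- series[[1L]]$site_order
  k <- length(site_order)
  states <- sort(apply(expand.grid(rep(list(c("D", "P")), k)), 1L, paste,
                       collapse = ""))
  ns <- length(states)
  counts <- matrix(0, ns, ns, dimnames = list(states, states))
  visits <- stats::setNames(numeric(ns), states)
  n_total <- 0L
  for (s in series) {
    stopifnot(identical(s$site_order, site_order))
    lab <- s$labels
    if (length(lab) == 0L) stop("empty microstate series")
    if (length(lab) <= lag) stop("series length must exceed lag")
    i <- factor(lab[seq_len(length(lab) - lag)], levels = states)
    j <- factor(lab[(lag + 1L):length(lab)], levels = states)
    counts <- counts + table(i, j)
    tv <- table(factor(lab, levels = states))
    visits <- visits + as.numeric(tv)
    n_total <- n_total + length(lab)
  }
  counts <- matrix(as.numeric(counts), ns, ns, dimnames = list(states, states))
  rs <- rowSums(counts)
  T <- counts / ifelse(rs > 0, rs, 1)
  T[rs == 0, ] <- 0
  diag(T)[rs == 0] <- 1              # never-visited: absorbing self-loop
  structure(list(states = states, T = T, counts = counts,
                 populations = visits / n_total, lag = as.integer(lag),
                 pH = series[[1L]]$pH),
            class = "microstate_network")
}

#' @export
print.microstate_network <- function(x, ...) {
  cat("microstate_network:", length(x$states), "states, lag", x$lag,
      "frames, pH", x$pH, "\n")
  pops <- sort(x$populations, decreasing = TRUE)
  cat("top populations:",
      paste(sprintf("%s=%.3f", names(pops)[seq_len(min(4, length(pops)))],
                    pops[seq_len(min(4, length(pops)))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Rank dominant microstates per pH
#'
#' Sorts microstates by population (ties broken alphabetically) for one
#' network per pH, supporting the selection of states for further analysis.
#'
#' @param networks A `microstate_network` or named/unnamed list of them.
#' @param top_k Number of states to keep per network (capped at state count).
#' @return Data frame with columns `pH`, `rank`, `state`, `population`.
#' @export
dominant_states <- function(networks, top_k = 4L) {
  if (inherits(networks, "microstate_network")) networks <- list(networks)
  out <- lapply(networks, function(net) {
    ord <- order(-net$populations, net$states)
    kk <- min(top_k, length(net$states))
    data.frame(pH = net$pH, rank = seq_len(kk),
               state = net$states[ord][seq_len(kk)],
               population = unname(net$populations[ord][seq_len(kk)]))
  })
  do.call(rbind, out)
}

#' Stationary distribution of a transition matrix
#'
#' Dominant left eigenvector of a row-stochastic matrix, normalized to a
#' probability vector; the eigen-based cross-check for empirical populations
#' of reversible chains.
#'
#' @param T Row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v <- abs(v) / sum(abs(v))
  stats::setNames(v, rownames(T))
}

#' Export a microstate network as edge and node tables
#'
#' @param net A `microstate_network`.
#' @param dir Output directory; writes `edges.csv`
#'   (`from,to,count,probability`) and `nodes.csv` (`state,population`).
#' @return Invisibly, the two file paths.
#' @export
write_network_csv <- function(net, dir) {
  stopifnot(inherits(net, "microstate_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- which(net$counts > 0, arr.ind = TRUE)
  edges <- data.frame(from = net$states[idx[, 1L]], to = net$states[idx[, 2L]],
                      count = net$counts[idx],
                      probability = net$T[idx])
  edges <- edges[order(edges$from, edges$to), ]
  nodes <- data.frame(state = net$states,
                      population = unname(net$populations))
  fe <- file.path(dir, "edges.csv"); fn <- file.path(dir, "nodes.csv")
  utils::write.csv(edges, fe, row.names = FALSE)
  utils::write.csv(nodes, fn, row.names = FALSE)
  invisible(c(fe, fn))
}
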