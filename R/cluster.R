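# Density-based clustering of tICA projections with a noise label, plus
# stratified sampling and representative-frame selection per cluster.
#
# The clustering is HDBSCAN (Campello-Moulavi-Sander): core distances at
# min_samples, mutual-reachability minimum spanning tree, single-linkage
# hierarchy, condensation at min_cluster_size, and excess-of-mass cluster
# selection over the condensed tree. All steps are deterministic.

#' Cluster projected frames by hierarchical density
#'
#' Runs HDBSCAN on the projection matrix: points in no persistent density
#' mode receive the noise label `-1`; clusters are numbered `1..K` in order
#' of first appearance. Cluster membership does not depend on any random
#' initialisation. Per-cluster protonation-microstate composition is
#' computed when per-frame provenance labels are supplied.
#'
#' @param projections Numeric matrix, frames x dims (dense distances are
#'   used; intended for up to a few thousand frames).
#' @param min_cluster_size Smallest cluster retained (default 0.5% of the
#'   frames, at least 5).
#' @param min_samples Neighborhood size for core distances (default
#'   `min(min_cluster_size, 15)`).
#' @param pms Optional character vector of per-frame microstate labels used
#'   for the composition bookkeeping.
#' @return A `cluster_set`: list with `labels` (integer per frame, -1 noise),
#'   `sizes` (named), `composition` (per-cluster named fraction vectors, or
#'   NULL), `pms`, `n_clusters`, and the parameters used.
#' @export
cluster_density <- function(projections,
                            min_cluster_size = NULL,
                            min_samples = NULL,
                            pms = NULL) {
  X <- as.matrix(projections)
  n <- nrow(X)
  if (is.null(min_cluster_size))
    min_cluster_size <- max(5L, ceiling(0.005 * n))
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  if (is.null(min_samples)) min_samples <- min(min_cluster_size, 15L)
  min_samples <- max(2L, min(as.integer(min_samples), n - 1L))
  if (n < min_cluster_size) stop("fewer points than min_cluster_size")
  if (!is.null(pms)) stopifnot(length(pms) == n)

  labels <- .hdbscan_labels(X, min_cluster_size, min_samples)
  if (all(labels == -1L))
    warning("all points classified as noise; empty cluster set")
  sizes <- table(labels[labels > 0L])
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  composition <- NULL
  if (!is.null(pms) && length(sizes) > 0L) {
    composition <- lapply(sort(unique(labels[labels > 0L])), function(cl) {
      tab <- table(pms[labels == cl])
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
    names(composition) <- names(sizes)
  }
  structure(list(labels = labels, sizes = sizes, composition = composition,
                 pms = pms, n_clusters = length(sizes),
                 min_cluster_size = min_cluster_size,
                 min_samples = min_samples),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", x$n_clusters, "cluster(s),",
      sum(x$labels == -1L), "noise point(s) of", length(x$labels), "\n")
  invisible(x)
}

# full HDBSCAN labelling; returns integer labels, -1 = noise
.hdbscan_labels <- function(X, mcs, ms) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  # core distance: distance to the ms-th nearest point (self included)
  core <- apply(D, 1L, function(r) sort(r, partial = ms)[ms])
  MR <- pmax(D, outer(core, core, pmax))
  mst <- .prim_mst(MR)
  tree <- .single_linkage(mst, n)
  .condense_and_select(tree, n, mcs)
}

# Prim MST on a dense distance matrix; returns edges (from,to,weight)
.prim_mst <- function(W) {
  n <- nrow(W)
  intree <- logical(n); intree[1L] <- TRUE
  d <- W[1L, ]; parent <- rep(1L, n); d[1L] <- Inf
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n - 1L)) {
    cand <- d; cand[intree] <- Inf
    j <- which.min(cand)
    edges[k, ] <- c(parent[j], j, d[j])
    intree[j] <- TRUE
    upd <- !intree & W[j, ] < d
    d[upd] <- W[j, upd]; parent[upd] <- j
  }
  edges[order(edges[, 3L]), , drop = FALSE]
}

# single-linkage merge tree from sorted MST edges (union-find)
# node ids: 1..n leaves, n+1..2n-1 internal merges
.single_linkage <- function(edges, n) {
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent_uf[i] != i) {
      parent_uf[i] <<- parent_uf[parent_uf[i]]
      i <- parent_uf[i]
    }
    i
  }
  node_of <- c(seq_len(n), integer(n - 1L))  # tree node of each component root
  left <- right <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (k in seq_len(n - 1L)) {
    ra <- find(edges[k, 1L]); rb <- find(edges[k, 2L])
    na <- node_of[ra]; nb <- node_of[rb]
    id <- n + k
    left[k] <- na; right[k] <- nb; height[k] <- edges[k, 3L]
    size[id] <- size[na] + size[nb]
    parent_uf[ra] <- id; parent_uf[rb] <- id; parent_uf[id] <- id
    node_of[id] <- id
  }
  list(left = left, right = right, height = height, size = size, n = n)
}

# collect leaf indices under a tree node (iterative)
.leaves_under <- function(tree, v) {
  n <- tree$n
  out <- integer(0L); stack <- v
  while (length(stack) > 0L) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u <= n) out <- c(out, u)
    else {
      k <- u - n
      stack <- c(stack, tree$left[k], tree$right[k])
    }
  }
  out
}

# condensed-tree construction + excess-of-mass selection -> labels
.condense_and_select <- function(tree, n, mcs) {
  root_node <- 2L * n - 1L
  max_cl <- max(2L, 2L * ceiling(n / mcs) + 2L)
  cl_parent <- integer(max_cl); cl_birth <- numeric(max_cl)
  cl_stab <- numeric(max_cl); cl_children <- vector("list", max_cl)
  n_cl <- 1L
  cl_parent[1L] <- 0L; cl_birth[1L] <- 0
  fallout <- integer(n); pt_cl <- integer(n)
  stack_node <- root_node; stack_cl <- 1L
  while (length(stack_node) > 0L) {
    v <- stack_node[length(stack_node)]; cc <- stack_cl[length(stack_cl)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cl <- stack_cl[-length(stack_cl)]
    k <- v - n
    lam <- if (tree$height[k] > 0) 1 / tree$height[k] else Inf
    c1 <- tree$left[k]; c2 <- tree$right[k]
    s1 <- tree$size[c1]; s2 <- tree$size[c2]
    big1 <- s1 >= mcs; big2 <- s2 >= mcs
    if (big1 && big2) {
      cl_stab[cc] <- cl_stab[cc] + tree$size[v] * (lam - cl_birth[cc])
      for (ch_node in c(c1, c2)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cc; cl_birth[n_cl] <- lam
        cl_children[[cc]] <- c(cl_children[[cc]], n_cl)
        if (ch_node > n) {
          stack_node <- c(stack_node, ch_node); stack_cl <- c(stack_cl, n_cl)
        } else {  # unreachable for mcs >= 2
          fallout[ch_node] <- n_cl; pt_cl[ch_node] <- n_cl
        }
      }
    } else if (big1 || big2) {
      small <- if (big1) c2 else c1
      keep <- if (big1) c1 else c2
      pts <- .leaves_under(tree, small)
      fallout[pts] <- cc
      cl_stab[cc] <- cl_stab[cc] + length(pts) * (lam - cl_birth[cc])
      if (keep > n) {
        stack_node <- c(stack_node, keep); stack_cl <- c(stack_cl, cc)
      } else fallout[keep] <- cc
    } else {
      pts <- .leaves_under(tree, v)
      fallout[pts] <- cc
      cl_stab[cc] <- cl_stab[cc] + length(pts) * (lam - cl_birth[cc])
    }
  }
  # excess-of-mass selection, bottom-up; root (cluster 1) never selected
  sel <- logical(n_cl); score <- numeric(n_cl)
  for (cc in seq.int(n_cl, 1L)) {
    kids <- cl_children[[cc]]
    if (length(kids) == 0L) {
      score[cc] <- cl_stab[cc]; sel[cc] <- TRUE
    } else {
      kid_score <- sum(score[kids])
      if (cl_stab[cc] > kid_score && cc != 1L) {
        score[cc] <- cl_stab[cc]; sel[cc] <- TRUE
      } else score[cc] <- kid_score
    }
  }
  sel[1L] <- FALSE
  # final selection: drop clusters with a selected ancestor
  final <- logical(n_cl)
  for (cc in seq_len(n_cl)) {
    if (!sel[cc]) next
    anc <- cl_parent[cc]; blocked <- FALSE
    while (anc != 0L) {
      if (sel[anc]) { blocked <- TRUE; break }
      anc <- cl_parent[anc]
    }
    final[cc] <- !blocked
  }
  # label points: walk up from fallout cluster to first finally-selected one
  labels <- rep(-1L, n)
  for (i in seq_len(n)) {
    cc <- fallout[i]
    while (cc != 0L) {
      if (final[cc]) { labels[i] <- cc; break }
      cc <- cl_parent[cc]
    }
  }
  # renumber clusters 1..K in order of appearance
  used <- unique(labels[labels > 0L])
  if (length(used) > 0L) {
    remap <- stats::setNames(seq_along(sort(used)), sort(used))
    labels[labels > 0L] <- remap[as.character(labels[labels > 0L])]
  }
  labels
}

#' Stratified sampling of frames per cluster, preserving composition
#'
#' Within each cluster, sample counts are allocated to microstate strata by
#' largest-remainder rounding of `composition * n_per_cluster`, then drawn
#' uniformly without replacement within each stratum (falling back to
#' with-replacement with a warning when a stratum is smaller than its
#' allocation).
#'
#' @param clusters A [cluster_density()] result with `pms` provenance.
#' @param n_per_cluster Samples per cluster (>= 1).
#' @param seed Integer seed.
#' @return Named list (one element per cluster) of integer frame indices.
#' @export
stratified_sample <- function(clusters, n_per_cluster, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_set"), n_per_cluster >= 1L)
  if (is.null(clusters$pms)) stop("cluster_set lacks microstate provenance")
  restore <- .with_seed(seed)
  on.exit(restore())
  out <- list()
  for (cl in sort(unique(clusters$labels[clusters$labels > 0L]))) {
    idx <- which(clusters$labels == cl)
    strata <- split(idx, clusters$pms[idx])
    comp <- vapply(strata, length, integer(1L)) / length(idx)
    alloc <- .largest_remainder(comp, n_per_cluster)
    picked <- integer(0L)
    for (sname in names(strata)) {
      k <- alloc[[sname]]
      if (k == 0L) next
      pool <- strata[[sname]]
      if (k > length(pool)) {
        warning(sprintf("stratum %s of cluster %d smaller than allocation; %s",
                        sname, cl, "sampling with replacement"))
        picked <- c(picked, sample(pool, k, replace = TRUE))
      } else if (length(pool) == 1L) {
        picked <- c(picked, rep(pool, k))
      } else {
        picked <- c(picked, sample(pool, k))
      }
    }
    out[[as.character(cl)]] <- picked
  }
  out
}

# largest-remainder apportionment; ties by remainder then name
.largest_remainder <- function(comp, n) {
  q <- comp * n
  base <- floor(q)
  rem <- q - base
  left <- n - sum(base)
  if (left > 0L) {
    ord <- order(-rem, names(comp))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(comp))
}

#' Representative frame of each cluster
#'
#' The frame minimizing the Euclidean distance to the cluster mean in
#' projection space; ties broken by lowest frame index.
#'
#' @param clusters A `cluster_set`.
#' @param projections The projection matrix the clustering was run on.
#' @return Named integer vector, one frame index per cluster.
#' @export
representative_frame <- function(clusters, projections) {
  stopifnot(inherits(clusters, "cluster_set"))
  X <- as.matrix(projections)
  cls <- sort(unique(clusters$labels[clusters$labels > 0L]))
  out <- vapply(cls, function(cl) {
    idx <- which(clusters$labels == cl)
    ctr <- colMeans(X[idx, , drop = FALSE])
    d2 <- rowSums(sweep(X[idx, , drop = FALSE], 2L, ctr)^2)
    idx[which.min(d2)]
  }, integer(1L))
  stats::setNames(out, cls)
}
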