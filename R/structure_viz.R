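#' Outgroup-f3 genetic distance matrix
#'
#' Outgroup-f3 statistics f3(i, j; outgroup) measure the drift shared by i
#' and j since their divergence from the outgroup; their inverses form a
#' pairwise genetic-distance matrix suitable for MDS and neighbor-joining.
#'
#' @param counts A [count_table()].
#' @param labels Populations to include.
#' @param outgroup Outgroup label (study convention: Yoruba).
#' @return A symmetric `dist_matrix` object (matrix with zero diagonal and a
#'   `provenance` attribute); pairwise SNP counts in attribute `n_snps`.
#' @export
outgroup_f3_distance <- function(counts, labels, outgroup) {
  stop_if_not(!outgroup %in% labels, "outgroup must not be among the labels")
  k <- length(labels)
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  NS <- matrix(0L, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fs <- f3_stat(counts, outgroup, labels[i], labels[j], outgroup_mode = TRUE)
    if (!is.finite(fs$estimate) || fs$estimate <= 0) {
      stop(sprintf("non-positive outgroup-f3 for pair (%s, %s): unsuitable outgroup",
                   labels[i], labels[j]), call. = FALSE)
    }
    D[i, j] <- D[j, i] <- 1 / fs$estimate
    NS[i, j] <- NS[j, i] <- fs$n_snps
  }
  structure(D, class = c("dist_matrix", "matrix"), provenance = "1/f3",
            n_snps = NS)
}

#' Classical (metric) multidimensional scaling
#'
#' Thin wrapper over double-centered eigendecomposition (`cmdscale`), with a
#' reproducible sign convention: on each axis the largest-magnitude
#' coordinate is made positive. Axes with non-positive eigenvalues are
#' suppressed (with a warning if `k` had to be truncated).
#'
#' @param D Distance matrix (symmetric, zero diagonal).
#' @param k Number of dimensions requested.
#' @return List with `points` (n x k'), `eig` (all eigenvalues), `k` used.
#' @export
classical_mds <- function(D, k = 2) {
  stop_if_not(k >= 1, "k must be >= 1")
  D <- as.matrix(D)
  stop_if_not(max(abs(D - t(D))) < 1e-12, "distance matrix must be symmetric")
  res <- cmdscale(as.dist(D), k = min(k, nrow(D) - 1), eig = TRUE)
  eig <- res$eig
  npos <- sum(eig > 1e-12 * max(abs(eig)))
  kk <- min(k, npos)
  if (kk < k) warning(sprintf("only %d positive eigenvalues; returning %d axes", npos, kk))
  pts <- res$points[, seq_len(kk), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, j])), j] < 0) pts[, j] <- -pts[, j]
  }
  list(points = pts, eig = eig, k = kk)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (lowest label
#' pair lexicographically on equal Q-criterion). Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling edge, preserving
#' path lengths through the parent. Optionally rooted on a leaf's edge.
#'
#' @param D Distance matrix with unique labels (>= 3).
#' @param root_at Optional leaf label to root on (the study roots its trees
#'   at an ancient Beringian genome).
#' @return An `ape::phylo` tree.
#' @export
neighbor_joining <- function(D, root_at = NULL) {
  D <- as.matrix(D)
  labs <- rownames(D) %||% colnames(D)
  stop_if_not(!is.null(labs), "distance matrix must carry labels")
  stop_if_not(!anyDuplicated(labs), "duplicate labels")
  n <- length(labs)
  stop_if_not(n >= 3, "need at least 3 taxa")
  act <- labs
  dm <- D
  dimnames(dm) <- list(act, act)
  # grow an edge list; internal nodes named I1, I2, ...
  edges <- list(); ni <- 0
  lens <- list()
  while (length(act) > 3) {
    m <- length(act)
    tot <- rowSums(dm[act, act])
    q <- matrix(Inf, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      q[i, j] <- (m - 2) * dm[act[i], act[j]] - tot[i] - tot[j]
    }
    best <- which(q == min(q), arr.ind = TRUE)
    if (nrow(best) > 1) {
      key <- apply(best, 1, function(r) paste(sort(c(act[r[1]], act[r[2]])), collapse = "\r"))
      best <- best[order(key)[1], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    a <- act[i]; b <- act[j]
    ni <- ni + 1
    u <- paste0("I", ni)
    la <- dm[a, b] / 2 + (tot[i] - tot[j]) / (2 * (m - 2))
    lb <- dm[a, b] - la
    # clamp negatives, moving the deficit to the sibling edge
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    edges[[length(edges) + 1]] <- c(u, a, la)
    edges[[length(edges) + 1]] <- c(u, b, lb)
    rest <- setdiff(act, c(a, b))
    newd <- (dm[a, rest] + dm[b, rest] - dm[a, b]) / 2
    dm <- rbind(cbind(dm, 0), 0)
    rownames(dm)[nrow(dm)] <- colnames(dm)[ncol(dm)] <- u
    dm[u, rest] <- newd; dm[rest, u] <- newd; dm[u, u] <- 0
    act <- c(rest, u)
  }
  # final three taxa joined in an unrooted star
  a <- act[1]; b <- act[2]; cc <- act[3]
  ni <- ni + 1; u <- paste0("I", ni)
  la <- (dm[a, b] + dm[a, cc] - dm[b, cc]) / 2
  lb <- (dm[a, b] + dm[b, cc] - dm[a, cc]) / 2
  lc <- (dm[a, cc] + dm[b, cc] - dm[a, b]) / 2
  if (la < 0) { lb <- lb + la; lc <- lc + la; la <- 0 }
  if (lb < 0) { la <- la + lb; lc <- lc + lb; lb <- 0 }
  if (lc < 0) { la <- la + lc; lb <- lb + lc; lc <- 0 }
  edges[[length(edges) + 1]] <- c(u, a, la)
  edges[[length(edges) + 1]] <- c(u, b, lb)
  edges[[length(edges) + 1]] <- c(u, cc, lc)
  # assemble Newick via ape
  em <- do.call(rbind, edges)
  children <- split(seq_len(nrow(em)), em[, 1])
  as_newick <- function(node) {
    kids <- children[[node]]
    if (is.null(kids)) return(node)
    parts <- vapply(kids, function(e)
      paste0(as_newick(em[e, 2]), ":", format(as.numeric(em[e, 3]), digits = 12)),
      character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(as_newick(u), ";")
  phy <- ape::read.tree(text = nwk)
  if (!is.null(root_at)) {
    stop_if_not(root_at %in% labs, paste0("root_at label not in matrix: ", root_at))
    phy <- ape::root(phy, outgroup = root_at, resolve.root = TRUE)
  }
  phy
}

#' Hierarchical clustering of an Fst matrix
#'
#' Agglomerative clustering of pairwise Fst distances. The default linkage is
#' average (UPGMA-style, robust for noisy Fst); complete linkage is exposed
#' because the wording of published "complete hierarchical clustering trees"
#' is ambiguous between completeness and the complete-linkage criterion.
#' Pairs below the pairwise SNP floor must be excluded upstream; `NA` cells
#' are an error.
#'
#' @param fst Symmetric matrix of pairwise Fst values.
#' @param method Linkage: `"average"` (default) or any `hclust` method.
#' @param cut_height Optional dendrogram cut height for flat clusters.
#' @return List with `hclust`, `newick` (dendrogram as a tree), and
#'   `clusters` (if `cut_height` given).
#' @export
fst_hclust <- function(fst, method = "average", cut_height = NULL) {
  fst <- as.matrix(fst)
  stop_if_not(!anyNA(fst), "NA cells in the Fst matrix (pairs below the SNP floor?)")
  hc <- hclust(as.dist(fst), method = method)
  phy <- ape::as.phylo(hc)
  out <- list(hclust = hc, newick = ape::write.tree(phy))
  if (!is.null(cut_height)) out$clusters <- cutree(hc, h = cut_height)
  out
}
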