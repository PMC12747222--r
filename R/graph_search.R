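#' Per-block f2 statistics for all population pairs
#'
#' The substrate of admixture-graph fitting: block-mean bias-corrected f2
#' values for every pair of populations, with per-block SNP-count weights and
#' jackknife estimates/SEs.
#'
#' @param counts A [count_table()].
#' @param pops Populations to include (default all).
#' @param correction Apply the finite-sample heterozygosity correction.
#' @return Object of class `f2_blocks`: `pairs` (P x 2), `bv` (blocks x P
#'   block means), `bw` (blocks x P weights), `est`, `se`, `pops`.
#' @export
f2_blocks <- function(counts, pops = counts$groups, correction = TRUE) {
  P <- combn(pops, 2)
  np <- ncol(P)
  g <- length(unique(counts$block))
  bv <- matrix(NA_real_, g, np); bw <- matrix(0, g, np)
  est <- se <- numeric(np)
  lev <- sort(unique(counts$block))
  for (k in seq_len(np)) {
    fs <- f2_stat(counts, P[1, k], P[2, k], correction = correction)
    bvk <- rep(NA_real_, g); bwk <- rep(0, g)
    bidx <- match(as.integer(names(fs$block_weights)), lev)
    bvk[bidx] <- fs$block_values
    bwk[bidx] <- fs$block_weights
    bv[, k] <- bvk; bw[, k] <- bwk
    est[k] <- fs$estimate; se[k] <- fs$se
  }
  structure(list(pairs = t(P), bv = bv, bw = bw, est = est, se = se,
                 pops = pops, n_blocks = g),
            class = "f2_blocks")
}

pair_index <- function(f2b, a, b) {
  hit <- which((f2b$pairs[, 1] == a & f2b$pairs[, 2] == b) |
                 (f2b$pairs[, 1] == b & f2b$pairs[, 2] == a))
  stop_if_not(length(hit) == 1, paste0("pair not found: ", a, ",", b))
  hit
}

#' Construct an admixture graph
#'
#' A rooted DAG in which every non-root node has either one parent (a drift
#' edge with length >= 0) or exactly two parents (an admixture node whose two
#' incoming edges carry mixing weights gamma and 1 - gamma and no drift).
#'
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"drift"` or `"admix"`) and `value` (drift length, or mixing weight for
#'   admix edges; may be `NA` before fitting).
#' @return Object of class `admixture_graph`.
#' @export
admixture_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stop_if_not(all(c("child", "parent", "type") %in% names(edges)),
              "edges needs child, parent, type")
  if (is.null(edges$value)) edges$value <- NA_real_
  stop_if_not(all(edges$type %in% c("drift", "admix")), "type must be drift/admix")
  npar <- table(edges$child)
  adm_children <- unique(edges$child[edges$type == "admix"])
  for (v in names(npar)) {
    if (v %in% adm_children) {
      stop_if_not(npar[[v]] == 2 && all(edges$type[edges$child == v] == "admix"),
                  paste0("admixture node must have exactly 2 admix parents: ", v))
    } else {
      stop_if_not(npar[[v]] == 1, paste0("node has multiple drift parents: ", v))
    }
  }
  nodes <- unique(c(edges$child, edges$parent))
  root <- setdiff(edges$parent, edges$child)
  stop_if_not(length(root) == 1, "graph must have exactly one root")
  # acyclicity via Kahn peeling
  rem <- edges
  while (nrow(rem) > 0) {
    sinks <- setdiff(rem$child, rem$parent)
    if (!length(sinks)) stop("graph contains a cycle", call. = FALSE)
    rem <- rem[!rem$child %in% sinks, , drop = FALSE]
  }
  leaves <- setdiff(edges$child, edges$parent)
  structure(list(edges = edges, root = root, leaves = sort(leaves), nodes = nodes),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  nadm <- length(unique(x$edges$child[x$edges$type == "admix"]))
  cat(sprintf("admixture_graph: %d leaves (%s), %d admixture events\n",
              length(x$leaves), paste(x$leaves, collapse = ","), nadm))
  if (!is.null(attr(x, "score"))) {
    cat(sprintf("  score %.4g, worst residual |Z| = %.2f\n",
                attr(x, "score"), attr(x, "worst_residual")))
  }
  invisible(x)
}

# Enumerate root-to-leaf path distributions: list per leaf of (drift-edge
# indicator matrix rows, probabilities), resolving each admixture node by its
# two parents.
leaf_path_table <- function(graph) {
  ed <- graph$edges
  drift_ids <- which(ed$type == "drift")
  nd <- length(drift_ids)
  memo <- new.env(parent = emptyenv())
  paths <- function(node) {
    if (node == graph$root) {
      return(list(mask = matrix(FALSE, 1, nd), pr = 1))
    }
    if (!is.null(memo[[node]])) return(memo[[node]])
    pe <- which(ed$child == node)
    if (length(pe) == 1) {
      up <- paths(ed$parent[pe])
      m <- up$mask
      j <- match(pe, drift_ids)
      m[, j] <- TRUE
      res <- list(mask = m, pr = up$pr)
    } else {
      w <- ed$value[pe]
      if (anyNA(w)) w <- c(0.5, 0.5)
      acc_m <- NULL; acc_p <- NULL
      for (t in 1:2) {
        up <- paths(ed$parent[pe[t]])
        acc_m <- rbind(acc_m, up$mask)
        acc_p <- c(acc_p, up$pr * w[t])
      }
      res <- list(mask = acc_m, pr = acc_p)
    }
    memo[[node]] <- res
    res
  }
  tab <- lapply(graph$leaves, paths)
  names(tab) <- graph$leaves
  list(paths = tab, drift_ids = drift_ids)
}

#' Expected f2 between two leaves of a parameterized admixture graph
#'
#' Path-overlap algebra: summing over pairs of root-to-leaf paths (admixture
#' nodes choose a parent with their mixing weight), the expected f2 is the
#' probability-weighted total drift on the symmetric difference of the two
#' paths' drift-edge sets.
#'
#' @param graph An [admixture_graph()] with drift lengths and weights set.
#' @param a,b Leaf labels.
#' @return Expected f2 in drift units.
#' @export
expected_f2 <- function(graph, a, b) {
  pt <- leaf_path_table(graph)
  len <- graph$edges$value[pt$drift_ids]
  pa <- pt$paths[[a]]; pb <- pt$paths[[b]]
  tot <- 0
  for (i in seq_along(pa$pr)) for (j in seq_along(pb$pr)) {
    sd <- xor(pa$mask[i, ], pb$mask[j, ])
    tot <- tot + pa$pr[i] * pb$pr[j] * sum(len[sd])
  }
  tot
}

# Linear design of expected f2 over drift-edge lengths for fixed admixture
# weights: rows = leaf pairs, cols = drift edges.
f2_design <- function(graph, pairs) {
  pt <- leaf_path_table(graph)
  nd <- length(pt$drift_ids)
  M <- matrix(0, nrow(pairs), nd)
  for (k in seq_len(nrow(pairs))) {
    pa <- pt$paths[[pairs[k, 1]]]; pb <- pt$paths[[pairs[k, 2]]]
    acc <- numeric(nd)
    for (i in seq_along(pa$pr)) for (j in seq_along(pb$pr)) {
      acc <- acc + pa$pr[i] * pb$pr[j] * xor(pa$mask[i, ], pb$mask[j, ])
    }
    M[k, ] <- acc
  }
  list(M = M, drift_ids = pt$drift_ids)
}

set_gammas <- function(graph, gammas) {
  ed <- graph$edges
  adm <- unique(ed$child[ed$type == "admix"])
  for (i in seq_along(adm)) {
    pe <- which(ed$child == adm[i])
    ed$value[pe[1]] <- gammas[i]
    ed$value[pe[2]] <- 1 - gammas[i]
  }
  graph$edges <- ed
  graph
}

#' Fit an admixture graph to observed f2 statistics
#'
#' For fixed admixture weights the expected f2 basis is linear in drift-edge
#' lengths, so lengths are profiled out by non-negative weighted least squares
#' (weights 1/se^2); the (at most few) mixing weights are then optimized by
#' grid search plus 1-D refinement per admixture node. The score is the
#' se-weighted squared deviation between expected and observed f2 over all
#' leaf pairs; the worst residual is the largest |Z| over all f4 statistics
#' implied by the f2 basis.
#'
#' @param graph An [admixture_graph()] (parameter values may be `NA`).
#' @param f2b An [f2_blocks()] covering all graph leaves.
#' @return The graph with fitted `value`s and attributes `score`,
#'   `worst_residual`, `fitted` (per-pair table).
#' @export
fit_graph <- function(graph, f2b) {
  stop_if_not(all(graph$leaves %in% f2b$pops),
              "graph leaves missing from the f2 table")
  prs <- t(combn(sort(graph$leaves), 2))
  ki <- vapply(seq_len(nrow(prs)), function(k) pair_index(f2b, prs[k, 1], prs[k, 2]),
               integer(1))
  y <- f2b$est[ki]
  se <- f2b$se[ki]
  wts <- 1 / pmax(se, 1e-9)^2
  sw <- sqrt(wts)
  adm <- unique(graph$edges$child[graph$edges$type == "admix"])
  solve_lengths <- function(gr) {
    des <- f2_design(gr, prs)
    A <- des$M * sw
    # tiny ridge augmentation: root-adjacent (and other jointly identifiable)
    # edges make the design rank-deficient; this picks the minimal-norm split
    # without affecting the score materially
    lam <- 1e-6 * max(abs(A), 1e-12)
    Areg <- rbind(A, diag(lam, ncol(A)))
    fit <- pracma::lsqnonneg(Areg, c(y * sw, rep(0, ncol(A))))
    len <- fit$x
    score <- sum((A %*% len - y * sw)^2)
    list(len = len, score = score, drift_ids = des$drift_ids)
  }
  best <- NULL; best_g <- numeric(0)
  if (length(adm) == 0) {
    best <- solve_lengths(graph)
    g_final <- graph
  } else {
    gam <- rep(0.5, length(adm))
    for (pass in 1:2) {
      for (i in seq_along(adm)) {
        grid <- seq(0.02, 0.98, length.out = 13)
        sc <- vapply(grid, function(gv) {
          gam[i] <- gv
          solve_lengths(set_gammas(graph, gam))$score
        }, numeric(1))
        lo <- max(0, grid[which.min(sc)] - 0.1)
        hi <- min(1, grid[which.min(sc)] + 0.1)
        op <- optimize(function(gv) {
          gam[i] <- gv
          solve_lengths(set_gammas(graph, gam))$score
        }, c(lo, hi))
        gam[i] <- op$minimum
      }
    }
    g_final <- set_gammas(graph, gam)
    best <- solve_lengths(g_final)
    best_g <- gam
  }
  g_final$edges$value[best$drift_ids] <- best$len
  fitted <- vapply(seq_len(nrow(prs)), function(k)
    expected_f2(g_final, prs[k, 1], prs[k, 2]), numeric(1))
  attr(g_final, "score") <- best$score
  attr(g_final, "fitted") <- data.frame(pop1 = prs[, 1], pop2 = prs[, 2],
                                        observed = y, fitted = fitted, se = se)
  attr(g_final, "worst_residual") <- worst_f4_residual(g_final, f2b)
  attr(g_final, "gammas") <- best_g
  g_final
}

# Largest |Z| over all f4(A,B;C,D) implied by the f2 basis:
# f4 = (f2(A,D) + f2(B,C) - f2(A,C) - f2(B,D)) / 2, per block, jackknifed.
worst_f4_residual <- function(graph, f2b) {
  leaves <- sort(graph$leaves)
  if (length(leaves) < 4) return(0)
  quads <- combn(leaves, 4)
  worst <- 0
  fitted_f2 <- function(a, b) expected_f2(graph, a, b)
  for (q in seq_len(ncol(quads))) {
    v <- quads[, q]
    splits <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    for (s in splits) {
      A <- v[s[1]]; B <- v[s[2]]; C <- v[s[3]]; D <- v[s[4]]
      ii <- c(pair_index(f2b, A, D), pair_index(f2b, B, C),
              pair_index(f2b, A, C), pair_index(f2b, B, D))
      bv <- (f2b$bv[, ii[1]] + f2b$bv[, ii[2]] - f2b$bv[, ii[3]] - f2b$bv[, ii[4]]) / 2
      bw <- rowMeans(f2b$bw[, ii, drop = FALSE])
      ok <- is.finite(bv) & bw > 0
      if (sum(ok) < 2) next
      jk <- block_jackknife(bv[ok], bw[ok])
      exp_f4 <- (fitted_f2(A, D) + fitted_f2(B, C) -
                   fitted_f2(A, C) - fitted_f2(B, D)) / 2
      if (jk$se > 0) worst <- max(worst, abs(jk$est - exp_f4) / jk$se)
    }
  }
  worst
}

#' Canonical topology hash of an admixture graph
#'
#' Iterative refinement (Weisfeiler-Lehman style) starting from leaf labels:
#' node signatures are repeatedly rebuilt from the sorted signatures of their
#' parents and children together with edge types, and the hash is the sorted
#' canonical edge list. Invariant under internal-node relabeling.
#'
#' @param graph An [admixture_graph()].
#' @return Character scalar.
#' @export
graph_hash <- function(graph) {
  graph <- simplify_topology(graph)
  ed <- graph$edges
  nodes <- unique(c(ed$child, ed$parent))
  lab <- ifelse(nodes %in% graph$leaves, nodes, "*")
  names(lab) <- nodes
  for (it in seq_len(length(nodes))) {
    new_lab <- vapply(nodes, function(v) {
      up <- ed[ed$child == v, , drop = FALSE]
      dn <- ed[ed$parent == v, , drop = FALSE]
      ups <- sort(paste0(up$type, ":", lab[up$parent]))
      dns <- sort(paste0(dn$type, ":", lab[dn$child]))
      paste0(lab[v], "<", paste(ups, collapse = ","), "|",
             paste(dns, collapse = ","), ">")
    }, character(1))
    # compress to small ids to keep strings bounded
    ids <- match(new_lab, sort(unique(new_lab)))
    pref <- ifelse(nodes %in% graph$leaves, nodes, "i")
    upd <- paste0(pref, ids)
    if (identical(unname(upd), unname(lab))) break
    lab <- setNames(upd, nodes)
  }
  key <- sort(paste0(lab[ed$child], "<-", ed$type, "-", lab[ed$parent]))
  paste(key, collapse = ";")
}

# ---- random graphs and topology moves (tree + admixture-event encoding) ----

random_tree_edges <- function(pops) {
  # sequential random coalescence into a rooted binary tree
  avail <- pops
  edges <- list(); nid <- 0
  while (length(avail) > 1) {
    pick <- sample(length(avail), 2)
    nid <- nid + 1
    anc <- paste0("n", nid)
    edges[[length(edges) + 1]] <- data.frame(child = avail[pick], parent = anc,
                                             type = "drift", value = NA_real_,
                                             stringsAsFactors = FALSE)
    avail <- c(avail[-pick], anc)
  }
  do.call(rbind, edges)
}

drift_row <- function(child, parent) {
  data.frame(child = child, parent = parent, type = "drift", value = NA_real_,
             stringsAsFactors = FALSE)
}

subtree_nodes <- function(edges, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- edges$child[edges$parent %in% frontier]
    frontier <- setdiff(kids, out)
    out <- c(out, frontier)
  }
  out
}

# Expand (tree, events) into a full admixture_graph. Each event taps a source
# on the edge above `src_child` and inserts the admixed node on the edge
# above `dst_child`.
build_graph <- function(tree, events) {
  ed <- tree
  if (length(events)) {
    for (k in seq_along(events)) {
      ev <- events[[k]]
      s_i <- which(ed$child == ev$src & ed$type == "drift")
      d_i <- which(ed$child == ev$dst & ed$type == "drift")
      if (length(s_i) != 1 || length(d_i) != 1) return(NULL)
      sN <- paste0("s", k); mN <- paste0("m", k)
      s_par <- ed$parent[s_i]; d_par <- ed$parent[d_i]
      ed$parent[s_i] <- sN
      ed$parent[d_i] <- mN
      ed <- rbind(ed,
                  data.frame(child = sN, parent = s_par, type = "drift",
                             value = NA_real_, stringsAsFactors = FALSE),
                  data.frame(child = mN, parent = d_par, type = "admix",
                             value = NA_real_, stringsAsFactors = FALSE),
                  data.frame(child = mN, parent = sN, type = "admix",
                             value = NA_real_, stringsAsFactors = FALSE))
    }
  }
  tryCatch(admixture_graph(ed), error = function(e) NULL)
}

random_events <- function(tree, n_admix) {
  if (n_admix == 0) return(list())
  events <- list()
  for (k in seq_len(n_admix)) {
    for (try in 1:50) {
      cand <- tree$child
      dst <- sample(cand, 1)
      forbidden <- subtree_nodes(tree, dst)
      src_ok <- setdiff(cand, forbidden)
      if (!length(src_ok)) next
      src <- if (length(src_ok) == 1) src_ok else sample(src_ok, 1)
      events[[k]] <- list(src = src, dst = dst)
      break
    }
    if (length(events) < k) return(NULL)
  }
  events
}

propose_move <- function(tree, events, pops) {
  kind <- sample(c("swap", "regraft", "admix"), 1,
                 prob = c(0.3, 0.5, if (length(events)) 0.2 else 0))
  if (kind == "swap") {
    pick <- sample(pops, 2)
    t2 <- tree
    t2$child[tree$child == pick[1]] <- pick[2]
    t2$child[tree$child == pick[2]] <- pick[1]
    ev2 <- lapply(events, function(e) {
      e$src <- if (e$src == pick[1]) pick[2] else if (e$src == pick[2]) pick[1] else e$src
      e$dst <- if (e$dst == pick[1]) pick[2] else if (e$dst == pick[2]) pick[1] else e$dst
      e
    })
    return(list(tree = t2, events = ev2))
  }
  if (kind == "regraft") {
    t2 <- regraft_tree(tree)
    if (is.null(t2)) return(NULL)
    ev2 <- lapply(events, function(e) {
      if (!e$src %in% t2$child) e$src <- sample(t2$child, 1)
      if (!e$dst %in% t2$child) e$dst <- sample(t2$child, 1)
      e
    })
    return(list(tree = t2, events = ev2))
  }
  ev2 <- events
  k <- sample(length(events), 1)
  ne <- random_events(tree, 1)
  if (is.null(ne)) return(NULL)
  ev2[[k]] <- ne[[1]]
  list(tree = tree, events = ev2)
}

# Prune-and-regraft. Unary pass-through nodes left behind by pruning are
# harmless for the f2 algebra and are suppressed by the canonical hash.
regraft_tree <- function(tree) {
  e_i <- sample(nrow(tree), 1)
  mov <- tree$child[e_i]
  sub <- subtree_nodes(tree, mov)
  t2 <- tree[-e_i, , drop = FALSE]
  if (!nrow(t2)) return(NULL)
  cand <- which(!(t2$child %in% sub))
  if (!length(cand)) return(NULL)
  pick <- sample(length(cand) + 1, 1)
  newn <- paste0("n", sample.int(1e9, 1))
  if (pick > length(cand)) {
    r2 <- setdiff(t2$parent, t2$child)
    r2 <- setdiff(r2, sub)
    if (length(r2) != 1) return(NULL)
    t2 <- rbind(t2, drift_row(r2, newn), drift_row(mov, newn))
  } else {
    d_i <- cand[pick]
    grand <- t2$parent[d_i]
    t2$parent[d_i] <- newn
    t2 <- rbind(t2, drift_row(newn, grand), drift_row(mov, newn))
  }
  t2
}

# Suppress topology-irrelevant structure before hashing: a root with a single
# drift child, and internal pass-through nodes with one drift parent and one
# drift child (consecutive drift edges are a single branch for f2 purposes).
simplify_topology <- function(graph) {
  ed <- graph$edges
  repeat {
    if (nrow(ed) <= 1) break
    root <- setdiff(ed$parent, ed$child)
    ri <- which(ed$parent == root)
    if (length(ri) == 1 && ed$type[ri] == "drift") { ed <- ed[-ri, , drop = FALSE]; next }
    out_deg <- table(ed$parent)
    in_deg <- table(ed$child)
    changed <- FALSE
    for (v in names(out_deg)[out_deg == 1]) {
      if (v %in% root) next
      pi <- which(ed$child == v); ci <- which(ed$parent == v)
      if (length(pi) == 1 && length(ci) == 1 &&
          ed$type[pi] == "drift" && ed$type[ci] == "drift") {
        ed$parent[ci] <- ed$parent[pi]
        ed$value[ci] <- ed$value[ci] + ed$value[pi]
        ed <- ed[-pi, , drop = FALSE]
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  admixture_graph(ed)
}

#' Randomized admixture-graph topology search
#'
#' Repeated hill climbs: each iteration starts from a random rooted binary
#' tree over the populations with exactly `n_admix` admixture events and
#' applies random topology moves (leaf swap, subtree regraft, admixture
#' relocation), accepting strict score improvements, until `stall`
#' consecutive proposals fail. Final graphs are deduplicated by canonical
#' topology hash, keeping each hash's best score.
#'
#' @param f2b An [f2_blocks()].
#' @param pops Populations (default all in `f2b`).
#' @param n_admix Number of admixture events per graph.
#' @param iterations Independent hill-climb restarts (the study protocol used
#'   100 per admixture count).
#' @param seed Integer seed.
#' @param stall Consecutive failed proposals before a climb stops.
#' @param max_steps Cap on proposals per climb.
#' @return Data frame with columns `hash`, `score`, `worst_residual` and a
#'   list column `graph`, sorted by score.
#' @export
find_graphs <- function(f2b, pops = f2b$pops, n_admix = 0, iterations = 100,
                        seed = 1, stall = 25, max_steps = 200) {
  stop_if_not(iterations >= 1, "iterations must be >= 1")
  with_seed(seed, {
    recs <- list()
    for (it in seq_len(iterations)) {
      tree <- random_tree_edges(pops)
      events <- random_events(tree, n_admix)
      if (is.null(events)) next
      cur <- build_graph(tree, events)
      if (is.null(cur)) next
      cur_fit <- fit_graph(cur, f2b)
      cur_score <- attr(cur_fit, "score")
      fails <- 0; steps <- 0
      while (fails < stall && steps < max_steps) {
        steps <- steps + 1
        prop <- propose_move(tree, events, pops)
        if (is.null(prop)) { fails <- fails + 1; next }
        cand <- build_graph(prop$tree, prop$events)
        if (is.null(cand) || length(cand$leaves) != length(pops) ||
            !setequal(cand$leaves, pops)) { fails <- fails + 1; next }
        cand_fit <- fit_graph(cand, f2b)
        if (attr(cand_fit, "score") < cur_score - 1e-12) {
          tree <- prop$tree; events <- prop$events
          cur_fit <- cand_fit; cur_score <- attr(cand_fit, "score")
          fails <- 0
        } else fails <- fails + 1
      }
      recs[[length(recs) + 1]] <-
        list(hash = graph_hash(cur_fit), score = cur_score,
             worst_residual = attr(cur_fit, "worst_residual"), graph = cur_fit)
    }
    hashes <- vapply(recs, `[[`, character(1), "hash")
    scores <- vapply(recs, `[[`, numeric(1), "score")
    keep <- !logical(length(recs))
    for (h in unique(hashes)) {
      idx <- which(hashes == h)
      keep[idx[-which.min(scores[idx])]] <- FALSE
    }
    recs <- recs[keep]
    out <- data.frame(hash = vapply(recs, `[[`, character(1), "hash"),
                      score = vapply(recs, `[[`, numeric(1), "score"),
                      worst_residual = vapply(recs, `[[`, numeric(1), "worst_residual"),
                      stringsAsFactors = FALSE)
    out$graph <- lapply(recs, `[[`, "graph")
    out[order(out$score), , drop = FALSE]
  })
}

#' Enumerate all rooted binary tree topologies over a label set
#'
#' Recursive leaf insertion; yields 3 labeled topologies for 3 leaves and 15
#' for 4 (the exhaustive oracle for desk-scale searches).
#'
#' @param pops Leaf labels (2 to ~6; growth is (2n-3)!!).
#' @return List of [admixture_graph()] objects.
#' @export
enumerate_tree_graphs <- function(pops) {
  stop_if_not(length(pops) >= 2, "need at least two populations")
  base <- data.frame(child = pops[1:2], parent = "R", type = "drift",
                     value = NA_real_, stringsAsFactors = FALSE)
  trees <- list(base)
  nid <- 0
  for (k in seq_along(pops)[-(1:2)]) {
    nxt <- list()
    for (tr in trees) {
      for (e_i in seq_len(nrow(tr))) {
        nid <- nid + 1
        newn <- paste0("e", nid)
        t2 <- tr
        grand <- t2$parent[e_i]
        t2$parent[e_i] <- newn
        t2 <- rbind(t2,
                    data.frame(child = newn, parent = grand, type = "drift",
                               value = NA_real_, stringsAsFactors = FALSE),
                    data.frame(child = pops[k], parent = newn, type = "drift",
                               value = NA_real_, stringsAsFactors = FALSE))
        nxt[[length(nxt) + 1]] <- t2
      }
      # insertion above the root
      nid <- nid + 1
      newn <- paste0("e", nid)
      root <- setdiff(tr$parent, tr$child)
      t2 <- rbind(tr,
                  data.frame(child = root, parent = newn, type = "drift",
                             value = NA_real_, stringsAsFactors = FALSE),
                  data.frame(child = pops[k], parent = newn, type = "drift",
                             value = NA_real_, stringsAsFactors = FALSE))
      nxt[[length(nxt) + 1]] <- t2
    }
    trees <- nxt
  }
  lapply(trees, admixture_graph)
}

#' Bootstrap/holdout comparison of two graph fits
#'
#' Blocks are split into a fitting half (odd blocks) and an evaluation half
#' (even blocks); both graphs are fitted on the fitting half, and the
#' out-of-sample per-block score difference on the evaluation half is
#' bootstrap-resampled. The two-sided p-value tests whether either graph fits
#' significantly better out of sample.
#'
#' @param graph_a,graph_b [admixture_graph()] objects over the same leaves.
#' @param f2b An [f2_blocks()] with at least 10 blocks.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `p`, `mean_diff` (positive means `graph_a` fits worse),
#'   and the per-block differences.
#' @export
compare_fits <- function(graph_a, graph_b, f2b, n_boot = 500, seed = 1) {
  stop_if_not(setequal(graph_a$leaves, graph_b$leaves), "graphs fit different populations")
  g <- f2b$n_blocks
  stop_if_not(g >= 10, "need at least 10 blocks for holdout comparison")
  fit_idx <- seq(1, g, by = 2); eval_idx <- seq(2, g, by = 2)
  sub <- f2b
  sub$bv <- f2b$bv[fit_idx, , drop = FALSE]
  sub$bw <- f2b$bw[fit_idx, , drop = FALSE]
  sub$n_blocks <- length(fit_idx)
  sub$est <- colSums(sub$bv * sub$bw, na.rm = TRUE) / colSums(sub$bw)
  fa <- fit_graph(graph_a, sub)
  fb <- fit_graph(graph_b, sub)
  prs <- t(combn(sort(graph_a$leaves), 2))
  ki <- vapply(seq_len(nrow(prs)), function(k) pair_index(f2b, prs[k, 1], prs[k, 2]),
               integer(1))
  wts <- 1 / pmax(f2b$se[ki], 1e-9)^2
  ev <- function(gr) vapply(seq_len(nrow(prs)), function(k)
    expected_f2(gr, prs[k, 1], prs[k, 2]), numeric(1))
  ea <- ev(fa); eb <- ev(fb)
  block_score <- function(e) {
    v <- f2b$bv[eval_idx, ki, drop = FALSE]
    sweep(v, 2, e, "-")^2 %*% wts
  }
  d <- drop(block_score(ea) - block_score(eb))
  d <- d[is.finite(d)]
  if (all(abs(d) < 1e-300)) return(list(p = 1, mean_diff = 0, diffs = d))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) mean(sample(d, length(d), replace = TRUE)),
           numeric(1))
  })
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  list(p = max(min(p, 1), 1 / n_boot), mean_diff = mean(d), diffs = d)
}

#' Serialize an admixture graph as an edge-list TSV or DOT
#'
#' @param graph An [admixture_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  write.table(graph$edges, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph
#' @export
write_graph_dot <- function(graph, path) {
  ed <- graph$edges
  lab <- ifelse(ed$type == "drift", sprintf("%.4f", ed$value),
                sprintf("%.2f", ed$value))
  lines <- c("digraph G {",
             sprintf('  "%s" -> "%s" [label="%s"%s];', ed$parent, ed$child, lab,
                     ifelse(ed$type == "admix", ", style=dashed", "")),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  admixture_graph(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
}
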