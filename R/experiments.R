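# Desk-scale simulation studies used to validate every stage of the stack.
# Each experiment generates its own data under a fixed seed, runs the
# estimator under test, and reports calibration/recovery summaries. These are
# the same designs exercised by the test suite and the acceptance script.

#' Clade-null calibration of f4 Z-scores
#'
#' Simulates a star clade of populations below a common ancestor, so every
#' f4(Pa, Pb; Pc, Pd) over distinct members has expectation zero, and
#' measures the fraction of |Z| > 1.96 over many f4 statistics. Statistics
#' are chosen as disjoint quadruples within repeated random partitions of
#' the population set: under the star null, two f4 statistics are correlated
#' only if they share a same-side population pair, so this selection makes
#' the 1000 statistics pairwise uncorrelated and the exceedance rate tightly
#' binomial around its nominal level.
#'
#' @param n_snps,n_blocks,n_stats,n_pops,chroms Design sizes.
#' @param n_datasets Independent clade simulations the statistics are spread
#'   over (magnitudes of Z-scores on one dataset are mildly dependent even
#'   when the scores are uncorrelated, so independent datasets keep the
#'   exceedance rate close to binomial).
#' @param seed Integer seed.
#' @return List with `z` (vector), `rate`, and the design sizes.
#' @export
experiment_clade_null <- function(n_snps = 1e5, n_blocks = 50, n_stats = 1000,
                                  n_pops = 8, chroms = 20, n_datasets = 40,
                                  seed = 1) {
  pops <- sprintf("P%02d", seq_len(n_pops))
  tree <- rbind(
    data.frame(parent = "root", child = "anc", F = 0.02),
    data.frame(parent = "anc", child = pops, F = 0.02))
  model <- demography_model(tree)
  per_round <- n_pops %/% 4
  per_ds <- ceiling(n_stats / n_datasets)
  z <- numeric(0)
  for (d in seq_len(n_datasets)) {
    cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks,
                      seed = seed + 1000 * d)
    freqs <- simulate_frequencies(model, cfg)
    counts <- simulate_counts(freqs[, pops], chroms = chroms,
                              n_blocks = n_blocks, seed = seed + 1000 * d + 1)
    quads <- with_seed(seed + 1000 * d + 2, {
      out <- list()
      while (length(out) < per_ds) {
        perm <- sample(n_pops)
        for (q in seq_len(per_round)) {
          if (length(out) < per_ds) {
            out[[length(out) + 1]] <- perm[(4 * q - 3):(4 * q)]
          }
        }
      }
      out
    })
    p <- counts$x / counts$n
    bl <- counts$block
    cnt <- as.numeric(rowsum(rep(1, nrow(p)), bl))
    num <- vapply(quads, function(q)
      (p[, q[1]] - p[, q[2]]) * (p[, q[3]] - p[, q[4]]), numeric(nrow(p)))
    sums <- rowsum(num, bl)
    z <- c(z, vapply(seq_along(quads), function(c_i) {
      jk <- block_jackknife(sums[, c_i] / cnt, cnt)
      jk$est / jk$se
    }, numeric(1)))
  }
  z <- z[seq_len(n_stats)]
  list(z = z, rate = mean(abs(z) > 1.96), n_snps = n_snps, n_stats = n_stats,
       n_blocks = n_blocks, n_datasets = n_datasets)
}

# Demography used by the qpAdm/qpWave experiments: an outgroup, four
# references interleaved with two sources along a backbone, and (optionally)
# a target admixed between the two sources.
qpadm_study_model <- function(alpha = 0.3, target = TRUE) {
  tree <- rbind(
    data.frame(parent = "root", child = "O", F = 0.08),
    data.frame(parent = "root", child = "x0", F = 0.02),
    data.frame(parent = "x0", child = "R1", F = 0.05),
    data.frame(parent = "x0", child = "x1", F = 0.02),
    data.frame(parent = "x1", child = "R2", F = 0.05),
    data.frame(parent = "x1", child = "x2", F = 0.02),
    data.frame(parent = "x2", child = "S1", F = 0.05),
    data.frame(parent = "x2", child = "x3", F = 0.02),
    data.frame(parent = "x3", child = "R3", F = 0.05),
    data.frame(parent = "x3", child = "x4", F = 0.02),
    data.frame(parent = "x4", child = "S2", F = 0.05),
    data.frame(parent = "x4", child = "R4", F = 0.05))
  adm <- if (target) {
    data.frame(recipient = "T", source_a = "S1", source_b = "S2",
               alpha = alpha, F_residual = 0.01)
  } else NULL
  demography_model(tree, adm)
}

#' qpAdm admixture-proportion recovery
#'
#' Plants a two-source mixture (default alpha = 0.3) in a structured
#' demography and re-estimates the proportion with [qpadm_fit()] across
#' replicates, reporting bias, 95% CI coverage of the truth, and the rate at
#' which the truth falls within 3 jackknife SEs.
#'
#' @param n_reps,n_snps,chroms,n_blocks Design sizes.
#' @param alpha True mixture proportion.
#' @param seed Integer seed.
#' @return List with per-replicate `w`, `se`, `p`, and summaries `mean_w`,
#'   `coverage95`, `within3se`.
#' @export
experiment_qpadm_recovery <- function(n_reps = 200, n_snps = 2e5, alpha = 0.3,
                                      chroms = 20, n_blocks = 50, seed = 1) {
  model <- qpadm_study_model(alpha = alpha)
  w <- se <- pv <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks, seed = seed + 7 * r)
    freqs <- simulate_frequencies(model, cfg)
    counts <- simulate_counts(freqs[, c("O", "R1", "R2", "R3", "R4", "S1", "S2", "T")],
                              chroms = chroms, n_blocks = n_blocks,
                              seed = seed + 7 * r + 3)
    fit <- qpadm_fit(counts, "T", c("S1", "S2"), c("O", "R1", "R2", "R3", "R4"))
    w[r] <- fit$weights["S1"]; se[r] <- fit$se["S1"]; pv[r] <- fit$p
  }
  list(w = w, se = se, p = pv, alpha = alpha,
       mean_w = mean(w),
       coverage95 = mean(abs(w - alpha) <= 1.96 * se),
       within3se = mean(abs(w - alpha) <= 3 * se))
}

#' qpWave rank-0 p-value calibration under the clade null
#'
#' Simulates left populations forming a single stream of ancestry relative
#' to the right set (a true clade), so the rank-0 test holds; collects its
#' p-values across replicates and tests uniformity (Kolmogorov-Smirnov).
#'
#' @param n_reps,n_snps,chroms,n_blocks Design sizes.
#' @param seed Integer seed.
#' @return List with `p` (vector), `ks_p`, `reject_rate05`.
#' @export
experiment_qpwave_null <- function(n_reps = 200, n_snps = 2e4, chroms = 20,
                                   n_blocks = 50, seed = 1) {
  tree <- rbind(
    data.frame(parent = "root", child = "AL", F = 0.03),
    data.frame(parent = "AL", child = c("L1", "L2"), F = 0.03),
    data.frame(parent = "root", child = "AR", F = 0.03),
    data.frame(parent = "AR", child = "R1", F = 0.04),
    data.frame(parent = "AR", child = "ar2", F = 0.02),
    data.frame(parent = "ar2", child = c("R2", "R3"), F = 0.04))
  model <- demography_model(tree)
  pv <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks, seed = seed + 13 * r)
    freqs <- simulate_frequencies(model, cfg)
    counts <- simulate_counts(freqs[, c("L1", "L2", "R1", "R2", "R3")],
                              chroms = chroms, n_blocks = n_blocks,
                              seed = seed + 13 * r + 5)
    fm <- f4_matrix(counts, c("L1", "L2"), c("R1", "R2", "R3"))
    pv[r] <- qpwave_rank_test(fm, 0)$p
  }
  ks <- suppressWarnings(ks.test(pv, "punif"))
  list(p = pv, ks_p = ks$p.value, reject_rate05 = mean(pv < 0.05))
}

#' Admixture-graph topology recovery
#'
#' Per simulation: draws one of the 15 labeled rooted 4-leaf topologies with
#' random drift per edge, simulates counts, fits all 15 topologies and asks
#' whether the generating topology attains the best score (rootings of the
#' same unrooted tree are f2-equivalent and may tie).
#'
#' @param n_sims,n_snps,chroms,n_blocks Design sizes.
#' @param seed Integer seed.
#' @return List with `success` (logical vector), `rate`, and per-sim margin.
#' @export
experiment_graph_recovery <- function(n_sims = 100, n_snps = 5e4, chroms = 20,
                                      n_blocks = 50, seed = 1) {
  pops <- c("A", "B", "C", "D")
  topos <- enumerate_tree_graphs(pops)
  success <- logical(n_sims)
  margin <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    pick <- with_seed(seed + 101 * s, sample(length(topos), 1))
    gtrue <- topos[[pick]]
    ed <- gtrue$edges
    ed$F <- with_seed(seed + 101 * s + 1, runif(nrow(ed), 0.01, 0.06))
    model <- demography_model(ed[, c("parent", "child", "F")])
    cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks, seed = seed + 101 * s + 2)
    freqs <- simulate_frequencies(model, cfg)
    counts <- simulate_counts(freqs[, pops], chroms = chroms,
                              n_blocks = n_blocks, seed = seed + 101 * s + 3)
    f2b <- f2_blocks(counts)
    scores <- vapply(topos, function(tp) attr(fit_graph(tp, f2b), "score"),
                     numeric(1))
    success[s] <- scores[pick] <= min(scores[-pick]) * (1 + 1e-6) + 1e-9
    margin[s] <- min(scores[-pick]) - scores[pick]
  }
  list(success = success, rate = mean(success), margin = margin)
}

#' Exhaustive versus randomized 3-population graph search
#'
#' With three populations and no admixture there are exactly 3 labeled
#' rooted topologies; [find_graphs()] must reach the same best score as
#' exhaustive enumeration, and the generating topology must win.
#'
#' @param n_snps,chroms,n_blocks Design sizes.
#' @param iterations Hill-climb restarts.
#' @param seed Integer seed.
#' @return List with `match` (best scores agree), `truth_wins`, both score
#'   tables.
#' @export
experiment_find_graphs_check <- function(n_snps = 5e4, chroms = 20,
                                         n_blocks = 50, iterations = 15,
                                         seed = 1) {
  pops <- c("A", "B", "C")
  tree <- rbind(
    data.frame(parent = "root", child = "A", F = 0.04),
    data.frame(parent = "root", child = "ab", F = 0.03),
    data.frame(parent = "ab", child = c("B", "C"), F = 0.03))
  model <- demography_model(tree)
  cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks, seed = seed)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, pops], chroms = chroms,
                            n_blocks = n_blocks, seed = seed + 1)
  f2b <- f2_blocks(counts)
  topos <- enumerate_tree_graphs(pops)
  ex_scores <- vapply(topos, function(tp) attr(fit_graph(tp, f2b), "score"),
                      numeric(1))
  ex_hashes <- vapply(topos, graph_hash, character(1))
  fg <- find_graphs(f2b, pops = pops, n_admix = 0, iterations = iterations,
                    seed = seed + 2)
  truth_hash <- graph_hash(build_graph(tree[, c("child", "parent")] |>
                                         transform(type = "drift", value = NA_real_),
                                       list()))
  tol <- function(s) 1e-6 * max(s, 1e-12) + 1e-9
  best <- min(ex_scores)
  # root placement is not identifiable from f2, so equivalent rootings tie;
  # the truth "wins" when its score is at the optimum
  list(match = abs(min(fg$score) - best) <= tol(best),
       truth_wins = ex_scores[ex_hashes == truth_hash] <= best + tol(best) &&
         any(fg$hash == truth_hash & fg$score <= best + tol(best)),
       exhaustive = data.frame(hash = ex_hashes, score = ex_scores),
       found = fg[, c("hash", "score", "worst_residual")])
}

#' Pseudo-haploid caller error-bound experiment
#'
#' Simulates pileups with strong terminal C-to-T damage and low central
#' error, estimates the stratified error table from monomorphic sites, calls
#' genotypes at the 0.02 threshold and measures the achieved per-call error
#' at truth-homozygous sites (which the threshold must bound from above).
#'
#' @param n_sites Polymorphic sites to call.
#' @param n_mono Monomorphic sites for error estimation.
#' @param mean_depth Poisson read depth.
#' @param seed Integer seed.
#' @return List with `error_rate`, `n_calls`, `binom_p` (test of rate <=
#'   0.02), `threshold`, `deterministic` (same seed reproduces calls).
#' @export
experiment_caller <- function(n_sites = 1e5, n_mono = 6e4, mean_depth = 3,
                              seed = 1) {
  profile <- rbind(
    data.frame(library_type = "ds_UDG", pos_class = "terminal_5",
               from = "C", to = "T", rate = 0.30),
    data.frame(library_type = "ds_UDG", pos_class = "terminal_3",
               from = "C", to = "T", rate = 0.30),
    data.frame(library_type = "ds_UDG", pos_class = "central",
               from = "C", to = "T", rate = 0.004),
    data.frame(library_type = "ds_UDG", pos_class = "terminal_5",
               from = "T", to = "C", rate = 0.004),
    data.frame(library_type = "ds_UDG", pos_class = "terminal_3",
               from = "T", to = "C", rate = 0.004),
    data.frame(library_type = "ds_UDG", pos_class = "central",
               from = "T", to = "C", rate = 0.004))
  # monomorphic reference panel: half fixed C, half fixed T
  snp_m <- data.frame(id = sprintf("m%d", 1:n_mono), chrom = "20",
                      gpos = NA_real_, ppos = seq_len(n_mono), ref = "C", alt = "T",
                      stringsAsFactors = FALSE)
  calls_m <- matrix(rep(c(0L, 1L), length.out = n_mono), n_mono, 1)
  gm_m <- genotype_matrix(calls_m, snp_m,
                          data.frame(id = "mono1", ploidy = 1L))
  pu_m <- simulate_pileups(gm_m, mean_depth = 4, error_profile = profile,
                           seed = seed + 1)
  etab <- estimate_error_rates(pu_m)
  # polymorphic C/T sites with known diploid truth
  p <- with_seed(seed + 2, runif(n_sites, 0.05, 0.95))
  truth <- with_seed(seed + 3, rbinom(n_sites, 2L, p))
  snp <- data.frame(id = sprintf("s%d", 1:n_sites), chrom = "1",
                    gpos = NA_real_, ppos = seq_len(n_sites), ref = "C", alt = "T",
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(as.integer(truth), n_sites, 1), snp,
                        data.frame(id = "study1", ploidy = 2L))
  pu <- simulate_pileups(gm, mean_depth = mean_depth, error_profile = profile,
                         seed = seed + 4)
  calls <- call_pseudohaploid(pu, etab, threshold = 0.02, seed = seed + 5)
  calls2 <- call_pseudohaploid(pu, etab, threshold = 0.02, seed = seed + 5)
  row <- match(calls$pos, snp$ppos)
  hom <- truth[row] %in% c(0L, 2L) & !is.na(calls$call)
  exp_base <- ifelse(truth[row] == 2L, "T", "C")
  err <- calls$call[hom] != exp_base[hom]
  bt <- binom.test(sum(err), length(err), p = 0.02, alternative = "less")
  list(error_rate = mean(err), n_calls = length(err), binom_p = bt$p.value,
       threshold = 0.02, missing_rate = mean(is.na(calls$call)),
       deterministic = identical(calls$call, calls2$call))
}

#' Kinship pairwise-mismatch-rate ladder
#'
#' Simulates identical, 1st, 2nd degree and unrelated pairs and checks that
#' mean mismatch-rate ratios track 0.5 / 0.75 / 0.875 / 1.0 of the unrelated
#' baseline, and that 1st-degree pairs classify correctly.
#'
#' @param n_sites Overlapping sites per pair.
#' @param n_pairs Pairs per degree class.
#' @param seed Integer seed.
#' @return List with `ratios` (mean per class), `se_ratio`, `expected`,
#'   `first_degree_accuracy`, `baseline`.
#' @export
experiment_kinship <- function(n_sites = 5e4, n_pairs = 30, seed = 1) {
  p <- with_seed(seed, runif(n_sites, 0.05, 0.95))
  degrees <- list(identical = 0, first = 1, second = 2, unrelated = Inf)
  rates <- list()
  for (di in seq_along(degrees)) {
    rates[[names(degrees)[di]]] <- vapply(seq_len(n_pairs), function(k) {
      pr <- simulate_relative_pair(p, degrees[[di]], seed = seed + 1000 * k + 31 * di)
      mean(pr$a != pr$b)
    }, numeric(1))
  }
  b <- mean(rates$unrelated)
  ratios <- vapply(rates, mean, numeric(1)) / b
  se_ratio <- vapply(rates, function(r) sd(r) / sqrt(length(r)), numeric(1)) / b
  cls <- vapply(rates$first, function(r)
    classify_degree(r, b, se = sqrt(r * (1 - r) / n_sites))$degree, character(1))
  list(ratios = ratios, se_ratio = se_ratio,
       expected = c(identical = 0.5, first = 0.75, second = 0.875, unrelated = 1),
       first_degree_accuracy = mean(cls == "first"),
       baseline = b)
}

#' ROH effective-size recovery
#'
#' Simulates ROH sets under a known constant Ne and re-estimates it with
#' [ne_mle()], reporting relative error of the mean point estimate and 95%
#' CI coverage across replicates.
#'
#' @param n_reps Replicates.
#' @param ne True effective size.
#' @param n_individuals Individuals per replicate.
#' @param seed Integer seed.
#' @return List with `ne_hat` (vector), `mean_ne`, `rel_err`, `coverage`.
#' @export
experiment_roh_recovery <- function(n_reps = 100, ne = 500, n_individuals = 40,
                                    seed = 1) {
  ne_hat <- numeric(n_reps); covered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    rs <- simulate_roh(ne, n_individuals = n_individuals, seed = seed + 17 * r)
    est <- ne_mle(rs)
    ne_hat[r] <- est$ne
    covered[r] <- est$ci[1] <= ne && ne <= est$ci[2]
  }
  list(ne_hat = ne_hat, mean_ne = mean(ne_hat),
       rel_err = abs(mean(ne_hat) - ne) / ne, coverage = mean(covered),
       true_ne = ne)
}

#' Neighbor-joining and MDS exactness
#'
#' NJ: 100 random binary trees (up to `max_leaves` leaves) are converted to
#' additive distance matrices; exact topology and branch-length recovery is
#' required. MDS: distances of planted 2-D point sets must be reproduced to
#' 1e-9.
#'
#' @param n_trees Number of random trees.
#' @param max_leaves Maximum leaf count.
#' @param seed Integer seed.
#' @return List with `nj_rate`, `nj_len_err`, `mds_max_err`.
#' @export
experiment_nj_mds <- function(n_trees = 100, max_leaves = 12, seed = 1) {
  ok <- logical(n_trees); lerr <- numeric(n_trees)
  with_seed(seed, {
    for (i in seq_len(n_trees)) {
      nl <- sample(4:max_leaves, 1)
      tr <- ape::rtree(nl, br = function(n) runif(n, 0.1, 1))
      D <- as.matrix(ape::cophenetic.phylo(tr))
      nj <- neighbor_joining(D)
      ok[i] <- ape::dist.topo(ape::unroot(tr), ape::unroot(nj)) == 0
      D2 <- as.matrix(ape::cophenetic.phylo(nj))[rownames(D), colnames(D)]
      lerr[i] <- max(abs(D2 - D))
    }
  })
  pts <- with_seed(seed + 1, matrix(rnorm(20), 10, 2))
  D <- as.matrix(dist(pts))
  md <- classical_mds(D, k = 2)
  Dr <- as.matrix(dist(md$points))
  list(nj_rate = mean(ok & lerr < 1e-8), nj_len_err = max(lerr),
       mds_max_err = max(abs(Dr - D)))
}
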