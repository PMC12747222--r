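# Shared in-code fixtures: everything is generated at test time.

# Exact population frequencies wrapped as a count_table (n = 1, corrections
# disabled by callers) for algebraic-identity tests.
exact_freq_counts <- function(n_snps = 500, n_pops = 5, n_blocks = 10, seed = 42) {
  pops <- LETTERS[seq_len(n_pops)]
  p <- withr::with_seed(seed, matrix(runif(n_snps * n_pops, 0.05, 0.95),
                                     n_snps, n_pops, dimnames = list(NULL, pops)))
  count_table(p, matrix(1, n_snps, n_pops, dimnames = dimnames(p)),
              block = rep(seq_len(n_blocks), each = n_snps / n_blocks))
}

# Tiny hand-written EIGENSTRAT trio on disk; returns the prefix.
# Individual 1 is pseudo-haploid (codes 0/2/9), individual 2 diploid.
write_toy_eigenstrat <- function(dir) {
  prefix <- file.path(dir, "toy")
  writeLines(c("09", "21", "20"), paste0(prefix, ".geno"))
  writeLines(c("rs1\t1\t0.0001\t100\tA\tG",
               "rs2\t1\t0.0002\t200\tC\tT",
               "rs3\t2\t0.0001\t150\tG\tA"), paste0(prefix, ".snp"))
  writeLines(c("ind1\tM\tPop1", "ind2\tF\tPop2"), paste0(prefix, ".ind"))
  prefix
}

# Two-population Balding-Nichols counts for estimator tests.
two_pop_counts <- function(F = 0.05, n_snps = 2e4, chroms = 20, n_blocks = 50,
                           seed = 7) {
  tree <- rbind(data.frame(parent = "root", child = "A", F = F),
                data.frame(parent = "root", child = "B", F = F))
  model <- demography_model(tree)
  cfg <- sim_config(n_snps = n_snps, n_blocks = n_blocks, seed = seed)
  freqs <- simulate_frequencies(model, cfg)
  simulate_counts(freqs[, c("A", "B")], chroms = chroms, n_blocks = n_blocks,
                  seed = seed + 1)
}

# Exact Balding-Nichols moment oracle for f2 between leaves of a drift tree:
# increments along the path are uncorrelated, each edge contributing
# F_e * E[p(1-p) at its parent], and E[p(1-p)] shrinks by (1-F) per edge
# below the Uniform(0.05, 0.95) ancestral heterozygosity.
expected_f2_tree_F <- function(ed, a, b) {
  m0 <- integrate(function(p) p * (1 - p) / 0.9, 0.05, 0.95)$value
  parent_of <- setNames(ed$parent, ed$child)
  f_of <- setNames(ed$F, ed$child)
  path_up <- function(x) {
    out <- character(0)
    while (x %in% names(parent_of)) { out <- c(out, x); x <- parent_of[[x]] }
    out
  }
  het_at <- function(node) {
    m0 * prod(1 - f_of[path_up(node)])
  }
  pa <- path_up(a); pb <- path_up(b)
  shared <- intersect(pa, pb)
  edges <- setdiff(c(pa, pb), shared)
  sum(vapply(edges, function(e) f_of[[e]] * het_at(parent_of[[e]]), numeric(1)))
}
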