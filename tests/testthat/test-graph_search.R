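toy_admix_graph <- function(gamma = 0.5, p = 0.03, q = 0.04, x = 0.02, z = 0.01) {
  admixture_graph(rbind(
    data.frame(child = "P", parent = "root", type = "drift", value = p),
    data.frame(child = "Q", parent = "root", type = "drift", value = q),
    data.frame(child = "X", parent = "P", type = "drift", value = x),
    data.frame(child = "M", parent = "P", type = "admix", value = gamma),
    data.frame(child = "M", parent = "Q", type = "admix", value = 1 - gamma),
    data.frame(child = "Z", parent = "M", type = "drift", value = z)))
}

test_that("expected f2 follows path-overlap algebra", {
  # two leaves joined at the root: f2 = a + b
  g <- admixture_graph(rbind(
    data.frame(child = "A", parent = "root", type = "drift", value = 0.02),
    data.frame(child = "B", parent = "root", type = "drift", value = 0.05)))
  expect_equal(expected_f2(g, "A", "B"), 0.07)
  g0 <- g; g0$edges$value <- 0
  expect_equal(expected_f2(g0, "A", "B"), 0)
  # 50:50 admixed leaf, hand-derived closed form:
  # E f2(X, Z) = x + z + gamma*(1-gamma)*(p + q) + (1-gamma)*(p + q) ... via
  # path pairs: 0.5*(x+z) + 0.5*(p+q+x+z) at gamma = 0.5
  tg <- toy_admix_graph(0.5)
  expect_equal(expected_f2(tg, "X", "Z"),
               0.5 * (0.02 + 0.01) + 0.5 * (0.03 + 0.04 + 0.02 + 0.01))
  # general gamma: paths through P share the P edge with X
  tg2 <- toy_admix_graph(0.3)
  expect_equal(expected_f2(tg2, "X", "Z"),
               0.3 * (0.02 + 0.01) + 0.7 * (0.03 + 0.04 + 0.02 + 0.01))
})

test_that("fitting the generating topology on exact expected f2 scores zero", {
  topos <- enumerate_tree_graphs(c("A", "B", "C", "D"))
  expect_length(topos, 15L)
  gtrue <- topos[[4]]
  gtrue$edges$value <- withr::with_seed(3, runif(nrow(gtrue$edges), 0.01, 0.06))
  prs <- t(combn(c("A", "B", "C", "D"), 2))
  exact <- vapply(seq_len(nrow(prs)), function(k)
    expected_f2(gtrue, prs[k, 1], prs[k, 2]), numeric(1))
  f2b <- structure(list(pairs = prs, bv = rbind(exact, exact), bw = matrix(1, 2, 6),
                        est = exact, se = rep(1e-4, 6), pops = c("A", "B", "C", "D"),
                        n_blocks = 2), class = "f2_blocks")
  fit <- fit_graph(gtrue, f2b)
  expect_lt(attr(fit, "score"), 1e-10)
  # fitted lengths reproduce the expected f2 basis
  ff <- attr(fit, "fitted")
  expect_equal(ff$fitted, ff$observed, tolerance = 1e-6)
})

test_that("topology hashes are invariant to relabeling and separate topologies", {
  topos <- enumerate_tree_graphs(c("A", "B", "C", "D"))
  hashes <- vapply(topos, graph_hash, character(1))
  expect_equal(length(unique(hashes)), 15L)
  # renaming internal nodes leaves the hash unchanged
  g <- topos[[7]]
  ed <- g$edges
  internal <- setdiff(unique(c(ed$child, ed$parent)), g$leaves)
  map <- setNames(paste0("zz", seq_along(internal)), internal)
  ed$child <- ifelse(ed$child %in% internal, map[ed$child], ed$child)
  ed$parent <- ifelse(ed$parent %in% internal, map[ed$parent], ed$parent)
  expect_equal(graph_hash(admixture_graph(ed)), hashes[7])
  # unary pass-through nodes do not change the hash
  ed2 <- g$edges
  ed2$parent[ed2$child == "A"] <- "mid"
  ed2 <- rbind(ed2, data.frame(child = "mid",
                               parent = g$edges$parent[g$edges$child == "A"],
                               type = "drift", value = NA_real_))
  expect_equal(graph_hash(admixture_graph(ed2)), hashes[7])
  # admixture changes the hash
  expect_false(graph_hash(toy_admix_graph()) %in% hashes)
})

test_that("graph fitting separates unrooted topology classes on simulated data", {
  pops <- c("A", "B", "C", "D")
  topos <- enumerate_tree_graphs(pops)
  gtrue <- topos[[1]]
  ed <- gtrue$edges; ed$F <- c(0.03, 0.03, 0.04, 0.05, 0.03, 0.04)
  model <- demography_model(ed[, c("parent", "child", "F")])
  cfg <- sim_config(n_snps = 2e4, n_blocks = 50, seed = 9)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, pops], chroms = 20, n_blocks = 50, seed = 10)
  f2b <- f2_blocks(counts)
  scores <- vapply(topos, function(tp) attr(fit_graph(tp, f2b), "score"), numeric(1))
  hashes <- vapply(topos, graph_hash, character(1))
  # the generating topology is at the optimum; wrong unrooted classes are far worse
  expect_lte(scores[1], min(scores[-1]) * (1 + 1e-6) + 1e-9)
  expect_gt(sort(unique(round(scores, 6)))[2] / max(scores[1], 1e-6), 10)
  # fitted worst residual of the truth is unremarkable
  expect_lt(attr(fit_graph(gtrue, f2b), "worst_residual"), 4)
})

test_that("length recovery on the generating 4-leaf topology is accurate", {
  pops <- c("A", "B", "C", "D")
  topos <- enumerate_tree_graphs(pops)
  gtrue <- topos[[2]]
  ed <- gtrue$edges; ed$F <- c(0.05, 0.04, 0.05, 0.03, 0.05, 0.04)
  model <- demography_model(ed[, c("parent", "child", "F")])
  cfg <- sim_config(n_snps = 2e5, n_blocks = 50, seed = 19)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, pops], chroms = 30, n_blocks = 50, seed = 20)
  fit <- fit_graph(gtrue, f2_blocks(counts))
  # pairwise expected f2 distances recovered within 10%
  prs <- t(combn(pops, 2))
  for (k in seq_len(nrow(prs))) {
    truth <- expected_f2_tree_F(ed, prs[k, 1], prs[k, 2])
    expect_lt(abs(expected_f2(fit, prs[k, 1], prs[k, 2]) - truth) / truth, 0.10)
  }
})

test_that("compare_fits returns p = 1 against itself and separates bad graphs", {
  pops <- c("A", "B", "C", "D")
  topos <- enumerate_tree_graphs(pops)
  gtrue <- topos[[1]]
  ed <- gtrue$edges; ed$F <- c(0.03, 0.03, 0.05, 0.05, 0.03, 0.04)
  model <- demography_model(ed[, c("parent", "child", "F")])
  cfg <- sim_config(n_snps = 4e4, n_blocks = 50, seed = 29)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, pops], chroms = 20, n_blocks = 50, seed = 30)
  f2b <- f2_blocks(counts)
  self <- compare_fits(gtrue, gtrue, f2b, n_boot = 200, seed = 1)
  expect_equal(self$p, 1)
  # a wrong unrooted class loses decisively
  wrong <- topos[[which(vapply(topos, function(tp)
    attr(fit_graph(tp, f2b), "score"), numeric(1)) > 100)[1]]]
  cmp <- compare_fits(gtrue, wrong, f2b, n_boot = 200, seed = 2)
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$mean_diff, 0)
  few <- f2b; few$bv <- f2b$bv[1:4, ]; few$bw <- f2b$bw[1:4, ]; few$n_blocks <- 4
  expect_error(compare_fits(gtrue, gtrue, few, seed = 1), "at least 10 blocks")
})

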