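test_that("frequency simulation honors degenerate drift and mixture settings", {
  tree <- rbind(data.frame(parent = "root", child = c("A", "B"), F = 0))
  adm <- data.frame(recipient = "M", source_a = "A", source_b = "B",
                    alpha = 1, F_residual = 0)
  model <- demography_model(tree, adm)
  cfg <- sim_config(n_snps = 1000, n_blocks = 10, seed = 3)
  freqs <- simulate_frequencies(model, cfg)
  # zero drift: all populations share the ancestral frequencies exactly
  expect_equal(freqs[, "A"], freqs[, "root"])
  expect_equal(freqs[, "B"], freqs[, "root"])
  # alpha = 1: recipient equals source_a exactly
  expect_equal(freqs[, "M"], unname(freqs[, "A"]), ignore_attr = TRUE)
  # invalid drift rejected
  expect_error(demography_model(rbind(data.frame(parent = "r", child = "A", F = 1))),
               "\\[0, 1\\)")
  # determinism under the seed
  expect_identical(freqs, simulate_frequencies(model, cfg))
})

test_that("two-population drift reproduces the Fst moment oracle", {
  counts <- two_pop_counts(F = 0.05, n_snps = 1e5, seed = 21)
  fst <- hudson_fst(counts, "A", "B")
  num <- integrate(function(p) 2 * 0.05 * p * (1 - p) / 0.9, 0.05, 0.95)$value
  den <- integrate(function(p) 2 * p * (1 - p) / 0.9, 0.05, 0.95)$value
  expect_lt(abs(fst$estimate - num / den) / (num / den), 0.10)
})

test_that("genotype sampling matches binomial expectations", {
  cfg <- sim_config(n_snps = 1e4, samples_per_pop = 20, n_blocks = 10, seed = 5)
  p <- withr::with_seed(9, runif(1e4, 0.05, 0.95))
  freqs <- matrix(p, ncol = 1, dimnames = list(NULL, "P"))
  sim <- simulate_genotypes(freqs, cfg)
  phat <- rowMeans(sim$gm$calls)
  mse <- mean((phat - p)^2)
  oracle <- mean(p * (1 - p)) / 20
  expect_lt(abs(mse - oracle) / oracle, 0.20)
  # all-missing and fixed-ancestral degenerate settings
  cfg1 <- sim_config(n_snps = 100, samples_per_pop = 3, missing_rate = 1,
                     n_blocks = 5, seed = 6)
  expect_true(all(is.na(simulate_genotypes(freqs[1:100, , drop = FALSE], cfg1)$gm$calls)))
  cfg0 <- sim_config(n_snps = 100, samples_per_pop = 3, n_blocks = 5, seed = 7)
  zero <- matrix(0, 100, 1, dimnames = list(NULL, "P"))
  expect_true(all(simulate_genotypes(zero, cfg0)$gm$calls == 0L))
})

test_that("pileup simulation respects error profile, depth and determinism", {
  snp <- data.frame(id = sprintf("s%d", 1:2000), chrom = "1", gpos = NA_real_,
                    ppos = 1:2000, ref = "C", alt = "T")
  gm <- genotype_matrix(matrix(0L, 2000, 1), snp, data.frame(id = "i1", ploidy = 1L))
  # no errors: every base equals the true allele
  pu0 <- simulate_pileups(gm, mean_depth = 3, seed = 1)
  expect_true(all(pu0$base == pu0$true_base))
  # planted terminal C->T at 0.3 lands within a binomial CI
  prof <- data.frame(library_type = "ds_UDG", pos_class = "terminal_5",
                     from = "C", to = "T", rate = 0.3)
  pu <- simulate_pileups(gm, mean_depth = 10, error_profile = prof, seed = 2)
  term <- pu[pu$pos_class == "terminal_5", ]
  rate <- mean(term$base == "T")
  ci <- binom.test(sum(term$base == "T"), nrow(term))$conf.int
  expect_true(0.3 >= ci[1] && 0.3 <= ci[2])
  expect_true(all(pu$base[pu$pos_class == "central"] == "C"))
  # zero depth yields an empty pileup
  expect_equal(nrow(simulate_pileups(gm, mean_depth = 0, seed = 3, fixed_depth = TRUE)), 0L)
  expect_identical(simulate_pileups(gm, mean_depth = 3, seed = 4),
                   simulate_pileups(gm, mean_depth = 3, seed = 4))
})

test_that("ROH simulation limit cases behave", {
  # enormous Ne: essentially no segments above 4 cM
  rs <- simulate_roh(1e7, n_individuals = 40, seed = 8)
  expect_lt(nrow(rs$segments), 5)
  # a single 0.05 Morgan chromosome cannot yield a segment above 5 cM
  rs2 <- simulate_roh(200, map_lengths = 0.05, n_individuals = 20, seed = 9)
  expect_true(all(rs2$segments$length_cM <= 5 + 1e-9))
  expect_true(all(rs2$segments$length_cM >= 4))
  # smaller Ne gives stochastically more ROH
  n_by_ne <- vapply(c(200, 800, 3200), function(ne)
    nrow(simulate_roh(ne, n_individuals = 10, seed = 10)$segments), numeric(1))
  expect_true(all(diff(n_by_ne) < 0))
})

test_that("relative pairs reproduce the PMR ladder expectations", {
  p <- withr::with_seed(11, runif(4e4, 0.05, 0.95))
  b_oracle <- mean(2 * p * (1 - p))
  pmr <- function(d, s) {
    pr <- simulate_relative_pair(p, d, seed = s)
    mean(pr$a != pr$b)
  }
  unrel <- vapply(1:8, function(s) pmr(Inf, s), numeric(1))
  ident <- vapply(1:8, function(s) pmr(0, 100 + s), numeric(1))
  first <- vapply(1:8, function(s) pmr(1, 200 + s), numeric(1))
  tol <- 4 * sqrt(b_oracle / 4e4)  # ~4 binomial SDs on a single pair
  expect_lt(abs(mean(unrel) - b_oracle), tol)
  expect_lt(abs(mean(ident) - b_oracle / 2), tol)
  expect_lt(abs(mean(first) - 0.75 * b_oracle), tol)
})
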