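test_that("f-statistics satisfy exact algebraic identities on frequencies", {
  ct <- exact_freq_counts()
  f2v <- function(a, b) f2_stat(ct, a, b, correction = FALSE)$estimate
  f3v <- function(a, b, c) f3_stat(ct, a, b, c, correction = FALSE)$estimate
  f4v <- function(a, b, c, d) f4_stat(ct, a, b, c, d)$estimate

  expect_equal(f2v("A", "A"), 0)
  expect_equal(f4v("A", "B", "C", "C"), 0)
  expect_equal(f4v("A", "B", "B", "B"), 0)
  # antisymmetry and pair swap
  expect_lt(abs(f4v("A", "B", "C", "D") + f4v("A", "B", "D", "C")), 1e-12)
  expect_lt(abs(f4v("A", "B", "C", "D") - f4v("C", "D", "A", "B")), 1e-12)
  # additivity in the second pair
  expect_lt(abs(f4v("A", "B", "C", "E") -
                  (f4v("A", "B", "C", "D") + f4v("A", "B", "D", "E"))), 1e-12)
  # f3 decomposition into f2 and the f3(A;B,B) identity
  expect_lt(abs(f3v("A", "B", "C") -
                  (f2v("A", "B") + f2v("A", "C") - f2v("B", "C")) / 2), 1e-12)
  expect_lt(abs(f3v("A", "B", "B") - f2v("A", "B")), 1e-12)
})

test_that("f2 matches a hand-computed toy and nulls out on resampled data", {
  x <- rbind(c(3, 1), c(5, 2), c(2, 4), c(0, 1), c(4, 5))
  n <- rbind(c(10, 8), c(10, 8), c(10, 8), c(10, 8), c(10, 8))
  ct <- count_table(x, n, block = c(1, 1, 1, 2, 2))
  colnames(ct$x) <- colnames(ct$n) <- c("A", "B")
  ct$groups <- c("A", "B")
  pa <- x[, 1] / 10; pb <- x[, 2] / 8
  d <- (pa - pb)^2 - pa * (1 - pa) / 9 - pb * (1 - pb) / 7
  expected <- sum(d) / 5  # SNP-weighted mean over blocks = overall mean
  expect_equal(f2_stat(ct, "A", "B")$estimate, expected, tolerance = 1e-12)

  # two samples of one population: bias-corrected f2 is centred on zero
  z <- vapply(1:40, function(r) {
    p <- withr::with_seed(r, runif(5000, 0.05, 0.95))
    x1 <- withr::with_seed(100 + r, rbinom(5000, 10, p))
    x2 <- withr::with_seed(200 + r, rbinom(5000, 10, p))
    ctr <- count_table(cbind(A = x1, B = x2),
                       matrix(10, 5000, 2, dimnames = list(NULL, c("A", "B"))),
                       block = rep(1:20, each = 250))
    fs <- f2_stat(ctr, "A", "B")
    fs$estimate / fs$se
  }, numeric(1))
  expect_lt(abs(mean(z)), 3 / sqrt(40) * 2 + 0.5)
  expect_true(all(abs(z) < 5))
})

test_that("admixed target yields significantly negative f3", {
  tree <- rbind(data.frame(parent = "root", child = c("B", "C"), F = 0.15))
  adm <- data.frame(recipient = "A", source_a = "B", source_b = "C",
                    alpha = 0.5, F_residual = 0)
  model <- demography_model(tree, adm)
  cfg <- sim_config(n_snps = 2e4, n_blocks = 50, seed = 11)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, c("A", "B", "C")], chroms = 20,
                            n_blocks = 50, seed = 12)
  fs <- f3_stat(counts, "A", "B", "C")
  expect_lt(fs$z, -3)
})

test_that("weighted block jackknife reduces to the classic form and guards input", {
  v <- c(0.2, 0.5, 0.1, 0.9, 0.4)
  jk <- block_jackknife(v, rep(3, 5))
  loo <- vapply(1:5, function(i) mean(v[-i]), numeric(1))
  classic <- sqrt((5 - 1) / 5 * sum((loo - mean(loo))^2))
  expect_equal(jk$se, classic, tolerance = 1e-12)
  expect_equal(jk$est, mean(v))
  expect_equal(block_jackknife(rep(0.3, 4), 1:4)$se, 0)
  expect_error(block_jackknife(1, 1), "at least 2 blocks")
})

test_that("Hudson Fst hits the Balding-Nichols moment oracle and boundary cases", {
  counts <- two_pop_counts(F = 0.05, n_snps = 2e4)
  fst <- hudson_fst(counts, "A", "B")
  # moment oracle by numerical integration over the ancestral law:
  # E num = 2 F p(1-p), E den = 2 p(1-p) under independent BN drift
  num <- integrate(function(p) 2 * 0.05 * p * (1 - p) / 0.9, 0.05, 0.95)$value
  den <- integrate(function(p) 2 * p * (1 - p) / 0.9, 0.05, 0.95)$value
  expect_lt(abs(fst$estimate - num / den) / (num / den), 0.10)

  # two independent samples of one population -> ~0 (identical underlying
  # frequencies); note literally identical tables give -1/(n-1) under the
  # bias correction, so the null is sampling from the same population
  p0 <- withr::with_seed(5, runif(6000, .2, .8))
  x1 <- withr::with_seed(6, rbinom(6000, 10, p0))
  x2 <- withr::with_seed(7, rbinom(6000, 10, p0))
  same <- count_table(cbind(A = x1, B = x2),
                      matrix(10, 6000, 2, dimnames = list(NULL, c("A", "B"))),
                      block = rep(1:10, each = 600))
  same_fst <- hudson_fst(same, "A", "B")
  expect_lt(abs(same_fst$estimate), 0.02)
  expect_lt(abs(same_fst$estimate), 4 * same_fst$se)
  opp <- count_table(cbind(A = rep(0, 6000), B = rep(10, 6000)),
                     matrix(10, 6000, 2, dimnames = list(NULL, c("A", "B"))),
                     block = rep(1:10, each = 600))
  expect_equal(hudson_fst(opp, "A", "B")$estimate, 1)
  expect_error(hudson_fst(counts, "A", "B", min_snps = 1e6), "below the floor")
})

test_that("Benjamini-Yekutieli correction matches the step-up oracle", {
  # m = 1: adjusted equals raw
  z1 <- 1.5
  expect_equal(by_correct(z1)$p_by, 2 * pnorm(-1.5))
  # reference values for p = {0.01, 0.02, 0.5}
  z <- qnorm(1 - c(0.01, 0.02, 0.5) / 2)
  r <- by_correct(z)
  expect_equal(round(r$p_by, 3), c(0.055, 0.055, 0.917))
  # independent reference implementation
  expect_equal(r$p_by, p.adjust(r$p, method = "BY"), tolerance = 1e-12)
  expect_equal(r$significant, r$p_by < 0.05)
  # signed adjusted Z round-trips the adjusted p
  expect_equal(2 * pnorm(-abs(r$z_by)), r$p_by, tolerance = 1e-12)
  expect_equal(sign(r$z_by), sign(r$z))
  expect_equal(nrow(by_correct(numeric(0))), 0L)
})
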