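test_that("f4 matrix entries agree with f4_stat and covariance is PSD", {
  counts <- withr::with_seed(31, {
    p <- matrix(runif(5000 * 6, 0.1, 0.9), 5000, 6,
                dimnames = list(NULL, c("L1", "L2", "L3", "R1", "R2", "R3")))
    simulate_counts(p, chroms = 12, n_blocks = 25, seed = 32)
  })
  fm <- f4_matrix(counts, c("L1", "L2", "L3"), c("R1", "R2", "R3"))
  expect_equal(dim(fm$X), c(2L, 2L))
  for (i in 1:2) for (j in 1:2) {
    fs <- f4_stat(counts, "L1", c("L2", "L3")[i], "R1", c("R2", "R3")[j])
    expect_equal(fm$X[i, j], fs$estimate, tolerance = 1e-12)
  }
  ev <- eigen(fm$Q, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12 * max(abs(ev))))
  # nL = nR = 2 collapses to a single f4 with its jackknife variance
  fm1 <- f4_matrix(counts, c("L1", "L2"), c("R1", "R2"))
  fs1 <- f4_stat(counts, "L1", "L2", "R1", "R2")
  expect_equal(drop(fm1$X), fs1$estimate, tolerance = 1e-12)
  expect_equal(sqrt(drop(fm1$Q)), fs1$se, tolerance = 0.05 * fs1$se)
})

test_that("rank-0 qpWave test has the closed chi-square form on a 1x1 matrix", {
  counts <- two_pop_counts(n_snps = 8000, seed = 41)
  # add two more independent pops for the right side
  p2 <- withr::with_seed(42, matrix(runif(8000 * 2, 0.1, 0.9), 8000, 2,
                             dimnames = list(NULL, c("C", "D"))))
  extra <- simulate_counts(p2, chroms = 20, n_blocks = 50, seed = 43)
  ct <- count_table(cbind(counts$x, extra$x), cbind(counts$n, extra$n),
                    block = counts$block)
  fm <- f4_matrix(ct, c("A", "B"), c("C", "D"))
  rt <- qpwave_rank_test(fm, 0)
  fs <- f4_stat(ct, "A", "B", "C", "D")
  expect_equal(rt$dof, 1L)
  expect_equal(rt$statistic, drop(fm$est^2 / fm$Q), tolerance = 1e-9)
  expect_equal(rt$p, pchisq(rt$statistic, 1, lower.tail = FALSE))
  # jackknife-variance route gives nearly the same standardization
  expect_equal(sqrt(rt$statistic), abs(fs$estimate / fs$se), tolerance = 0.05)
})

test_that("qpAdm on a target identical to a source returns weight (1, 0)", {
  model <- qpadm_study_model(alpha = 0.3)
  cfg <- sim_config(n_snps = 3e4, n_blocks = 50, seed = 51)
  freqs <- simulate_frequencies(model, cfg)
  freqs <- cbind(freqs, T2 = freqs[, "S1"])  # target IS source 1
  counts <- simulate_counts(freqs[, c("O", "R1", "R2", "R3", "R4", "S1", "S2", "T2")],
                            chroms = 40, n_blocks = 50, seed = 52)
  fit <- qpadm_fit(counts, "T2", c("S1", "S2"), c("O", "R1", "R2", "R3", "R4"))
  expect_lt(abs(fit$weights["S1"] - 1), 0.05)
  expect_lt(abs(fit$weights["S2"]), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_gt(fit$p, 0.001)
})

test_that("qpAdm recovers a planted mixture and weights sum to one", {
  model <- qpadm_study_model(alpha = 0.3)
  cfg <- sim_config(n_snps = 5e4, n_blocks = 50, seed = 61)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, c("O", "R1", "R2", "R3", "R4", "S1", "S2", "T")],
                            chroms = 20, n_blocks = 50, seed = 62)
  fit <- qpadm_fit(counts, "T", c("S1", "S2"), c("O", "R1", "R2", "R3", "R4"))
  expect_lt(abs(fit$weights["S1"] - 0.3), 3 * fit$se["S1"])
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(fit$feasible)
})

test_that("model rotation escalates only when single sources fail", {
  model <- qpadm_study_model(alpha = 0.5)
  cfg <- sim_config(n_snps = 4e4, n_blocks = 50, seed = 71)
  freqs <- simulate_frequencies(model, cfg)
  counts <- simulate_counts(freqs[, c("O", "R1", "R2", "R3", "R4", "S1", "S2", "T")],
                            chroms = 20, n_blocks = 50, seed = 72)
  res <- rotate_models(counts, "T", pool = c("S1", "S2", "R2"),
                       fixed_refs = c("O", "R1", "R3", "R4"), max_sources = 2)
  # the true pair passes; every single-source model fails
  expect_false(any(res$pass[res$n_sources == 1]))
  best <- res[res$pass, , drop = FALSE]
  expect_true("S1+S2" %in% best$sources)
  # a pool of one candidate evaluates exactly one model
  res1 <- rotate_models(counts, "T", pool = "S1",
                        fixed_refs = c("O", "R1", "R2", "R3", "R4"))
  expect_equal(nrow(res1), 1L)
})

test_that("inverse-variance meta-analysis matches the closed form and guards input", {
  fits <- list(
    structure(list(weights = c(S = 0.2), se = c(S = 0.1), sources = "S",
                   p = 0.5, feasible = TRUE), class = "qpadm_fit"),
    structure(list(weights = c(S = 0.4), se = c(S = 0.1), sources = "S",
                   p = 0.6, feasible = TRUE), class = "qpadm_fit"))
  mw <- meta_weights(fits, "S")
  expect_equal(mw$estimate, 0.3)
  expect_equal(mw$se, 0.1 / sqrt(2), tolerance = 1e-12)
  # single fit: identity
  expect_equal(meta_weights(fits[1], "S")$estimate, 0.2)
  # zero-variance and infeasible-only inputs are rejected
  bad <- fits
  bad[[1]]$se <- c(S = 0); bad[[2]]$feasible <- FALSE
  expect_error(meta_weights(bad, "S"), "no usable fits")
})
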