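toy_roh <- function() {
  meta <- data.frame(
    individual = c("i1", "i2", "i3", "i4", "i5"),
    group = c("g1", "g1", "g2", "g2", "g2"),
    date_bp = c(1000, 3500, 2000, 1500, 2900),
    covered_snps = c(500000, 450000, 399999, 600000, 410000))
  segments <- data.frame(
    individual = c("i1", "i1", "i2", "i4", "i4", "i5"),
    chrom = "1",
    start_cM = c(0, 50, 10, 0, 60, 5),
    end_cM = c(25, 75, 18, 30, 85, 14),
    length_cM = c(25, 25, 8, 30, 25, 9))
  roh_set(segments, meta)
}

test_that("eligibility filters apply the coverage, date and inbreeding rules", {
  rs <- toy_roh()
  # coverage floor: 399,999 covered SNPs is dropped
  cov_only <- eligibility_filter(rs)
  expect_setequal(cov_only$meta$individual, c("i1", "i2", "i4", "i5"))
  # Ne rules: i2 dropped by date > 3000; i1 has sum(>20) = 50 exactly -> dropped
  # (strict <); i4 has 55 -> dropped; i5 has 0 -> kept
  ne_set <- eligibility_filter(rs, for_ne = TRUE)
  expect_setequal(ne_set$meta$individual, "i5")
  # boundary: exactly 50 cM of long ROH is excluded
  expect_false("i1" %in% ne_set$meta$individual)
})

test_that("Ne MLE flags unbounded estimates and scales with sample size", {
  empty <- roh_set(toy_roh()$segments[0, ],
                   data.frame(individual = "i9", group = "g", date_bp = 100,
                              covered_snps = 5e5))
  est <- ne_mle(empty)
  expect_true(est$unbounded)
  expect_equal(est$ci[2], Inf)
  # doubling individuals shrinks the CI roughly by sqrt(2) (Fisher scaling)
  rs1 <- simulate_roh(500, n_individuals = 30, seed = 41)
  rs2 <- simulate_roh(500, n_individuals = 60, seed = 42)
  w1 <- diff(log(ne_mle(rs1)$ci))
  w2 <- diff(log(ne_mle(rs2)$ci))
  expect_lt(abs(w2 / w1 - 1 / sqrt(2)), 0.25 / sqrt(2))
})

test_that("fractional individual weights scale the likelihood information", {
  rs <- simulate_roh(500, n_individuals = 20, seed = 43)
  half <- rs; half$meta$weight <- 0.5
  full <- ne_mle(rs); halved <- ne_mle(half)
  # same point estimate, wider interval with half the effective sample
  expect_lt(abs(log(halved$ne / full$ne)), 0.02)
  expect_gt(diff(log(halved$ci)), diff(log(full$ci)))
})

test_that("group tests match the rank-statistic oracle on a fixed table", {
  y <- c(10, 12, 14, 9, 30, 35, 32, 28, 11, 13, 33, 31,
         15, 8, 29, 34, 12, 36, 10, 27, 14, 31, 9, 35)
  grp <- rep(c("a", "b", "c"), each = 8)
  meta <- data.frame(individual = sprintf("i%d", 1:24), group = grp,
                     date_bp = 1000, covered_snps = 5e5)
  segments <- data.frame(individual = sprintf("i%d", 1:24), chrom = "1",
                         start_cM = 0, end_cM = 20 + y, length_cM = 20 + y)
  rs <- roh_set(segments, meta)
  res <- roh_group_tests(rs, range_cM = c(20, Inf))
  # omnibus equals the reference Kruskal-Wallis implementation
  ref <- kruskal.test(20 + y, factor(grp))
  expect_equal(unname(res$kruskal$statistic), unname(ref$statistic))
  expect_equal(res$kruskal$p.value, ref$p.value)
  # Conover t for a pair, recomputed from first principles in this test
  N <- 24; k <- 3; r <- rank(20 + y)
  H <- unname(ref$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  sc <- S2 * (N - 1 - H) / (N - k)
  rbar <- tapply(r, grp, mean)
  t_ab <- (rbar["a"] - rbar["b"]) / sqrt(sc * (1 / 8 + 1 / 8))
  row_ab <- res$pairwise[res$pairwise$group1 == "a" & res$pairwise$group2 == "b", ]
  expect_equal(row_ab$t, unname(t_ab), tolerance = 1e-12)
  expect_equal(row_ab$p, 2 * pt(-abs(unname(t_ab)), N - k), tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, p.adjust(res$pairwise$p, "BH"))
  # all-tied data: H = 0, p = 1
  rs0 <- rs; rs0$segments$length_cM <- 25; rs0$segments$end_cM <- 25
  res0 <- roh_group_tests(rs0)
  expect_equal(unname(res0$kruskal$statistic), 0)
  expect_equal(res0$kruskal$p.value, 1)
  # H is invariant under monotone transforms of the response
  rs_t <- rs; rs_t$segments$end_cM <- rs$segments$length_cM^3
  rs_t$segments$length_cM <- rs$segments$length_cM^3
  res_t <- roh_group_tests(rs_t, range_cM = c(20^3, Inf))
  expect_equal(unname(res_t$kruskal$statistic), unname(res$kruskal$statistic))
})

test_that("group tests detect a planted +30 cM shift", {
  detected <- vapply(1:20, function(r) {
    base <- simulate_roh(800, n_individuals = 30, seed = 50 + r)
    meta <- base$meta
    meta$group <- rep(c("g1", "g2", "g3"), each = 10)
    shift <- meta$individual[meta$group == "g3"]
    extra <- data.frame(individual = shift, chrom = "1", start_cM = 0,
                        end_cM = 30, length_cM = 30)
    rs <- roh_set(rbind(base$segments, extra), meta)
    roh_group_tests(rs)$kruskal$p.value < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("temporal regression recovers exact lines and flags degenerate input", {
  meta <- data.frame(individual = sprintf("i%d", 1:6), group = "g",
                     date_bp = c(100, 400, 800, 1200, 1600, 2000),
                     covered_snps = 5e5)
  segments <- data.frame(individual = meta$individual, chrom = "1",
                         start_cM = 0, end_cM = 2 * meta$date_bp / 100 + 5,
                         length_cM = 2 * meta$date_bp / 100 + 5)
  segments$length_cM <- pmin(segments$length_cM, 12)  # keep within 4-12 window
  segments$end_cM <- segments$length_cM
  y <- vapply(split(segments$length_cM, segments$individual)[meta$individual],
              sum, numeric(1))
  fit <- lm(y ~ meta$date_bp)
  res <- roh_time_regression(roh_set(segments, meta))
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-9)
  expect_false(res$flagged)
  # exact line y = 2 x within the window
  m2 <- data.frame(individual = c("a", "b", "c"), group = "g",
                   date_bp = c(2, 3, 4), covered_snps = 5e5)
  s2 <- data.frame(individual = c("a", "b", "c"), chrom = "1", start_cM = 0,
                   end_cM = c(4, 6, 8), length_cM = c(4, 6, 8))
  r2 <- suppressWarnings(roh_time_regression(roh_set(s2, m2), max_date_bp = 10))
  expect_equal(r2$slope, 2, tolerance = 1e-9)
  expect_lt(r2$p, 1e-6)
  # degenerate constant response
  s3 <- s2; s3$length_cM <- 5; s3$end_cM <- 5
  r3 <- roh_time_regression(roh_set(s3, m2), max_date_bp = 10)
  expect_true(r3$flagged)
  expect_equal(r3$p, 1)
  expect_error(roh_time_regression(roh_set(s2[1:2, ], m2[1:2, ]), max_date_bp = 10),
               "at least 3")
})
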