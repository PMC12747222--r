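test_that("read positions classify with the >10 bp rule, nearer end, tie to 5'", {
  expect_equal(classify_position(11, 50), "central")
  expect_equal(classify_position(10, 50), "terminal_5")
  expect_equal(classify_position(50, 3), "terminal_3")
  expect_equal(classify_position(5, 5), "terminal_5")
  expect_equal(classify_position(c(11, 10), c(50, 50)),
               c("central", "terminal_5"))
  expect_error(classify_position(-1, 5), "non-negative")
})

make_mono_pileup <- function(n, seed, rate_terminal_ct = 0) {
  snp <- data.frame(id = sprintf("m%d", 1:n), chrom = "9", gpos = NA_real_,
                    ppos = 1:n, ref = "C", alt = "T")
  gm <- genotype_matrix(matrix(rep(c(0L, 1L), length.out = n), n, 1), snp,
                        data.frame(id = "lib1", ploidy = 1L))
  prof <- if (rate_terminal_ct > 0) {
    data.frame(library_type = "ds_UDG", pos_class = "terminal_5",
               from = "C", to = "T", rate = rate_terminal_ct)
  } else NULL
  simulate_pileups(gm, mean_depth = 4, error_profile = prof, seed = seed)
}

test_that("error rates are estimated per stratum and zero without errors", {
  pu <- make_mono_pileup(4000, seed = 1)
  tab <- estimate_error_rates(pu)
  expect_true(all(tab$rate == 0))
  expect_setequal(unique(tab$from), c("C", "T"))
  # stratification axes are exactly library type, base pair, position,
  # strand, MQ bin, BQ bin
  expect_setequal(setdiff(names(tab), c("rate", "n_obs")),
                  c("library_type", "pos_class", "strand", "mq_bin", "bq_bin",
                    "from", "to"))
  # planted 1% terminal C->T shows up in that cell only
  pu2 <- make_mono_pileup(60000, seed = 2, rate_terminal_ct = 0.01)
  tab2 <- estimate_error_rates(pu2)
  cell <- tab2[tab2$pos_class == "terminal_5" & tab2$from == "C" & tab2$to == "T", ]
  pooled <- sum(cell$rate * cell$n_obs) / sum(cell$n_obs)
  ci <- binom.test(round(pooled * sum(cell$n_obs)), sum(cell$n_obs))$conf.int
  expect_true(0.01 >= ci[1] && 0.01 <= ci[2])
  central <- tab2[tab2$pos_class == "central" & tab2$from == "C" & tab2$to == "T", ]
  expect_true(all(central$rate == 0))
})

test_that("symmetric error is the max of directed rates and propagates NA", {
  tab <- structure(data.frame(library_type = "ds_UDG", pos_class = "central",
                              strand = "+", mq_bin = "mq30+", bq_bin = "bq30+",
                              from = c("C", "T"), to = c("T", "C"),
                              rate = c(0.01, 0.05), n_obs = 1000),
                   class = c("error_table", "data.frame"))
  s <- symmetric_error(tab, "ds_UDG", "central", "+", 37, 35, "C", "T")
  expect_equal(s, 0.05)
  expect_equal(s, symmetric_error(tab, "ds_UDG", "central", "+", 37, 35, "T", "C"))
  # undefined stratum -> NA
  expect_true(is.na(symmetric_error(tab, "ds_UDG", "terminal_5", "+", 37, 35, "C", "T")))
  tab0 <- tab; tab0$rate <- 0
  expect_equal(symmetric_error(tab0, "ds_UDG", "central", "+", 37, 35, "C", "T"), 0)
})

test_that("pseudo-haploid calls honor the reliability threshold and keyed RNG", {
  base_col <- function(bases) {
    data.frame(chrom = "1", pos = 500L, ref = "C", alt = "T", base = bases,
               strand = "+", pos_class = "central", mq = 37L, bq = 35L,
               library_id = "i1", library_type = "ds_UDG",
               stringsAsFactors = FALSE)
  }
  tab_hi <- structure(data.frame(library_type = "ds_UDG", pos_class = "central",
                                 strand = "+", mq_bin = "mq30+", bq_bin = "bq30+",
                                 from = c("C", "T"), to = c("T", "C"),
                                 rate = c(0.5, 0.5), n_obs = 1000),
                      class = c("error_table", "data.frame"))
  # all observations above threshold -> missing call
  out <- call_pseudohaploid(base_col(c("C", "T")), tab_hi, seed = 1)
  expect_true(is.na(out$call))
  expect_equal(out$reliable_depth, 0L)
  # default threshold is 0.02
  expect_equal(formals(call_pseudohaploid)$threshold, 0.02)
  # raising the threshold never shrinks the reliable pileup
  tab_mid <- tab_hi; tab_mid$rate <- 0.05
  lo <- call_pseudohaploid(base_col(c("C", "C", "T")), tab_mid,
                           threshold = 0.02, seed = 1)
  hi <- call_pseudohaploid(base_col(c("C", "C", "T")), tab_mid,
                           threshold = 0.2, seed = 1)
  expect_gte(hi$reliable_depth, lo$reliable_depth)
  # uniform selection: {C, C, T} gives T with frequency ~ 1/3 across seeds
  tab0 <- tab_hi; tab0$rate <- 0
  picks <- vapply(1:4000, function(s)
    call_pseudohaploid(base_col(c("C", "C", "T")), tab0, seed = s)$call,
    character(1))
  ci <- binom.test(sum(picks == "T"), length(picks))$conf.int
  expect_true(1 / 3 >= ci[1] && 1 / 3 <= ci[2])
  # determinism and order independence at fixed seed
  col2 <- rbind(base_col(c("C", "C", "T")),
                transform(base_col(c("T", "C")), pos = 900L))
  a <- call_pseudohaploid(col2, tab0, seed = 7)
  b <- call_pseudohaploid(col2[rev(seq_len(nrow(col2))), ], tab0, seed = 7)
  expect_equal(a$call[order(a$pos)], b$call[order(b$pos)])
  # tri-allelic reads are never eligible
  tri <- call_pseudohaploid(base_col(c("G", "G")), tab0, seed = 1)
  expect_true(is.na(tri$call))
})

test_that("damage QC applies the 3%/10% thresholds by UDG treatment", {
  expect_true(damage_qc(0.00, udg_treated = TRUE))    # flagged
  expect_false(damage_qc(0.05, udg_treated = TRUE))   # passes the 3% rule
  expect_true(damage_qc(0.05, udg_treated = FALSE))   # fails the 10% rule
  expect_false(damage_qc(0.12, udg_treated = FALSE))
  expect_equal(damage_qc(c(0.02, 0.2), c(TRUE, TRUE)), c(TRUE, FALSE))
})

test_that("error tables and pileups round-trip through TSV", {
  dir <- withr::local_tempdir()
  pu <- make_mono_pileup(500, seed = 3)
  write_pileup(pu, file.path(dir, "p.tsv"))
  expect_equal(read_pileup(file.path(dir, "p.tsv"))$base, pu$base)
  tab <- estimate_error_rates(pu)
  write_error_table(tab, file.path(dir, "e.tsv"))
  tab2 <- read_error_table(file.path(dir, "e.tsv"))
  expect_equal(tab2$rate, tab$rate)
})
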