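#' Weighted delete-one block jackknife
#'
#' Combines per-block values of a statistic into an estimate and a standard
#' error using the weighted jackknife for unequal block sizes (Busing-style
#' pseudovalues). With equal weights this reduces to the classic delete-one
#' jackknife.
#'
#' @param values Per-block statistic values.
#' @param weights Positive per-block weights (typically SNP counts).
#' @return List with `est` (full-data weighted estimate), `se`, `jk_est`
#'   (bias-corrected jackknife estimate), `n_blocks`, and `loo` (leave-one-out
#'   estimates).
#' @export
block_jackknife <- function(values, weights) {
  keep <- is.finite(values) & is.finite(weights) & weights > 0
  values <- values[keep]; weights <- weights[keep]
  g <- length(values)
  stop_if_not(g >= 2, "block jackknife needs at least 2 blocks with positive weight")
  W <- sum(weights)
  Tot <- sum(weights * values)
  est <- Tot / W
  loo <- (Tot - weights * values) / (W - weights)
  h <- W / weights
  tau <- h * est - (h - 1) * loo
  jk_est <- g * est - sum((1 - weights / W) * loo)
  var_jk <- sum((tau - jk_est)^2 / (h - 1)) / g
  list(est = est, se = sqrt(var_jk), jk_est = jk_est, n_blocks = g, loo = loo)
}

# Shared machinery: per-SNP numerator values -> block means -> jackknife.
# num: per-SNP values; use: logical usable-SNP mask; block: per-SNP block index.
fstat_from_snps <- function(num, use, block, label) {
  stop_if_not(any(use), paste0("no usable SNPs for ", label))
  b <- block[use]
  v <- num[use]
  sums <- rowsum(v, b)
  cnt <- rowsum(rep(1, length(v)), b)
  if (nrow(sums) < 2) stop(paste0(label, ": fewer than 2 non-empty blocks"), call. = FALSE)
  jk <- block_jackknife(sums[, 1] / cnt[, 1], cnt[, 1])
  structure(list(stat = label, estimate = jk$est, se = jk$se,
                 z = if (jk$se > 0) jk$est / jk$se else NA_real_,
                 n_snps = sum(use), n_blocks = jk$n_blocks,
                 block_values = sums[, 1] / cnt[, 1], block_weights = cnt[, 1],
                 loo = jk$loo),
            class = "fstat")
}

#' @export
print.fstat <- function(x, ...) {
  cat(sprintf("%s: %.6g (se %.3g, Z = %.2f), %d SNPs in %d blocks\n",
              x$stat, x$estimate, x$se, x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

freq_of <- function(counts, pop) {
  stop_if_not(pop %in% counts$groups, paste0("unknown group: ", pop))
  n <- counts$n[, pop]
  p <- ifelse(n > 0, counts$x[, pop] / n, NA_real_)
  list(p = p, n = n)
}

# Unbiased within-group heterozygosity term h/n = p(1-p)/(n-1); needs n >= 2.
# Groups observed with a single chromosome get no correction (warned once by
# callers when this matters).
het_term <- function(p, n, warn_label = NULL) {
  if (!is.null(warn_label) && any(n == 1, na.rm = TRUE)) {
    warning(sprintf("%s: %d SNPs observed as a single chromosome; correction skipped there",
                    warn_label, sum(n == 1, na.rm = TRUE)), call. = FALSE)
  }
  ifelse(n >= 2, p * (1 - p) / (n - 1), 0)
}

#' f2 statistic with block jackknife
#'
#' Bias-corrected estimator of the squared allele-frequency drift distance
#' between groups A and B: per SNP
#' \eqn{(\hat p_A-\hat p_B)^2 - h_A/n_A - h_B/n_B} with
#' \eqn{h = \hat p(1-\hat p)\,n/(n-1)}, averaged per block and jackknifed.
#'
#' @param counts A [count_table()].
#' @param A,B Group labels.
#' @param correction Apply the finite-sample heterozygosity correction
#'   (requires \eqn{n \ge 2}; groups observed as a single chromosome are left
#'   uncorrected). Set `FALSE` on exact-frequency inputs.
#' @return An `fstat` object.
#' @export
f2_stat <- function(counts, A, B, correction = TRUE) {
  a <- freq_of(counts, A); b <- freq_of(counts, B)
  use <- a$n > 0 & b$n > 0
  lab <- sprintf("f2(%s,%s)", A, B)
  num <- (a$p - b$p)^2
  if (correction) num <- num - het_term(a$p, a$n, lab) - het_term(b$p, b$n, lab)
  fstat_from_snps(num, use & is.finite(num), counts$block, lab)
}

#' f3 statistic with block jackknife
#'
#' \eqn{f_3(A;B,C) = E[(\hat p_A-\hat p_B)(\hat p_A-\hat p_C)]} with the
#' within-A correction \eqn{-h_A/n_A}. A significantly negative f3 signals
#' that A is admixed between sources related to B and C. In outgroup mode the
#' correction is omitted, matching outgroup-f3 shared-drift usage where only
#' relative magnitudes across pairs (B, C) matter.
#'
#' @inheritParams f2_stat
#' @param C Third group label.
#' @param outgroup_mode Omit the within-target correction.
#' @return An `fstat` object.
#' @export
f3_stat <- function(counts, A, B, C, outgroup_mode = FALSE, correction = TRUE) {
  a <- freq_of(counts, A); b <- freq_of(counts, B); cc <- freq_of(counts, C)
  use <- a$n > 0 & b$n > 0 & cc$n > 0
  num <- (a$p - b$p) * (a$p - cc$p)
  if (correction && !outgroup_mode) num <- num - het_term(a$p, a$n)
  fstat_from_snps(num, use & is.finite(num), counts$block,
                  sprintf("f3(%s;%s,%s)", A, B, C))
}

#' f4 statistic with block jackknife
#'
#' \eqn{f_4(A,B;C,D) = E[(\hat p_A-\hat p_B)(\hat p_C-\hat p_D)]}; zero when
#' (A, B) or (C, D) form a clade with respect to the other pair. No
#' finite-sample correction is needed. With `allsnps = TRUE` (the default
#' convention for sparse capture data) each statistic uses every SNP at which
#' its own four groups are observed; with `FALSE` the caller should
#' pre-intersect sites across a larger population set.
#'
#' @inheritParams f3_stat
#' @param D Fourth group label.
#' @param allsnps Use the per-statistic maximal SNP set.
#' @param snp_mask Optional logical mask restricting usable SNPs (used to
#'   implement global-intersection mode).
#' @return An `fstat` object.
#' @export
f4_stat <- function(counts, A, B, C, D, allsnps = TRUE, snp_mask = NULL) {
  a <- freq_of(counts, A); b <- freq_of(counts, B)
  cc <- freq_of(counts, C); d <- freq_of(counts, D)
  use <- a$n > 0 & b$n > 0 & cc$n > 0 & d$n > 0
  if (!allsnps || !is.null(snp_mask)) {
    mask <- snp_mask %||% (rowSums(counts$n == 0) == 0)
    use <- use & mask
  }
  num <- (a$p - b$p) * (cc$p - d$p)
  fstat_from_snps(num, use & is.finite(num), counts$block,
                  sprintf("f4(%s,%s;%s,%s)", A, B, C, D))
}

#' Hudson Fst (ratio of averages) with block jackknife
#'
#' Hudson's estimator, \eqn{\sum_s N_s / \sum_s D_s} with per-SNP
#' \eqn{N = (\hat p_1-\hat p_2)^2 - h_1/n_1 - h_2/n_2} and
#' \eqn{D = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1)}. With `inbreed = TRUE`
#' (the pseudo-haploid-safe mode) samples are treated as haploid lineages, so
#' within-group heterozygosity comes from allele counts over observed
#' chromosomes rather than from diploid genotype heterozygosity; this requires
#' \eqn{n \ge 2} chromosomes per group at a usable SNP. The jackknife is taken
#' on the ratio.
#'
#' @inheritParams f2_stat
#' @param inbreed Treat samples as haploid lineages (recommended and default
#'   for pseudo-haploid data; the diploid-frequency algebra is identical at
#'   the level of allele counts, so this flag currently gates only the
#'   \eqn{n \ge 2} usability rule).
#' @param min_snps Refuse to report when fewer usable SNPs than this are
#'   available (the study rule is 5000).
#' @return An `fstat` object.
#' @export
hudson_fst <- function(counts, A, B, inbreed = TRUE, min_snps = 5000) {
  a <- freq_of(counts, A); b <- freq_of(counts, B)
  use <- if (inbreed) a$n >= 2 & b$n >= 2 else a$n > 0 & b$n > 0
  num <- (a$p - b$p)^2 - het_term(a$p, a$n) - het_term(b$p, b$n)
  den <- a$p * (1 - b$p) + b$p * (1 - a$p)
  use <- use & is.finite(num) & is.finite(den) & den >= 0
  if (sum(use) < min_snps) {
    stop(sprintf("hudson_fst(%s,%s): %d usable SNPs, below the floor of %d",
                 A, B, sum(use), min_snps), call. = FALSE)
  }
  bl <- counts$block[use]
  ns <- rowsum(num[use], bl); ds <- rowsum(den[use], bl)
  cnt <- rowsum(rep(1, sum(use)), bl)
  Ntot <- sum(ns); Dtot <- sum(ds)
  est <- Ntot / Dtot
  loo <- (Ntot - ns[, 1]) / (Dtot - ds[, 1])
  w <- cnt[, 1]; W <- sum(w); g <- length(w)
  h <- W / w
  tau <- h * est - (h - 1) * loo
  jk_est <- g * est - sum((1 - w / W) * loo)
  se <- sqrt(sum((tau - jk_est)^2 / (h - 1)) / g)
  structure(list(stat = sprintf("Fst(%s,%s)", A, B), estimate = est, se = se,
                 z = if (se > 0) est / se else NA_real_,
                 n_snps = sum(use), n_blocks = g,
                 block_values = ns[, 1] / pmax(ds[, 1], .Machine$double.eps),
                 block_weights = w, loo = loo),
            class = "fstat")
}

#' Benjamini-Yekutieli correction of f4 Z-scores
#'
#' Converts two-sided Z-scores to p-values, applies the Benjamini-Yekutieli
#' step-up procedure (valid under arbitrary dependence, with harmonic factor
#' \eqn{c(m)=\sum_{k=1}^m 1/k}), and reports the adjusted p, significance at
#' the requested FDR, and the signed adjusted Z
#' \eqn{Z_{BY} = \mathrm{sign}(Z)\,\Phi^{-1}(1-p_{adj}/2)}.
#'
#' @param z Vector of f4 Z-scores.
#' @param fdr False discovery rate threshold (default 0.05).
#' @return Data frame with columns `z`, `p`, `p_by`, `significant`, `z_by`.
#' @export
by_correct <- function(z, fdr = 0.05) {
  if (length(z) == 0) {
    return(data.frame(z = numeric(0), p = numeric(0), p_by = numeric(0),
                      significant = logical(0), z_by = numeric(0)))
  }
  stop_if_not(all(is.finite(z)), "Z-scores must be finite")
  p <- 2 * pnorm(-abs(z))
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)                         # stable; ties keep input order
  padj <- numeric(m)
  # step-up: adj_(k) = min_{j >= k} m * c(m) * p_(j) / j, capped at 1
  scaled <- m * cm * p[ord] / seq_len(m)
  padj[ord] <- pmin(1, rev(cummin(rev(scaled))))
  data.frame(z = z, p = p, p_by = padj, significant = padj < fdr,
             z_by = sign(z) * qnorm(1 - pmin(padj, 1) / 2))
}
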