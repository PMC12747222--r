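#' Construct a ROH segment set
#'
#' @param segments Data frame: `individual`, `chrom`, `start_cM`, `end_cM`,
#'   `length_cM` (all segments >= the 4 cM calling floor).
#' @param meta Data frame: `individual`, `group`, `date_bp`, `covered_snps`,
#'   optional `weight` (fractional membership across groupings, default 1).
#' @return Object of class `roh_set`.
#' @export
roh_set <- function(segments, meta) {
  segments <- as.data.frame(segments)
  meta <- as.data.frame(meta)
  stop_if_not(all(c("individual", "chrom", "start_cM", "end_cM", "length_cM")
                  %in% names(segments)), "segments missing required columns")
  stop_if_not(all(c("individual", "group", "date_bp", "covered_snps") %in% names(meta)),
              "meta missing required columns")
  if (is.null(meta$weight)) meta$weight <- 1
  stop_if_not(all(segments$individual %in% meta$individual),
              "segments name individuals absent from meta")
  stop_if_not(all(is.finite(meta$date_bp)), "dates must be finite")
  structure(list(segments = segments, meta = meta), class = "roh_set")
}

#' @export
print.roh_set <- function(x, ...) {
  cat(sprintf("roh_set: %d segments >= %.3g cM in %d individuals\n",
              nrow(x$segments),
              if (nrow(x$segments)) min(x$segments$length_cM) else NA,
              nrow(x$meta)))
  invisible(x)
}

#' Read/write ROH segment TSVs (hapROH-style exports)
#'
#' @param path Segment TSV (`individual`, `chrom`, `start_cM`, `end_cM`,
#'   `length_cM`).
#' @param meta_path Metadata TSV (`individual`, `group`, `date_bp`,
#'   `covered_snps`, optional `weight`).
#' @return A [roh_set()].
#' @export
read_roh <- function(path, meta_path) {
  roh_set(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
          read.table(meta_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_roh
#' @param rs A [roh_set()].
#' @param prefix Output prefix (`<prefix>_segments.tsv`, `<prefix>_meta.tsv`).
#' @export
write_roh <- function(rs, prefix) {
  write.table(rs$segments, paste0(prefix, "_segments.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  write.table(rs$meta, paste0(prefix, "_meta.tsv"), quote = FALSE,
              sep = "\t", row.names = FALSE)
  invisible(prefix)
}

# Per-individual cumulative ROH length within a cM range.
roh_sums <- function(rs, range_cM = c(20, Inf)) {
  seg <- rs$segments
  sel <- seg$length_cM >= range_cM[1] & seg$length_cM <= range_cM[2]
  s <- rowsum(seg$length_cM[sel], seg$individual[sel])
  out <- setNames(rep(0, nrow(rs$meta)), rs$meta$individual)
  out[rownames(s)] <- s[, 1]
  out
}

#' Eligibility filters for ROH-based analyses
#'
#' Keeps individuals with at least `min_snps` covered SNPs (the study floor is
#' 400,000 on the 1240k set). For effective-size estimation, additionally
#' requires a mean date of at most `max_date_bp` (3000 BP) and a cumulative
#' sum of segments longer than 20 cM strictly below `max_sum20` (50 cM, to
#' avoid biases due to recent inbreeding).
#'
#' @param rs A [roh_set()].
#' @param min_snps Coverage floor (default 400000).
#' @param for_ne Apply the date and inbreeding filters as well.
#' @param max_date_bp Date ceiling for Ne estimation (default 3000).
#' @param max_sum20 Strict upper bound on cumulative ROH > 20 cM (default 50).
#' @return The filtered [roh_set()].
#' @export
eligibility_filter <- function(rs, min_snps = 400000, for_ne = FALSE,
                               max_date_bp = 3000, max_sum20 = 50) {
  keep <- rs$meta$covered_snps >= min_snps
  if (for_ne) {
    s20 <- roh_sums(rs, c(20, Inf))[rs$meta$individual]
    keep <- keep & rs$meta$date_bp <= max_date_bp & s20 < max_sum20
  }
  ids <- rs$meta$individual[keep]
  roh_set(rs$segments[rs$segments$individual %in% ids, , drop = FALSE],
          rs$meta[keep, , drop = FALSE])
}

# Expected number of observed segments per genome with genetic length in
# [a, b] Morgans under constant Ne (beta = 1/(2 Ne)), from the segment
# intensity lambda(l) = 8 beta / (2 l + beta)^3 per Morgan, in closed form
# including chromosome-edge clipping:
#   unclipped starts: int_a^b lambda(l) (L - l) dl
#   clipped tails observed at length u in [a, b]: int_a^b Lambda(u) du,
#     Lambda(u) = 2 beta / (2 u + beta)^2 (intensity of segments >= u).
roh_expected_counts <- function(ne, bins_M, map_lengths) {
  beta <- 1 / (2 * ne)
  vapply(seq_len(nrow(bins_M)), function(i) {
    a <- bins_M[i, 1]; b <- bins_M[i, 2]
    ta <- 2 * a + beta; tb <- 2 * b + beta
    q <- 2 * beta * (1 / ta^2 - 1 / tb^2)
    int_l <- 2 * beta * ((1 / ta - 1 / tb) + (beta / 2) * (1 / tb^2 - 1 / ta^2))
    j <- beta * (1 / ta - 1 / tb)
    sum(vapply(map_lengths, function(L) {
      if (L > b) L * q - int_l + j else max(L - (a + b) / 2, 0) * q
    }, numeric(1)))
  }, numeric(1))
}

#' Effective population size from ROH length distributions
#'
#' Maximum-likelihood estimate of a constant diploid effective size from the
#' distribution of ROH segment lengths in `fit_range` (default 4-20 cM, the
#' background-relatedness window). Segment counts per length bin are modeled
#' as Poisson with means from the constant-Ne segment intensity
#' \eqn{8\beta/(2\ell+\beta)^3} per Morgan of map (\eqn{\beta = 1/(2N_e)}),
#' the closed form obtained by integrating Exponential(mean 2 Ne)
#' within-individual coalescence times against Exponential(2g) segment
#' lengths. Individual weights multiply log-likelihood contributions
#' (fractional group membership). The 95% CI is likelihood-ratio based
#' (drop of 1.92); with zero observed segments in range the estimate is
#' flagged unbounded above.
#'
#' @param rs A [roh_set()] (already filtered; see [eligibility_filter()]).
#' @param fit_range Length window in cM (default `c(4, 20)`).
#' @param map_lengths Chromosome map lengths in Morgans.
#' @param n_bins Number of log-spaced length bins (default 8).
#' @param ne_bounds Search interval for Ne.
#' @return Object of class `ne_estimate`: `ne`, `ci` (length 2), `n_ind`
#'   (sum of weights), `n_segments`, `unbounded` flag.
#' @export
ne_mle <- function(rs, fit_range = c(4, 20),
                   map_lengths = default_chromosome_lengths(), n_bins = 8,
                   ne_bounds = c(10, 1e7)) {
  stop_if_not(nrow(rs$meta) >= 1, "need at least one eligible individual")
  edges_cM <- exp(seq(log(fit_range[1]), log(fit_range[2]), length.out = n_bins + 1))
  bins_M <- cbind(edges_cM[-length(edges_cM)], edges_cM[-1]) / 100
  w <- rs$meta$weight
  seg <- rs$segments
  counts <- matrix(0, nrow(rs$meta), n_bins)
  for (i in seq_len(nrow(rs$meta))) {
    l <- seg$length_cM[seg$individual == rs$meta$individual[i]] / 100
    l <- l[l >= bins_M[1, 1] & l <= bins_M[n_bins, 2]]
    if (length(l)) {
      counts[i, ] <- vapply(seq_len(n_bins), function(k)
        sum(l >= bins_M[k, 1] & l < bins_M[k, 2] |
              (k == n_bins & l == bins_M[k, 2])), numeric(1))
    }
  }
  nseg <- sum(counts * w)
  negll <- function(log_ne) {
    mu <- pmax(roh_expected_counts(exp(log_ne), bins_M, map_lengths), 1e-12)
    -sum(w * (counts %*% log(mu))) + sum(w) * sum(mu)
  }
  opt <- optimize(negll, log(ne_bounds))
  ne_hat <- exp(opt$minimum)
  unbounded <- nseg == 0 || ne_hat >= ne_bounds[2] * 0.99
  ll0 <- -opt$objective
  cutoff <- 1.92
  lo <- tryCatch(exp(uniroot(function(x) (-negll(x)) - (ll0 - cutoff),
                             c(log(ne_bounds[1]), opt$minimum))$root),
                 error = function(e) ne_bounds[1])
  hi <- if (unbounded) Inf else
    tryCatch(exp(uniroot(function(x) (-negll(x)) - (ll0 - cutoff),
                         c(opt$minimum, log(ne_bounds[2])))$root),
             error = function(e) Inf)
  structure(list(ne = if (unbounded) Inf else ne_hat, ci = c(lo, hi),
                 n_ind = sum(w), n_segments = nseg,
                 unbounded = unbounded || !is.finite(hi)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne = %.0f (95%% CI %.0f - %s), %d segments in range, n = %.1f\n",
              x$ne, x$ci[1], if (is.finite(x$ci[2])) sprintf("%.0f", x$ci[2]) else "Inf",
              round(x$n_segments), x$n_ind))
  invisible(x)
}

#' Group comparison of long-ROH burdens
#'
#' Omnibus Kruskal-Wallis test (tie-corrected) on the per-individual
#' cumulative length of ROH segments above `range_cM[1]` (default > 20 cM,
#' informative of recent close parental relatedness), followed by pairwise
#' Conover-Iman rank tests with Benjamini-Hochberg FDR correction at
#' `fdr`.
#'
#' @param rs A [roh_set()].
#' @param range_cM Segment length window (default `c(20, Inf)`).
#' @param fdr FDR threshold for the pairwise table (default 0.05).
#' @return List with `kruskal` (htest), `pairwise` data frame (`group1`,
#'   `group2`, `t`, `p`, `p_adj`, `significant`), and the per-individual
#'   response.
#' @export
roh_group_tests <- function(rs, range_cM = c(20, Inf), fdr = 0.05) {
  y <- roh_sums(rs, range_cM)[rs$meta$individual]
  grp <- factor(rs$meta$group)
  stop_if_not(nlevels(grp) >= 2, "need at least 2 groups")
  stop_if_not(all(table(grp) >= 2), "each group needs at least 2 individuals")
  if (all(y == y[1])) {
    kw <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               p.value = 1, parameter = c(df = nlevels(grp) - 1))
    class(kw) <- "htest"
  } else {
    kw <- kruskal.test(y, grp)
  }
  # Conover-Iman post hoc on ranks
  N <- length(y); k <- nlevels(grp)
  r <- rank(y)
  ni <- tabulate(grp)
  rbar <- tapply(r, grp, mean)
  H <- unname(kw$statistic)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  denom_scale <- S2 * (N - 1 - H) / (N - k)
  prs <- combn(levels(grp), 2)
  tt <- pp <- numeric(ncol(prs))
  for (m in seq_len(ncol(prs))) {
    i <- match(prs[1, m], levels(grp)); j <- match(prs[2, m], levels(grp))
    se <- sqrt(denom_scale * (1 / ni[i] + 1 / ni[j]))
    tt[m] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    pp[m] <- 2 * pt(-abs(tt[m]), df = N - k)
  }
  padj <- p.adjust(pp, method = "BH")
  pw <- data.frame(group1 = prs[1, ], group2 = prs[2, ], t = tt, p = pp,
                   p_adj = padj, significant = padj < fdr,
                   stringsAsFactors = FALSE)
  list(kruskal = kw, pairwise = pw, response = y)
}

#' Temporal trend in background-relatedness ROH
#'
#' Ordinary least squares of the per-individual cumulative sum of ROH in
#' `length_range` (default 4-12 cM, informative of effective population
#' size) on mean date BP, restricted to individuals dated at most
#' `max_date_bp` (default 2500 BP, the study's window).
#'
#' @param rs A [roh_set()].
#' @param length_range Segment window in cM (default `c(4, 12)`).
#' @param max_date_bp Date ceiling (default 2500).
#' @return List with `slope` (cM per year BP), `se`, `p`, `n`, `flagged`
#'   (degenerate response).
#' @export
roh_time_regression <- function(rs, length_range = c(4, 12), max_date_bp = 2500) {
  keep <- rs$meta$date_bp <= max_date_bp
  stop_if_not(sum(keep) >= 3, "need at least 3 individuals in the date window")
  y <- roh_sums(rs, length_range)[rs$meta$individual][keep]
  x <- rs$meta$date_bp[keep]
  if (sd(y) == 0 || sd(x) == 0) {
    return(list(slope = 0, se = NA_real_, p = 1, n = sum(keep), flagged = TRUE))
  }
  fit <- summary(lm(y ~ x))
  list(slope = fit$coefficients["x", "Estimate"],
       se = fit$coefficients["x", "Std. Error"],
       p = fit$coefficients["x", "Pr(>|t|)"], n = sum(keep), flagged = FALSE)
}
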