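#' Pairwise mismatch rate between two pseudo-haploid individuals
#'
#' The fraction of overlapping (both-covered) sites at which the two
#' pseudo-haploid calls differ, with a block-jackknife standard error.
#' Computed on non-CpG autosomal sites when a mask is supplied; with no mask
#' all sites are used with a warning. Pairs overlapping fewer than
#' `min_overlap` sites are reported as uninformative and never classified.
#'
#' @param gm A [genotype_matrix()].
#' @param id1,id2 Individual ids (must be pseudo-haploid).
#' @param site_mask Optional logical vector (or index vector) of usable sites
#'   (e.g. non-CpG autosomal).
#' @param block Per-SNP block assignment (defaults to [assign_blocks()]).
#' @param min_overlap Overlap floor (default 5000 sites).
#' @return Object of class `mismatch_result`: `rate`, `se`, `n_overlap`,
#'   `informative`.
#' @export
pairwise_mismatch <- function(gm, id1, id2, site_mask = NULL, block = NULL,
                              min_overlap = 5000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j1 <- match(id1, gm$ind$id); j2 <- match(id2, gm$ind$id)
  stop_if_not(!is.na(j1) && !is.na(j2), "unknown individual id")
  stop_if_not(all(gm$ind$ploidy[c(j1, j2)] == 1L),
              "mismatch rates are defined for pseudo-haploid individuals")
  if (is.null(site_mask)) {
    warning("no site mask supplied; using all sites (non-CpG autosomal mask recommended)")
    site_mask <- rep(TRUE, nrow(gm$snp))
  }
  if (!is.logical(site_mask)) {
    site_mask <- seq_len(nrow(gm$snp)) %in% site_mask
  }
  a <- gm$calls[, j1]; b <- gm$calls[, j2]
  usable <- site_mask & !is.na(a) & !is.na(b)
  n_ov <- sum(usable)
  if (is.null(block)) block <- assign_blocks(gm)
  res <- list(id1 = id1, id2 = id2, n_overlap = n_ov, rate = NA_real_,
              se = NA_real_, informative = n_ov >= min_overlap)
  if (res$informative) {
    mis <- (a != b)[usable]
    bl <- block[usable]
    if (length(unique(bl)) >= 2) {
      sums <- rowsum(mis + 0, bl); cnt <- rowsum(rep(1, n_ov), bl)
      jk <- block_jackknife(sums[, 1] / cnt[, 1], cnt[, 1])
      res$rate <- jk$est; res$se <- jk$se
    } else {
      # everything in one block (e.g. a single short chromosome): fall back
      # to the binomial SE
      res$rate <- mean(mis)
      res$se <- sqrt(res$rate * (1 - res$rate) / n_ov)
    }
  }
  structure(res, class = "mismatch_result")
}

#' @export
print.mismatch_result <- function(x, ...) {
  if (x$informative) {
    cat(sprintf("PMR(%s, %s) = %.4f +/- %.4f over %d sites\n",
                x$id1, x$id2, x$rate, x$se, x$n_overlap))
  } else {
    cat(sprintf("PMR(%s, %s): uninformative (%d overlapping sites)\n",
                x$id1, x$id2, x$n_overlap))
  }
  invisible(x)
}

#' Within-individual mismatch rate (identical-genome anchor)
#'
#' The mismatch rate between two independent pseudo-haploid call replicates
#' of one individual (e.g. from two libraries): the rate of difference
#' between the individual's two chromosomes, which anchors the identical
#' end of the relatedness scale at about half the unrelated baseline.
#'
#' @param rep1,rep2 Integer call vectors (0/1/NA) over the same sites.
#' @param site_mask Optional usable-site mask.
#' @return List with `rate`, `n_overlap`.
#' @export
within_individual_rate <- function(rep1, rep2, site_mask = NULL) {
  stop_if_not(length(rep1) == length(rep2), "replicates must cover the same sites")
  use <- !is.na(rep1) & !is.na(rep2)
  if (!is.null(site_mask)) use <- use & site_mask
  list(rate = mean(rep1[use] != rep2[use]), n_overlap = sum(use))
}

#' Baseline (unrelated) mismatch rate for a set of individuals
#'
#' Median pairwise rate over all informative pairs: robust to a small number
#' of related pairs in the set. When a within-individual anchor is available
#' it should be preferred (`2 * within rate`); the median fallback is flagged.
#'
#' @param rates Numeric vector of pairwise mismatch rates.
#' @return List with `baseline` and `anchor` ("median_pairs").
#' @export
baseline_rate <- function(rates) {
  rates <- rates[is.finite(rates)]
  stop_if_not(length(rates) > 0, "no informative pair rates")
  list(baseline = median(rates), anchor = "median_pairs")
}

#' Classify relatedness degree from a mismatch rate
#'
#' Expected pairwise mismatch rates relative to the unrelated baseline b are
#' 0.5 b (identical/twin), 0.75 b (1st degree), 0.875 b (2nd degree) and b
#' (unrelated); class boundaries sit at the midpoints (0.625, 0.8125,
#' 0.90625) x b. A related class is only asserted when the rate is at least
#' two standard errors below the unrelated boundary; pairs classified 2nd
#' degree or closer are recommended for exclusion (keeping the
#' higher-coverage member).
#'
#' @param result A `mismatch_result` (or a rate; then supply `se`).
#' @param baseline Unrelated baseline rate b (> 0).
#' @param se Standard error when `result` is a bare rate.
#' @return List with `degree` (`"identical"`, `"first"`, `"second"`,
#'   `"third_or_unrelated"`, or `"uninformative"`), `ratio`, and
#'   `exclude_recommended`.
#' @export
classify_degree <- function(result, baseline, se = NULL) {
  stop_if_not(baseline > 0, "baseline must be positive")
  if (inherits(result, "mismatch_result")) {
    if (!result$informative) {
      return(list(degree = "uninformative", ratio = NA_real_,
                  exclude_recommended = FALSE))
    }
    rate <- result$rate; se <- result$se
  } else {
    rate <- result
    stop_if_not(!is.null(se), "supply se with a bare rate")
  }
  ratio <- rate / baseline
  unrel_boundary <- 0.90625 * baseline
  candidate <- if (ratio < 0.625) "identical" else if (ratio < 0.8125) "first"
    else if (ratio < 0.90625) "second" else "third_or_unrelated"
  if (candidate != "third_or_unrelated" && rate + 2 * se > unrel_boundary) {
    candidate <- "third_or_unrelated"
  }
  list(degree = candidate, ratio = ratio,
       exclude_recommended = candidate %in% c("identical", "first", "second"))
}

#' All-pairs kinship screen
#'
#' Computes pairwise mismatch rates for every pair of pseudo-haploid
#' individuals, derives the unrelated baseline (median of informative
#' pairs), classifies each pair and recommends exclusions for 2nd degree or
#' closer, keeping the higher-coverage member.
#'
#' @inheritParams pairwise_mismatch
#' @param ids Individuals to screen (default all pseudo-haploid).
#' @return Data frame with one row per pair: rates, SEs, ratio, degree,
#'   `exclude` (the id recommended for removal, or `NA`).
#' @export
kinship_screen <- function(gm, ids = NULL, site_mask = NULL, block = NULL,
                           min_overlap = 5000) {
  if (is.null(ids)) ids <- gm$ind$id[gm$ind$ploidy == 1L]
  stop_if_not(length(ids) >= 2, "need at least two individuals")
  if (is.null(block)) block <- assign_blocks(gm)
  prs <- combn(ids, 2)
  res <- lapply(seq_len(ncol(prs)), function(k)
    pairwise_mismatch(gm, prs[1, k], prs[2, k], site_mask = site_mask,
                      block = block, min_overlap = min_overlap))
  rates <- vapply(res, function(r) r$rate %||% NA_real_, numeric(1))
  b <- baseline_rate(rates)$baseline
  cov_n <- colSums(!is.na(gm$calls))
  rows <- lapply(seq_along(res), function(k) {
    r <- res[[k]]
    cl <- classify_degree(r, b)
    excl <- NA_character_
    if (isTRUE(cl$exclude_recommended)) {
      excl <- if (cov_n[[r$id1]] >= cov_n[[r$id2]]) r$id2 else r$id1
    }
    data.frame(id1 = r$id1, id2 = r$id2, n_overlap = r$n_overlap,
               rate = r$rate, se = r$se, ratio = cl$ratio, degree = cl$degree,
               exclude = excl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- b
  out
}
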