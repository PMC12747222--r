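#' Construct a genotype matrix
#'
#' Container for per-individual, per-SNP derived-allele dosages. Pseudo-haploid
#' individuals have ploidy 1 (dosage 0/1/NA); diploid individuals have ploidy 2
#' (dosage 0/1/2/NA). SNPs must be sorted by chromosome and physical position.
#'
#' @param calls Integer matrix, SNPs in rows, individuals in columns; `NA`
#'   encodes missing.
#' @param snp Data frame with columns `id`, `chrom`, `gpos` (genetic position,
#'   Morgans; may be `NA`), `ppos` (physical position, bp, 1-based), `ref`,
#'   `alt`.
#' @param ind Data frame with columns `id` and `ploidy` (1 = pseudo-haploid,
#'   2 = diploid).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snp, ind) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stop_if_not(nrow(calls) == nrow(snp), "calls and snp table disagree on SNP count")
  stop_if_not(ncol(calls) == nrow(ind), "calls and ind table disagree on individual count")
  stop_if_not(!anyDuplicated(ind$id), "individual ids must be unique")
  stop_if_not(all(ind$ploidy %in% c(1L, 2L)), "ploidy must be 1 or 2")
  ok <- is.na(calls) | sweep(calls, 2, ind$ploidy, "<=") & calls >= 0L
  stop_if_not(all(ok), "dosage exceeds ploidy or is negative")
  ord <- order(snp$chrom, snp$ppos)
  stop_if_not(all(ord == seq_len(nrow(snp))), "SNPs must be sorted by (chrom, physical_pos)")
  colnames(calls) <- ind$id
  rownames(calls) <- snp$id
  structure(list(calls = calls, snp = as.data.frame(snp), ind = as.data.frame(ind)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d individuals (%d pseudo-haploid, %d diploid)\n",
              nrow(x$snp), nrow(x$ind), sum(x$ind$ploidy == 1), sum(x$ind$ploidy == 2)))
  cat(sprintf("  missingness: %.3f\n", mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read EIGENSTRAT .geno/.snp/.ind files
#'
#' The `.geno` code is the count of the `.snp` file's first (reference) allele;
#' 9 is missing. Internally dosages count the alternate allele. Individuals
#' whose observed codes are confined to \{0, 2, 9\} are auto-flagged
#' pseudo-haploid (ploidy 1) unless `ploidy` overrides this.
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp`, `<prefix>.ind`
#'   must exist.
#' @param ploidy Optional integer vector (1 or 2 per individual) overriding
#'   pseudo-haploid auto-detection.
#' @return A [genotype_matrix()].
#' @export
read_eigenstrat <- function(prefix, ploidy = NULL) {
  fg <- paste0(prefix, ".geno"); fs <- paste0(prefix, ".snp"); fi <- paste0(prefix, ".ind")
  for (f in c(fg, fs, fi)) stop_if_not(file.exists(f), paste0("missing file: ", f))
  ind <- read.table(fi, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "sex", "group"))
  snp <- read.table(fs, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "chrom", "gpos", "ppos", "ref", "alt"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  lines <- readLines(fg)
  if (nrow(snp) != length(lines)) {
    stop(sprintf(".snp has %d rows but .geno has %d lines (first offending line: %d)",
                 nrow(snp), length(lines), min(nrow(snp), length(lines)) + 1L), call. = FALSE)
  }
  nc <- nchar(lines)
  bad <- which(nc != nrow(ind))
  if (length(bad)) {
    stop(sprintf(".geno line %d has %d columns, expected %d individuals",
                 bad[1], nc[bad[1]], nrow(ind)), call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow = length(lines), ncol = nrow(ind))
  allowed <- c("0", "1", "2", "9")
  for (j in seq_len(nrow(ind))) {
    cj <- substr(lines, j, j)
    ok <- cj %in% allowed
    if (!all(ok)) {
      stop(sprintf("unknown genotype code '%s' at .geno line %d, individual %d",
                   cj[which(!ok)[1]], which(!ok)[1], j), call. = FALSE)
    }
    codes[, j] <- as.integer(cj)
  }
  codes[codes == 9L] <- NA_integer_
  if (is.null(ploidy)) {
    # codes are ref-allele counts on a diploid representation; pure 0/2/9
    # columns are the pseudo-haploid convention
    ploidy <- ifelse(apply(codes, 2, function(v) all(is.na(v) | v %in% c(0L, 2L))), 1L, 2L)
  }
  ploidy <- as.integer(ploidy)
  # dosage of the alternate allele on the individual's own ploidy scale
  calls <- matrix(NA_integer_, nrow(codes), ncol(codes))
  for (j in seq_len(ncol(codes))) {
    calls[, j] <- if (ploidy[j] == 1L) 1L - codes[, j] %/% 2L else 2L - codes[, j]
  }
  gm <- genotype_matrix(calls, snp, data.frame(id = ind$id, ploidy = ploidy,
                                               stringsAsFactors = FALSE))
  gm$ind$sex <- ind$sex
  gm$ind$group <- ind$group
  gm
}

#' Write EIGENSTRAT .geno/.snp/.ind files
#'
#' Inverse of [read_eigenstrat()]. Pseudo-haploid individuals are written as
#' diploid homozygotes (codes 0/2/9); a heterozygous dosage on a
#' pseudo-haploid individual is an error.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param groups Optional [group_map()] supplying the `.ind` group column.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(gm, prefix, groups = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ph <- gm$ind$ploidy == 1L
  codes <- gm$calls
  for (j in seq_len(ncol(codes))) {
    v <- gm$calls[, j]
    codes[, j] <- if (ph[j]) 2L * (1L - v) else 2L - v
  }
  codes[is.na(codes)] <- 9L
  lines <- if (nrow(codes)) apply(codes, 1, paste, collapse = "") else character(0)
  writeLines(lines, paste0(prefix, ".geno"))
  snp <- gm$snp
  snp$gpos[is.na(snp$gpos)] <- 0
  write.table(snp[, c("id", "chrom", "gpos", "ppos", "ref", "alt")],
              paste0(prefix, ".snp"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  grp <- if (!is.null(groups)) unname(groups[gm$ind$id]) else gm$ind$group %||% "Control"
  grp[is.na(grp)] <- "Control"
  sex <- gm$ind$sex %||% "U"
  write.table(data.frame(gm$ind$id, sex, grp), paste0(prefix, ".ind"),
              quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Construct or read a group map
#'
#' @param ids Individual ids.
#' @param groups Group labels, parallel to `ids`.
#' @return Named character vector mapping individual id to group label.
#' @export
group_map <- function(ids, groups) {
  stop_if_not(length(ids) == length(groups), "ids and groups must be parallel")
  setNames(as.character(groups), as.character(ids))
}

#' @rdname group_map
#' @param path TSV file with columns `id`, `group`.
#' @export
read_group_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  group_map(d$id, d$group)
}

#' @rdname group_map
#' @param gmap A group map.
#' @export
write_group_map <- function(gmap, path) {
  write.table(data.frame(id = names(gmap), group = unname(gmap)), path,
              quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Per-group derived-allele counts
#'
#' Collapses a genotype matrix to the substrate of all f-statistics: per
#' (group, SNP) the derived-allele count `x` and the number of observed
#' chromosomes `n` (sum of ploidies of non-missing members; `n = 0` encodes a
#' group-missing site).
#'
#' @param gm A [genotype_matrix()].
#' @param groups A [group_map()]; every mapped id must exist in `gm`.
#' @param block Optional per-SNP block assignment (see [assign_blocks()]),
#'   carried along for jackknifing.
#' @return An object of class `count_table` with fields `x`, `n` (SNP x group
#'   matrices), `snp`, `groups`, `block`.
#' @export
group_counts <- function(gm, groups, block = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stop_if_not(length(groups) > 0, "groups must be non-empty")
  stop_if_not(all(names(groups) %in% gm$ind$id),
              "group map names individuals absent from the matrix")
  labs <- unique(unname(groups))
  x <- matrix(0, nrow(gm$snp), length(labs), dimnames = list(NULL, labs))
  n <- x
  for (g in labs) {
    ids <- names(groups)[groups == g]
    stop_if_not(length(ids) > 0, paste0("group has zero members: ", g))
    j <- match(ids, gm$ind$id)
    sub <- gm$calls[, j, drop = FALSE]
    obs <- !is.na(sub)
    x[, g] <- rowSums(sub, na.rm = TRUE)
    n[, g] <- as.numeric(obs %*% gm$ind$ploidy[j])
  }
  count_table(x, n, snp = gm$snp, block = block)
}

#' Construct an allele-count table directly
#'
#' @param x Derived-allele count matrix (SNP x group).
#' @param n Observed chromosome count matrix (same shape); `n = 0` marks a
#'   group-missing site. For exact (noise-free) population frequencies, pass
#'   the frequencies as `x` with `n = 1` and disable small-sample corrections
#'   in the f-statistics.
#' @param snp Optional SNP metadata data frame.
#' @param block Optional per-SNP block index.
#' @return A `count_table`.
#' @export
count_table <- function(x, n, snp = NULL, block = NULL) {
  x <- as.matrix(x); n <- as.matrix(n)
  stop_if_not(all(dim(x) == dim(n)), "x and n must have the same shape")
  stop_if_not(all(x <= n + 1e-9 & x >= -1e-9), "need 0 <= x <= n")
  if (!is.null(block)) {
    stop_if_not(length(block) == nrow(x), "block assignment must cover every SNP")
  }
  structure(list(x = x, n = n, groups = colnames(x), snp = snp,
                 block = if (is.null(block)) rep(1L, nrow(x)) else as.integer(block)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d SNPs x %d groups, %d blocks\n",
              nrow(x$x), ncol(x$x), length(unique(x$block))))
  invisible(x)
}

#' Filter SNPs on group-level missingness and minor allele frequency
#'
#' Drops SNPs whose fraction of groups with no observed chromosomes exceeds
#' `maxmiss`, and SNPs whose overall minor allele frequency (pooled over
#' groups) is below `min_maf`. The default `maxmiss = 0.15` is the extraction
#' setting used for admixture-graph searches on capture data.
#'
#' @param counts A `count_table`.
#' @param maxmiss Maximum tolerated fraction of missing groups per SNP.
#' @param min_maf Minimum pooled minor allele frequency.
#' @return The filtered `count_table`; a `report` attribute carries counts of
#'   SNPs kept, dropped, and polymorphic among the kept groups.
#' @export
filter_sites <- function(counts, maxmiss = 0.15, min_maf = 0) {
  stopifnot(inherits(counts, "count_table"))
  stop_if_not(maxmiss >= 0 && maxmiss <= 1, "maxmiss must be in [0, 1]")
  missfrac <- rowMeans(counts$n == 0)
  ntot <- rowSums(counts$n)
  xtot <- rowSums(counts$x)
  p <- ifelse(ntot > 0, xtot / ntot, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- missfrac <= maxmiss & (min_maf <= 0 | (!is.na(maf) & maf >= min_maf))
  out <- count_table(counts$x[keep, , drop = FALSE], counts$n[keep, , drop = FALSE],
                     snp = if (!is.null(counts$snp)) counts$snp[keep, , drop = FALSE],
                     block = counts$block[keep])
  poly <- sum(keep & !is.na(maf) & maf > 0)
  attr(out, "report") <- c(kept = sum(keep), dropped = sum(!keep), polymorphic = poly)
  out
}

#' Assign contiguous jackknife blocks
#'
#' Greedy contiguous blocks of at most `block_length` per chromosome;
#' chromosome boundaries always break blocks. When genetic positions are
#' available the default block length is 0.05 Morgan; otherwise 5 Mb of
#' physical distance is used.
#'
#' @param snp SNP table (or a [genotype_matrix()]).
#' @param block_length Block span; interpreted in Morgans if genetic positions
#'   are usable, else bp.
#' @return Integer vector of 1-based block indices, one per SNP, with a
#'   `weights` attribute of per-block SNP counts.
#' @export
assign_blocks <- function(snp, block_length = NULL) {
  if (inherits(snp, "genotype_matrix")) snp <- snp$snp
  has_g <- !is.null(snp$gpos) && !anyNA(snp$gpos) && any(snp$gpos > 0)
  pos <- if (has_g) snp$gpos else snp$ppos
  if (is.null(block_length)) block_length <- if (has_g) 0.05 else 5e6
  stop_if_not(block_length > 0, "block_length must be positive")
  chrom <- as.character(snp$chrom)
  idx <- integer(length(pos))
  b <- 0L
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    p <- pos[sel]
    stop_if_not(!is.unsorted(p), "SNPs are not sorted within chromosome")
    local <- floor((p - p[1]) / block_length)
    idx[sel] <- b + match(local, unique(local))
    b <- max(idx[sel])
  }
  w <- tabulate(idx)
  attr(idx, "weights") <- w
  idx
}
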