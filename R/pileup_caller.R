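#' Classify a read position as terminal or central
#'
#' Positions more than 10 bases from both the 5' and 3' read ends are
#' central; otherwise the nearer end wins, with ties assigned to the 5'
#' terminal class.
#'
#' @param distance_5prime,distance_3prime Distances (bp, >= 0) from the read
#'   ends; vectorized.
#' @return Character vector in `{"terminal_5", "terminal_3", "central"}`.
#' @export
classify_position <- function(distance_5prime, distance_3prime) {
  stop_if_not(all(distance_5prime >= 0 & distance_3prime >= 0),
              "distances must be non-negative")
  ifelse(distance_5prime > 10 & distance_3prime > 10, "central",
         ifelse(distance_5prime <= distance_3prime, "terminal_5", "terminal_3"))
}

# Default quality bins: the stratification axes are fixed (library type, base
# pair, read position, strand, MQ, BQ); the bin boundaries are tunable.
mq_bin <- function(mq) ifelse(mq >= 30, "mq30+", "mq<30")
bq_bin <- function(bq) ifelse(bq >= 30, "bq30+", ifelse(bq >= 20, "bq20-29", "bq<20"))

stratum_key <- function(library_type, pos_class, strand, mq, bq) {
  paste(library_type, pos_class, strand, mq_bin(mq), bq_bin(bq), sep = "|")
}

#' Estimate stratified empirical error rates from monomorphic sites
#'
#' Adaptive error model of the pseudo-haploid caller: at sites assumed
#' monomorphic (the truth base is known), the directed rate E(a -> b) is the
#' fraction of reads with true base a observed as b, within each stratum of
#' (library type, read-position class, strand, MQ bin, BQ bin). Strata with
#' zero observations of the source base are undefined and flagged; they fail
#' the reliability threshold downstream.
#'
#' @param pileup Pileup data frame (see [simulate_pileups()] /
#'   [read_pileup()]) with a `true_base` column carrying the assumed
#'   monomorphic base per site.
#' @return An object of class `error_table`: data frame with the stratum
#'   axes, `from`, `to`, `rate`, `n_obs`.
#' @export
estimate_error_rates <- function(pileup) {
  stop_if_not("true_base" %in% names(pileup),
              "pileup must carry the assumed-true base (true_base)")
  bases <- c("A", "C", "G", "T")
  stop_if_not(all(pileup$base %in% bases), "bases must be A/C/G/T")
  key <- stratum_key(pileup$library_type, pileup$pos_class, pileup$strand,
                     pileup$mq, pileup$bq)
  dkey <- paste(key, pileup$true_base, sep = "|")
  denom <- table(dkey)
  mis <- pileup$base != pileup$true_base
  mcount <- table(paste(dkey[mis], pileup$base[mis], sep = "|"))
  # one row per observed (stratum, from) and every possible to != from,
  # so zero-mismatch cells carry an explicit rate of 0
  parts <- do.call(rbind, strsplit(names(denom), "|", fixed = TRUE))
  dn <- as.integer(denom)
  rows <- lapply(seq_len(nrow(parts)), function(i) {
    from <- parts[i, 6]
    to <- setdiff(bases, from)
    cnt <- as.integer(mcount[paste(names(denom)[i], to, sep = "|")])
    cnt[is.na(cnt)] <- 0L
    data.frame(library_type = parts[i, 1], pos_class = parts[i, 2],
               strand = parts[i, 3], mq_bin = parts[i, 4], bq_bin = parts[i, 5],
               from = from, to = to, rate = cnt / dn[i], n_obs = dn[i],
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("error_table", "data.frame"))
}

#' Look up a directed error rate
#'
#' @param table An `error_table`.
#' @param library_type,pos_class,strand,mq,bq Stratum of the observation
#'   (raw MQ/BQ values are binned internally).
#' @param from,to Ordered base pair.
#' @return Rate in `[0, 1]`, or `NA` if the stratum/base cell has no
#'   observations of `from` (undefined, conservative fail downstream).
#'   Vectorized over observations.
#' @export
error_rate <- function(table, library_type, pos_class, strand, mq, bq, from, to) {
  tkey <- paste(table$library_type, table$pos_class, table$strand,
                table$mq_bin, table$bq_bin, table$from, table$to, sep = "|")
  qkey <- paste(library_type, pos_class, strand, mq_bin(mq), bq_bin(bq),
                from, to, sep = "|")
  # NA = the (stratum, from) cell has no observations: undefined, which
  # conservatively fails the reliability threshold downstream
  table$rate[match(qkey, tkey)]
}

#' Symmetric error rate S for an allele pair
#'
#' The caller thresholds a symmetric function of the two directed rates,
#' `S = max(E(a -> b), E(b -> a))`, so that thresholding does not bias
#' towards whichever direction happens to be better estimated. Undefined in
#' strata where either directed rate is unresolvable.
#'
#' @inheritParams error_rate
#' @param a,b The SNP's two alleles.
#' @return `S` (vectorized), `NA` where undefined.
#' @export
symmetric_error <- function(table, library_type, pos_class, strand, mq, bq, a, b) {
  pmax(error_rate(table, library_type, pos_class, strand, mq, bq, a, b),
       error_rate(table, library_type, pos_class, strand, mq, bq, b, a))
}

#' Pseudo-haploid calling from a pileup
#'
#' For each biallelic site, observations whose symmetric error `S` is below
#' the threshold (default 0.02) and whose base matches the site's ref or alt
#' allele form the reliable pileup; one reliable base is selected uniformly
#' at random with an RNG keyed by `(seed, chrom, pos)`, so calls are
#' order-independent and reproducible. An empty reliable pileup yields a
#' missing call. The threshold is an upper bound on the error of every base
#' admitted to the pileup, hence on the achieved call error.
#'
#' @param pileup Pileup data frame covering one or many sites/individuals;
#'   calls are made per (library_id, chrom, pos).
#' @param table An `error_table` from [estimate_error_rates()].
#' @param threshold Reliability threshold on S (default 0.02).
#' @param seed Integer master seed for the keyed per-site RNG.
#' @return Data frame with one row per (library_id, chrom, pos): the called
#'   base (`NA` if missing) and the reliable-depth used.
#' @export
call_pseudohaploid <- function(pileup, table, threshold = 0.02, seed = 1) {
  if (nrow(pileup) == 0) {
    return(data.frame(library_id = character(0), chrom = character(0),
                      pos = integer(0), call = character(0),
                      reliable_depth = integer(0)))
  }
  S <- symmetric_error(table, pileup$library_type, pileup$pos_class,
                       pileup$strand, pileup$mq, pileup$bq,
                       pileup$ref, pileup$alt)
  reliable <- !is.na(S) & S < threshold &
    (pileup$base == pileup$ref | pileup$base == pileup$alt)
  grp <- paste(pileup$library_id, pileup$chrom, pileup$pos, sep = "\r")
  sites <- !duplicated(grp)
  out <- data.frame(library_id = pileup$library_id[sites],
                    chrom = pileup$chrom[sites], pos = pileup$pos[sites],
                    call = NA_character_, reliable_depth = 0L,
                    stringsAsFactors = FALSE)
  idx <- split(which(reliable), grp[reliable])
  keys <- site_key(seed, out$chrom, out$pos)
  gkey <- paste(out$library_id, out$chrom, out$pos, sep = "\r")
  rows <- idx[gkey]
  calls <- rep(NA_character_, nrow(out))
  depth <- integer(nrow(out))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (is.null(r) || length(r) == 0) next
    depth[i] <- length(r)
    if (length(r) == 1) {
      calls[i] <- pileup$base[r]
    } else {
      # canonical (sorted) base order so the keyed draw is independent of
      # the order reads arrive in
      bases <- sort(pileup$base[r])
      set.seed(keys[i])
      calls[i] <- bases[sample.int(length(bases), 1)]
    }
  }
  if (had) assign(".Random.seed", old, envir = globalenv())
  out$call <- calls
  out$reliable_depth <- depth
  out
}

#' Terminal-damage authenticity check
#'
#' Ancient-DNA libraries authenticate through residual terminal C-to-T
#' deamination; libraries with too little damage are flagged as potentially
#' contaminated: below 3% for UDG-treated libraries, below 10% for
#' non-UDG-treated libraries.
#'
#' @param terminal_ct_rate Terminal C-to-T substitution rate in `[0, 1]`.
#' @param udg_treated Logical; was the library UDG-treated?
#' @return Logical: `TRUE` if flagged as potentially contaminated.
#' @export
damage_qc <- function(terminal_ct_rate, udg_treated) {
  stop_if_not(all(terminal_ct_rate >= 0 & terminal_ct_rate <= 1),
              "rate must be in [0, 1]")
  ifelse(udg_treated, terminal_ct_rate < 0.03, terminal_ct_rate < 0.10)
}

#' Read/write pileup and error-table TSVs
#'
#' @param path TSV path.
#' @return `read_pileup`/`read_error_table` return data frames; writers
#'   return `path` invisibly.
#' @export
read_pileup <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_pileup
#' @param pileup Pileup data frame.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname read_pileup
#' @export
read_error_table <- function(path) {
  structure(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
            class = c("error_table", "data.frame"))
}

#' @rdname read_pileup
#' @param table An `error_table`.
#' @export
write_error_table <- function(table, path) {
  write.table(table, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Convert pseudo-haploid calls to a genotype matrix
#'
#' @param calls Output of [call_pseudohaploid()].
#' @param snp SNP table (id, chrom, gpos, ppos, ref, alt) defining site order.
#' @return A [genotype_matrix()] with one pseudo-haploid individual per
#'   `library_id`.
#' @export
calls_to_genotype_matrix <- function(calls, snp) {
  ids <- sort(unique(calls$library_id))
  mat <- matrix(NA_integer_, nrow(snp), length(ids))
  skey <- paste(snp$chrom, snp$ppos, sep = "\r")
  for (j in seq_along(ids)) {
    sub <- calls[calls$library_id == ids[j] & !is.na(calls$call), , drop = FALSE]
    row <- match(paste(sub$chrom, sub$pos, sep = "\r"), skey)
    ok <- !is.na(row)
    mat[row[ok], j] <- as.integer(sub$call[ok] == snp$alt[row[ok]])
  }
  genotype_matrix(mat, snp, data.frame(id = ids, ploidy = 1L, stringsAsFactors = FALSE))
}
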