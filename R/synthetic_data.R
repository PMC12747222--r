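#' Specify a demographic model for the synthetic-data generator
#'
#' A rooted population tree with per-edge drift plus optional two-source
#' admixture edges. Drift along each edge follows the Balding-Nichols law:
#' given parent frequency p and drift F, the child frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p(1-p).
#' F = 0 passes frequencies through unchanged.
#'
#' @param tree Data frame with columns `parent`, `child`, `F` (drift in
#'   `[0, 1)`). The root is the unique parent that never appears as a child.
#' @param admixture Optional data frame with columns `recipient`, `source_a`,
#'   `source_b`, `alpha` (weight on `source_a`, in `[0, 1]`) and optionally
#'   `F_residual` (post-admixture drift, default 0). Edges are applied in row
#'   order, so later recipients may use earlier ones as sources.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(tree, admixture = NULL) {
  tree <- as.data.frame(tree)
  stop_if_not(all(c("parent", "child", "F") %in% names(tree)),
              "tree needs columns parent, child, F")
  stop_if_not(all(tree$F >= 0 & tree$F < 1), "drift F must be in [0, 1)")
  stop_if_not(!anyDuplicated(tree$child), "each node may have only one tree parent")
  roots <- setdiff(tree$parent, tree$child)
  stop_if_not(length(unique(roots)) == 1, "tree must have exactly one root")
  # acyclicity: iteratively strip leaves
  edges <- tree
  while (nrow(edges) > 0) {
    leaf <- setdiff(edges$child, edges$parent)
    if (length(leaf) == 0) stop("tree contains a cycle", call. = FALSE)
    edges <- edges[!edges$child %in% leaf, , drop = FALSE]
  }
  if (!is.null(admixture)) {
    admixture <- as.data.frame(admixture)
    stop_if_not(all(c("recipient", "source_a", "source_b", "alpha") %in% names(admixture)),
                "admixture needs columns recipient, source_a, source_b, alpha")
    stop_if_not(all(admixture$alpha >= 0 & admixture$alpha <= 1),
                "alpha must be in [0, 1]")
    if (is.null(admixture$F_residual)) admixture$F_residual <- 0
    stop_if_not(all(admixture$F_residual >= 0 & admixture$F_residual < 1),
                "F_residual must be in [0, 1)")
  }
  leaves <- setdiff(tree$child, tree$parent)
  pops <- unique(c(leaves, if (!is.null(admixture)) admixture$recipient))
  structure(list(tree = tree, admixture = admixture, root = roots[1],
                 populations = pops, leaves = leaves),
            class = "demography_model")
}

#' Simulation configuration
#'
#' @param n_snps Number of biallelic SNPs.
#' @param samples_per_pop Individuals sampled per population.
#' @param missing_rate Per-(individual, SNP) missingness probability.
#' @param ancestral_freq_law Function of `n` drawing ancestral frequencies;
#'   default Uniform(0.05, 0.95), bounded away from 0/1 to avoid monomorphic
#'   sites.
#' @param n_blocks Number of contiguous jackknife blocks (>= 2).
#' @param seed Mandatory integer seed; one global RNG stream per run.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50000, samples_per_pop = 10, missing_rate = 0,
                       ancestral_freq_law = function(n) runif(n, 0.05, 0.95),
                       n_blocks = 50, seed) {
  stop_if_not(!missing(seed), "seed is mandatory")
  stop_if_not(n_snps >= n_blocks && n_blocks >= 2, "need n_snps >= n_blocks >= 2")
  stop_if_not(missing_rate >= 0 && missing_rate <= 1, "missing_rate must be in [0, 1]")
  structure(list(n_snps = as.integer(n_snps),
                 samples_per_pop = as.integer(samples_per_pop),
                 missing_rate = missing_rate,
                 ancestral_freq_law = ancestral_freq_law,
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols transition, vectorized over SNPs; F = 0 is the identity.
bn_drift <- function(p, F) {
  if (F == 0) return(p)
  k <- (1 - F) / F
  q <- rbeta(length(p), pmax(p * k, 1e-12), pmax((1 - p) * k, 1e-12))
  # guard against numerically fixed sites so downstream ratios stay defined
  pmin(pmax(q, 1e-9), 1 - 1e-9)
}

#' Simulate per-population allele frequencies under drift and admixture
#'
#' Ancestral frequencies are drawn from the configured law and propagated
#' down the tree with Balding-Nichols drift per edge; admixture edges then
#' set the recipient to \eqn{\alpha p_a + (1-\alpha) p_b} followed by optional
#' residual drift. Deterministic under the config seed.
#'
#' @param model A [demography_model()].
#' @param config A [sim_config()].
#' @return Numeric matrix, `n_snps` x population, of derived-allele
#'   frequencies for every model population (tree nodes and admixed groups).
#' @export
simulate_frequencies <- function(model, config) {
  stopifnot(inherits(model, "demography_model"), inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_snps
    nodes <- unique(c(model$tree$parent, model$tree$child))
    freq <- matrix(NA_real_, n, length(nodes), dimnames = list(NULL, nodes))
    freq[, model$root] <- config$ancestral_freq_law(n)
    todo <- model$tree
    while (nrow(todo) > 0) {
      ready <- which(!is.na(freq[1, todo$parent]))
      stop_if_not(length(ready) > 0, "tree is not connected to the root")
      for (k in ready) {
        freq[, todo$child[k]] <- bn_drift(freq[, todo$parent[k]], todo$F[k])
      }
      todo <- todo[-ready, , drop = FALSE]
    }
    if (!is.null(model$admixture)) {
      for (k in seq_len(nrow(model$admixture))) {
        e <- model$admixture[k, ]
        stop_if_not(e$source_a %in% colnames(freq) || e$source_a %in% colnames(freq),
                    "admixture source not available")
        p <- e$alpha * freq[, e$source_a] + (1 - e$alpha) * freq[, e$source_b]
        freq <- cbind(freq, bn_drift(p, e$F_residual))
        colnames(freq)[ncol(freq)] <- e$recipient
      }
    }
    freq
  })
}

#' Simulate pseudo-haploid genotypes from population frequencies
#'
#' Each individual carries one Bernoulli(p) allele per covered site
#' (`ploidy = 1`) or a Binomial(2, p) diploid dosage (`ploidy = 2`). Sites
#' are set missing independently at the configured rate; jackknife blocks are
#' assigned as equal-SNP-count contiguous runs. No linkage is simulated
#' between SNPs beyond the block labels.
#'
#' @param freqs Frequency matrix from [simulate_frequencies()] (columns are
#'   populations; only those named in `pops` are sampled).
#' @param config A [sim_config()].
#' @param pops Populations to sample; default all columns of `freqs`.
#' @param ploidy 1 (pseudo-haploid, default) or 2 (diploid).
#' @return List with `gm` (a [genotype_matrix()]), `groups` (a [group_map()])
#'   and `block` (per-SNP block index).
#' @export
simulate_genotypes <- function(freqs, config, pops = colnames(freqs), ploidy = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n <- nrow(freqs)
    m <- config$samples_per_pop
    calls <- matrix(NA_integer_, n, length(pops) * m)
    ids <- character(length(pops) * m)
    grp <- character(length(pops) * m)
    j <- 0L
    for (pop in pops) {
      p <- freqs[, pop]
      for (i in seq_len(m)) {
        j <- j + 1L
        calls[, j] <- rbinom(n, ploidy, p)
        ids[j] <- sprintf("%s_%d", pop, i)
        grp[j] <- pop
      }
    }
    if (config$missing_rate > 0) {
      calls[matrix(runif(length(calls)) < config$missing_rate,
                   nrow(calls), ncol(calls))] <- NA_integer_
    }
    snp <- data.frame(id = sprintf("rs%d", seq_len(n)), chrom = "1",
                      gpos = seq_len(n) * 1e-4, ppos = seq_len(n) * 10000L,
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
    gm <- genotype_matrix(calls, snp,
                          data.frame(id = ids, ploidy = as.integer(ploidy),
                                     stringsAsFactors = FALSE))
    block <- as.integer(ceiling(seq_len(n) / (n / config$n_blocks)))
    list(gm = gm, groups = group_map(ids, grp), block = block)
  })
}

#' Simulate allele-count tables directly
#'
#' Convenience generator for f-statistic studies: samples
#' Binomial(`chroms`, p) derived-allele counts per population without
#' materializing individuals. Equivalent to [simulate_genotypes()] followed by
#' [group_counts()] for pseudo-haploid samples with no missingness.
#'
#' @param freqs Frequency matrix (SNP x population).
#' @param chroms Observed chromosomes per population (scalar or named vector).
#' @param n_blocks Number of contiguous blocks.
#' @param seed Integer seed.
#' @return A [count_table()].
#' @export
simulate_counts <- function(freqs, chroms = 10, n_blocks = 50, seed) {
  with_seed(seed, {
    pops <- colnames(freqs)
    if (length(chroms) == 1) chroms <- setNames(rep(chroms, length(pops)), pops)
    n <- nrow(freqs)
    x <- matrix(0, n, length(pops), dimnames = list(NULL, pops))
    nn <- x
    for (pop in pops) {
      nn[, pop] <- chroms[[pop]]
      x[, pop] <- rbinom(n, chroms[[pop]], freqs[, pop])
    }
    block <- as.integer(ceiling(seq_len(n) / (n / n_blocks)))
    count_table(x, nn, block = block)
  })
}

#' Simulate ancient-DNA pileups from true genotypes
#'
#' Per covered site each individual receives a Poisson(`mean_depth`) stack of
#' reads; each read carries a strand, a read-position class (terminal within
#' 10 bp of either end, else central), MQ/BQ values and a library type, and
#' its base is the individual's true allele flipped according to the
#' stratified error profile. Deterministic under the seed.
#'
#' @param gm A [genotype_matrix()] of true genotypes (the truth, not calls).
#' @param mean_depth Mean read depth per site (Poisson), or a fixed depth if
#'   `fixed_depth = TRUE`.
#' @param error_profile Data frame with columns `library_type`, `pos_class`,
#'   `from`, `to`, `rate`: the probability that a read whose true base is
#'   `from` is observed as `to` in that stratum. Unlisted combinations have
#'   rate 0.
#' @param seed Integer seed.
#' @param fixed_depth Use a deterministic depth instead of Poisson.
#' @param p_terminal Probability a read covers the site within 10 bp of the
#'   5' (and likewise 3') end; remaining mass is central.
#' @param library_type Library type label per individual (recycled).
#' @return Data frame pileup with columns `chrom`, `pos`, `ref`, `alt`,
#'   `base`, `true_base`, `strand`, `pos_class`, `mq`, `bq`, `library_id`,
#'   `library_type`.
#' @export
simulate_pileups <- function(gm, mean_depth = 2, error_profile = NULL, seed,
                             fixed_depth = FALSE, p_terminal = 0.15,
                             library_type = "ds_UDG") {
  stopifnot(inherits(gm, "genotype_matrix"))
  stop_if_not(is.null(error_profile) || all(error_profile$rate >= 0 & error_profile$rate <= 1),
              "error rates must be in [0, 1]")
  library_type <- rep_len(library_type, nrow(gm$ind))
  with_seed(seed, {
    out <- vector("list", nrow(gm$ind))
    for (j in seq_len(nrow(gm$ind))) {
      dosage <- gm$calls[, j]
      covered <- which(!is.na(dosage))
      depth <- if (fixed_depth) rep(as.integer(mean_depth), length(covered)) else
        rpois(length(covered), mean_depth)
      keep <- depth > 0
      covered <- covered[keep]; depth <- depth[keep]
      if (!length(covered)) { out[[j]] <- NULL; next }
      s <- rep(covered, depth)
      ploidy <- gm$ind$ploidy[j]
      # true base per read: draw one of the individual's alleles
      alt_prob <- dosage[s] / ploidy
      is_alt <- runif(length(s)) < alt_prob
      true_base <- ifelse(is_alt, gm$snp$alt[s], gm$snp$ref[s])
      u <- runif(length(s))
      pos_class <- ifelse(u < p_terminal, "terminal_5",
                          ifelse(u < 2 * p_terminal, "terminal_3", "central"))
      strand <- ifelse(runif(length(s)) < 0.5, "+", "-")
      mq <- ifelse(runif(length(s)) < 0.9, 37L, 25L)
      bq <- sample(c(35L, 25L, 15L), length(s), replace = TRUE,
                   prob = c(0.8, 0.15, 0.05))
      base <- true_base
      if (!is.null(error_profile)) {
        for (k in seq_len(nrow(error_profile))) {
          e <- error_profile[k, ]
          hit <- true_base == e$from & pos_class == e$pos_class &
            library_type[j] == e$library_type
          flip <- hit & runif(length(s)) < e$rate
          base[flip] <- e$to
        }
      }
      out[[j]] <- data.frame(chrom = gm$snp$chrom[s], pos = gm$snp$ppos[s],
                             ref = gm$snp$ref[s], alt = gm$snp$alt[s],
                             base = base, true_base = true_base,
                             strand = strand, pos_class = pos_class,
                             mq = mq, bq = bq,
                             library_id = gm$ind$id[j],
                             library_type = library_type[j],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out) %||% data.frame()
  })
}

#' Simulate runs of homozygosity under constant effective size
#'
#' The genome of each individual is tiled by a renewal process of
#' homozygosity-by-descent segments: per segment a coalescence time g is drawn
#' from the length-biased stationary law Gamma(2, rate 1/(2 Ne)) -- so that the
#' time at a random genomic point is Exponential with mean 2 Ne generations,
#' the constant-Ne law -- and the segment length is Exponential with
#' recombination rate 2 g per Morgan. Only segments of at least `min_cM`
#' (hapROH's calling floor, 4 cM) are retained. When the expected number of
#' segments per chromosome is very large the equivalent marked-Poisson limit
#' for retained segments is used, with intensity
#' \eqn{8\beta/(2\ell+\beta)^3} per Morgan (\eqn{\beta = 1/(2 N_e)}).
#'
#' @param ne Diploid effective population size (> 0).
#' @param map_lengths Chromosome genetic map lengths in Morgans; default a
#'   22-autosome human-like map (~35.5 M total), see
#'   [default_chromosome_lengths()].
#' @param n_individuals Number of individuals.
#' @param seed Integer seed.
#' @param min_cM Calling floor in cM (default 4).
#' @return An object of class `roh_set`: list with `segments` (data frame
#'   `individual`, `chrom`, `start_cM`, `end_cM`, `length_cM`) and `meta`
#'   (per-individual `group`, `date_bp`, `covered_snps`, `weight`).
#' @export
simulate_roh <- function(ne, map_lengths = default_chromosome_lengths(),
                         n_individuals = 40, seed, min_cM = 4) {
  stop_if_not(ne > 0, "ne must be positive")
  stop_if_not(all(map_lengths > 0), "map lengths must be positive")
  beta <- 1 / (2 * ne)
  with_seed(seed, {
    segs <- list(); si <- 0L
    for (i in seq_len(n_individuals)) {
      for (ci in seq_along(map_lengths)) {
        L <- map_lengths[ci]
        expected <- L * 2 / beta          # renewal rate 1/E[len] = 2/beta
        if (expected <= 1e6) {
          starts <- numeric(0); lens <- numeric(0); pos <- 0
          while (pos < L) {
            batch <- max(64L, ceiling((L - pos) * 2 / beta * 1.2))
            g <- rgamma(batch, shape = 2, rate = beta)
            l <- rexp(batch, rate = 2 * g)
            cs <- pos + cumsum(l)
            starts <- c(starts, c(pos, head(cs, -1)))
            lens <- c(lens, l)
            pos <- cs[length(cs)]
          }
          ends <- pmin(starts + lens, L)
          keep <- starts < L & (ends - starts) >= min_cM / 100
          starts <- starts[keep]; ends <- ends[keep]
        } else {
          # Poisson limit: retained segments are rare events
          lam <- roh_intensity_tail(min_cM / 100, beta) * L
          k <- rpois(1, lam)
          if (k > 0) {
            lens <- roh_sample_lengths(k, min_cM / 100, beta)
            starts <- runif(k, 0, L)
            ends <- pmin(starts + lens, L)
            keep <- (ends - starts) >= min_cM / 100
            starts <- starts[keep]; ends <- ends[keep]
          } else starts <- ends <- numeric(0)
        }
        if (length(starts)) {
          si <- si + 1L
          segs[[si]] <- data.frame(individual = sprintf("ind%03d", i),
                                   chrom = as.character(ci),
                                   start_cM = starts * 100, end_cM = ends * 100,
                                   length_cM = (ends - starts) * 100,
                                   stringsAsFactors = FALSE)
        }
      }
    }
    segments <- if (si) do.call(rbind, segs) else
      data.frame(individual = character(0), chrom = character(0),
                 start_cM = numeric(0), end_cM = numeric(0), length_cM = numeric(0))
    meta <- data.frame(individual = sprintf("ind%03d", seq_len(n_individuals)),
                       group = "simulated", date_bp = 1000,
                       covered_snps = 600000, weight = 1,
                       stringsAsFactors = FALSE)
    roh_set(segments, meta)
  })
}

# Integrated intensity of retained segments (length >= a Morgans) per Morgan:
# integral of 8 beta / (2 l + beta)^3 from a to Inf = 2 beta / (2 a + beta)^2.
roh_intensity_tail <- function(a, beta) 2 * beta / (2 * a + beta)^2

# Inverse-CDF sampling of segment lengths (Morgans) from the truncated
# intensity on [a, Inf): survival S(l) = ((2a+beta)/(2l+beta))^2.
roh_sample_lengths <- function(k, a, beta) {
  u <- runif(k)
  ((2 * a + beta) / sqrt(u) - beta) / 2
}

#' Human-like autosomal genetic map lengths
#'
#' Approximate sex-averaged genetic lengths (Morgans) of the 22 human
#' autosomes, totalling about 35.5 Morgans.
#'
#' @return Named numeric vector of 22 map lengths.
#' @export
default_chromosome_lengths <- function() {
  setNames(c(2.86, 2.69, 2.23, 2.14, 2.04, 1.92, 1.87, 1.70, 1.68, 1.81,
             1.58, 1.75, 1.26, 1.20, 1.42, 1.35, 1.30, 1.19, 1.08, 1.08,
             0.62, 0.74), as.character(1:22))
}

#' Simulate a pair of relatives as pseudo-haploid genotype vectors
#'
#' Two diploid genomes are constructed so that a fraction \eqn{2^{1-d}} of
#' sites share exactly one haplotype identical by descent (degree d >= 1);
#' degree 0 ("identical") shares both haplotypes, and `degree = Inf` (or
#' `"unrelated"`) shares none. Pseudo-haploid sampling (one random allele per
#' site) is applied independently afterwards. Expected pairwise mismatch
#' rates relative to the unrelated baseline b = mean 2p(1-p) are 0.5, 0.75,
#' 0.875 and 1 for identical, 1st, 2nd degree and unrelated.
#'
#' @param freqs Vector of allele frequencies (one per site).
#' @param degree 0 (identical), 1, 2, 3, or `Inf`/"unrelated".
#' @param seed Integer seed.
#' @return List with integer vectors `a` and `b` (pseudo-haploid calls) and
#'   the underlying shared-haplotype mask `shared`.
#' @export
simulate_relative_pair <- function(freqs, degree, seed) {
  if (identical(degree, "unrelated")) degree <- Inf
  stop_if_not(degree >= 0, "degree must be >= 0")
  with_seed(seed, {
    n <- length(freqs)
    h1a <- as.integer(runif(n) < freqs)  # shared candidate haplotype
    h1b <- as.integer(runif(n) < freqs)
    h2a <- as.integer(runif(n) < freqs)
    h2b <- as.integer(runif(n) < freqs)
    if (degree == 0) {
      g2a <- h1a; g2b <- h1b; shared <- rep(TRUE, n)
    } else if (is.infinite(degree)) {
      g2a <- h2a; g2b <- h2b; shared <- rep(FALSE, n)
    } else {
      frac <- 2^(1 - degree)
      shared <- runif(n) < frac
      g2a <- ifelse(shared, h1a, h2a); g2b <- h2b
    }
    a <- ifelse(runif(n) < 0.5, h1a, h1b)
    b <- ifelse(runif(n) < 0.5, g2a, g2b)
    list(a = as.integer(a), b = as.integer(b), shared = shared)
  })
}
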