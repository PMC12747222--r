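#' Generate the bundled synthetic fixture set
#'
#' Deterministic desk-scale bundle: a six-population demography with one
#' admixture event (EIGENSTRAT trio + group map), pileups for four
#' individuals, ROH tables for three groups at different effective sizes,
#' and two related pairs. Every file is plain text and loads through the
#' package's own readers; a truth YAML records the generating parameters so
#' tests can assert recovery.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_snps,n_blocks Genotype design sizes.
#' @return Invisible list of file paths and the truth parameters.
#' @export
make_fixtures <- function(dir, seed = 1, n_snps = 5e4, n_blocks = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  tree <- rbind(
    data.frame(parent = "root", child = "Outgroup", F = 0.08),
    data.frame(parent = "root", child = "x1", F = 0.02),
    data.frame(parent = "x1", child = "North", F = 0.04),
    data.frame(parent = "x1", child = "x2", F = 0.02),
    data.frame(parent = "x2", child = "Center", F = 0.04),
    data.frame(parent = "x2", child = "x3", F = 0.02),
    data.frame(parent = "x3", child = "South", F = 0.04),
    data.frame(parent = "x3", child = "Coast", F = 0.04))
  adm <- data.frame(recipient = "Admixed", source_a = "North", source_b = "South",
                    alpha = 0.3, F_residual = 0.01)
  model <- demography_model(tree, adm)
  cfg <- sim_config(n_snps = n_snps, samples_per_pop = 8, missing_rate = 0.05,
                    n_blocks = n_blocks, seed = seed)
  freqs <- simulate_frequencies(model, cfg)
  pops <- c("Outgroup", "North", "Center", "South", "Coast", "Admixed")
  sim <- simulate_genotypes(freqs, cfg, pops = pops)
  write_eigenstrat(sim$gm, pth("fixture"), groups = sim$groups)
  write_group_map(sim$groups, pth("fixture_groups.tsv"))
  # pileups for 4 individuals at damage-prone C/T sites
  sub <- sim$gm
  keep_ind <- sim$gm$ind$id[seq(1, nrow(sim$gm$ind), length.out = 4)]
  j <- match(keep_ind, sim$gm$ind$id)
  gm4 <- genotype_matrix(sim$gm$calls[seq_len(2000), j, drop = FALSE],
                         sim$gm$snp[seq_len(2000), ],
                         sim$gm$ind[j, c("id", "ploidy")])
  profile <- data.frame(library_type = "ds_UDG",
                        pos_class = c("terminal_5", "terminal_3", "central"),
                        from = "C", to = "T", rate = c(0.25, 0.25, 0.004))
  pu <- simulate_pileups(gm4, mean_depth = 2, error_profile = profile,
                         seed = seed + 11)
  write_pileup(pu, pth("fixture_pileup.tsv"))
  # ROH sets for three groups
  nes <- c(North = 400, Center = 1200, South = 3000)
  rsets <- lapply(seq_along(nes), function(i) {
    rs <- simulate_roh(nes[i], n_individuals = 12, seed = seed + 100 + i)
    rs$meta$group <- names(nes)[i]
    rs$meta$individual <- paste0(names(nes)[i], "_", rs$meta$individual)
    rs$segments$individual <- paste0(names(nes)[i], "_", rs$segments$individual)
    rs$meta$date_bp <- with_seed(seed + 200 + i, round(runif(12, 500, 2400)))
    rs
  })
  roh <- roh_set(do.call(rbind, lapply(rsets, `[[`, "segments")),
                 do.call(rbind, lapply(rsets, `[[`, "meta")))
  write_roh(roh, pth("fixture_roh"))
  # two related pairs
  pr1 <- simulate_relative_pair(freqs[, "Center"], 1, seed = seed + 301)
  pr2 <- simulate_relative_pair(freqs[, "Center"], 2, seed = seed + 302)
  write.table(data.frame(site = seq_along(pr1$a), first_a = pr1$a, first_b = pr1$b,
                         second_a = pr2$a, second_b = pr2$b),
              pth("fixture_pairs.tsv"), quote = FALSE, sep = "\t", row.names = FALSE)
  truth <- list(seed = seed, n_snps = n_snps, n_blocks = n_blocks,
                alpha = 0.3, admixed = "Admixed",
                sources = c("North", "South"), ne = as.list(nes))
  yaml::write_yaml(truth, pth("fixture_truth.yaml"))
  invisible(list(prefix = pth("fixture"),
                 groups = pth("fixture_groups.tsv"),
                 pileup = pth("fixture_pileup.tsv"),
                 roh_prefix = pth("fixture_roh"),
                 pairs = pth("fixture_pairs.tsv"),
                 truth = truth))
}

#' Run the full analysis pipeline on a configuration
#'
#' Sequences the stack in dependency order -- genotype input, site filtering,
#' group counts, f-statistics with BY correction, qpAdm, outgroup-f3
#' distances with MDS and neighbor joining, kinship screening, and ROH
#' demography -- writing per-stage outputs and a JSON manifest with input
#' checksums and seeds. Completed stages (outputs already present) are
#' skipped on re-runs unless `force = TRUE`.
#'
#' @param config Either a YAML path or a list with entries `geno_prefix`,
#'   `groups`, `out_dir`, `seed`, and optionally `outgroup`, `target`,
#'   `sources`, `refs`, `roh_prefix`, `stages` (character subset of
#'   c("fstats", "qpadm", "structure", "kinship", "roh")), and thresholds
#'   `maxmiss` (0.15), `fdr` (0.05), `fst_min_snps` (5000),
#'   `roh_min_snps` (400000).
#' @param force Recompute stages whose outputs already exist.
#' @return The manifest list, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (req in c("geno_prefix", "groups", "out_dir", "seed")) {
    stop_if_not(!is.null(config[[req]]), paste0("config missing: ", req))
  }
  for (f in paste0(config$geno_prefix, c(".geno", ".snp", ".ind"))) {
    stop_if_not(file.exists(f), paste0("missing input: ", f))
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("fstats", "qpadm", "structure", "kinship", "roh")
  manifest <- list(seed = config$seed, stages = list(),
                   inputs = as.list(tools::md5sum(paste0(config$geno_prefix,
                                                         c(".geno", ".snp", ".ind")))))
  done <- function(files) all(file.exists(files)) && !force
  gm <- read_eigenstrat(config$geno_prefix)
  groups <- read_group_map(config$groups)
  block <- assign_blocks(gm)
  counts <- filter_sites(group_counts(gm, groups, block = block),
                         maxmiss = config$maxmiss %||% 0.15)
  manifest$snps <- unname(attr(counts, "report")["kept"])
  pops <- unique(unname(groups))
  og <- config$outgroup %||% pops[1]

  if ("fstats" %in% stages) {
    f <- file.path(out, "f4_stats.tsv")
    if (!done(f)) {
      others <- setdiff(pops, og)
      quads <- if (length(others) >= 4) combn(others, 4, simplify = FALSE) else list()
      rows <- lapply(quads, function(q) {
        fs <- f4_stat(counts, og, q[1], q[2], q[3])
        data.frame(A = og, B = q[1], C = q[2], D = q[3], estimate = fs$estimate,
                   se = fs$se, z = fs$z, n_snps = fs$n_snps, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      if (!is.null(tab) && nrow(tab)) {
        tab <- cbind(tab, by_correct(tab$z, fdr = config$fdr %||% 0.05)[
          c("p", "p_by", "significant", "z_by")])
      }
      write.table(tab, f, quote = FALSE, sep = "\t", row.names = FALSE)
    }
    manifest$stages$fstats <- f
  }
  if ("qpadm" %in% stages && !is.null(config$target)) {
    f <- file.path(out, "qpadm.json")
    if (!done(f)) {
      fit <- qpadm_fit(counts, config$target, unlist(config$sources),
                       unlist(config$refs))
      jsonlite::write_json(list(target = fit$target, sources = fit$sources,
                                weights = unname(fit$weights),
                                se = unname(fit$se), p = fit$p,
                                feasible = fit$feasible, n_snps = fit$n_snps),
                           f, auto_unbox = TRUE, digits = NA)
    }
    manifest$stages$qpadm <- f
  }
  if ("structure" %in% stages) {
    f_mds <- file.path(out, "mds.tsv"); f_nj <- file.path(out, "nj.nwk")
    if (!done(c(f_mds, f_nj))) {
      labs <- setdiff(pops, og)
      D <- outgroup_f3_distance(counts, labs, og)
      md <- classical_mds(D, k = 2)
      write.table(data.frame(pop = rownames(md$points), md$points),
                  f_mds, quote = FALSE, sep = "\t", row.names = FALSE)
      ape::write.tree(neighbor_joining(D), f_nj)
    }
    manifest$stages$structure <- c(f_mds, f_nj)
  }
  if ("kinship" %in% stages) {
    f <- file.path(out, "kinship.tsv")
    if (!done(f)) {
      scr <- suppressWarnings(kinship_screen(gm, block = block,
                                             min_overlap = config$kin_min_overlap %||% 5000))
      write.table(scr, f, quote = FALSE, sep = "\t", row.names = FALSE)
    }
    manifest$stages$kinship <- f
  }
  if ("roh" %in% stages && !is.null(config$roh_prefix)) {
    f <- file.path(out, "roh_ne.tsv")
    if (!done(f)) {
      rs <- read_roh(paste0(config$roh_prefix, "_segments.tsv"),
                     paste0(config$roh_prefix, "_meta.tsv"))
      rs <- eligibility_filter(rs, min_snps = config$roh_min_snps %||% 400000,
                               for_ne = TRUE)
      rows <- lapply(split(seq_len(nrow(rs$meta)), rs$meta$group), function(ix) {
        sub <- roh_set(rs$segments[rs$segments$individual %in%
                                     rs$meta$individual[ix], , drop = FALSE],
                       rs$meta[ix, , drop = FALSE])
        est <- ne_mle(sub)
        data.frame(group = rs$meta$group[ix[1]], ne = est$ne,
                   ci_lo = est$ci[1], ci_hi = est$ci[2],
                   n_ind = est$n_ind, n_segments = est$n_segments)
      })
      write.table(do.call(rbind, rows), f, quote = FALSE, sep = "\t",
                  row.names = FALSE)
    }
    manifest$stages$roh <- f
  }
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
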