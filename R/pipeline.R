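# End-to-end orchestration: simulate or load inputs, filter, window
# statistics, outlier scan, phylogeny, and a written artifact bundle.

#' Pipeline run configuration
#'
#' All module parameters with their standard defaults: pooled-MAF depth
#' filter 15 reads and at least 2 variant reads, caller maximum quality 999,
#' indel exclusion 3 bp, 50-kb windows with 25-kb step, at least 100 variant
#' sites per window for F_ST, 5\% run tails and 1\% extreme tails with at
#' least 2 consecutive outlier windows. Exactly one of \code{sim} (a
#' \code{\link{sim_config}}) or \code{paths} (named list with entries
#' \code{vcf}, \code{lengths}, \code{pop_map} and optionally \code{counts},
#' \code{genes}) must be given.
#'
#' @param sim a \code{\link{sim_config}}, or NULL to read real inputs.
#' @param paths named list of input paths, or NULL to simulate.
#' @param out_dir output directory for the artifact bundle.
#' @param min_depth,min_variant_reads pooled-MAF site filters.
#' @param max_qual,indel_exclusion variant-retention filters.
#' @param window_size,window_step window tiling in bp.
#' @param min_fst_sites minimum variant sites per window for F_ST.
#' @param min_sites_maf minimum contributing sites per window for mean MAF.
#' @param include_monomorphic include zero-variant-read sites as MAF 0.
#' @param fst_method \code{"weighted"} (ratio of sums) or \code{"mean"}.
#' @param scan a \code{\link{scan_config}}.
#' @param pool_sample name of the pool sample in the VCF.
#' @param tree logical: compute the IBS neighbor-joining tree.
#' @param tree_boot_reps bootstrap replicates for the tree.
#' @param max_tree_sites at most this many SNPs (evenly subsampled) enter
#'   the distance matrix and bootstrap.
#' @param seed integer master seed for all randomness in the run.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, paths = NULL, out_dir = tempfile("scan"),
                       min_depth = 15, min_variant_reads = 2,
                       max_qual = 999, indel_exclusion = 3,
                       window_size = 50000, window_step = 25000,
                       min_fst_sites = 100, min_sites_maf = 1,
                       include_monomorphic = FALSE,
                       fst_method = "weighted",
                       scan = scan_config(),
                       pool_sample = "POOL",
                       tree = TRUE, tree_boot_reps = 100,
                       max_tree_sites = 20000,
                       seed = 1) {
  if (is.null(sim) == is.null(paths))
    stop("exactly one of sim / paths must be given")
  structure(as.list(environment()), class = "run_config")
}

# population labels for the simulated design: species letter, pool separate
sim_pop_map <- function(samples, pool_sample = "POOL") {
  pops <- ifelse(samples == pool_sample, "focal",
                 substr(samples, 1L, 1L))
  stats::setNames(pops, samples)
}

#' Run the full scan
#'
#' Orchestrates the pipeline end to end: obtain inputs (simulated or from
#' disk), apply the variant-retention filters, estimate pooled MAF per site,
#' tile windows and aggregate mean MAF and weighted F_ST, run the joint
#' quantile-tail outlier scan, annotate candidate regions with genes,
#' compute conspecific fixed-difference window counts, and build the IBS
#' neighbor-joining tree with bootstrap supports. Writes the artifact bundle
#' to \code{cfg$out_dir} and returns the in-memory results.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return invisible list with elements \code{window_stats},
#'   \code{regions}, \code{tree} (or NULL), \code{fixed_diffs},
#'   \code{summary} and \code{paths}.
#' @export
run_scan <- function(cfg) {
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  writeLines(character(0), log_path)

  truth <- NULL
  if (!is.null(cfg$sim)) {
    cfg$sim$seed <- cfg$seed
    ds <- simulate_dataset(cfg$sim)
    sites <- data.frame(scaffold = ds$freqs$scaffold, pos = ds$freqs$pos,
                        ref = "A", alt = "T", qual = cfg$max_qual,
                        type = "snp", n_alt = 1L, stringsAsFactors = FALSE)
    geno <- ds$geno
    rownames(geno) <- NULL
    pool_counts <- ds$pool[, c("ref_count", "alt_count")]
    lengths_tab <- ds$scaffold_lengths
    genes <- toy_gene_annotation(ds$cfg)
    pops <- sim_pop_map(ds$samples, cfg$pool_sample)
    sample_names <- setdiff(ds$samples, cfg$pool_sample)
    colnames(geno) <- sample_names
    truth <- ds$truth
    logf("simulated dataset: %d sites, seed %d", nrow(sites), cfg$seed)
  } else {
    p <- cfg$paths
    for (need in c("vcf", "lengths", "pop_map"))
      if (is.null(p[[need]]) || !file.exists(p[[need]]))
        stop("missing or unreadable input: ", need)
    vv <- read_vcf_sites(p$vcf, cfg$pool_sample)
    sites <- vv$sites
    geno <- vv$geno
    sample_names <- setdiff(colnames(geno), cfg$pool_sample)
    geno <- geno[, sample_names, drop = FALSE]
    pool_counts <- if (!is.null(p$counts)) {
      ct <- read_pool_counts(p$counts)
      data.frame(ref_count = ct$refCount, alt_count = ct$altCount)
    } else vv$pool_counts
    if (is.null(pool_counts))
      stop("no pool allele counts: provide a counts table or a VCF AD field")
    lengths_tab <- read_scaffold_lengths(p$lengths)
    genes <- if (!is.null(p$genes)) read_bed(p$genes) else NULL
    pm <- read_pop_map(p$pop_map)
    pops <- pm$pops
    missing_pop <- setdiff(c(sample_names, cfg$pool_sample),
                           c(names(pops), pm$excluded))
    if (length(missing_pop) > 0L)
      stop("samples missing from population map: ",
           paste(missing_pop, collapse = ", "))
    logf("loaded %d sites from %s", nrow(sites), p$vcf)
  }

  # variant retention
  n0 <- nrow(sites)
  keep_tab <- filter_variants(sites, max_qual = cfg$max_qual,
                              indel_exclusion = cfg$indel_exclusion)
  keep <- rownames(sites) %in% rownames(keep_tab)
  logf("retention filter: %d of %d records kept (removed: %d low-quality/indel/multiallelic or indel-adjacent)",
       sum(keep), n0, n0 - sum(keep))
  sites <- sites[keep, , drop = FALSE]
  geno <- geno[keep, , drop = FALSE]
  pool_counts <- pool_counts[keep, , drop = FALSE]

  # pooled MAF
  maf_tab <- pool_maf_table(cbind(ref = pool_counts$ref_count,
                                  alt = pool_counts$alt_count),
                            min_depth = cfg$min_depth,
                            min_variant_reads = cfg$min_variant_reads)
  site_maf <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                         maf = maf_tab$maf, status = maf_tab$status,
                         stringsAsFactors = FALSE)
  for (st in c("ok", "low_depth", "singleton_variant", "monomorphic"))
    logf("MAF sites with status %s: %d", st, sum(maf_tab$status == st))

  # F_ST: individuals plus pseudodiploid pool, per population
  pool_dosage <- encode_pseudodiploid(pool_counts$ref_count,
                                      pool_counts$alt_count,
                                      min_depth = cfg$min_depth,
                                      min_variant_reads = cfg$min_variant_reads)
  fst_geno <- cbind(geno, pool_dosage)
  fst_samples <- c(colnames(geno), cfg$pool_sample)
  fst_pops <- unname(pops[fst_samples])
  use_col <- !is.na(fst_pops)
  vc <- wc_components(fst_geno[, use_col, drop = FALSE], fst_pops[use_col])
  vc$scaffold <- sites$scaffold
  vc$pos <- sites$pos

  # windows
  windows <- tile_windows(lengths_tab, cfg$window_size, cfg$window_step)
  ws <- window_mean_maf(site_maf, windows, cfg$window_size, cfg$window_step,
                        min_sites_maf = cfg$min_sites_maf,
                        include_monomorphic = cfg$include_monomorphic)
  ws <- window_fst(vc, ws, cfg$window_size, cfg$window_step,
                   min_sites = cfg$min_fst_sites)
  logf("windows: %d tiled, %d with both statistics defined", nrow(ws),
       sum(!is.na(ws$mean_maf) & !is.na(ws$fst)))

  # outlier scan
  flagged <- joint_quantile_flags(ws, cfg$scan)
  regions <- merge_outlier_runs(flagged, cfg$scan)
  if (!is.null(genes)) regions <- annotate_regions(regions, genes)
  logf("candidate regions: %d sweep, %d balancing",
       sum(regions$type == "sweep"), sum(regions$type == "balancing"))

  # conspecific fixed differences in non-overlapping windows
  nw <- tile_windows(lengths_tab, cfg$window_size, cfg$window_size)
  pops_ind <- pops[colnames(geno)]
  fixed <- NULL
  for (pp in unique(pops_ind)) {
    cols <- which(pops_ind == pp)
    if (length(cols) < 2L) next
    fd <- window_fixed_differences(sites$scaffold, sites$pos,
                                   geno[, cols[1L]], geno[, cols[2L]],
                                   nw, cfg$window_size)
    fd$pair <- paste(colnames(geno)[cols[1:2]], collapse = "-")
    fixed <- rbind(fixed, fd)
  }

  # IBS neighbor-joining tree with pseudodiploid pool
  tree_res <- NULL
  if (isTRUE(cfg$tree)) {
    tg <- t(fst_geno)
    rownames(tg) <- fst_samples
    if (ncol(tg) > cfg$max_tree_sites) {
      pick <- round(seq(1L, ncol(tg), length.out = cfg$max_tree_sites))
      tg <- tg[, pick, drop = FALSE]
    }
    tree_res <- bootstrap_support(tg, n_reps = cfg$tree_boot_reps,
                                  seed = cfg$seed + 1L)
  }

  # artifact bundle
  paths <- list(window_stats = file.path(cfg$out_dir, "window_stats.tsv"),
                regions_bed = file.path(cfg$out_dir, "regions.bed"),
                regions_tsv = file.path(cfg$out_dir, "regions.tsv"),
                tree = file.path(cfg$out_dir, "tree.nwk"),
                fixed = file.path(cfg$out_dir, "fixed_differences.tsv"),
                summary = file.path(cfg$out_dir, "summary.json"),
                log = log_path)
  write_window_stats(flagged, paths$window_stats)
  write_regions_bed(regions, paths$regions_bed)
  utils::write.table(regions, paths$regions_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(tree_res))
    ape::write.tree(tree_res$tree, paths$tree)
  if (!is.null(fixed))
    utils::write.table(fixed, paths$fixed, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  summary <- list(
    seed = cfg$seed,
    n_sites_input = n0,
    n_sites_retained = nrow(sites),
    n_windows = nrow(ws),
    n_windows_analyzed = sum(flagged$analyzed),
    n_sweep_run_flagged = sum(flagged$sweep_run),
    n_balancing_run_flagged = sum(flagged$balancing_run),
    n_regions_sweep = sum(regions$type == "sweep"),
    n_regions_balancing = sum(regions$type == "balancing"))
  if (!is.null(truth)) {
    ev <- evaluate_recovery(regions, truth, flagged)
    summary <- c(summary, ev[c("n_truth_sweep", "n_truth_balancing",
                               "recovered_sweep", "recovered_balancing",
                               "false_regions", "n_background_windows")])
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logf("parameters: min_depth=%d min_variant_reads=%d max_qual=%d window=%d step=%d min_fst_sites=%d run_tail=%g extreme_tail=%g min_run=%d",
       cfg$min_depth, cfg$min_variant_reads, cfg$max_qual, cfg$window_size,
       cfg$window_step, cfg$min_fst_sites, cfg$scan$run_tail,
       cfg$scan$extreme_tail, cfg$scan$min_run)
  invisible(list(window_stats = flagged, regions = regions,
                 tree = tree_res, fixed_diffs = fixed, summary = summary,
                 truth = truth, paths = paths))
}

#' Compare reported regions with planted truth
#'
#' A truth region counts as recovered if some reported region of the same
#' type shares at least one bp with it; a reported region not overlapping
#' any truth region of its type is a false region. Background windows are
#' analyzed windows not overlapping any truth region.
#'
#' @param regions reported regions (\code{\link{merge_outlier_runs}}).
#' @param truth truth-region table (scaffold, start, end, type).
#' @param flagged window table with an \code{analyzed} column, or NULL to
#'   skip the background-window count.
#' @return list with counts: truth regions per type, recovered per type,
#'   false regions, background windows.
#' @export
evaluate_recovery <- function(regions, truth, flagged = NULL) {
  overlaps <- function(a, b)
    a$scaffold == b$scaffold & a$start < b$end & b$start < a$end
  rec <- function(type) {
    tt <- truth[truth$type == type, , drop = FALSE]
    rr <- regions[regions$type == type, , drop = FALSE]
    hit <- vapply(seq_len(nrow(tt)), function(i)
      any(overlaps(rr, tt[i, ])), logical(1))
    sum(hit)
  }
  false_region <- vapply(seq_len(nrow(regions)), function(i) {
    tt <- truth[truth$type == regions$type[i], , drop = FALSE]
    !any(overlaps(tt, regions[i, ]))
  }, logical(1))
  n_bg <- NA_integer_
  if (!is.null(flagged)) {
    an <- flagged[flagged$analyzed, , drop = FALSE]
    in_truth <- vapply(seq_len(nrow(an)), function(i)
      any(overlaps(truth, an[i, ])), logical(1))
    n_bg <- sum(!in_truth)
  }
  list(n_truth_sweep = sum(truth$type == "sweep"),
       n_truth_balancing = sum(truth$type == "balancing"),
       recovered_sweep = rec("sweep"),
       recovered_balancing = rec("balancing"),
       false_regions = sum(false_region),
       n_background_windows = n_bg)
}
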