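# Readers and writers for the standard formats the pipeline consumes and
# emits. Positions are 1-based in VCF and the count table, 0-based
# half-open in BED; internal tables follow the format they mirror.

#' Write a simulated dataset to disk
#'
#' Emits the full input bundle for a pipeline run: a multisample VCF 4.2
#' (GT for individuals, GT:AD for the pool, all records at the caller
#' maximum quality), a per-site allele-count TSV for the pool, a
#' scaffold-length TSV, a toy gene annotation BED and the truth-region BED.
#'
#' @param ds a \code{sim_dataset} from \code{\link{simulate_dataset}}.
#' @param out_dir output directory (created if missing).
#' @param max_qual quality written for every record.
#' @return invisibly, a named list of the file paths written.
#' @export
write_dataset <- function(ds, out_dir, max_qual = 999) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "sites.vcf"),
    counts = file.path(out_dir, "pool_counts.tsv"),
    lengths = file.path(out_dir, "scaffolds.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    truth = file.path(out_dir, "truth_regions.bed"))

  f <- ds$freqs
  n <- nrow(f)
  # VCF
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep-simulate",
    sprintf("##contig=<ID=%s,length=%d>", ds$scaffold_lengths$scaffold,
            ds$scaffold_lengths$length),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  ind <- apply(ds$geno, 2, function(g) paste0(gt_str[g + 1L], ":."))
  pool_gt <- encode_pseudodiploid(ds$pool$ref_count, ds$pool$alt_count)
  pool_col <- paste0(ifelse(is.na(pool_gt), "./.", gt_str[pool_gt + 1L]),
                     ":", ds$pool$ref_count, ",", ds$pool$alt_count)
  body <- paste(f$scaffold, f$pos, ".", "A", "T", max_qual, "PASS", ".",
                "GT:AD",
                apply(cbind(ind, pool_col), 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), paths$vcf)

  # pool count table
  utils::write.table(
    data.frame(scaffold = f$scaffold, pos = f$pos, ref = "A", alt = "T",
               refCount = ds$pool$ref_count, altCount = ds$pool$alt_count),
    paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.table(ds$scaffold_lengths, paths$lengths, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  genes <- toy_gene_annotation(ds$cfg)
  utils::write.table(genes[, c("scaffold", "start", "end", "gene_id")],
                     paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  tr <- ds$truth
  utils::write.table(tr[, c("scaffold", "start", "end", "type")],
                     paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a multisample VCF into a site table
#'
#' Parses a VCF with \code{vcfR} into the table the pipeline operates on:
#' per-site metadata, a dosage matrix for the genotyped samples and, if an
#' \code{AD} field is present for the pool sample, the pool's ref/alt read
#' counts. Multiallelic records are kept in the table (flagged by
#' \code{n_alt}) so that the retention filter can drop them; indels are
#' classified by allele length.
#'
#' @param path VCF file path.
#' @param pool_sample name of the pool sample column, or NULL for none.
#' @return list with \code{sites} (data.frame: scaffold, pos, ref, alt,
#'   qual, type, n_alt), \code{geno} (dosage matrix, sites x samples) and
#'   \code{pool_counts} (data.frame ref_count/alt_count or NULL).
#' @export
read_vcf_sites <- function(path, pool_sample = "POOL") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  is_indel <- nchar(fix[, "REF"]) != 1L |
    vapply(strsplit(alt, ",", fixed = TRUE),
           function(a) any(nchar(a) != 1L), logical(1))
  sites <- data.frame(
    scaffold = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt,
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    type = ifelse(is_indel, "indel", "snp"),
    n_alt = n_alt, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  pool_counts <- NULL
  if (!is.null(pool_sample) && pool_sample %in% colnames(gt)) {
    ad <- vcfR::extract.gt(v, element = "AD")[, pool_sample]
    parts <- strsplit(ad, ",", fixed = TRUE)
    rc <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    ac <- suppressWarnings(as.integer(vapply(parts, function(x)
      if (length(x) >= 2L) x[2L] else NA_character_, "")))
    pool_counts <- data.frame(ref_count = rc, alt_count = ac)
  }
  list(sites = sites, geno = dos, pool_counts = pool_counts)
}

#' Read a per-site pool allele-count table
#'
#' @param path TSV with header columns scaffold, pos, ref, alt, refCount,
#'   altCount (extra allele-count columns are preserved).
#' @return data.frame as on disk.
#' @export
read_pool_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read scaffold lengths (FASTA .fai style: first two columns)
#'
#' @param path TSV without header; column 1 scaffold name, column 2 length.
#' @return data.frame with columns \code{scaffold}, \code{length}.
#' @export
read_scaffold_lengths <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  data.frame(scaffold = x[[1]], length = as.numeric(x[[2]]),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path BED path (0-based half-open); columns beyond the fourth are
#'   ignored.
#' @param name_col name to give the fourth column (default
#'   \code{"gene_id"}).
#' @return data.frame with columns \code{scaffold}, \code{start},
#'   \code{end} and, if present, the name column.
#' @export
read_bed <- function(path, name_col = "gene_id") {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(scaffold = x[[1]], start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4L) out[[name_col]] <- x[[4]]
  out
}

#' Read a sample-to-population map
#'
#' @param path TSV without header: column 1 sample, column 2 population;
#'   a sample mapped to the population \code{"-"} is excluded.
#' @return list with \code{pops} (named character vector) and
#'   \code{excluded} (character vector of excluded samples).
#' @export
read_pop_map <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  excl <- x[[1]][x[[2]] == "-"]
  keep <- x[[2]] != "-"
  pops <- stats::setNames(x[[2]][keep], x[[1]][keep])
  list(pops = pops, excluded = excl)
}

#' Write the window-statistics table
#'
#' One row per window with both coordinates, site counts, mean pooled MAF
#' and windowed F_ST; numeric statistics are written with fixed formatting
#' so repeated runs are byte-identical.
#'
#' @param ws window-stats data.frame.
#' @param path output TSV path.
#' @export
write_window_stats <- function(ws, path) {
  out <- ws
  for (col in c("mean_maf", "fst"))
    if (col %in% names(out))
      out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                           sprintf("%.6f", out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write candidate regions as BED
#'
#' BED name is the region type, score the member-window count.
#'
#' @param regions region data.frame from \code{\link{merge_outlier_runs}}.
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  utils::write.table(
    data.frame(regions$scaffold, regions$start, regions$end,
               regions$type, regions$n_windows),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
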