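# Per-site filters and the pooled minor-allele-frequency estimator.

#' Pooled minor allele frequency at one site
#'
#' Estimates the folded minor allele frequency of a population pool directly
#' from per-allele read counts, applying the standard pool-seq retention
#' filters: sites with fewer than \code{min_depth} aligned reads are dropped,
#' as are sites whose non-major reads number at least one but fewer than
#' \code{min_variant_reads} (a lone variant read is indistinguishable from a
#' sequencing error). The MAF is the summed frequency of all non-major
#' alleles, so tri- and tetra-allelic sites are handled by the same rule.
#'
#' @param counts named numeric vector of read counts per allele (names are
#'   allele strings, typically A/C/G/T). All counts must be non-negative and
#'   at least one must be positive.
#' @param min_depth minimum total read depth for a site to be used.
#' @param min_variant_reads minimum number of non-major reads for a site to
#'   count as polymorphic; sites below this (but above zero) are discarded
#'   rather than treated as monomorphic.
#' @return a list with elements \code{maf} (numeric or \code{NA}),
#'   \code{depth}, \code{status} (one of \code{"ok"}, \code{"low_depth"},
#'   \code{"singleton_variant"}, \code{"monomorphic"}) and
#'   \code{major_allele}. \code{maf} is non-\code{NA} only when
#'   \code{status == "ok"}.
#' @details When two alleles tie for the maximum count the lexicographically
#'   smallest allele is taken as major, which makes the estimator
#'   deterministic; the MAF value itself is unaffected by the choice among
#'   tied alleles.
#' @examples
#' site_pool_maf(c(A = 10, C = 5))          # maf = 5/15
#' site_pool_maf(c(A = 13, C = 1))          # low_depth
#' site_pool_maf(c(A = 20, C = 1))          # singleton_variant
#' site_pool_maf(c(A = 10, C = 4, G = 2))   # maf = 6/16
#' @export
site_pool_maf <- function(counts, min_depth = 15, min_variant_reads = 2) {
  if (length(counts) == 0L)
    stop("empty allele count map")
  if (any(counts < 0) || all(counts == 0))
    stop("allele counts must be non-negative with at least one positive")
  depth <- sum(counts)
  ord <- order(-counts, names(counts))   # ties: lexicographically smallest
  major <- names(counts)[ord[1L]]
  nonmajor <- depth - counts[[ord[1L]]]
  if (depth < min_depth) {
    status <- "low_depth"; maf <- NA_real_
  } else if (nonmajor == 0) {
    status <- "monomorphic"; maf <- NA_real_
  } else if (nonmajor < min_variant_reads) {
    status <- "singleton_variant"; maf <- NA_real_
  } else {
    status <- "ok"; maf <- nonmajor / depth
  }
  list(maf = maf, depth = depth, status = status, major_allele = major)
}

#' Pooled MAF for a table of sites
#'
#' Vectorised form of \code{\link{site_pool_maf}} for a matrix of allele
#' counts (sites in rows, alleles in columns).
#'
#' @param counts numeric matrix, one row per site, one column per allele;
#'   column names are allele strings.
#' @inheritParams site_pool_maf
#' @return data.frame with columns \code{depth}, \code{maf}, \code{status},
#'   one row per input site.
#' @export
pool_maf_table <- function(counts, min_depth = 15, min_variant_reads = 2) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L || nrow(counts) < 1L)
    stop("counts must be a non-empty site x allele matrix")
  depth <- rowSums(counts)
  major_count <- apply(counts, 1L, max)
  nonmajor <- depth - major_count
  status <- rep("ok", nrow(counts))
  status[nonmajor == 0] <- "monomorphic"
  status[nonmajor > 0 & nonmajor < min_variant_reads] <- "singleton_variant"
  status[depth < min_depth] <- "low_depth"
  maf <- ifelse(status == "ok", nonmajor / depth, NA_real_)
  data.frame(depth = depth, maf = maf, status = status,
             stringsAsFactors = FALSE)
}

#' Filter raw variant records to retained biallelic SNPs
#'
#' Applies the variant-retention rules used throughout the scan: only
#' biallelic SNPs are kept, only records at the caller's maximum quality are
#' trusted, indel records are never retained, and SNPs within
#' \code{indel_exclusion} positions of any called indel on the same scaffold
#' are removed because alignment around indels is unreliable.
#'
#' @param records data.frame with columns \code{scaffold}, \code{pos}
#'   (1-based), \code{qual}, \code{type} (\code{"snp"} or \code{"indel"}) and
#'   \code{n_alt} (number of alternate alleles). Must be sorted by scaffold
#'   then position.
#' @param max_qual the caller's programmatic maximum quality; records with
#'   \code{qual < max_qual} are removed.
#' @param indel_exclusion SNPs whose position differs from a called indel's
#'   anchor position by at most this many bp (on the same scaffold) are
#'   removed.
#' @return the retained rows of \code{records}, same columns.
#' @details The proximity rule is applied against all called indels,
#'   including indels that themselves fail the quality filter: a low-quality
#'   indel still marks the alignment as untrustworthy. The filter is
#'   idempotent.
#' @export
filter_variants <- function(records, max_qual = 999, indel_exclusion = 3) {
  req <- c("scaffold", "pos", "qual", "type", "n_alt")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) return(records)
  o <- order(match(records$scaffold, unique(records$scaffold)), records$pos)
  if (is.unsorted(o) && any(o != seq_len(nrow(records))))
    stop("records must be sorted by scaffold then position")
  keep <- records$type == "snp" &
    records$qual >= max_qual &
    records$n_alt == 1L
  # proximity to any called indel on the same scaffold
  indels <- records[records$type == "indel", c("scaffold", "pos")]
  if (nrow(indels) > 0L) {
    near <- rep(FALSE, nrow(records))
    for (sc in unique(indels$scaffold)) {
      ip <- sort(indels$pos[indels$scaffold == sc])
      on_sc <- which(records$scaffold == sc)
      idx <- findInterval(records$pos[on_sc], ip)
      d_lo <- ifelse(idx >= 1L, records$pos[on_sc] - ip[pmax(idx, 1L)], Inf)
      d_hi <- ifelse(idx < length(ip),
                     ip[pmin(idx + 1L, length(ip))] - records$pos[on_sc], Inf)
      near[on_sc] <- pmin(d_lo, d_hi) <= indel_exclusion
    }
    keep <- keep & !near
  }
  records[keep, , drop = FALSE]
}
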