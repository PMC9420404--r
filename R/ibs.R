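# Identity-by-state distances, neighbor joining and site-bootstrap support.

#' Pseudodiploid coding of pooled allele counts
#'
#' Codes a population pool as a single diploid sample per site so that it can
#' enter genotype-based analyses alongside individuals: a site where both
#' alleles are supported by at least \code{min_variant_reads} reads becomes a
#' heterozygote (dosage 1); otherwise the pool is coded homozygous for its
#' majority allele; sites below \code{min_depth} total reads are missing.
#' Segregating sites in the pool are thus generally represented as
#' heterozygotes, which exaggerates the pool's terminal branch but permits a
#' pairwise identity-by-state computation.
#'
#' @param ref_count,alt_count numeric vectors of reference- and
#'   alternate-allele read counts per site.
#' @param min_depth minimum total depth for a call.
#' @param min_variant_reads minimum reads supporting an allele for it to be
#'   considered present.
#' @return integer vector of dosages \{0, 1, 2\} with \code{NA} below the
#'   depth threshold.
#' @export
encode_pseudodiploid <- function(ref_count, alt_count, min_depth = 15,
                                 min_variant_reads = 2) {
  depth <- ref_count + alt_count
  both <- ref_count >= min_variant_reads & alt_count >= min_variant_reads
  dosage <- ifelse(both, 1L, ifelse(alt_count > ref_count, 2L, 0L))
  dosage[depth < min_depth] <- NA_integer_
  as.integer(dosage)
}

#' Identity-by-state distance matrix
#'
#' Computes pairwise distances 1 - mean IBS between samples from a dosage
#' matrix. At a comparable site (both samples called) the IBS proportion is
#' \code{(2 - |d_i - d_j|) / 2}; the mean is taken over pairwise-complete
#' sites, so each pair may use a different site set.
#'
#' @param geno integer matrix of dosages \{0,1,2,NA\}, samples in rows,
#'   sites in columns, with rownames as sample labels.
#' @return list with \code{dist}: symmetric numeric matrix of distances in
#'   [0, 1] with zero diagonal, and \code{n_sites}: matrix of comparable
#'   site counts per pair.
#' @export
ibs_distance_matrix <- function(geno) {
  geno <- as.matrix(geno)
  ns <- nrow(geno)
  if (ns < 2L) stop("at least two samples are required")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("S", seq_len(ns))
  d <- matrix(0, ns, ns, dimnames = list(rownames(geno), rownames(geno)))
  nmat <- matrix(0L, ns, ns, dimnames = dimnames(d))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      both <- !is.na(geno[i, ]) & !is.na(geno[j, ])
      n <- sum(both)
      if (n == 0L)
        stop("samples ", rownames(geno)[i], " and ", rownames(geno)[j],
             " share no comparable sites")
      ibs <- (2 - abs(geno[i, both] - geno[j, both])) / 2
      d[i, j] <- d[j, i] <- 1 - mean(ibs)
      nmat[i, j] <- nmat[j, i] <- n
    }
  }
  list(dist = d, n_sites = nmat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree (Saitou-Nei agglomeration in the
#' Studier-Keppler formulation) from a symmetric distance matrix. On an
#' additive matrix the tree's path distances reproduce the input exactly.
#' Negative branch-length estimates are clamped to zero on output.
#'
#' @param d symmetric numeric matrix with zero diagonal and non-negative
#'   entries, labeled rows/columns.
#' @return an \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  if (nrow(d) < 3L) stop("at least three samples are required")
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Site-bootstrap support for the IBS neighbor-joining tree
#'
#' Resamples sites with replacement, recomputes the IBS distance matrix and
#' NJ tree per replicate, and reports for each internal bipartition of the
#' reference tree the percentage of replicates containing it (as an unrooted
#' split).
#'
#' @param geno dosage matrix, samples in rows, sites in columns.
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed; the computation is deterministic given the
#'   seed.
#' @return list with \code{tree}: the reference \code{phylo} tree with
#'   \code{node.label} set to support percentages, and \code{support}:
#'   numeric vector of supports for the internal nodes (root first).
#' @export
bootstrap_support <- function(geno, n_reps = 100, seed = 1) {
  ref <- neighbor_joining(ibs_distance_matrix(geno)$dist)
  nsite <- ncol(geno)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(nsite, nsite, replace = TRUE)
    reps[[r]] <- neighbor_joining(ibs_distance_matrix(
      geno[, cols, drop = FALSE])$dist)
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  ref$node.label <- support
  list(tree = ref, support = support)
}
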