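# Genomic window tiling and per-window aggregation.

#' Tile sliding windows over scaffolds
#'
#' Generates sliding genomic windows of a given size and step over each
#' scaffold. Windows start at 0, step, 2*step, ...; the first window that
#' reaches past the scaffold end is truncated there and closes the tiling
#' (later starts would fall wholly inside the already-covered tail), so a
#' scaffold shorter than one window yields a single truncated window and a
#' non-overlapping tiling (step == size) covers every bp exactly once.
#' Windows are addressed by their start coordinate (0-based half-open).
#'
#' @param scaffold_lengths data.frame with columns \code{scaffold} and
#'   \code{length} (bp), or a named numeric vector of lengths.
#' @param size window size in bp.
#' @param step distance between consecutive window starts in bp; must not
#'   exceed \code{size}.
#' @return data.frame with columns \code{scaffold}, \code{start}, \code{end}
#'   (0-based half-open) and \code{widx} (0-based window index within the
#'   scaffold), ordered by scaffold then start.
#' @export
tile_windows <- function(scaffold_lengths, size = 50000, step = 25000) {
  if (is.numeric(scaffold_lengths) && !is.null(names(scaffold_lengths)))
    scaffold_lengths <- data.frame(scaffold = names(scaffold_lengths),
                                   length = unname(scaffold_lengths))
  if (!all(c("scaffold", "length") %in% names(scaffold_lengths)))
    stop("scaffold_lengths needs columns scaffold, length")
  if (any(scaffold_lengths$length <= 0))
    stop("scaffold lengths must be positive")
  if (step <= 0 || size < step)
    stop("need size >= step > 0")
  out <- lapply(seq_len(nrow(scaffold_lengths)), function(i) {
    L <- scaffold_lengths$length[i]
    # window k (k >= 1) is emitted iff window k-1 was full-length and the
    # start is inside the scaffold
    n_extra <- max(0, min(floor((L - size) / step) + 1,
                          ceiling(L / step) - 1))
    starts <- seq(0L, by = step, length.out = 1L + n_extra)
    data.frame(scaffold = scaffold_lengths$scaffold[i],
               start = starts,
               end = pmin(starts + size, L),
               widx = seq_along(starts) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# 0-based window indices covering a 0-based position: i*step <= pos < i*step+size
window_indices_for_pos <- function(pos0, size, step, n_windows) {
  i_max <- pmin(pos0 %/% step, n_windows - 1L)
  i_min <- pmax(0L, (pos0 - size) %/% step + 1L)
  list(min = i_min, max = i_max)
}

# Accumulate per-site values into overlapping windows. Returns per-window
# sum and count of non-NA values, aligned to `windows` rows.
accumulate_windows <- function(windows, scaffold, pos0, value, size, step) {
  stopifnot(length(scaffold) == length(pos0), length(pos0) == length(value))
  wsum <- numeric(nrow(windows))
  wn <- integer(nrow(windows))
  key <- paste0(windows$scaffold, ":", windows$widx)
  row_of <- seq_len(nrow(windows))
  names(row_of) <- key
  nw_per_sc <- tapply(windows$widx, windows$scaffold, max) + 1L
  n_off <- ceiling(size / step)
  keepv <- !is.na(value)
  scaffold <- scaffold[keepv]; pos0 <- pos0[keepv]; value <- value[keepv]
  nw_site <- nw_per_sc[scaffold]
  for (off in 0:(n_off - 1L)) {
    idx <- pos0 %/% step - off
    ok <- idx >= 0L & idx <= nw_site - 1L & (pos0 - idx * step) < size
    if (!any(ok)) next
    rows <- row_of[paste0(scaffold[ok], ":", idx[ok])]
    add_s <- tapply(value[ok], rows, sum)
    add_n <- tapply(rep(1L, sum(ok)), rows, sum)
    at <- as.integer(names(add_s))
    wsum[at] <- wsum[at] + as.numeric(add_s)
    wn[at] <- wn[at] + as.integer(add_n)
  }
  list(sum = wsum, n = wn)
}

#' Mean pooled MAF per window
#'
#' Averages per-site pooled MAF estimates over sliding windows. Only sites
#' with status \code{"ok"} contribute; optionally monomorphic sites (zero
#' variant reads at adequate depth) are included as MAF 0. A site falling in
#' several overlapping windows contributes to each of them.
#'
#' @param site_maf data.frame with columns \code{scaffold}, \code{pos}
#'   (1-based), \code{maf}, \code{status} (as from
#'   \code{\link{pool_maf_table}}).
#' @param windows window tiling from \code{\link{tile_windows}}.
#' @param size,step the tiling parameters used to build \code{windows}.
#' @param min_sites_maf minimum number of contributing sites for the window
#'   mean to be defined.
#' @param include_monomorphic if TRUE, monomorphic sites passing the depth
#'   filter enter the average with MAF 0.
#' @return \code{windows} with added columns \code{mean_maf} and
#'   \code{n_maf_sites}.
#' @export
window_mean_maf <- function(site_maf, windows, size = 50000, step = 25000,
                            min_sites_maf = 1, include_monomorphic = FALSE) {
  val <- site_maf$maf
  if (include_monomorphic)
    val[site_maf$status == "monomorphic"] <- 0
  val[!(site_maf$status == "ok" |
          (include_monomorphic & site_maf$status == "monomorphic"))] <- NA
  acc <- accumulate_windows(windows, as.character(site_maf$scaffold),
                            site_maf$pos - 1L, val, size, step)
  windows$n_maf_sites <- acc$n
  windows$mean_maf <- ifelse(acc$n >= min_sites_maf, acc$sum / acc$n, NA_real_)
  windows
}

#' Windowed weighted F_ST over a tiling
#'
#' Aggregates per-site Weir-Cockerham variance components into sliding
#' windows and forms the weighted (ratio-of-sums) theta-hat per window.
#'
#' @param vc data.frame of per-site components with columns \code{scaffold},
#'   \code{pos} (1-based) plus the columns of \code{\link{wc_components}}.
#' @param windows window tiling from \code{\link{tile_windows}}.
#' @param size,step tiling parameters used to build \code{windows}.
#' @param min_sites minimum polymorphic usable sites per window.
#' @return \code{windows} with added columns \code{fst} and
#'   \code{n_fst_sites}.
#' @export
window_fst <- function(vc, windows, size = 50000, step = 25000,
                       min_sites = 100) {
  use <- vc$usable & vc$polymorphic
  use[is.na(use)] <- FALSE
  a <- ifelse(use, vc$a, NA_real_)
  tot <- ifelse(use, vc$a + vc$b + vc$c, NA_real_)
  sc <- as.character(vc$scaffold)
  acc_a <- accumulate_windows(windows, sc, vc$pos - 1L, a, size, step)
  acc_t <- accumulate_windows(windows, sc, vc$pos - 1L, tot, size, step)
  windows$n_fst_sites <- acc_a$n
  windows$fst <- ifelse(acc_a$n >= min_sites & acc_t$sum != 0,
                        acc_a$sum / acc_t$sum, NA_real_)
  windows
}

#' Fixed differences between two individuals per window
#'
#' Counts, in non-overlapping windows, the sites at which two individuals
#' carry opposite homozygous genotypes (dosage 0 versus 2). Sites with a
#' missing genotype in either individual are ignored.
#'
#' @param scaffold,pos site coordinates (pos 1-based), parallel vectors.
#' @param dosage_a,dosage_b derived-allele dosages \{0,1,2,NA\} for the two
#'   individuals at the same sites.
#' @param windows non-overlapping tiling from \code{\link{tile_windows}}
#'   with \code{step == size}.
#' @param size window size used to build \code{windows}.
#' @return \code{windows} with an added column \code{fixed_diffs}.
#' @export
window_fixed_differences <- function(scaffold, pos, dosage_a, dosage_b,
                                     windows, size = 50000) {
  fd <- as.numeric((dosage_a == 0 & dosage_b == 2) |
                     (dosage_a == 2 & dosage_b == 0))
  acc <- accumulate_windows(windows, as.character(scaffold), pos - 1L,
                            fd, size, size)
  windows$fixed_diffs <- as.integer(acc$sum)
  windows
}

#' Read pairs per kilobase per million mapped reads
#'
#' @param pairs_in_feature read pairs mapped within the feature.
#' @param feature_length feature length in bp.
#' @param total_mapped_pairs total mapped read pairs in the library.
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(pairs_in_feature, feature_length, total_mapped_pairs) {
  if (any(feature_length <= 0) || any(total_mapped_pairs <= 0))
    stop("feature_length and total_mapped_pairs must be positive")
  pairs_in_feature / (feature_length / 1000) / (total_mapped_pairs / 1e6)
}

#' Window depth scaled to the genome-wide median
#'
#' @param window_depths numeric vector of per-window mean depths.
#' @return depths divided by their median; the median of the output is 1.
#' @export
relative_window_depth <- function(window_depths) {
  m <- stats::median(window_depths, na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("median window depth is zero or undefined")
  window_depths / m
}
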