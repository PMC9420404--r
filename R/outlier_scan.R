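# Joint two-variable quantile-tail outlier scan over window statistics.

#' Scan configuration
#'
#' Bundles the thresholds of the two-variable outlier scan. A window enters
#' an outlier run if its MAF and F_ST both lie beyond their
#' \code{run_tail} empirical quantiles in the mode's directions (sweep: low
#' MAF and high F_ST; balancing: high MAF and low F_ST); a run of at least
#' \code{min_run} consecutive flagged windows is reported only if at least
#' one member window lies beyond the \code{extreme_tail} quantiles of both
#' statistics.
#'
#' @param extreme_tail quantile defining the confirmation tails (default
#'   0.01, i.e. the 1\%/99\% tails).
#' @param run_tail quantile defining run membership (default 0.05).
#' @param min_run minimum number of consecutive flagged windows (default 2).
#' @return a list of class \code{scan_config}.
#' @export
scan_config <- function(extreme_tail = 0.01, run_tail = 0.05, min_run = 2) {
  if (!(extreme_tail > 0 && extreme_tail <= run_tail && run_tail < 0.5))
    stop("need 0 < extreme_tail <= run_tail < 0.5")
  if (min_run < 2) stop("min_run must be at least 2")
  structure(list(extreme_tail = extreme_tail, run_tail = run_tail,
                 min_run = min_run), class = "scan_config")
}

#' Flag windows in joint quantile tails
#'
#' For each analyzed window (both statistics defined) computes, per mode,
#' whether the window lies beyond the run-membership and extreme quantile
#' thresholds of both the MAF and F_ST distributions. Quantiles are taken
#' over all analyzed windows genome-wide, with linear interpolation;
#' comparison against a threshold is strict, so a degenerate (constant)
#' distribution yields no flags.
#'
#' @param window_stats data.frame with columns \code{mean_maf} and
#'   \code{fst} (rows with either undefined are ignored for quantiles and
#'   never flagged).
#' @param cfg a \code{\link{scan_config}}.
#' @return \code{window_stats} with added logical columns
#'   \code{sweep_run}, \code{sweep_extreme}, \code{balancing_run},
#'   \code{balancing_extreme} and \code{analyzed}.
#' @export
joint_quantile_flags <- function(window_stats, cfg = scan_config()) {
  analyzed <- !is.na(window_stats$mean_maf) & !is.na(window_stats$fst)
  if (sum(analyzed) < 2L)
    stop("fewer than two windows with both statistics defined")
  maf <- window_stats$mean_maf
  fst <- window_stats$fst
  q <- function(x, p) stats::quantile(x[analyzed], p, names = FALSE, type = 7)
  flag <- function(tail) {
    lo_maf <- q(maf, tail);      hi_maf <- q(maf, 1 - tail)
    lo_fst <- q(fst, tail);      hi_fst <- q(fst, 1 - tail)
    list(sweep = analyzed & maf < lo_maf & fst > hi_fst,
         balancing = analyzed & maf > hi_maf & fst < lo_fst)
  }
  run <- flag(cfg$run_tail)
  ext <- flag(cfg$extreme_tail)
  window_stats$analyzed <- analyzed
  window_stats$sweep_run <- run$sweep
  window_stats$sweep_extreme <- ext$sweep
  window_stats$balancing_run <- run$balancing
  window_stats$balancing_extreme <- ext$balancing
  window_stats
}

#' Merge consecutive outlier windows into candidate regions
#'
#' Finds maximal runs of at least \code{min_run} consecutive run-flagged
#' windows of one mode within a scaffold's tiling and reports each run as a
#' candidate region, provided at least one member window is extreme-flagged.
#' Consecutiveness is defined over the ordered tiling including windows
#' without estimates, so a gap window (no estimate) breaks a run. The region
#' span is the union of the member window intervals.
#'
#' @param flagged output of \code{\link{joint_quantile_flags}} joined to the
#'   tiling columns \code{scaffold}, \code{start}, \code{end}, \code{widx}.
#' @param cfg a \code{\link{scan_config}}.
#' @return data.frame of candidate regions with columns \code{scaffold},
#'   \code{start}, \code{end}, \code{type} (\code{"sweep"} or
#'   \code{"balancing"}), \code{n_windows}, \code{has_extreme_window},
#'   \code{first_widx}, \code{last_widx}.
#' @export
merge_outlier_runs <- function(flagged, cfg = scan_config()) {
  out <- list()
  for (mode in c("sweep", "balancing")) {
    rf <- flagged[[paste0(mode, "_run")]]
    ef <- flagged[[paste0(mode, "_extreme")]]
    for (sc in unique(flagged$scaffold)) {
      i <- which(flagged$scaffold == sc)
      i <- i[order(flagged$widx[i])]
      r <- rle(rf[i])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= cfg$min_run)) {
        mem <- i[starts[k]:ends[k]]
        # runs must be over consecutive window indices
        if (any(diff(flagged$widx[mem]) != 1L)) next
        if (!any(ef[mem])) next
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc,
          start = min(flagged$start[mem]),
          end = max(flagged$end[mem]),
          type = mode,
          n_windows = length(mem),
          has_extreme_window = TRUE,
          first_widx = min(flagged$widx[mem]),
          last_widx = max(flagged$widx[mem]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), type = character(),
                      n_windows = integer(), has_extreme_window = logical(),
                      first_widx = integer(), last_widx = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(match(res$scaffold, unique(flagged$scaffold)), res$start), ,
      drop = FALSE]
}

#' Annotate candidate regions with overlapping genes
#'
#' Attaches to each region the identifiers of genes whose interval shares at
#' least one bp with the region; both use 0-based half-open coordinates, so
#' a gene starting exactly at the region end does not overlap.
#'
#' @param regions data.frame from \code{\link{merge_outlier_runs}}.
#' @param genes data.frame with columns \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open) and \code{gene_id}.
#' @return \code{regions} with added columns \code{n_genes} and
#'   \code{genes} (comma-separated ids sorted by gene start).
#' @export
annotate_regions <- function(regions, genes) {
  regions$n_genes <- integer(nrow(regions))
  regions$genes <- character(nrow(regions))
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(regions)
  for (sc in unique(regions$scaffold)) {
    ri <- which(regions$scaffold == sc)
    gi <- which(genes$scaffold == sc)
    if (length(gi) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri]),
      IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi]))
    for (j in seq_along(ri)) {
      gg <- gi[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == j]]
      gg <- gg[order(genes$start[gg])]
      regions$n_genes[ri[j]] <- length(gg)
      regions$genes[ri[j]] <- paste(genes$gene_id[gg], collapse = ",")
    }
  }
  regions
}
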