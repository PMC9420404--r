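# Weir-Cockerham (1984) variance components and windowed weighted F_ST.

#' Per-site Weir-Cockerham variance components
#'
#' Computes, for every biallelic site, the three variance components of the
#' Weir-Cockerham (1984) theta-hat estimator of F_ST from diploid genotypes
#' grouped into populations: \code{a} (among populations), \code{b} (among
#' individuals within populations) and \code{c} (within individuals, i.e.
#' the observed-heterozygosity term). Population pools coded as a single
#' pseudodiploid genotype simply enter as a population of one individual.
#'
#' @param geno integer matrix of derived-allele dosages in \{0, 1, 2\} with
#'   \code{NA} for missing genotypes; sites in rows, samples in columns.
#' @param pops character or factor vector, one population label per column
#'   of \code{geno}.
#' @return data.frame with one row per site: \code{a}, \code{b}, \code{c},
#'   \code{n_pops} (populations with at least one called genotype),
#'   \code{polymorphic} (whether the site is variable across the called
#'   samples), and \code{usable} (whether components are defined: at least
#'   two called populations and mean sample size above one). Components at
#'   unusable sites are \code{NA}.
#' @details Per-site theta-hat can be negative; negative values are retained
#'   so that windowed ratio-of-sums estimates stay unbiased. Sites
#'   monomorphic across all called samples have \code{a = b = c = 0} and an
#'   undefined per-site ratio.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_components <- function(geno, pops) {
  geno <- as.matrix(geno)
  if (ncol(geno) != length(pops))
    stop("length(pops) must equal ncol(geno)")
  pops <- as.character(pops)
  labs <- unique(pops)
  if (length(labs) < 2L)
    stop("at least two populations are required")
  ok <- !is.na(geno) & geno %in% c(0, 1, 2)
  if (any(!is.na(geno) & !geno %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  nsite <- nrow(geno)
  r_lab <- length(labs)
  # per-population, per-site: sample size, allele frequency, het frequency
  n_i <- p_i <- h_i <- matrix(0, nsite, r_lab)
  for (k in seq_len(r_lab)) {
    cols <- which(pops == labs[k])
    g <- geno[, cols, drop = FALSE]
    called <- !is.na(g)
    n_i[, k] <- rowSums(called)
    sum_g <- rowSums(g, na.rm = TRUE)
    p_i[, k] <- ifelse(n_i[, k] > 0, sum_g / (2 * n_i[, k]), NA_real_)
    h_i[, k] <- ifelse(n_i[, k] > 0,
                       rowSums(g == 1, na.rm = TRUE) / n_i[, k], NA_real_)
  }
  present <- n_i > 0
  r <- rowSums(present)                       # called populations per site
  n_tot <- rowSums(n_i)
  nbar <- n_tot / r
  sum_n2 <- rowSums(n_i^2)
  nc <- (n_tot - sum_n2 / n_tot) / (r - 1)
  pbar <- rowSums(n_i * p_i, na.rm = TRUE) / n_tot
  s2 <- rowSums(n_i * (p_i - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(n_i * h_i, na.rm = TRUE) / n_tot
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  usable <- r >= 2 & nbar > 1
  a[!usable] <- b[!usable] <- cc[!usable] <- NA_real_
  data.frame(a = a, b = b, c = cc, n_pops = r,
             polymorphic = pbar > 0 & pbar < 1 & !is.na(pbar),
             usable = usable)
}

#' Weir-Cockerham components for a single site
#'
#' Convenience wrapper around \code{\link{wc_components}} for one site.
#'
#' @param genotypes list of integer dosage vectors, one vector per
#'   population.
#' @return one-row data.frame as returned by \code{\link{wc_components}}.
#' @export
wc_components_site <- function(genotypes) {
  if (!is.list(genotypes) || length(genotypes) < 2L)
    stop("genotypes must be a list with one dosage vector per population (>= 2)")
  pops <- rep(paste0("pop", seq_along(genotypes)), lengths(genotypes))
  geno <- matrix(unlist(genotypes), nrow = 1L)
  wc_components(geno, pops)
}

#' Per-site theta-hat
#'
#' The ratio \code{a / (a + b + c)} of Weir-Cockerham variance components;
#' undefined (NA) when the denominator is zero. Negative estimates are not
#' clamped.
#'
#' @param vc data.frame with columns \code{a}, \code{b}, \code{c}.
#' @return numeric vector of per-site theta-hat values.
#' @export
fst_site <- function(vc) {
  denom <- vc$a + vc$b + vc$c
  ifelse(!is.na(denom) & denom != 0, vc$a / denom, NA_real_)
}

#' Windowed weighted theta-hat
#'
#' The ratio-of-sums ("weighted") windowed F_ST: the sum of among-population
#' components over the window divided by the sum of total components,
#' requiring a minimum number of variant sites per window. The mean of
#' per-site ratios is available as an alternative.
#'
#' @param vc data.frame of variance components for the sites of one window
#'   (as returned by \code{\link{wc_components}}).
#' @param min_sites minimum number of polymorphic, usable sites for the
#'   window estimate to be defined.
#' @param method \code{"weighted"} (ratio of sums, the default) or
#'   \code{"mean"} (mean of per-site ratios).
#' @return a single numeric value, or \code{NA} if the window has fewer than
#'   \code{min_sites} qualifying sites or a zero denominator.
#' @export
fst_window <- function(vc, min_sites = 100, method = c("weighted", "mean")) {
  method <- match.arg(method)
  use <- vc$usable & vc$polymorphic
  use[is.na(use)] <- FALSE
  if (sum(use) < min_sites) return(NA_real_)
  if (method == "weighted") {
    denom <- sum(vc$a[use] + vc$b[use] + vc$c[use])
    if (denom == 0) return(NA_real_)
    sum(vc$a[use]) / denom
  } else {
    mean(fst_site(vc[use, , drop = FALSE]), na.rm = TRUE)
  }
}
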