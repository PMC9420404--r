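# Independent oracles used to cross-check the package's estimators. Each is
# written from the defining formulas in a deliberately naive style and never
# shares code with the implementation it checks.

# Weir-Cockerham variance components via the hierarchical ANOVA mean
# squares on raw allele indicators (populations / individuals / alleles).
oracle_wc <- function(genotypes) {
  r <- length(genotypes)
  n_i <- lengths(genotypes)
  p_i <- sapply(genotypes, function(g) sum(g) / (2 * length(g)))
  n_tot <- sum(n_i)
  pbar <- sum(n_i * p_i) / n_tot
  # within-individual SS: alleles about the individual mean (het -> 0.5)
  SSG <- sum(unlist(lapply(genotypes, function(g) ifelse(g == 1, 0.5, 0))))
  # among individuals within populations
  SSI <- 2 * sum(unlist(mapply(function(g, p) (g / 2 - p)^2,
                               genotypes, as.list(p_i), SIMPLIFY = FALSE)))
  # among populations
  SSP <- 2 * sum(n_i * (p_i - pbar)^2)
  MSG <- SSG / n_tot
  MSI <- SSI / sum(n_i - 1)
  MSP <- SSP / (r - 1)
  nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# random genotype configuration for the oracle comparison: r populations,
# each with 1-8 diploids, guaranteed mean sample size > 1
random_geno_config <- function() {
  repeat {
    r <- sample(2:6, 1)
    gl <- lapply(seq_len(r), function(k)
      sample(0:2, sample(1:8, 1), replace = TRUE))
    if (sum(lengths(gl)) > r) return(gl)
  }
}

# naive per-position window membership: all-pairs interval test
oracle_window_membership <- function(pos0, windows) {
  lapply(pos0, function(p)
    which(windows$start <= p & p < windows$end))
}

# naive all-pairs interval intersection (0-based half-open)
oracle_interval_overlap <- function(a, b) {
  hits <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      hits[i, j] <- a$scaffold[i] == b$scaffold[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
  hits
}

# Monte-Carlo expectation of the filtered pooled-MAF estimator at a fixed
# pool frequency: simulate counts and apply the filters independently.
oracle_mean_maf <- function(f, mean_depth, n_sites, min_depth = 15,
                            min_variant_reads = 2) {
  depth <- rpois(n_sites, mean_depth)
  alt <- rbinom(n_sites, depth, f)
  ref <- depth - alt
  nonmajor <- pmin(ref, alt)
  ok <- depth >= min_depth & nonmajor >= min_variant_reads
  list(mean = mean(nonmajor[ok] / depth[ok]), n = sum(ok),
       sd = sd(nonmajor[ok] / depth[ok]))
}

# a small simulated dataset configuration used by several fast tests;
# scale-free properties only (the study-scale defaults are exercised in the
# acceptance suite)
small_sim <- function(seed = 1, n_scaffolds = 3, scaffold_length = 4e5, ...) {
  sim_config(n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
             seed = seed, ...)
}
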