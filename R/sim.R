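# Synthetic multi-species pooled/individual resequencing datasets with
# planted selection regions and a known species tree.

#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. The generator emulates the
#' sampling design the scan assumes: four diverged congener species with two
#' diploid individuals each, plus one focal population pool sequenced at
#' depth, on a fixed balanced species tree ((A,B),(C,D)) with the focal pool
#' branching off species A. Allele-frequency evolution is modeled as
#' independent truncated-Gaussian drift per branch in frequency space, which
#' is sufficient to induce the among-species differentiation structure the
#' scan consumes without a full coalescent.
#'
#' @param n_scaffolds number of scaffolds to simulate.
#' @param scaffold_length scaffold length in bp (all scaffolds equal).
#' @param n_species number of congener species; the current generator
#'   supports the fixed 4-species balanced tree.
#' @param individuals_per_species diploid individuals sampled per species.
#' @param pool_chromosomes number of chromosomes in the focal pool (48 by
#'   default, i.e. 24 diploids).
#' @param species_divergence per-branch drift variance in allele-frequency
#'   space (0 to 0.25). Zero means all species share identical frequencies.
#' @param pool_branch_scale fraction of \code{species_divergence} applied on
#'   the short branch from species A to the focal pool.
#' @param snp_density expected polymorphic sites per bp.
#' @param mean_depth mean pool read depth per site.
#' @param depth_dispersion negative-binomial overdispersion of depth
#'   (variance = mean + dispersion * mean^2); 0 gives Poisson depth.
#' @param sweep_regions,balancing_regions data.frames with columns
#'   \code{scaffold} (1-based scaffold index), \code{start}, \code{end}
#'   (0-based half-open bp), or NULL.
#' @param sweep_maf_ceiling maximum folded MAF of the focal pool inside
#'   sweep regions (0 <= value < 0.5).
#' @param sweep_fst_floor minimum allele-frequency separation between the
#'   focal lineage and each other species inside sweep regions.
#' @param balancing_shrink inside balancing regions, frequencies are pulled
#'   toward 0.5 as 0.5 + shrink * (p - 0.5); small values mean strong
#'   balancing.
#' @param seed integer seed; a fixed seed makes every downstream artifact
#'   byte-identical across runs.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_scaffolds = 20, scaffold_length = 2e6,
                       n_species = 4, individuals_per_species = 2,
                       pool_chromosomes = 48,
                       species_divergence = 0.1, pool_branch_scale = 0.1,
                       snp_density = 0.005,
                       mean_depth = 40, depth_dispersion = 0.2,
                       sweep_regions = NULL, balancing_regions = NULL,
                       sweep_maf_ceiling = 0.02, sweep_fst_floor = 0.6,
                       balancing_shrink = 0.15,
                       seed = 1) {
  if (n_scaffolds < 1 || scaffold_length <= 0)
    stop("scaffold dimensions must be positive")
  if (n_species != 4)
    stop("the generator implements the fixed 4-species balanced tree")
  if (species_divergence < 0 || species_divergence > 0.25)
    stop("species_divergence must be in [0, 0.25]")
  if (sweep_maf_ceiling < 0 || sweep_maf_ceiling >= 0.5)
    stop("sweep_maf_ceiling must be in [0, 0.5)")
  chk_regions <- function(reg, what) {
    if (is.null(reg) || nrow(reg) == 0L) return(invisible())
    bad <- reg$scaffold < 1 | reg$scaffold > n_scaffolds |
      reg$start < 0 | reg$end > scaffold_length | reg$start >= reg$end
    if (any(bad))
      stop(what, " region outside simulated scaffolds: row ",
           which(bad)[1L])
  }
  chk_regions(sweep_regions, "sweep")
  chk_regions(balancing_regions, "balancing")
  structure(list(
    n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
    n_species = n_species, individuals_per_species = individuals_per_species,
    pool_chromosomes = pool_chromosomes,
    species_divergence = species_divergence,
    pool_branch_scale = pool_branch_scale,
    snp_density = snp_density, mean_depth = mean_depth,
    depth_dispersion = depth_dispersion,
    sweep_regions = sweep_regions, balancing_regions = balancing_regions,
    sweep_maf_ceiling = sweep_maf_ceiling,
    sweep_fst_floor = sweep_fst_floor,
    balancing_shrink = balancing_shrink,
    seed = as.integer(seed)), class = "sim_config")
}

# one truncated-Gaussian drift step per site, exact via inverse CDF
drift_step <- function(p, sd) {
  if (sd == 0) return(p)
  lo <- stats::pnorm(0, p, sd)
  hi <- stats::pnorm(1, p, sd)
  stats::qnorm(lo + stats::runif(length(p)) * (hi - lo), p, sd)
}

#' Simulate per-site species allele frequencies on the fixed tree
#'
#' Draws ancestral frequencies uniformly on (0.05, 0.95) at randomly placed
#' polymorphic sites and evolves them down the balanced species tree
#' ((A,B),(C,D)) by independent truncated-Gaussian drift per branch (variance
#' \code{species_divergence}); the focal pool lineage branches off species A
#' with variance scaled by \code{pool_branch_scale}.
#'
#' @param cfg a \code{\link{sim_config}}. The configured seed is consumed
#'   here; downstream sampling continues the same stream.
#' @return data.frame with columns \code{scaffold} (name), \code{pos}
#'   (1-based), frequency columns \code{A}, \code{B}, \code{C}, \code{D} and
#'   \code{pool}.
#' @export
simulate_species_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  sites <- lapply(seq_len(cfg$n_scaffolds), function(i) {
    n <- stats::rpois(1, cfg$snp_density * cfg$scaffold_length)
    n <- max(n, 1L)
    pos <- sort(sample.int(cfg$scaffold_length, min(n, cfg$scaffold_length)))
    data.frame(scaffold = sprintf("scaf%d", i), pos = pos,
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, sites)
  n <- nrow(sites)
  sd_b <- sqrt(cfg$species_divergence)
  sd_p <- sqrt(cfg$species_divergence * cfg$pool_branch_scale)
  p0 <- stats::runif(n, 0.05, 0.95)
  pAB <- drift_step(p0, sd_b)
  pCD <- drift_step(p0, sd_b)
  sites$A <- drift_step(pAB, sd_b)
  sites$B <- drift_step(pAB, sd_b)
  sites$C <- drift_step(pCD, sd_b)
  sites$D <- drift_step(pCD, sd_b)
  sites$pool <- drift_step(sites$A, sd_p)
  sites
}

# logical index of sites falling in the given regions
sites_in_regions <- function(freqs, regions, cfg) {
  inr <- rep(FALSE, nrow(freqs))
  if (is.null(regions) || nrow(regions) == 0L) return(inr)
  scafs <- sprintf("scaf%d", regions$scaffold)
  for (k in seq_len(nrow(regions))) {
    inr <- inr | (freqs$scaffold == scafs[k] &
                    freqs$pos - 1L >= regions$start[k] &
                    freqs$pos - 1L < regions$end[k])
  }
  inr
}

#' Plant sweep and balancing-selection signatures
#'
#' Modifies the simulated frequencies inside the configured regions. In
#' sweep regions the focal lineage (pool and species A) is driven to a
#' folded frequency at most \code{sweep_maf_ceiling} while every other
#' species is pushed at least \code{sweep_fst_floor} away in frequency,
#' producing locally low pool polymorphism and high among-species
#' differentiation. In balancing regions all lineages are pulled toward 0.5
#' (intermediate frequencies shared across species), producing locally high
#' pool polymorphism and low differentiation. Sites outside the regions are
#' untouched.
#'
#' @param freqs data.frame from \code{\link{simulate_species_frequencies}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return \code{freqs} with modified frequency columns and added logical
#'   columns \code{in_sweep}, \code{in_balancing}.
#' @export
plant_selection_regions <- function(freqs, cfg) {
  sw <- sites_in_regions(freqs, cfg$sweep_regions, cfg)
  ba <- sites_in_regions(freqs, cfg$balancing_regions, cfg)
  if (any(sw)) {
    n <- sum(sw)
    # focal lineage: folded MAF at most the ceiling, on the ancestral side
    f_focal <- stats::runif(n, 0, cfg$sweep_maf_ceiling)
    freqs$pool[sw] <- f_focal
    freqs$A[sw] <- f_focal
    floor_ <- cfg$sweep_fst_floor
    for (spp in c("B", "C", "D")) {
      p <- freqs[[spp]][sw]
      freqs[[spp]][sw] <- pmin(1, pmax(p, f_focal + floor_))
    }
  }
  if (any(ba)) {
    for (col in c("A", "B", "C", "D", "pool")) {
      p <- freqs[[col]][ba]
      freqs[[col]][ba] <- 0.5 + cfg$balancing_shrink * (p - 0.5)
    }
  }
  freqs$in_sweep <- sw
  freqs$in_balancing <- ba
  freqs
}

#' Sample pooled read counts
#'
#' Draws the focal pool's per-site read counts: the realized pool frequency
#' comes from \code{pool_chromosomes} binomial draws of the pool lineage
#' frequency, depth from a negative binomial with the configured mean and
#' dispersion (Poisson when dispersion is 0), and variant reads from a
#' binomial of the realized frequency.
#'
#' @param freq numeric vector of per-site pool lineage frequencies.
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with columns \code{ref_count}, \code{alt_count},
#'   \code{depth} and \code{realized_freq}.
#' @export
sample_pool_counts <- function(freq, cfg) {
  n <- length(freq)
  realized <- stats::rbinom(n, cfg$pool_chromosomes, freq) /
    cfg$pool_chromosomes
  depth <- if (cfg$depth_dispersion > 0)
    stats::rnbinom(n, mu = cfg$mean_depth, size = 1 / cfg$depth_dispersion)
  else
    stats::rpois(n, cfg$mean_depth)
  alt <- stats::rbinom(n, depth, realized)
  data.frame(ref_count = depth - alt, alt_count = alt, depth = depth,
             realized_freq = realized)
}

#' Sample individual diploid genotypes
#'
#' Draws Hardy-Weinberg genotypes for every congener individual from its
#' species' per-site allele frequency.
#'
#' @param freqs data.frame from \code{\link{plant_selection_regions}} (or
#'   \code{\link{simulate_species_frequencies}}).
#' @param cfg a \code{\link{sim_config}}.
#' @return integer matrix of derived-allele dosages, sites in rows; columns
#'   named \code{A1, A2, B1, ...} per species and individual.
#' @export
sample_individual_genotypes <- function(freqs, cfg) {
  spp <- c("A", "B", "C", "D")
  n <- nrow(freqs)
  cols <- list()
  for (s in spp) {
    for (k in seq_len(cfg$individuals_per_species)) {
      cols[[paste0(s, k)]] <- stats::rbinom(n, 2, freqs[[s]])
    }
  }
  geno <- do.call(cbind, cols)
  storage.mode(geno) <- "integer"
  geno
}

#' Simulate a complete dataset
#'
#' Runs the full generator: species frequencies on the fixed tree, planted
#' selection regions, pooled read counts and individual genotypes. All
#' randomness flows from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list of class \code{sim_dataset} with elements \code{cfg},
#'   \code{freqs} (per-site lineage frequencies and truth flags),
#'   \code{geno} (individual dosage matrix), \code{pool} (pool count table),
#'   \code{scaffold_lengths}, \code{truth} (truth-region table) and
#'   \code{samples} (sample names, pool last).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  freqs <- simulate_species_frequencies(cfg)
  freqs <- plant_selection_regions(freqs, cfg)
  geno <- sample_individual_genotypes(freqs, cfg)
  pool <- sample_pool_counts(freqs$pool, cfg)
  lens <- data.frame(scaffold = sprintf("scaf%d", seq_len(cfg$n_scaffolds)),
                     length = cfg$scaffold_length, stringsAsFactors = FALSE)
  truth <- truth_regions(cfg)
  structure(list(cfg = cfg, freqs = freqs, geno = geno, pool = pool,
                 scaffold_lengths = lens, truth = truth,
                 samples = c(colnames(geno), "POOL")),
            class = "sim_dataset")
}

#' Truth-region table for a configuration
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with columns \code{scaffold} (name), \code{start},
#'   \code{end} (0-based half-open) and \code{type}.
#' @export
truth_regions <- function(cfg) {
  mk <- function(reg, type) {
    if (is.null(reg) || nrow(reg) == 0L)
      return(data.frame(scaffold = character(), start = integer(),
                        end = integer(), type = character(),
                        stringsAsFactors = FALSE))
    data.frame(scaffold = sprintf("scaf%d", reg$scaffold),
               start = reg$start, end = reg$end, type = type,
               stringsAsFactors = FALSE)
  }
  rbind(mk(cfg$sweep_regions, "sweep"), mk(cfg$balancing_regions, "balancing"))
}

#' Toy gene annotation for a simulated genome
#'
#' Places genes deterministically along each scaffold (one gene every
#' \code{spacing} bp, of length \code{gene_length}), so that genes fall both
#' inside and outside any planted regions.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param spacing distance between gene starts in bp.
#' @param gene_length gene length in bp.
#' @return data.frame with columns \code{scaffold}, \code{start}, \code{end}
#'   (0-based half-open), \code{gene_id}.
#' @export
toy_gene_annotation <- function(cfg, spacing = 100000, gene_length = 20000) {
  out <- lapply(seq_len(cfg$n_scaffolds), function(i) {
    starts <- seq(10000, cfg$scaffold_length - gene_length, by = spacing)
    data.frame(scaffold = sprintf("scaf%d", i),
               start = as.integer(starts),
               end = as.integer(starts + gene_length),
               gene_id = sprintf("gene_s%d_%03d", i, seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
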