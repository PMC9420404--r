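test_that("zero divergence gives identical frequencies in all lineages", {
  cfg <- small_sim(seed = 501, species_divergence = 0)
  f <- simulate_species_frequencies(cfg)
  for (col in c("B", "C", "D", "pool"))
    expect_equal(f[[col]], f$A)
  expect_true(all(f$A >= 0 & f$A <= 1))
})

test_that("tree distance orders mean frequency differences", {
  cfg <- small_sim(seed = 502, species_divergence = 0.25,
                   n_scaffolds = 1, scaffold_length = 2e6)
  f <- simulate_species_frequencies(cfg)
  expect_gt(nrow(f), 5000)
  # A and C are separated by four branches, A and B by two
  expect_gt(mean(abs(f$A - f$C)), mean(abs(f$A - f$B)))
  for (col in c("A", "B", "C", "D", "pool"))
    expect_true(all(f[[col]] >= 0 & f[[col]] <= 1))
})

test_that("planting selection regions modifies only the targeted sites", {
  sw <- data.frame(scaffold = 1, start = 0, end = 1e5)
  ba <- data.frame(scaffold = 2, start = 1e5, end = 2e5)
  cfg <- small_sim(seed = 503, sweep_regions = sw, balancing_regions = ba)
  f0 <- simulate_species_frequencies(cfg)
  f <- plant_selection_regions(f0, cfg)

  out <- !f$in_sweep & !f$in_balancing
  for (col in c("A", "B", "C", "D", "pool"))
    expect_equal(f[[col]][out], f0[[col]][out])

  # sweep: focal folded MAF below the ceiling, others far away
  folded <- pmin(f$pool[f$in_sweep], 1 - f$pool[f$in_sweep])
  expect_true(all(folded <= cfg$sweep_maf_ceiling))
  for (col in c("B", "C", "D"))
    expect_true(all(abs(f[[col]][f$in_sweep] - f$pool[f$in_sweep]) >=
                      cfg$sweep_fst_floor - 1e-12))

  # balancing: folded MAF raised above the genome-wide background
  fb <- pmin(f$pool[f$in_balancing], 1 - f$pool[f$in_balancing])
  expect_gt(mean(fb), mean(pmin(f$pool[out], 1 - f$pool[out])))

  # degenerate ceiling of zero: monomorphic focal pool
  cfg0 <- small_sim(seed = 504, sweep_regions = sw, sweep_maf_ceiling = 0)
  fz <- plant_selection_regions(simulate_species_frequencies(cfg0), cfg0)
  expect_true(all(fz$pool[fz$in_sweep] %in% c(0, 1)))

  # no regions: a no-op
  cfgn <- small_sim(seed = 503)
  fn <- plant_selection_regions(simulate_species_frequencies(cfgn), cfgn)
  expect_equal(fn$pool, f0$pool)

  # a region outside the simulated scaffolds is rejected by name
  expect_error(small_sim(sweep_regions = data.frame(scaffold = 99,
                                                    start = 0, end = 10)),
               "region outside")
})

test_that("pool read counts follow the depth and binomial sampling model", {
  cfg <- small_sim(seed = 505)
  set.seed(505)
  z <- sample_pool_counts(rep(0, 1000), cfg)
  expect_true(all(z$alt_count == 0))

  set.seed(506)
  p <- sample_pool_counts(rep(0.5, 10000), cfg)
  frac <- with(p[p$depth > 0, ], alt_count / depth)
  target <- mean(p$realized_freq[p$depth > 0])
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - target), 3 * se)

  # dispersion 0 limit: Poisson depth (variance close to mean)
  cfg0 <- small_sim(seed = 507, depth_dispersion = 0)
  set.seed(507)
  d0 <- sample_pool_counts(rep(0.5, 20000), cfg0)$depth
  expect_lt(abs(var(d0) / mean(d0) - 1), 0.1)
  # positive dispersion inflates depth variance
  set.seed(508)
  d1 <- sample_pool_counts(rep(0.5, 20000), cfg)$depth
  expect_gt(var(d1) / mean(d1), 1.5)
})

test_that("individual genotypes are Hardy-Weinberg draws of species frequencies", {
  cfg <- small_sim(seed = 509)
  f <- simulate_species_frequencies(cfg)
  f$A[] <- 1; f$B[] <- 0; f$C[] <- 0.5
  set.seed(509)
  g <- sample_individual_genotypes(f, cfg)
  expect_true(all(g[, c("A1", "A2")] == 2L))
  expect_true(all(g[, c("B1", "B2")] == 0L))
  het <- mean(g[, "C1"] == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / nrow(f)))
})

test_that("a written dataset round-trips through the readers", {
  sw <- data.frame(scaffold = 1, start = 1e5, end = 2e5)
  ba <- data.frame(scaffold = 2, start = 0, end = 5e4)
  cfg <- small_sim(seed = 510, n_scaffolds = 2, scaffold_length = 2e5,
                   sweep_regions = sw, balancing_regions = ba)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)

  v <- read_vcf_sites(paths$vcf)
  expect_equal(v$sites$scaffold, ds$freqs$scaffold)
  expect_equal(v$sites$pos, ds$freqs$pos)
  expect_equal(unname(v$geno[, colnames(ds$geno)]), unname(ds$geno))
  expect_equal(v$pool_counts$ref_count, ds$pool$ref_count)
  expect_equal(v$pool_counts$alt_count, ds$pool$alt_count)

  ct <- read_pool_counts(paths$counts)
  expect_equal(ct$refCount, ds$pool$ref_count)
  expect_equal(ct$altCount, ds$pool$alt_count)

  lens <- read_scaffold_lengths(paths$lengths)
  expect_equal(lens, ds$scaffold_lengths)

  tr <- read_bed(paths$truth, name_col = "type")
  expect_equal(nrow(tr), nrow(sw) + nrow(ba))
  expect_equal(tr$type, c("sweep", "balancing"))

  # VCF header declares every sample
  hdr <- grep("^#CHROM", readLines(paths$vcf), value = TRUE)
  expect_true(all(vapply(ds$samples, grepl, logical(1), hdr, fixed = TRUE)))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- small_sim(seed = 511, n_scaffolds = 2, scaffold_length = 1e5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (fn in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))))
  }
})
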