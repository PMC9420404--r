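mk_ws <- function(maf, fst, scaffold = "s", widx = seq_along(maf) - 1L) {
  data.frame(scaffold = scaffold, start = widx * 25000L,
             end = widx * 25000L + 50000L, widx = widx,
             mean_maf = maf, fst = fst, stringsAsFactors = FALSE)
}

test_that("joint quantile flags mark the extreme corner and nothing degenerate", {
  set.seed(301)
  maf <- runif(200, 0.1, 0.3)
  fst <- runif(200, 0.2, 0.5)
  maf[17] <- 0.01; fst[17] <- 0.95        # unique extreme sweep corner
  fl <- joint_quantile_flags(mk_ws(maf, fst))
  expect_true(fl$sweep_extreme[17])
  expect_true(fl$sweep_run[17])
  expect_false(any(fl$balancing_extreme[17]))

  # constant statistics: strict comparison yields no flags
  fl0 <- joint_quantile_flags(mk_ws(rep(0.2, 50), rep(0.3, 50)))
  expect_false(any(fl0$sweep_run | fl0$balancing_run))

  expect_error(joint_quantile_flags(mk_ws(c(0.1, NA), c(NA, 0.2))),
               "fewer than two")
})

test_that("flag rate under independent uniforms is near the squared tail", {
  set.seed(302)
  rates <- replicate(5, {
    fl <- joint_quantile_flags(mk_ws(runif(10000), runif(10000)),
                               scan_config(extreme_tail = 0.05,
                                           run_tail = 0.1))
    mean(fl$sweep_extreme)
  })
  p <- 0.05^2
  se <- sqrt(p * (1 - p) / (5 * 10000))
  expect_lt(abs(mean(rates) - p), 3 * se)
})

test_that("runs of consecutive flagged windows are merged per the rules", {
  set.seed(303)
  maf <- 0.25 + rnorm(60, 0, 1e-3)  # jitter breaks exact ties
  fst <- 0.4 + rnorm(60, 0, 1e-3)
  # a minimal sweep run of two windows, one of them extreme
  maf[30:31] <- c(0.01, 0.03); fst[30:31] <- c(0.95, 0.90)
  fl <- joint_quantile_flags(mk_ws(maf, fst))
  reg <- merge_outlier_runs(fl)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$type, "sweep")
  expect_equal(reg$n_windows, 2L)
  expect_equal(reg$start, 29L * 25000L)
  expect_equal(reg$end, 30L * 25000L + 50000L)

  # an isolated flagged window is not reported
  maf2 <- maf; fst2 <- fst
  maf2[31] <- 0.25; fst2[31] <- 0.4
  reg2 <- merge_outlier_runs(joint_quantile_flags(mk_ws(maf2, fst2)))
  expect_equal(nrow(reg2), 0L)

  # a run with no window in the extreme tails is not reported; the lone
  # extreme corner (window 1) is isolated and so not reported either
  maf3 <- c(0.001, seq(0.2, 0.3, length.out = 300), rep(0.203, 3))
  fst3 <- c(0.95, seq(0.3, 0.4, length.out = 300), rep(0.3965, 3))
  reg3 <- merge_outlier_runs(joint_quantile_flags(mk_ws(maf3, fst3)))
  expect_equal(nrow(reg3), 0L)
})

test_that("a gap window with no estimate breaks a run", {
  set.seed(304)
  maf <- runif(50, 0.2, 0.3); fst <- runif(50, 0.3, 0.4)
  maf[20:22] <- 0.001; fst[20:22] <- 0.95
  maf[21] <- NA                     # masked window inside the run
  fl <- joint_quantile_flags(mk_ws(maf, fst))
  reg <- merge_outlier_runs(fl)
  expect_false(any(reg$n_windows >= 3))
})

test_that("raising the run tail never removes a reported region", {
  set.seed(305)
  maf <- runif(400); fst <- runif(400)
  maf[100:102] <- 0.001; fst[100:102] <- 1.5
  for (tail in c(0.05, 0.1, 0.2)) {
    fl <- joint_quantile_flags(mk_ws(maf, fst),
                               scan_config(run_tail = tail))
    reg <- merge_outlier_runs(fl, scan_config(run_tail = tail))
    if (tail == 0.05) base <- reg
    # every region reported at the tighter tail persists (possibly wider)
    for (i in seq_len(nrow(base)))
      expect_true(any(reg$type == base$type[i] &
                        reg$start <= base$start[i] &
                        reg$end >= base$end[i]))
  }
})

test_that("gene annotation uses half-open overlap and matches an oracle", {
  reg <- data.frame(scaffold = "s", start = 100L, end = 200L, type = "sweep",
                    n_windows = 2L, has_extreme_window = TRUE,
                    first_widx = 0L, last_widx = 1L)
  genes <- data.frame(scaffold = "s",
                      start = c(120L, 200L, 50L),
                      end = c(180L, 300L, 101L),
                      gene_id = c("inside", "abutting", "edge"))
  out <- annotate_regions(reg, genes)
  # fully inside and 1-bp overlap reported; gene starting at region end not
  expect_equal(out$genes, "edge,inside")
  expect_equal(out$n_genes, 2L)

  set.seed(306)
  rr <- data.frame(scaffold = sample(c("s1", "s2"), 20, TRUE),
                   start = sample.int(1000, 20))
  rr$end <- rr$start + sample.int(200, 20)
  rr$type <- "sweep"; rr$n_windows <- 1L; rr$has_extreme_window <- TRUE
  rr$first_widx <- 0L; rr$last_widx <- 0L
  gg <- data.frame(scaffold = sample(c("s1", "s2"), 30, TRUE),
                   start = sample.int(1200, 30))
  gg$end <- gg$start + sample.int(150, 30)
  gg$gene_id <- sprintf("g%02d", 1:30)
  out2 <- annotate_regions(rr, gg)
  hits <- oracle_interval_overlap(rr, gg)
  for (i in 1:20) {
    ids <- gg$gene_id[hits[i, ]]
    ids <- ids[order(gg$start[hits[i, ]])]
    expect_equal(out2$genes[i], paste(ids, collapse = ","))
  }
})
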