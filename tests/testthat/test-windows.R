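test_that("window tiling follows the start/step/truncation rule", {
  w <- tile_windows(data.frame(scaffold = "s", length = 100000),
                    size = 50000, step = 25000)
  expect_equal(w$start, c(0, 25000, 50000, 75000))
  expect_equal(w$end, c(50000, 75000, 100000, 100000))

  # scaffold shorter than one window
  w2 <- tile_windows(data.frame(scaffold = "s", length = 40000))
  expect_equal(nrow(w2), 1L)
  expect_equal(c(w2$start, w2$end), c(0, 40000))

  # step == size: exact non-overlapping cover
  w3 <- tile_windows(data.frame(scaffold = "s", length = 120000),
                     size = 50000, step = 50000)
  expect_equal(w3$start, c(0, 50000, 100000))
  expect_equal(sum(w3$end - w3$start), 120000)

  expect_error(tile_windows(data.frame(scaffold = "s", length = 0)),
               "positive")
  expect_error(tile_windows(data.frame(scaffold = "s", length = 10),
                            size = 10, step = 20), "size >= step")
})

test_that("site-to-window assignment matches a brute-force membership oracle", {
  set.seed(201)
  lens <- data.frame(scaffold = c("s1", "s2"), length = c(237000, 61000))
  w <- tile_windows(lens, size = 50000, step = 25000)
  for (sc in lens$scaffold) {
    pos0 <- sample.int(lens$length[lens$scaffold == sc], 200) - 1L
    wsc <- w[w$scaffold == sc, ]
    expected <- oracle_window_membership(pos0, wsc)
    maf <- data.frame(scaffold = sc, pos = pos0 + 1L, maf = 1, status = "ok")
    got <- window_mean_maf(maf, wsc)  # counts = membership multiplicity
    counts <- tabulate(unlist(expected), nbins = nrow(wsc))
    expect_equal(got$n_maf_sites, counts)
    expect_true(all(lengths(expected) <= ceiling(50000 / 25000)))
  }
})

test_that("window mean MAF averages ok sites, with boundary sites shared", {
  w <- tile_windows(data.frame(scaffold = "s", length = 100000))
  maf <- data.frame(scaffold = "s",
                    pos = c(1000, 2000, 3000, 26000, 60000),
                    maf = c(0.1, 0.3, NA, 0.2, 0.4),
                    status = c("ok", "ok", "low_depth", "ok", "ok"))
  ws <- window_mean_maf(maf, w)
  expect_equal(ws$mean_maf[1], mean(c(0.1, 0.3, 0.2)))  # window [0,50k)
  # sites at 26000 and 60000 both fall in [25k,75k); 26000 is shared with
  # the first window
  expect_equal(ws$mean_maf[2], mean(c(0.2, 0.4)))
  expect_equal(ws$n_maf_sites, c(3L, 2L, 1L, 0L))

  # empty window undefined
  maf2 <- maf[maf$pos < 50000, ]
  ws2 <- window_mean_maf(maf2, w)
  expect_true(is.na(ws2$mean_maf[4]))

  # monomorphic sites enter as zero only when requested
  maf3 <- data.frame(scaffold = "s", pos = c(1000, 2000),
                     maf = c(0.4, NA), status = c("ok", "monomorphic"))
  expect_equal(window_mean_maf(maf3, w)$mean_maf[1], 0.4)
  expect_equal(window_mean_maf(maf3, w, include_monomorphic = TRUE)$mean_maf[1],
               0.2)
})

test_that("fixed-difference counts are conserved across a non-overlapping tiling", {
  set.seed(202)
  lens <- data.frame(scaffold = c("s1", "s2"), length = c(200000, 90000))
  nw <- tile_windows(lens, size = 50000, step = 50000)
  n <- 500
  sc <- sample(lens$scaffold, n, replace = TRUE)
  pos <- ifelse(sc == "s1", sample.int(200000, n, TRUE),
                sample.int(90000, n, TRUE))
  a <- sample(c(0:2, NA), n, replace = TRUE)
  b <- sample(c(0:2, NA), n, replace = TRUE)
  fd <- window_fixed_differences(sc, pos, a, b, nw)
  total <- sum((a == 0 & b == 2) | (a == 2 & b == 0), na.rm = TRUE)
  expect_equal(sum(fd$fixed_diffs), total)

  # definitional cases
  one <- window_fixed_differences("s1", 10, 0, 2, nw[nw$scaffold == "s1", ])
  expect_equal(one$fixed_diffs[1], 1L)
  het <- window_fixed_differences("s1", 10, 1, 2, nw[nw$scaffold == "s1", ])
  expect_equal(sum(het$fixed_diffs), 0L)
  ident <- window_fixed_differences(sc, pos, a, a, nw)
  expect_equal(sum(ident$fixed_diffs, na.rm = TRUE), 0L)
})

test_that("RPKM and median-scaled depth follow their definitions", {
  expect_equal(rpkm(100, 1000, 1e6), 100)
  expect_equal(rpkm(100, 1000, 2e6), 50)   # doubling the library halves it
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_error(rpkm(10, 0, 1e6), "positive")

  expect_equal(relative_window_depth(c(10, 20, 30)), c(0.5, 1, 1.5))
  expect_equal(relative_window_depth(rep(7, 5)), rep(1, 5))
  set.seed(203)
  for (i in 1:10) {
    x <- rgamma(2 * sample(5:50, 1) + 1, 5, 0.1)  # odd count
    expect_equal(stats::median(relative_window_depth(x)), 1)
  }
})
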