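test_that("sliding-window means are exact", {
  tr <- make_track(c1 = rep(5L, 10000))
  wm <- sliding_window_mean(tr, w = 2000, step = 500)
  expect_true(all(wm$mean == 5))
  expect_equal(wm$end - wm$start, rep(2000, nrow(wm)))

  # a single base carrying depth w averages to exactly 1 in its best window
  d <- integer(10000); d[5000] <- 2000L
  tr2 <- make_track(c1 = d)
  expect_equal(max(sliding_window_mean(tr2, w = 2000, step = 100)$mean), 1)

  # brute-force re-summation oracle on random tracks
  for (seed in 1:4) {
    set.seed(seed)
    d <- as.integer(rpois(50000, 4))
    tr3 <- make_track(c1 = d)
    w <- sample(c(1000, 2000, 5000), 1); st <- sample(c(100, 250, 500), 1)
    expect_equal(sliding_window_mean(tr3, w = w, step = st)$mean,
                 naive_window_means(d, w, st), tolerance = 1e-9)
  }

  expect_error(sliding_window_mean(make_track(c1 = rep(1L, 100)), w = 200,
                                   step = 50),
               "exceeds")
  expect_error(sliding_window_mean(tr, w = 100, step = 200), "step")
})

test_that("background threshold is mean + 3 sample SD of window means", {
  tr <- make_track(c1 = rep(3L, 8000))
  expect_equal(as.numeric(background_threshold(tr, w = 2000, step = 2000)), 3)

  # window means {0,0,0,4}: mean 1, sd 2, threshold 7
  d <- c(rep(0L, 6000), rep(4L, 2000))
  thr <- background_threshold(make_track(c1 = d), w = 2000, step = 2000)
  expect_equal(as.numeric(thr), 7)
  expect_equal(attr(thr, "mean"), 1)
  expect_equal(attr(thr, "sd"), 2)

  expect_error(background_threshold(
    make_track(c1 = rep(1L, 4000)), exclude = data.frame(
      chrom = "c1", start = 0, end = 4000), w = 2000, step = 2000),
    "fewer than 2")
})

test_that("enriched loci exceed the reference background threshold", {
  runs <- cached_paired_runs()
  enr <- runs$enriched; ref <- runs$reference
  thr <- as.numeric(background_threshold(ref$track, w = 20000, step = 2000))
  wm_enr <- sliding_window_mean(enr$track, 20000, 2000)
  wm_ref <- sliding_window_mean(ref$track, 20000, 2000)
  at_loci <- function(wm) {
    hit <- rep(FALSE, nrow(wm))
    for (i in seq_len(nrow(enr$genome$loci))) {
      m <- enr$genome$loci$midpoint[i]
      hit <- hit | (wm$chrom == enr$genome$loci$chrom[i] &
                      wm$start <= m & wm$end > m)
    }
    hit
  }
  expect_true(all(wm_enr$mean[at_loci(wm_enr)] > thr))
  expect_true(all(wm_ref$mean[at_loci(wm_ref)] < thr))
})

test_that("the specificity scan finds exactly the planted differences", {
  set.seed(99)
  d <- as.integer(rpois(50000, 3))
  tr <- make_track(c1 = d)
  # self-comparison is empty for any threshold
  expect_equal(nrow(specificity_scan(tr, tr, X = 1, w = 2000, step = 500)), 0)
  expect_equal(nrow(specificity_scan(tr, tr, X = 100, w = 2000, step = 500)), 0)

  # one planted >=X region merges into a single enriched-only interval
  d2 <- d; d2[20001:26000] <- d2[20001:26000] + 60L
  tr2 <- make_track(c1 = d2)
  sc <- specificity_scan(tr2, tr, X = 30, w = 2000, step = 500)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$direction, "enriched_only")
  expect_lte(sc$start, 20000)
  expect_gte(sc$end, 26000)
  expect_lt(sc$end - sc$start, 6000 + 2 * 2000 + 1000)

  # X above the global maximum: empty
  expect_equal(nrow(specificity_scan(tr2, tr, X = 1e6)), 0)
  expect_error(specificity_scan(tr, make_track(c1 = rep(1L, 100))),
               "different genomes")
})

test_that("fold enrichment is a depth ratio with the right invariances", {
  tr <- make_track(c1 = rep(7L, 100000))
  locus <- data.frame(chrom = "c1", midpoint = 50000)
  expect_equal(as.numeric(fold_enrichment(tr, locus, 20000)), 1)

  # genome mean 2, probe window mean 63.2 -> 31.6-fold
  d <- integer(100000)
  win <- 49501:50500
  d[win] <- c(rep(63L, 800), rep(64L, 200))
  rest <- setdiff(seq_len(100000), win)
  d[rest[1:37800]] <- d[rest[1:37800]] + 2L
  d[rest[-(1:37800)]] <- d[rest[-(1:37800)]] + 1L
  stopifnot(sum(d) == 200000)
  tr2 <- make_track(c1 = d)
  expect_equal(as.numeric(fold_enrichment(tr2, locus, 1000)), 31.6,
               tolerance = 1e-12)

  # scale invariance: tripling the track leaves folds unchanged
  tr3 <- make_track(c1 = 3L * d)
  expect_equal(as.numeric(fold_enrichment(tr3, locus, 1000)),
               as.numeric(fold_enrichment(tr2, locus, 1000)))

  expect_attr_clipped <- fold_enrichment(tr2, data.frame(chrom = "c1",
                                                         midpoint = 100),
                                         10000)
  expect_true(attr(expect_attr_clipped, "clipped"))
  expect_error(fold_enrichment(make_track(c1 = integer(100)), locus, 10),
               "zero")
})

test_that("FWHM of an exact triangle equals the fragment length", {
  L <- 1000L
  mid <- 25000L
  d <- pmax(0L, 1000L - abs(seq_len(50000) - mid))
  tr <- make_track(c1 = d)
  locus <- data.frame(chrom = "c1", midpoint = mid)
  est <- fwhm_fragment_size(tr, locus, half_span = 20000, baseline = "none",
                            smooth_w = NULL)
  expect_equal(as.numeric(est), L)

  # flat profile: no peak above baseline
  expect_error(fwhm_fragment_size(make_track(c1 = rep(5L, 50000)), locus,
                                  half_span = 20000),
               "no coverage peak")

  # clipped profile: a crossing side is missing
  half <- pmax(0L, 1000L - abs(seq_len(50000) - 1L))
  expect_error(fwhm_fragment_size(make_track(c1 = half),
                                  data.frame(chrom = "c1", midpoint = 1),
                                  half_span = 20000, baseline = "none",
                                  smooth_w = NULL),
               "left")
})

test_that("box smoothing bias is corrected on triangular peaks", {
  mid <- 100000L
  L <- 40000
  d <- as.integer(round(pmax(0, 1 - abs(seq_len(2e5) - mid) / L) * 1000))
  tr <- make_track(c1 = d)
  locus <- data.frame(chrom = "c1", midpoint = mid)
  est <- fwhm_fragment_size(tr, locus, half_span = 90000, baseline = "none",
                            smooth_w = 5000)
  expect_lt(abs(as.numeric(est) - L) / L, 0.01)
})

test_that("coverage uniformity fractions form a valid survival curve", {
  tr <- make_track(c1 = rep(30L, 1000))
  reg <- data.frame(chrom = "c1", start = 0, end = 1000)
  u <- coverage_uniformity(tr, reg, depths = c(30, 31))
  expect_equal(unname(u$fractions), c(1, 0))

  tr2 <- make_track(c1 = c(5L, 10L, 15L, 20L))
  u2 <- coverage_uniformity(tr2, data.frame(chrom = "c1", start = 0, end = 4),
                            depths = 10)
  expect_equal(unname(u2$fractions), 0.75)
  # strict mode drops the boundary base
  u2s <- coverage_uniformity(tr2, data.frame(chrom = "c1", start = 0, end = 4),
                             depths = 10, at_or_above = FALSE)
  expect_equal(unname(u2s$fractions), 0.5)

  # CDF is non-increasing, starts at 1 for depth 0 regions with zeros
  set.seed(7)
  d <- as.integer(rpois(20000, 30))
  u3 <- coverage_uniformity(make_track(c1 = d),
                            data.frame(chrom = "c1", start = 0, end = 20000),
                            depths = 30)
  expect_true(all(diff(u3$cdf$fraction) <= 0))
  # Poisson survival oracle: P[X >= 30], X ~ Pois(30)
  p30 <- 1 - ppois(29, 30)
  expect_lt(abs(u3$fractions[[1]] - p30), 3 * sqrt(p30 * (1 - p30) / 20000))

  expect_error(coverage_uniformity(tr, reg[0, ]), "non-empty")
})
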