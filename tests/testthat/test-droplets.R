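test_that("fragmentation tiles the genome exactly and reproducibly", {
  g <- tiny_genome(len = 10000, seed = 1)
  fm <- fragment_model(mean = 1000, family = "fixed")
  fr <- fragment_genome(g, fm, n_copies = 1, phase = "zero", seed = 2)
  expect_equal(nrow(fr), 10)
  expect_equal(sum(fr$end - fr$start), 10000)
  # every base covered exactly once
  cov <- naive_coverage(fr, 10000)
  expect_true(all(cov == 1L))

  fr2 <- fragment_genome(g, fm, n_copies = 1, phase = "zero", seed = 2)
  expect_identical(fr, fr2)

  # random phase: still an exact single-coverage tiling, but breakpoints
  # differ between copies
  frp <- fragment_genome(g, fm, n_copies = 2, seed = 3)
  expect_true(all(naive_coverage(frp[frp$copy == 1, ], 10000) == 1L))
  expect_false(identical(frp$start[frp$copy == 1][2],
                         frp$start[frp$copy == 2][2]))

  # conservation across copies for random lengths
  fr3 <- fragment_genome(g, fragment_model(mean = 700, sd = 100,
                                           min_len = 60), 4, seed = 3)
  expect_equal(sum(fr3$end - fr3$start), 4 * 10000)

  expect_error(fragment_genome(g, fragment_model(mean = 20000), 1, seed = 1),
               "exceeds")
})

test_that("fragment lengths recover the configured distribution", {
  g <- build_genome(c(c1 = 5e6), n_loci = 0, seed = 9)
  fr <- fragment_genome(g, fragment_model(mean = 52400, sd = 5706,
                                          min_len = 200), 10, seed = 4)
  # exclude the phase/end-truncated fragments at the chromosome boundaries
  interior <- fr$start > 0 & fr$end < 5e6
  full <- (fr$end - fr$start)[interior]
  expect_lt(abs(mean(full) - 52400), 3 * 5706 / sqrt(length(full)))
})

test_that("encapsulation follows the digital-PCR Poisson law", {
  g <- tiny_genome(len = 20000, seed = 5, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 6)
  # lambda_t = 0: no positives
  d0 <- encapsulate(fr, 1000, lambda_t = 0, lambda_b = 1,
                    amplicons = g$loci, seed = 7)
  expect_equal(sum(d0$taqman), 0)

  # positive fraction within 3 binomial SE of 1 - exp(-lambda)
  lam <- 0.013085
  N <- 2e5
  d <- encapsulate(fr, N, lambda_t = lam, lambda_b = 0,
                   amplicons = g$loci, replace = "always", seed = 8)
  p <- positive_fraction(lam)
  expect_lt(abs(mean(d$taqman) - p), 3 * sqrt(p * (1 - p) / N))

  # occupancy histogram consistent with Poisson(2)
  db <- encapsulate(fr, 1e5, lambda_t = 0, lambda_b = 2, seed = 9)
  occ <- db$n_background
  kmax <- 8
  obs <- tabulate(pmin(occ, kmax) + 1L, nbins = kmax + 1L)
  pr <- c(dpois(0:(kmax - 1), 2), 1 - ppois(kmax - 1, 2))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)

  expect_error(encapsulate(fr[0, ], 100, lambda_t = 0.5, lambda_b = 0,
                           amplicons = g$loci, seed = 1), "no target")
})

test_that("without-replacement encapsulation conserves molecules", {
  g <- tiny_genome(len = 50000, seed = 10, min_spacing = 10000)
  fr <- fragment_genome(g, fragment_model(mean = 500, family = "fixed"),
                        10, seed = 11)
  d <- encapsulate(fr, 200, lambda_t = 0.01, lambda_b = 0.5,
                   amplicons = g$loci, replace = "never", seed = 12)
  expect_false(d$replace_used)
  # each physical fragment in at most one droplet
  expect_false(any(duplicated(d$assignment$fragment)))
  # droplet content sums match the Poisson draws
  expect_equal(nrow(d$assignment), sum(d$n_target) + sum(d$n_background))
  expect_error(encapsulate(fr, 1e5, lambda_t = 1, lambda_b = 1,
                           amplicons = g$loci, replace = "never", seed = 1),
               "too small")
})

test_that("fluorescence separates classes and forms merged droplets", {
  g <- tiny_genome(len = 20000, seed = 13, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 14)
  d <- encapsulate(fr, 2e4, lambda_t = 0.05, lambda_b = 0.1,
                   amplicons = g$loci, replace = "always", seed = 15)
  f <- fluoresce(d, mu_neg = 0.2, sd_neg = 0, mu_pos = 0.8, sd_pos = 0,
                 merge_rate = 0, seed = 16)
  expect_true(all(f$amplitude[f$taqman] == 0.8))
  expect_true(all(f$amplitude[!f$taqman] == 0.2))

  fm <- fluoresce(d, merge_rate = 0.02, seed = 17)
  pm <- mean(fm$merged)
  expect_lt(abs(pm - 0.02), 3 * sqrt(0.02 * 0.98 / d$n))
  expect_gt(mean(fm$width[fm$merged]), 1.8 * mean(fm$width[!fm$merged]))

  # PCR-failed positives fluoresce like negatives
  dfail <- encapsulate(fr, 5e3, lambda_t = 0.5, lambda_b = 0,
                       amplicons = g$loci, pcr_failure_rate = 1,
                       replace = "always", seed = 18)
  ff <- fluoresce(dfail, sd_neg = 0, sd_pos = 0, seed = 19)
  expect_true(all(ff$amplitude[dfail$n_target > 0] == 0.2))
})

test_that("sorting computes purity and reacts to gates and false sorts", {
  g <- tiny_genome(len = 20000, seed = 20, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 21)
  d <- encapsulate(fr, 5e4, lambda_t = 0.02, lambda_b = 0.05,
                   amplicons = g$loci, replace = "always", seed = 22)
  f <- fluoresce(d, sd_neg = 0, sd_pos = 0, seed = 23)

  # perfect separation: purity 1, all positives recovered
  pool <- sort_droplets(f, threshold = 0.5, seed = 24)
  expect_equal(pool$counts$purity, 1)
  expect_equal(pool$counts$sorted, sum(d$taqman))

  # threshold above all amplitudes: warning + empty pool
  expect_warning(empty <- sort_droplets(f, threshold = 99, seed = 25),
                 "empty pool")
  expect_equal(empty$counts$sorted, 0)
  expect_equal(nrow(empty$fragments), 0)

  # purity decreases with false sorts, matching the analytic droplet purity
  f2 <- sort_droplets(f, threshold = 0.5, false_sort_rate = 0.01, seed = 26)
  expect_lt(f2$counts$purity, 1)
  exp_p <- expected_droplet_purity(0.02, 0.01)
  se <- sqrt(exp_p * (1 - exp_p) / f2$counts$sorted)
  expect_lt(abs(f2$counts$purity - exp_p), 4 * se)
})

test_that("sorted purity reproduces the 2.3% -> 87.6% enrichment", {
  g <- tiny_genome(len = 20000, seed = 27, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 28)
  lam <- lambda_from_fraction(0.023)
  fsr <- calibrate_false_sort_rate(lam, 0.876)
  d <- encapsulate(fr, 4e5, lambda_t = lam, lambda_b = 0.05,
                   amplicons = g$loci, replace = "always", seed = 29)
  f <- fluoresce(d, sd_neg = 0, sd_pos = 0, seed = 30)
  pool <- sort_droplets(f, threshold = 0.5, false_sort_rate = fsr, seed = 31)
  se <- sqrt(0.876 * (1 - 0.876) / pool$counts$sorted)
  expect_lt(abs(pool$counts$purity - 0.876), 3 * se)
})

test_that("amplicon removal and WGA behave as specified", {
  g <- tiny_genome(len = 20000, seed = 32, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 33)
  d <- encapsulate(fr, 2e4, lambda_t = 0.05, lambda_b = 0.05,
                   amplicons = g$loci, replace = "always", seed = 34)
  f <- fluoresce(d, sd_neg = 0, sd_pos = 0, seed = 35)
  pool <- sort_droplets(f, threshold = 0.5, amplicon_copies = 500, seed = 36)
  n_genomic <- nrow(pool$fragments)
  expect_gt(sum(pool$amplicons$copies), 0)

  cleaned <- remove_amplicons(pool, 0)
  expect_null(cleaned$amplicons)
  expect_equal(nrow(cleaned$fragments), n_genomic)

  # residual amplicons show up as a coverage spike over the amplicon interval
  kept <- remove_amplicons(pool, 1)
  rd_kept <- simulate_reads(kept, g, n_reads = 2e4, read_len = 50,
                            error_rate = 0, seed = 37)
  rd_clean <- simulate_reads(cleaned, g, n_reads = 2e4, read_len = 50,
                             error_rate = 0, seed = 37)
  amp_mid <- g$loci$midpoint[1]
  cov_kept <- coverage_track(rd_kept, g)$depth[["c1"]][amp_mid]
  cov_clean <- coverage_track(rd_clean, g)$depth[["c1"]][amp_mid]
  expect_gt(cov_kept, 3 * max(cov_clean, 1))

  # WGA: identity at sigma 0; copies never drop below 1
  expect_identical(wga_amplify(pool, 0, seed = 38)$fragments$copies,
                   pool$fragments$copies)
  amp <- wga_amplify(pool, 1, seed = 39)
  expect_true(all(amp$fragments$copies >= 1))
  expect_gte(sum(amp$fragments$copies), nrow(amp$fragments))
})

test_that("WGA copy dispersion matches the truncated-lognormal moments", {
  pool <- structure(list(
    fragments = data.frame(chrom = "c1", start = 0, end = 100,
                           is_target = FALSE, amp_id = NA,
                           copies = rep(1, 1e4)),
    amplicons = NULL,
    counts = list(screened = 0, taqman_positive = 0, sorted = 0,
                  merged_sorted = 0, target_sorted = 0, purity = NA),
    replace_used = FALSE), class = "mesa_pool")
  sig <- 1
  amp <- wga_amplify(pool, sig, seed = 40)
  cp <- amp$fragments$copies

  # independent oracle: moments of pmax(1, round(LN(0, sig)/exp(sig^2/2)))
  # computed from the lognormal CDF, not by re-running the sampler
  kmax <- 200
  edges <- seq(0.5, kmax + 0.5)
  pk <- diff(plnorm(edges * exp(sig^2 / 2), 0, sig))
  p1 <- plnorm(1.5 * exp(sig^2 / 2), 0, sig)     # mass mapped to copy 1
  probs <- c(p1, pk[-1])
  k <- seq_len(kmax)
  mu <- sum(k * probs) + kmax * (1 - sum(probs))
  v <- sum((k - mu)^2 * probs)
  expect_lt(abs(mean(cp) - mu), 3 * sqrt(v / length(cp)))
  cv_expected <- sqrt(v) / mu
  cv_obs <- sd(cp) / mean(cp)
  expect_lt(abs(cv_obs - cv_expected) / cv_expected, 0.1)
})

test_that("purity and recovery respond monotonically to error rates", {
  g <- tiny_genome(len = 20000, seed = 41, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 42)
  purity_at <- function(fsr) {
    d <- encapsulate(fr, 1e5, lambda_t = 0.02, lambda_b = 0.05,
                     amplicons = g$loci, replace = "always", seed = 43)
    f <- fluoresce(d, sd_neg = 0, sd_pos = 0, seed = 44)
    sort_droplets(f, threshold = 0.5, false_sort_rate = fsr,
                  seed = 45)$counts$purity
  }
  p <- vapply(c(0, 0.005, 0.02, 0.1), purity_at, numeric(1))
  expect_true(all(diff(p) <= 0))

  recovery_at <- function(pf) {
    d <- encapsulate(fr, 1e5, lambda_t = 0.02, lambda_b = 0,
                     amplicons = g$loci, pcr_failure_rate = pf,
                     replace = "always", seed = 46)
    f <- fluoresce(d, sd_neg = 0, sd_pos = 0, seed = 47)
    sum(sort_droplets(f, threshold = 0.5, seed = 48)$fragments$is_target)
  }
  r <- vapply(c(0, 0.2, 0.5, 0.9), recovery_at, numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("the droplet stage is bit-identical under a fixed seed", {
  g <- tiny_genome(len = 20000, seed = 49, min_spacing = 4000)
  fr <- fragment_genome(g, fragment_model(mean = 2000, family = "fixed"),
                        2, seed = 50)
  run_once <- function() {
    d <- encapsulate(fr, 1e4, lambda_t = 0.02, lambda_b = 0.05,
                     amplicons = g$loci, replace = "always", seed = 51)
    f <- fluoresce(d, merge_rate = 0.02, seed = 52)
    sort_droplets(f, threshold = 0.5, false_sort_rate = 0.002, seed = 53)
  }
  expect_identical(run_once(), run_once())
})
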