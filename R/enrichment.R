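# Coverage-based enrichment statistics: sliding-window means, mean+3SD
# background threshold, differential specificity scan, probe-centered fold
# enrichment versus window size, FWHM fragment-size estimation, and
# coverage-uniformity CDFs.

#' Sliding-window mean coverage
#'
#' Window `k` covers `[k*step, k*step + w)`; tails shorter than `w` are
#' dropped (the count of dropped tail windows is recorded in the
#' `"n_dropped_tails"` attribute), not rescaled.
#'
#' @param track A `mesa_coverage`.
#' @param w Window size in bp (default 20 kb).
#' @param step Step in bp (default 2 kb); must not exceed `w`.
#' @return data.frame with `chrom`, `start`, `end`, `mean`.
#' @export
sliding_window_mean <- function(track, w = 20000, step = 2000) {
  stopifnot(inherits(track, "mesa_coverage"))
  .assert_scalar_number(w, "w", 1)
  .assert_scalar_number(step, "step", 1)
  if (step > w) stop("step must not exceed window size", call. = FALSE)
  n_dropped <- 0L
  out <- lapply(names(track$depth), function(cn) {
    d <- track$depth[[cn]]
    len <- length(d)
    if (w > len) stop(sprintf("window (%d) exceeds chromosome %s (%d)",
                              w, cn, len), call. = FALSE)
    starts <- seq.int(0L, len, by = step)
    full <- starts + w <= len
    n_dropped <<- n_dropped + sum(!full)
    starts <- starts[full]
    cs <- c(0, cumsum(as.numeric(d)))
    data.frame(chrom = cn, start = starts, end = starts + w,
               mean = (cs[starts + w + 1L] - cs[starts + 1L]) / w,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_tails") <- n_dropped
  res
}

# Windows overlapping any exclusion interval (0-based half-open).
.windows_excluded <- function(windows, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0L) {
    return(rep(FALSE, nrow(windows)))
  }
  wg <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start + 1L,
                                                windows$end))
  eg <- GenomicRanges::GRanges(exclude$chrom,
                               IRanges::IRanges(exclude$start + 1L,
                                                exclude$end))
  IRanges::overlapsAny(wg, eg)
}

#' Background coverage threshold: mean + 3 SD of window means
#'
#' The classic significance heuristic for calling a region's coverage
#' "enhanced": windows of a (reference) track are summarized and any window
#' above `mean + 3*sd` of those means is beyond background variation. The
#' sample (n-1) standard deviation is used.
#'
#' @param track A `mesa_coverage`.
#' @param exclude Optional data.frame of intervals whose overlapping windows
#'   are excluded (e.g. the target loci themselves).
#' @param w,step Window parameters, as in [sliding_window_mean()].
#' @return Numeric threshold; attributes `mean` and `sd` carry the pieces.
#' @export
background_threshold <- function(track, exclude = NULL, w = 20000,
                                 step = 2000) {
  wm <- sliding_window_mean(track, w = w, step = step)
  wm <- wm[!.windows_excluded(wm, exclude), , drop = FALSE]
  if (nrow(wm) < 2L) {
    stop("fewer than 2 windows remain after exclusion", call. = FALSE)
  }
  mu <- mean(wm$mean)
  sdev <- stats::sd(wm$mean)
  structure(mu + 3 * sdev, mean = mu, sd = sdev)
}

#' Differential specificity scan between two coverage tracks
#'
#' Finds windows whose mean coverage reaches the minimum threshold `X` in one
#' track but not the other, and merges consecutive qualifying windows into
#' maximal intervals. This is the genome-wide check that enrichment appears
#' only at the intended loci.
#'
#' @param enriched,reference `mesa_coverage` tracks over the same genome.
#' @param X Minimum mean coverage threshold (default 56).
#' @param w,step Window parameters.
#' @return data.frame with `chrom`, `start`, `end`, `direction`
#'   (`"enriched_only"` / `"reference_only"`), `max_mean`.
#' @export
specificity_scan <- function(enriched, reference, X = 56, w = 20000,
                             step = 2000) {
  stopifnot(inherits(enriched, "mesa_coverage"),
            inherits(reference, "mesa_coverage"))
  if (!identical(lapply(enriched$depth, length),
                 lapply(reference$depth, length))) {
    stop("tracks are over different genomes", call. = FALSE)
  }
  we <- sliding_window_mean(enriched, w = w, step = step)
  wr <- sliding_window_mean(reference, w = w, step = step)

  merge_runs <- function(win, means, direction) {
    if (nrow(win) == 0L) return(NULL)
    o <- order(win$chrom, win$start)
    win <- win[o, , drop = FALSE]
    means <- means[o]
    new_run <- c(TRUE, win$chrom[-1] != win$chrom[-nrow(win)] |
                   win$start[-1] > win$end[-nrow(win)])
    run <- cumsum(new_run)
    data.frame(
      chrom = tapply(win$chrom, run, `[`, 1L),
      start = as.vector(tapply(win$start, run, min)),
      end = as.vector(tapply(win$end, run, max)),
      direction = direction,
      max_mean = as.vector(tapply(means, run, max)),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  up <- we$mean >= X & wr$mean < X
  dn <- wr$mean >= X & we$mean < X
  res <- rbind(merge_runs(we[up, , drop = FALSE], we$mean[up], "enriched_only"),
               merge_runs(wr[dn, , drop = FALSE], wr$mean[dn], "reference_only"))
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      direction = character(), max_mean = numeric(),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Probe-centered fold enrichment
#'
#' Mean depth over the window of size `s` centered on the probe midpoint,
#' divided by the genome-wide mean depth (which includes the target regions:
#' a conservative denominator). Windows clipped at chromosome ends are used
#' as clipped and flagged.
#'
#' @param track A `mesa_coverage`.
#' @param locus A one-row data.frame with `chrom` and `midpoint` (e.g. one row
#'   of `genome$loci`).
#' @param s Window size in bp.
#' @return Fold enrichment (numeric); attribute `clipped` is `TRUE` when the
#'   window hit a chromosome end.
#' @export
fold_enrichment <- function(track, locus, s) {
  stopifnot(inherits(track, "mesa_coverage"))
  .assert_scalar_number(s, "s", 1)
  if (track$mean_depth == 0) stop("genome-wide mean depth is zero",
                                  call. = FALSE)
  d <- track$depth[[locus$chrom[1]]]
  if (is.null(d)) stop("locus chromosome not in track", call. = FALSE)
  mid <- locus$midpoint[1]
  lo <- max(0L, as.integer(round(mid - s / 2)))
  hi <- min(length(d), as.integer(round(mid + s / 2)))
  clipped <- (hi - lo) < s
  fold <- mean(d[(lo + 1L):hi]) / track$mean_depth
  structure(fold, clipped = clipped)
}

#' Estimate encapsulated fragment size from the coverage peak width (FWHM)
#'
#' A fragment of length `L` that covers the probe point covers a point at
#' distance `d` with probability `max(0, 1 - |d|/L)`, so the mean coverage
#' profile around a probe is triangular with full width at half maximum equal
#' to `L`. The estimator subtracts a baseline (genome-wide mean by default),
#' finds the profile maximum near the probe, and locates the two half-maximum
#' crossings by scanning outward from the peak with linear interpolation.
#'
#' @param track A `mesa_coverage`.
#' @param locus One-row data.frame with `chrom`, `midpoint`.
#' @param half_span Half-width of the profile extracted around the probe
#'   (default 150 kb; must exceed the expected fragment length).
#' @param baseline `"genome"` subtracts the genome-wide mean depth, `"none"`
#'   uses the raw profile, or a number.
#' @param smooth_w Box-smoothing window in bp (default 5 kb), needed because
#'   raw per-base profiles carry sharp duplicate/WGA spikes that defeat the
#'   half-maximum search. A box of width `w` widens a triangular peak's FWHM
#'   by exactly `w/4`; that bias is subtracted from the estimate. Use
#'   `smooth_w = NULL` for the raw profile (appropriate for dense, low-noise
#'   profiles).
#' @return FWHM in bp; attributes `peak_pos` and `peak_height`.
#' @export
fwhm_fragment_size <- function(track, locus, half_span = 150000,
                               baseline = "genome", smooth_w = 5000) {
  stopifnot(inherits(track, "mesa_coverage"))
  d <- track$depth[[locus$chrom[1]]]
  if (is.null(d)) stop("locus chromosome not in track", call. = FALSE)
  mid <- locus$midpoint[1]
  lo <- max(0L, as.integer(mid - half_span))
  hi <- min(length(d), as.integer(mid + half_span))
  prof <- as.numeric(d[(lo + 1L):hi])
  widen <- 0
  if (!is.null(smooth_w) && smooth_w > 1) {
    k <- as.integer(smooth_w)
    prof <- as.numeric(stats::filter(prof, rep(1 / k, k), sides = 2))
    widen <- k / 4
  }
  base <- if (identical(baseline, "genome")) {
    track$mean_depth
  } else if (identical(baseline, "none")) 0 else as.numeric(baseline)
  prof <- prof - base

  ok <- which(!is.na(prof))
  peak <- ok[which.max(prof[ok])]
  h <- prof[peak]
  # tolerance guards against float residue of a flat profile minus baseline
  if (!is.finite(h) || h <= 1e-6 * max(1, base)) {
    stop("no coverage peak above baseline at this locus", call. = FALSE)
  }
  half <- h / 2

  cross <- function(side) {
    idx <- if (side == "left") seq(peak, 1L) else seq(peak, length(prof))
    v <- prof[idx]
    below <- which(!is.na(v) & v < half)
    if (length(below) == 0L) {
      stop(sprintf("profile clipped: no half-maximum crossing on the %s side",
                   side), call. = FALSE)
    }
    j <- below[1]
    # linear interpolation between samples j-1 (>= half) and j (< half)
    v1 <- v[j - 1L]; v2 <- v[j]
    frac <- (v1 - half) / (v1 - v2)
    (j - 2L + frac) # distance from the peak in bp
  }
  left <- cross("left")
  right <- cross("right")
  structure(max(left + right - widen, 0),
            peak_pos = lo + peak - 1L, peak_height = h)
}

#' Coverage uniformity within target regions
#'
#' Cumulative fraction of region bases covered at or above each depth.
#'
#' @param track A `mesa_coverage`.
#' @param regions data.frame of intervals (`chrom`, `start`, `end`).
#' @param depths Depth cutoffs of interest (default 10 and 30).
#' @param at_or_above If `TRUE` (default) a base at exactly depth `d` counts
#'   toward the `d` cutoff (`>= d`); `FALSE` uses strict `> d`.
#' @return list with `fractions` (named numeric, one per cutoff) and `cdf`
#'   (data.frame `depth`, `fraction` for every observed depth: the fraction of
#'   bases at or above that depth).
#' @export
coverage_uniformity <- function(track, regions, depths = c(10, 30),
                                at_or_above = TRUE) {
  stopifnot(inherits(track, "mesa_coverage"))
  if (is.null(regions) || nrow(regions) == 0L) {
    stop("regions must be non-empty", call. = FALSE)
  }
  vals <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    d <- track$depth[[regions$chrom[i]]]
    if (is.null(d)) stop("region chromosome not in track", call. = FALSE)
    d[(regions$start[i] + 1L):regions$end[i]]
  }), use.names = FALSE)
  n <- length(vals)
  fr <- vapply(depths, function(dd) {
    if (at_or_above) mean(vals >= dd) else mean(vals > dd)
  }, numeric(1))
  names(fr) <- paste0(if (at_or_above) ">=" else ">", depths, "X")
  tab <- table(vals)
  dep <- as.integer(names(tab))
  surv <- rev(cumsum(rev(as.numeric(tab)))) / n
  list(fractions = fr, cdf = data.frame(depth = dep, fraction = surv))
}

#' Full enrichment report for a simulated run
#'
#' Bundles the locus statistics: fold enrichment per probe-centered window
#' size, FWHM fragment-size estimates, uniformity within the probe-centered
#' uniformity window, and the sliding-window background threshold of a
#' reference track when given.
#'
#' @param track Enriched-sample `mesa_coverage`.
#' @param loci data.frame of target loci (`genome$loci`).
#' @param window_sizes Probe-centered window sizes in bp (default 50--200 kb).
#' @param w,step Sliding-window parameters.
#' @param depths Uniformity cutoffs.
#' @param uniformity_window Window (bp) around probes for uniformity
#'   (default 50 kb).
#' @param reference Optional reference `mesa_coverage` for the background
#'   threshold.
#' @return list of class `mesa_enrichment`: `folds` (locus x window size
#'   data.frame), `mean_folds`, `fwhm`, `uniformity`, `threshold`.
#' @export
enrichment_report <- function(track, loci,
                              window_sizes = c(50, 100, 150, 200) * 1000,
                              w = 20000, step = 2000, depths = c(10, 30),
                              uniformity_window = 50000, reference = NULL) {
  folds <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    data.frame(
      locus = loci$name[i],
      window_size = window_sizes,
      fold = vapply(window_sizes, function(s) {
        as.numeric(fold_enrichment(track, loci[i, ], s))
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }))
  mean_folds <- tapply(folds$fold, folds$window_size, mean)
  fwhm <- vapply(seq_len(nrow(loci)), function(i) {
    tryCatch(as.numeric(fwhm_fragment_size(track, loci[i, ])),
             error = function(e) NA_real_)
  }, numeric(1))
  names(fwhm) <- loci$name
  regions <- data.frame(
    chrom = loci$chrom,
    start = pmax(0, loci$midpoint - uniformity_window / 2),
    end = loci$midpoint + uniformity_window / 2)
  unif <- coverage_uniformity(track, regions, depths = depths)
  thr <- if (!is.null(reference)) {
    as.numeric(background_threshold(reference, w = w, step = step))
  } else NA_real_
  structure(list(folds = folds, mean_folds = mean_folds, fwhm = fwhm,
                 uniformity = unif, threshold = thr),
            class = "mesa_enrichment")
}

#' @export
print.mesa_enrichment <- function(x, ...) {
  cat("mesa_enrichment report\n")
  cat("  mean fold enrichment by window size:\n")
  for (s in names(x$mean_folds)) {
    cat(sprintf("    %6s kb: %.1f-fold\n",
                format(as.numeric(s) / 1000), x$mean_folds[[s]]))
  }
  cat(sprintf("  FWHM fragment-size estimates: %s bp\n",
              paste(format(round(x$fwhm)), collapse = ", ")))
  cat(sprintf("  target-base uniformity: %s\n",
              paste(sprintf("%s: %.1f%%", names(x$uniformity$fractions),
                            100 * x$uniformity$fractions), collapse = ", ")))
  if (!is.na(x$threshold)) {
    cat(sprintf("  reference background threshold (mean+3SD): %.2fx\n",
                x$threshold))
  }
  invisible(x)
}
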