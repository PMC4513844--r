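# Droplet workflow simulation: genome fragmentation, Poisson co-encapsulation
# into TaqMan digital-PCR droplets, fluorescence, threshold sorting with
# merged droplets and false sorts, enzymatic amplicon removal, and WGA copy
# dispersion.

#' Fragment-length model for high-molecular-weight input DNA
#'
#' Defaults describe gel-protected genomic DNA sheared to ~52.4 kb
#' (sd ~5.7 kb), the regime in which a single droplet-PCR-positive fragment
#' carries tens of kb of sequence flanking the ~100 bp assay site.
#'
#' @param mean Mean fragment length in bp.
#' @param sd Length standard deviation in bp (`family = "normal"` only).
#' @param min_len Minimum fragment length in bp (must be at least the read
#'   length used downstream).
#' @param family `"normal"` (truncated at `min_len`) or `"fixed"`.
#' @return A list of class `mesa_fragment_model`.
#' @export
fragment_model <- function(mean = 52400, sd = 5706, min_len = 200,
                           family = c("normal", "fixed")) {
  family <- match.arg(family)
  .assert_scalar_number(mean, "mean", 1)
  .assert_scalar_number(sd, "sd", 0)
  .assert_scalar_number(min_len, "min_len", 1)
  structure(list(mean = mean, sd = sd, min_len = min_len, family = family),
            class = "mesa_fragment_model")
}

.draw_lengths <- function(model, n) {
  if (model$family == "fixed" || model$sd == 0) {
    rep(model$mean, n)
  } else {
    plo <- stats::pnorm(model$min_len, model$mean, model$sd)
    stats::qnorm(stats::runif(n, plo, 1), model$mean, model$sd)
  }
}

#' Fragment a genome into high-molecular-weight pieces
#'
#' Each genome copy is cut independently at random breakpoints so that
#' fragments tile every chromosome without gaps or overlap: total fragment
#' bases equal `n_copies * G` exactly (the last fragment of each chromosome is
#' truncated at the end).
#'
#' @param genome A `mesa_genome`.
#' @param model A [fragment_model()].
#' @param n_copies Number of genome copies to fragment.
#' @param phase `"random"` (default) starts each copy's tiling at a uniformly
#'   random offset into the first fragment draw, so breakpoints are
#'   independent across copies — the stationary-renewal picture of physical
#'   shearing (with `"fixed"`-length fragments, phase 0 would give every copy
#'   identical breakpoints). `"zero"` anchors the first breakpoint at the
#'   chromosome start, giving a deterministic tiling for fixed lengths.
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `copy` (genome copy id).
#' @export
fragment_genome <- function(genome, model = fragment_model(), n_copies = 1,
                            phase = c("random", "zero"), seed = 1) {
  phase <- match.arg(phase)
  stopifnot(inherits(genome, "mesa_genome"),
            inherits(model, "mesa_fragment_model"))
  .assert_scalar_number(n_copies, "n_copies", 1)
  if (model$mean > max(genome$lengths)) {
    stop("mean fragment length exceeds every chromosome length", call. = FALSE)
  }
  .seed_stage(seed, "fragment")
  out <- vector("list", n_copies * length(genome$lengths))
  k <- 0L
  for (copy in seq_len(n_copies)) {
    for (chrom in names(genome$lengths)) {
      len <- genome$lengths[[chrom]]
      lens <- round(.draw_lengths(model, 1L))
      u <- if (phase == "random") floor(stats::runif(1) * lens[1]) else 0
      while (sum(lens) - u < len) {
        need <- ceiling((len + u - sum(lens)) / model$mean * 1.3) + 8L
        lens <- c(lens, round(.draw_lengths(model, need)))
      }
      cs <- cumsum(lens) - u
      bps <- cs[cs > 0 & cs < len]
      k <- k + 1L
      out[[k]] <- data.frame(chrom = chrom, start = c(0, bps),
                             end = c(bps, len),
                             copy = copy, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Mark fragments that fully contain an amplicon (both primer sites on the
# fragment); boundary-overlapping fragments cannot amplify and stay negative.
.classify_fragments <- function(fragments, amplicons) {
  fragments$is_target <- rep(FALSE, nrow(fragments))
  fragments$amp_id <- rep(NA_integer_, nrow(fragments))
  if (is.null(amplicons) || nrow(amplicons) == 0L ||
      nrow(fragments) == 0L) return(fragments)
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  am <- GenomicRanges::GRanges(amplicons$chrom,
                               IRanges::IRanges(amplicons$start + 1L,
                                                amplicons$end))
  hits <- GenomicRanges::findOverlaps(am, fr, type = "within")
  frag_hit <- S4Vectors::subjectHits(hits)
  amp_hit <- S4Vectors::queryHits(hits)
  keep <- !duplicated(frag_hit)
  fragments$is_target[frag_hit[keep]] <- TRUE
  fragments$amp_id[frag_hit[keep]] <- amp_hit[keep]
  fragments
}

#' Encapsulate fragments into digital-PCR droplets
#'
#' Per-droplet occupancy is Poisson: target and background fragment counts are
#' drawn independently as Poisson(`lambda_t`) and Poisson(`lambda_b`)
#' (equivalent to Poisson(`lambda_t + lambda_b`) total occupancy with
#' multinomial type labels). A droplet is TaqMan-positive iff it holds at
#' least one fragment fully containing an amplicon and its PCR did not fail.
#' The expected positive fraction is the digital-PCR law
#' `1 - exp(-lambda_t)` (times `1 - pcr_failure_rate`).
#'
#' @param fragments data.frame from [fragment_genome()].
#' @param n_droplets Number of droplets `N`.
#' @param lambda_t,lambda_b Mean target / background fragments per droplet.
#' @param amplicons data.frame of amplicon intervals (e.g. `genome$loci`).
#' @param pcr_failure_rate Probability a target-containing droplet fails to
#'   fluoresce.
#' @param replace `"auto"` samples fragments without replacement when the pool
#'   suffices and with replacement otherwise (recorded in the result);
#'   `"never"` errors instead of reusing molecules; `"always"` forces reuse so
#'   a desk-scale pool can feed millions of droplets.
#' @param seed Integer seed.
#' @return An object of class `mesa_droplets`.
#' @export
encapsulate <- function(fragments, n_droplets, lambda_t, lambda_b,
                        amplicons = NULL, pcr_failure_rate = 0,
                        replace = c("auto", "never", "always"), seed = 1) {
  replace <- match.arg(replace)
  .assert_scalar_number(n_droplets, "n_droplets", 1)
  .assert_scalar_number(lambda_t, "lambda_t", 0)
  .assert_scalar_number(lambda_b, "lambda_b", 0)
  .assert_rate(pcr_failure_rate, "pcr_failure_rate")
  n_droplets <- as.integer(n_droplets)

  fragments <- .classify_fragments(fragments, amplicons)
  target_pool <- which(fragments$is_target)
  bg_pool <- which(!fragments$is_target)
  if (lambda_t > 0 && length(target_pool) == 0L) {
    stop("lambda_t > 0 but no target-containing fragments", call. = FALSE)
  }
  if (lambda_b > 0 && length(bg_pool) == 0L) {
    stop("lambda_b > 0 but no background fragments", call. = FALSE)
  }

  .seed_stage(seed, "encapsulate")
  t_i <- stats::rpois(n_droplets, lambda_t)
  b_i <- stats::rpois(n_droplets, lambda_b)
  n_t <- sum(t_i)
  n_b <- sum(b_i)
  need_replace <- n_t > length(target_pool) || n_b > length(bg_pool)
  if (replace == "never" && need_replace) {
    stop("fragment pool too small for without-replacement encapsulation",
         call. = FALSE)
  }
  rep_used <- replace == "always" || need_replace

  draw <- function(pool, n) {
    if (n == 0L) return(integer(0))
    if (length(pool) == 1L) {
      if (!rep_used && n > 1L) stop("pool exhausted", call. = FALSE)
      return(rep(pool, n))
    }
    sample(pool, n, replace = rep_used)
  }
  assignment <- data.frame(
    droplet = c(rep.int(which(t_i > 0L), t_i[t_i > 0L]),
                rep.int(which(b_i > 0L), b_i[b_i > 0L])),
    fragment = c(draw(target_pool, n_t), draw(bg_pool, n_b)),
    is_target = rep(c(TRUE, FALSE), c(n_t, n_b))
  )

  pos_raw <- t_i > 0L
  pcr_failed <- pos_raw & stats::runif(n_droplets) < pcr_failure_rate

  structure(
    list(n = n_droplets,
         n_target = t_i, n_background = b_i,
         taqman = pos_raw & !pcr_failed,
         pcr_failed = pcr_failed,
         merged = rep(FALSE, n_droplets),
         amplitude = NULL, width = NULL,
         assignment = assignment, fragments = fragments,
         amplicons = amplicons,
         lambda_t = lambda_t, lambda_b = lambda_b,
         pcr_failure_rate = pcr_failure_rate,
         replace_used = rep_used),
    class = "mesa_droplets"
  )
}

#' @export
print.mesa_droplets <- function(x, ...) {
  cat(sprintf(
    "mesa_droplets: %s droplets, %s TaqMan-positive (%.3f%%), lambda_t=%.4g, lambda_b=%.4g\n",
    format(x$n, big.mark = ","), format(sum(x$taqman), big.mark = ","),
    100 * mean(x$taqman), x$lambda_t, x$lambda_b))
  if (!is.null(x$amplitude)) {
    cat(sprintf("  fluorescence assigned; %s merged droplets (%.2f%%)\n",
                format(sum(x$merged), big.mark = ","), 100 * mean(x$merged)))
  }
  if (x$replace_used) cat("  fragments sampled with replacement\n")
  invisible(x)
}

#' Assign fluorescence amplitudes and droplet widths; form merged droplets
#'
#' Amplitudes are drawn from class-conditional normals: TaqMan-positive
#' droplets from `N(mu_pos, sd_pos)`, negatives (including PCR failures) from
#' `N(mu_neg, sd_neg)`. A fraction `merge_rate` of droplets is merged with an
#' independently drawn partner droplet due to emulsion instability: the merged
#' droplet carries both content loads, twice the width, and the maximum of the
#' two amplitudes — the mechanism by which merged droplets carry extra
#' background through the sorter.
#'
#' @param droplets A `mesa_droplets` from [encapsulate()].
#' @param mu_neg,sd_neg,mu_pos,sd_pos Class-conditional amplitude parameters
#'   (arbitrary fluorescence units).
#' @param width_mean,width_sd Droplet width (temporal-size proxy) parameters.
#' @param merge_rate Fraction of droplets that are merged.
#' @param seed Integer seed.
#' @return The droplets with `amplitude`, `width` and `merged` populated.
#' @export
fluoresce <- function(droplets, mu_neg = 0.2, sd_neg = 0.05,
                      mu_pos = 0.8, sd_pos = 0.08,
                      width_mean = 25, width_sd = 1,
                      merge_rate = 0, seed = 1) {
  stopifnot(inherits(droplets, "mesa_droplets"))
  for (s in c(sd_neg, sd_pos, width_sd)) .assert_scalar_number(s, "sd", 0)
  .assert_rate(merge_rate, "merge_rate")
  .seed_stage(seed, "fluoresce")
  n <- droplets$n

  draw_amp <- function(positive) {
    ifelse(positive,
           stats::rnorm(length(positive), mu_pos, sd_pos),
           stats::rnorm(length(positive), mu_neg, sd_neg))
  }
  amp <- draw_amp(droplets$taqman)
  width <- stats::rnorm(n, width_mean, width_sd)

  merged <- stats::runif(n) < merge_rate
  m <- sum(merged)
  if (m > 0L) {
    idx <- which(merged)
    t2 <- stats::rpois(m, droplets$lambda_t)
    b2 <- stats::rpois(m, droplets$lambda_b)
    pos2 <- t2 > 0L &
      !(stats::runif(m) < droplets$pcr_failure_rate)
    amp[idx] <- pmax(amp[idx], draw_amp(pos2))
    width[idx] <- 2 * width[idx]
    droplets$n_target[idx] <- droplets$n_target[idx] + t2
    droplets$n_background[idx] <- droplets$n_background[idx] + b2
    droplets$taqman[idx] <- droplets$taqman[idx] | pos2
    # partner fragments join the merged droplet's content
    target_pool <- which(droplets$fragments$is_target)
    bg_pool <- which(!droplets$fragments$is_target)
    extra_t <- sum(t2)
    extra_b <- sum(b2)
    samp <- function(pool, k) {
      if (k == 0L) return(integer(0))
      if (length(pool) == 1L) return(rep(pool, k))
      sample(pool, k, replace = TRUE)
    }
    if (extra_t + extra_b > 0L) {
      droplets$assignment <- rbind(
        droplets$assignment,
        data.frame(
          droplet = c(rep.int(idx[t2 > 0L], t2[t2 > 0L]),
                      rep.int(idx[b2 > 0L], b2[b2 > 0L])),
          fragment = c(samp(target_pool, extra_t), samp(bg_pool, extra_b)),
          is_target = rep(c(TRUE, FALSE), c(extra_t, extra_b))))
    }
  }
  droplets$amplitude <- amp
  droplets$width <- width
  droplets$merged <- merged
  droplets
}

#' Sort droplets by fluorescence threshold and width gate
#'
#' Collects every droplet whose amplitude reaches `threshold` and whose width
#' lies inside `width_gate`, plus gate-negative droplets collected by mistake
#' at `false_sort_rate` (electrode mistiming). Reports the sorted-droplet
#' purity: the fraction of collected droplets that truly contain a target
#' fragment.
#'
#' @param droplets A `mesa_droplets` after [fluoresce()].
#' @param threshold Amplitude threshold.
#' @param width_gate Length-2 numeric `[min, max]` width gate.
#' @param false_sort_rate Probability a gate-negative droplet is collected.
#' @param amplicon_copies TaqMan amplicon molecules produced per positive
#'   collected droplet (removed later by [remove_amplicons()]).
#' @param seed Integer seed.
#' @return An object of class `mesa_pool`: retained genomic fragments (one row
#'   per molecule, `copies = 1` before WGA), carried-over amplicon molecules,
#'   and screening counts including purity.
#' @export
sort_droplets <- function(droplets, threshold = 0.5, width_gate = c(0, Inf),
                          false_sort_rate = 0, amplicon_copies = 1000,
                          seed = 1) {
  stopifnot(inherits(droplets, "mesa_droplets"))
  if (is.null(droplets$amplitude)) {
    stop("droplets carry no fluorescence; run fluoresce() first", call. = FALSE)
  }
  .assert_rate(false_sort_rate, "false_sort_rate")
  .seed_stage(seed, "sort")

  gate <- droplets$amplitude >= threshold &
    droplets$width >= width_gate[1] & droplets$width <= width_gate[2]
  false_sort <- !gate & stats::runif(droplets$n) < false_sort_rate
  collected <- gate | false_sort
  n_sorted <- sum(collected)
  if (n_sorted == 0L) {
    warning("sorting gates exclude all droplets; empty pool", call. = FALSE)
  }

  keep <- collected[droplets$assignment$droplet]
  asg <- droplets$assignment[keep, , drop = FALSE]
  frag <- droplets$fragments[asg$fragment, c("chrom", "start", "end",
                                             "is_target", "amp_id")]
  frag$copies <- rep(1, nrow(frag))
  rownames(frag) <- NULL

  # amplicon carry-over: every collected fluorescing droplet has amplified its
  # assay's ~100 bp amplicon to high copy
  amp_tab <- NULL
  fired <- asg$is_target & droplets$taqman[asg$droplet]
  if (any(fired) && amplicon_copies > 0 && !is.null(droplets$amplicons)) {
    amp_ids <- droplets$fragments$amp_id[asg$fragment[fired]]
    # one amplicon burst per (droplet, assay) pair
    dd <- unique(data.frame(droplet = asg$droplet[fired], amp = amp_ids))
    counts <- table(dd$amp)
    amp <- droplets$amplicons[as.integer(names(counts)), , drop = FALSE]
    amp_tab <- data.frame(
      name = if (!is.null(amp$name)) amp$name else
        sprintf("amp_%d", as.integer(names(counts))),
      chrom = amp$chrom, start = amp$start, end = amp$end,
      copies = as.integer(counts) * amplicon_copies,
      stringsAsFactors = FALSE)
    rownames(amp_tab) <- NULL
  }

  purity <- if (n_sorted > 0L) {
    sum(droplets$n_target > 0L & collected) / n_sorted
  } else NA_real_

  structure(
    list(fragments = frag,
         amplicons = amp_tab,
         counts = list(
           screened = droplets$n,
           taqman_positive = sum(droplets$taqman),
           sorted = n_sorted,
           merged_sorted = sum(droplets$merged & collected),
           target_sorted = sum(droplets$n_target > 0L & collected),
           purity = purity),
         replace_used = droplets$replace_used),
    class = "mesa_pool"
  )
}

#' @export
print.mesa_pool <- function(x, ...) {
  cts <- x$counts
  cat(sprintf(
    "mesa_pool: %s droplets screened, %s sorted (purity %.1f%%), %s fragment molecules\n",
    format(cts$screened, big.mark = ","), format(cts$sorted, big.mark = ","),
    100 * cts$purity, format(nrow(x$fragments), big.mark = ",")))
  amp <- if (is.null(x$amplicons)) 0 else sum(x$amplicons$copies)
  cat(sprintf("  amplicon molecules carried over: %s\n",
              format(amp, big.mark = ",")))
  invisible(x)
}

#' @export
summary.mesa_pool <- function(object, ...) {
  cts <- object$counts
  data.frame(
    n_screened = cts$screened,
    n_positive = cts$taqman_positive,
    n_sorted = cts$sorted,
    n_merged_sorted = cts$merged_sorted,
    purity = cts$purity,
    n_fragments = nrow(object$fragments),
    target_fraction = if (nrow(object$fragments)) {
      mean(object$fragments$is_target)
    } else NA_real_
  )
}

#' Enzymatic removal of carried-over TaqMan amplicons
#'
#' Models uracil-DNA-glycosylase destruction of dU-containing PCR amplicons
#' before library preparation: amplicon molecule counts are scaled by
#' `residual_fraction` (0 = complete removal); genomic fragments are untouched.
#'
#' @param pool A `mesa_pool`.
#' @param residual_fraction Fraction of amplicon molecules surviving, in
#'   `[0, 1]`.
#' @return The pool with amplicon copies scaled.
#' @export
remove_amplicons <- function(pool, residual_fraction = 0) {
  stopifnot(inherits(pool, "mesa_pool"))
  .assert_rate(residual_fraction, "residual_fraction")
  if (!is.null(pool$amplicons)) {
    pool$amplicons$copies <- pool$amplicons$copies * residual_fraction
    if (all(pool$amplicons$copies == 0)) pool$amplicons <- NULL
  }
  pool
}

#' Whole-genome amplification with lognormal copy dispersion
#'
#' Multiple-displacement amplification is modelled abstractly: each fragment
#' receives an integer copy number drawn from a lognormal with log-sd
#' `sigma_wga`, rescaled to mean 1, rounded, floored at 1. `sigma_wga = 0` is
#' the identity. Copy dispersion later shows up as duplicate reads and less
#' uniform coverage.
#'
#' @param pool A `mesa_pool`.
#' @param sigma_wga Lognormal log-scale sd (>= 0).
#' @param seed Integer seed.
#' @return The pool with `copies` multiplied by the drawn copy numbers.
#' @export
wga_amplify <- function(pool, sigma_wga, seed = 1) {
  stopifnot(inherits(pool, "mesa_pool"))
  .assert_scalar_number(sigma_wga, "sigma_wga", 0)
  if (sigma_wga == 0 || nrow(pool$fragments) == 0L) return(pool)
  .seed_stage(seed, "wga")
  n <- nrow(pool$fragments)
  x <- stats::rlnorm(n, 0, sigma_wga) / exp(sigma_wga^2 / 2)
  pool$fragments$copies <- pool$fragments$copies * pmax(1, round(x))
  pool
}

#' Write a droplet/pool screening summary TSV
#' @param pool A `mesa_pool`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_droplet_summary <- function(pool, path) {
  utils::write.table(summary(pool), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
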