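# End-to-end orchestration: configuration with presets, seeded pipeline runs
# (genome -> fragments -> droplets -> sorting -> reads -> coverage ->
# enrichment -> variants), artifact writing, and paired-run comparison.

#' Build a pipeline configuration
#'
#' Two presets set coherent desk-scale study conditions; any field can be
#' overridden through `...` (named nested lists merged over the preset).
#' `"test"` is a minutes-scale smoke configuration; `"desk"` emulates the full
#' workflow at a size a laptop handles.
#'
#' Defaults tied to the modelled experiment: target loading
#' `lambda_t = 0.013085` (a 1.3% positive-droplet rate), ~52.4 kb (+/- 5.7 kb)
#' fragments, 2% merged droplets, 50-bp reads, 20-kb/2-kb analysis windows,
#' depth/quality >= 10 variant filters. `lambda_b = NULL` resolves to
#' whole-genome DNA composition at the same dilution,
#' `lambda_t * (G/L - n_loci)/n_loci`; `false_sort_rate = NULL` resolves via
#' [calibrate_false_sort_rate()] to the rate implying an 87.6% sorted-droplet
#' purity.
#'
#' @param preset `"test"` or `"desk"`.
#' @param ... Named overrides, e.g. `droplets = list(n_droplets = 1e5)`.
#' @param seed Global seed; every stochastic stage derives a named substream
#'   from it via [substream_seed()].
#' @return A nested list of class `mesa_config`.
#' @export
mesa_config <- function(preset = c("test", "desk"), ..., seed = 1) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = seed,
    genome = list(
      chrom_sizes = if (preset == "desk") {
        c(chr16 = 5e6, chr1 = 1e6)
      } else c(chr16 = 2e6, chr1 = 5e5),
      n_loci = if (preset == "desk") 5 else 3,
      amplicon_len = 100,
      min_spacing = 200000,
      variant_density = 1e-3,
      het_fraction = 0.5),
    fragments = list(mean = 52400, sd = 5706, min_len = 200,
                     family = "normal",
                     n_copies = 10),
    droplets = list(
      n_droplets = if (preset == "desk") 1e5 else 2e4,
      lambda_t = 0.013085,
      lambda_b = NULL,
      pcr_failure_rate = 0,
      merge_rate = 0.02),
    fluor = list(mu_neg = 0.2, sd_neg = 0.05, mu_pos = 0.8, sd_pos = 0.08,
                 width_mean = 25, width_sd = 1),
    sorter = list(threshold = 0.5, width_gate = c(0, Inf),
                  false_sort_rate = NULL, target_droplet_purity = 0.876,
                  amplicon_copies = 1000),
    residual_amplicon = 0,
    sigma_wga = 1,
    reads = list(n_reads = if (preset == "desk") 6e5 else 1.5e5,
                 read_len = 50, error_rate = 0.001),
    analysis = list(w = 20000, step = 2000, X = 56,
                    window_sizes = c(50, 100, 150, 200) * 1000,
                    depths = c(10, 30), uniformity_window = 50000),
    variants = list(min_depth = 10, min_qual = 10)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  structure(base, class = "mesa_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `mesa_config`.
#' @return The config, invisibly; errors list every offending key.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(is.numeric(config$genome$chrom_sizes) &&
        all(config$genome$chrom_sizes > 0) &&
        !is.null(names(config$genome$chrom_sizes)), "genome.chrom_sizes")
  chk(config$genome$n_loci >= 1, "genome.n_loci")
  chk(config$genome$amplicon_len >= 40 && config$genome$amplicon_len <= 500,
      "genome.amplicon_len")
  chk(config$genome$variant_density >= 0, "genome.variant_density")
  chk(config$fragments$mean > 0 && config$fragments$sd >= 0, "fragments")
  chk(config$fragments$min_len >= config$reads$read_len,
      "fragments.min_len (< read_len)")
  chk(config$droplets$n_droplets >= 1, "droplets.n_droplets")
  chk(config$droplets$lambda_t >= 0, "droplets.lambda_t")
  chk(is.null(config$droplets$lambda_b) || config$droplets$lambda_b >= 0,
      "droplets.lambda_b")
  chk(config$droplets$merge_rate >= 0 && config$droplets$merge_rate <= 1,
      "droplets.merge_rate")
  chk(config$residual_amplicon >= 0 && config$residual_amplicon <= 1,
      "residual_amplicon")
  chk(config$sigma_wga >= 0, "sigma_wga")
  chk(config$reads$n_reads >= 1, "reads.n_reads")
  chk(config$reads$error_rate >= 0 && config$reads$error_rate < 1,
      "reads.error_rate")
  chk(config$analysis$step <= config$analysis$w, "analysis.step (> w)")
  chk(config$variants$min_depth >= 0 && config$variants$min_qual >= 0,
      "variants")
  if (length(bad) > 0) {
    stop("invalid configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(config)
}

# Fill lambda_b and false_sort_rate defaults that depend on other fields.
.resolve_config <- function(config) {
  validate_config(config)
  G <- sum(config$genome$chrom_sizes)
  L <- config$fragments$mean
  n <- config$genome$n_loci
  if (is.null(config$droplets$lambda_b)) {
    config$droplets$lambda_b <- config$droplets$lambda_t * (G / L - n) / n
  }
  if (is.null(config$sorter$false_sort_rate)) {
    config$sorter$false_sort_rate <- calibrate_false_sort_rate(
      config$droplets$lambda_t, config$sorter$target_droplet_purity)
  }
  config
}

#' Run the full enrichment pipeline (or its non-enriched reference arm)
#'
#' `mode = "enriched"` performs the whole workflow: fragment the genome,
#' encapsulate into droplets, fluoresce, sort, remove amplicons, WGA, then
#' sequence the sorted pool. `mode = "reference"` sequences the unsorted
#' genome with the same number of reads — the equal-read comparison sample.
#' Both modes share the same genome and truth variants for a given seed.
#'
#' @param config A `mesa_config`.
#' @param mode `"enriched"` or `"reference"`.
#' @param out_dir Optional directory to write artifacts into (loci BED, truth
#'   VCF, droplet summary TSV, window TSV, calls VCF, coverage TSV, summary
#'   TSV, resolved config).
#' @return An object of class `mesa_run` containing the genome, truth set,
#'   pool summary, coverage track, enrichment report, calls, concordance, and
#'   a one-row `summary` data.frame.
#' @export
run_pipeline <- function(config, mode = c("enriched", "reference"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  config <- .resolve_config(config)
  seed <- config$seed

  genome <- build_genome(config$genome$chrom_sizes,
                         n_loci = config$genome$n_loci,
                         amplicon_len = config$genome$amplicon_len,
                         min_spacing = config$genome$min_spacing,
                         seed = seed)
  truth <- plant_variants(genome, config$genome$variant_density,
                          config$genome$het_fraction, seed = seed)

  pool <- NULL
  dup <- NULL
  if (mode == "enriched") {
    fm <- fragment_model(config$fragments$mean, config$fragments$sd,
                         config$fragments$min_len, config$fragments$family)
    frags <- fragment_genome(genome, fm, config$fragments$n_copies,
                             seed = seed)
    dr <- encapsulate(frags, config$droplets$n_droplets,
                      config$droplets$lambda_t, config$droplets$lambda_b,
                      amplicons = genome$loci,
                      pcr_failure_rate = config$droplets$pcr_failure_rate,
                      replace = "auto", seed = seed)
    dr <- fluoresce(dr, config$fluor$mu_neg, config$fluor$sd_neg,
                    config$fluor$mu_pos, config$fluor$sd_pos,
                    config$fluor$width_mean, config$fluor$width_sd,
                    merge_rate = config$droplets$merge_rate, seed = seed)
    pool <- sort_droplets(dr, config$sorter$threshold,
                          config$sorter$width_gate,
                          config$sorter$false_sort_rate,
                          config$sorter$amplicon_copies, seed = seed)
    pool <- remove_amplicons(pool, config$residual_amplicon)
    pool <- wga_amplify(pool, config$sigma_wga, seed = seed)
    src <- pool
  } else {
    src <- genome
  }
  message(sprintf("[%s] simulating %g reads", mode, config$reads$n_reads))
  reads <- simulate_reads(src, genome, n_reads = config$reads$n_reads,
                          read_len = config$reads$read_len,
                          error_rate = config$reads$error_rate,
                          variants = truth, seed = seed)
  dup <- mark_duplicates(reads)
  track <- coverage_track(reads, genome)

  report <- enrichment_report(track, genome$loci,
                              window_sizes = config$analysis$window_sizes,
                              w = config$analysis$w,
                              step = config$analysis$step,
                              depths = config$analysis$depths,
                              uniformity_window =
                                config$analysis$uniformity_window)
  calls <- call_variants(reads, genome,
                         min_depth = config$variants$min_depth,
                         min_qual = config$variants$min_qual,
                         error_rate = config$reads$error_rate)
  windows <- data.frame(
    chrom = genome$loci$chrom,
    start = pmax(0, genome$loci$midpoint -
                   config$analysis$uniformity_window / 2),
    end = genome$loci$midpoint + config$analysis$uniformity_window / 2)
  conc <- concordance(calls, truth, windows = windows)

  smry <- data.frame(
    mode = mode,
    n_screened = if (is.null(pool)) NA else pool$counts$screened,
    n_positive = if (is.null(pool)) NA else pool$counts$taqman_positive,
    n_sorted = if (is.null(pool)) NA else pool$counts$sorted,
    purity = if (is.null(pool)) NA else pool$counts$purity,
    n_merged_sorted = if (is.null(pool)) NA else pool$counts$merged_sorted,
    n_reads = nrow(reads),
    dup_fraction = dup$dup_fraction,
    mean_depth = track$mean_depth,
    stringsAsFactors = FALSE)
  for (s in names(report$mean_folds)) {
    smry[[paste0("fold_", as.numeric(s) / 1000, "kb")]] <-
      report$mean_folds[[s]]
  }
  smry$fwhm_mean <- mean(report$fwhm, na.rm = TRUE)
  for (nm in names(report$uniformity$fractions)) {
    smry[[paste0("frac_", sub(">=", "ge", nm, fixed = TRUE))]] <-
      report$uniformity$fractions[[nm]]
  }
  smry$n_pass_calls <- conc$n_pass
  smry$n_pass_in_windows <- conc$in_windows$n_pass
  smry$precision <- conc$precision
  smry$recall <- conc$recall

  run <- structure(
    list(config = config, mode = mode, genome = genome, truth = truth,
         pool = pool, track = track, report = report, calls = calls,
         concordance = conc, windows = windows, summary = smry),
    class = "mesa_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.mesa_run <- function(x, ...) {
  cat(sprintf("mesa_run (%s, preset %s, seed %d)\n",
              x$mode, x$config$preset, x$config$seed))
  if (!is.null(x$pool)) print(x$pool)
  cat(sprintf("  %s reads, mean depth %.2fx, %.1f%% duplicates\n",
              format(x$summary$n_reads, big.mark = ","),
              x$summary$mean_depth, 100 * x$summary$dup_fraction))
  print(x$report)
  print(x$concordance)
  invisible(x)
}

#' @export
summary.mesa_run <- function(object, ...) object$summary

#' Write run artifacts to a directory
#'
#' Emits the loci BED, truth VCF, calls VCF, droplet summary TSV, sliding
#' window TSV, fold-enrichment TSV, run-length coverage TSV, one-row summary
#' TSV, and the resolved configuration as `key=value` lines (provenance).
#'
#' @param run A `mesa_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_bed(run$genome$loci, p("loci.bed"))
  write_vcf(run$truth, p("truth.vcf"), genome = run$genome)
  if (!is.null(run$pool)) write_droplet_summary(run$pool, p("droplets.tsv"))
  wm <- sliding_window_mean(run$track, run$config$analysis$w,
                            run$config$analysis$step)
  utils::write.table(wm, p("windows.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$report$folds, p("fold_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_coverage_tsv(run$track, p("coverage.tsv"))
  write_vcf(run$calls, p("calls.vcf"), genome = run$genome)
  utils::write.table(run$summary, p("summary.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- unlist(run$config)
  writeLines(paste0(names(cfg), "=", vapply(cfg, format, character(1))),
             p("config.txt"))
  invisible(out_dir)
}

#' Compare an enriched run against its non-enriched reference
#'
#' Runs the differential specificity scan between the two coverage tracks and
#' contrasts PASS variant-call counts inside the probe-centered target
#' windows.
#'
#' @param enriched,reference `mesa_run` objects sharing a genome.
#' @param X Minimum mean coverage for the scan (default: the enriched run's
#'   configured threshold).
#' @return list of class `mesa_comparison`: `scan` (differential intervals),
#'   `calls` (PASS counts in/out of windows for both runs), `delta_in_windows`.
#' @export
compare_runs <- function(enriched, reference, X = NULL) {
  stopifnot(inherits(enriched, "mesa_run"), inherits(reference, "mesa_run"))
  if (!identical(enriched$genome$lengths, reference$genome$lengths)) {
    stop("runs are over different genomes", call. = FALSE)
  }
  if (is.null(X)) X <- enriched$config$analysis$X
  scan <- specificity_scan(enriched$track, reference$track, X = X,
                           w = enriched$config$analysis$w,
                           step = enriched$config$analysis$step)
  calls <- data.frame(
    run = c("enriched", "reference"),
    n_pass = c(enriched$concordance$n_pass, reference$concordance$n_pass),
    n_pass_in_windows = c(enriched$concordance$in_windows$n_pass,
                          reference$concordance$in_windows$n_pass))
  structure(
    list(scan = scan, calls = calls,
         delta_in_windows = diff(rev(calls$n_pass_in_windows)),
         X = X),
    class = "mesa_comparison")
}

#' @export
print.mesa_comparison <- function(x, ...) {
  cat(sprintf("mesa_comparison (scan threshold %gx)\n", x$X))
  cat(sprintf("  differential regions: %d\n", nrow(x$scan)))
  if (nrow(x$scan) > 0) {
    for (i in seq_len(nrow(x$scan))) {
      cat(sprintf("    %s:%d-%d (%s, max %.1fx)\n", x$scan$chrom[i],
                  x$scan$start[i], x$scan$end[i], x$scan$direction[i],
                  x$scan$max_mean[i]))
    }
  }
  cat(sprintf("  PASS calls in target windows: enriched %d vs reference %d\n",
              x$calls$n_pass_in_windows[1], x$calls$n_pass_in_windows[2]))
  invisible(x)
}
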