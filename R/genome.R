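# Synthetic reference genome, target loci and planted truth variants.
#
# Coordinates are 0-based half-open everywhere in memory and in BED output;
# VCF output converts to 1-based. Sequence composition is i.i.d. uniform over
# A/C/G/T: the enrichment statistics implemented here are composition
# independent, so no repeat or GC structure is modelled.

#' Build a synthetic genome with probe-targeted loci
#'
#' Constructs a multi-chromosome random genome and places `n_loci`
#' non-overlapping TaqMan amplicons (default ~100 bp, the amount of prior
#' sequence information a droplet enrichment assay needs) on one chromosome.
#' Loci are separated by at least `min_spacing` so that the probe-centered
#' analysis windows of neighbouring loci never overlap.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_loci Number of target loci to place.
#' @param loci_chrom Chromosome carrying the loci (default: first chromosome).
#' @param amplicon_len Amplicon length in bp (40--500, default 100).
#' @param min_spacing Minimum distance between locus midpoints in bp; defaults
#'   to 200 kb, the largest probe-centered analysis window, so windows of
#'   neighbouring loci are disjoint.
#' @param seed Integer seed; the genome is deterministic given the seed.
#' @return An object of class `mesa_genome`: a list with `seq` (named character
#'   vector, one string per chromosome), `lengths`, total size `G`, and a
#'   `loci` data.frame (`name`, `chrom`, `start`, `end`, `midpoint`; 0-based
#'   half-open amplicon intervals).
#' @examples
#' g <- build_genome(c(chr16 = 1e6), n_loci = 1, seed = 7)
#' g$G
#' @export
build_genome <- function(chrom_sizes,
                         n_loci = 5,
                         loci_chrom = names(chrom_sizes)[1],
                         amplicon_len = 100,
                         min_spacing = 200000,
                         seed = 1) {
  stopifnot(is.numeric(chrom_sizes), length(chrom_sizes) >= 1,
            !is.null(names(chrom_sizes)), all(chrom_sizes > 0))
  .assert_scalar_number(amplicon_len, "amplicon_len", 40, 500)
  .assert_scalar_number(n_loci, "n_loci", 0)
  if (!loci_chrom %in% names(chrom_sizes)) {
    stop("loci_chrom not among chromosome names", call. = FALSE)
  }
  chrom_sizes <- round(chrom_sizes)
  target_len <- chrom_sizes[[loci_chrom]]
  # margin keeps a full half-window inside the chromosome on both sides
  margin <- ceiling(min_spacing / 2)
  if (n_loci > 0) {
    span_needed <- 2 * margin + (n_loci - 1) * min_spacing
    if (span_needed > target_len) {
      stop(sprintf(
        "cannot place %d loci %d bp apart on a %d bp chromosome", n_loci,
        min_spacing, target_len), call. = FALSE)
    }
  }

  .seed_stage(seed, "genome")
  bases <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  seqs <- vapply(chrom_sizes, function(len) {
    rawToChar(bases[sample.int(4L, len, replace = TRUE)])
  }, character(1))

  loci <- NULL
  if (n_loci > 0) {
    slack <- target_len - 2 * margin - (n_loci - 1) * min_spacing
    offsets <- sort(round(runif(n_loci, 0, slack)))
    midpoints <- margin + offsets + (seq_len(n_loci) - 1) * min_spacing
    start <- midpoints - floor(amplicon_len / 2)
    loci <- data.frame(
      name = sprintf("locus_%02d", seq_len(n_loci)),
      chrom = loci_chrom,
      start = start,
      end = start + amplicon_len,
      midpoint = midpoints,
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(seq = seqs,
         lengths = stats::setNames(as.integer(chrom_sizes), names(chrom_sizes)),
         G = sum(chrom_sizes),
         loci = loci),
    class = "mesa_genome"
  )
}

#' @export
print.mesa_genome <- function(x, ...) {
  cat(sprintf("mesa_genome: %d chromosome(s), G = %s bp\n",
              length(x$lengths), format(x$G, big.mark = ",")))
  for (nm in names(x$lengths)) {
    cat(sprintf("  %s: %s bp\n", nm, format(x$lengths[[nm]], big.mark = ",")))
  }
  if (!is.null(x$loci)) {
    cat(sprintf("  %d target locus/loci on %s at midpoints: %s\n",
                nrow(x$loci), x$loci$chrom[1],
                paste(format(x$loci$midpoint, big.mark = ","), collapse = ", ")))
  }
  invisible(x)
}

#' Plant single-nucleotide variants into a genome
#'
#' Draws variant positions at the given per-base density (the count on each
#' chromosome is Binomial(length, density)), assigns each a random alternate
#' base and a zygosity, and returns a truth set against which calls can later
#' be scored. The genome sequence itself is not modified: variants are applied
#' at read-simulation time according to zygosity.
#'
#' @param genome A `mesa_genome`.
#' @param density Expected variants per bp (e.g. `1e-3`).
#' @param het_fraction Fraction of variants that are heterozygous.
#' @param seed Integer seed.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, `zygosity`
#'   (`"hom"`/`"het"`), sorted by chromosome then position, unique positions.
#' @export
plant_variants <- function(genome, density, het_fraction = 0.5, seed = 1) {
  stopifnot(inherits(genome, "mesa_genome"))
  .assert_scalar_number(density, "density", 0)
  .assert_rate(het_fraction, "het_fraction")
  .seed_stage(seed, "variants")

  out <- lapply(names(genome$lengths), function(chrom) {
    len <- genome$lengths[[chrom]]
    n <- stats::rbinom(1L, len, min(density, 1))
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(len, n)) - 1L
    ref <- substring(genome$seq[[chrom]], pos + 1L, pos + 1L)
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1), USE.NAMES = FALSE)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               zygosity = ifelse(stats::runif(n) < het_fraction, "het", "hom"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), zygosity = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
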