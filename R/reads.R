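# Read simulation from sorted pools (or whole genomes for the non-enriched
# reference), per-base coverage tracks, and duplicate marking.
#
# No aligner is involved: reads carry their true coordinates, so coverage is
# exact by construction and alignment artifacts are out of scope. Base strings
# are stored in reference orientation; FASTQ export reverse-complements
# minus-strand reads.

.new_coverage <- function(depth_list) {
  depth_list <- lapply(depth_list, as.integer)
  G <- sum(vapply(depth_list, length, numeric(1)))
  total <- sum(vapply(depth_list, function(d) sum(as.numeric(d)), numeric(1)))
  structure(
    list(depth = depth_list, G = G, total_bases = total,
         mean_depth = total / G),
    class = "mesa_coverage"
  )
}

#' @export
print.mesa_coverage <- function(x, ...) {
  cat(sprintf("mesa_coverage: G = %s bp, mean depth %.3fx\n",
              format(x$G, big.mark = ","), x$mean_depth))
  invisible(x)
}

# Substitute characters at (index, offset) pairs into strings, handling
# multiple edits to the same string by rounds of vectorized substr().
.edit_bases <- function(seqs, idx, off, base) {
  while (length(idx) > 0L) {
    first <- !duplicated(idx)
    i <- idx[first]; k <- off[first]; b <- base[first]
    seqs[i] <- paste0(substr(seqs[i], 1L, k - 1L), b,
                      substr(seqs[i], k + 1L, nchar(seqs[i])))
    idx <- idx[!first]; off <- off[!first]; base <- base[!first]
  }
  seqs
}

#' Simulate short reads from a sorted pool or a whole genome
#'
#' Source molecules are chosen proportional to copy number, read starts are
#' uniform within the molecule, strands are uniform. For a `mesa_genome`
#' source (the non-enriched reference sample) reads are uniform over the
#' genome. Planted variants are applied per read: homozygous variants always,
#' heterozygous ones with probability 1/2. Sequencing errors are i.i.d.
#' substitutions at `error_rate` per base.
#'
#' @param x A `mesa_pool` or `mesa_genome` to draw from.
#' @param genome The `mesa_genome` providing sequence (defaults to `x` when
#'   `x` is a genome).
#' @param n_reads Number of reads.
#' @param read_len Read length in bp (default 50).
#' @param error_rate Per-base substitution error rate in `[0, 1)`.
#' @param variants Optional truth variants from [plant_variants()].
#' @param seed Integer seed.
#' @return data.frame of class `mesa_reads`: `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `seq`. Attribute `n_skipped` counts molecules
#'   shorter than the read length that were excluded from sampling.
#' @export
simulate_reads <- function(x, genome = NULL, n_reads, read_len = 50,
                           error_rate = 0.001, variants = NULL, seed = 1) {
  .assert_scalar_number(n_reads, "n_reads", 1)
  .assert_scalar_number(read_len, "read_len", 1)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  if (inherits(x, "mesa_genome") && is.null(genome)) genome <- x
  stopifnot(inherits(genome, "mesa_genome"))

  if (inherits(x, "mesa_pool")) {
    mol <- x$fragments[, c("chrom", "start", "end", "copies")]
    if (!is.null(x$amplicons) && nrow(x$amplicons) > 0L) {
      amp <- x$amplicons
      mol <- rbind(mol, data.frame(chrom = amp$chrom, start = amp$start,
                                   end = amp$end, copies = amp$copies))
    }
  } else if (inherits(x, "mesa_genome")) {
    mol <- data.frame(chrom = names(x$lengths), start = 0L,
                      end = as.integer(x$lengths),
                      copies = 1, stringsAsFactors = FALSE)
  } else {
    stop("x must be a mesa_pool or mesa_genome", call. = FALSE)
  }
  len <- mol$end - mol$start
  ok <- len >= read_len & mol$copies > 0
  n_skipped <- sum(!ok)
  mol <- mol[ok, , drop = FALSE]
  len <- len[ok]
  if (nrow(mol) == 0L) stop("no molecule is long enough to sequence",
                            call. = FALSE)

  .seed_stage(seed, "reads")
  # weight by copies and by the number of valid start positions so coverage
  # per base is proportional to molecule copy number
  w <- mol$copies * (len - read_len + 1)
  i <- sample.int(nrow(mol), n_reads, replace = TRUE, prob = w)
  offset <- floor(stats::runif(n_reads) * (len[i] - read_len + 1))
  start <- mol$start[i] + offset
  chrom <- mol$chrom[i]
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  seqs <- character(n_reads)
  for (cn in unique(chrom)) {
    j <- chrom == cn
    seqs[j] <- substring(genome$seq[[cn]], start[j] + 1L, start[j] + read_len)
  }

  reads <- data.frame(chrom = chrom, start = start, end = start + read_len,
                      strand = strand, seq = seqs, stringsAsFactors = FALSE)

  if (!is.null(variants) && nrow(variants) > 0L) {
    rgr <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(reads$start + 1L, reads$end))
    vgr <- GenomicRanges::GRanges(variants$chrom,
                                  IRanges::IRanges(variants$pos + 1L,
                                                   variants$pos + 1L))
    hits <- GenomicRanges::findOverlaps(vgr, rgr)
    vi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    if (length(vi) > 0L) {
      apply_het <- variants$zygosity[vi] != "het" |
        stats::runif(length(vi)) < 0.5
      vi <- vi[apply_het]; ri <- ri[apply_het]
      off <- variants$pos[vi] - reads$start[ri] + 1L
      reads$seq <- .edit_bases(reads$seq, ri, off, variants$alt[vi])
    }
  }

  if (error_rate > 0) {
    k <- stats::rbinom(1L, n_reads * read_len, error_rate)
    if (k > 0L) {
      flat <- sample(n_reads * read_len, k)
      ri <- (flat - 1L) %/% read_len + 1L
      off <- (flat - 1L) %% read_len + 1L
      cur <- substr(reads$seq[ri], off, off)
      sub <- vapply(cur, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1), USE.NAMES = FALSE)
      reads$seq <- .edit_bases(reads$seq, ri, off, sub)
    }
  }

  attr(reads, "read_len") <- read_len
  attr(reads, "n_skipped") <- n_skipped
  class(reads) <- c("mesa_reads", "data.frame")
  reads
}

#' Compute a per-base coverage track from reads
#'
#' Depth conservation holds exactly: the sum of all depths equals the sum of
#' read lengths.
#'
#' @param reads A `mesa_reads` (or data.frame with `chrom`, `start`, `end`).
#' @param genome A `mesa_genome` giving chromosome lengths.
#' @return An object of class `mesa_coverage`: per-chromosome integer depth
#'   vectors with `G`, `total_bases`, `mean_depth`.
#' @export
coverage_track <- function(reads, genome) {
  stopifnot(inherits(genome, "mesa_genome"))
  .check_intervals(reads, genome, "read")
  depth <- lapply(names(genome$lengths), function(cn) {
    j <- reads$chrom == cn
    cov <- IRanges::coverage(
      IRanges::IRanges(start = reads$start[j] + 1L, end = reads$end[j]),
      width = genome$lengths[[cn]])
    as.integer(cov)
  })
  names(depth) <- names(genome$lengths)
  .new_coverage(depth)
}

#' Mark and remove duplicate reads
#'
#' Duplicates share (chromosome, start, strand) — the 5'-position criterion
#' for single-end reads. After a stable sort the first read of each group is
#' kept, so the result is deterministic.
#'
#' @param reads A `mesa_reads`.
#' @return list with `reads` (deduplicated, original row order),
#'   `dup_fraction`, and `n_duplicates`.
#' @export
mark_duplicates <- function(reads) {
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, dup_fraction = 0, n_duplicates = 0L))
  # sequence as final sort key: the kept read of each duplicate group does not
  # depend on input order, so downstream calling is shuffle-invariant
  o <- if (is.null(reads$seq)) {
    order(reads$chrom, reads$start, reads$strand)
  } else {
    order(reads$chrom, reads$start, reads$strand, reads$seq)
  }
  key <- paste(reads$chrom[o], reads$start[o], reads$strand[o], sep = "\r")
  dup_sorted <- duplicated(key)
  dup <- logical(n)
  dup[o] <- dup_sorted
  list(reads = reads[!dup, , drop = FALSE],
       dup_fraction = mean(dup),
       n_duplicates = sum(dup))
}

#' Write reads as FASTQ
#'
#' Minus-strand reads are reverse-complemented into sequencing orientation;
#' base qualities are uniform `I` (Q40), since no per-base quality model is
#' simulated.
#' @param reads A `mesa_reads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- reads$seq
  neg <- reads$strand == "-"
  if (any(neg)) {
    seqs[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[neg])))
  }
  ids <- sprintf("@read_%d %s:%d-%d/%s", seq_len(nrow(reads)), reads$chrom,
                 reads$start, reads$end, reads$strand)
  qual <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(ids, seqs, "+", qual)), path)
  invisible(path)
}

#' Plot window-averaged coverage along a chromosome
#' @param x A `mesa_coverage`.
#' @param chrom Chromosome to plot (default: first).
#' @param w,step Averaging window and step in bp.
#' @param ... Passed to [plot()].
#' @export
plot.mesa_coverage <- function(x, chrom = names(x$depth)[1],
                               w = 20000, step = 2000, ...) {
  wm <- sliding_window_mean(x, w = w, step = step)
  wm <- wm[wm$chrom == chrom, , drop = FALSE]
  plot((wm$start + wm$end) / 2 / 1e6, wm$mean,
       type = "l", xlab = sprintf("%s position (Mb)", chrom),
       ylab = sprintf("mean depth (%g kb windows)", w / 1000), ...)
  invisible(x)
}
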