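# File formats: FASTA (Biostrings), BED6 (rtracklayer), minimal VCF v4.2,
# and a run-length TSV dump for per-base coverage tracks.

#' Write a genome to FASTA
#' @param genome A `mesa_genome`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "mesa_genome"))
  dna <- Biostrings::DNAStringSet(genome$seq)
  names(dna) <- names(genome$seq)
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' Loci/variants are not part of FASTA; the returned genome has `loci = NULL`.
#' @param path FASTA file.
#' @return A `mesa_genome`.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dna)
  names(seqs) <- sub("\\s.*$", "", names(dna))
  structure(
    list(seq = seqs,
         lengths = stats::setNames(Biostrings::width(dna), names(seqs)),
         G = sum(Biostrings::width(dna)),
         loci = NULL),
    class = "mesa_genome"
  )
}

#' Write intervals to BED6
#'
#' Intervals are 0-based half-open, matching BED natively.
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if ("name" %in% names(df)) gr$name <- df$name
  gr$score <- if ("score" %in% names(df)) df$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read BED intervals
#' @param path BED file.
#' @return data.frame with `chrom`, `start` (0-based), `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write variants to a minimal VCF v4.2
#'
#' Eight fixed columns; positions convert from internal 0-based to VCF 1-based.
#' Truth variants (with a `zygosity` column) carry `ZYG=` in INFO; calls (with
#' `depth`/`qual`/`filter` columns) carry `DP=` and their QUAL/FILTER values.
#'
#' @param variants data.frame with `chrom`, `pos` (0-based), `ref`, `alt` and
#'   optionally `zygosity` or `depth`/`qual`/`filter`.
#' @param path Output file.
#' @param genome Optional `mesa_genome` used to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  hdr <- c("##fileformat=VCFv4.2", "##source=mesasim")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$lengths), genome$lengths))
  }
  if ("zygosity" %in% names(variants)) {
    hdr <- c(hdr, "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Planted zygosity\">")
  }
  if ("depth" %in% names(variants)) {
    hdr <- c(hdr, "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  qual <- if ("qual" %in% names(v)) formatC(v$qual, format = "f", digits = 2) else "."
  filt <- if ("filter" %in% names(v)) v$filter else "."
  info <- rep(".", nrow(v))
  if ("zygosity" %in% names(v)) info <- paste0("ZYG=", v$zygosity)
  if ("depth" %in% names(v)) info <- paste0("DP=", v$depth)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                  v$chrom, v$pos + 1L, v$ref, v$alt, qual, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF
#'
#' Parses the eight fixed columns of a VCF written by [write_vcf()] (or any
#' single-sample-free VCF body); positions convert back to 0-based.
#' @param path VCF file.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, `qual`,
#'   `filter`, plus `zygosity` or `depth` when present in INFO.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), filter = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  f <- do.call(rbind, f)
  out <- data.frame(
    chrom = f[, 1], pos = as.integer(f[, 2]) - 1L, ref = f[, 4], alt = f[, 5],
    qual = suppressWarnings(as.numeric(f[, 6])), filter = f[, 7],
    stringsAsFactors = FALSE
  )
  info <- f[, 8]
  zyg <- regmatches(info, regexpr("(?<=ZYG=)[a-z]+", info, perl = TRUE))
  if (length(zyg) == nrow(out)) out$zygosity <- zyg
  dp <- regmatches(info, regexpr("(?<=DP=)[0-9]+", info, perl = TRUE))
  if (length(dp) == nrow(out)) out$depth <- as.integer(dp)
  out
}

#' Write a coverage track as run-length TSV
#'
#' Versioned plain-text dump (`# mesasim-coverage v1`): one row per constant
#' run of depth, columns `chrom`, `start` (0-based), `end`, `depth`.
#' @param track A `mesa_coverage`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(track, path) {
  stopifnot(inherits(track, "mesa_coverage"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mesasim-coverage v1", "chrom\tstart\tend\tdepth"), con)
  for (chrom in names(track$depth)) {
    r <- rle(track$depth[[chrom]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", chrom, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Read a run-length coverage TSV written by [write_coverage_tsv()]
#' @param path Input file.
#' @return A `mesa_coverage`.
#' @export
read_coverage_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "# mesasim-coverage v1")) {
    stop("not a mesasim-coverage v1 file", call. = FALSE)
  }
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  depth <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    rep(as.integer(d$depth), d$end - d$start)
  })
  depth <- depth[unique(df$chrom)]
  .new_coverage(depth)
}
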