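# Minimal pileup SNP caller and truth-concordance evaluation.
#
# The genotype model is deliberately simple — a binomial error-tail quality
# plus allele-fraction heuristics — because what matters downstream is the
# hard depth/quality filtering and the enrichment effect on call counts, not
# caller sophistication.

#' Per-position pileup of read bases
#'
#' Tabulates A/C/G/T counts at every covered position (or at the supplied
#' positions). Depth equals the sum of base counts and matches
#' [coverage_track()] at every position. Intended for modest instance sizes;
#' [call_variants()] uses a mismatch-only path that scales to large read sets.
#'
#' @param reads A `mesa_reads` with base strings.
#' @param genome A `mesa_genome`.
#' @param positions Optional data.frame (`chrom`, `pos` 0-based) restricting
#'   the pileup.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `A`, `C`, `G`,
#'   `T`, `depth`.
#' @export
pileup <- function(reads, genome, positions = NULL) {
  stopifnot(inherits(genome, "mesa_genome"))
  read_len <- attr(reads, "read_len")
  if (is.null(read_len)) read_len <- unique(reads$end - reads$start)[1]
  n <- nrow(reads)
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), depth = integer()))
  }
  pos <- rep(reads$start, each = read_len) + rep.int(0:(read_len - 1L), n)
  chrom <- rep(reads$chrom, each = read_len)
  base <- unlist(strsplit(reads$seq, "", fixed = TRUE), use.names = FALSE)
  if (!is.null(positions)) {
    want <- paste(positions$chrom, positions$pos)
    keep <- paste(chrom, pos) %in% want
    pos <- pos[keep]; chrom <- chrom[keep]; base <- base[keep]
  }
  key <- paste(chrom, pos)
  tab <- table(key, factor(base, levels = c("A", "C", "G", "T")))
  parts <- strsplit(rownames(tab), " ", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    A = as.integer(tab[, "A"]), C = as.integer(tab[, "C"]),
    G = as.integer(tab[, "G"]), T = as.integer(tab[, "T"]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$ref <- substring(genome$seq[out$chrom], out$pos + 1L, out$pos + 1L)
  out$depth <- out$A + out$C + out$G + out$T
  rownames(out) <- NULL
  out[, c("chrom", "pos", "ref", "A", "C", "G", "T", "depth")]
}

# Mismatch positions of reads against the reference: data.frame
# (chrom, pos, base), one row per mismatching read base.
.read_mismatches <- function(reads, genome) {
  refsub <- character(nrow(reads))
  for (cn in unique(reads$chrom)) {
    j <- reads$chrom == cn
    refsub[j] <- substring(genome$seq[[cn]], reads$start[j] + 1L, reads$end[j])
  }
  differs <- which(reads$seq != refsub)
  if (length(differs) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      base = character(), stringsAsFactors = FALSE))
  }
  offs <- vector("list", length(differs))
  bases <- vector("list", length(differs))
  for (k in seq_along(differs)) {
    i <- differs[k]
    a <- charToRaw(reads$seq[i]); b <- charToRaw(refsub[i])
    off <- which(a != b)
    offs[[k]] <- off
    bases[[k]] <- a[off]
  }
  lens <- lengths(offs)
  data.frame(chrom = rep.int(reads$chrom[differs], lens),
             pos = rep.int(reads$start[differs], lens) +
               unlist(offs, use.names = FALSE) - 1L,
             base = rawToChar(as.raw(unlist(bases, use.names = FALSE)),
                              multiple = TRUE),
             stringsAsFactors = FALSE)
}

#' Call SNPs from simulated reads with depth and quality filters
#'
#' Candidate sites need at least 2 reads supporting the same alternate base.
#' The call quality is the phred-scaled binomial tail probability of seeing
#' that many (or more) errors at the site:
#' `-10 log10 P[X >= alt_count]`, `X ~ Binomial(depth, error_rate)`.
#' A call PASSes iff `depth >= min_depth`, `qual >= min_qual`, and the
#' alternate allele fraction supports a genotype (het in `[0.2, 0.8]`,
#' hom-alt `>= 0.8`). Duplicate reads are removed before counting by default.
#'
#' @param reads A `mesa_reads`.
#' @param genome A `mesa_genome`.
#' @param min_depth Minimum read depth for PASS (default 10).
#' @param min_qual Minimum phred quality for PASS (default 10).
#' @param error_rate Assumed per-base error rate in `(0, 0.5)`.
#' @param dedup Remove duplicate reads before calling (default `TRUE`).
#' @return data.frame of class `mesa_calls`: `chrom`, `pos` (0-based), `ref`,
#'   `alt`, `depth`, `alt_count`, `alt_frac`, `qual`, `genotype`, `filter`
#'   (`"PASS"`, `"low_depth"`, `"low_qual"`, `"low_af"`).
#' @export
call_variants <- function(reads, genome, min_depth = 10, min_qual = 10,
                          error_rate = 0.001, dedup = TRUE) {
  stopifnot(inherits(genome, "mesa_genome"))
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must be in (0, 0.5)", call. = FALSE)
  }
  if (dedup) reads <- mark_duplicates(reads)$reads

  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      alt_count = integer(), alt_frac = numeric(),
                      qual = numeric(), genotype = character(),
                      filter = character(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(structure(empty, class = c("mesa_calls",
                                                           "data.frame")))
  mm <- .read_mismatches(reads, genome)
  if (nrow(mm) == 0L) return(structure(empty, class = c("mesa_calls",
                                                        "data.frame")))

  cnt <- stats::aggregate(list(alt_count = rep(1L, nrow(mm))),
                          by = list(chrom = mm$chrom, pos = mm$pos,
                                    alt = mm$base), FUN = sum)
  cnt <- cnt[cnt$alt_count >= 2L, , drop = FALSE]
  if (nrow(cnt) == 0L) return(structure(empty, class = c("mesa_calls",
                                                         "data.frame")))
  # keep the best-supported alternate per site (ties: alphabetical)
  cnt <- cnt[order(cnt$chrom, cnt$pos, -cnt$alt_count, cnt$alt), , drop = FALSE]
  cnt <- cnt[!duplicated(cnt[, c("chrom", "pos")]), , drop = FALSE]

  cov <- coverage_track(reads, genome)
  depth <- mapply(function(cn, p) cov$depth[[cn]][p + 1L],
                  cnt$chrom, cnt$pos)
  qual <- -10 / log(10) * stats::pbinom(cnt$alt_count - 1L, depth, error_rate,
                                        lower.tail = FALSE, log.p = TRUE)
  qual <- pmin(qual, 10000)
  af <- cnt$alt_count / depth
  genotype <- ifelse(af >= 0.8, "hom",
                     ifelse(af >= 0.2, "het", "."))
  filter <- ifelse(depth < min_depth, "low_depth",
                   ifelse(qual < min_qual, "low_qual",
                          ifelse(genotype == ".", "low_af", "PASS")))
  out <- data.frame(
    chrom = cnt$chrom, pos = cnt$pos,
    ref = substring(genome$seq[cnt$chrom], cnt$pos + 1L, cnt$pos + 1L),
    alt = cnt$alt, depth = as.integer(depth),
    alt_count = cnt$alt_count, alt_frac = af, qual = qual,
    genotype = genotype, filter = filter, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mesa_calls", "data.frame"))
}

#' Concordance of calls against planted truth variants
#'
#' PASS calls are matched to truth by exact (chromosome, position, alternate
#' base). Optionally tallies the same quantities restricted to target windows
#' (e.g. probe-centered 50-kb regions).
#'
#' @param calls A `mesa_calls`.
#' @param truth Truth variants from [plant_variants()] (or [read_vcf()]).
#' @param windows Optional data.frame of intervals (`chrom`, `start`, `end`).
#' @return list of class `mesa_concordance`: `n_pass`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, and — when windows are given — `in_windows` with
#'   the same fields restricted to the windows.
#' @export
concordance <- function(calls, truth, windows = NULL) {
  if (nrow(calls) > 0 && nrow(truth) > 0 &&
      !any(calls$chrom %in% truth$chrom)) {
    stop("calls and truth share no chromosome; genome mismatch?",
         call. = FALSE)
  }
  score <- function(cl, tr) {
    pass <- cl[cl$filter == "PASS", , drop = FALSE]
    ck <- paste(pass$chrom, pass$pos, pass$alt)
    tk <- paste(tr$chrom, tr$pos, tr$alt)
    tp <- sum(ck %in% tk)
    fp <- nrow(pass) - tp
    fn <- sum(!tk %in% ck)
    list(n_pass = nrow(pass), tp = tp, fp = fp, fn = fn,
         precision = if (nrow(pass) > 0) tp / nrow(pass) else NA_real_,
         recall = if (nrow(tr) > 0) tp / nrow(tr) else NA_real_)
  }
  res <- score(calls, truth)
  if (!is.null(windows)) {
    inw <- function(df) {
      if (nrow(df) == 0L) return(df)
      g <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$pos + 1L, df$pos + 1L))
      wg <- GenomicRanges::GRanges(windows$chrom,
                                   IRanges::IRanges(windows$start + 1L,
                                                    windows$end))
      df[IRanges::overlapsAny(g, wg), , drop = FALSE]
    }
    res$in_windows <- score(inw(calls), inw(truth))
  }
  structure(res, class = "mesa_concordance")
}

#' @export
print.mesa_concordance <- function(x, ...) {
  cat(sprintf(
    "mesa_concordance: %d PASS calls; TP %d, FP %d, FN %d; precision %s, recall %s\n",
    x$n_pass, x$tp, x$fp, x$fn,
    ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
    ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))))
  if (!is.null(x$in_windows)) {
    w <- x$in_windows
    cat(sprintf("  in target windows: %d PASS (TP %d, FP %d, FN %d)\n",
                w$n_pass, w$tp, w$fp, w$fn))
  }
  invisible(x)
}
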