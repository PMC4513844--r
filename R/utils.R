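# Internal helpers: seed substreams, argument checks.

#' Derive a named substream seed from a global seed
#'
#' Each stochastic stage of a pipeline run draws from its own substream so a
#' stage can be re-run in isolation and still reproduce the end-to-end result.
#' The substream seed is a deterministic 31-bit hash of the global seed and the
#' stage name.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"fragment"`, `"encapsulate"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in seq_along(codes)) {
    h <- (h * 131 + codes[k]) %% 2147483647
  }
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Seed the RNG for a stage if a seed is supplied.
.seed_stage <- function(seed, stage) {
  if (!is.null(seed)) set.seed(substream_seed(seed, stage))
  invisible(NULL)
}

.assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

.assert_rate <- function(x, name) .assert_scalar_number(x, name, 0, 1)

# 0-based half-open interval data.frame sanity check against a genome.
.check_intervals <- function(df, genome, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- !(df$chrom %in% names(genome$lengths))
  if (any(bad)) {
    stop(sprintf("%s on unknown chromosome: %s", what,
                 paste(unique(df$chrom[bad]), collapse = ", ")), call. = FALSE)
  }
  len <- genome$lengths[df$chrom]
  if (any(df$start < 0 | df$end > len | df$end <= df$start)) {
    stop(sprintf("%s outside chromosome bounds or empty", what), call. = FALSE)
  }
  invisible(df)
}
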