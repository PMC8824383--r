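# internal helpers shared across modules

#' @importFrom tibble tibble as_tibble
#' @importFrom stats rpois rbinom runif rnorm sd median setNames p.adjust pt
#' @importFrom utils head tail
NULL

#' Tile chromosomes with fixed-width windows
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_bp window width in bp; the last window of each chromosome may
#'   be shorter (partial windows are retained).
#' @return tibble with `chrom`, `start` (0-based), `end` (half-open).
#' @export
tile_windows <- function(chrom_lengths, window_bp = 5e5) {
  stopifnot(length(chrom_lengths) > 0, window_bp > 0)
  if (is.null(names(chrom_lengths))) {
    stop("chrom_lengths must be named by chromosome")
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_bp)
    tibble(chrom = ch, start = starts, end = pmin(starts + window_bp, len))
  })
  do.call(rbind, out)
}

# deterministic sub-stream seed per module, kept below 2^31
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset) %% 2147483629)
}

# 0-based window index for positions (pos is 1-based bp)
window_index <- function(pos, window_bp) as.integer(floor((pos - 1) / window_bp))

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
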