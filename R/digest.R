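#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R not followed by P (the
#' classic trypsin rule used as the default by common search engines) and
#' enumerates all peptides spanning up to `missed_cleavages` internal
#' cleavage sites, including the terminal peptides. Peptides are then
#' filtered to the inclusive length window; set `min_len = 1` and
#' `max_len = Inf` for the unfiltered digest.
#'
#' @param sequence A single non-empty amino-acid string.
#' @param missed_cleavages Maximum internal cleavage sites per peptide
#'   (default 2).
#' @param min_len,max_len Inclusive peptide length window (defaults 6 and
#'   144).
#' @return A tibble ordered by start position then length with columns
#'   `peptide`, `start`, `end` (1-based residue positions) and `n_missed`.
#' @examples
#' tryptic_digest("AAAAKRPAAAAAA", missed_cleavages = 0, min_len = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 2,
                           min_len = 6, max_len = 144) {
  stopifnot(length(sequence) == 1, !is.na(sequence))
  if (!nzchar(sequence)) abort("`sequence` must be non-empty.")
  if (missed_cleavages < 0) abort("`missed_cleavages` must be >= 0.")
  if (min_len > max_len) abort("`min_len` must be <= `max_len`.")
  frag <- tryptic_fragments(sequence)
  n_frag <- length(frag$start)
  m <- min(missed_cleavages, n_frag - 1)
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (k in 0:m) {
    i <- seq_len(n_frag - k)
    starts <- c(starts, frag$start[i])
    ends <- c(ends, frag$end[i + k])
    missed <- c(missed, rep.int(k, n_frag - k))
  }
  len <- ends - starts + 1L
  keep <- which(len >= min_len & len <= max_len)
  keep <- keep[order(starts[keep], ends[keep])]
  tibble(
    peptide = substring(sequence, starts[keep], ends[keep]),
    start = starts[keep],
    end = ends[keep],
    n_missed = missed[keep]
  )
}

# Fully cleaved tryptic fragments: start/end positions between consecutive
# cleavage sites (after K/R not before P).
tryptic_fragments <- function(sequence) {
  n <- nchar(sequence)
  sites <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1]]
  sites <- sites[sites > 0 & sites <= n] # positions of first residue after a cut
  start <- c(1L, as.integer(sites))
  end <- c(as.integer(sites) - 1L, n)
  list(start = start, end = end)
}

#' Number of internal tryptic cleavage sites in a sequence
#'
#' Counts positions after which trypsin cleaves (K or R not followed by P),
#' excluding a terminal K/R, i.e. the number of fully cleaved fragments
#' minus one.
#'
#' @param sequence A single amino-acid string.
#' @return Integer count of internal cleavage sites.
#' @export
n_cleavage_sites <- function(sequence) {
  length(tryptic_fragments(sequence)$start) - 1L
}
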