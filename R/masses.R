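# Average (not monoisotopic) residue masses in daltons. Whole-protein
# molecular weight is what matters here, so the average-mass convention is
# used throughout; the <0.1% difference from monoisotopic masses cannot
# change a decile ranking. B/Z take the mean of their two possible residues,
# X a conventional 110.0 Da mean residue mass.
AA_AVERAGE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132,
  U = 150.0379, O = 237.3018,
  B = (114.1038 + 115.0886) / 2,
  Z = (128.1307 + 129.1155) / 2,
  X = 110.0
)

WATER_MASS <- 18.0153

AA_ALPHABET <- names(AA_AVERAGE_MASS)
AA_AMBIGUOUS <- c("B", "Z", "X")

#' Average molecular mass of a protein or peptide sequence
#'
#' Computes the average (isotope-abundance-weighted) molecular mass of an
#' unmodified polypeptide: the sum of standard average residue masses plus one
#' water (18.0153 Da). The twenty canonical residues plus selenocysteine (U)
#' and pyrrolysine (O) use published average residue masses; the ambiguity
#' codes B and Z use the mean of their two possible residues and X uses a
#' conventional 110.0 Da mean residue mass, so that predicted proteomes
#' containing ambiguous residues can still be processed.
#'
#' @param sequence Character vector of amino-acid sequences (case-insensitive).
#' @return Numeric vector of masses in daltons, one per input sequence.
#' @examples
#' average_mass("G") # 75.07 Da
#' average_mass(c("GG", "PEPTIDE"))
#' @export
average_mass <- function(sequence) {
  if (length(sequence) == 0) return(numeric(0))
  if (any(is.na(sequence))) abort("`sequence` must not contain NA.")
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) abort("`sequence` must be non-empty.")
  chars <- strsplit(sequence, "", fixed = TRUE)
  vapply(seq_along(chars), function(i) {
    res <- chars[[i]]
    bad <- setdiff(unique(res), AA_ALPHABET)
    if (length(bad) > 0) {
      abort(sprintf(
        "Sequence %d contains non-amino-acid character(s): %s",
        i, paste(bad, collapse = ", ")
      ))
    }
    sum(AA_AVERAGE_MASS[res]) + WATER_MASS
  }, numeric(1))
}

# Count of ambiguous residues (B/Z/X) per sequence; used for per-record
# warnings when reading databases.
count_ambiguous <- function(sequence) {
  vapply(
    strsplit(toupper(sequence), "", fixed = TRUE),
    function(res) sum(res %in% AA_AMBIGUOUS),
    integer(1)
  )
}
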