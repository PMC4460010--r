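#' @useDynLib ferromap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm ks.test setNames
#' @importFrom utils write.table read.table
NULL

# The 20 standard residues, in the fixed order used by every scoring table
# in the package. "X" is handled separately as an unknown residue.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Robinson & Robinson-style background amino-acid frequencies, renormalized
# over the 20 standard residues. Used as the null emission model for
# profiles, for null-sequence calibration and for composition-matched decoys.
ROBINSON_BG <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
)
ROBINSON_BG <- ROBINSON_BG / sum(ROBINSON_BG)

#' Background residue frequencies
#'
#' The packaged background distribution over the 20 standard amino acids
#' (Robinson-Robinson-style table, renormalized). This is the null model
#' used for profile log-odds emissions, extreme-value calibration and
#' composition-matched decoy generation.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function() ROBINSON_BG

# BLOSUM62 as shipped with Biostrings, subset to the residues we score.
blosum62 <- function() {
  m <- NULL
  utils::data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

# Similarity-biased substitution table: for each residue, a probability
# vector over the 19 other residues proportional to 2^(BLOSUM62 score),
# so conservative replacements are preferred when simulating divergence.
substitution_table <- function() {
  b <- blosum62()[AA20, AA20]
  p <- 2^b
  diag(p) <- 0
  sweep(p, 1, rowSums(p), "/")
}

# Validate a peptide string: standard residues plus X only.
check_peptide <- function(x, what = "peptide") {
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains illegal residue characters: %s",
                 what, paste(utils::head(names(x)[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Map non-standard residue codes (B, Z, J, U, O, *, .) to X, uppercase.
sanitize_peptide <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X", x)
}
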