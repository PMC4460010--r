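#' E-value of a bit score under a calibrated profile
#'
#' `E = database_size * P(S >= s)` with the exceedance probability taken
#' from the profile's fitted Gumbel null:
#' `P = 1 - exp(-exp(-lambda * (s - mu)))`. Strictly non-increasing in the
#' score and exactly linear in the database size.
#'
#' @param profile Calibrated `ProfileModel`.
#' @param score_bits Bit score.
#' @param database_size Number of peptides searched (>= 1).
#' @return Expected number of equal-or-better scores.
#' @export
evalue_of <- function(profile, score_bits, database_size = 1L) {
  if (is.na(profile$evd_mu) || is.na(profile$evd_lambda))
    stop("profile '", profile$family_id,
         "' is not calibrated; run calibrate_evd() first", call. = FALSE)
  stopifnot(database_size >= 1)
  p <- -expm1(-exp(-profile$evd_lambda * (score_bits - profile$evd_mu)))
  database_size * p
}

#' Search peptides against a set of calibrated profiles
#'
#' Scores every (profile, peptide) pair and emits candidate hits at or
#' below the e-value cutoff (default 1e-05). The span fraction recorded
#' per hit is candidate ungapped length over the family's mature length.
#' By default each peptide is then assigned to its best-scoring family
#' only; set `best_per_orf = FALSE` to keep every family that passes.
#'
#' @param profiles List of calibrated `ProfileModel`s.
#' @param peptides data.frame of candidate peptides (as produced by
#'   [translate_contigs()]), or a named character vector.
#' @param evalue_cutoff Inclusion threshold (default 1e-05).
#' @param database_size Database size for e-values; defaults to the number
#'   of peptides searched (per-strain normalization).
#' @param best_per_orf Keep only the best family per peptide.
#' @return data.frame of hits, sorted by family, e-value, then peptide id.
#' @export
search <- function(profiles, peptides, evalue_cutoff = 1e-05,
                   database_size = NULL, best_per_orf = TRUE) {
  peps <- as_peptide_frame(peptides)
  if (nrow(peps) == 0L) return(empty_hits())
  if (is.null(database_size)) database_size <- nrow(peps)
  hits <- list()
  for (pf in profiles) {
    # Viterbi decides inclusion; the costlier forward log-sum is computed
    # for passing hits only.
    sc <- score_peptides(pf, peps$peptide, forward = FALSE)
    ev <- evalue_of(pf, sc[, 1L], database_size)
    keep <- which(ev <= evalue_cutoff)
    if (!length(keep)) next
    fwd <- score_peptides(pf, peps$peptide[keep], forward = TRUE)[, 2L]
    h <- peps[keep, , drop = FALSE]
    h$family_id <- pf$family_id
    h$viterbi_bits <- sc[keep, 1L]
    h$forward_bits <- fwd
    h$evalue <- ev[keep]
    h$span_fraction <- nchar(h$peptide) / pf$mature_length
    hits[[pf$family_id]] <- h
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out$hit_id <- sprintf("%s|%s|%s|f%+d@%d", out$strain_id, out$contig_id,
                        out$family_id, out$frame, out$start_nt)
  if (best_per_orf) {
    key <- paste(out$strain_id, out$contig_id, out$frame, out$start_nt)
    out <- out[order(key, out$evalue, out$family_id), , drop = FALSE]
    out <- out[!duplicated(paste(out$strain_id, out$contig_id, out$frame,
                                 out$start_nt)), , drop = FALSE]
  }
  out <- out[order(out$family_id, out$evalue, out$contig_id,
                   out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_peptide_frame <- function(peptides) {
  if (is.data.frame(peptides)) return(peptides)
  if (length(peptides) == 0L)
    return(empty_hits()[, c("contig_id", "strain_id", "frame", "start_nt",
                            "end_nt", "peptide")])
  data.frame(contig_id = if (is.null(names(peptides)))
    sprintf("pep%03d", seq_along(peptides)) else names(peptides),
    strain_id = "strain", frame = 1L, start_nt = 1L,
    end_nt = 3L * nchar(peptides), peptide = unname(peptides),
    stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(contig_id = character(), strain_id = character(),
             frame = integer(), start_nt = integer(), end_nt = integer(),
             peptide = character(), family_id = character(),
             viterbi_bits = numeric(), forward_bits = numeric(),
             evalue = numeric(), span_fraction = numeric(),
             hit_id = character(), stringsAsFactors = FALSE)
}
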