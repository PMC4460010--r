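#' Detect a plastid transit peptide on a ferredoxin candidate
#'
#' Diatom plastid-targeted proteins carry a conserved motif at the
#' signal/transit-peptide cleavage site, with cleavage falling between an
#' A/G and the following F. A call is positive iff (a) the candidate has
#' at least `min_extension` residues upstream of the position where the
#' mature anchor's first column maps, and (b) the degenerate pattern
#' (default `[AG]-F-[AVMLI]-P`) matches with its A/G inside that upstream
#' leader. The mature chain then begins at the F.
#'
#' @param candidate Candidate peptide.
#' @param map [map_to_anchor()] result vs the mature family anchor.
#' @param pattern A [motif_rule()]; default the packaged cleavage motif.
#' @param min_extension Minimum leader length in residues (default 15).
#' @return A `TransitPeptideCall` list: `present`, `motif_start`,
#'   `cleavage_site` (position of the F), `n_extension_len`, `variant`.
#' @export
detect_transit_peptide <- function(candidate, map,
                                   pattern = transit_peptide_motif(),
                                   min_extension = 15L) {
  mstart <- mapped_anchor_start(map)
  n_ext <- if (is.na(mstart)) 0L else mstart - 1L
  call_absent <- list(present = FALSE, motif_start = NA_integer_,
                      cleavage_site = NA_integer_,
                      n_extension_len = n_ext, variant = NA_character_)
  if (n_ext < min_extension) return(structure(call_absent,
                                              class = "TransitPeptideCall"))
  # search the leader plus enough residues for the motif to straddle the
  # cleavage point (its A/G is the last leader residue)
  window_end <- min(nchar(candidate), mstart + length(pattern$sets) - 2L)
  region <- substr(candidate, 1L, window_end)
  starts <- match_motif(region, pattern)
  starts <- starts[starts < mstart]
  if (!length(starts)) return(structure(call_absent,
                                        class = "TransitPeptideCall"))
  ms <- starts[length(starts)]   # motif closest to the mature start
  structure(list(present = TRUE, motif_start = ms,
                 cleavage_site = ms + 1L, n_extension_len = n_ext,
                 variant = substr(candidate, ms,
                                  ms + length(pattern$sets) - 1L)),
            class = "TransitPeptideCall")
}

#' The packaged transit-peptide cleavage motif
#'
#' `[AG]-F-[AVMLI]-P`, cleavage immediately before the F. Accepted
#' variations of the canonical motif are expressed by editing this rule.
#'
#' @return A [motif_rule()].
#' @export
transit_peptide_motif <- function() motif_rule("ASAFAP", "[AG]-F-[AVMLI]-P")

#' Detect a ubiquitin fusion upstream of a NiSOD candidate
#'
#' Most diatom NiSOD transcripts encode ubiquitin immediately upstream of
#' the Ni-hook; post-translational cleavage after the ubiquitin-terminal
#' diglycine releases the active enzyme. A call is positive iff the region
#' upstream of the Ni-hook scores against the ubiquitin profile at or
#' below `evalue_cutoff` AND ends in a diglycine whose second G lies
#' within `max_linker` residues of the NiSOD region start. Mutations
#' strictly downstream of the hook cannot change the call.
#'
#' @param candidate Candidate peptide.
#' @param hook_position Start of the Ni-hook match in the candidate.
#' @param ubq_profile Calibrated ubiquitin `ProfileModel`.
#' @param evalue_cutoff Acceptance e-value for the ubiquitin match
#'   (default 1e-05).
#' @param max_linker Maximum residues between the diglycine and the hook
#'   region start (default 5).
#' @return A `FusionCall` list: `present`, `ubq_span`, `cleavage_after`,
#'   `ubq_evalue`.
#' @export
detect_ubq_fusion <- function(candidate, hook_position, ubq_profile,
                              evalue_cutoff = 1e-05, max_linker = 5L) {
  absent <- structure(list(present = FALSE, ubq_span = NULL,
                           cleavage_after = NA_integer_,
                           ubq_evalue = NA_real_),
                      class = "FusionCall")
  if (hook_position <= 1L) return(absent)
  upstream <- substr(candidate, 1L, hook_position - 1L)
  if (nchar(upstream) < 2L) return(absent)
  sc <- score_peptide(ubq_profile, upstream)
  ev <- evalue_of(ubq_profile, sc[["viterbi_bits"]], 1L)
  if (ev > evalue_cutoff) return(absent)
  # rightmost diglycine in the upstream region whose second G is within
  # max_linker residues of the hook start
  up <- strsplit(upstream, "")[[1]]
  gg <- which(up[-length(up)] == "G" & up[-1L] == "G") + 1L  # second G
  gg <- gg[hook_position - gg - 1L <= max_linker]
  if (!length(gg)) return(absent)
  cleave <- max(gg)
  structure(list(present = TRUE, ubq_span = c(1L, cleave),
                 cleavage_after = cleave, ubq_evalue = unname(ev)),
            class = "FusionCall")
}

#' The 76-residue ubiquitin reference peptide
#'
#' The canonical eukaryotic ubiquitin sequence (ending in the diglycine
#' processed by ubiquitin-specific proteases), used to seed the ubiquitin
#' profile for fusion detection and by the community simulator to build
#' fusion genes.
#'
#' @return Peptide string of length 76.
#' @export
ubiquitin_reference <- function() {
  paste0("MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN",
         "IQKESTLHLVLRLRGG")
}
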