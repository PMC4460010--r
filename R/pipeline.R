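#' Assemble a run configuration
#'
#' Bundles the inputs and thresholds of one screening run. The threshold
#' defaults are the screen's canonical constants: e-value 1e-05, span
#' bounds 25/500 percent, 50 aa insertion limit, 95 percent dereplication,
#' 30 aa minimum ORF, 15 residue minimum transit-peptide extension.
#'
#' @param strain_fastas Named character vector: strain id -> contig FASTA
#'   (nucleotide) or peptide FASTA path.
#' @param strain_meta data.frame with `strain_id` and `species`.
#' @param references Named list of [reference_family()] objects (must
#'   include UBQ when fusion detection is wanted).
#' @param input_type "nt" (six-frame translated) or "aa".
#' @param evalue_cutoff,span_min_pct,span_max_pct,max_insertion_aa
#'   Screening thresholds.
#' @param derep_pct Dereplication identity threshold.
#' @param min_orf_aa Minimum ORF length.
#' @param min_extension Minimum transit-peptide leader length.
#' @param seed Seed for profile calibration.
#' @param out_dir Where stage TSVs, trees and the run log are written.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(strain_fastas, strain_meta, references,
                       input_type = c("nt", "aa"), evalue_cutoff = 1e-05,
                       span_min_pct = 25, span_max_pct = 500,
                       max_insertion_aa = 50L, derep_pct = 95,
                       min_orf_aa = 30L, min_extension = 15L, seed = 1L,
                       out_dir = tempfile("ferromap_run")) {
  input_type <- match.arg(input_type)
  missing_files <- strain_fastas[!file.exists(strain_fastas)]
  if (length(missing_files))
    stop("missing strain input(s): ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  stopifnot(all(c("strain_id", "species") %in% names(strain_meta)),
            all(names(strain_fastas) %in% strain_meta$strain_id),
            evalue_cutoff > 0, span_min_pct > 0, span_max_pct > 0,
            max_insertion_aa > 0, derep_pct > 0, min_orf_aa > 0)
  structure(list(strain_fastas = strain_fastas, strain_meta = strain_meta,
                 references = references, input_type = input_type,
                 evalue_cutoff = evalue_cutoff,
                 span_min_pct = span_min_pct, span_max_pct = span_max_pct,
                 max_insertion_aa = max_insertion_aa,
                 derep_pct = derep_pct, min_orf_aa = min_orf_aa,
                 min_extension = min_extension, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "RunConfig")
}

label_to_column <- function(label) {
  map <- c(FeSOD = "FESOD", MnSOD = "MNSOD")
  out <- ifelse(label %in% names(map), map[label], label)
  ifelse(out %in% canonical_columns(), out, NA_character_)
}

#' Run the full screening pipeline
#'
#' translate -> profile search -> span/insertion/duplicate filters ->
#' motif and residue classification -> transit-peptide and fusion calls ->
#' dereplication -> neighbor-joining trees -> same-species clade collapse
#' -> presence/copy matrix. Every stage's table is written as TSV under
#' `config$out_dir`; re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List: `profiles`, `hits`, `filter_reports`, `classifications`,
#'   `copy_records`, `matrix`, `trees`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  refs <- config$references
  flda_anchors <- attr(refs$FLDA, "clade_anchors")

  say("building and calibrating %d profiles", length(refs))
  profiles <- list()
  for (i in seq_along(refs)) {
    pf <- build_profile(refs[[i]])
    profiles[[names(refs)[i]]] <-
      calibrate_evd(pf, seed = config$seed + i)
  }
  search_profiles <- profiles[setdiff(names(profiles), "UBQ")]

  all_hits <- list()
  reports <- list()
  for (s in names(config$strain_fastas)) {
    say("screening strain %s", s)
    if (config$input_type == "nt") {
      contigs <- read_fasta(config$strain_fastas[[s]], "DNA",
                            allow_empty = TRUE)
      peps <- if (length(contigs))
        translate_contigs(contigs, s, config$min_orf_aa)
      else empty_hits()[, c("contig_id", "strain_id", "frame", "start_nt",
                            "end_nt", "peptide")]
    } else {
      aa <- read_fasta(config$strain_fastas[[s]], "AA", allow_empty = TRUE)
      peps <- data.frame(contig_id = names(aa), strain_id = s, frame = 1L,
                         start_nt = 1L, end_nt = 3L * nchar(aa),
                         peptide = sanitize_peptide(unname(aa)),
                         stringsAsFactors = FALSE)
    }
    hits <- search(search_profiles, peps,
                   evalue_cutoff = config$evalue_cutoff)
    rep <- apply_screen_filters(hits, refs, config$span_min_pct,
                                config$span_max_pct,
                                config$max_insertion_aa)
    all_hits[[s]] <- hits
    reports[[s]] <- rep
  }
  hits <- do.call(rbind, c(all_hits, list(make.row.names = FALSE)))
  survivors <- do.call(rbind, c(lapply(reports, `[[`, "survivors"),
                                list(make.row.names = FALSE)))

  say("classifying %d surviving candidates", NROW(survivors))
  cls <- classify_hits(survivors, refs, profiles,
                       evalue_cutoff = config$evalue_cutoff,
                       min_extension = config$min_extension)

  say("building trees and counting copies")
  cc <- count_family_copies(cls, config$strain_meta,
                            derep_pct = config$derep_pct)

  mat <- presence_matrix(cc$records,
                         strains = config$strain_meta$strain_id)

  write_outputs(config, hits, reports, cls, cc, mat)
  list(profiles = profiles, hits = hits, filter_reports = reports,
       classifications = cls, copy_records = cc$records,
       matrix = mat, trees = cc$trees, out_dir = config$out_dir)
}

#' Classify screened survivors under the packaged rule sets
#'
#' Runs motif/residue classification for every surviving candidate,
#' including ubiquitin-fusion detection for NiSOD candidates (with the
#' Ni-hook window re-anchored at the cleavage site) and transit-peptide
#' detection for ferredoxin candidates. The `effective_peptide` column
#' holds the mature chain after any cleavage and is what downstream tree
#' building should use.
#'
#' @param survivors Hit data.frame surviving [apply_screen_filters()].
#' @param refs Named list of [reference_family()] objects (UBQ included
#'   when fusion detection is wanted).
#' @param profiles Named list of calibrated profiles (for the UBQ score).
#' @param rulesets Family rule sets (default [default_rulesets()]).
#' @param evalue_cutoff Acceptance e-value for the ubiquitin match.
#' @param min_extension Minimum transit-peptide leader length.
#' @return data.frame, one row per candidate, with `label`, `column`,
#'   `transit`/`fusion` flags, cleavage coordinates and peptides.
#' @export
classify_hits <- function(survivors, refs, profiles,
                          rulesets = default_rulesets(),
                          evalue_cutoff = 1e-05, min_extension = 15L) {
  flda_anchors <- attr(refs$FLDA, "clade_anchors")
  if (is.null(flda_anchors) && !is.null(refs$FLDA)) {
    mm <- refs$FLDA$members
    ii <- grep("cladeII", names(mm))
    if (length(ii))
      flda_anchors <- list(cladeI = refs$FLDA$anchor,
                           cladeII = unname(mm[ii[1L]]))
  }
  hook_any <- motif_rule("Ni-hook", "H-C-X-X-P-C-G-X-Y")
  rows <- vector("list", NROW(survivors))
  if (!NROW(survivors)) {
    return(data.frame(hit_id = character(), strain_id = character(),
                      contig_id = character(), family_id = character(),
                      label = character(), column = character(),
                      rejected_reason = character(),
                      conservation = character(), transit = logical(),
                      cleavage_site = integer(), fusion = logical(),
                      cleavage_after = integer(),
                      effective_peptide = character(),
                      peptide = character(), stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(survivors))) {
    h <- survivors[i, ]
    fam <- refs[[h$family_id]]
    map <- map_to_anchor(h$peptide, fam)
    transit <- FALSE; cleav_site <- NA_integer_
    fusion <- FALSE; cleav_after <- NA_integer_
    offset <- 1L
    if (h$family_id == "NISOD") {
      starts <- match_motif(h$peptide, hook_any)
      if (length(starts)) {
        fc <- detect_ubq_fusion(h$peptide, starts[1L], profiles$UBQ,
                                evalue_cutoff)
        if (fc$present) {
          fusion <- TRUE
          cleav_after <- fc$cleavage_after
          offset <- 1L - cleav_after
        }
      }
    }
    res <- classify(h$peptide, rulesets[[h$family_id]], map,
                    flda_references = flda_anchors, offset = offset)
    if (h$family_id == "PETF" && res$label == "PETF") {
      tp <- detect_transit_peptide(h$peptide, map,
                                   min_extension = min_extension)
      transit <- tp$present
      cleav_site <- tp$cleavage_site
    }
    eff <- h$peptide
    if (fusion) eff <- substr(eff, cleav_after + 1L, nchar(eff))
    if (transit) eff <- substr(eff, cleav_site, nchar(eff))
    rows[[i]] <- data.frame(
      hit_id = h$hit_id, strain_id = h$strain_id, contig_id = h$contig_id,
      family_id = h$family_id, label = res$label,
      column = label_to_column(res$label),
      rejected_reason = res$rejected_reason,
      conservation = res$conservation, transit = transit,
      cleavage_site = cleav_site, fusion = fusion,
      cleavage_after = cleav_after, effective_peptide = eff,
      peptide = h$peptide, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Dereplicate, build trees and count per-strain copies per family
#'
#' For each family/subtype column: single-linkage dereplication at
#' `derep_pct`, identity-based distances, neighbor-joining, midpoint
#' rooting, and collapse of maximal same-species clades; each strain is
#' then credited one copy per collapsed group containing at least one of
#' its sequences (dereplicated members included). Transit-peptide and
#' fusion flags are propagated into the `PETF_TP`/`NISOD_UBQ` columns.
#'
#' @param cls Classification table from [classify_hits()].
#' @param strain_meta data.frame with `strain_id` and `species`.
#' @param derep_pct Dereplication identity threshold (default 95).
#' @return List: `records` (strain/column/copy_number data.frame) and
#'   `trees` (named list of rooted `phylo` objects).
#' @export
count_family_copies <- function(cls, strain_meta, derep_pct = 95) {
  meta <- strain_meta
  species_of_strain <- stats::setNames(meta$species, meta$strain_id)
  acc <- cls[!is.na(cls$column) & cls$label != "rejected", , drop = FALSE]
  records <- list()
  trees <- list()
  for (col in setdiff(canonical_columns(), c("PETF_TP", "NISOD_UBQ"))) {
    sub <- acc[acc$column == col, , drop = FALSE]
    if (!nrow(sub)) next
    seqs <- stats::setNames(sub$effective_peptide, sub$hit_id)
    strain_by_seq <- stats::setNames(sub$strain_id, sub$hit_id)
    flag_by_seq <- stats::setNames(
      if (col == "PETF") sub$transit
      else if (col == "NISOD") sub$fusion
      else rep(FALSE, nrow(sub)), sub$hit_id)
    idm <- identity_matrix_of(seqs)
    der <- dereplicate(seqs, derep_pct, identity_matrix = idm)
    reps <- der$representatives
    members <- stats::setNames(der$clusters, reps)
    tip_species <- stats::setNames(
      species_of_strain[strain_by_seq[reps]], reps)
    if (length(reps) <= 2L) {
      groups <- if (length(reps) == 2L &&
                    tip_species[1L] == tip_species[2L])
        list(reps) else as.list(reps)
    } else {
      d <- identity_distances(seqs[reps],
                              identity_matrix = idm[reps, reps])
      tr <- midpoint_root(nj_tree(d))
      tr$edge.length[tr$edge.length < 0] <- 0
      trees[[col]] <- tr
      groups <- clade_groups(tr, tip_species)
    }
    for (s in unique(sub$strain_id)) {
      n_copy <- 0L; n_flag <- 0L
      for (g in groups) {
        ids <- unlist(members[g], use.names = FALSE)
        mine <- ids[strain_by_seq[ids] == s]
        if (length(mine)) {
          n_copy <- n_copy + 1L
          if (any(flag_by_seq[mine])) n_flag <- n_flag + 1L
        }
      }
      records[[length(records) + 1L]] <- data.frame(
        strain_id = s, column = col, copy_number = n_copy,
        stringsAsFactors = FALSE)
      flag_col <- if (col == "PETF") "PETF_TP"
      else if (col == "NISOD") "NISOD_UBQ" else NA_character_
      if (!is.na(flag_col))
        records[[length(records) + 1L]] <- data.frame(
          strain_id = s, column = flag_col, copy_number = n_flag,
          stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records))
    do.call(rbind, c(records, list(make.row.names = FALSE)))
  else data.frame(strain_id = character(), column = character(),
                  copy_number = integer(), stringsAsFactors = FALSE)
  list(records = records, trees = trees)
}

write_outputs <- function(config, hits, reports, cls, cc, mat) {
  od <- config$out_dir
  wt <- function(x, f) utils::write.table(
    x, file.path(od, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(hits, "hits.tsv")
  counts <- do.call(rbind, lapply(names(reports), function(s)
    data.frame(strain_id = s, t(reports[[s]]$counts))))
  wt(counts, "filter_report.tsv")
  wt(cls[, setdiff(names(cls), "effective_peptide")], "classifications.tsv")
  wt(cc$records, "copy_counts.tsv")
  pm <- data.frame(strain_id = rownames(mat), mat, check.names = FALSE)
  wt(pm, "presence_matrix.tsv")
  if (length(cc$trees)) {
    td <- file.path(od, "trees")
    dir.create(td, showWarnings = FALSE)
    for (nm in names(cc$trees))
      ape::write.tree(cc$trees[[nm]], file.path(td, paste0(nm, ".nwk")))
  }
  log <- c(sprintf("ferromap %s", as.character(utils::packageVersion("ferromap"))),
           sprintf("seed: %d", config$seed),
           sprintf("evalue_cutoff: %g", config$evalue_cutoff),
           sprintf("span: %g-%g %%", config$span_min_pct, config$span_max_pct),
           sprintf("max_insertion_aa: %d", config$max_insertion_aa),
           sprintf("derep_pct: %g", config$derep_pct),
           sprintf("min_orf_aa: %d", config$min_orf_aa),
           sprintf("min_extension: %d", config$min_extension))
  writeLines(log, file.path(od, "run_log.txt"))
  invisible(od)
}
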