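#' Build a reference family from in-memory peptides
#'
#' Star-aligns members to the anchor and wraps them as a
#' [reference_family()]; convenience used by the simulator and tests.
#'
#' @param family_id Family symbol.
#' @param members Named character vector of peptides.
#' @param anchor_id Anchor member id.
#' @return A `ReferenceFamily`.
#' @export
family_from_members <- function(family_id, members, anchor_id) {
  star <- star_align(members, anchor_id, c(1L, nchar(members[[anchor_id]])))
  reference_family(family_id, members, star$alignment, anchor_id,
                   insert_counts = star$insert_counts)
}

#' Generate the packaged synthetic reference families
#'
#' Miniature reference families whose anchors embed the packaged motif and
#' residue rules at exactly the anchor coordinates the rules test (e.g.
#' cysteines at ferredoxin positions 37/42/45/75, superoxide dismutase
#' diagnostic sites 77/146, the four Fet3p-numbered Cu regions). Each
#' family carries `n_members` reference peptides derived from the anchor
#' at high identity with all rule sites protected, plus the protected-site
#' annotation the simulator uses when planting homologs.
#'
#' @param seed RNG seed.
#' @param n_members Reference peptides per family (default 4).
#' @param member_identity Identity of non-anchor members to the anchor.
#' @return Named list of `ReferenceFamily` objects with a `protected`
#'   attribute (integer positions) and, for FLDA, a `clade_anchors`
#'   attribute.
#' @export
make_reference_families <- function(seed = 101L, n_members = 4L,
                                    member_identity = 0.9) {
  with_seed(seed, {
    bg <- background_frequencies()
    rp <- function(n) paste(sample(AA20, n, replace = TRUE, prob = bg),
                            collapse = "")
    plant <- function(seq, at, what) {
      ch <- strsplit(seq, "")[[1]]
      ch[seq(at, at + nchar(what) - 1L)] <- strsplit(what, "")[[1]]
      paste(ch, collapse = "")
    }
    plant_each <- function(seq, pos, res) {
      ch <- strsplit(seq, "")[[1]]
      ch[pos] <- res
      paste(ch, collapse = "")
    }

    defs <- list()

    fre <- rp(300)
    fre <- plant(fre, 60L, "HPFTV")
    fre <- plant(fre, 180L, "CGP")
    defs$FRE <- list(anchor = fre, protected = c(60:64, 180:182))

    mco <- rp(500)
    mco <- plant_each(mco, c(81, 83, 124, 126, 128, 416, 418, 420,
                             482, 487, 489), "H")
    mco <- plant_each(mco, 485L, "C")
    mco <- plant_each(mco, c(185, 283, 409), c("E", "D", "D"))
    defs$MCO <- list(anchor = mco,
                     protected = c(81, 83, 124, 126, 128, 416, 418, 420,
                                   482, 485, 487, 489, 185, 283, 409))

    ftr <- rp(350)
    ftr <- plant(ftr, 100L, "REAAE")
    ftr <- plant(ftr, 250L, "RELLE")
    defs$FTR <- list(anchor = ftr, protected = c(100:104, 250:254))

    ftn <- rp(170)
    ftn <- plant_each(ftn, c(17, 50, 53, 94, 130, 131, 57, 121),
                      c("E", "E", "H", "E", "E", "E", "D", "E"))
    defs$FTN <- list(anchor = ftn,
                     protected = c(17, 50, 53, 94, 130, 131, 57, 121))

    flda1 <- rp(170)
    flda2_base <- substr(flda1, 1L, 150L)
    flda2 <- evolve_homolog(flda2_base, 0.6, seed = sample.int(2^31 - 1, 1))
    defs$FLDA <- list(anchor = flda1, protected = integer(),
                      clade_anchors = list(cladeI = flda1, cladeII = flda2))

    petf <- rp(96)
    petf <- plant(petf, 1L, "FAP")
    petf <- plant_each(petf, c(37, 42, 45, 75), "C")
    defs$PETF <- list(anchor = petf, protected = c(1:3, 37, 42, 45, 75))

    pcyn <- rp(99)
    pcyn <- plant_each(pcyn, c(37, 84, 87, 92), c("H", "C", "H", "M"))
    defs$PCYN <- list(anchor = pcyn, protected = c(37, 84, 87, 92))

    defs$CYTC6 <- list(anchor = rp(90), protected = integer())

    fesod <- rp(200)
    fesod <- plant_each(fesod, c(77, 146), c("Q", "A"))
    defs$FESOD <- list(anchor = fesod, protected = c(77, 146))

    mnsod <- evolve_homolog(fesod, 0.75, protected = c(77, 146),
                            seed = sample.int(2^31 - 1, 1))
    mnsod <- plant_each(mnsod, c(77, 146), c("G", "Q"))
    defs$MNSOD <- list(anchor = mnsod, protected = c(77, 146))

    czsod <- rp(154)
    czsod <- plant_each(czsod, c(46, 48, 63, 71, 80, 120, 83),
                        c("H", "H", "H", "H", "H", "H", "D"))
    defs$CUZNSOD <- list(anchor = czsod,
                         protected = c(46, 48, 63, 71, 80, 120, 83))

    nisod <- rp(120)
    nisod <- plant(nisod, 1L, "HCDLPCGVY")
    defs$NISOD <- list(anchor = nisod, protected = 1:9)

    defs$UBQ <- list(anchor = ubiquitin_reference(), protected = 73:76)

    fams <- list()
    for (fid in names(defs)) {
      d <- defs[[fid]]
      anchor_id <- paste0(fid, "_ref1")
      members <- stats::setNames(d$anchor, anchor_id)
      if (fid == "FLDA") {
        members <- c(members,
                     stats::setNames(d$clade_anchors$cladeII,
                                     paste0(fid, "_cladeII_ref")))
        extra <- n_members - 2L
      } else extra <- n_members - 1L
      for (i in seq_len(max(extra, 0L))) {
        src <- if (fid == "FLDA" && i %% 2 == 0)
          d$clade_anchors$cladeII else d$anchor
        m <- evolve_homolog(src, member_identity, protected = d$protected,
                            seed = sample.int(2^31 - 1, 1))
        members[paste0(fid, "_ref", length(members) + 1L)] <- m
      }
      fam <- family_from_members(fid, members, anchor_id)
      attr(fam, "protected") <- as.integer(d$protected)
      if (fid == "FLDA") attr(fam, "clade_anchors") <- d$clade_anchors
      fams[[fid]] <- fam
    }
    fams
  })
}

#' Mutate a peptide to a target identity with protected sites
#'
#' Substitutes residues at uniformly chosen unprotected positions until
#' the realized identity is within two percentage points of the target
#' (exact by construction: `round((1 - target) * length)` distinct
#' positions are substituted). Replacement residues are drawn from a
#' similarity-biased table (BLOSUM62 rows, renormalized over non-identical
#' residues), so conservative changes dominate. Deterministic given the
#' seed.
#'
#' @param peptide Peptide string.
#' @param target_identity Fraction in (0, 1].
#' @param protected Integer positions that must not change.
#' @param seed RNG seed.
#' @return Mutated peptide of the same length.
#' @export
evolve_homolog <- function(peptide, target_identity, protected = integer(),
                           seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 1)
  n <- nchar(peptide)
  k <- round((1 - target_identity) * n)
  if (k == 0L) return(peptide)
  unprot <- setdiff(seq_len(n), protected)
  if (k > length(unprot))
    stop(sprintf(
      "target identity %.2f unreachable: %d protected positions impose a floor of %.2f",
      target_identity, length(protected), 1 - length(unprot) / n))
  tab <- substitution_table()
  with_seed(seed, {
    ch <- strsplit(peptide, "")[[1]]
    sites <- sample(unprot, k)
    for (p in sites) {
      from <- ch[p]
      if (!from %in% AA20) next
      ch[p] <- sample(AA20, 1L, prob = tab[from, ])
    }
    paste(ch, collapse = "")
  })
}

#' Apply assembly/architecture features to a planted homolog
#'
#' Emulates the artifacts and architectures the screen must handle:
#' truncation to a fragment of a given span, an internal mis-assembly
#' insertion, an N-terminal ubiquitin + diglycine cassette, or a plastid
#' transit-peptide leader ending in the cleavage motif. A fragment cannot
#' be combined with a leader or fusion.
#'
#' @param peptide Mature peptide.
#' @param features Character subset of
#'   `c("fragment", "insertion", "ubq_fusion", "transit_peptide")`.
#' @param params List: `fragment_span` (fraction, default 0.2),
#'   `insertion_len` (residues, default 60), `leader_len` (default 25).
#' @param protected Positions (on the mature peptide) an insertion must
#'   not interrupt.
#' @param seed RNG seed.
#' @return List: `peptide`, `details` (named list of realized parameters).
#' @export
plant_features <- function(peptide, features = character(), params = list(),
                           protected = integer(), seed = 1L) {
  if ("fragment" %in% features &&
      any(c("transit_peptide", "ubq_fusion") %in% features))
    stop("a fragment cannot carry a transit peptide or fusion cassette")
  p <- utils::modifyList(list(fragment_span = 0.2, insertion_len = 60L,
                              leader_len = 25L), params)
  details <- list()
  with_seed(seed, {
    out <- peptide
    if ("insertion" %in% features) {
      n <- nchar(out)
      cand <- setdiff(seq(5L, n - 5L), protected)
      # avoid splitting a protected run: site s inserts between s and s+1
      cand <- cand[!((cand + 1L) %in% protected & cand %in% protected)]
      site <- sample(cand, 1L)
      seg <- paste(sample(AA20, p$insertion_len, replace = TRUE,
                          prob = background_frequencies()), collapse = "")
      out <- paste0(substr(out, 1L, site), seg, substr(out, site + 1L, n))
      details$insertion_site <- site
      details$insertion_len <- p$insertion_len
    }
    if ("fragment" %in% features) {
      n <- nchar(out)
      len <- max(1L, round(p$fragment_span * n))
      start <- sample(seq_len(n - len + 1L), 1L)
      out <- substr(out, start, start + len - 1L)
      details$fragment_start <- start
      details$fragment_len <- len
    }
    if ("transit_peptide" %in% features) {
      lead <- c(sample(setdiff(AA20, "F"), p$leader_len - 1L, replace = TRUE),
                "A")
      out <- paste0(paste(lead, collapse = ""), out)
      details$leader_len <- p$leader_len
    }
    if ("ubq_fusion" %in% features) {
      out <- paste0(ubiquitin_reference(), out)
      details$ubq_len <- nchar(ubiquitin_reference())
    }
    list(peptide = out, details = details)
  })
}

#' Reverse-translate a peptide into a synthetic contig
#'
#' Random synonymous codons under the standard genetic code, an in-frame
#' stop immediately before and after the coding region, and random
#' non-coding flanks; on the minus strand the contig is
#' reverse-complemented. [six_frame_translate()] recovers the peptide
#' exactly.
#'
#' @param peptide Peptide (no stops).
#' @param seed RNG seed.
#' @param strand "+" or "-".
#' @param flank_nt Flank length in nucleotides (default 60).
#' @return Nucleotide contig string.
#' @export
reverse_translate <- function(peptide, seed = 1L, strand = "+",
                              flank_nt = 60L) {
  code <- Biostrings::GENETIC_CODE
  syn <- split(names(code), unname(code))
  stops <- names(code)[code == "*"]
  with_seed(seed, {
    ch <- strsplit(peptide, "")[[1]]
    cod <- vapply(ch, function(a) {
      cands <- syn[[a]]
      cands[sample.int(length(cands), 1L)]
    }, "")
    rand_flank <- function(n) {
      if (n <= 0L) return("")
      repeat {
        f <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
        if (n < 90L) return(f)
        if (nrow(six_frame_translate(f, min_orf_aa = 30L)) == 0L) return(f)
      }
    }
    ctg <- paste0(rand_flank(flank_nt),
                  stops[sample.int(3L, 1L)],
                  paste(cod, collapse = ""),
                  stops[sample.int(3L, 1L)],
                  rand_flank(flank_nt))
    if (strand == "-")
      ctg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ctg)))
    ctg
  })
}

#' Specify a synthetic community
#'
#' The default specification is the package's study condition: 12 strains
#' (two of which are subspecies of one species), the 12 screened gene
#' families with the copy structure below, planted homologs at 55-95%
#' final identity to the references with all rule sites protected,
#' fragment and long-insertion violators at 8% each, transit peptides on
#' 75% of ferredoxin plantings, ubiquitin fusions on 75% of NiSOD
#' plantings, and 15 composition-matched shuffled decoys per strain.
#'
#' @param n_strains Number of strains.
#' @param families_per_strain Named integer vector: subtype column ->
#'   copies per strain.
#' @param identity_range Final identity range versus the reference.
#' @param fragment_rate,insertion_rate Per-planting violator rates.
#' @param fusion_rate,transit_rate Architecture rates (NISOD / PETF only).
#' @param decoys_per_strain Shuffled decoys per strain.
#' @param seed Community seed; all outputs are deterministic given it.
#' @return A `CommunitySpec` list.
#' @export
community_spec <- function(n_strains = 12L,
                           families_per_strain = c(
                             FRE = 2L, MCO = 1L, FTR = 1L, FTN = 1L,
                             "FLDA-I" = 1L, "FLDA-II" = 1L, PETF = 1L,
                             PCYN = 1L, CYTC6 = 1L, FESOD = 1L,
                             MNSOD = 2L, CUZNSOD = 1L, NISOD = 1L),
                           identity_range = c(0.55, 0.95),
                           fragment_rate = 0.08, insertion_rate = 0.08,
                           fusion_rate = 0.75, transit_rate = 0.75,
                           decoys_per_strain = 15L, seed = 42L) {
  stopifnot(identity_range[1] > 0, identity_range[1] <= identity_range[2],
            identity_range[2] <= 1,
            all(c(fragment_rate, insertion_rate, fusion_rate,
                  transit_rate) >= 0),
            all(c(fragment_rate, insertion_rate, fusion_rate,
                  transit_rate) <= 1))
  structure(list(n_strains = as.integer(n_strains),
                 families_per_strain = families_per_strain,
                 identity_range = identity_range,
                 fragment_rate = fragment_rate,
                 insertion_rate = insertion_rate,
                 fusion_rate = fusion_rate, transit_rate = transit_rate,
                 decoys_per_strain = as.integer(decoys_per_strain),
                 seed = as.integer(seed)),
            class = "CommunitySpec")
}

subtype_to_family <- function(subtype) {
  ifelse(subtype %in% c("FLDA-I", "FLDA-II"), "FLDA", subtype)
}

positional_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Build a synthetic community with a truth manifest
#'
#' Writes one contig FASTA per strain (planted homologs, feature
#' violators, fusion/leader architectures and shuffled decoys), the
#' reference family FASTAs, a strain metadata table and a truth manifest.
#' The manifest's `expected_survival` and `expected_label` are computed
#' from the planted parameters and the declared screen thresholds alone,
#' never by running the pipeline, so pipeline-versus-manifest agreement is
#' a genuine test.
#'
#' @param spec A [community_spec()].
#' @param out_dir Output directory (created).
#' @param references Optional pre-built reference families.
#' @return List: `spec`, `out_dir`, `strain_fastas`, `strain_meta`,
#'   `manifest`, `references`.
#' @export
build_community <- function(spec = community_spec(),
                            out_dir = tempfile("community"),
                            references = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- if (is.null(references))
    make_reference_families(seed = spec$seed + 1000L) else references
  flda_anchors <- attr(refs$FLDA, "clade_anchors")
  anchor_of <- function(subtype) {
    if (subtype == "FLDA-I") return(flda_anchors$cladeI)
    if (subtype == "FLDA-II") return(flda_anchors$cladeII)
    refs[[subtype]]$anchor
  }
  protected_of <- function(subtype) {
    if (subtype == "FLDA-II") return(integer())
    attr(refs[[subtype_to_family(subtype)]], "protected")
  }

  set.seed(spec$seed)
  strains <- sprintf("S%02d", seq_len(spec$n_strains))
  species <- sprintf("sp%02d", pmin(seq_len(spec$n_strains),
                                    spec$n_strains - 1L))
  strain_meta <- data.frame(strain_id = strains, species = species,
                            stringsAsFactors = FALSE)

  # ortholog-group ancestors shared by all strains, per subtype x copy
  ancestors <- list()
  for (st in names(spec$families_per_strain)) {
    k <- spec$families_per_strain[[st]]
    if (k < 1L) next
    ancestors[[st]] <- lapply(seq_len(k), function(j) {
      evolve_homolog(anchor_of(st), stats::runif(1, 0.68, 0.80),
                     protected = protected_of(st),
                     seed = sample.int(2^31 - 1, 1))
    })
  }

  manifest <- list()
  fasta_paths <- character()
  for (s in strains) {
    contigs <- character()
    idx <- 0L
    planted_peps <- character()
    for (st in names(spec$families_per_strain)) {
      k <- spec$families_per_strain[[st]]
      if (k < 1L) next
      for (j in seq_len(k)) {
        idx <- idx + 1L
        cid <- sprintf("%s_c%03d", s, idx)
        pep <- evolve_homolog(ancestors[[st]][[j]],
                              stats::runif(1, 0.90, 0.96),
                              protected = protected_of(st),
                              seed = sample.int(2^31 - 1, 1))
        ident <- positional_identity(pep, anchor_of(st))
        u <- stats::runif(1)
        feats <- character()
        if (u < spec$fragment_rate) feats <- "fragment"
        else if (u < spec$fragment_rate + spec$insertion_rate)
          feats <- "insertion"
        if (!length(feats)) {
          if (st == "PETF" && stats::runif(1) < spec$transit_rate)
            feats <- "transit_peptide"
          if (st == "NISOD" && stats::runif(1) < spec$fusion_rate)
            feats <- "ubq_fusion"
        }
        pf <- plant_features(pep, feats, protected = protected_of(st),
                             seed = sample.int(2^31 - 1, 1))
        survives <- !any(c("fragment", "insertion") %in% feats)
        strand <- sample(c("+", "-"), 1L)
        contigs[cid] <- reverse_translate(pf$peptide,
                                          seed = sample.int(2^31 - 1, 1),
                                          strand = strand)
        planted_peps <- c(planted_peps, pep)
        manifest[[length(manifest) + 1L]] <- data.frame(
          strain_id = s, contig_id = cid,
          family_id = subtype_to_family(st), subtype = st,
          planted_identity = round(ident, 4),
          features = if (length(feats)) feature_tag(feats, pf$details)
          else "",
          expected_survival = survives,
          expected_label = if (survives) st else "",
          stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(spec$decoys_per_strain)) {
      idx <- idx + 1L
      cid <- sprintf("%s_c%03d", s, idx)
      src <- planted_peps[sample.int(length(planted_peps), 1L)]
      dec <- paste(sample(strsplit(src, "")[[1]]), collapse = "")
      contigs[cid] <- reverse_translate(dec,
                                        seed = sample.int(2^31 - 1, 1),
                                        strand = sample(c("+", "-"), 1L))
      manifest[[length(manifest) + 1L]] <- data.frame(
        strain_id = s, contig_id = cid, family_id = "", subtype = "",
        planted_identity = NA_real_, features = "decoy",
        expected_survival = FALSE, expected_label = "",
        stringsAsFactors = FALSE)
    }
    fp <- file.path(out_dir, paste0(s, ".fasta"))
    write_fasta(contigs, fp)
    fasta_paths[s] <- fp
  }

  manifest <- if (length(manifest)) do.call(rbind, manifest)
  else data.frame(strain_id = character(), contig_id = character(),
                  family_id = character(), subtype = character(),
                  planted_identity = numeric(), features = character(),
                  expected_survival = logical(),
                  expected_label = character(), stringsAsFactors = FALSE)
  ref_dir <- file.path(out_dir, "references")
  dir.create(ref_dir, showWarnings = FALSE)
  for (fid in names(refs))
    write_fasta(refs[[fid]]$members, file.path(ref_dir,
                                               paste0(fid, ".fasta")))
  utils::write.table(manifest, file.path(out_dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(strain_meta, file.path(out_dir, "strain_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(spec = spec, out_dir = out_dir, strain_fastas = fasta_paths,
       strain_meta = strain_meta, manifest = manifest, references = refs)
}

feature_tag <- function(feats, details) {
  tags <- vapply(feats, function(f) {
    if (f == "insertion")
      sprintf("insertion_%d_aa", details$insertion_len) else f
  }, "")
  paste(tags, collapse = ",")
}

#' Truth presence/copy matrix from a manifest
#'
#' Derived from the manifest's planted parameters only (a planting counts
#' iff `expected_survival` is true); the flag columns count surviving
#' plantings carrying the transit-peptide or fusion feature.
#'
#' @param manifest Manifest data.frame from [build_community()].
#' @param strains Row order (default: strains present).
#' @return Integer matrix matching [presence_matrix()] layout.
#' @export
truth_matrix <- function(manifest, strains = NULL) {
  if (is.null(strains)) strains <- sort(unique(manifest$strain_id))
  cols <- canonical_columns()
  m <- matrix(0L, length(strains), length(cols),
              dimnames = list(strains, cols))
  surv <- manifest[manifest$expected_survival, , drop = FALSE]
  for (i in seq_len(nrow(surv))) {
    s <- surv$strain_id[i]; lab <- surv$expected_label[i]
    if (!nzchar(lab)) next
    m[s, lab] <- m[s, lab] + 1L
    if (grepl("transit_peptide", surv$features[i]))
      m[s, "PETF_TP"] <- m[s, "PETF_TP"] + 1L
    if (grepl("ubq_fusion", surv$features[i]))
      m[s, "NISOD_UBQ"] <- m[s, "NISOD_UBQ"] + 1L
  }
  m
}

#' Cell agreement between two presence matrices
#'
#' @param a,b Matrices with identical dimnames.
#' @return Fraction of equal cells.
#' @export
matrix_agreement <- function(a, b) {
  stopifnot(identical(dimnames(a), dimnames(b)))
  mean(a == b)
}
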