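test_that("evolution hits its identity target and honors protection", {
  set.seed(191)
  base <- random_peptide(400)
  expect_identical(evolve_homolog(base, 1, seed = 1), base)
  for (s in 1:20) {
    out <- evolve_homolog(base, 0.6, seed = s)
    ident <- 100 * mean(strsplit(out, "")[[1]] == strsplit(base, "")[[1]])
    expect_gte(ident, 58); expect_lte(ident, 62)
  }
  prot <- 50:70
  out <- evolve_homolog(base, 0.4, protected = prot, seed = 9)
  expect_identical(substr(out, 50, 70), substr(base, 50, 70))
  expect_error(evolve_homolog(random_peptide(20), 0.01,
                              protected = 1:15, seed = 1),
               "floor")
})

test_that("feature planting produces the declared architectures", {
  set.seed(201)
  pep <- random_peptide(200)
  fr <- plant_features(pep, "fragment", list(fragment_span = 0.2), seed = 2)
  expect_equal(nchar(fr$peptide), 40L)
  expect_true(grepl(fr$peptide, pep, fixed = TRUE))

  ins <- plant_features(pep, "insertion", list(insertion_len = 60L),
                        seed = 3)
  expect_equal(nchar(ins$peptide), 260L)
  expect_equal(ins$details$insertion_len, 60L)

  tp <- plant_features(pep, "transit_peptide", list(leader_len = 25L),
                       seed = 4)
  expect_equal(nchar(tp$peptide), 225L)
  expect_equal(substr(tp$peptide, 26, 225), pep)
  expect_equal(substr(tp$peptide, 25, 25), "A")

  fu <- plant_features(pep, "ubq_fusion", seed = 5)
  expect_equal(substr(fu$peptide, 1, 76), ubiquitin_reference())

  expect_error(plant_features(pep, c("fragment", "transit_peptide")),
               "fragment")
})

test_that("reverse translation round-trips through the translator", {
  set.seed(211)
  for (i in 1:5) {
    pep <- random_peptide(sample(40:120, 1))
    strand <- sample(c("+", "-"), 1)
    ctg <- reverse_translate(pep, seed = i, strand = strand)
    orfs <- six_frame_translate(ctg, min_orf_aa = 30L)
    hit <- orfs[orfs$peptide == pep, ]
    expect_equal(nrow(hit), 1L)
    if (strand == "-") expect_lt(hit$frame, 0)
    else expect_gt(hit$frame, 0)
    # flanks are too short to harbor a spurious 30-residue frame
    expect_true(all(nchar(orfs$peptide) < 30L | orfs$peptide == pep |
                      vapply(orfs$peptide, function(p)
                        grepl(p, pep, fixed = TRUE) ||
                          nchar(p) >= 30, TRUE)))
  }
  c1 <- reverse_translate("MKLV" , seed = 7)
  c2 <- reverse_translate("MKLV", seed = 7)
  expect_identical(c1, c2)
})

test_that("community building is deterministic and the manifest accounts for every contig", {
  spec <- community_spec(n_strains = 2L, decoys_per_strain = 3L,
                        seed = 99L)
  d1 <- file.path(tempfile("commA"))
  d2 <- file.path(tempfile("commB"))
  c1 <- build_community(spec, d1)
  c2 <- build_community(spec, d2)
  expect_identical(c1$manifest, c2$manifest)
  for (s in names(c1$strain_fastas))
    expect_identical(readLines(c1$strain_fastas[[s]]),
                     readLines(c2$strain_fastas[[s]]))

  plantings <- sum(spec$families_per_strain) * spec$n_strains
  expect_equal(nrow(c1$manifest),
               plantings + spec$n_strains * spec$decoys_per_strain)
  for (s in names(c1$strain_fastas)) {
    n_contigs <- length(read_fasta(c1$strain_fastas[[s]], "DNA"))
    expect_equal(n_contigs, sum(c1$manifest$strain_id == s))
  }
  # decoy-only community
  spec0 <- community_spec(n_strains = 1L,
                          families_per_strain = c(PETF = 0L),
                          decoys_per_strain = 0L, seed = 1L)
  expect_error(build_community(spec0), NA)
})

test_that("expected survival in the manifest reflects planted features only", {
  spec <- community_spec(n_strains = 3L, decoys_per_strain = 2L,
                         fragment_rate = 0.5, insertion_rate = 0.5,
                         seed = 17L)
  comm <- build_community(spec, tempfile("commC"))
  m <- comm$manifest
  viol <- grepl("fragment|insertion", m$features) | m$features == "decoy"
  expect_identical(m$expected_survival, !viol)
  tm <- truth_matrix(m)
  surv <- m[m$expected_survival & nzchar(m$expected_label), ]
  expect_equal(sum(tm[, setdiff(colnames(tm),
                                c("PETF_TP", "NISOD_UBQ"))]),
               nrow(surv))
})
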