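test_that("six-frame translation finds simple and reverse-strand ORFs", {
  orfs <- six_frame_translate("ATGGCTTAA", min_orf_aa = 2L)
  fwd <- orfs[orfs$frame == 1L, ]
  expect_equal(fwd$peptide, "MA")
  expect_equal(fwd$start_nt, 1L)
  expect_equal(fwd$end_nt, 6L)

  ctg <- "ATGGCTGCATTGGATTAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctg)))
  o1 <- six_frame_translate(ctg, min_orf_aa = 2L)
  o2 <- six_frame_translate(rc, min_orf_aa = 2L)
  expect_true("MAALD" %in% o1$peptide[o1$frame > 0])
  expect_true("MAALD" %in% o2$peptide[o2$frame < 0])
  # strand symmetry: same peptide multiset with flipped strand labels
  expect_setequal(o1$peptide, o2$peptide)
})

test_that("every reported ORF retranslates from its coordinates", {
  set.seed(41)
  ctg <- paste(sample(c("A", "C", "G", "T", "N"), 9000,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
  orfs <- six_frame_translate(ctg, min_orf_aa = 10L)
  expect_gt(nrow(orfs), 0)
  for (i in seq_len(nrow(orfs))) {
    seg <- substr(ctg, orfs$start_nt[i], orfs$end_nt[i])
    if (orfs$frame[i] < 0)
      seg <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seg)))
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(seg), no.init.codon = TRUE,
      if.fuzzy.codon = "X")))
    expect_identical(aa, orfs$peptide[i])
    expect_equal((orfs$end_nt[i] - orfs$start_nt[i] + 1L) %% 3L, 0L)
  }
})

test_that("illegal nucleotides are rejected with their position", {
  expect_error(six_frame_translate("ACGTRACGT"), "position 5")
})

test_that("Viterbi matches the closed-form sum on a consensus path", {
  fam <- family_from_members("Z", c(a = "ACDE"), "a")
  pf <- build_profile(fam)
  s <- score_peptide(pf, "ACDE")
  expected <- sum(vapply(1:4, function(k) max(pf$emissions[k, 1:20]), 1)) +
    sum(pf$transitions$tMM)
  expect_equal(unname(s["viterbi_bits"]), expected, tolerance = 1e-9)
})

test_that("DP scores equal exhaustive path enumeration on tiny profiles", {
  set.seed(51)
  for (rep in 1:6) {
    fam <- random_small_profile(L = 3L)
    pf <- build_profile(fam)
    pep <- random_peptide(6L)
    dp <- score_peptide(pf, pep)
    bf <- enumerate_profile_paths(pf, pep)
    expect_equal(unname(dp["viterbi_bits"]), bf$viterbi, tolerance = 1e-9)
    expect_equal(unname(dp["forward_bits"]), bf$forward, tolerance = 1e-9)
  }
})

test_that("forward dominates Viterbi on random profile/peptide pairs", {
  set.seed(61)
  for (rep in 1:25) {
    pf <- build_profile(random_small_profile(L = sample(5:15, 1)))
    pep <- random_peptide(sample(10:40, 1))
    s <- score_peptide(pf, pep)
    expect_gte(s[["forward_bits"]], s[["viterbi_bits"]])
  }
})

test_that("e-values follow the calibrated Gumbel tail", {
  pf <- calibrate_evd(build_profile(random_small_profile(L = 15L)),
                      null_count = 80L, null_length = 60L, seed = 3L)
  # at the location parameter the exceedance is 1 - exp(-1)
  expect_equal(evalue_of(pf, pf$evd_mu, 1L), 1 - exp(-1), tolerance = 1e-12)
  grid <- seq(pf$evd_mu - 5, pf$evd_mu + 20, length.out = 50)
  ev <- vapply(grid, function(s) evalue_of(pf, s, 1L), 1)
  expect_true(all(diff(ev) <= 1e-15))
  expect_lt(evalue_of(pf, 1e6, 1L), 1e-300)
  # database-size scaling is exactly linear
  expect_equal(evalue_of(pf, 12, 7L), 7 * evalue_of(pf, 12, 1L))
  un <- build_profile(random_small_profile(L = 5L))
  expect_error(evalue_of(un, 10), "not calibrated")
})

test_that("search recovers planted homologs and respects its cutoff", {
  refs <- make_reference_families(seed = 77L)
  pf <- calibrate_evd(build_profile(refs$PETF), seed = 9L)
  hom <- evolve_homolog(refs$PETF$anchor, 0.8,
                        protected = attr(refs$PETF, "protected"), seed = 5L)
  hits <- ferromap::search(list(pf), c(h1 = hom))
  expect_equal(nrow(hits), 1L)
  expect_lt(hits$evalue, 1e-10)

  # cutoff boundary: kept at E <= c, dropped just below the hit's E
  e <- hits$evalue
  expect_equal(nrow(ferromap::search(list(pf), c(h1 = hom),
                                     evalue_cutoff = e)), 1L)
  expect_equal(nrow(ferromap::search(list(pf), c(h1 = hom),
                                     evalue_cutoff = e / 2)), 0L)

  expect_equal(nrow(ferromap::search(list(pf), character())), 0L)
})

test_that("search output is invariant under permutation of input order", {
  set.seed(71)
  refs <- make_reference_families(seed = 77L)
  pf <- calibrate_evd(build_profile(refs$PETF), seed = 9L)
  peps <- vapply(1:6, function(i)
    evolve_homolog(refs$PETF$anchor, 0.75,
                   protected = attr(refs$PETF, "protected"),
                   seed = i), "")
  names(peps) <- sprintf("p%02d", 1:6)
  h1 <- ferromap::search(list(pf), peps, database_size = 6L)
  h2 <- ferromap::search(list(pf), peps[sample(6)], database_size = 6L)
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(h1[order(h1$contig_id), ], h2[order(h2$contig_id), ],
               ignore_attr = TRUE)
})
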