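rules <- default_rulesets()

test_that("the FAD and NADPH motifs match as printed", {
  fad <- rules$FRE$motif_rules[[1]]
  expect_equal(match_motif("AHPFTVG", fad), 2L)
  expect_length(match_motif("HPFGV", fad), 0L)
  nadph <- rules$FRE$motif_rules[[2]]
  expect_equal(match_motif("WCAPW", nadph), 2L)  # A accepted for G
  expect_equal(match_motif("WCVPW", nadph), 2L)  # V accepted for G
  expect_length(match_motif("WCWPW", nadph), 0L)
})

test_that("the iron permease needs two REXXE motifs", {
  ftr <- rules$FTR$motif_rules[[1]]
  two <- "WWREAAEWWWWWREXYEWW"
  two <- gsub("X", "L", two)
  one <- "WWREAAEWWWWW"
  expect_true(length(match_motif(two, ftr)) >= 2)
  expect_false(length(match_motif(one, ftr)) >= ftr$count)
  expect_true(ferromap:::motif_passes(ftr, match_motif(two, ftr)))
  expect_false(ferromap:::motif_passes(ftr, match_motif(one, ftr)))
})

test_that("the Ni-hook is only accepted near the N terminus", {
  hook <- rules$NISOD$motif_rules[[1]]
  pep <- paste0("MA", "HCDLPCGVY", random_peptide(60))
  expect_equal(match_motif(pep, hook), 3L)
  far <- paste0(random_peptide(50), "HCDLPCGVY")
  expect_length(match_motif(far, hook), 0L)
  # the window is anchored at the cleavage site after fusion processing
  expect_equal(match_motif(far, hook, offset = -48L), 51L)
})

test_that("the motif engine agrees with a regex oracle", {
  set.seed(111)
  all_rules <- c(unlist(lapply(rules, `[[`, "motif_rules"),
                        recursive = FALSE),
                 list(transit_peptide_motif()))
  for (r in all_rules) {
    for (i in 1:500) {
      pep <- random_peptide(sample(15:60, 1))
      expect_identical(match_motif(pep, r), motif_regex_oracle(pep, r))
    }
  }
})

test_that("residue reports map anchor sites through the alignment", {
  refs <- make_reference_families(seed = 77L)
  petf <- refs$PETF
  map <- map_to_anchor(petf$anchor, petf)
  rep <- check_residues(petf$anchor, rules$PETF$residue_rules, map)
  expect_true(all(rep$pass))
  expect_equal(rep$anchor_position, c(37L, 42L, 45L, 75L))

  mut <- petf$anchor
  substr(mut, 37, 37) <- "S"
  rep2 <- check_residues(mut, rules$PETF$residue_rules,
                         map_to_anchor(mut, petf))
  expect_false(rep2$pass[rep2$anchor_position == 37])
  expect_true(all(rep2$pass[rep2$anchor_position != 37]))
})

test_that("the ferritin ferroxidase pair passes as an either/or group", {
  refs <- make_reference_families(seed = 77L)
  ftn <- refs$FTN
  mut <- ftn$anchor
  substr(mut, 130, 130) <- "A"   # Glu130 lost, Glu131 intact
  res <- classify(mut, rules$FTN, map_to_anchor(mut, ftn))
  expect_equal(res$label, "FTN")
  both <- mut
  substr(both, 131, 131) <- "A"
  res2 <- classify(both, rules$FTN, map_to_anchor(both, ftn))
  expect_equal(res2$label, "rejected")
})

test_that("SOD metalloforms are called from sites 77 and 146", {
  refs <- make_reference_families(seed = 77L)
  fe <- refs$FESOD$anchor
  map <- map_to_anchor(fe, refs$FESOD)
  expect_equal(classify_sod(fe, map), "FeSOD")
  g146 <- fe; substr(g146, 146, 146) <- "G"
  expect_equal(classify_sod(g146, map_to_anchor(g146, refs$FESOD)), "FeSOD")
  mn <- fe
  substr(mn, 77, 77) <- "G"; substr(mn, 146, 146) <- "Q"
  expect_equal(classify_sod(mn, map_to_anchor(mn, refs$FESOD)), "MnSOD")
  amb <- fe; substr(amb, 146, 146) <- "Q"
  expect_equal(classify_sod(amb, map_to_anchor(amb, refs$FESOD)),
               "ambiguous")
})

test_that("flavodoxin clades are assigned by nearest anchor", {
  refs <- make_reference_families(seed = 77L)
  an <- attr(refs$FLDA, "clade_anchors")
  expect_equal(classify_flda(an$cladeI, an), "FLDA-I")
  mut <- an$cladeII
  for (p in c(3, 20, 40, 60, 80))
    substr(mut, p, p) <- "W"
  expect_equal(classify_flda(mut, an), "FLDA-II")
  expect_warning(out <- classify_flda(an$cladeI,
                                      list(cladeI = an$cladeI,
                                           cladeII = an$cladeI)),
                 "tied")
  expect_equal(out, "FLDA-I")
})

test_that("classification rejects an MCO lacking one Cu region", {
  refs <- make_reference_families(seed = 77L)
  mco <- refs$MCO
  ok <- classify(mco$anchor, rules$MCO, map_to_anchor(mco$anchor, mco))
  expect_equal(ok$label, "MCO")
  mut <- mco$anchor
  substr(mut, 416, 416) <- "A"   # break region III
  bad <- classify(mut, rules$MCO, map_to_anchor(mut, mco))
  expect_equal(bad$label, "rejected")
  expect_match(bad$rejected_reason, "416")
})

test_that("CuZn-SOD conservation grades full vs partial without rejecting", {
  refs <- make_reference_families(seed = 77L)
  cz <- refs$CUZNSOD
  full <- classify(cz$anchor, rules$CUZNSOD, map_to_anchor(cz$anchor, cz))
  expect_equal(full$label, "CUZNSOD")
  expect_equal(full$conservation, "full")
  part <- cz$anchor
  for (p in c(46, 48, 63, 80, 120)) substr(part, p, p) <- "A"
  res <- classify(part, rules$CUZNSOD, map_to_anchor(part, cz))
  expect_equal(res$label, "CUZNSOD")
  expect_equal(res$conservation, "partial")
})

test_that("report-only rules never change the label", {
  refs <- make_reference_families(seed = 77L)
  pc <- refs$PCYN
  for (res in AA) {
    mut <- pc$anchor
    substr(mut, 87, 87) <- res
    substr(mut, 92, 92) <- res
    out <- classify(mut, rules$PCYN, map_to_anchor(mut, pc))
    expect_equal(out$label, "PCYN")
  }
  gate <- pc$anchor
  substr(gate, 37, 37) <- "Q"    # required Cu ligand lost
  out <- classify(gate, rules$PCYN, map_to_anchor(gate, pc))
  expect_equal(out$label, "rejected")
})

test_that("protected sites keep planted homologs classifiable at low identity", {
  refs <- make_reference_families(seed = 77L)
  for (fid in c("PETF", "FTN", "FRE", "NISOD")) {
    fam <- refs[[fid]]
    for (ident in c(0.45, 0.6, 0.75, 0.9)) {
      hom <- evolve_homolog(fam$anchor, ident,
                            protected = attr(fam, "protected"),
                            seed = round(1000 * ident))
      res <- classify(hom, rules[[fid]], map_to_anchor(hom, fam))
      expect_false(res$label == "rejected",
                   label = sprintf("%s at %.2f rejected", fid, ident))
    }
  }
})
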