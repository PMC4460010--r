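test_that("load_family keeps identical peptides gap-free over the full trim", {
  seqs <- c(r1 = "MKLVDEAT", r2 = "MKLVDEAT", r3 = "MKLVDEAT")
  fp <- write_temp_fasta(seqs)
  fam <- load_family(fp, "r1")
  expect_equal(length(fam$members), 3L)
  expect_equal(fam$mature_length, 8L)
  expect_false(any(grepl("-", fam$mature_alignment)))
  expect_equal(unname(fam$mature_alignment[["r2"]]), "MKLVDEAT")
})

test_that("trim_range restricts the alignment to anchor coordinates", {
  seqs <- c(anc = "ABCDEFGH", oth = "ABCDEFGH")
  seqs <- gsub("B", "W", seqs)  # keep to the amino-acid alphabet
  fp <- write_temp_fasta(seqs)
  fam <- load_family(fp, "anc", trim_range = c(2L, 4L))
  expect_equal(fam$mature_length, 3L)
  expect_equal(unname(fam$mature_alignment[["anc"]]), "WCD")
})

test_that("load_family fails fatally on missing anchor and illegal residues", {
  fp <- write_temp_fasta(c(a = "MKLV", b = "MKLV"))
  expect_error(load_family(fp, "zz"), "zz")
  fp2 <- write_temp_fasta(c(a = "MK1V"))
  expect_error(load_family(fp2, "a"), "a")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(load_family(empty, "a"), "empty|not found")
})

test_that("match emissions follow the pseudocount smoothing formula", {
  fam <- family_from_members("T", c(a = "AC"), "a")
  bg <- stats::setNames(rep(0.05, 20), AA)
  pf <- build_profile(fam, pseudocount_weight = 1, background = bg)
  # state 1, residue A: log2(((1 + 1*0.05)/(1 + 1))/0.05) = log2(10.5)
  expect_equal(unname(pf$emissions[1, "A"]), log2(10.5), tolerance = 1e-12)
  expect_equal(unname(pf$emissions[2, "C"]), log2(10.5), tolerance = 1e-12)
})

test_that("a column matching the background scores zero bits everywhere", {
  # 20 members, each contributing one distinct residue per column
  mem <- stats::setNames(vapply(AA, function(a) paste(rep(a, 3),
                                                      collapse = ""), ""),
                         paste0("m", 1:20))
  fam <- family_from_members("U", mem, "m1")
  bg <- stats::setNames(rep(0.05, 20), AA)
  pf <- build_profile(fam, background = bg)
  # counts 1 each, n_eff 20, w 1: p = (1 + 0.05)/21 = 0.05 exactly
  expect_true(all(abs(pf$emissions[, 1:20]) < 1e-12))
  # X scores the background expectation of the column: also 0 here
  expect_true(all(abs(pf$emissions[, "X"]) < 1e-12))
})

test_that("X emission is the background expectation at every state", {
  fam <- random_small_profile(L = 12L)
  pf <- build_profile(fam)
  expected <- as.numeric(pf$emissions[, 1:20] %*% pf$background)
  expect_equal(unname(pf$emissions[, "X"]), expected, tolerance = 1e-12)
})

test_that("gapped members induce nonzero delete transitions; rows normalize", {
  mem <- c(a = "ACDEFGHIKL", b = "ACDEFGIKL")  # b lacks one residue
  fam <- family_from_members("G", mem, "a")
  pf <- build_profile(fam)
  for (p in pf$transition_probs) {
    expect_equal(sum(p$M), 1, tolerance = 1e-9)
    expect_equal(sum(p$I), 1, tolerance = 1e-9)
    expect_equal(sum(p$D), 1, tolerance = 1e-9)
  }
  # some boundary must carry more delete probability than the prior alone
  tMD <- vapply(pf$transition_probs, function(p) p$M[3], 1)
  expect_true(max(tMD) > 0.05 / 1.0 * 0.9)
})

test_that("Gumbel ML fit recovers known parameters", {
  set.seed(11)
  mu <- 5; lambda <- 0.7
  x <- mu - (1 / lambda) * log(-log(runif(2000)))
  fit <- gumbel_fit_ml(x)
  expect_lt(abs(fit$mu - mu), 0.15)
  expect_lt(abs(fit$lambda - lambda), 0.05)
})

test_that("calibration is deterministic given the seed and guards its inputs", {
  fam <- random_small_profile(L = 20L)
  pf <- build_profile(fam)
  a <- calibrate_evd(pf, null_count = 60L, null_length = 80L, seed = 5L)
  b <- calibrate_evd(pf, null_count = 60L, null_length = 80L, seed = 5L)
  expect_identical(a$evd_mu, b$evd_mu)
  expect_identical(a$evd_lambda, b$evd_lambda)
  c <- calibrate_evd(pf, null_count = 60L, null_length = 80L, seed = 6L)
  expect_false(identical(a$evd_mu, c$evd_mu))
  expect_error(calibrate_evd(pf, null_count = 10L), ">= 50")
})

test_that("map_to_anchor handles identity, deletions and insertions", {
  set.seed(21)
  anchor <- random_peptide(40)
  m1 <- map_to_anchor(anchor, anchor)
  expect_equal(m1$pairs$anchor_position, 1:40)
  expect_equal(m1$pairs$query_position, 1:40)

  del <- substr(anchor, 11, 40)
  m2 <- map_to_anchor(del, anchor)
  expect_equal(m2$pairs$anchor_position[1], 11L)
  expect_equal(m2$pairs$query_position[1], 1L)

  ins <- paste0(substr(anchor, 1, 3), "WWWWWWW", substr(anchor, 4, 40))
  m3 <- map_to_anchor(ins, anchor)
  p <- m3$pairs
  expect_equal(p$query_position[match(4L, p$anchor_position)], 11L)
  expect_equal(p$query_position[match(1L, p$anchor_position)], 1L)
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_peptide(sample(20:60, 1))
    b <- random_peptide(sample(20:60, 1))
    expect_equal(map_to_anchor(a, b)$score, map_to_anchor(b, a)$score)
  }
})
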