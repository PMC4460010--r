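fake_hits <- function(peptides, family = "FAM", strain = "S01",
                      contigs = NULL) {
  n <- length(peptides)
  data.frame(contig_id = if (is.null(contigs)) sprintf("c%03d", seq_len(n))
             else contigs,
             strain_id = strain, frame = 1L, start_nt = 1L,
             end_nt = 3L * nchar(peptides), peptide = peptides,
             family_id = family, viterbi_bits = 10, forward_bits = 11,
             evalue = 1e-10, span_fraction = NA_real_,
             hit_id = sprintf("h%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("span filter keeps 25% and 500% and removes just beyond", {
  ml <- c(FAM = 400L)
  peps <- vapply(c(100L, 99L, 2000L, 2004L, 400L), random_peptide, "")
  h <- fake_hits(peps)
  out <- span_filter(h, ml)
  kept_len <- nchar(out$kept$peptide)
  expect_setequal(kept_len, c(100L, 2000L, 400L))
  expect_setequal(nchar(out$removed$peptide), c(99L, 2004L))
})

test_that("insertion filter tolerates 50 aa and removes over 50", {
  set.seed(81)
  anchor <- random_peptide(200)
  fam <- family_from_members("FAM", c(a = anchor), "a")
  mk <- function(k) paste0(substr(anchor, 1, 100),
                           random_peptide(k),
                           substr(anchor, 101, 200))
  two <- paste0(substr(anchor, 1, 70), random_peptide(30),
                substr(anchor, 71, 140), random_peptide(30),
                substr(anchor, 141, 200))
  h <- fake_hits(c(mk(50L), mk(51L), anchor, two))
  out <- insertion_filter(h, list(FAM = fam))
  expect_equal(nrow(out$kept), 3L)
  expect_equal(nchar(out$removed$peptide), 200L + 51L)
  # separate 30-residue insertions are not summed
  expect_true(two %in% out$kept$peptide)
})

test_that("within-strain 100%-identity duplicates collapse; scope is the strain", {
  p <- random_peptide(60)
  q <- sub("^.", if (substr(p, 1, 1) == "A") "C" else "A", p)
  h <- rbind(fake_hits(c(p, p), strain = "S01",
                       contigs = c("long_contig_name", "c2")),
             fake_hits(p, strain = "S02"),
             fake_hits(q, strain = "S01"))
  out <- dedup_identical(h)
  expect_equal(nrow(out$kept), 3L)
  expect_equal(nrow(out$removed), 1L)
  # the longest contig id is the survivor of the duplicate pair
  s1 <- out$kept[out$kept$strain_id == "S01" & out$kept$peptide == p, ]
  expect_equal(s1$contig_id, "long_contig_name")
})

test_that("filters are idempotent and the report counts are conserved", {
  set.seed(91)
  anchor <- random_peptide(400)
  fam <- family_from_members("FAM", c(a = anchor), "a")
  peps <- c(substr(anchor, 1, 90),                       # short
            paste0(substr(anchor, 1, 200), random_peptide(70),
                   substr(anchor, 201, 400)),            # long insertion
            anchor, anchor,                              # duplicates
            evolve_homolog(anchor, 0.8, seed = 2))
  h <- fake_hits(peps)
  rep1 <- apply_screen_filters(h, list(FAM = fam))
  expect_equal(sum(rep1$counts[c("removed_short", "removed_long",
                                 "removed_insertion", "removed_duplicate",
                                 "survivors")]),
               unname(rep1$counts["input_count"]))
  rep2 <- apply_screen_filters(rep1$survivors, list(FAM = fam))
  expect_equal(nrow(rep2$survivors), nrow(rep1$survivors))
  expect_true(all(rep2$counts[c("removed_short", "removed_long",
                                "removed_insertion",
                                "removed_duplicate")] == 0))
})

test_that("span and dedup commute; insertion order does not matter", {
  set.seed(101)
  anchor <- random_peptide(300)
  fam <- family_from_members("FAM", c(a = anchor), "a")
  ml <- c(FAM = 300L)
  peps <- c(anchor, anchor, substr(anchor, 1, 60),
            evolve_homolog(anchor, 0.7, seed = 3))
  h <- fake_hits(peps)
  a <- dedup_identical(span_filter(h, ml)$kept)$kept
  b <- span_filter(dedup_identical(h)$kept, ml)$kept
  expect_setequal(a$peptide, b$peptide)
  c1 <- insertion_filter(dedup_identical(h)$kept, list(FAM = fam))$kept
  c2 <- dedup_identical(insertion_filter(h, list(FAM = fam))$kept)$kept
  expect_setequal(c1$peptide, c2$peptide)
})
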