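test_that("pairwise identity is the fraction of matching aligned columns", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  set.seed(121)
  for (i in 1:5) {
    a <- random_peptide(30); b <- random_peptide(25)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

mutate_at <- function(seq, k, seed = 1) {
  ferromap:::with_seed(seed, {
    ch <- strsplit(seq, "")[[1]]
    pos <- sample(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(AA, ch[p]), 1)
    paste(ch, collapse = "")
  })
}

test_that("dereplication merges strictly above 95% and chains by single linkage", {
  set.seed(131)
  base <- random_peptide(100)
  at96 <- mutate_at(base, 4, seed = 2)     # 96% identity
  at95 <- mutate_at(base, 5, seed = 3)     # exactly 95%
  d1 <- dereplicate(c(a = base, b = at96))
  expect_length(d1$clusters, 1L)
  d2 <- dereplicate(c(a = base, b = at95))
  expect_length(d2$clusters, 2L)

  # chain a~b 96%, b~c 96%, a~c ~92%: one cluster of three
  b <- at96
  c_ <- mutate_at(b, 4, seed = 4)
  stopifnot(pairwise_identity(base, c_) <= 95)
  d3 <- dereplicate(c(a = base, b = b, c = c_))
  expect_length(d3$clusters, 1L)
  expect_setequal(d3$clusters[[1]], c("a", "b", "c"))

  # all pairs at or below the threshold: never merged
  x <- c(a = base, b = at95, c = mutate_at(base, 6, seed = 5))
  im <- identity_matrix_of(x)
  stopifnot(all(im[upper.tri(im)] <= 95))
  expect_length(dereplicate(x, identity_matrix = im)$clusters, 3L)
})

test_that("dereplication is deterministic under permutation and picks the longest representative", {
  set.seed(141)
  base <- random_peptide(120)
  longer <- paste0(base, "AA")             # > 95% identical, longer
  x <- c(zz = base, aa = longer)
  d <- dereplicate(x)
  expect_equal(d$representatives, "aa")
  d2 <- dereplicate(rev(x))
  expect_equal(d2$representatives, "aa")
})

test_that("neighbor joining recovers additive trees and validates input", {
  set.seed(151)
  for (i in 1:20) {
    tr <- ape::rtree(sample(5:10, 1))
    tr$edge.length <- tr$edge.length + 0.05
    d <- tree_distances(tr)
    rec <- nj_tree(d)
    expect_setequal(split_set(rec), split_set(tr))
  }
  tr3 <- nj_tree(tree_distances(ape::rtree(3)))
  expect_equal(ape::Ntip(tr3), 3L)
  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  expect_error(nj_tree(bad), "symmetric")
})

test_that("midpoint rooting balances the longest tip-to-tip path", {
  two <- ape::read.tree(text = "(a:1,b:3);")
  r <- midpoint_root(two)
  expect_equal(unname(tree_distances(r)["a", "b"]), 4)
  depths <- ape::node.depth.edgelength(r)[1:2]
  expect_equal(depths, c(2, 2))

  set.seed(161)
  tr <- ape::rtree(20)
  r2 <- midpoint_root(tr)
  d <- tree_distances(tr)
  maxdepth <- max(ape::node.depth.edgelength(r2)[1:20])
  expect_equal(maxdepth, max(d) / 2, tolerance = 1e-9)
})

test_that("copy counting collapses maximal same-species clades", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,(A3:1,B2:1):1):1);")
  species <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B")
  strains <- stats::setNames(species, names(species))
  a <- count_copies(tr, "A", species, strains)
  expect_equal(a$copy_number, 2L)          # {A1,A2} collapses; A3 alone
  b <- count_copies(tr, "B", species, strains)
  expect_equal(b$copy_number, 2L)

  one <- ape::read.tree(text = "((x1:1,x2:1):1,(x3:1,x4:1):1);")
  sp1 <- stats::setNames(rep("X", 4), one$tip.label)
  expect_equal(count_copies(one, "X", sp1, sp1)$copy_number, 1L)

  expect_error(count_copies(tr, "A", species[-1], strains), "unlabeled")
})

test_that("copy counts match the brute-force clade oracle on random trees", {
  set.seed(171)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    tr <- ape::rtree(n)
    nsp <- sample(2:5, 1)
    species <- stats::setNames(sample(LETTERS[1:nsp], n, replace = TRUE),
                               tr$tip.label)
    strains <- species
    groups <- clade_groups(tr, species)
    oracle <- clade_partition_oracle(tr, species)
    canon <- function(g) {
      g <- lapply(g, sort)
      g[order(vapply(g, `[`, "", 1L))]
    }
    expect_identical(canon(groups), canon(oracle))
    for (s in unique(species)) {
      got <- count_copies(tr, s, species, strains)$copy_number
      expect_equal(got, oracle_copy_count(tr, species, strains, s))
    }
  }
})

test_that("copy number is invariant under child rotation", {
  set.seed(181)
  tr <- ape::rtree(12)
  species <- stats::setNames(sample(c("A", "B"), 12, replace = TRUE),
                             tr$tip.label)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  for (s in c("A", "B"))
    expect_equal(count_copies(tr, s, species, species)$copy_number,
                 count_copies(rot, s, species, species)$copy_number)
})

test_that("the presence matrix is zero-filled with stable column order", {
  rec <- data.frame(strain_id = c("S1", "S1"),
                    column = c("PETF", "NISOD"),
                    copy_number = c(2L, 1L))
  m <- presence_matrix(rec, strains = c("S1", "S2"))
  expect_equal(colnames(m), canonical_columns())
  expect_equal(unname(m["S1", "PETF"]), 2L)
  expect_true(all(m["S2", ] == 0L))
})
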