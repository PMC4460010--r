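# Independent oracles used across the suite. Each reimplements the checked
# behaviour by a different route (regex, exhaustive enumeration, brute
# force) and never calls the code path under test.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- regex oracle for the motif engine ------------------------------------
# Non-overlapping leftmost matches via gregexpr (which is exactly that),
# with the n_terminal window applied afterwards.
motif_regex_oracle <- function(peptide, rule) {
  rx <- paste(vapply(rule$sets, function(s) {
    if (identical(s, "*")) "." else sprintf("[%s]", paste(s, collapse = ""))
  }, ""), collapse = "")
  m <- gregexpr(rx, peptide)[[1]]
  starts <- as.integer(m[m > 0])
  if (rule$region == "n_terminal" && !is.na(rule$window))
    starts <- starts[starts <= rule$window]
  starts
}

# --- brute-force maximal monospecific clade partition ----------------------
# Enumerates every clade's tip set, keeps monospecific ones, takes the
# inclusion-maximal sets, and completes the partition with singletons.
clade_partition_oracle <- function(tree, species) {
  tips <- tree$tip.label
  n <- length(tips)
  nodesets <- list()
  for (v in (n + 1):(n + tree$Nnode)) {
    tv <- tips[tip_descendants(tree, v)]
    if (length(unique(species[tv])) == 1L)
      nodesets[[length(nodesets) + 1L]] <- sort(tv)
  }
  # inclusion-maximal monospecific clades
  keep <- rep(TRUE, length(nodesets))
  for (i in seq_along(nodesets)) for (j in seq_along(nodesets)) {
    if (i != j && keep[i] && all(nodesets[[i]] %in% nodesets[[j]]) &&
        length(nodesets[[j]]) > length(nodesets[[i]])) keep[i] <- FALSE
  }
  groups <- nodesets[keep]
  covered <- unlist(groups)
  groups <- c(groups, as.list(sort(setdiff(tips, covered))))
  # canonical form for comparison
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, "", 1L))]
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer()
  stack <- node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  sort(out)
}

oracle_copy_count <- function(tree, species, strains_by_tip, strain) {
  groups <- clade_partition_oracle(tree, species)
  sum(vapply(groups, function(g)
    any(strains_by_tip[g] == strain), TRUE))
}

# --- exhaustive local-path enumeration for the profile DP ------------------
# Enumerates every local path through the match/insert/delete states for a
# tiny profile and query; returns max path score and log2-sum of 2^score.
enumerate_profile_paths <- function(profile, peptide) {
  qc <- strsplit(peptide, "")[[1]]
  qi <- match(qc, c(AA, "X"))
  n <- length(qi); L <- profile$L
  em <- profile$emissions
  tr <- profile$transitions
  scores <- numeric(0)
  # state: list(i = query pos consumed so far, k = state index, kind)
  # paths start at any (i, k) in M and may end at any M
  recurse <- function(i, k, kind, acc) {
    if (kind == "M") scores[[length(scores) + 1L]] <<- acc
    if (k < L) {
      # M/I/D -> next
      if (kind == "M") {
        if (i < n) {
          recurse(i + 1L, k + 1L, "M",
                  acc + tr$tMM[k] + em[k + 1L, qi[i + 1L]])
          if (k < L)
            recurse(i + 1L, k, "I", acc + tr$tMI[k])
        }
        recurse(i, k + 1L, "D", acc + tr$tMD[k])
      } else if (kind == "I") {
        if (i < n) {
          recurse(i + 1L, k, "I", acc + tr$tII[k])
          recurse(i + 1L, k + 1L, "M",
                  acc + tr$tIM[k] + em[k + 1L, qi[i + 1L]])
        }
      } else { # D
        recurse(i, k + 1L, "D", acc + tr$tDD[k])
        if (i < n)
          recurse(i + 1L, k + 1L, "M",
                  acc + tr$tDM[k] + em[k + 1L, qi[i + 1L]])
      }
    }
  }
  for (i in seq_len(n)) for (k in seq_len(L)) {
    recurse(i, k, "M", em[k, qi[i]])
  }
  list(viterbi = max(scores), forward = log2(sum(2^scores)))
}

# --- misc ------------------------------------------------------------------
# A random profile over a small random family.
random_small_profile <- function(L = 8L, members = 3L, id = "RND") {
  base <- random_peptide(L)
  mem <- c(base, replicate(members - 1L, {
    ch <- strsplit(base, "")[[1]]
    flip <- sample(L, max(1L, L %/% 4L))
    ch[flip] <- sample(AA, length(flip), replace = TRUE)
    paste(ch, collapse = "")
  }))
  names(mem) <- paste0("m", seq_along(mem))
  family_from_members(id, mem, "m1")
}

write_temp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile("fam", tmpdir = dir, fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}

# Distances implied by a tree (additive metric).
tree_distances <- function(tree) ape::cophenetic.phylo(tree)

split_set <- function(tree) {
  # unrooted splits as sorted tip-name strings (smaller side)
  tips <- sort(tree$tip.label)
  sp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(sp, "labels")
  out <- character()
  for (s in sp) {
    side <- sort(labs[s])
    other <- setdiff(tips, side)
    if (length(side) <= 1 || length(other) <= 1) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = ",") < paste(other, collapse = ",")))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  sort(unique(out))
}
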