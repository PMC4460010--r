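#' Single-linkage dereplication at an identity threshold
#'
#' Sequences are clustered by single linkage on pairwise global-alignment
#' identity strictly greater than `threshold_pct` (a pair at exactly the
#' threshold stays separate). One representative per cluster is kept: the
#' longest member, ties broken lexicographically by id. Deterministic
#' under input permutation.
#'
#' @param seqs Named character vector of peptides.
#' @param threshold_pct Identity threshold in percent (default 95).
#' @param identity_matrix Optional precomputed identity matrix (dimnames =
#'   ids) to avoid realigning.
#' @return List: `clusters` (list of id vectors), `representatives`
#'   (named character: representative id per cluster), `membership`
#'   (named integer: cluster index per id).
#' @export
dereplicate <- function(seqs, threshold_pct = 95, identity_matrix = NULL) {
  ids <- sort(names(seqs))
  seqs <- seqs[ids]
  n <- length(ids)
  if (is.null(identity_matrix)) {
    identity_matrix <- identity_matrix_of(seqs)
  } else {
    identity_matrix <- identity_matrix[ids, ids, drop = FALSE]
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (identity_matrix[i, j] > threshold_pct) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  idx <- match(roots, sort(unique(roots)))
  clusters <- split(ids, idx)
  reps <- vapply(clusters, function(m) {
    m[order(-nchar(seqs[m]), m)][1L]
  }, "")
  membership <- stats::setNames(idx, ids)
  list(clusters = unname(clusters), representatives = unname(reps),
       membership = membership)
}

#' Pairwise identity matrix
#'
#' @param seqs Named character vector of peptides.
#' @return Symmetric percent-identity matrix with 100 on the diagonal.
#' @export
identity_matrix_of <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param dist Symmetric numeric matrix with zero diagonal and dimnames.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(dist)) > 1e-12))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  ape::nj(stats::as.dist(dist))
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#'
#' @param tree A `phylo` tree with non-negative branch lengths.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  phangorn::midpoint(tree)
}

#' Alignment-identity distances for tree building
#'
#' Per-pair global-alignment identity transformed as
#' `d = -ln(max(identity/100, 0.01))` (Poisson-style correction with a
#' floor so that unrelated pairs stay finite).
#'
#' @param seqs Named character vector of peptides.
#' @param identity_matrix Optional precomputed identity matrix.
#' @return Symmetric distance matrix.
#' @export
identity_distances <- function(seqs, identity_matrix = NULL) {
  if (is.null(identity_matrix)) identity_matrix <- identity_matrix_of(seqs)
  d <- -log(pmax(identity_matrix / 100, 0.01))
  diag(d) <- 0
  d
}

#' Partition tree tips into maximal same-species clades
#'
#' Every maximal clade whose tips all share one species key is collapsed
#' into a single group; tips under mixed parents form singleton groups.
#' This is the deterministic reading of counting "independently clustering
#' paralogs": sequences of one species clustering immediately adjacent are
#' treated as the same gene.
#'
#' @param tree Rooted `phylo` tree.
#' @param species Named character vector: species key per tip label.
#' @return List of character vectors (tip labels), a partition of the tips.
#' @export
clade_groups <- function(tree, species) {
  tips <- tree$tip.label
  if (anyNA(species[tips]))
    stop("unlabeled tip(s): ",
         paste(tips[is.na(species[tips])], collapse = ", "), call. = FALSE)
  n <- length(tips)
  if (n == 1L) return(list(tips))
  nnode <- tree$Nnode
  # species key of each node if its clade is monospecific, else NA
  key <- rep(NA_character_, n + nnode)
  key[seq_len(n)] <- species[tips]
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  # postorder edge traversal: a child's subtree is complete before the
  # edge to its parent is visited, so parent keys can fold incrementally
  po <- ape::reorder.phylo(tree, "postorder")$edge
  seen <- rep(FALSE, n + nnode)
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    kc <- key[ch]
    if (!seen[p]) { key[p] <- kc; seen[p] <- TRUE }
    else if (is.na(key[p]) || is.na(kc) || key[p] != kc)
      key[p] <- NA_character_
  }
  # maximal monospecific nodes: monospecific, parent not monospecific
  parent <- integer(n + nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  is_max <- function(v) !is.na(key[v]) && (v == root || is.na(key[parent[v]]))
  groups <- list()
  assigned <- rep(FALSE, n)
  for (v in seq_len(n + nnode)) {
    if (!is_max(v)) next
    tv <- clade_tips(tree, v, children)
    if (any(assigned[tv])) next
    groups[[length(groups) + 1L]] <- tips[tv]
    assigned[tv] <- TRUE
  }
  if (!all(assigned)) groups <- c(groups, as.list(tips[!assigned]))
  groups
}

clade_tips <- function(tree, node, children = NULL) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  if (is.null(children)) children <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, children[[as.character(v)]])
  }
  out
}

#' Per-strain paralog copy number from a labeled tree
#'
#' Collapses maximal same-species clades ([clade_groups()]) and counts,
#' for the given strain, the number of collapsed groups containing at
#' least one of the strain's sequences. When tips are dereplication
#' representatives, `members` maps each tip to all sequence ids it stands
#' for, so strains folded into a representative still count.
#'
#' @param tree Rooted `phylo` tree with labeled tips.
#' @param strain Strain id to count.
#' @param species Named character vector: species key per tip.
#' @param strains Named character vector: strain id per sequence id.
#' @param members Optional named list: tip label -> member sequence ids
#'   (defaults to the tip itself).
#' @return A `CopyCountRecord` list: `strain_id`, `copy_number`,
#'   `representative_ids`.
#' @export
count_copies <- function(tree, strain, species, strains, members = NULL) {
  groups <- clade_groups(tree, species)
  if (is.null(members))
    members <- stats::setNames(as.list(tree$tip.label), tree$tip.label)
  reps <- character()
  k <- 0L
  for (g in groups) {
    seq_ids <- unlist(members[g], use.names = FALSE)
    if (any(strains[seq_ids] == strain)) {
      k <- k + 1L
      reps <- c(reps, g[[1L]])
    }
  }
  structure(list(strain_id = strain, copy_number = k,
                 representative_ids = reps),
            class = "CopyCountRecord")
}

#' Presence/copy-number matrix over strains and families
#'
#' @param records data.frame with columns `strain_id`, `column`
#'   (family or subtype label), `copy_number`.
#' @param strains Character vector fixing row order.
#' @param columns Character vector fixing column order; defaults to the
#'   canonical family/subtype panel.
#' @return Integer matrix, strains x columns, 0 = not detected.
#' @export
presence_matrix <- function(records, strains = NULL, columns = NULL) {
  if (is.null(columns)) columns <- canonical_columns()
  if (is.null(strains)) strains <- sort(unique(records$strain_id))
  m <- matrix(0L, length(strains), length(columns),
              dimnames = list(strains, columns))
  for (i in seq_len(nrow(records))) {
    s <- records$strain_id[i]; f <- records$column[i]
    if (s %in% strains && f %in% columns)
      m[s, f] <- m[s, f] + as.integer(records$copy_number[i])
  }
  m
}

#' Canonical presence-matrix column order
#' @return Character vector of family/subtype columns including the
#'   transit-peptide and ubiquitin-fusion flag columns.
#' @export
canonical_columns <- function() {
  c("FRE", "MCO", "FTR", "FTN", "FLDA-I", "FLDA-II", "PETF", "PETF_TP",
    "PCYN", "CYTC6", "FESOD", "MNSOD", "CUZNSOD", "NISOD", "NISOD_UBQ")
}
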