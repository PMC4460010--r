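#' Build a position-specific scoring model from a reference family
#'
#' One match state per anchor-ungapped alignment column. Match emissions
#' are Dirichlet-style smoothed log-odds in bits:
#' `log2(((count + w * bg) / (n_eff + w)) / bg)` where `w` is
#' `pseudocount_weight`, `bg` the background frequency and `n_eff` the
#' number of residues observed in the column. Transition probabilities
#' between match/insert/delete states are estimated from the alignment's
#' gap and insertion structure with Laplace-style pseudocounts, normalized
#' to sum to one per state before the log transform. The unknown residue X
#' scores the background-weighted expectation of the column's scores.
#'
#' @param family A [reference_family()] object.
#' @param pseudocount_weight Positive smoothing weight (default 1).
#' @param background Named 20-vector of residue frequencies.
#' @return A `ProfileModel` (uncalibrated; see [calibrate_evd()]).
#' @export
build_profile <- function(family, pseudocount_weight = 1,
                          background = background_frequencies()) {
  stopifnot(inherits(family, "ReferenceFamily"), pseudocount_weight > 0)
  bg <- background / sum(background)
  rows <- do.call(rbind, strsplit(family$mature_alignment, ""))
  anchor_row <- rows[match(family$anchor_id, names(family$mature_alignment)), ]
  keep <- anchor_row != "-"
  rows <- rows[, keep, drop = FALSE]
  L <- ncol(rows)
  if (L < 1L) stop("profile must have at least one match state")

  emissions <- matrix(0, nrow = L, ncol = 21L,
                      dimnames = list(NULL, c(AA20, "X")))
  for (k in seq_len(L)) {
    col <- rows[, k]
    col <- col[col %in% AA20]
    if (length(col) == 0L && all(rows[, k] == "-"))
      stop("all-gap column at match state ", k)
    cnt <- table(factor(col, levels = AA20))
    n_eff <- sum(cnt)
    p <- (as.numeric(cnt) + pseudocount_weight * bg) /
      (n_eff + pseudocount_weight)
    emissions[k, seq_len(20L)] <- log2(p / bg)
    emissions[k, 21L] <- sum(bg * emissions[k, seq_len(20L)])
  }

  trans <- estimate_transitions(rows, family$insert_counts)

  structure(
    list(family_id = family$family_id, L = L, emissions = emissions,
         transitions = trans$log2, transition_probs = trans$probs,
         background = bg, evd_mu = NA_real_, evd_lambda = NA_real_,
         calibration_n = NA_integer_, seed = NA_integer_,
         mature_length = family$mature_length),
    class = "ProfileModel")
}

#' @export
print.ProfileModel <- function(x, ...) {
  cat(sprintf("ProfileModel %s: %d match states, %s\n", x$family_id, x$L,
              if (is.na(x$evd_mu)) "uncalibrated"
              else sprintf("Gumbel(mu=%.3f, lambda=%.3f, n=%d)",
                           x$evd_mu, x$evd_lambda, x$calibration_n)))
  invisible(x)
}

# Transition estimation: per inter-state boundary, count observed
# match->match / match->delete / delete->delete / delete->match moves from
# the gap structure, and match->insert moves from recorded insertion
# lengths; smooth with weak priors and normalize per source state.
estimate_transitions <- function(rows, insert_counts) {
  L <- ncol(rows)
  nb <- max(L - 1L, 1L)
  prior <- list(M = c(M = 0.9, I = 0.05, D = 0.05),
                I = c(M = 0.7, I = 0.3),
                D = c(M = 0.5, D = 0.5))
  strength <- 1
  tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- numeric(nb)
  pr <- vector("list", nb)
  for (k in seq_len(nb)) {
    from_m <- rows[, k] != "-"
    to_m <- rows[, k + 1L] != "-"
    ins_here <- if (!is.null(insert_counts))
      insert_counts[, k + 1L] else rep(0L, nrow(rows))
    mm <- sum(from_m & to_m & ins_here == 0L)
    mi <- sum(from_m & ins_here > 0L)
    md <- sum(from_m & !to_m & ins_here == 0L)
    dm <- sum(!from_m & to_m)
    dd <- sum(!from_m & !to_m)
    ii <- sum(pmax(ins_here - 1L, 0L))
    im <- mi
    pM <- c(mm, mi, md) + strength * prior$M
    pM <- pM / sum(pM)
    pI <- c(im, ii) + strength * prior$I
    pI <- pI / sum(pI)
    pD <- c(dm, dd) + strength * prior$D
    pD <- pD / sum(pD)
    tMM[k] <- log2(pM[1]); tMI[k] <- log2(pM[2]); tMD[k] <- log2(pM[3])
    tIM[k] <- log2(pI[1]); tII[k] <- log2(pI[2])
    tDM[k] <- log2(pD[1]); tDD[k] <- log2(pD[2])
    pr[[k]] <- list(M = pM, I = pI, D = pD)
  }
  list(log2 = list(tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM, tII = tII,
                   tDM = tDM, tDD = tDD),
       probs = pr)
}

peptide_to_index <- function(peptide) {
  idx <- match(strsplit(peptide, "")[[1]], c(AA20, "X")) - 1L
  if (anyNA(idx)) stop("peptide contains residues outside the alphabet")
  idx
}

#' Score a peptide against a profile
#'
#' Local dynamic programming (free entry into and exit from any match
#' state) over the profile's match/insert/delete states. Returns the best
#' single path (Viterbi) and the log-sum over all local paths (forward),
#' both in bits; forward >= Viterbi always.
#'
#' @param profile A `ProfileModel`.
#' @param peptide Peptide string.
#' @return Named numeric: `viterbi_bits`, `forward_bits`.
#' @export
score_peptide <- function(profile, peptide) {
  stopifnot(inherits(profile, "ProfileModel"), nzchar(peptide))
  s <- profile_score_cpp(profile$emissions, profile$transitions,
                         peptide_to_index(peptide), TRUE)
  c(viterbi_bits = s[1], forward_bits = s[2])
}

score_peptides <- function(profile, peptides, forward = TRUE) {
  qs <- lapply(peptides, peptide_to_index)
  profile_score_batch_cpp(profile$emissions, profile$transitions, qs, forward)
}

#' Calibrate a profile's extreme-value null distribution
#'
#' Draws i.i.d. null sequences from the background distribution, records
#' each sequence's best local Viterbi score, and fits a Gumbel
#' (location/scale) by maximum likelihood with Newton iterations. The
#' fitted parameters drive [evalue_of()].
#'
#' @param profile A `ProfileModel`.
#' @param null_count Number of null sequences (>= 50; default 200).
#' @param null_length Length of each null sequence (default 400).
#' @param seed RNG seed; calibration is bit-reproducible given the seed.
#' @return The profile with `evd_mu`, `evd_lambda`, `calibration_n`,
#'   `seed` filled in.
#' @export
calibrate_evd <- function(profile, null_count = 200L, null_length = 400L,
                          seed = 1L) {
  stopifnot(inherits(profile, "ProfileModel"))
  if (null_count < 50L)
    stop("null_count must be >= 50 for a stable extreme-value fit")
  seqs <- with_seed(seed, replicate(null_count, paste(
    sample(AA20, null_length, replace = TRUE, prob = profile$background),
    collapse = "")))
  scores <- score_peptides(profile, seqs, forward = FALSE)[, 1L]
  if (stats::var(scores) < 1e-12)
    stop("degenerate null score variance (", stats::var(scores),
         "): profile cannot be calibrated")
  fit <- gumbel_fit_ml(scores)
  profile$evd_mu <- fit$mu
  profile$evd_lambda <- fit$lambda
  profile$calibration_n <- as.integer(null_count)
  profile$seed <- as.integer(seed)
  profile
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and rate `lambda` (scale `1/lambda`) of a Gumbel
#' (max) distribution by Newton iteration on the profile-likelihood score
#' equation for the scale.
#'
#' @param x Numeric sample.
#' @param tol Convergence tolerance on the scale update.
#' @param max_iter Iteration cap.
#' @return List with `mu`, `lambda`.
#' @export
gumbel_fit_ml <- function(x, tol = 1e-9, max_iter = 200L) {
  n <- length(x)
  xbar <- mean(x)
  beta <- stats::sd(x) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) stop("degenerate sample for Gumbel fit")
  for (it in seq_len(max_iter)) {
    z <- exp(-(x - xbar) / beta)        # center for numerical stability
    A <- sum(z); B <- sum((x - xbar) * z); C <- sum((x - xbar)^2 * z)
    f <- beta - xbar + (B / A + xbar)
    fp <- 1 + (C * A - B * B) / (A * A * beta * beta)
    step <- f / fp
    beta_new <- beta - step
    if (beta_new <= 0) beta_new <- beta / 2
    if (abs(beta_new - beta) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  z <- exp(-(x - xbar) / beta)
  mu <- xbar - beta * log(mean(z))
  list(mu = mu, lambda = 1 / beta)
}

# Evaluate an expression with a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
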