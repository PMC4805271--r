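#' Filter alignment rows by coverage
#'
#' Removes rows whose non-gap fraction over the reference (structure) columns
#' falls below `min_coverage`. The reference row is always kept. If the
#' number of surviving homologs (non-reference rows) does not exceed
#' `min_homologs`, a warning is recorded; the alignment is still returned.
#'
#' @param aln an `alignment_set`.
#' @param min_coverage minimum non-gap fraction (default 0.8).
#' @param min_homologs homolog count the curated datasets require (default
#'   100).
#' @return the filtered `alignment_set`, with attribute `n_homologs`.
#' @export
filter_alignment <- function(aln, min_coverage = 0.8, min_homologs = 100) {
  ref_cols <- which(aln$ali[aln$ref, ] != "-")
  cov <- rowMeans(aln$ali[, ref_cols, drop = FALSE] != "-")
  keep <- cov >= min_coverage
  keep[aln$ref] <- TRUE
  if (!any(keep)) stop("alignment empty after coverage filtering")
  out <- aln
  out$ali <- aln$ali[keep, , drop = FALSE]
  out$ids <- aln$ids[keep]
  out$ref <- match(aln$ref, which(keep))
  n_hom <- sum(keep) - 1L
  if (n_hom <= min_homologs)
    warning("only ", n_hom, " homolog(s) survive coverage filtering ",
            "(<= ", min_homologs, ")")
  attr(out, "n_homologs") <- n_hom
  out
}

#' Henikoff position-based sequence weights
#'
#' In each column a sequence receives 1 / (r * s), where r is the number of
#' distinct residue types in the column and s the number of sequences sharing
#' its own type; gap cells contribute nothing. Per-sequence sums are
#' normalized to total 1. The weights downweight redundant subfamilies when
#' estimating amino-acid frequencies.
#'
#' @param aln an `alignment_set` (at least two rows).
#' @return numeric weight vector summing to 1.
#' @export
henikoff_weights <- function(aln) {
  ali <- aln$ali
  if (nrow(ali) < 2L) stop("need at least 2 sequences")
  w <- numeric(nrow(ali))
  for (col in seq_len(ncol(ali))) {
    a <- ali[, col]
    obs <- a != "-"
    if (!any(obs)) next
    tab <- table(a[obs])
    r <- length(tab)
    w[obs] <- w[obs] + 1 / (r * as.numeric(tab[a[obs]]))
  }
  if (sum(w) == 0) stop("all-gap alignment")
  w / sum(w)
}

#' Per-column conservation index
#'
#' Weighted amino-acid frequencies (gaps excluded, renormalized), Shannon
#' entropy in nats, and index = 1 - H / ln(20): 1 for an invariant column,
#' 0 for twenty equiprobable residues. Fully gapped columns yield `NA`.
#'
#' @param aln an `alignment_set`.
#' @param weights sequence weights from [henikoff_weights()].
#' @param gap_flag columns with a gap fraction above this are flagged in the
#'   `low_confidence` attribute (default 0.5).
#' @return numeric vector of per-column indices in \[0, 1\].
#' @export
conservation_index <- function(aln, weights, gap_flag = 0.5) {
  ali <- aln$ali
  stopifnot(length(weights) == nrow(ali))
  idx <- vapply(seq_len(ncol(ali)), function(col) {
    a <- ali[, col]
    obs <- a != "-"
    if (!any(obs)) return(NA_real_)
    p <- tapply(weights[obs], a[obs], sum)
    p <- p / sum(p)
    h <- -sum(p * log(p))
    1 - h / log(20)
  }, numeric(1))
  gapfrac <- colMeans(ali == "-")
  attr(idx, "low_confidence") <- which(gapfrac > gap_flag)
  idx
}

#' Evolutionary conservation Z-scores per structure residue
#'
#' Standardizes the conservation indices of the structure-mapped alignment
#' columns: mean 0, sd 1 over scored positions, higher = more conserved.
#'
#' @param indices per-column conservation indices.
#' @param mapping column index of each structure residue (see
#'   [map_alignment()]).
#' @return A `conservation_profile`: data.frame with `column`, `index`,
#'   `zscore_evol`, one row per structure residue.
#' @export
zscore_evolution <- function(indices, mapping) {
  x <- indices[mapping]
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("fewer than 2 mapped, scored positions")
  s <- sd(x[ok])
  if (s < 1e-12) stop("constant conservation indices; z-score undefined")
  z <- rep(NA_real_, length(x))
  z[ok] <- (x[ok] - mean(x[ok])) / s
  out <- data.frame(column = mapping, index = x, zscore_evol = z)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Correlate perturbation and conservation score profiles
#'
#' Spearman rank correlation (two-sided) between the neighbor-averaged
#' ZscoreS and Zscore_evol profiles. A negative correlation indicates that
#' residues whose mutation most disrupts the binding-relevant mode subspace
#' are the evolutionarily conserved ones.
#'
#' @param zscore_s,zscore_evol equal-length numeric profiles (typically 7 A
#'   neighbor-averaged).
#' @return list with `rho`, `p` and `n`.
#' @export
correlate_scores <- function(zscore_s, zscore_evol) {
  ok <- is.finite(zscore_s) & is.finite(zscore_evol)
  if (sum(ok) < 3L) stop("need at least 3 paired values")
  if (sd(zscore_s[ok]) < 1e-12 || sd(zscore_evol[ok]) < 1e-12)
    stop("constant input profile")
  ct <- suppressWarnings(cor.test(zscore_s[ok], zscore_evol[ok],
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
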