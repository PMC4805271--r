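#' B-factor-weighted conformational-change vector
#'
#' Difference between superposed bound and free C-alpha coordinates, with
#' each residue's three components damped by exp(-(B_free + B_bound) * w) so
#' that intrinsically flexible, poorly resolved regions (loops, termini) do
#' not dominate the direction of the conformational change. The result is
#' normalized to unit length.
#'
#' @param pair a superposed `conformer_pair`.
#' @param bfactors_free,bfactors_bound per-residue B-factors of each
#'   conformer (theoretical profiles from each conformer's own network by
#'   convention; experimental profiles may be supplied instead).
#' @param w dimensionless damping scale (default 0.01).
#' @return A `displacement_vector`: list with `v` (unit length 3N), `w`,
#'   `source`.
#' @export
weighted_difference <- function(pair, bfactors_free, bfactors_bound,
                                w = 0.01) {
  fi <- pair$mapping[, "free"]; bi <- pair$mapping[, "bound"]
  n <- length(pair$free$resno)
  stopifnot(length(bfactors_free) == n,
            length(bfactors_bound) == length(pair$bound$resno))
  d <- matrix(0, n, 3)
  d[fi, ] <- pair$bound$xyz[bi, , drop = FALSE] -
    pair$free$xyz[fi, , drop = FALSE]
  wt <- rep(1, n)
  wt[fi] <- exp(-(bfactors_free[fi] + bfactors_bound[bi]) * w)
  v <- flatten_xyz(d * wt)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) stop("no conformational change between the conformers")
  structure(list(v = v / nv, w = w, source = "conformational-change"),
            class = "displacement_vector")
}

#' Expand a displacement vector on the internal modes
#'
#' Dot products with each internal mode give the expansion coefficients.
#' A residual rigid-body (null-space) component can survive superposition;
#' the coefficients are renormalized to unit length within the internal-mode
#' span (the discarded fraction is reported) so that the participation number
#' stays in \[1, 3N-6\]. The participation number P = 1 / sum(c^4) is the
#' effective number of modes carrying the vector; the subspace size is
#' M = ceiling(P).
#'
#' @param v a `displacement_vector` (or bare unit numeric vector).
#' @param modes a `mode_set` of the ligand-free conformer.
#' @return A `mode_expansion`: list with `coefficients` (per internal mode,
#'   renormalized), `p`, `m`, `ranked` (internal-mode indices by decreasing
#'   squared coefficient, ties by ascending index), `discarded` (squared
#'   fraction outside the internal span), `source`.
#' @export
expand_on_modes <- function(v, modes) {
  src <- if (inherits(v, "displacement_vector")) v$source else "vector"
  vec <- if (inherits(v, "displacement_vector")) v$v else v
  Q <- modes$vectors[, modes$internal, drop = FALSE]
  if (length(vec) != nrow(Q)) stop("dimension mismatch")
  cf <- as.vector(crossprod(Q, vec))
  ss <- sum(cf^2)
  if (ss < 1e-6)
    stop("vector lies in the rigid-body span; no internal-mode content")
  cf <- cf / sqrt(ss)
  p <- 1 / sum(cf^4)
  m <- as.integer(ceiling(p - 1e-9))
  ranked <- order(-cf^2, seq_along(cf))
  structure(list(coefficients = cf, p = p, m = m, ranked = ranked,
                 discarded = max(0, 1 - ss), source = src),
            class = "mode_expansion")
}

#' @export
print.mode_expansion <- function(x, ...) {
  cat(sprintf(
    "mode_expansion (%s): P = %.3f, M = %d, leading modes %s\n",
    x$source, x$p, x$m,
    paste(utils::head(x$ranked, min(5, x$m)), collapse = ", ")))
  invisible(x)
}

#' Expand the B-factor profile on the internal modes
#'
#' The per-residue B-factor is replicated over that residue's three Cartesian
#' components, unit-normalized, and expanded as a displacement vector. The
#' resulting participation number P_B and subspace S_B describe how many
#' modes shape the flexibility pattern.
#'
#' @param bfactors per-residue B-factor profile (length N).
#' @param modes a `mode_set`.
#' @return a `mode_expansion` with source `"bfactor"`.
#' @export
bfactor_expansion <- function(bfactors, modes) {
  if (all(bfactors == 0)) stop("all-zero B-factor profile")
  v <- rep(as.numeric(bfactors), each = 3)
  v <- v / sqrt(sum(v^2))
  out <- expand_on_modes(v, modes)
  out$source <- "bfactor"
  out
}

#' Select the minimal mode subspace
#'
#' Takes the M = ceiling(P) internal modes with the largest squared
#' coefficients (ties broken by ascending mode index) and assembles their
#' orthonormal basis.
#'
#' @param expansion a `mode_expansion`.
#' @param modes the `mode_set` the expansion was computed on.
#' @param label subspace label (`"S"` for the conformational change, `"S_B"`
#'   for the flexibility pattern).
#' @return A `mode_subspace`: list with `modes` (internal-mode indices in
#'   decreasing-coefficient order), `basis` (3N x M orthonormal), `label`.
#' @export
select_subspace <- function(expansion, modes, label = "S") {
  sel <- expansion$ranked[seq_len(expansion$m)]
  basis <- modes$vectors[, modes$internal[sel], drop = FALSE]
  structure(list(modes = sel, basis = basis, label = label),
            class = "mode_subspace")
}

#' @export
print.mode_subspace <- function(x, ...) {
  cat(sprintf("mode_subspace %s: M = %d (modes %s)\n", x$label,
              length(x$modes), paste(x$modes, collapse = ", ")))
  invisible(x)
}

#' Degree of collectivity of a mode
#'
#' Exponential Shannon entropy of the per-residue squared amplitudes,
#' normalized by N: 1 for a mode distributing motion uniformly over all
#' residues, 1/N for a mode moving a single residue.
#'
#' @param q mode vector of length 3N (need not be normalized).
#' @param n number of residues.
#' @return collectivity kappa in \[1/N, 1\].
#' @export
collectivity <- function(q, n) {
  r2 <- per_residue_sq(q)
  if (length(r2) != n) stop("length(q) must be 3 * n")
  r2 <- r2 / sum(r2)
  h <- -sum(ifelse(r2 > 0, r2 * log(r2), 0))
  exp(h) / n
}

#' Write a subspace report
#'
#' TSV of the expansion over internal modes: mode index, eigenvalue, squared
#' coefficient, cumulative sum, collectivity.
#'
#' @param expansion a `mode_expansion`.
#' @param modes the `mode_set`.
#' @param file output path.
#' @return the table, invisibly.
#' @export
write_subspace_report <- function(expansion, modes, file) {
  r <- expansion$ranked
  c2 <- expansion$coefficients[r]^2
  kap <- vapply(modes$internal[r],
                function(cl) collectivity(modes$vectors[, cl], modes$n),
                numeric(1))
  tab <- data.frame(mode = r, eigenvalue = modes$values[modes$internal[r]],
                    c_sq = c2, cum_c_sq = cumsum(c2), collectivity = kap)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
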