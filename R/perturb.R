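#' Perturb the springs of one residue
#'
#' Simulates a point mutation at residue `i` by scaling every spring incident
#' to it: k_ij -> k_ij (1 + delta). The multiplicative form keeps the
#' spring-class ratios and the positive semi-definiteness of the Hessian for
#' either sign of delta. The Hessian is rebuilt.
#'
#' @param model an `enm_model`.
#' @param i residue index.
#' @param delta signed fractional change, |delta| <= 0.5.
#' @return a new `enm_model`.
#' @export
perturb_residue <- function(model, i, delta) {
  if (abs(delta) > 0.5) stop("|delta| must be <= 0.5")
  sp <- model$springs
  hit <- sp$i == i | sp$j == i
  if (!any(hit)) stop("residue ", i, " has no springs")
  sp$k[hit] <- sp$k[hit] * (1 + delta)
  build_hessian(model$structure, sp, model$gamma, model$r_c)
}

#' Match perturbed to unperturbed modes by linear assignment
#'
#' Perturbations reorder and mix nearly degenerate modes, so the
#' energy-ordering correspondence breaks down. The one-to-one correspondence
#' maximizing the summed squared overlaps (dot products) between the two
#' internal-mode sets is computed as a linear assignment problem over the
#' full internal space, so the permutation is globally consistent.
#'
#' @param unperturbed,perturbed `mode_set` objects of equal dimension.
#' @return integer vector `perm` with `perm[k]` the perturbed internal-mode
#'   index assigned to unperturbed internal mode `k`; attribute `objective`
#'   carries the achieved sum of squared overlaps.
#' @export
match_modes <- function(unperturbed, perturbed) {
  Q <- unperturbed$vectors[, unperturbed$internal, drop = FALSE]
  Qp <- perturbed$vectors[, perturbed$internal, drop = FALSE]
  if (!identical(dim(Q), dim(Qp))) stop("mode sets differ in dimension")
  O <- crossprod(Q, Qp)
  perm <- solve_assignment(-(O * O))
  attr(perm, "objective") <- sum(O[cbind(seq_along(perm), perm)]^2)
  perm
}

#' Image of a subspace under the mode correspondence
#'
#' Collects the perturbed modes assigned to each member of `S`, in `S`'s
#' order, as the perturbed subspace S_i.
#'
#' @param S a `mode_subspace` of the unperturbed model.
#' @param perm permutation from [match_modes()].
#' @param perturbed the perturbed `mode_set`.
#' @return a `mode_subspace` labelled `"S_i"`.
#' @export
perturbed_subspace <- function(S, perm, perturbed) {
  idx <- perm[S$modes]
  structure(list(modes = idx,
                 basis = perturbed$vectors[, perturbed$internal[idx],
                                           drop = FALSE],
                 label = "S_i"),
            class = "mode_subspace")
}

#' Gramian similarity between two mode subspaces
#'
#' Projects each perturbed mode onto the span of `S`, forms the Gramian of
#' the projections, and averages its eigenvalues: zeta = sum(lambda_k) / M.
#' Equals 1 for identical spans, 0 for orthogonal subspaces. Eigenvalues are
#' clipped to \[0, 1\] at a 1e-9 tolerance.
#'
#' @param S,S_i `mode_subspace` objects of equal dimension M.
#' @return zeta in \[0, 1\].
#' @export
subspace_similarity <- function(S, S_i) {
  m <- ncol(S$basis)
  if (ncol(S_i$basis) != m) stop("subspace dimension mismatch")
  A <- crossprod(S$basis, S_i$basis)   # A[k, j] = q_k . q^i_j
  G <- crossprod(A)                    # Gramian of the projections
  lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-9) || any(lam > 1 + 1e-9))
    stop("Gramian eigenvalue outside [0, 1]")
  lam <- pmin(pmax(lam, 0), 1)
  sum(lam) / m
}

#' Perturbation scan over all residues
#'
#' For every residue, perturbs its springs by +delta and -delta, rediagonalizes,
#' re-matches modes, and computes the Gramian similarity between the
#' ligand-binding subspace `S` and its perturbed image. The two similarities
#' are averaged and standardized over residues into ZscoreS (mean 0, sd 1);
#' low values mark residues whose mutation most disrupts the binding-relevant
#' subspace.
#'
#' @param model the ligand-free `enm_model`.
#' @param modes its `mode_set` (as returned by [enm_modes()]).
#' @param S the `mode_subspace` associated to the conformational change.
#' @param delta perturbation magnitude (default 0.05; results are stable in
#'   the 0.01-0.1 range).
#' @return A `score_profile` data.frame: `chain`, `resnum`, `aa`,
#'   `zeta_plus`, `zeta_minus`, `zeta_mean`, `zscore_s`; attribute `delta`.
#' @export
scan_all_residues <- function(model, modes, S, delta = 0.05) {
  n <- length(model$structure$resno)
  zp <- zm <- numeric(n)
  for (i in seq_len(n)) {
    for (sgn in c(1, -1)) {
      pm <- perturb_residue(model, i, sgn * delta)
      pmodes <- enm_modes(pm)
      perm <- match_modes(modes, pmodes)
      Si <- perturbed_subspace(S, perm, pmodes)
      z <- subspace_similarity(S, Si)
      if (sgn > 0) zp[i] <- z else zm[i] <- z
    }
  }
  zbar <- (zp + zm) / 2
  s <- sd(zbar)
  if (s < 1e-10)
    stop("degenerate zeta profile: zero variance across residues")
  out <- data.frame(chain = model$structure$chain,
                    resnum = model$structure$resno,
                    aa = model$structure$aa,
                    zeta_plus = zp, zeta_minus = zm, zeta_mean = zbar,
                    zscore_s = (zbar - mean(zbar)) / s,
                    stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  class(out) <- c("score_profile", "data.frame")
  out
}

#' Average a per-residue profile over spatial neighbors
#'
#' Replaces each residue's value by the mean over all residues whose C-alpha
#' lies within `radius` of its own (self included). Used to read the scan and
#' conservation profiles as spatial regions rather than single residues.
#'
#' @param values numeric vector of length N.
#' @param structure a [ca_structure()].
#' @param radius neighborhood radius in Angstrom (default 7).
#' @return averaged numeric vector.
#' @export
neighbor_average <- function(values, structure, radius = 7) {
  n <- length(structure$resno)
  stopifnot(length(values) == n)
  D <- as.matrix(dist(structure$xyz))
  vapply(seq_len(n), function(i) mean(values[D[i, ] <= radius]), numeric(1))
}

#' Select key positions
#'
#' The ceiling(fraction * N) residues with the lowest ZscoreS, ties at the
#' boundary broken by ascending residue index.
#'
#' @param profile a `score_profile` or bare numeric vector of scores.
#' @param fraction fraction of residues to select (default 0.05).
#' @return A `key_positions`: list with `indices` (sorted residue indices),
#'   `fraction`, `count`.
#' @export
select_key_positions <- function(profile, fraction = 0.05) {
  z <- if (inherits(profile, "score_profile")) profile$zscore_s
       else as.numeric(profile)
  n <- length(z)
  if (n < 1L) stop("empty score profile")
  m <- as.integer(ceiling(fraction * n))
  idx <- sort(order(z, seq_len(n))[seq_len(m)])
  structure(list(indices = idx, fraction = fraction, count = m),
            class = "key_positions")
}

#' @export
print.key_positions <- function(x, ...) {
  cat(sprintf("key_positions: %d residues (lowest %.0f%%): %s\n",
              x$count, 100 * x$fraction, paste(x$indices, collapse = ", ")))
  invisible(x)
}

#' Write the per-residue score table
#'
#' @param profile a `score_profile`.
#' @param structure the scanned [ca_structure()] (for 7 A averaging).
#' @param keys a `key_positions` set.
#' @param file output TSV path.
#' @param radius neighbor-averaging radius in Angstrom.
#' @return the table, invisibly.
#' @export
write_score_table <- function(profile, structure, keys, file, radius = 7) {
  tab <- as.data.frame(profile)
  tab$zscore_s_avg <- neighbor_average(profile$zscore_s, structure, radius)
  tab$is_key <- seq_len(nrow(tab)) %in% keys$indices
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
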