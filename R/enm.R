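#' Assign chemically weighted spring constants
#'
#' Applies the force-constant rules of the elastic network: covalent
#' neighbors and disulfide bridges get the full constant gamma; hydrogen
#' bonds / salt bridges within the cutoff get 0.1 gamma; all remaining pairs
#' within the cutoff get 0.01 gamma. Hydrogen-bond and generic classes are
#' distance-gated by `r_c`; covalent and disulfide springs are not.
#'
#' @param contacts a `contact_graph` from [detect_contacts()].
#' @param gamma overall spring-constant scale (the absolute value only sets
#'   the B-factor scale; rank correlations and normalized mode vectors are
#'   unaffected).
#' @return data.frame of springs with columns `i`, `j`, `k`.
#' @export
assign_force_constants <- function(contacts, gamma = 1) {
  e <- contacts$edges
  k <- numeric(nrow(e))
  k[e$class == "covalent"] <- gamma
  k[e$class == "disulfide"] <- gamma
  k[e$class == "hbond"] <- ifelse(e$d[e$class == "hbond"] <= contacts$r_c,
                                  0.1 * gamma, 0)
  k[e$class == "generic"] <- 0.01 * gamma
  sp <- data.frame(i = e$i, j = e$j, k = k)
  sp[sp$k > 0, , drop = FALSE]
}

#' Build the anisotropic network Hessian
#'
#' Assembles the 3N x 3N second-derivative matrix of the pairwise harmonic
#' potential at the crystallographic equilibrium: each spring contributes the
#' 3 x 3 block k_ij (r_hat r_hat^T) on the diagonal blocks of i and j and its
#' negative on the (i, j) off-diagonal blocks.
#'
#' @param structure a [ca_structure()] giving equilibrium positions.
#' @param springs data.frame `i`, `j`, `k` from [assign_force_constants()].
#' @param gamma,r_c recorded on the model for provenance.
#' @return An `enm_model`: list with `structure`, `springs`, `gamma`, `r_c`,
#'   `hessian`.
#' @export
build_hessian <- function(structure, springs, gamma = 1, r_c = NA_real_) {
  n <- length(structure$resno)
  H <- matrix(0, 3 * n, 3 * n)
  xyz <- structure$xyz
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]; k <- springs$k[s]
    rij <- xyz[i, ] - xyz[j, ]
    d2 <- sum(rij^2)
    if (d2 < 1e-12)
      stop("coincident C-alpha positions on spring (", i, ", ", j, ")")
    blk <- (k / d2) * tcrossprod(rij)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  structure(list(structure = structure, springs = springs, gamma = gamma,
                 r_c = r_c, hessian = H),
            class = "enm_model")
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("enm_model: %d residues, %d springs, r_c = %s A\n",
              length(x$structure$resno), nrow(x$springs),
              format(x$r_c)))
  invisible(x)
}

# connected components of the spring graph (used for error reporting)
spring_components <- function(n, springs) {
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (s in seq_len(nrow(springs))) {
      m <- min(comp[springs$i[s]], comp[springs$j[s]])
      new[springs$i[s]] <- min(new[springs$i[s]], m)
      new[springs$j[s]] <- min(new[springs$j[s]], m)
    }
    if (identical(new, comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

#' Diagonalize an elastic network model
#'
#' Eigen-decomposes the Hessian with eigenvalues in ascending order. Null
#' (rigid-body) modes are identified by a relative threshold; a non-collinear
#' connected network has exactly six. More than six signals a disconnected
#' network and is an error naming the components.
#'
#' @param model an `enm_model`.
#' @param tol relative null-mode threshold (eigenvalues below
#'   `tol * max(lambda)` are treated as zero).
#' @return A `mode_set`: list with `values` (ascending), `vectors`
#'   (orthonormal columns), `n_zero`, `internal` (column indices of the
#'   3N - n_zero internal modes, ascending eigenvalue), `n` (residues).
#' @export
enm_modes <- function(model, tol = 1e-8) {
  eig <- eigen(model$hessian, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  thr <- tol * max(values)
  if (min(values) < -thr)
    stop("Hessian is not positive semi-definite (negative spring constant?)")
  n_zero <- sum(values < thr)
  if (n_zero > 6L) {
    comp <- spring_components(length(model$structure$resno), model$springs)
    stop("network is disconnected (", n_zero, " null modes, ",
         max(comp), " components)")
  }
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 internal = (n_zero + 1L):length(values),
                 n = length(model$structure$resno)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d residues, %d null + %d internal modes\n",
              x$n, x$n_zero, length(x$internal)))
  invisible(x)
}

#' Theoretical B-factors from internal modes
#'
#' Per-residue mean-square fluctuation summed over internal modes with
#' inverse-eigenvalue weights, times the 8 pi^2 / 3 crystallographic
#' prefactor (k_B T = 1; the absolute scale is arbitrary).
#'
#' @param modes a `mode_set`.
#' @param scale_to optional experimental B-factor vector; when given, the
#'   theoretical profile is rescaled to the same mean, emulating the gamma
#'   calibration that matches theory to experiment (shape is unchanged).
#' @return numeric vector of length N, strictly positive for a connected
#'   network.
#' @export
theoretical_bfactors <- function(modes, scale_to = NULL) {
  lam <- modes$values[modes$internal]
  if (any(lam <= 0)) stop("zero eigenvalue among internal modes")
  W <- modes$vectors[, modes$internal, drop = FALSE]
  msf <- 3 * as.vector((W^2) %*% (1 / lam))          # 3 k_B T sum_k ...
  b <- (8 * pi^2 / 3) * colSums(matrix(msf, nrow = 3))
  if (!is.null(scale_to)) b <- b * mean(scale_to) / mean(b)
  b
}

#' Calibrate the cutoff radius against experimental B-factors
#'
#' Scans `r_c` over a grid, rebuilding the network and its theoretical
#' B-factor profile at each value, and returns the cutoff maximizing the
#' Spearman rank correlation with the experimental B-factors (ties broken
#' toward the smaller cutoff, favoring sparser networks).
#'
#' @param structure a [ca_structure()] with experimental B-factors.
#' @param full_atom_path optional full-atom PDB for contact typing.
#' @param grid cutoff grid in Angstrom.
#' @param gamma spring-constant scale.
#' @param exp_b experimental B-factors; defaults to `structure$bfactor`.
#' @return list with `r_c` (optimum), `spearman` (at the optimum) and
#'   `curve` (data.frame `r_c`, `spearman`).
#' @export
calibrate_cutoff <- function(structure, full_atom_path = NULL,
                             grid = seq(7, 20, by = 0.5), gamma = 1,
                             exp_b = structure$bfactor) {
  if (sd(exp_b) < 1e-12)
    stop("experimental B-factors are constant; correlation undefined")
  rho <- vapply(grid, function(rc) {
    contacts <- suppressWarnings(detect_contacts(structure, full_atom_path,
                                                 r_c = rc))
    springs <- assign_force_constants(contacts, gamma)
    model <- build_hessian(structure, springs, gamma, rc)
    modes <- tryCatch(enm_modes(model), error = function(e) NULL)
    if (is.null(modes)) return(NA_real_)
    cor(theoretical_bfactors(modes), exp_b, method = "spearman")
  }, numeric(1))
  if (all(is.na(rho))) stop("no connected network on the cutoff grid")
  best <- which.max(rho)   # first maximum = smallest r_c on an ascending grid
  list(r_c = grid[best], spearman = rho[best],
       curve = data.frame(r_c = grid, spearman = rho))
}

#' Build the elastic network model for a structure in one call
#'
#' Convenience wrapper: contacts at `r_c`, force constants, Hessian.
#'
#' @inheritParams detect_contacts
#' @inheritParams assign_force_constants
#' @return an `enm_model`.
#' @export
build_enm <- function(structure, full_atom_path = NULL, r_c = 10, gamma = 1) {
  contacts <- suppressWarnings(detect_contacts(structure, full_atom_path, r_c))
  springs <- assign_force_constants(contacts, gamma)
  build_hessian(structure, springs, gamma, r_c)
}

#' Write a mode table
#'
#' Plain-text table of internal modes: index, eigenvalue, collectivity.
#'
#' @param modes a `mode_set`.
#' @param file output TSV path.
#' @return the table, invisibly.
#' @export
write_mode_table <- function(modes, file) {
  idx <- seq_along(modes$internal)
  kap <- vapply(modes$internal,
                function(c) collectivity(modes$vectors[, c], modes$n),
                numeric(1))
  tab <- data.frame(mode = idx, eigenvalue = modes$values[modes$internal],
                    collectivity = kap)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
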