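#' Specification of a synthetic fixture
#'
#' Collects everything that determines a synthetic conformer-pair fixture:
#' topology, size, which internal modes the bound conformer is displaced
#' along (the planted ground truth), B-factor noise, and the coupled-MSA
#' parameters. A fixture is a deterministic function of its spec; separate
#' seed streams are used for geometry, B-factor noise and the MSA so changing
#' one component does not shift the others.
#'
#' @param seed integer master seed.
#' @param topology `"two-domain-hinge"`, `"helix-pair"` or
#'   `"random-globule"`.
#' @param n number of residues (>= 10).
#' @param planted_modes internal-mode indices the bound conformer is
#'   displaced along.
#' @param amplitudes displacement amplitude per planted mode, Angstrom
#'   (recycled). Small by default so the contact topology is preserved.
#' @param bfactor_noise_sd Gaussian noise added to the model B-factor
#'   profile; `NULL` = 20% of the profile's spread.
#' @param msa list `n_rows`, `coupling`, `noise_sd` for [make_coupled_msa()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1,
                         topology = c("two-domain-hinge", "helix-pair",
                                      "random-globule"),
                         n = 60, planted_modes = c(1L, 2L),
                         amplitudes = c(0.4, 0.28),
                         bfactor_noise_sd = NULL,
                         msa = list(n_rows = 150, coupling = 1,
                                    noise_sd = 1)) {
  topology <- match.arg(topology)
  if (n < 10) stop("n must be >= 10")
  structure(list(seed = as.integer(seed), topology = topology,
                 n = as.integer(n), planted_modes = as.integer(planted_modes),
                 amplitudes = rep_len(amplitudes, length(planted_modes)),
                 bfactor_noise_sd = bfactor_noise_sd, msa = msa),
            class = "fixture_spec")
}

# random unit vector
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# self-avoiding random walk confined to a sphere; returns n x 3 matrix
confined_walk <- function(n, center, radius, start, step = 3.8,
                          min_sep = 3.3, tries = 400L) {
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- start
  for (i in seq_len(n)[-1]) {
    best <- NULL; best_pen <- Inf
    for (t in seq_len(tries)) {
      cand <- pts[i - 1, ] + step * runit()
      out <- max(0, sqrt(sum((cand - center)^2)) - radius)
      clash <- if (i > 2) {
        dd <- sqrt(rowSums((pts[seq_len(i - 2), , drop = FALSE] -
                              matrix(cand, i - 2, 3, byrow = TRUE))^2))
        sum(pmax(0, min_sep - dd))
      } else 0
      pen <- out + clash
      if (pen == 0) { best <- cand; break }
      if (pen < best_pen) { best <- cand; best_pen <- pen }
    }
    pts[i, ] <- best
  }
  pts
}

# Two compact domains facing each other across a narrow interface (clamshell
# arrangement), joined by a short curled linker near the interface. The
# interface gap keeps a patch of weak generic springs between the domains, so
# the network is rigid (no mechanisms) while the softest internal modes are
# genuine inter-domain motions pivoting on the linker/interface region.
make_two_domain <- function(n) {
  h <- 3L
  n1 <- as.integer(floor((n - h) / 2))
  n2 <- n - n1 - h
  r1 <- max(7, 3.0 * n1^(1 / 3))
  r2 <- max(7, 3.0 * n2^(1 / 3))
  gap <- 6
  p1 <- c(r1, 0, 0)                       # exit point on domain 1's surface
  d1 <- confined_walk(n1, c(0, 0, 0), r1, start = p1)
  d1 <- d1[rev(seq_len(n1)), , drop = FALSE]   # chain ends at the surface
  lcen <- c(r1 + gap / 2, 0, 0)           # linker curls inside the gap
  lnk <- confined_walk(h, lcen, 4.5, start = p1 + c(3.4, 0, 1.6))
  c2 <- c(r1 + gap + r2, 0, 0)
  to_c2 <- c2 - lnk[h, ]
  start2 <- lnk[h, ] + 3.8 * to_c2 / sqrt(sum(to_c2^2))
  d2 <- confined_walk(n2, c2, r2, start = start2)
  xyz <- rbind(d1, lnk, d2)
  # ground truth hinge/contact region: linker plus interfacial residues
  ctr <- colMeans(lnk)
  near <- which(sqrt(rowSums((xyz - matrix(ctr, n, 3, byrow = TRUE))^2)) <= 8)
  list(xyz = xyz, hinge = sort(unique(c((n1):(n1 + h + 1L), near))))
}

# ideal C-alpha helix: radius 2.3 A, rise 1.5 A, 100 degrees per residue
helix_coords <- function(n, origin = c(0, 0, 0), axis_z = TRUE) {
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1], 2.3 * sin(ang) + origin[2],
        1.5 * i + origin[3])
}

make_helix_pair <- function(n) {
  n1 <- floor((n - 3) / 2)
  n2 <- n - 3 - n1
  h1 <- helix_coords(n1)
  # second helix alongside the first, antiparallel, ~10 A away
  h2 <- helix_coords(n2, origin = c(10, 0, 1.5 * n2))
  h2[, 3] <- rev(h2[, 3])
  last <- h1[n1, ]
  first2 <- h2[1, ]
  lnk <- t(vapply(1:3, function(i) last + (first2 - last) * i / 4,
                  numeric(3)))
  lnk <- lnk + matrix(rnorm(9, 0, 0.3), 3, 3)
  list(xyz = rbind(h1, lnk, h2), hinge = (n1):(n1 + 4L))
}

make_globule <- function(n) {
  r <- max(8, 3.0 * n^(1 / 3))
  xyz <- confined_walk(n, c(0, 0, 0), r, start = c(2, 0, 0))
  list(xyz = xyz, hinge = integer())
}

#' Generate a synthetic C-alpha structure with pseudo full atoms
#'
#' Builds the seeded bead geometry for the requested topology (two compact
#' domains bridged by a narrow hinge, an antiparallel helix pair, or a single
#' compact globule), assigns a random sequence, and places one pseudo
#' backbone N, backbone O and side-chain atom per residue so the typed
#' contact rules have atoms to work on. B-factors are initialized to zero and
#' filled in by [make_bfactors()].
#'
#' @param spec a [fixture_spec()].
#' @return list with `structure` (a [ca_structure()]), `atoms` (full-atom
#'   data.frame), `hinge` (ground-truth hinge residue indices).
#' @export
make_structure <- function(spec) {
  with_seed(spec$seed, {
    geo <- switch(spec$topology,
                  "two-domain-hinge" = make_two_domain(spec$n),
                  "helix-pair" = make_helix_pair(spec$n),
                  "random-globule" = make_globule(spec$n))
    aa <- sample(names(AA_321), spec$n, replace = TRUE)
    st <- ca_structure(chain = rep("A", spec$n), resno = seq_len(spec$n),
                       icode = rep("", spec$n), aa = aa, xyz = geo$xyz,
                       bfactor = rep(0, spec$n),
                       name = paste0("synthetic-", spec$topology))
    atoms <- synth_atoms(st)
    list(structure = st, atoms = atoms, hinge = geo$hinge)
  })
}

# pseudo full-atom records: CA + N + O + one side-chain atom per residue
synth_atoms <- function(st) {
  n <- length(st$resno)
  rows <- lapply(seq_len(n), function(i) {
    ca <- st$xyz[i, ]
    sc_name <- if (st$aa[i] == "GLY") NULL
               else if (st$aa[i] == "CYS") "SG" else "CB"
    elety <- c("N", "CA", "C", "O", sc_name)
    off <- rbind(1.46 * runit(), c(0, 0, 0), 1.52 * runit(), 2.4 * runit(),
                 if (!is.null(sc_name)) 1.9 * runit())
    data.frame(elety = elety, resid = st$aa[i], chain = st$chain[i],
               resno = st$resno[i], insert = "",
               x = ca[1] + off[, 1], y = ca[2] + off[, 2],
               z = ca[3] + off[, 3],
               o = 1, b = st$bfactor[i],
               elesy = substr(elety, 1, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Displace a structure along planted internal modes
#'
#' bound = free + sum(amplitude_k q_k), followed by a seeded rigid rotation
#' and translation (so the downstream superposition is exercised). Because
#' internal modes are orthogonal to the rigid-body span, small amplitudes are
#' recovered exactly by the expansion stage.
#'
#' @param free the free [ca_structure()].
#' @param modes the free conformer's `mode_set`.
#' @param planted internal-mode indices.
#' @param amplitudes amplitude per mode, Angstrom.
#' @param seed seed for the rigid transform.
#' @param check_rc if non-`NULL`, verify that the generic contact topology at
#'   this cutoff is unchanged by the displacement and error otherwise.
#' @return the bound [ca_structure()].
#' @export
make_bound <- function(free, modes, planted, amplitudes, seed = 1,
                       check_rc = NULL) {
  planted <- as.integer(planted)
  if (any(planted < 1 | planted > length(modes$internal)))
    stop("planted indices must be internal modes")
  amplitudes <- rep_len(amplitudes, length(planted))
  disp <- numeric(3 * modes$n)
  for (k in seq_along(planted))
    disp <- disp + amplitudes[k] *
      modes$vectors[, modes$internal[planted[k]]]
  new_xyz <- free$xyz + unflatten_xyz(disp)
  if (!is.null(check_rc)) {
    edge_set <- function(x) {
      D <- as.matrix(dist(x))
      which(upper.tri(D) & D <= check_rc)
    }
    if (!identical(edge_set(free$xyz), edge_set(new_xyz)))
      stop("planted amplitude changes the contact topology at r_c = ",
           check_rc)
  }
  with_seed(seed, {
    ax <- runit(); ang <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    tr <- rnorm(3, 0, 10)
    new_xyz <- sweep(new_xyz %*% t(R), 2, -tr)
  })
  bound <- free
  bound$xyz <- new_xyz
  bound$name <- paste0(free$name, "-bound")
  bound
}

#' Experimental-style B-factors from a mode set
#'
#' The theoretical inverse-eigenvalue profile plus seeded Gaussian noise,
#' floored at a small positive value.
#'
#' @param modes a `mode_set`.
#' @param noise_sd Gaussian noise standard deviation in Angstrom^2 (on the
#'   rescaled profile); `NULL` = 20% of the profile's standard deviation.
#' @param seed seed for the noise stream.
#' @param mean_b target mean of the profile, Angstrom^2 (default 30, a
#'   typical crystallographic magnitude).
#' @return numeric vector of positive B-factors.
#' @export
make_bfactors <- function(modes, noise_sd = NULL, seed = 1, mean_b = 30) {
  b <- theoretical_bfactors(modes)
  b <- b * mean_b / mean(b)
  if (is.null(noise_sd)) noise_sd <- 0.2 * sd(b)
  with_seed(seed, b <- b + rnorm(length(b), 0, noise_sd))
  pmax(b, 1e-3)
}

#' Generate an MSA whose conservation is coupled to a score profile
#'
#' Per column, the substitution probability is
#' plogis(2 * coupling * z + noise), with z the standardized score: columns
#' with low scores (key-position-like) are conserved, high-scoring columns
#' vary freely. Rows are sampled independently; the reference sequence is
#' preserved as the first row. With coupling 0 conservation is unrelated to
#' the scores.
#'
#' @param ref_aa reference sequence (one-letter vector).
#' @param score per-residue score profile (e.g. ZscoreS).
#' @param coupling coupling strength in \[0, 1\].
#' @param n_rows number of homolog rows to sample.
#' @param noise_sd per-column logistic noise.
#' @param seed seed for the MSA stream.
#' @return an `alignment_set` with the reference as row 1.
#' @export
make_coupled_msa <- function(ref_aa, score, coupling = 1, n_rows = 150,
                             noise_sd = 1, seed = 1) {
  stopifnot(coupling >= 0, coupling <= 1,
            length(ref_aa) == length(score))
  n <- length(ref_aa)
  z <- if (sd(score) > 0) (score - mean(score)) / sd(score) else score * 0
  aa20 <- unname(AA_321)
  with_seed(seed, {
    psub <- stats::plogis(2 * coupling * z + rnorm(n, 0, noise_sd))
    rows <- t(vapply(seq_len(n_rows), function(r) {
      sub <- runif(n) < psub
      out <- ref_aa
      out[sub] <- sample(aa20, sum(sub), replace = TRUE)
      out
    }, character(n)))
  })
  ali <- rbind(ref = ref_aa, rows)
  ids <- c("reference", paste0("homolog_", seq_len(n_rows)))
  rownames(ali) <- ids
  structure(list(ali = ali, ids = ids, ref = 1L), class = "alignment_set")
}

#' Generate a complete synthetic fixture
#'
#' Runs the generator end to end: geometry, elastic network of the free
#' conformer, bound conformer displaced along the planted modes,
#' experimental-style B-factors for both conformers, and (optionally, once a
#' score profile exists) a coupled MSA. The returned structures carry the
#' noisy B-factors, so the fixture behaves like parsed crystal structures.
#'
#' @param spec a [fixture_spec()].
#' @param r_c cutoff used for the fixture's network (default 10 A).
#' @return list with `spec`, `free`, `bound` ([ca_structure()]s), `atoms`
#'   (full-atom table of the free conformer), `hinge`, `model`, `modes` (free
#'   conformer's network and modes used for generation).
#' @export
synth_fixture <- function(spec, r_c = 12) {
  base <- make_structure(spec)
  free <- base$structure
  contacts <- suppressWarnings(detect_contacts(free, NULL, r_c))
  springs <- assign_force_constants(contacts)
  model <- build_hessian(free, springs, 1, r_c)
  modes <- enm_modes(model)
  bound <- make_bound(free, modes, spec$planted_modes, spec$amplitudes,
                      seed = spec$seed + 101L)
  free$bfactor <- make_bfactors(modes, spec$bfactor_noise_sd,
                                seed = spec$seed + 211L)
  bound_model <- build_enm(bound, NULL, r_c)
  bound$bfactor <- make_bfactors(enm_modes(bound_model),
                                 spec$bfactor_noise_sd,
                                 seed = spec$seed + 307L)
  base$atoms$b <- free$bfactor[match(base$atoms$resno, free$resno)]
  list(spec = spec, free = free, bound = bound, atoms = base$atoms,
       hinge = base$hinge, model = model, modes = modes)
}

#' Write fixture files in standard formats
#'
#' Writes free and bound conformers as PDB (C-alpha plus the pseudo full
#' atoms for the free conformer) and, when supplied, the MSA as aligned
#' FASTA, so fixtures are consumed through the same readers as real data.
#'
#' @param fix output of [synth_fixture()].
#' @param dir output directory (created if needed).
#' @param msa optional `alignment_set` to write alongside.
#' @return named character vector of written paths.
#' @export
write_fixture <- function(fix, dir, msa = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(free = file.path(dir, "free.pdb"),
             bound = file.path(dir, "bound.pdb"))
  write_atoms_pdb(fix$atoms, paths["free"])
  bound_atoms <- fix$atoms
  # move the pseudo atoms rigidly with their residue's C-alpha
  shift <- fix$bound$xyz[match(bound_atoms$resno, fix$bound$resno), ] -
    fix$free$xyz[match(bound_atoms$resno, fix$free$resno), ]
  bound_atoms$x <- bound_atoms$x + shift[, 1]
  bound_atoms$y <- bound_atoms$y + shift[, 2]
  bound_atoms$z <- bound_atoms$z + shift[, 3]
  bound_atoms$b <- fix$bound$bfactor[match(bound_atoms$resno,
                                           fix$bound$resno)]
  write_atoms_pdb(bound_atoms, paths["bound"])
  if (!is.null(msa)) {
    paths <- c(paths, msa = file.path(dir, "alignment.fasta"))
    write_msa_fasta(msa, paths["msa"])
  }
  paths
}

# write a full-atom table through bio3d
write_atoms_pdb <- function(atoms, file) {
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(cbind(atoms$x, atoms$y, atoms$z))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = atoms$chain, o = atoms$o, b = atoms$b)
  invisible(file)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `alignment_set`.
#' @param file output path.
#' @export
write_msa_fasta <- function(aln, file) {
  lines <- as.vector(rbind(paste0(">", aln$ids),
                           apply(aln$ali, 1, paste, collapse = "")))
  writeLines(lines, file)
  invisible(file)
}
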