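# Shared in-code fixtures and independent oracles.

# --- tiny structures ------------------------------------------------------

# equilateral triangle in the xy-plane, side 3.8 A
triangle_structure <- function() {
  s <- 3.8
  xyz <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  ca_structure(chain = rep("A", 3), resno = 1:3, icode = rep("", 3),
               aa = c("ALA", "GLY", "SER"), xyz = xyz,
               bfactor = c(1, 1, 1), name = "triangle")
}

all_pair_springs <- function(n, k = 1) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], k = k)
}

# compact random bead cloud; uses the package generator where it applies and
# a direct seeded sphere packing for the tiny oracle networks (n < 10)
random_chain_structure <- function(n, seed = 1) {
  if (n >= 10) {
    spec <- fixture_spec(seed = seed, topology = "random-globule", n = n)
    return(make_structure(spec)$structure)
  }
  set.seed(seed)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  for (i in seq_len(n)[-1]) {
    repeat {
      cand <- runif(3, -6, 6)
      dd <- sqrt(rowSums((xyz[seq_len(i - 1), , drop = FALSE] -
                            matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (all(dd >= 3.5)) break
    }
    xyz[i, ] <- cand
  }
  ca_structure(chain = rep("A", n), resno = seq_len(n), icode = rep("", n),
               aa = rep("ALA", n), xyz = xyz, bfactor = rep(1, n),
               name = "tiny-cloud")
}

# --- oracles --------------------------------------------------------------

# pairwise harmonic energy of a spring network at coordinates x (flat 3N)
network_energy <- function(x, x0, springs) {
  xm <- matrix(x, ncol = 3, byrow = TRUE)
  x0m <- matrix(x0, ncol = 3, byrow = TRUE)
  e <- 0
  for (s in seq_len(nrow(springs))) {
    i <- springs$i[s]; j <- springs$j[s]
    d <- sqrt(sum((xm[i, ] - xm[j, ])^2))
    d0 <- sqrt(sum((x0m[i, ] - x0m[j, ])^2))
    e <- e + 0.5 * springs$k[s] * (d - d0)^2
  }
  e
}

# central finite-difference Hessian of the network energy at equilibrium
fd_hessian <- function(structure, springs, h = 1e-4) {
  x0 <- as.vector(t(structure$xyz))
  m <- length(x0)
  H <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      xpp <- x0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
      xpm <- x0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
      xmp <- x0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
      xmm <- x0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
      H[a, b] <- (network_energy(xpp, x0, springs) -
                    network_energy(xpm, x0, springs) -
                    network_energy(xmp, x0, springs) +
                    network_energy(xmm, x0, springs)) / (4 * h * h)
      H[b, a] <- H[a, b]
    }
  }
  H
}

# closed-form least-squares superposition via Horn's quaternion method;
# returns the minimal RMSD of mobile onto fixed
quaternion_rmsd <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(fixed, 2, cf); B <- sweep(mobile, 2, cm)
  S <- t(B) %*% A
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  mu <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * mu) / nrow(fixed)
  sqrt(max(0, msd))
}

# random rotation matrix (seeded by the caller's RNG state)
random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3)))
}

# random set of m orthonormal vectors of length d
random_orthonormal <- function(d, m) {
  qr.Q(qr(matrix(rnorm(d * m), d, m)))
}

# best assignment by exhaustive enumeration (maximize sum of squared
# overlaps); rows = unperturbed, cols = perturbed
exhaustive_assignment <- function(O2) {
  n <- nrow(O2)
  perms <- permute_all(seq_len(n))
  best <- NULL; best_val <- -Inf
  for (p in perms) {
    val <- sum(O2[cbind(seq_len(n), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(perm = best, value = best_val)
}

permute_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permute_all(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# --- PDB text fixtures ----------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resname, chain, resno, x, y, z, occ, b)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# three-residue toy PDB with B-factors 10/20/30 and a resolution record
toy_pdb_3res <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 1.4, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0, 0, 0, b = 10),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0, b = 20),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0, b = 30))
  write_toy_pdb(path, lines)
}

# scan one fixture at w = 0 and return scores plus ground truth
scan_fixture <- function(seed, n = 60, delta = 0.05) {
  fix <- synth_fixture(fixture_spec(seed = seed, n = n))
  pair <- pair_and_superpose(fix$free, fix$bound)
  v <- weighted_difference(pair, fix$free$bfactor, fix$bound$bfactor, w = 0)
  S <- select_subspace(expand_on_modes(v, fix$modes), fix$modes)
  scores <- scan_all_residues(fix$model, fix$modes, S, delta)
  list(fix = fix, pair = pair, S = S, scores = scores)
}
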