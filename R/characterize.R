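# Characterization analyses of key positions: incidence ratios, SSE
# geometry, active-site distances, accessibility and contact correlates.

# Shared incidence kernel: relative frequency of each category among key
# residues divided by its relative frequency among the rest. Cells whose
# denominator frequency is zero are NA (undefined), never numbers.
incidence_table <- function(is_key, category, levels) {
  if (!any(is_key)) stop("empty key-position set")
  out <- vapply(levels, function(lv) {
    fk <- mean(category[is_key] == lv)
    fr <- mean(category[!is_key] == lv)
    if (!any(!is_key) || fr == 0) return(NA_real_)
    fk / fr
  }, numeric(1))
  data.frame(level = levels, incidence = out,
             n_key = vapply(levels, function(lv) sum(category[is_key] == lv),
                            integer(1)),
             n_rest = vapply(levels, function(lv) sum(category[!is_key] == lv),
                             integer(1)),
             stringsAsFactors = FALSE)
}

#' Amino-acid incidence among key positions
#'
#' Ratio of each amino-acid type's frequency among key residues to its
#' frequency among the remaining residues; values above 1 mark types
#' over-represented at key positions.
#'
#' @param keys a `key_positions` set.
#' @param structure the scanned [ca_structure()].
#' @return data.frame `level` (three-letter type), `incidence`, `n_key`,
#'   `n_rest`.
#' @export
incidence_amino_acid <- function(keys, structure) {
  is_key <- seq_along(structure$resno) %in% keys$indices
  incidence_table(is_key, structure$aa, sort(unique(structure$aa)))
}

#' Secondary-structure incidence among key positions
#'
#' @param keys a `key_positions` set.
#' @param sse per-residue 8-letter secondary-structure vector (H, B, E, G,
#'   I, T, S, N).
#' @return data.frame as in [incidence_amino_acid()].
#' @export
incidence_sse <- function(keys, sse) {
  is_key <- seq_along(sse) %in% keys$indices
  incidence_table(is_key, sse, c("H", "B", "E", "G", "I", "T", "S", "N"))
}

#' Contiguous secondary-structure segments
#'
#' @param sse per-residue SSE letters.
#' @return data.frame `type`, `start`, `end` (residue indices), one row per
#'   run.
#' @export
sse_segments <- function(sse) {
  r <- rle(sse)
  end <- cumsum(r$lengths)
  data.frame(type = r$values, start = end - r$lengths + 1L, end = end,
             stringsAsFactors = FALSE)
}

# residues with a non-covalent contact to a different segment of type Y
inter_sse_contact_flags <- function(sse, contacts, y) {
  seg <- sse_segments(sse)
  seg_of <- rep(seq_len(nrow(seg)), seg$end - seg$start + 1L)
  e <- contacts$edges[contacts$edges$class != "covalent", , drop = FALSE]
  e <- e[seg_of[e$i] != seg_of[e$j], , drop = FALSE]
  flag <- logical(length(sse))
  hit_i <- sse[e$j] == y
  hit_j <- sse[e$i] == y
  flag[e$i[hit_i]] <- TRUE
  flag[e$j[hit_j]] <- TRUE
  flag
}

#' Inter-SSE contact incidence among key positions
#'
#' For residues on elements of type X (strand E or helix H): the frequency
#' with which key residues on X carry a contact to a residue on a different
#' element of type Y, relative to the same frequency among non-key residues
#' on X. High values mark key positions acting as pivots bridging regular
#' elements.
#'
#' @param keys a `key_positions` set.
#' @param sse per-residue SSE letters.
#' @param contacts a `contact_graph`.
#' @return data.frame `x`, `y`, `incidence`, `n_key`, `n_rest`; `NA` where a
#'   denominator is empty.
#' @export
incidence_inter_sse <- function(keys, sse, contacts) {
  is_key <- seq_along(sse) %in% keys$indices
  ys <- c("E", "B", "H", "G", "S", "T", "N", "I")
  rows <- list()
  for (x in c("E", "H")) {
    on_x <- sse == x
    for (y in ys) {
      flag <- inter_sse_contact_flags(sse, contacts, y)
      nk <- sum(on_x & is_key)
      nr <- sum(on_x & !is_key)
      inc <- if (nk == 0 || nr == 0) NA_real_ else {
        fr <- mean(flag[on_x & !is_key])
        if (fr == 0) NA_real_ else mean(flag[on_x & is_key]) / fr
      }
      rows[[length(rows) + 1L]] <-
        data.frame(x = x, y = y, incidence = inc,
                   n_key = sum(flag & on_x & is_key),
                   n_rest = sum(flag & on_x & !is_key),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# principal axes (columns, descending spread) of a segment's C-alpha cloud
gyration_axes <- function(xyz) {
  if (nrow(xyz) < 3L) stop("segment shorter than 3 residues")
  x <- scale(xyz, scale = FALSE)
  eig <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  if (eig$values[2] < 1e-6 * max(eig$values[1], 1e-300))
    stop("degenerate gyration tensor (collinear segment)")
  eig$vectors
}

# angle between two axes folded to [0, 90] degrees (sign-disambiguated)
axis_angle <- function(a, b) {
  d <- min(1, abs(sum(a * b) / sqrt(sum(a^2) * sum(b^2))))
  acos(d) * 180 / pi
}

#' Change in relative orientation of two SSE segments upon binding
#'
#' Computes, for each of the three principal inertial axes of the C-alpha
#' gyration tensor, the angle between segment X's and segment Y's axis in
#' the free and in the bound conformer; the largest absolute angle change
#' over the three axes is returned. Axes are sign-disambiguated so all
#' angles lie in \[0, 90\] degrees; the measure is invariant to rigid
#' transforms of either conformer.
#'
#' @param pair a `conformer_pair`.
#' @param seg_x,seg_y integer index vectors of the two segments (free-
#'   structure residue indices; both must be mapped in the bound conformer
#'   and span at least 3 residues).
#' @return list with `delta_theta` (degrees), `theta_free`, `theta_bound`
#'   (length-3 vectors, one angle per principal axis).
#' @export
inter_sse_angle_change <- function(pair, seg_x, seg_y) {
  map <- pair$mapping
  to_bound <- function(idx) {
    bi <- map[match(idx, map[, "free"]), "bound"]
    if (anyNA(bi)) stop("segment residue(s) unmapped in bound conformer")
    bi
  }
  ax_f_x <- gyration_axes(pair$free$xyz[seg_x, , drop = FALSE])
  ax_f_y <- gyration_axes(pair$free$xyz[seg_y, , drop = FALSE])
  ax_b_x <- gyration_axes(pair$bound$xyz[to_bound(seg_x), , drop = FALSE])
  ax_b_y <- gyration_axes(pair$bound$xyz[to_bound(seg_y), , drop = FALSE])
  th_f <- vapply(1:3, function(a) axis_angle(ax_f_x[, a], ax_f_y[, a]),
                 numeric(1))
  th_b <- vapply(1:3, function(a) axis_angle(ax_b_x[, a], ax_b_y[, a]),
                 numeric(1))
  list(delta_theta = max(abs(th_f - th_b)),
       theta_free = th_f, theta_bound = th_b)
}

#' Minimum distance of each residue to an active-site center of mass
#'
#' Each site's center is the centroid of its member C-alphas; each residue's
#' distance is the minimum over sites.
#'
#' @param structure a [ca_structure()].
#' @param sites list of integer residue-index vectors, one per site.
#' @return numeric vector of distances in Angstrom.
#' @export
active_site_distance <- function(structure, sites) {
  if (!length(sites) || any(!lengths(sites)))
    stop("each site needs at least one residue")
  dmat <- vapply(sites, function(s) {
    ctr <- colMeans(structure$xyz[s, , drop = FALSE])
    sqrt(rowSums((structure$xyz - matrix(ctr, nrow(structure$xyz), 3,
                                         byrow = TRUE))^2))
  }, numeric(nrow(structure$xyz)))
  apply(as.matrix(dmat), 1, min)
}

#' Correlates of the perturbation score
#'
#' Pearson and Spearman correlations (with p-values) of a score profile
#' against each supplied per-residue covariate (RSA, contact counts,
#' per-residue RMSD, active-site distance, ...).
#'
#' @param score numeric per-residue score (e.g. ZscoreS or Zscore_evol).
#' @param covariates named list of numeric per-residue vectors.
#' @return data.frame `covariate`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
residue_correlates <- function(score, covariates) {
  stopifnot(is.list(covariates), length(names(covariates)) ==
              length(covariates))
  rows <- lapply(names(covariates), function(nm) {
    y <- covariates[[nm]]
    ok <- is.finite(score) & is.finite(y)
    if (sum(ok) < 3L || sd(score[ok]) < 1e-12 || sd(y[ok]) < 1e-12)
      stop("constant or insufficient data for covariate '", nm, "'")
    pe <- cor.test(score[ok], y[ok], method = "pearson")
    sp <- suppressWarnings(cor.test(score[ok], y[ok], method = "spearman",
                                    exact = FALSE))
    data.frame(covariate = nm, pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value, spearman_rho = unname(sp$estimate),
               spearman_p = sp$p.value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heavy-atom inter-residue contact counts
#'
#' Number of distinct residues j with any heavy-atom pair within `cutoff` of
#' residue i's heavy atoms, excluding sequence neighbors (|i - j| >= 2).
#'
#' @param full_atom_path full-atom PDB path.
#' @param structure the matching [ca_structure()].
#' @param cutoff distance cutoff in Angstrom (default 5).
#' @return integer vector of per-residue counts.
#' @export
contact_counts <- function(full_atom_path, structure, cutoff = 5) {
  at <- read_atom_table(full_atom_path, unique(structure$chain))
  at <- at[at$elesy != "H" | is.na(at$elesy), , drop = FALSE]
  keys <- residue_keys(structure$chain, structure$resno, structure$icode)
  ridx <- match(residue_keys(at$chain, at$resno, at$insert), keys)
  keep <- !is.na(ridx)
  at <- at[keep, , drop = FALSE]; ridx <- ridx[keep]
  axyz <- cbind(at$x, at$y, at$z)
  D <- as.matrix(dist(axyz))
  hit <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  pi_ <- ridx[hit[, 1]]; pj <- ridx[hit[, 2]]
  # sequence separation in residue numbers (chain breaks always count)
  sep <- abs(structure$resno[pi_] - structure$resno[pj])
  sep[structure$chain[pi_] != structure$chain[pj]] <- Inf
  ok <- sep >= 2
  pairs <- unique(cbind(pmin(pi_[ok], pj[ok]), pmax(pi_[ok], pj[ok])))
  counts <- integer(length(structure$resno))
  if (nrow(pairs)) {
    t1 <- table(factor(pairs[, 1], levels = seq_along(counts)))
    t2 <- table(factor(pairs[, 2], levels = seq_along(counts)))
    counts <- as.integer(t1 + t2)
  }
  counts
}

# Maximum accessibility of residue X in an extended ALA-X-ALA tripeptide
# (theoretical values of Tien et al. 2013, PLoS ONE 8:e80635), Angstrom^2.
MAX_ACC <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

#' Relative solvent accessibility from DSSP accessibilities
#'
#' RSA_i = 100 * ACC_i / maxACC(aa_i), with the embedded extended
#' ALA-X-ALA tripeptide reference maxima. Residues of unknown type get `NA`
#' with a warning. A residue is flagged exposed when RSA >= 10%.
#'
#' @param dssp data.frame from [read_dssp()] (columns `aa`, `acc`).
#' @return data.frame `rsa` (percent) and `exposed` (logical).
#' @export
rsa_from_dssp <- function(dssp) {
  mx <- MAX_ACC[dssp$aa]
  if (anyNA(mx))
    warning(sum(is.na(mx)), " residue(s) of unknown type skipped")
  rsa <- 100 * dssp$acc / unname(mx)
  data.frame(rsa = rsa, exposed = rsa >= 10)
}

#' Approximate secondary structure from C-alpha geometry
#'
#' Coarse fallback assigner for synthetic fixtures where no DSSP output
#' exists: residues matching the characteristic C-alpha distance pattern of
#' an alpha-helix (d(i,i+3) ~ 5.3, d(i,i+4) ~ 6.2 A) are labelled H, an
#' extended strand pattern (d(i,i+2) ~ 6.7 A) E, everything else N. This is
#' an approximation, not a DSSP replacement.
#'
#' @param structure a [ca_structure()].
#' @return character vector of per-residue letters in {H, E, N}.
#' @export
approximate_sse <- function(structure) {
  xyz <- structure$xyz
  n <- nrow(xyz)
  d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  sse <- rep("N", n)
  for (i in seq_len(n)) {
    if (i + 4 <= n) {
      d3 <- d(i, i + 3); d4 <- d(i, i + 4)
      if (d3 > 4.3 && d3 < 6.2 && d4 > 5.0 && d4 < 7.2) {
        sse[i:(i + 4)] <- "H"
        next
      }
    }
    if (i + 2 <= n && sse[i] == "N") {
      d2 <- d(i, i + 2)
      if (d2 > 6.1 && d2 < 7.4) sse[i:(i + 2)] <- "E"
    }
  }
  sse
}
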