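keyset <- function(idx, n) {
  structure(list(indices = sort(idx), fraction = length(idx) / n,
                 count = length(idx)), class = "key_positions")
}

test_that("amino-acid incidence matches hand arithmetic", {
  st <- random_chain_structure(40, seed = 101)
  st$aa <- rep(c("ALA", "VAL", "CYS", "GLY"), each = 10)
  keys <- keyset(c(21, 22, 1, 35), 40)   # 2 CYS, 1 ALA, 1 GLY
  tab <- incidence_amino_acid(keys, st)
  # hand counts: keys 4 total, rest 36
  # CYS: (2/4) / (8/36) = 2.25; ALA: (1/4)/(9/36) = 1; VAL: 0/... = 0
  expect_equal(tab$incidence[tab$level == "CYS"], 2.25)
  expect_equal(tab$incidence[tab$level == "ALA"], 1)
  expect_equal(tab$incidence[tab$level == "VAL"], 0)

  # an amino acid absent from the rest gives an undefined cell
  st2 <- st
  st2$aa[c(21, 22)] <- "TRP"
  st2$aa[23:30] <- "ALA"
  keys2 <- keyset(c(21, 22), 40)         # all TRP are keys
  tab2 <- incidence_amino_acid(keys2, st2)
  expect_true(is.na(tab2$incidence[tab2$level == "TRP"]))
})

test_that("uniform random key sampling gives incidence near one", {
  set.seed(111)
  st <- random_chain_structure(60, seed = 103)
  st$aa <- sample(c("ALA", "VAL", "LEU"), 60, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  vals <- replicate(1000, {
    keys <- keyset(sample(60, 12), 60)
    incidence_amino_acid(keys, st)$incidence[1]   # ALA cell
  })
  expect_equal(mean(vals, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("SSE incidence reflects placement of key positions", {
  sse <- rep(c("H", "E", "T", "N"), each = 10)
  keys <- keyset(c(11, 12, 13), 40)      # all keys on strands
  tab <- incidence_sse(keys, sse)
  expect_gt(tab$incidence[tab$level == "E"], 1)
  expect_equal(tab$incidence[tab$level == "H"], 0)
  expect_true(is.na(tab$incidence[tab$level == "I"]))  # letter absent

  # uniform placement: one key per stratum of equal size
  keys_u <- keyset(c(1, 11, 21, 31), 40)
  tab_u <- incidence_sse(keys_u, sse)
  expect_equal(tab_u$incidence[tab_u$level %in% c("H", "E", "T", "N")],
               rep(1, 4))
})

test_that("inter-SSE incidence detects bridging key residues", {
  # residues 1-5 strand E, 6-10 helix H; contact 3-8 bridges them
  sse <- c(rep("E", 5), rep("H", 5))
  edges <- data.frame(i = c(1, 3, 6), j = c(2, 8, 7),
                      class = c("covalent", "generic", "covalent"),
                      d = c(3.8, 6, 3.8))
  cg <- structure(list(edges = edges, r_c = 10, n = 10),
                  class = "contact_graph")
  keys <- keyset(3L, 10)
  tab <- incidence_inter_sse(keys, sse, cg)
  eh <- tab[tab$x == "E" & tab$y == "H", ]
  # the only key on E bridges to H; no non-key E residue does
  expect_true(is.na(eh$incidence) || eh$incidence > 1)
  expect_equal(eh$n_key, 1L)
  expect_equal(eh$n_rest, 0L)

  # no inter-SSE contacts at all: cells undefined
  cg0 <- structure(list(edges = edges[edges$class == "covalent", ],
                        r_c = 10, n = 10), class = "contact_graph")
  tab0 <- incidence_inter_sse(keys, sse, cg0)
  expect_equal(tab0$n_key, rep(0L, nrow(tab0)))
})

test_that("inter-SSE incidence matches hand counts on a larger toy", {
  sse <- c(rep("E", 6), rep("T", 2), rep("H", 6))
  # E residues 1..6; keys = 1, 2; contacts to H: 1-10, 2-11, 3-12
  edges <- data.frame(i = c(1, 2, 3), j = c(10, 11, 12),
                      class = "generic", d = 6)
  cg <- structure(list(edges = edges, r_c = 10, n = 14),
                  class = "contact_graph")
  keys <- keyset(c(1L, 2L), 14)
  tab <- incidence_inter_sse(keys, sse, cg)
  eh <- tab[tab$x == "E" & tab$y == "H", ]
  # keys on E: 2/2 bridge; rest on E: 1/4 bridge -> incidence 4
  expect_equal(eh$incidence, (2 / 2) / (1 / 4))
})

helix_structure <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1], 2.3 * sin(ang) + origin[2],
        1.5 * i + origin[3])
}

rotation_about <- function(axis, deg) {
  ax <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

test_that("inter-SSE angle change recovers a constructed rotation", {
  xa <- helix_structure(12)
  xb <- helix_structure(12, origin = c(15, 0, 0))
  xyz_free <- rbind(xa, xb)
  st_free <- ca_structure(chain = rep("A", 24), resno = 1:24,
                          icode = rep("", 24), aa = rep("ALA", 24),
                          xyz = xyz_free, bfactor = rep(1, 24))
  # rotate helix B rigidly by 20 degrees about x (normal to its axis z)
  R <- rotation_about(c(1, 0, 0), 20)
  cb <- colMeans(xb)
  xb_rot <- sweep(sweep(xb, 2, cb) %*% t(R), 2, -cb)
  st_bound <- st_free
  st_bound$xyz <- rbind(xa, xb_rot)
  pair <- pair_and_superpose(st_free, st_bound)
  res <- inter_sse_angle_change(pair, 1:12, 13:24)
  expect_equal(res$delta_theta, 20, tolerance = 0.5)

  # identical conformers: no angle change
  pair0 <- pair_and_superpose(st_free, st_free)
  expect_equal(inter_sse_angle_change(pair0, 1:12, 13:24)$delta_theta, 0,
               tolerance = 1e-6)

  # global rigid transform of the bound conformer leaves delta unchanged
  set.seed(121)
  Rg <- random_rotation()
  st_b2 <- st_bound
  st_b2$xyz <- sweep(st_bound$xyz %*% t(Rg), 2, c(-30, 4, 12))
  pair2 <- pair_and_superpose(st_free, st_b2)
  res2 <- inter_sse_angle_change(pair2, 1:12, 13:24)
  expect_equal(res2$delta_theta, res$delta_theta, tolerance = 1e-6)

  # symmetric in segment order
  res3 <- inter_sse_angle_change(pair, 13:24, 1:12)
  expect_equal(res3$delta_theta, res$delta_theta, tolerance = 1e-9)

  expect_error(inter_sse_angle_change(pair, 1:2, 13:24), "3 residues")
})

test_that("active-site distances take the minimum over site centroids", {
  st <- random_chain_structure(30, seed = 107)
  sites <- list(c(1, 2, 3), c(20, 21))
  d <- active_site_distance(st, sites)
  # loop oracle
  c1 <- colMeans(st$xyz[1:3, ]); c2 <- colMeans(st$xyz[20:21, ])
  or <- vapply(1:30, function(i)
    min(sqrt(sum((st$xyz[i, ] - c1)^2)), sqrt(sum((st$xyz[i, ] - c2)^2))),
    numeric(1))
  expect_equal(d, or, tolerance = 1e-12)

  # a single-residue site measures distance to that C-alpha
  d1 <- active_site_distance(st, list(5L))
  expect_equal(d1[5], 0)
  expect_equal(d1[6], sqrt(sum((st$xyz[6, ] - st$xyz[5, ])^2)))

  # triangle inequality against inter-residue distances
  D <- as.matrix(dist(st$xyz))
  expect_true(all(d <= D[, 5] + d[5] + 1e-9))

  expect_error(active_site_distance(st, list()), "at least one")
})

test_that("score correlates recover a planted linear relation", {
  set.seed(131)
  score <- rnorm(80)
  rsa <- 10 * score + rnorm(80, 0, 3)       # positive relation
  contacts <- -4 * score + rnorm(80, 0, 2)  # negative relation
  tab <- residue_correlates(score, list(rsa = rsa, contacts = contacts))
  expect_gt(tab$pearson_r[tab$covariate == "rsa"], 0.5)
  expect_lt(tab$pearson_r[tab$covariate == "contacts"], -0.5)
  expect_true(all(tab$pearson_p < 0.01))

  tab_id <- residue_correlates(score, list(self = score,
                                           anti = -score))
  expect_equal(tab_id$pearson_r[1], 1, tolerance = 1e-12)
  expect_equal(tab_id$spearman_rho[2], -1, tolerance = 1e-12)
})

test_that("heavy-atom contact counts match an all-pairs loop", {
  fix <- make_structure(fixture_spec(seed = 109, n = 20))
  dir <- tempfile(); dir.create(dir)
  path <- file.path(dir, "fa.pdb")
  confkeys:::write_atoms_pdb(fix$atoms, path)
  counts <- contact_counts(path, fix$structure, cutoff = 5)
  at <- fix$atoms
  D <- as.matrix(dist(cbind(at$x, at$y, at$z)))
  or <- integer(20)
  for (i in 1:20) {
    partners <- unique(at$resno[apply(
      D[at$resno == i, , drop = FALSE] <= 5, 2, any)])
    or[i] <- sum(abs(partners - i) >= 2)
  }
  expect_equal(counts, or)

  # two residues with atoms at 4 A count each other once
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "ALA", "A", 3, 4, 0, 0),
             pdb_atom_line(3, "CA", "ALA", "A", 5, 50, 0, 0))
  p2 <- write_toy_pdb(tempfile(fileext = ".pdb"), lines)
  st2 <- read_ca_structure(p2)
  expect_equal(contact_counts(p2, st2, 5), c(1L, 1L, 0L))
})

test_that("relative accessibility uses the tripeptide reference maxima", {
  dssp <- data.frame(aa = c("G", "G", "A", "W"),
                     acc = c(104, 0, 129, 142.5))
  rsa <- rsa_from_dssp(dssp)
  expect_equal(rsa$rsa, c(100, 0, 100, 50))
  expect_equal(rsa$exposed, c(TRUE, FALSE, TRUE, TRUE))
  expect_warning(rsa_from_dssp(data.frame(aa = "X", acc = 10)), "unknown")
})

test_that("the fallback SSE assigner labels an ideal helix", {
  xyz <- helix_structure(15)
  st <- ca_structure(chain = rep("A", 15), resno = 1:15,
                     icode = rep("", 15), aa = rep("ALA", 15),
                     xyz = xyz, bfactor = rep(1, 15))
  sse <- approximate_sse(st)
  expect_gt(mean(sse == "H"), 0.7)
})
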