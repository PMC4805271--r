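test_that("PDB reading copies residue records and resolution faithfully", {
  path <- toy_pdb_3res()
  st <- read_ca_structure(path, "A")
  expect_s3_class(st, "ca_structure")
  expect_length(st, 3)
  expect_equal(st$bfactor, c(10, 20, 30))
  expect_equal(st$aa, c("ALA", "GLY", "SER"))
  expect_equal(st$xyz[, 1], c(0, 3.8, 7.6))
  expect_equal(st$resolution, 1.9)
})

test_that("alternate locations resolve by occupancy, then altloc letter", {
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, b = 5,
                  alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.5, 0, 0, occ = 0.6, b = 7,
                  alt = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0, b = 20),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0, b = 30)))
  st <- read_ca_structure(path, "A")
  expect_equal(st$bfactor[1], 7)        # higher occupancy wins
  expect_equal(st$xyz[1, 1], 0.5)

  path2 <- write_toy_pdb(tempfile(fileext = ".pdb"), c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.5, b = 5,
                  alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.5, 0, 0, occ = 0.5, b = 7,
                  alt = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0, b = 20),
    pdb_atom_line(4, "CA", "SER", "A", 3, 7.6, 0, 0, b = 30)))
  st2 <- read_ca_structure(path2, "A")
  expect_equal(st2$bfactor[1], 5)       # tie -> altloc 'A'
})

test_that("files without usable records are rejected", {
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), empty)
  expect_error(read_ca_structure(empty), "ATOM")
  path <- toy_pdb_3res()
  expect_error(read_ca_structure(path, chain = "Z"), "chain")
})

test_that("superposition recovers rigid transforms exactly", {
  st <- random_chain_structure(30, seed = 3)
  shifted <- st
  shifted$xyz <- sweep(st$xyz, 2, c(-5, 0, 0))   # translation by (5,0,0)
  pair <- pair_and_superpose(st, shifted)
  expect_lt(pair$rmsd, 1e-9)

  rot <- st
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  rot$xyz <- st$xyz %*% t(Rz)
  pair2 <- pair_and_superpose(st, rot)
  expect_lt(pair2$rmsd, 1e-9)

  # idempotence: re-superposing changes nothing
  pair3 <- pair_and_superpose(pair2$free, pair2$bound)
  expect_lt(abs(pair3$rmsd - pair2$rmsd), 1e-9)
})

test_that("per-residue and global RMSD match the quaternion oracle", {
  st <- random_chain_structure(100, seed = 11)
  moved <- st
  moved$xyz[42, ] <- moved$xyz[42, ] + c(1, 0, 0)
  # apply an arbitrary rigid transform on top
  set.seed(5)
  R <- random_rotation()
  moved$xyz <- sweep(moved$xyz %*% t(R), 2, -c(3, -8, 2))
  pair <- pair_and_superpose(st, moved)
  oracle <- quaternion_rmsd(st$xyz, moved$xyz)
  expect_equal(pair$rmsd, oracle, tolerance = 1e-8)
  expect_equal(pair$rmsd_i[42], max(pair$rmsd_i), tolerance = 1e-8)
  expect_gt(pair$rmsd_i[42], 0.9)
  expect_lt(median(pair$rmsd_i), 0.1)

  # RMSD invariant to a rigid transform of the free input too
  st2 <- st
  set.seed(6)
  R2 <- random_rotation()
  st2$xyz <- sweep(st$xyz %*% t(R2), 2, c(1, 2, 3))
  pair2 <- pair_and_superpose(st2, moved)
  expect_equal(pair2$rmsd, oracle, tolerance = 1e-8)
})

test_that("superposition validates its inputs", {
  st <- triangle_structure()
  other <- st
  other$aa <- c("ALA", "ALA", "SER")
  expect_error(pair_and_superpose(st, other), "mismatch")
  lin <- ca_structure(chain = rep("A", 3), resno = 1:3, icode = rep("", 3),
                      aa = rep("GLY", 3),
                      xyz = cbind(c(0, 3.8, 7.6), 0, 0),
                      bfactor = rep(1, 3))
  expect_error(pair_and_superpose(lin, lin), "collinear")
})

test_that("contact classes follow the stated geometric rules", {
  # 3 collinear residues, no side chains, generous cutoff
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
             pdb_atom_line(3, "CA", "ALA", "A", 3, 7.6, 0, 0))
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), lines)
  st <- read_ca_structure(path)
  cg <- detect_contacts(st, path, r_c = 12)
  e <- cg$edges
  expect_setequal(paste(e$i, e$j, e$class),
                  c("1 2 covalent", "2 3 covalent", "1 3 generic"))

  # CYS pair with SG-SG at 2.0 A -> disulfide
  lines2 <- c(pdb_atom_line(1, "CA", "CYS", "A", 1, 0, 0, 0),
              pdb_atom_line(2, "SG", "CYS", "A", 1, 2.0, 0, 0),
              pdb_atom_line(3, "CA", "ALA", "A", 2, 3.8, 0, 0),
              pdb_atom_line(4, "CA", "CYS", "A", 3, 6.0, 0, 0),
              pdb_atom_line(5, "SG", "CYS", "A", 3, 4.0, 0, 0))
  path2 <- write_toy_pdb(tempfile(fileext = ".pdb"), lines2)
  st2 <- read_ca_structure(path2)
  cg2 <- detect_contacts(st2, path2, r_c = 12)
  expect_equal(cg2$edges$class[cg2$edges$i == 1 & cg2$edges$j == 3],
               "disulfide")

  # ASP Od - LYS Nz at 3.2 A -> hbond/salt-bridge class
  lines3 <- c(pdb_atom_line(1, "CA", "ASP", "A", 1, 0, 0, 0),
              pdb_atom_line(2, "OD1", "ASP", "A", 1, 1.5, 0, 0),
              pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
              pdb_atom_line(4, "CA", "LYS", "A", 3, 7.0, 0, 0),
              pdb_atom_line(5, "NZ", "LYS", "A", 3, 4.7, 0, 0))
  path3 <- write_toy_pdb(tempfile(fileext = ".pdb"), lines3)
  st3 <- read_ca_structure(path3)
  cg3 <- detect_contacts(st3, path3, r_c = 12)
  expect_equal(cg3$edges$class[cg3$edges$i == 1 & cg3$edges$j == 3],
               "hbond")

  # degraded mode without full atoms: covalent + generic only, with warning
  expect_warning(cg4 <- detect_contacts(st3, NULL, r_c = 12), "full-atom")
  expect_setequal(unique(cg4$edges$class), c("covalent", "generic"))
})

test_that("contact graphs are symmetric-canonical and order-independent", {
  st <- random_chain_structure(25, seed = 9)
  cg <- suppressWarnings(detect_contacts(st, NULL, r_c = 10))
  e <- cg$edges
  expect_true(all(e$i < e$j))
  expect_false(any(duplicated(paste(e$i, e$j))))
  expect_true(all(e$d[e$class == "generic"] <= 10))
})

test_that("QC report applies the curation thresholds", {
  st <- triangle_structure()
  st$resolution <- 3.0
  pair <- pair_and_superpose(st, st)
  qc <- qc_pair(pair, bfactor_spearman = 0.5, msa_coverage = 0.9,
                n_homologs = 150)
  expect_true(attr(qc, "all_pass"))

  qc2 <- qc_pair(pair, bfactor_spearman = 0.35, msa_coverage = 0.9,
                 n_homologs = 150)
  expect_false(qc2$pass[qc2$criterion == "bfactor_spearman"])

  qc3 <- qc_pair(pair, bfactor_spearman = 0.5, msa_coverage = 0.9,
                 n_homologs = 99)
  expect_false(qc3$pass[qc3$criterion == "n_homologs"])

  gappy <- st
  gappy$resno <- c(1L, 2L, 5L)
  pair_g <- pair_and_superpose(gappy, gappy)
  qc4 <- qc_pair(pair_g)
  expect_false(qc4$pass[qc4$criterion == "complete_residues"])
})

test_that("DSSP files and alignments are parsed into usable tables", {
  dssp <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    "    1    1 A A  H           0   0  100",
    "    2    2 A G  E           0   0   52",
    "    3    3 A S              0   0    0"), dssp)
  tab <- read_dssp(dssp)
  expect_equal(tab$sse, c("H", "E", "N"))
  expect_equal(tab$acc, c(100, 52, 0))
  expect_equal(tab$aa, c("A", "G", "S"))

  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">ref", "AGS-", ">h1", "AGSA", ">h2", "--SA"), fa)
  aln <- read_msa(fa)
  expect_equal(dim(aln$ali), c(3L, 4L))
  expect_equal(unname(aln$ali[3, 1]), "-")

  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "ref  AG", "h1   AG", "",
               "ref  S-", "h1   SA", "//"), sto)
  aln2 <- read_msa(sto)
  expect_equal(unname(aln2$ali["ref", ]), c("A", "G", "S", "-"))
  expect_equal(unname(aln2$ali["h1", ]), c("A", "G", "S", "A"))

  st <- triangle_structure()   # ALA GLY SER
  expect_equal(map_alignment(aln, st), 1:3)
  bad <- st
  bad$aa <- c("TRP", "GLY", "SER")
  expect_error(map_alignment(aln, bad), "mismatch")
})
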