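#' Construct a C-alpha structure object
#'
#' Low-level constructor for the per-residue C-alpha representation used
#' throughout the package: one record per residue carrying chain, residue
#' number, insertion code, three-letter amino-acid type, C-alpha coordinates
#' (Angstrom) and the experimental B-factor (Angstrom^2).
#'
#' @param chain character vector of chain identifiers.
#' @param resno integer vector of residue numbers.
#' @param icode insertion codes ("" when absent).
#' @param aa three-letter residue names.
#' @param xyz N x 3 coordinate matrix in Angstrom.
#' @param bfactor non-negative B-factors, one per residue.
#' @param name free-text label.
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @return An object of class `ca_structure`.
#' @export
ca_structure <- function(chain, resno, icode, aa, xyz, bfactor,
                         name = "", resolution = NA_real_) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3, length(chain) == n, length(resno) == n,
            length(icode) == n, length(aa) == n, length(bfactor) == n)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (anyNA(bfactor) || any(bfactor < 0)) stop("B-factors must be >= 0")
  keys <- residue_keys(chain, resno, icode)
  if (anyDuplicated(keys)) stop("duplicate (chain, resno, icode) residue keys")
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 icode = as.character(icode), aa = toupper(aa),
                 xyz = unname(xyz), bfactor = as.numeric(bfactor),
                 name = name, resolution = resolution),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("ca_structure '%s': %d residues, chain(s) %s%s\n",
              x$name, length(x$resno),
              paste(unique(x$chain), collapse = ","),
              if (is.finite(x$resolution))
                sprintf(", resolution %.2f A", x$resolution) else ""))
  invisible(x)
}

#' @export
length.ca_structure <- function(x) length(x$resno)

# Parse "REMARK   2 RESOLUTION.  x.xx ANGSTROMS." from a PDB header.
parse_resolution <- function(path) {
  lines <- tryCatch(readLines(path, n = 500L, warn = FALSE),
                    error = function(e) character())
  hit <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(hit)) return(NA_real_)
  # skip the record name columns so the "2" of REMARK 2 is not matched
  tail <- substring(hit[1], 23)
  m <- regmatches(tail, regexpr("[0-9]+\\.?[0-9]*", tail))
  if (!length(m)) NA_real_ else as.numeric(m)
}

# Resolve alternate locations: keep highest occupancy, tie -> first
# alphabetically (''/NA sorts first, matching the keep-'A' convention).
resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  o <- at$o
  o[is.na(o)] <- 1
  grp <- paste(residue_keys(at$chain, at$resno, at$insert), at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    idx[order(-o[idx], alt[idx])][1L]
  }), use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

# Full-atom table for one chain with altlocs resolved; first model only.
read_atom_table <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  resolve_altloc(at)
}

#' Read one chain of a PDB file as a C-alpha structure
#'
#' Keeps one C-alpha per residue (alternate locations resolved by highest
#' occupancy, ties by altloc letter), preserves file order, and records the
#' experimental B-factor of each C-alpha. Residues lacking a C-alpha atom are
#' excluded with a warning. Only the first model of multi-model files is used.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @return A [ca_structure()].
#' @export
read_ca_structure <- function(path, chain = NULL) {
  at <- read_atom_table(path, chain)
  all_keys <- unique(residue_keys(at$chain, at$resno, at$insert))
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha atoms found in ", path)
  ca_keys <- residue_keys(ca$chain, ca$resno, ca$insert)
  missing <- setdiff(all_keys, ca_keys)
  if (length(missing))
    warning(length(missing), " residue(s) lacking a C-alpha excluded: ",
            paste(utils::head(missing, 5), collapse = ", "))
  if (anyNA(ca$b))
    stop("missing B-factor on C-alpha record(s); experimental B-factors ",
         "are required")
  ca_structure(chain = ca$chain, resno = ca$resno, icode = ca$insert,
               aa = ca$resid, xyz = cbind(ca$x, ca$y, ca$z), bfactor = ca$b,
               name = basename(path), resolution = parse_resolution(path))
}

#' Pair and superpose a ligand-free/ligand-bound conformer pair
#'
#' Maps residues between the two conformers by (chain, residue number,
#' insertion code), requires identical amino-acid types at mapped positions,
#' and rigidly superposes the bound conformer onto the free one by
#' least-squares over the mapped C-alphas. Global and per-residue RMSD are
#' recorded.
#'
#' @param free,bound [ca_structure()] objects of the same protein.
#' @return A `conformer_pair`: list with elements `free`, `bound` (bound
#'   coordinates transformed onto the free frame), `mapping` (two-column
#'   index matrix, free/bound), `rmsd` (global, Angstrom) and `rmsd_i`
#'   (per free residue; `NA` where unmapped).
#' @export
pair_and_superpose <- function(free, bound) {
  kf <- residue_keys(free$chain, free$resno, free$icode)
  kb <- residue_keys(bound$chain, bound$resno, bound$icode)
  common <- intersect(kf, kb)
  fi <- match(common, kf)
  bi <- match(common, kb)
  ord <- order(fi)
  fi <- fi[ord]; bi <- bi[ord]
  if (length(fi) < 3L) stop("fewer than 3 mapped residues")
  mism <- free$aa[fi] != bound$aa[bi]
  if (any(mism))
    stop("amino-acid mismatch at mapped position(s): ",
         paste(utils::head(common[ord][mism], 5), collapse = ", "))
  cf <- scale(free$xyz[fi, , drop = FALSE], scale = FALSE)
  if (qr(cf)$rank < 2L) stop("mapped residues are collinear")
  fitted <- bio3d::fit.xyz(fixed = flatten_xyz(free$xyz),
                           mobile = flatten_xyz(bound$xyz),
                           fixed.inds = bio3d::atom2xyz(fi),
                           mobile.inds = bio3d::atom2xyz(bi))
  bxyz <- unflatten_xyz(as.numeric(fitted))
  d <- sqrt(rowSums((free$xyz[fi, , drop = FALSE] -
                       bxyz[bi, , drop = FALSE])^2))
  rmsd_i <- rep(NA_real_, length(free$resno))
  rmsd_i[fi] <- d
  bound$xyz <- bxyz
  structure(list(free = free, bound = bound,
                 mapping = cbind(free = fi, bound = bi),
                 rmsd = sqrt(mean(d^2)), rmsd_i = rmsd_i),
            class = "conformer_pair")
}

#' @export
print.conformer_pair <- function(x, ...) {
  cat(sprintf("conformer_pair: %d mapped residues, global RMSD %.3f A\n",
              nrow(x$mapping), x$rmsd))
  invisible(x)
}

# side-chain charged-group atoms used for the salt-bridge rule
ACID_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASE_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
               HIS = c("ND1", "NE2"))

#' Detect typed residue contacts
#'
#' Classifies residue pairs for the elastic-network force-constant rules:
#' covalent neighbors (|i-j| = 1 along a chain), disulfides (CYS SG-SG
#' <= 2.5 A), hydrogen bonds or salt bridges (geometric rule: any N/O atom
#' pair <= 3.5 A, or opposite-charge side-chain N/O pair <= 4.0 A), and
#' generic pairs with C-alpha distance <= `r_c`. Precedence: covalent >
#' disulfide > hbond/salt bridge > generic. Without full-atom coordinates the
#' graph degrades to covalent + generic with a warning.
#'
#' @param structure a [ca_structure()].
#' @param full_atom_path optional PDB with full-atom records for the same
#'   chain (may be the same file `structure` was read from).
#' @param r_c cutoff radius in Angstrom for generic contacts.
#' @return A `contact_graph`: list with `edges` (data.frame `i`, `j`,
#'   `class`, `d` with `i < j`; `d` is the C-alpha distance), `r_c`, `n`.
#' @export
detect_contacts <- function(structure, full_atom_path = NULL, r_c = 10) {
  n <- length(structure$resno)
  keys <- residue_keys(structure$chain, structure$resno, structure$icode)
  D <- as.matrix(dist(structure$xyz))
  cls <- matrix("", n, n)

  same_chain <- structure$chain[-n] == structure$chain[-1]
  cov <- cbind(which(same_chain), which(same_chain) + 1L)

  ss <- hb <- matrix(integer(), 0, 2)
  if (!is.null(full_atom_path)) {
    at <- read_atom_table(full_atom_path, unique(structure$chain))
    akey <- residue_keys(at$chain, at$resno, at$insert)
    if (!all(keys %in% akey))
      stop("residue mismatch between C-alpha and full-atom records")
    ridx <- match(akey, keys)        # residue index of each atom (NA = extra)
    keep <- !is.na(ridx)
    at <- at[keep, , drop = FALSE]; ridx <- ridx[keep]
    axyz <- cbind(at$x, at$y, at$z)

    pair_within <- function(sel_a, sel_b, cut) {
      if (!length(sel_a) || !length(sel_b)) return(matrix(integer(), 0, 2))
      dd <- sqrt(outer(rowSums(axyz[sel_a, , drop = FALSE]^2),
                       rowSums(axyz[sel_b, , drop = FALSE]^2), "+") -
                   2 * axyz[sel_a, , drop = FALSE] %*%
                   t(axyz[sel_b, , drop = FALSE]))
      hit <- which(dd <= cut, arr.ind = TRUE)
      if (!nrow(hit)) return(matrix(integer(), 0, 2))
      ij <- cbind(ridx[sel_a[hit[, 1]]], ridx[sel_b[hit[, 2]]])
      ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
      unique(cbind(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2])))
    }

    sg <- which(at$resid == "CYS" & at$elety == "SG")
    ss <- pair_within(sg, sg, 2.5)

    no <- which(substr(at$elety, 1, 1) %in% c("N", "O"))
    hb1 <- pair_within(no, no, 3.5)
    acid <- which(mapply(function(r, e) r %in% names(ACID_O) &&
                           e %in% ACID_O[[r]], at$resid, at$elety))
    base <- which(mapply(function(r, e) r %in% names(BASE_N) &&
                           e %in% BASE_N[[r]], at$resid, at$elety))
    hb2 <- pair_within(acid, base, 4.0)
    hb <- unique(rbind(hb1, hb2))
  } else {
    warning("no full-atom coordinates: contact classes restricted to ",
            "covalent + generic")
  }

  assign_class <- function(m, label) {
    if (!nrow(m)) return(invisible())
    sel <- cls[m] == ""
    cls[m[sel, , drop = FALSE]] <<- label
  }
  assign_class(cov, "covalent")
  assign_class(ss, "disulfide")
  assign_class(hb, "hbond")
  gen <- which(upper.tri(D) & D <= r_c, arr.ind = TRUE)
  assign_class(gen, "generic")

  idx <- which(cls != "", arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      class = cls[idx], d = D[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, r_c = r_c, n = n), class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  tab <- table(x$edges$class)
  cat(sprintf("contact_graph: %d residues, r_c = %.1f A; %s\n", x$n, x$r_c,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Dataset quality-control report for a conformer pair
#'
#' Evaluates the curation filters used to admit a pair into analysis:
#' resolution below 4 Angstrom for both conformers, no missing residues
#' (no gaps in residue numbering), optimal B-factor Spearman correlation
#' above 0.4, alignment coverage of at least 80%, and more than 100 homologs.
#' Criteria with missing inputs are reported as `NA`, never as failures.
#'
#' @param pair a `conformer_pair`.
#' @param bfactor_spearman optimal Spearman correlation between experimental
#'   and theoretical B-factors (see [calibrate_cutoff()]).
#' @param msa_coverage alignment coverage fraction of the reference sequence.
#' @param n_homologs number of homologous sequences in the alignment.
#' @return A data.frame of class `qc_report` with columns `criterion`,
#'   `value`, `threshold`, `pass`, plus a logical attribute `all_pass`.
#' @export
qc_pair <- function(pair, bfactor_spearman = NA_real_,
                    msa_coverage = NA_real_, n_homologs = NA_integer_) {
  res <- suppressWarnings(max(pair$free$resolution, pair$bound$resolution,
                              na.rm = TRUE))
  if (!is.finite(res)) res <- NA_real_
  gaps <- function(s) {
    by_chain <- split(s$resno, s$chain)
    any(vapply(by_chain, function(r) any(diff(r) > 1L), logical(1)))
  }
  complete <- !(gaps(pair$free) || gaps(pair$bound))
  rep <- data.frame(
    criterion = c("resolution", "complete_residues", "bfactor_spearman",
                  "msa_coverage", "n_homologs"),
    value = c(res, as.numeric(complete), bfactor_spearman,
              msa_coverage, as.numeric(n_homologs)),
    threshold = c("< 4 A", "no gaps", "> 0.4", ">= 0.8", "> 100"),
    pass = c(if (is.na(res)) NA else res < 4,
             complete,
             if (is.na(bfactor_spearman)) NA else bfactor_spearman > 0.4,
             if (is.na(msa_coverage)) NA else msa_coverage >= 0.8,
             if (is.na(n_homologs)) NA else n_homologs > 100),
    stringsAsFactors = FALSE)
  attr(rep, "all_pass") <- all(rep$pass %in% TRUE)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Read a DSSP output file
#'
#' Fixed-width parser for classic DSSP output. Blank secondary-structure
#' assignments are reported as `"N"` (unclassified); chain-break records are
#' skipped; lowercase amino-acid letters (half-cystines) are mapped to `"C"`.
#'
#' @param path path to a DSSP output file.
#' @param chain optional chain filter.
#' @return data.frame with columns `chain`, `resno`, `icode`, `aa`
#'   (one-letter), `sse` (8-letter alphabet H,B,E,G,I,T,S,N) and `acc`
#'   (absolute accessibility, Angstrom^2).
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("not a DSSP output file: ", path)
  body <- lines[(hdr[1] + 1L):length(lines)]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & nzchar(trimws(substr(body, 6, 10)))
  body <- body[keep]; aa <- aa[keep]
  aa[aa %in% letters] <- "C"
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "N"
  out <- data.frame(
    chain = substr(body, 12, 12),
    resno = as.integer(substr(body, 6, 10)),
    icode = trimws(substr(body, 11, 11)),
    aa = aa, sse = ss,
    acc = as.numeric(substr(body, 35, 38)),
    stringsAsFactors = FALSE)
  if (!is.null(chain)) out <- out[out$chain %in% chain, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA (via bio3d) and Stockholm. Rows are upper-cased and
#' `.` gaps normalized to `-`. The reference row (default: first) is the
#' sequence of the analyzed structure.
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"stockholm"`.
#' @param ref index or identifier of the reference row.
#' @return An `alignment_set`: list with `ali` (character matrix), `ids`,
#'   `ref` (row index).
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"), ref = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    fa <- bio3d::read.fasta(path)
    ali <- fa$ali
    ids <- rownames(ali)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    parts <- regmatches(lines, regexpr("\\S+", lines))
    seqs <- trimws(substring(lines, nchar(parts) + 1L))
    agg <- tapply(seqs, factor(parts, levels = unique(parts)), paste,
                  collapse = "")
    ids <- names(agg)
    ali <- do.call(rbind, strsplit(unname(agg), ""))
    rownames(ali) <- ids
  }
  ali <- toupper(ali)
  ali[ali == "."] <- "-"
  if (is.character(ref)) ref <- match(ref, ids)
  if (is.na(ref) || ref < 1 || ref > nrow(ali)) stop("invalid reference row")
  structure(list(ali = ali, ids = ids, ref = as.integer(ref)),
            class = "alignment_set")
}

#' Map alignment columns onto structure residues
#'
#' Non-gap columns of the reference row are mapped, in order, onto the
#' residues of the structure; the sequences must agree.
#'
#' @param aln an `alignment_set`.
#' @param structure a [ca_structure()].
#' @return integer vector of length N: alignment column of each residue.
#' @export
map_alignment <- function(aln, structure) {
  cols <- which(aln$ali[aln$ref, ] != "-")
  n <- length(structure$resno)
  if (length(cols) != n)
    stop("reference row has ", length(cols), " residues; structure has ", n)
  ref_aa <- aln$ali[aln$ref, cols]
  str_aa <- aa_three_to_one(structure$aa)
  bad <- ref_aa != str_aa & str_aa != "X" & ref_aa != "X"
  if (any(bad))
    stop("reference sequence mismatch at ", sum(bad), " position(s)")
  cols
}

#' Read an active-site residue list
#'
#' Tab-separated file with columns `chain` and `resnum`, optionally `site`
#' to distinguish multiple binding sites.
#'
#' @param path TSV file.
#' @param structure a [ca_structure()] used to convert residue numbers to
#'   indices.
#' @return list of integer vectors of residue indices, one per site.
#' @export
read_site_list <- function(path, structure) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chain", "resnum") %in% names(tab)))
    stop("site list needs columns 'chain' and 'resnum'")
  keys <- residue_keys(structure$chain, structure$resno, structure$icode)
  idx <- match(residue_keys(tab$chain, tab$resnum, ""), keys)
  if (anyNA(idx))
    stop("site residue(s) not present in structure: ",
         paste(tab$resnum[is.na(idx)], collapse = ", "))
  site <- if ("site" %in% names(tab)) tab$site else rep(1L, nrow(tab))
  unname(split(idx, site))
}

#' Write the per-residue pair report
#'
#' @param pair a `conformer_pair`.
#' @param file output TSV path.
#' @return the report data.frame, invisibly.
#' @export
write_pair_report <- function(pair, file) {
  f <- pair$free
  bb <- rep(NA_real_, length(f$resno))   # bound B aligned through the mapping
  bb[pair$mapping[, "free"]] <- pair$bound$bfactor[pair$mapping[, "bound"]]
  rep <- data.frame(chain = f$chain, resnum = f$resno, aa = f$aa,
                    rmsd_i = pair$rmsd_i,
                    bfactor_free = f$bfactor,
                    bfactor_bound = bb,
                    stringsAsFactors = FALSE)
  utils::write.table(rep, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
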