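# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps fixture generation from
# perturbing user RNG streams.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Three-letter -> one-letter amino-acid code (standard 20 only).
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V")

#' Convert three-letter residue names to one-letter codes
#'
#' Nonstandard residues map to `"X"`.
#'
#' @param aa character vector of three-letter residue names.
#' @return character vector of one-letter codes.
#' @export
aa_three_to_one <- function(aa) {
  out <- AA_321[toupper(aa)]
  out[is.na(out)] <- "X"
  unname(out)
}

# residue identity keys used to map residues across files/conformers
residue_keys <- function(chain, resno, icode) {
  icode[is.na(icode) | icode == ""] <- " "
  paste(chain, resno, icode, sep = "|")
}

# N x 3 coordinate matrix -> flat length-3N vector (x1,y1,z1,x2,...)
flatten_xyz <- function(xyz) as.vector(t(xyz))

unflatten_xyz <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Sum squared vector entries per residue triplet: length-3N -> length-N.
per_residue_sq <- function(v) {
  m <- matrix(v^2, nrow = 3)
  colSums(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
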