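#' @importFrom stats median quantile sd setNames
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ligand instance key
#'
#' Canonical identifier of one ligand occurrence, `<HET>_<chain>_<resnum>-<entryid>`,
#' the same scheme used for ensemble names (an ensemble is named after its
#' search ligand).
#'
#' @param het het code (1-3 characters)
#' @param chain author chain identifier
#' @param resnum residue number
#' @param entry_id 4-character entry identifier
#' @return character key
#' @export
ligand_key <- function(het, chain, resnum, entry_id) {
  sprintf("%s_%s_%s-%s", het, chain, resnum, entry_id)
}

lig_key <- function(lig) {
  ligand_key(lig$residue_name, lig$chain_id, lig$residue_number, lig$entry_id)
}

# Bondi van der Waals radii (Angstrom); 1.70 fallback for unlisted elements.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10,
  Se = 1.90
)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Metallic elements recognized by the metal-ion skip rule.
METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo",
  "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La", "Ce",
  "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

# Three-letter -> one-letter amino acid codes; non-standard residues map to X.
aa_one_letter <- function(resname) {
  tab <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  out <- tab[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Pairwise Euclidean distances between the rows of two coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

min_dist <- function(a, b) min(cross_dist(a, b))

ov_log <- function(fmt, ...) {
  message(sprintf(paste0("[overlayset] ", fmt), ...))
}
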