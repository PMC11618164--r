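#' Molecular perception and descriptors
#'
#' Bond orders, protonation and canonical SMILES are perceived from 3D
#' coordinates plus element identities with OpenBabel; the descriptors used
#' by the filter cascade (rotatable bonds under the Veber-style definition,
#' Lipinski-style HBD/HBA counts, Wildman-Crippen SlogP, molecular weight,
#' heavy atom count, element set) are computed on the perceived molecule.
#'
#' @name chem_properties
NULL

ob_binary <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH", call. = FALSE)
  p
}

# Run obabel on `text` (format `from`), return output text lines for `to`.
ob_convert <- function(text, from, to, extra = character()) {
  fin <- tempfile(fileext = paste0(".", from))
  fout <- tempfile(fileext = paste0(".", to))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(text, fin)
  status <- suppressWarnings(system2(
    ob_binary(),
    c(fin, paste0("-O", fout), extra),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0 || !file.exists(fout)) return(NULL)
  out <- readLines(fout, warn = FALSE)
  if (!length(out)) return(NULL)
  out
}

# Fixed-column HETATM block for one ligand's atoms (element + coordinates),
# the exchange dialect used to hand a residue group to the perception engine.
ligand_pdb_text <- function(atoms, het = "LIG", chain = "A", resnum = 1L) {
  el <- atoms$element
  name <- sprintf("%s%d", toupper(substr(el, 1, 1)), seq_along(el))
  lines <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_along(el), substr(name, 1, 4), substr(het, 1, 3), chain, resnum,
    atoms$x, atoms$y, atoms$z, el
  )
  c(lines, "END")
}

parse_sdf_text <- function(sdf_lines) {
  f <- tempfile(fileext = ".sdf")
  on.exit(unlink(f), add = TRUE)
  writeLines(sdf_lines, f)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(f))
  if (!length(sdfset)) return(NULL)
  sdfset
}

# Internal molecule representation built from a perceived SDF record:
# elements, coordinates, explicit-H flags, bond table (a1, a2, order),
# the ChemmineR SDF object and the canonical SMILES.
mol_from_sdf <- function(sdf, smiles = NA_character_) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1, dimnames = list(names(ab)[1], NULL))
  elements <- gsub("_.*$", "", rownames(ab))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0), byrow = TRUE)
  if (nrow(bb) && ncol(bb) >= 3) {
    bonds <- data.frame(
      a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  structure(list(
    elements = elements,
    coords = unname(as.matrix(ab[, 1:3, drop = FALSE])),
    is_h = elements == "H",
    bonds = bonds,
    sdf = sdf,
    smiles = smiles
  ), class = "ov_mol")
}

#' @export
print.ov_mol <- function(x, ...) {
  cat(sprintf(
    "<ov_mol> %s | %d atoms (%d heavy), %d bonds\n",
    x$smiles, length(x$elements), sum(!x$is_h), nrow(x$bonds)
  ))
  invisible(x)
}

# Perceive a molecule from raw atoms (data.frame element/x/y/z).
# Returns an ov_mol or NULL if perception fails.
perceive_atoms <- function(atoms, het = "LIG") {
  atoms <- atoms[atoms$element != "", , drop = FALSE]
  if (!nrow(atoms) || !any(atoms$element != "H")) return(NULL)
  pdb <- ligand_pdb_text(atoms, het = het)
  smi <- ob_convert(pdb, "pdb", "can")
  # -h materializes implicit hydrogens so downstream SDF handling always sees
  # complete atom records (descriptors are unaffected)
  sdf <- ob_convert(pdb, "pdb", "sdf", extra = "-h")
  if (is.null(smi) || is.null(sdf)) return(NULL)
  smiles <- strsplit(smi[1], "\t")[[1]][1]
  if (is.na(smiles) || !nzchar(smiles)) return(NULL)
  sdfset <- parse_sdf_text(sdf)
  if (is.null(sdfset)) return(NULL)
  mol_from_sdf(sdfset[[1]], smiles = smiles)
}

# Canonical SMILES of a SMILES string (canonicalization fixed point helper).
canonical_smiles <- function(smiles) {
  out <- ob_convert(smiles, "smi", "can")
  if (is.null(out)) return(NA_character_)
  strsplit(out[1], "\t")[[1]][1]
}

# Build an ov_mol directly from SMILES via 3D coordinate generation.
mol_from_smiles <- function(smiles) {
  sdf <- ob_convert(smiles, "smi", "sdf", extra = "--gen3d")
  if (is.null(sdf)) stop("3D generation failed for SMILES: ", smiles)
  sdfset <- parse_sdf_text(sdf)
  if (is.null(sdfset)) stop("3D generation failed for SMILES: ", smiles)
  mol_from_sdf(sdfset[[1]], smiles = canonical_smiles(smiles))
}

heavy_degree <- function(mol) {
  deg <- integer(length(mol$elements))
  hb <- mol$bonds[!mol$is_h[mol$bonds$a1] & !mol$is_h[mol$bonds$a2], , drop = FALSE]
  for (i in seq_len(nrow(hb))) {
    deg[hb$a1[i]] <- deg[hb$a1[i]] + 1L
    deg[hb$a2[i]] <- deg[hb$a2[i]] + 1L
  }
  deg
}

# Bond-order sum per atom (explicit bonds, any partner).
bond_order_sum <- function(mol) {
  s <- numeric(length(mol$elements))
  for (i in seq_len(nrow(mol$bonds))) {
    s[mol$bonds$a1[i]] <- s[mol$bonds$a1[i]] + mol$bonds$order[i]
    s[mol$bonds$a2[i]] <- s[mol$bonds$a2[i]] + mol$bonds$order[i]
  }
  s
}

# Hydrogen total per atom: explicit H neighbours plus implicit fill-up to the
# element's default valence (standard molfile convention).
hydrogen_count <- function(mol) {
  bos <- bond_order_sum(mol)
  expl <- integer(length(mol$elements))
  for (i in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[i]; a2 <- mol$bonds$a2[i]
    if (mol$is_h[a2]) expl[a1] <- expl[a1] + 1L
    if (mol$is_h[a1]) expl[a2] <- expl[a2] + 1L
  }
  defv <- function(el, s) {
    switch(el,
      C = 4, B = 3, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
      P = if (s > 3) 5 else 3,
      S = if (s > 4) 6 else if (s > 2) 4 else 2,
      0
    )
  }
  impl <- vapply(seq_along(mol$elements), function(i) {
    if (mol$is_h[i]) return(0L)
    as.integer(max(0, defv(mol$elements[i], bos[i]) - bos[i]))
  }, integer(1))
  expl + impl
}

# TRUE for each bond that is part of a ring (endpoints stay connected after
# removing the bond).
ring_bond_flags <- function(mol) {
  n <- length(mol$elements)
  bonds <- mol$bonds
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], i)
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], i)
  }
  connected_without <- function(skip, from, to) {
    seen <- logical(n)
    queue <- from
    seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (bi in adj[[v]]) {
        if (bi == skip) next
        w <- if (bonds$a1[bi] == v) bonds$a2[bi] else bonds$a1[bi]
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }
  vapply(seq_len(nrow(bonds)), function(i) {
    connected_without(i, bonds$a1[i], bonds$a2[i])
  }, logical(1))
}

ring_atom_flags <- function(mol) {
  fl <- logical(length(mol$elements))
  rb <- ring_bond_flags(mol)
  fl[c(mol$bonds$a1[rb], mol$bonds$a2[rb])] <- TRUE
  fl
}

# Indices of nitrogen atoms that are part of a C#N nitrile group, and their
# carbons.
nitrile_atoms <- function(mol) {
  idx <- integer(0)
  for (i in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[i, ]
    if (b$order == 3) {
      pair <- c(mol$elements[b$a1], mol$elements[b$a2])
      if (setequal(pair, c("C", "N"))) idx <- c(idx, b$a1, b$a2)
    }
  }
  unique(idx)
}

# Amide C-N bonds: N single-bonded to a carbon that carries a double bond to
# oxygen.
is_amide_bond <- function(mol, a1, a2) {
  els <- mol$elements
  cand <- if (els[a1] == "C" && els[a2] == "N") a1
          else if (els[a2] == "C" && els[a1] == "N") a2
          else return(FALSE)
  b <- mol$bonds
  any(b$order == 2 &
        ((b$a1 == cand & els[b$a2] == "O") |
         (b$a2 == cand & els[b$a1] == "O")))
}

#' Count rotatable bonds
#'
#' A bond counts as rotatable if it is an acyclic single bond, but not an
#' amide C-N bond, not a bond involving a nitrile-group atom, and not a bond
#' where either end is a terminal heavy atom (heavy-atom degree 1).
#'
#' @param mol perceived molecule (`ov_mol`)
#' @return integer count
#' @export
count_rotatable_bonds <- function(mol) {
  stopifnot(inherits(mol, "ov_mol"))
  if (!nrow(mol$bonds)) return(0L)
  ringb <- ring_bond_flags(mol)
  deg <- heavy_degree(mol)
  nitr <- nitrile_atoms(mol)
  n_rot <- 0L
  for (i in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[i, ]
    if (b$order != 1 || ringb[i]) next
    if (mol$is_h[b$a1] || mol$is_h[b$a2]) next
    if (deg[b$a1] <= 1L || deg[b$a2] <= 1L) next
    if (b$a1 %in% nitr || b$a2 %in% nitr) next
    if (is_amide_bond(mol, b$a1, b$a2)) next
    n_rot <- n_rot + 1L
  }
  n_rot
}

#' Count hydrogen-bond donors and acceptors
#'
#' HBD counts hydrogens attached to nitrogen or oxygen (a donating heteroatom
#' contributes once per attached hydrogen). HBA counts nitrogen and oxygen
#' atoms, excluding pyrrole-type N-H nitrogens (hydrogen-bearing nitrogens in
#' an aromatic ring) and amide nitrogens.
#'
#' @param mol perceived molecule (`ov_mol`)
#' @return named integer vector `c(hbd = ..., hba = ...)`
#' @export
count_hbd_hba <- function(mol) {
  stopifnot(inherits(mol, "ov_mol"))
  els <- mol$elements
  hcount <- hydrogen_count(mol)
  hetero <- which(els %in% c("N", "O"))
  hbd <- sum(hcount[hetero])
  arom_atoms <- aromatic_atom_flags(mol)
  hba <- 0L
  for (i in hetero) {
    if (els[i] == "N") {
      if (arom_atoms[i] && hcount[i] > 0) next   # pyrrole-type N-H
      amide <- any(vapply(seq_len(nrow(mol$bonds)), function(k) {
        b <- mol$bonds[k, ]
        (b$a1 == i || b$a2 == i) && b$order == 1 &&
          is_amide_bond(mol, b$a1, b$a2)
      }, logical(1)))
      if (amide) next
    }
    hba <- hba + 1L
  }
  c(hbd = as.integer(hbd), hba = as.integer(hba))
}

# Flags atoms that belong to an aromatic ring (ChemmineR ring perception).
aromatic_atom_flags <- function(mol) {
  fl <- logical(length(mol$elements))
  rb <- ring_bond_flags(mol)
  if (!any(rb)) return(fl)
  r <- tryCatch(
    ChemmineR::rings(mol$sdf, type = "all", arom = TRUE),
    error = function(e) NULL
  )
  if (is.null(r) || !length(r$RINGS)) return(fl)
  for (k in seq_along(r$RINGS)) {
    if (isTRUE(r$AROMATIC[[k]])) {
      idx <- as.integer(gsub("^[A-Za-z]+_", "", r$RINGS[[k]]))
      fl[idx] <- TRUE
    }
  }
  fl
}

#' Predict SlogP
#'
#' Wildman-Crippen atomic-contribution logP (sum of per-atom contributions
#' from the published table), computed on the perceived molecule.
#'
#' @param mol perceived molecule (`ov_mol`)
#' @return unitless logP estimate
#' @export
predict_slogp <- function(mol) {
  stopifnot(inherits(mol, "ov_mol"))
  p <- ob_props(mol)
  as.numeric(p$logP)
}

# OpenBabel property block (cached on first use per molecule object is not
# possible with plain lists; calls are cheap at fixture scale).
ob_props <- function(mol) {
  ChemmineR::propOB(as_sdfset(list(mol$sdf)))
}

as_sdfset <- function(sdfs) {
  methods::new(
    "SDFset",
    SDF = sdfs,
    ID = paste0("m", seq_along(sdfs))
  )
}

#' Compute the per-ligand descriptor set
#'
#' Perceives bond orders and protonation from the ligand's 3D coordinates and
#' element identities, emits canonical (isomeric) SMILES, and populates all
#' descriptor fields used downstream.
#'
#' @param ligand a `LigandInstance` (list with `atoms` data.frame and identity
#'   fields) or a raw atoms data.frame with columns element/x/y/z
#' @return a `LigandProperties` list: smiles, molecular_weight,
#'   heavy_atom_count, rotatable_bonds, elements, hbd, hba, slogp, plus the
#'   perceived molecule under `$mol`; `NULL` if perception fails
#' @export
perceive_molecule <- function(ligand) {
  atoms <- if (is.data.frame(ligand)) ligand else ligand$atoms
  het <- if (is.data.frame(ligand)) "LIG" else ligand$residue_name %||% "LIG"
  mol <- perceive_atoms(atoms, het = het)
  if (is.null(mol)) return(NULL)
  p <- ob_props(mol)
  hh <- count_hbd_hba(mol)
  list(
    smiles = mol$smiles,
    molecular_weight = as.numeric(p$MW),
    heavy_atom_count = sum(!mol$is_h),
    rotatable_bonds = count_rotatable_bonds(mol),
    elements = sort(unique(mol$elements[!mol$is_h])),
    hbd = unname(hh["hbd"]),
    hba = unname(hh["hba"]),
    slogp = as.numeric(p$logP),
    mol = mol
  )
}

# MACCS 166-bit structural fingerprint matrix for a list of ov_mol objects.
maccs_fingerprints <- function(mols) {
  sdfset <- as_sdfset(lapply(mols, function(m) m$sdf))
  fp <- ChemmineR::fingerprintOB(sdfset, "MACCS")
  m <- fp@fpma
  storage.mode(m) <- "numeric"
  m
}
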