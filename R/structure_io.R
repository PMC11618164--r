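#' Parse a protein-ligand structure in PDB format
#'
#' Reads one entry (first model only): chains with per-residue backbone
#' records, crystallographic resolution (REMARK 2), release date (first
#' REVDAT revision, falling back to the HEADER deposition date), and all
#' HETATM residue groups as ligand candidates. Standard solvents (HOH, DOD)
#' are dropped before candidate listing; alternate conformers other than
#' altLoc ' ' or 'A' are dropped with a warning.
#'
#' @param pdb character vector of PDB lines, a single string, or a file path
#' @param entry_id optional override for the 4-character entry identifier
#'   (defaults to the HEADER id, else the file name)
#' @return a `StructureEntry` list: entry_id, resolution, release_date,
#'   chains, protein_atoms, ligand_candidates, exclusion
#' @export
parse_structure <- function(pdb, entry_id = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(entry_id)) {
      entry_id <- tolower(sub("\\.pdb$", "", basename(pdb)))
    }
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop("parse error: empty PDB input", call. = FALSE)
  }

  rec <- substr(lines, 1, 6)
  coord_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(coord_idx)) {
    stop("parse error: no coordinate records found", call. = FALSE)
  }
  for (i in coord_idx) {
    ln <- lines[i]
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (nchar(ln) < 54 || anyNA(xyz) || any(!is.finite(xyz))) {
      stop(sprintf("parse error: malformed coordinate record at line %d", i),
           call. = FALSE)
    }
  }

  header_line <- lines[rec == "HEADER"][1]
  if (is.null(entry_id) && !is.na(header_line) && nchar(header_line) >= 66) {
    id <- tolower(trimws(substr(header_line, 63, 66)))
    if (nzchar(id)) entry_id <- id
  }
  entry_id <- entry_id %||% "xxxx"

  resolution <- parse_resolution(lines)
  release_date <- parse_release_date(lines, header_line)

  # coordinates via bio3d (first model)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdbobj <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE))
  at <- pdbobj$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  dropped_alt <- at$alt != "" & at$alt != "A"
  if (any(dropped_alt)) {
    ov_log("entry %s: dropping %d alternate-conformer atoms (altLoc != A)",
           entry_id, sum(dropped_alt))
    at <- at[!dropped_alt, , drop = FALSE]
  }
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    toupper(substr(trimws(at$elety[is.na(at$elesy) | at$elesy == ""]), 1, 1))

  prot <- at[at$type == "ATOM", , drop = FALSE]
  protein_atoms <- data.frame(
    chain = prot$chain, resno = prot$resno, ins = prot$insert,
    resname = prot$resid, atom_name = trimws(prot$elety),
    element = prot$elesy, x = prot$x, y = prot$y, z = prot$z,
    stringsAsFactors = FALSE
  )
  protein_atoms$is_backbone <-
    protein_atoms$atom_name %in% c("N", "CA", "C", "O")

  chains <- build_chains(protein_atoms)

  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "DOD")), ,
            drop = FALSE]
  candidates <- list()
  if (nrow(het)) {
    het$ins <- het$insert
    grp <- interaction(het$chain, het$resno, het$ins, het$resid, drop = TRUE)
    for (g in levels(grp)) {
      sub <- het[grp == g, , drop = FALSE]
      lig <- list(
        entry_id = entry_id,
        residue_name = sub$resid[1],
        chain_id = sub$chain[1],
        residue_number = sub$resno[1],
        atoms = data.frame(
          element = sub$elesy, x = sub$x, y = sub$y, z = sub$z,
          is_hydrogen = sub$elesy == "H",
          atom_name = trimws(sub$elety),
          stringsAsFactors = FALSE
        ),
        smiles = NULL, properties = NULL, skip_reason = NULL
      )
      class(lig) <- "LigandInstance"
      candidates[[ligand_key(lig$residue_name, lig$chain_id,
                             lig$residue_number, entry_id)]] <- lig
    }
  }

  entry <- list(
    entry_id = entry_id,
    resolution = resolution,
    release_date = release_date,
    chains = chains,
    protein_atoms = protein_atoms,
    ligand_candidates = candidates,
    exclusion = if (!length(candidates)) "no_ligand" else NULL
  )
  class(entry) <- "StructureEntry"
  entry
}

#' @export
print.StructureEntry <- function(x, ...) {
  cat(sprintf(
    "<StructureEntry %s> resolution %s A, %d chains, %d ligand candidates%s\n",
    x$entry_id, ifelse(is.na(x$resolution), "NA", format(x$resolution)),
    length(x$chains), length(x$ligand_candidates),
    if (!is.null(x$exclusion)) paste0(" [", x$exclusion, "]") else ""
  ))
  invisible(x)
}

parse_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s+ANGSTROM)",
                                 rl[1], perl = TRUE))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

parse_release_date <- function(lines, header_line) {
  rev <- lines[substr(lines, 1, 6) == "REVDAT"]
  datestr <- NA_character_
  if (length(rev)) {
    modnum <- suppressWarnings(as.integer(substr(rev, 8, 10)))
    first <- rev[which(modnum == 1L)]
    if (length(first)) datestr <- trimws(substr(first[1], 14, 22))
  }
  if (is.na(datestr) && !is.na(header_line)) {
    d <- trimws(substr(header_line, 51, 59))
    if (nzchar(d)) datestr <- d
  }
  if (is.na(datestr) || !nzchar(datestr)) return(as.Date(NA))
  as.Date(datestr, format = "%d-%b-%y")
}

build_chains <- function(protein_atoms) {
  chains <- list()
  for (ch in unique(protein_atoms$chain)) {
    sub <- protein_atoms[protein_atoms$chain == ch, , drop = FALSE]
    keys <- unique(paste(sub$resno, sub$ins, sep = "\r"))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    resno <- as.integer(vapply(parts, `[`, "", 1))
    ins <- vapply(parts, function(p) if (length(p) > 1) p[2] else "", "")
    ord <- order(resno, ins)
    resno <- resno[ord]; ins <- ins[ord]
    n <- length(resno)
    resname <- character(n)
    bb <- array(NA_real_, dim = c(n, 4, 3),
                dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
    for (i in seq_len(n)) {
      rsub <- sub[sub$resno == resno[i] & sub$ins == ins[i], , drop = FALSE]
      resname[i] <- rsub$resname[1]
      for (a in c("N", "CA", "C", "O")) {
        hit <- which(rsub$atom_name == a)
        if (length(hit)) {
          bb[i, a, ] <- as.numeric(rsub[hit[1], c("x", "y", "z")])
        }
      }
    }
    complete <- apply(bb, 1, function(m) !anyNA(m))
    chains[[ch]] <- list(
      chain_id = ch,
      residues = data.frame(
        resno = resno, ins = ins, resname = resname,
        one = aa_one_letter(resname), backbone_complete = complete,
        stringsAsFactors = FALSE
      ),
      backbone = bb
    )
  }
  chains
}

#' Assign construction-time exclusion flags to ligand candidates
#'
#' Flags, in order of precedence: `metal_ion` (single non-carbon heavy atom of
#' a metallic element), `covalent` (any ligand heavy atom within
#' `covalent_cutoff` of a protein heavy atom), `polymer` (bonded to another
#' HETATM residue group at the same cutoff), `unparseable` (bond perception
#' failure). Candidates passing all checks get their perceived molecule and
#' descriptors attached. Idempotent.
#'
#' @param entry a `StructureEntry`
#' @param covalent_cutoff heavy-atom distance gate in Angstrom
#' @return the entry with flags and perceived properties filled in
#' @export
classify_candidates <- function(entry, covalent_cutoff = 1.9) {
  stopifnot(inherits(entry, "StructureEntry"))
  cands <- entry$ligand_candidates
  if (!length(cands)) return(entry)
  prot_heavy <- entry$protein_atoms[entry$protein_atoms$element != "H",
                                    c("x", "y", "z"), drop = FALSE]
  heavy_coords <- lapply(cands, function(lig) {
    as.matrix(lig$atoms[!lig$atoms$is_hydrogen, c("x", "y", "z"),
                        drop = FALSE])
  })
  for (k in names(cands)) {
    lig <- cands[[k]]
    hc <- heavy_coords[[k]]
    lig$skip_reason <- NULL
    if (nrow(hc) == 1 && lig$atoms$element[!lig$atoms$is_hydrogen][1] %in% METALS) {
      lig$skip_reason <- "metal_ion"
    } else if (nrow(prot_heavy) && nrow(hc) &&
               min_dist(hc, prot_heavy) < covalent_cutoff) {
      lig$skip_reason <- "covalent"
    } else {
      others <- setdiff(names(cands), k)
      linked <- any(vapply(others, function(o) {
        nrow(heavy_coords[[o]]) > 0 &&
          min_dist(hc, heavy_coords[[o]]) < covalent_cutoff
      }, logical(1)))
      if (linked) lig$skip_reason <- "polymer"
    }
    if (is.null(lig$skip_reason) && is.null(lig$properties)) {
      props <- perceive_molecule(lig)
      if (is.null(props)) {
        lig$skip_reason <- "unparseable"
      } else {
        lig$properties <- props[setdiff(names(props), "mol")]
        lig$mol <- props$mol
        lig$smiles <- props$smiles
      }
    }
    cands[[k]] <- lig
  }
  entry$ligand_candidates <- cands
  entry
}

#' Write a ligand ensemble as a multi-record SDF file
#'
#' One record per member with superimposed 3D coordinates in the ensemble
#' frame and named data fields (source entry id, het code, chain, residue
#' number, backbone RMSD, canonical SMILES, ensemble name). Records are
#' ordered by ascending backbone RMSD with the search ligand first.
#'
#' @param ensemble a `LigandEnsemble`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_ensemble_sdf <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "LigandEnsemble"))
  members <- ensemble$members
  if (!length(members)) stop("ensemble has no members")
  for (m in members) {
    if (is.null(m$coords) || anyNA(m$coords)) {
      stop("refusing to write: member ", m$key, " has no superimposed coordinates")
    }
  }
  is_search <- vapply(members, function(m) m$key == ensemble$search_ligand,
                      logical(1))
  rmsd <- vapply(members, function(m) m$backbone_rmsd, numeric(1))
  ord <- order(!is_search, rmsd)
  sdfs <- lapply(members[ord], function(m) {
    sdf <- m$mol$sdf
    ab <- ChemmineR::atomblock(sdf)
    # SDF V2000 carries 4 decimals; rounding also keeps the writer out of
    # scientific notation for near-zero values
    ab[, 1:3] <- round(m$coords, 4)
    sdf@atomblock <- ab
    sdf@datablock <- c(
      ENTRY_ID = m$entry_id,
      HET = m$residue_name,
      CHAIN = m$chain_id,
      RESNUM = as.character(m$residue_number),
      LIGAND_KEY = m$key,
      BACKBONE_RMSD = sprintf("%.3f", m$backbone_rmsd),
      SMILES = m$smiles,
      ENSEMBLE = ensemble$name
    )
    sdf
  })
  sdfset <- as_sdfset(sdfs)
  ChemmineR::write.SDF(sdfset, file = path, cid = FALSE)
  invisible(path)
}

#' Read an ensemble SDF written by [write_ensemble_sdf()]
#'
#' @param path SDF file path
#' @return a `LigandEnsemble` with member coordinates, RMSDs and identity
#'   fields restored
#' @export
read_ensemble_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  members <- lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    mol <- mol_from_sdf(sdf, smiles = unname(db["SMILES"]))
    list(
      key = unname(db["LIGAND_KEY"]),
      entry_id = unname(db["ENTRY_ID"]),
      residue_name = unname(db["HET"]),
      chain_id = unname(db["CHAIN"]),
      residue_number = as.integer(db["RESNUM"]),
      smiles = unname(db["SMILES"]),
      backbone_rmsd = as.numeric(db["BACKBONE_RMSD"]),
      coords = mol$coords,
      mol = mol
    )
  })
  names(members) <- vapply(members, function(m) m$key, character(1))
  name <- ChemmineR::datablock(sdfset[[1]])["ENSEMBLE"]
  ens <- list(
    name = unname(name),
    search_ligand = members[[1]]$key,
    members = members,
    complexes = vapply(members, function(m) m$key, character(1)),
    removed = FALSE
  )
  class(ens) <- "LigandEnsemble"
  ens
}
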