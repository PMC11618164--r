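#' Filter thresholds
#'
#' Defaults are the selection gates applied to the full structure collection:
#' resolution at most 2.5 A, EDIA_m strictly greater than 0.8, molecular
#' weight at most 975 g/mol, at most 10 rotatable bonds, elements restricted
#' to C/O/N/S/P/Cl/F/Br/I/B, at least 10 heavy atoms, ligand efficiency
#' strictly greater than 0.3, and buriedness at least 0.5.
#'
#' @param max_resolution Angstrom
#' @param min_edia unitless, strict lower gate
#' @param max_molecular_weight g/mol
#' @param max_rotatable_bonds integer
#' @param allowed_elements character vector of element symbols
#' @param min_heavy_atoms integer
#' @param min_ligand_efficiency unitless, strict lower gate
#' @param min_buriedness fraction in [0, 1]
#' @return a `FilterThresholds` list
#' @export
filter_thresholds <- function(max_resolution = 2.5,
                              min_edia = 0.8,
                              max_molecular_weight = 975,
                              max_rotatable_bonds = 10L,
                              allowed_elements = c("C", "O", "N", "S", "P",
                                                   "Cl", "F", "Br", "I", "B"),
                              min_heavy_atoms = 10L,
                              min_ligand_efficiency = 0.3,
                              min_buriedness = 0.5) {
  th <- list(
    max_resolution = max_resolution, min_edia = min_edia,
    max_molecular_weight = max_molecular_weight,
    max_rotatable_bonds = max_rotatable_bonds,
    allowed_elements = allowed_elements,
    min_heavy_atoms = min_heavy_atoms,
    min_ligand_efficiency = min_ligand_efficiency,
    min_buriedness = min_buriedness
  )
  stopifnot(all(vapply(th[c(1:4, 6:8)], function(v) is.numeric(v) && v > 0,
                       logical(1))))
  class(th) <- "FilterThresholds"
  th
}

#' Read an EDIA support table
#'
#' TSV with columns `entry_id het chain resnum edia_m`. Scores are consumed,
#' never computed; a ligand with no row fails the EDIA step.
#'
#' @param path TSV file path
#' @return data.frame
#' @export
read_edia_table <- function(path) {
  df <- read_tsv(path)
  needed <- c("entry_id", "het", "chain", "resnum", "edia_m")
  if (!all(needed %in% names(df))) {
    stop("EDIA table must have columns: ", paste(needed, collapse = ", "))
  }
  df
}

lookup_edia <- function(lig, edia_table) {
  if (is.null(edia_table) || !nrow(edia_table)) return(NA_real_)
  hit <- edia_table$entry_id == lig$entry_id &
    edia_table$het == lig$residue_name &
    edia_table$chain == lig$chain_id &
    edia_table$resnum == lig$residue_number
  if (!any(hit)) return(NA_real_)
  max(edia_table$edia_m[hit])
}

#' Remove duplicate ligand instances by electron-density support
#'
#' Within each (entry_id, canonical SMILES) group only the instance with the
#' highest EDIA_m is kept. Ties keep the instance with the lexicographically
#' smallest (chain_id, residue_number) and are logged.
#'
#' @param ligands list of perceived `LigandInstance` objects carrying `$edia`
#' @return the deduplicated list
#' @export
dedupe_by_edia <- function(ligands) {
  if (!length(ligands)) return(ligands)
  grp <- vapply(ligands, function(l) paste(l$entry_id, l$smiles, sep = "\r"),
                character(1))
  keep <- logical(length(ligands))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    edia <- vapply(ligands[idx], function(l) l$edia %||% NA_real_, numeric(1))
    best <- max(edia, na.rm = TRUE)
    cand <- idx[!is.na(edia) & edia == best]
    if (length(cand) > 1) {
      ord <- order(
        vapply(ligands[cand], function(l) l$chain_id, character(1)),
        vapply(ligands[cand], function(l) l$residue_number, numeric(1))
      )
      ov_log("EDIA tie in duplicate removal (%s): keeping %s",
             ligands[[cand[ord[1]]]]$entry_id, lig_key(ligands[[cand[ord[1]]]]))
      cand <- cand[ord[1]]
    } else {
      cand <- cand[1]
    }
    keep[cand] <- TRUE
  }
  ligands[keep]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-spiral point sampling on each atom's solvent-expanded
#' sphere; a point is accessible if it is outside every other atom's expanded
#' sphere (including occluders).
#'
#' @param coords n x 3 matrix of atom coordinates (Angstrom)
#' @param elements element symbols (for Bondi vdW radii)
#' @param occluders optional m x 3 matrix of additional occluding atoms
#' @param occluder_elements element symbols of the occluders
#' @param probe probe radius, Angstrom
#' @param n_points sphere sample points per atom
#' @return total SASA in Angstrom^2
#' @export
shrake_rupley_sasa <- function(coords, elements, occluders = NULL,
                               occluder_elements = NULL, probe = 1.4,
                               n_points = 512L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- vdw_radius(elements) + probe
  all_coords <- coords
  all_radii <- radii
  if (!is.null(occluders) && nrow(occluders)) {
    all_coords <- rbind(coords, as.matrix(occluders))
    all_radii <- c(radii, vdw_radius(occluder_elements) + probe)
  }
  sphere <- golden_spiral_points(n_points)
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sphere * radii[i], 2, coords[i, ], "+")
    # neighbours whose expanded sphere can reach atom i's surface
    d_center <- sqrt(colSums((t(all_coords) - coords[i, ])^2))
    nb <- which(d_center < radii[i] + all_radii & seq_along(d_center) != i)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- colSums((t(pts) - all_coords[j, ])^2)
      acc <- acc & d2 >= all_radii[j]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * radii[i]^2 * mean(acc)
  }
  total
}

# Deterministic, approximately uniform unit-sphere points (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Buriedness of a ligand within its protein environment
#'
#' Default operator: SASA burial fraction,
#' 1 - SASA(ligand in complex) / SASA(ligand alone), Shrake-Rupley with a
#' 1.4 A probe on heavy atoms, clamped to [0, 1]. The `"neighbors"` variant
#' is a coordination-count heuristic (mean per-atom protein-neighbour count
#' within 8 A, saturating at 15 neighbours).
#'
#' @param ligand `LigandInstance` (or atoms data.frame)
#' @param protein_atoms data.frame with element/x/y/z columns
#' @param method `"sasa"` (default) or `"neighbors"`
#' @param probe probe radius for the SASA variant
#' @param n_points sphere samples per atom for the SASA variant
#' @return fraction in [0, 1]
#' @export
compute_buriedness <- function(ligand, protein_atoms,
                               method = c("sasa", "neighbors"),
                               probe = 1.4, n_points = 512L) {
  method <- match.arg(method)
  atoms <- if (is.data.frame(ligand)) ligand else ligand$atoms
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  lig_xyz <- as.matrix(heavy[, c("x", "y", "z")])
  prot <- protein_atoms[protein_atoms$element != "H", , drop = FALSE]
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  if (method == "neighbors") {
    if (!nrow(prot_xyz)) return(0)
    d <- cross_dist(lig_xyz, prot_xyz)
    counts <- rowSums(d <= 8)
    return(min(1, max(0, mean(pmin(counts, 15) / 15))))
  }
  free <- shrake_rupley_sasa(lig_xyz, heavy$element, probe = probe,
                             n_points = n_points)
  if (free <= 0) stop("degenerate ligand geometry: zero free SASA")
  complexed <- shrake_rupley_sasa(lig_xyz, heavy$element,
                                  occluders = prot_xyz,
                                  occluder_elements = prot$element,
                                  probe = probe, n_points = n_points)
  min(1, max(0, 1 - complexed / free))
}

CASCADE_STEPS <- data.frame(
  step = 3:12,
  name = c("resolution", "edia", "molecular_weight", "rotatable_bonds",
           "element", "heavy_atoms", "duplicate_removal", "activity",
           "ligand_efficiency", "buriedness"),
  stringsAsFactors = FALSE
)

#' Apply the ligand selection cascade
#'
#' Applies the selection steps in fixed order (resolution, EDIA, molecular
#' weight, rotatable bonds, element filter, heavy atoms, duplicate removal,
#' activity presence, ligand efficiency, buriedness) and attributes every
#' discard to its first failing step. Entries with unknown resolution fail
#' the resolution step; ligands without an EDIA score fail the EDIA step.
#'
#' @param ligands list of perceived `LigandInstance` objects (no skip_reason)
#' @param activity data.frame of activity records (see
#'   [read_activity_table()])
#' @param edia_table data.frame of EDIA scores or `NULL`
#' @param thresholds a `FilterThresholds` object
#' @param entries named list of `StructureEntry` objects (resolution lookup
#'   and protein atoms for buriedness)
#' @param le_selection passed to [min_le_for_ligand()]
#' @param buriedness_method passed to [compute_buriedness()]
#' @return a `FilterReport` list: `report` (per-step data.frame), `survivors`
#'   (ligand keys), `ligands` (surviving instances with le/buriedness/edia
#'   attached)
#' @export
apply_cascade <- function(ligands, activity = NULL, edia_table = NULL,
                          thresholds = filter_thresholds(),
                          entries = list(),
                          le_selection = "min_p",
                          buriedness_method = "sasa") {
  stopifnot(inherits(thresholds, "FilterThresholds"))
  report <- CASCADE_STEPS
  report$entries_discarded <- 0L
  report$entries_remaining <- NA_integer_
  pool <- ligands
  n_remaining <- length(pool)

  discard_step <- function(keep, step_name) {
    idx <- which(report$name == step_name)
    report$entries_discarded[idx] <<- n_remaining - sum(keep)
    n_remaining <<- sum(keep)
    report$entries_remaining[idx] <<- n_remaining
    pool[keep]
  }

  # 3: resolution
  keep <- vapply(pool, function(l) {
    res <- entries[[l$entry_id]]$resolution %||% NA_real_
    !is.na(res) && res <= thresholds$max_resolution
  }, logical(1))
  pool <- discard_step(keep, "resolution")

  # 4: EDIA_m
  pool <- lapply(pool, function(l) { l$edia <- lookup_edia(l, edia_table); l })
  keep <- vapply(pool, function(l) !is.na(l$edia) && l$edia > thresholds$min_edia,
                 logical(1))
  pool <- discard_step(keep, "edia")

  # 5: molecular weight
  keep <- vapply(pool, function(l)
    l$properties$molecular_weight <= thresholds$max_molecular_weight,
    logical(1))
  pool <- discard_step(keep, "molecular_weight")

  # 6: rotatable bonds
  keep <- vapply(pool, function(l)
    l$properties$rotatable_bonds <= thresholds$max_rotatable_bonds,
    logical(1))
  pool <- discard_step(keep, "rotatable_bonds")

  # 7: element filter
  keep <- vapply(pool, function(l)
    all(l$properties$elements %in% thresholds$allowed_elements),
    logical(1))
  pool <- discard_step(keep, "element")

  # 8: heavy atoms
  keep <- vapply(pool, function(l)
    l$properties$heavy_atom_count >= thresholds$min_heavy_atoms,
    logical(1))
  pool <- discard_step(keep, "heavy_atoms")

  # 9: duplicate removal (best EDIA per (entry, SMILES))
  kept <- dedupe_by_edia(pool)
  kept_keys <- vapply(kept, lig_key, character(1))
  keep <- vapply(pool, function(l) lig_key(l) %in% kept_keys, logical(1))
  pool <- discard_step(keep, "duplicate_removal")

  # 10: activity presence + 11: ligand efficiency
  pool <- lapply(pool, function(l) {
    recs <- NULL
    if (!is.null(activity) && nrow(activity)) {
      recs <- activity[activity$entry_id == l$entry_id &
                         activity$het == l$residue_name, , drop = FALSE]
    }
    eff <- min_le_for_ligand(recs, l$properties$heavy_atom_count,
                             selection = le_selection)
    l$efficiency <- eff
    l
  })
  keep <- vapply(pool, function(l) !is.null(l$efficiency), logical(1))
  pool <- discard_step(keep, "activity")

  keep <- vapply(pool, function(l)
    l$efficiency$ligand_efficiency > thresholds$min_ligand_efficiency,
    logical(1))
  pool <- discard_step(keep, "ligand_efficiency")

  # 12: buriedness
  pool <- lapply(pool, function(l) {
    if (is.null(l$buriedness)) {
      entry <- entries[[l$entry_id]]
      l$buriedness <- if (is.null(entry)) 0 else
        compute_buriedness(l, entry$protein_atoms, method = buriedness_method)
    }
    l
  })
  keep <- vapply(pool, function(l)
    l$buriedness >= thresholds$min_buriedness, logical(1))
  pool <- discard_step(keep, "buriedness")

  out <- list(
    report = report,
    survivors = vapply(pool, lig_key, character(1), USE.NAMES = FALSE),
    ligands = pool,
    n_input = length(ligands)
  )
  class(out) <- "FilterReport"
  out
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("<FilterReport> %d in -> %d surviving\n", x$n_input,
              length(x$survivors)))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Export a filter report as TSV
#'
#' @param x a `FilterReport`
#' @param path output path
#' @return the path, invisibly
#' @export
write_filter_report <- function(x, path) {
  stopifnot(inherits(x, "FilterReport"))
  df <- x$report
  names(df) <- c("step", "filter", "entries_discarded", "entries_remaining")
  write_tsv(df, path)
}
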