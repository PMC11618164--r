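#' Extract the binding site of a ligand
#'
#' The pocket is every residue with at least one atom (hydrogens included)
#' within `radius` of any ligand atom. The site records the selected
#' residues, their backbone coordinates (N, CA, C, O per backbone-complete
#' residue) and a canonical sequence signature: per-chain concatenation of
#' one-letter codes in residue order, with chains ordered by (selected-run
#' length descending, sequence string, chain id); non-standard residues map
#' to 'X'.
#'
#' @param ligand `LigandInstance` belonging to `structure`
#' @param structure the `StructureEntry` holding the ligand
#' @param radius pocket radius in Angstrom
#' @return a `BindingSite` list
#' @export
extract_binding_site <- function(ligand, structure, radius = 6.5) {
  stopifnot(inherits(structure, "StructureEntry"))
  lig_xyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  sel_chain <- character(0); sel_resno <- integer(0); sel_ins <- character(0)
  sel_one <- character(0); sel_complete <- logical(0)
  sel_bb <- list()
  for (ch in structure$chains) {
    res <- ch$residues
    pa <- structure$protein_atoms[structure$protein_atoms$chain == ch$chain_id, ,
                                  drop = FALSE]
    for (i in seq_len(nrow(res))) {
      ra <- pa[pa$resno == res$resno[i] & pa$ins == res$ins[i], , drop = FALSE]
      if (!nrow(ra)) next
      if (min_dist(as.matrix(ra[, c("x", "y", "z")]), lig_xyz) <= radius) {
        sel_chain <- c(sel_chain, ch$chain_id)
        sel_resno <- c(sel_resno, res$resno[i])
        sel_ins <- c(sel_ins, res$ins[i])
        sel_one <- c(sel_one, res$one[i])
        sel_complete <- c(sel_complete, res$backbone_complete[i])
        sel_bb[[length(sel_bb) + 1L]] <- ch$backbone[i, , ]
      }
    }
  }
  if (!length(sel_resno)) {
    stop("no residue within ", radius, " A of ligand ", lig_key(ligand))
  }
  residues <- data.frame(
    chain = sel_chain, resno = sel_resno, ins = sel_ins, one = sel_one,
    backbone_complete = sel_complete, stringsAsFactors = FALSE
  )
  # canonical chain ordering for the signature and the 1:1 residue pairing
  chain_seq <- vapply(split(residues$one, residues$chain), paste,
                      character(1), collapse = "")
  ord_chains <- names(chain_seq)[order(-nchar(chain_seq), chain_seq,
                                       names(chain_seq))]
  ord <- order(match(residues$chain, ord_chains))
  residues <- residues[ord, , drop = FALSE]
  sel_bb <- sel_bb[ord]
  site <- list(
    ligand_key = lig_key(ligand),
    entry_id = ligand$entry_id,
    residues = residues,
    backbone = sel_bb,
    signature = paste(chain_seq[ord_chains], collapse = "|")
  )
  class(site) <- "BindingSite"
  site
}

#' Build a binding-site index
#'
#' One site per surviving ligand, grouped by sequence signature for exact
#' matching.
#'
#' @param entries named list of `StructureEntry` objects
#' @param survivor_keys ligand keys that passed the filter cascade
#' @param radius pocket radius in Angstrom
#' @return a `SiteIndex` list with `sites` (named by ligand key) and
#'   `by_signature`
#' @export
build_site_index <- function(entries, survivor_keys, radius = 6.5) {
  sites <- list()
  for (entry in entries) {
    for (key in names(entry$ligand_candidates)) {
      if (!(key %in% survivor_keys)) next
      lig <- entry$ligand_candidates[[key]]
      sites[[key]] <- extract_binding_site(lig, entry, radius = radius)
    }
  }
  sigs <- vapply(sites, function(s) s$signature, character(1))
  idx <- list(sites = sites, by_signature = split(names(sites), sigs))
  class(idx) <- "SiteIndex"
  idx
}

#' Find all sites with a sequence identical to the query's
#'
#' Exact signature matching (chains paired under the canonical chain order,
#' which realizes the chain bijection for multi-chain pockets). The query's
#' own site is included in the result.
#'
#' @param query a `BindingSite`
#' @param site_index a `SiteIndex`
#' @return list of matching `BindingSite` objects
#' @export
find_identical_sites <- function(query, site_index) {
  hits <- site_index$by_signature[[query$signature]]
  site_index$sites[hits %||% character(0)]
}

#' Kabsch superposition
#'
#' Least-squares rigid transform (proper rotation) minimizing the RMSD
#' between two equal-length ordered point sets.
#'
#' @param ref_coords n x 3 reference points
#' @param mov_coords n x 3 moving points (rows paired with `ref_coords`)
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd`, and `transform(x)` applying the fit to new points; the fitted
#'   points are `mov %*% rotation + translation`
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref <- as.matrix(ref_coords); mov <- as.matrix(mov_coords)
  if (nrow(ref) != nrow(mov)) stop("point sets must have equal length")
  if (nrow(ref) < 3) stop("need at least 3 points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  r0 <- sweep(ref, 2, cr); m0 <- sweep(mov, 2, cm)
  sv_r <- svd(r0)$d
  if (sv_r[2] < 1e-8 * max(sv_r[1], 1)) stop("degenerate (collinear) points")
  s <- svd(t(m0) %*% r0)
  d <- sign(det(s$u) * det(s$v))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cr - cm %*% rot
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(
    rotation = rot,
    translation = as.numeric(trans),
    rmsd = rmsd,
    transform = function(x) sweep(as.matrix(x) %*% rot, 2, as.numeric(trans), "+")
  )
}

site_backbone_matrix <- function(site, use = NULL) {
  use <- use %||% which(site$residues$backbone_complete)
  if (!length(use)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, site$backbone[use])
}

#' Build a ligand ensemble from a query pocket
#'
#' Superimposes the backbone of every sequence-identical site onto the query
#' site's backbone (over the residues backbone-complete in both sites of the
#' 1:1 pairing), transforms each matched site's ligand into the query frame
#' and records the backbone RMSD. The ensemble is named after the query
#' (search) ligand. Matched sites with fewer than 3 usable backbone residues
#' are skipped with a log entry.
#'
#' @param query_key ligand key of the search ligand
#' @param site_index a `SiteIndex`
#' @param entries named list of `StructureEntry` objects
#' @return a `LigandEnsemble`
#' @export
build_ensemble <- function(query_key, site_index, entries) {
  qsite <- site_index$sites[[query_key]]
  if (is.null(qsite)) stop("no site for ligand ", query_key)
  hits <- find_identical_sites(qsite, site_index)
  members <- list()
  for (hit in hits) {
    usable <- which(qsite$residues$backbone_complete &
                      hit$residues$backbone_complete)
    if (length(usable) < 3) {
      ov_log("skipping site %s for query %s: <3 usable backbone residues",
             hit$ligand_key, query_key)
      next
    }
    ref <- site_backbone_matrix(qsite, usable)
    mov <- site_backbone_matrix(hit, usable)
    fit <- kabsch_superpose(ref, mov)
    lig <- entries[[hit$entry_id]]$ligand_candidates[[hit$ligand_key]]
    members[[hit$ligand_key]] <- list(
      key = hit$ligand_key,
      entry_id = lig$entry_id,
      residue_name = lig$residue_name,
      chain_id = lig$chain_id,
      residue_number = lig$residue_number,
      smiles = lig$smiles,
      mol = lig$mol,
      coords = fit$transform(lig$mol$coords),
      backbone_rmsd = fit$rmsd
    )
  }
  ens <- list(
    name = query_key,
    search_ligand = query_key,
    members = members,
    complexes = vapply(members, function(m) m$key, character(1), USE.NAMES = FALSE),
    removed = FALSE
  )
  class(ens) <- "LigandEnsemble"
  ens
}

#' @export
print.LigandEnsemble <- function(x, ...) {
  cat(sprintf("<LigandEnsemble %s> %d members%s\n", x$name,
              length(x$members), if (isTRUE(x$removed)) " [removed]" else ""))
  invisible(x)
}

#' Deduplicate ensemble members by unique SMILES
#'
#' Within one ensemble, only one member per canonical SMILES is retained: the
#' one with the lowest binding-site backbone RMSD (ties keep the
#' lexicographically smallest ligand key and are logged). Ensembles left with
#' fewer than 2 members are marked removed.
#'
#' @param ensemble a `LigandEnsemble`
#' @return the deduplicated ensemble
#' @export
deduplicate_members <- function(ensemble) {
  stopifnot(inherits(ensemble, "LigandEnsemble"))
  members <- ensemble$members
  if (length(members)) {
    smiles <- vapply(members, function(m) m$smiles, character(1))
    keep <- character(0)
    for (s in unique(smiles)) {
      idx <- which(smiles == s)
      rmsd <- vapply(members[idx], function(m) m$backbone_rmsd, numeric(1))
      best <- idx[rmsd == min(rmsd)]
      if (length(best) > 1) {
        keys <- vapply(members[best], function(m) m$key, character(1))
        best <- best[order(keys)][1]
        ov_log("RMSD tie in ensemble %s: keeping %s", ensemble$name,
               members[[best]]$key)
      }
      keep <- c(keep, members[[best[1]]]$key)
    }
    members <- members[vapply(members, function(m) m$key %in% keep, logical(1))]
  }
  ensemble$members <- members
  ensemble$complexes <- vapply(members, function(m) m$key, character(1),
                               USE.NAMES = FALSE)
  ensemble$removed <- length(members) < 2
  ensemble
}

#' Build, deduplicate and prune all ensembles for a survivor set
#'
#' One ensemble per surviving ligand (as search ligand); members are
#' SMILES-deduplicated and singleton ensembles are dropped.
#'
#' @param entries named list of `StructureEntry` objects
#' @param survivor_keys ligand keys that passed the filter cascade
#' @param radius pocket radius in Angstrom
#' @return named list of retained `LigandEnsemble` objects
#' @export
build_all_ensembles <- function(entries, survivor_keys, radius = 6.5) {
  idx <- build_site_index(entries, survivor_keys, radius = radius)
  out <- list()
  for (key in names(idx$sites)) {
    ens <- deduplicate_members(build_ensemble(key, idx, entries))
    if (!ens$removed) out[[ens$name]] <- ens
  }
  out
}
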