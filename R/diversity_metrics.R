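#' Bemis-Murcko scaffold
#'
#' Ring systems plus the linkers connecting them; acyclic terminal
#' substituents are pruned iteratively, then atoms multiple-bonded to the
#' retained framework (e.g. linker carbonyl oxygens) are restored. Acyclic
#' molecules yield the empty scaffold "" (its own scaffold class).
#'
#' @param mol perceived molecule (`ov_mol`)
#' @return canonical scaffold SMILES ("" if the molecule has no ring)
#' @export
bemis_murcko_scaffold <- function(mol) {
  stopifnot(inherits(mol, "ov_mol"))
  heavy <- which(!mol$is_h)
  if (!length(heavy)) return("")
  bonds <- mol$bonds[!mol$is_h[mol$bonds$a1] & !mol$is_h[mol$bonds$a2], ,
                     drop = FALSE]
  keep <- rep(FALSE, length(mol$elements))
  keep[heavy] <- TRUE
  # iterative pruning of terminal heavy atoms -> rings + linkers remain
  repeat {
    deg <- integer(length(mol$elements))
    act <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
    for (i in seq_len(nrow(act))) {
      deg[act$a1[i]] <- deg[act$a1[i]] + 1L
      deg[act$a2[i]] <- deg[act$a2[i]] + 1L
    }
    terminal <- which(keep & deg <= 1L)
    if (!length(terminal)) break
    keep[terminal] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return("")
  # restore atoms attached to the framework by a multiple bond
  repeat {
    add <- integer(0)
    for (i in seq_len(nrow(bonds))) {
      b <- bonds[i, ]
      if (b$order < 2) next
      if (keep[b$a1] && !keep[b$a2]) add <- c(add, b$a2)
      if (keep[b$a2] && !keep[b$a1]) add <- c(add, b$a1)
    }
    if (!length(add)) break
    keep[add] <- TRUE
  }
  idx <- which(keep)
  atoms <- data.frame(
    element = mol$elements[idx],
    x = mol$coords[idx, 1], y = mol$coords[idx, 2], z = mol$coords[idx, 3],
    stringsAsFactors = FALSE
  )
  sub <- perceive_atoms(atoms, het = "SCF")
  if (is.null(sub)) return("")
  sub$smiles
}

#' Area under the scaffold recovery curve
#'
#' Scaffolds sorted by frequency descending; the curve runs through the
#' origin and the points (i / N_scaffolds, cumulative molecule fraction);
#' AUC by the trapezoid rule. 0.5 means every molecule has its own scaffold
#' (maximal diversity); values toward 1 indicate scaffold concentration.
#' With a single scaffold class the curve degenerates to the diagonal and
#' the result carries attribute `degenerate = TRUE`.
#'
#' @param scaffolds character vector of scaffold labels, one per molecule
#' @return AUC in [0.5, 1]
#' @export
scaffold_auc <- function(scaffolds) {
  if (!length(scaffolds)) stop("empty molecule set")
  counts <- sort(table(scaffolds), decreasing = TRUE)
  ns <- length(counts)
  xs <- c(0, seq_len(ns) / ns)
  ys <- c(0, cumsum(as.numeric(counts)) / sum(counts))
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  if (ns == 1) attr(auc, "degenerate") <- TRUE
  auc
}

#' Median pairwise MACCS Tanimoto similarity
#'
#' 166-key structural fingerprints; median of the Tanimoto coefficient over
#' all unordered distinct pairs.
#'
#' @param mols list of perceived molecules (`ov_mol`), length >= 2
#' @return median similarity in [0, 1], or `NA` for fewer than 2 molecules
#' @export
median_pairwise_similarity <- function(mols) {
  if (length(mols) < 2) return(NA_real_)
  fp <- maccs_fingerprints(mols)
  sims <- numeric(0)
  for (i in seq_len(nrow(fp) - 1)) {
    for (j in seq(i + 1, nrow(fp))) {
      a <- fp[i, ] > 0; b <- fp[j, ] > 0
      u <- sum(a | b)
      sims <- c(sims, if (u == 0) 0 else sum(a & b) / u)
    }
  }
  median(sims)
}

#' Consensus diversity coordinates for molecule sets
#'
#' One row per set: median MACCS Tanimoto similarity and Bemis-Murcko
#' scaffold recovery AUC, the two axes of a consensus diversity plot.
#'
#' @param sets named list; each element a list of `ov_mol` molecules
#' @return data.frame (set_id, set_size, median_fp_similarity, scaffold_auc)
#' @export
consensus_diversity <- function(sets) {
  rows <- lapply(names(sets), function(nm) {
    mols <- sets[[nm]]
    data.frame(
      set_id = nm,
      set_size = length(mols),
      median_fp_similarity = median_pairwise_similarity(mols),
      scaffold_auc = as.numeric(scaffold_auc(
        vapply(mols, bemis_murcko_scaffold, character(1)))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Heavy-atom-count statistics of an ensemble
#'
#' Mean and sample (n-1) standard deviation of the members' heavy atom
#' counts.
#'
#' @param ensemble a `LigandEnsemble` (or numeric vector of HACs)
#' @return an `EnsembleStats` list: n_members, hac_mean, hac_sd, hac_range
#' @export
ensemble_stats <- function(ensemble) {
  hacs <- if (is.numeric(ensemble)) ensemble else
    vapply(ensemble$members, function(m) sum(!m$mol$is_h), numeric(1))
  out <- list(
    n_members = length(hacs),
    hac_mean = mean(hacs),
    hac_sd = sd(hacs),
    hac_range = range(hacs)
  )
  class(out) <- "EnsembleStats"
  out
}

#' Property distribution summary of a molecule set
#'
#' Quantiles (min, quartiles, median, max) per descriptor: molecular weight,
#' SlogP, HBD, HBA, rotatable bonds.
#'
#' @param props list of `LigandProperties` (as attached by
#'   [perceive_molecule()])
#' @return data.frame with one row per property
#' @export
property_distribution_summary <- function(props) {
  get <- function(field) vapply(props, function(p) as.numeric(p[[field]]),
                                numeric(1))
  fields <- c(molecular_weight = "molecular_weight", slogp = "slogp",
              hbd = "hbd", hba = "hba", rotatable_bonds = "rotatable_bonds")
  rows <- lapply(names(fields), function(nm) {
    v <- get(fields[[nm]])
    qs <- quantile(v, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(property = nm, min = qs[1], q25 = qs[2], median = qs[3],
               q75 = qs[4], max = qs[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Release-date growth of the pair set
#'
#' Each pair is counted in the later of its two entries' release years;
#' pairs with a missing date are excluded with a log entry.
#'
#' @param pairs data.frame with template_key and query_key columns
#' @param release_dates named vector/list of entry release `Date`s
#' @return data.frame (year, n_pairs, cumulative)
#' @export
release_growth <- function(pairs, release_dates) {
  entry_of <- function(key) sub("^.*-", "", key)
  years <- vapply(seq_len(nrow(pairs)), function(i) {
    e1 <- entry_of(pairs$template_key[i]); e2 <- entry_of(pairs$query_key[i])
    d1 <- release_dates[[e1]] %||% as.Date(NA)
    d2 <- release_dates[[e2]] %||% as.Date(NA)
    if (is.na(d1) || is.na(d2)) return(NA_integer_)
    max(as.integer(format(d1, "%Y")), as.integer(format(d2, "%Y")))
  }, integer(1))
  if (anyNA(years)) {
    ov_log("release_growth: excluding %d pair(s) with missing dates",
           sum(is.na(years)))
    years <- years[!is.na(years)]
  }
  tab <- table(years)
  df <- data.frame(
    year = as.integer(names(tab)),
    n_pairs = as.integer(tab)
  )
  df <- df[order(df$year), , drop = FALSE]
  df$cumulative <- cumsum(df$n_pairs)
  df
}
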