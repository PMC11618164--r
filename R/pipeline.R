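#' Run configuration
#'
#' Bundles inputs and tunables of a full run; persisted verbatim into every
#' stage manifest so a run is reproducible from (inputs, config).
#'
#' @param input_dir directory of PDB entries (`*.pdb`)
#' @param activity_tsv activity table path (may be `NULL`)
#' @param edia_tsv EDIA table path (may be `NULL`)
#' @param out_dir output root
#' @param thresholds a [filter_thresholds()] object
#' @param pocket_radius binding-site radius, Angstrom
#' @param grid_spacing volume-overlap lattice spacing, Angstrom
#' @param le_value_selection `"min_p"` or `"min_molar"`
#' @param clustering_variant `"merge"` or `"first_match"`
#' @param covalent_cutoff heavy-atom covalency gate, Angstrom
#' @param buriedness_method `"sasa"` or `"neighbors"`
#' @param seed integer seed recorded in manifests
#' @return a `RunConfig` list
#' @export
run_config <- function(input_dir, activity_tsv = NULL, edia_tsv = NULL,
                       out_dir = "overlayset_run",
                       thresholds = filter_thresholds(),
                       pocket_radius = 6.5, grid_spacing = 0.4,
                       le_value_selection = "min_p",
                       clustering_variant = "merge",
                       covalent_cutoff = 1.9,
                       buriedness_method = "sasa",
                       seed = 1L) {
  cfg <- list(
    input_dir = input_dir, activity_tsv = activity_tsv, edia_tsv = edia_tsv,
    out_dir = out_dir, thresholds = thresholds,
    pocket_radius = pocket_radius, grid_spacing = grid_spacing,
    le_value_selection = le_value_selection,
    clustering_variant = clustering_variant,
    covalent_cutoff = covalent_cutoff,
    buriedness_method = buriedness_method,
    seed = as.integer(seed)
  )
  if (!le_value_selection %in% c("min_p", "min_molar")) {
    stop_config("le_value_selection must be min_p or min_molar")
  }
  if (!clustering_variant %in% c("merge", "first_match")) {
    stop_config("clustering_variant must be merge or first_match")
  }
  class(cfg) <- "RunConfig"
  cfg
}

stop_config <- function(msg) {
  stop(structure(class = c("overlayset_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_missing_input <- function(msg) {
  stop(structure(class = c("overlayset_missing_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stage_manifest <- function(config, stage, counts, dir) {
  jsonlite::write_json(
    list(
      stage = stage,
      counts = counts,
      config = config[setdiff(names(config), "thresholds")],
      thresholds = unclass(config$thresholds)
    ),
    file.path(dir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

.entry_cache <- new.env(parent = emptyenv())

# Parse + classify every entry of the input directory. Cached in-process per
# (directory, file set, mtimes) so consecutive stages of one run do not
# re-perceive identical inputs; artifacts on disk stay plain text.
load_entries <- function(config) {
  files <- sort(list.files(config$input_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  if (!length(files)) {
    stop_missing_input(paste0("no PDB entries found in ", config$input_dir))
  }
  key <- digest_key(c(files, format(file.mtime(files), "%Y%m%d%H%M%OS6"),
                      format(config$covalent_cutoff)))
  if (!is.null(.entry_cache[[key]])) return(.entry_cache[[key]])
  entries <- list()
  for (f in files) {
    e <- classify_candidates(parse_structure(f),
                             covalent_cutoff = config$covalent_cutoff)
    entries[[e$entry_id]] <- e
  }
  .entry_cache[[key]] <- entries
  entries
}

digest_key <- function(parts) {
  paste0("k", sum(utf8ToInt(paste(parts, collapse = "|")) *
                    seq_along(utf8ToInt(paste(parts, collapse = "|")))))
}

clean_ligands <- function(entries) {
  ligs <- list()
  for (e in entries) {
    for (l in e$ligand_candidates) {
      if (is.null(l$skip_reason)) ligs[[lig_key(l)]] <- l
    }
  }
  ligs
}

#' Run one pipeline stage
#'
#' Stages: `extract` (parse + classify + descriptor table), `filter` (the
#' selection cascade), `ensembles` (site index + superimposed ensembles as
#' SDF), `cluster`, `pairs` (Shape Tversky subsets from representative
#' ensembles), `stats` (diversity analytics), `all`. Each stage writes its
#' TSV/SDF outputs plus a JSON stage manifest under `config$out_dir`.
#'
#' @param stage stage name
#' @param config a [run_config()] object
#' @return invisibly, a list of stage artifacts
#' @export
run_stage <- function(stage = c("all", "extract", "filter", "ensembles",
                                "cluster", "pairs", "stats"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    out <- list()
    for (s in c("extract", "filter", "ensembles", "cluster", "pairs",
                "stats")) {
      out[[s]] <- run_stage(s, config)
    }
    return(invisible(out))
  }
  switch(stage,
    extract = stage_extract(config),
    filter = stage_filter(config),
    ensembles = stage_ensembles(config),
    cluster = stage_cluster(config),
    pairs = stage_pairs(config),
    stats = stage_stats(config)
  )
}

stage_extract <- function(config) {
  entries <- load_entries(config)
  ent_rows <- lapply(entries, function(e) data.frame(
    entry_id = e$entry_id,
    resolution = e$resolution %||% NA_real_,
    release_date = as.character(e$release_date %||% NA),
    n_chains = length(e$chains),
    n_candidates = length(e$ligand_candidates),
    exclusion = e$exclusion %||% "",
    stringsAsFactors = FALSE
  ))
  lig_rows <- lapply(clean_and_skipped(entries), function(l) data.frame(
    ligand_key = lig_key(l),
    entry_id = l$entry_id, het = l$residue_name, chain = l$chain_id,
    resnum = l$residue_number,
    skip_reason = l$skip_reason %||% "",
    smiles = l$smiles %||% "",
    molecular_weight = l$properties$molecular_weight %||% NA_real_,
    heavy_atom_count = l$properties$heavy_atom_count %||% NA_integer_,
    rotatable_bonds = l$properties$rotatable_bonds %||% NA_integer_,
    hbd = l$properties$hbd %||% NA_integer_,
    hba = l$properties$hba %||% NA_integer_,
    slogp = l$properties$slogp %||% NA_real_,
    stringsAsFactors = FALSE
  ))
  write_tsv(do.call(rbind, ent_rows), file.path(config$out_dir, "entries.tsv"))
  write_tsv(do.call(rbind, lig_rows), file.path(config$out_dir, "ligands.tsv"))
  stage_manifest(config, "extract",
                 list(entries = length(entries),
                      ligand_candidates = length(clean_and_skipped(entries)),
                      clean_ligands = length(clean_ligands(entries))),
                 config$out_dir)
  invisible(list(entries = entries))
}

clean_and_skipped <- function(entries) {
  out <- list()
  for (e in entries) for (l in e$ligand_candidates) out[[lig_key(l)]] <- l
  out
}

read_activity_maybe <- function(config) {
  if (is.null(config$activity_tsv)) return(NULL)
  if (!file.exists(config$activity_tsv)) {
    stop_missing_input(paste0("activity table not found: ",
                              config$activity_tsv))
  }
  read_activity_table(config$activity_tsv)
}

read_edia_maybe <- function(config) {
  if (is.null(config$edia_tsv)) return(NULL)
  if (!file.exists(config$edia_tsv)) {
    stop_missing_input(paste0("EDIA table not found: ", config$edia_tsv))
  }
  read_edia_table(config$edia_tsv)
}

stage_filter <- function(config) {
  entries <- load_entries(config)
  ligs <- clean_ligands(entries)
  rep <- apply_cascade(
    ligs,
    activity = read_activity_maybe(config),
    edia_table = read_edia_maybe(config),
    thresholds = config$thresholds,
    entries = entries,
    le_selection = config$le_value_selection,
    buriedness_method = config$buriedness_method
  )
  write_filter_report(rep, file.path(config$out_dir, "filter_report.tsv"))
  write_tsv(data.frame(ligand_key = rep$survivors),
            file.path(config$out_dir, "survivors.tsv"))
  stage_manifest(config, "filter",
                 list(input = rep$n_input, survivors = length(rep$survivors)),
                 config$out_dir)
  invisible(list(report = rep, entries = entries))
}

require_artifact <- function(config, file, producer) {
  path <- file.path(config$out_dir, file)
  if (!file.exists(path)) {
    stop_missing_input(sprintf(
      "missing artifact %s (run the %s stage first)", path, producer))
  }
  path
}

stage_ensembles <- function(config) {
  survivors <- read_tsv(require_artifact(config, "survivors.tsv",
                                         "filter"))$ligand_key
  entries <- load_entries(config)
  idx <- build_site_index(entries, survivors, radius = config$pocket_radius)
  site_rows <- lapply(idx$sites, function(s) data.frame(
    signature = s$signature, entry_id = s$entry_id,
    ligand_key = s$ligand_key, stringsAsFactors = FALSE
  ))
  write_tsv(do.call(rbind, site_rows),
            file.path(config$out_dir, "site_index.tsv"))
  ens_dir <- file.path(config$out_dir, "ensembles")
  dir.create(ens_dir, showWarnings = FALSE)
  kept <- list()
  ens_rows <- list()
  for (key in names(idx$sites)) {
    ens <- deduplicate_members(build_ensemble(key, idx, entries))
    ens_rows[[key]] <- data.frame(
      ensemble_name = ens$name,
      search_ligand = ens$search_ligand,
      n_members = length(ens$members),
      removed_singleton = ens$removed,
      stringsAsFactors = FALSE
    )
    if (!ens$removed) {
      kept[[ens$name]] <- ens
      write_ensemble_sdf(ens, file.path(ens_dir, paste0(ens$name, ".sdf")))
    }
  }
  write_tsv(do.call(rbind, ens_rows),
            file.path(config$out_dir, "ensembles.tsv"))
  stage_manifest(config, "ensembles",
                 list(sites = length(idx$sites), kept = length(kept)),
                 config$out_dir)
  invisible(list(ensembles = kept))
}

read_kept_ensembles <- function(config) {
  ens_dir <- file.path(config$out_dir, "ensembles")
  if (!dir.exists(ens_dir)) {
    stop_missing_input(sprintf(
      "missing artifact %s (run the ensembles stage first)", ens_dir))
  }
  files <- sort(list.files(ens_dir, pattern = "\\.sdf$", full.names = TRUE))
  ens <- lapply(files, read_ensemble_sdf)
  names(ens) <- vapply(ens, function(e) e$name, character(1))
  ens
}

stage_cluster <- function(config) {
  ens <- read_kept_ensembles(config)
  clusters <- cluster_ensembles(order_ensembles(ens),
                                variant = config$clustering_variant)
  write_cluster_table(clusters, file.path(config$out_dir, "clusters.tsv"))
  stage_manifest(config, "cluster",
                 list(ensembles = length(ens), clusters = length(clusters)),
                 config$out_dir)
  invisible(list(clusters = clusters))
}

representative_ensembles <- function(config) {
  path <- require_artifact(config, "clusters.tsv", "cluster")
  tab <- read_tsv(path)
  ens <- read_kept_ensembles(config)
  ens[tab$ensemble_name[tab$is_representative == TRUE |
                          tab$is_representative == "TRUE"]]
}

stage_pairs <- function(config) {
  reps <- representative_ensembles(config)
  pairs <- score_pairs(reps, spacing = config$grid_spacing)
  write_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))
  # per-subset directories with one SDF per pair (template record first)
  sub_root <- file.path(config$out_dir, "subsets")
  dir.create(sub_root, showWarnings = FALSE)
  for (i in seq_len(nrow(pairs))) {
    sdir <- file.path(sub_root, pairs$subset[i])
    dir.create(sdir, showWarnings = FALSE)
    ens <- reps[[pairs$ensemble_name[i]]]
    keys <- vapply(ens$members, function(m) m$key, character(1))
    pair_ens <- ens
    pair_ens$members <- ens$members[c(which(keys == pairs$template_key[i]),
                                      which(keys == pairs$query_key[i]))]
    pair_ens$search_ligand <- pairs$template_key[i]
    fname <- sprintf("%s__%s.sdf",
                     gsub("/", "_", pairs$template_key[i]),
                     gsub("/", "_", pairs$query_key[i]))
    write_ensemble_sdf(pair_ens, file.path(sdir, fname))
  }
  stage_manifest(config, "pairs",
                 list(representatives = length(reps), pairs = nrow(pairs)),
                 config$out_dir)
  invisible(list(pairs = pairs))
}

stage_stats <- function(config) {
  reps <- representative_ensembles(config)
  pairs_path <- require_artifact(config, "pairs.tsv", "pairs")
  pairs <- read_tsv(pairs_path)
  sets <- lapply(reps, function(e) lapply(e$members, function(m) m$mol))
  cdp <- consensus_diversity(sets)
  write_tsv(cdp, file.path(config$out_dir, "cdp.tsv"))
  st_rows <- lapply(reps, function(e) {
    s <- ensemble_stats(e)
    data.frame(ensemble_name = e$name, n_members = s$n_members,
               hac_mean = s$hac_mean, hac_sd = s$hac_sd,
               hac_min = s$hac_range[1], hac_max = s$hac_range[2],
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, st_rows),
            file.path(config$out_dir, "ensemble_stats.tsv"))
  entries_tab <- read_tsv(require_artifact(config, "entries.tsv", "extract"))
  dates <- setNames(as.list(as.Date(entries_tab$release_date)),
                    entries_tab$entry_id)
  growth <- release_growth(pairs, dates)
  write_tsv(growth, file.path(config$out_dir, "growth.tsv"))
  lig_tab <- read_tsv(require_artifact(config, "ligands.tsv", "extract"))
  surv <- read_tsv(require_artifact(config, "survivors.tsv", "filter"))
  lt <- lig_tab[lig_tab$ligand_key %in% surv$ligand_key, , drop = FALSE]
  props <- lapply(seq_len(nrow(lt)), function(i) as.list(lt[i, ]))
  write_tsv(property_distribution_summary(props),
            file.path(config$out_dir, "property_summary.tsv"))
  stage_manifest(config, "stats",
                 list(representatives = length(reps), pairs = nrow(pairs)),
                 config$out_dir)
  invisible(list(cdp = cdp, growth = growth))
}

#' Validate cross-file consistency of a completed run
#'
#' Checks: survivor keys are a subset of extracted ligand keys; every pair's
#' members belong to exactly one representative ensemble; subset sizes sum to
#' the total pair count; the filter report conserves counts at every step.
#'
#' @param run_dir the run output directory
#' @return character vector of violations (empty if the run is consistent)
#' @export
validate_outputs <- function(run_dir) {
  violations <- character(0)
  need <- c("ligands.tsv", "survivors.tsv", "filter_report.tsv",
            "clusters.tsv", "pairs.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing)) {
    return(sprintf("%s: missing artifact", file.path(run_dir, missing)))
  }
  ligands <- read_tsv(file.path(run_dir, "ligands.tsv"))
  survivors <- read_tsv(file.path(run_dir, "survivors.tsv"))
  bad <- setdiff(survivors$ligand_key, ligands$ligand_key)
  if (length(bad)) {
    violations <- c(violations, sprintf(
      "survivors.tsv: key %s not among extracted ligands", bad))
  }
  rep <- read_tsv(file.path(run_dir, "filter_report.tsv"))
  before <- c(nrow(survivors) + sum(rep$entries_discarded),
              rep$entries_remaining[-nrow(rep)])
  ok <- before - rep$entries_discarded == rep$entries_remaining
  if (!all(ok)) {
    violations <- c(violations, sprintf(
      "filter_report.tsv: count conservation violated at step %d",
      rep$step[!ok]))
  }
  clusters <- read_tsv(file.path(run_dir, "clusters.tsv"))
  reps <- clusters$ensemble_name[clusters$is_representative %in%
                                   c(TRUE, "TRUE")]
  pairs <- read_tsv(file.path(run_dir, "pairs.tsv"))
  if (nrow(pairs)) {
    bad <- !(pairs$ensemble_name %in% reps)
    if (any(bad)) {
      violations <- c(violations, sprintf(
        "pairs.tsv row %d: ensemble %s is not a representative",
        which(bad), pairs$ensemble_name[bad]))
    }
    member_keys <- unique(c(pairs$template_key, pairs$query_key))
    ens_of <- lapply(member_keys, function(k)
      unique(pairs$ensemble_name[pairs$template_key == k |
                                   pairs$query_key == k]))
    multi <- lengths(ens_of) > 1
    if (any(multi)) {
      violations <- c(violations, sprintf(
        "pairs.tsv: ligand %s occurs in more than one representative ensemble",
        member_keys[multi]))
    }
    tab <- table(pairs$subset)
    if (sum(tab) != nrow(pairs)) {
      violations <- c(violations, "pairs.tsv: subset sizes do not sum to total")
    }
  }
  violations
}
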