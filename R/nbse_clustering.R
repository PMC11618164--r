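#' Order ensembles for clustering
#'
#' Largest member count first; ties broken by ensemble name ascending.
#'
#' @param ensembles list of `LigandEnsemble` objects
#' @return the reordered list
#' @export
order_ensembles <- function(ensembles) {
  nm <- vapply(ensembles, function(e) e$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate ensemble names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  sizes <- vapply(ensembles, function(e) length(e$members), integer(1))
  ensembles[order(-sizes, nm)]
}

#' Group intersecting ensembles into clusters
#'
#' Two ensembles intersect if they share a protein-ligand complex. Ensembles
#' are processed in the given order: one intersecting no existing cluster
#' founds a new cluster, one intersecting exactly one joins it, and one
#' intersecting several merges them all (full transitive merging, so the
#' result equals the connected components of the shares-a-complex graph).
#' The `"first_match"` variant joins only the first intersecting cluster and
#' never merges.
#'
#' @param ensembles list of `LigandEnsemble` objects, typically from
#'   [order_ensembles()]
#' @param variant `"merge"` (default) or `"first_match"`
#' @return list of `EnsembleCluster` objects (fields `ensembles`,
#'   `representative`)
#' @export
cluster_ensembles <- function(ensembles, variant = c("merge", "first_match")) {
  variant <- match.arg(variant)
  clusters <- list()   # each: list(ensembles = list, complexes = character)
  for (ens in ensembles) {
    hit <- which(vapply(clusters, function(cl)
      any(ens$complexes %in% cl$complexes), logical(1)))
    if (!length(hit)) {
      clusters[[length(clusters) + 1L]] <-
        list(ensembles = list(ens), complexes = ens$complexes)
    } else if (length(hit) == 1 || variant == "first_match") {
      h <- hit[1]
      clusters[[h]]$ensembles <- c(clusters[[h]]$ensembles, list(ens))
      clusters[[h]]$complexes <- union(clusters[[h]]$complexes, ens$complexes)
    } else {
      merged <- list(ensembles = list(ens), complexes = ens$complexes)
      for (h in hit) {
        merged$ensembles <- c(merged$ensembles, clusters[[h]]$ensembles)
        merged$complexes <- union(merged$complexes, clusters[[h]]$complexes)
      }
      clusters <- clusters[-hit]
      clusters[[length(clusters) + 1L]] <- merged
    }
  }
  lapply(clusters, function(cl) {
    cl$representative <- pick_representative(cl)
    class(cl) <- "EnsembleCluster"
    cl
  })
}

#' Pick the representative ensemble of a cluster
#'
#' The ensemble whose search ligand has the highest heavy atom count; ties
#' are broken by ensemble name ascending (logged).
#'
#' @param cluster an `EnsembleCluster` (or list with an `ensembles` field)
#' @return the representative's ensemble name
#' @export
pick_representative <- function(cluster) {
  ens <- cluster$ensembles
  stopifnot(length(ens) > 0)
  hac <- vapply(ens, function(e) {
    m <- e$members[[e$search_ligand]]
    if (!is.null(m$mol)) sum(!m$mol$is_h) else e$search_hac %||% NA_integer_
  }, numeric(1))
  nm <- vapply(ens, function(e) e$name, character(1))
  best <- which(hac == max(hac))
  if (length(best) > 1) {
    best <- best[order(nm[best])]
    ov_log("representative HAC tie: choosing %s", nm[best[1]])
  }
  nm[best[1]]
}

#' Export a cluster table as TSV
#'
#' One row per (cluster, ensemble) with the representative flag, member count
#' and search-ligand heavy atom count.
#'
#' @param clusters list of `EnsembleCluster` objects
#' @param path output path
#' @return the path, invisibly
#' @export
write_cluster_table <- function(clusters, path) {
  rows <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    for (e in cl$ensembles) {
      m <- e$members[[e$search_ligand]]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = i,
        ensemble_name = e$name,
        is_representative = e$name == cl$representative,
        n_members = length(e$members),
        search_ligand_hac = if (!is.null(m$mol)) sum(!m$mol$is_h)
                            else e$search_hac %||% NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  write_tsv(do.call(rbind, rows), path)
}
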