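#' Ordered ligand pairs, Shape Tversky scores and difficulty subsets
#'
#' Within an ensemble every ordered (template, query) combination is a pair;
#' the Shape Tversky Index with t = 1, q = 0 measures the fraction of the
#' template's van der Waals volume covered by the query, and pairs are binned
#' into 0.1-wide difficulty subsets.
#'
#' @name pair_shapes
NULL

#' Enumerate all ordered pairs of an ensemble
#'
#' @param ensemble a `LigandEnsemble` with >= 2 members carrying superimposed
#'   coordinates
#' @return data.frame with template/query member indices and keys
#' @export
enumerate_pairs <- function(ensemble) {
  stopifnot(inherits(ensemble, "LigandEnsemble"))
  n <- length(ensemble$members)
  if (n < 2) stop("ensemble must have at least 2 members")
  idx <- expand.grid(template = seq_len(n), query = seq_len(n))
  idx <- idx[idx$template != idx$query, , drop = FALSE]
  keys <- vapply(ensemble$members, function(m) m$key, character(1))
  data.frame(
    template = idx$template, query = idx$query,
    template_key = keys[idx$template], query_key = keys[idx$query],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

member_heavy_coords <- function(member) {
  member$coords[!member$mol$is_h, , drop = FALSE]
}

member_heavy_elements <- function(member) {
  member$mol$elements[!member$mol$is_h]
}

#' Grid-counted van der Waals volume overlap of two molecules
#'
#' Hard-sphere occupancy (Bondi radii) on a common cubic lattice spanning the
#' pair's bounding box plus a margin of twice the largest radius. Volumes are
#' occupied-cell counts times spacing^3.
#'
#' @param template_coords,query_coords heavy-atom coordinate matrices in the
#'   common ensemble frame
#' @param template_elements,query_elements element symbols for radii
#' @param spacing lattice spacing in Angstrom
#' @return list with `overlap`, `non_overlap_template`, `non_overlap_query`
#'   (Angstrom^3) and the occupied-cell counts
#' @export
volume_overlap <- function(template_coords, query_coords,
                           template_elements, query_elements,
                           spacing = 0.4) {
  if (spacing <= 0) stop("spacing must be positive")
  tc <- as.matrix(template_coords); qc <- as.matrix(query_coords)
  tr <- vdw_radius(template_elements); qr <- vdw_radius(query_elements)
  margin <- 2 * max(tr, qr)
  lo <- pmin(apply(tc, 2, min), apply(qc, 2, min)) - margin
  hi <- pmax(apply(tc, 2, max), apply(qc, 2, max)) + margin
  dims <- pmax(1L, ceiling((hi - lo) / spacing))
  ax <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 0.5) * spacing)

  occupancy <- function(coords, radii) {
    occ <- array(FALSE, dim = dims)
    for (i in seq_len(nrow(coords))) {
      rng <- lapply(1:3, function(k) {
        which(abs(ax[[k]] - coords[i, k]) <= radii[i])
      })
      if (any(!lengths(rng))) next
      sub <- expand.grid(rng[[1]], rng[[2]], rng[[3]])
      d2 <- (ax[[1]][sub[, 1]] - coords[i, 1])^2 +
        (ax[[2]][sub[, 2]] - coords[i, 2])^2 +
        (ax[[3]][sub[, 3]] - coords[i, 3])^2
      inside <- d2 <= radii[i]^2
      occ[as.matrix(sub[inside, , drop = FALSE])] <- TRUE
    }
    occ
  }

  occ_t <- occupancy(tc, tr)
  occ_q <- occupancy(qc, qr)
  cell <- spacing^3
  n_both <- sum(occ_t & occ_q)
  n_t_only <- sum(occ_t & !occ_q)
  n_q_only <- sum(occ_q & !occ_t)
  list(
    overlap = n_both * cell,
    non_overlap_template = n_t_only * cell,
    non_overlap_query = n_q_only * cell,
    cells = c(both = n_both, template_only = n_t_only, query_only = n_q_only)
  )
}

#' Shape Tversky Index
#'
#' `overlap / (overlap + t * nonOverlap(T) + q * nonOverlap(Q))`. With the
#' default t = 1, q = 0 this is the fraction of the template volume covered
#' by the query.
#'
#' @param template,query members (lists with `coords` and `mol`) or heavy-atom
#'   coordinate matrices
#' @param t,q Tversky weights
#' @param spacing grid spacing passed to [volume_overlap()]
#' @param template_elements,query_elements element symbols when raw matrices
#'   are given (default carbon radii)
#' @return index in [0, 1]
#' @export
shape_tversky <- function(template, query, t = 1, q = 0, spacing = 0.4,
                          template_elements = NULL, query_elements = NULL) {
  if (is.list(template) && !is.null(template$mol)) {
    template_elements <- member_heavy_elements(template)
    template <- member_heavy_coords(template)
  }
  if (is.list(query) && !is.null(query$mol)) {
    query_elements <- member_heavy_elements(query)
    query <- member_heavy_coords(query)
  }
  template_elements <- template_elements %||% rep("C", nrow(template))
  query_elements <- query_elements %||% rep("C", nrow(query))
  v <- volume_overlap(template, query, template_elements, query_elements,
                      spacing = spacing)
  denom_t <- v$overlap + v$non_overlap_template
  if (denom_t <= 0) stop("template volume is zero")
  v$overlap / (v$overlap + t * v$non_overlap_template + q * v$non_overlap_query)
}

#' Assign a pair to its difficulty subset
#'
#' Half-open 0.1-wide bins `subset_XX` with XX = 10 * floor(10 * index); an
#' index of exactly 1.0 closes the top bin (subset_90).
#'
#' @param index Shape Tversky Index in [0, 1]
#' @return subset label
#' @export
assign_subset <- function(index) {
  if (any(index < 0 | index > 1)) stop("index must be within [0, 1]")
  bin <- pmin(9L, as.integer(floor(index * 10)))
  sprintf("subset_%d", bin * 10L)
}

#' Score all ordered pairs of one or more ensembles
#'
#' @param ensembles list of `LigandEnsemble` objects (typically cluster
#'   representatives)
#' @param spacing grid spacing in Angstrom
#' @param t,q Tversky weights
#' @return data.frame: ensemble_name, template_key, query_key, shape_tversky,
#'   subset
#' @export
score_pairs <- function(ensembles, spacing = 0.4, t = 1, q = 0) {
  rows <- list()
  for (ens in ensembles) {
    pairs <- enumerate_pairs(ens)
    sti <- vapply(seq_len(nrow(pairs)), function(i) {
      shape_tversky(ens$members[[pairs$template[i]]],
                    ens$members[[pairs$query[i]]],
                    t = t, q = q, spacing = spacing)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      ensemble_name = ens$name,
      template_key = pairs$template_key,
      query_key = pairs$query_key,
      shape_tversky = sti,
      subset = assign_subset(sti),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows) %||% data.frame()
}
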