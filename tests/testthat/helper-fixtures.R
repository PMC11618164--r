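# Shared fixtures, memoized per test process: scenario generation and the
# full pipeline run are the expensive parts of the suite, so every test file
# reuses one instance.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

fixture_mol <- function(smiles) {
  memo(paste0("mol_", smiles), function() overlayset:::mol_from_smiles(smiles))
}

filter_scenario <- function() {
  memo("filter_scenario", function() make_filter_scenario(seed = 1L))
}

# Parse + classify all entries of a generated scenario.
scenario_entries <- function(scenario) {
  entries <- list()
  for (id in names(scenario$entries_pdb)) {
    e <- parse_structure(paste(scenario$entries_pdb[[id]], collapse = "\n"),
                         entry_id = id)
    entries[[id]] <- classify_candidates(e)
  }
  entries
}

scenario_clean_ligands <- function(entries) {
  ligs <- list()
  for (e in entries) {
    for (l in e$ligand_candidates) {
      if (is.null(l$skip_reason)) ligs[[overlayset:::lig_key(l)]] <- l
    }
  }
  ligs
}

filter_run <- function() {
  memo("filter_run", function() {
    sc <- filter_scenario()
    entries <- scenario_entries(sc)
    ligs <- scenario_clean_ligands(entries)
    rep <- apply_cascade(ligs, sc$activity, sc$edia, filter_thresholds(),
                         entries)
    list(scenario = sc, entries = entries, ligands = ligs, report = rep)
  })
}

ensemble_entries <- function() {
  memo("ensemble_entries", function() {
    scenario_entries(ensemble_run()$scenario)
  })
}

# Full pipeline (`all` stages) on the ensemble scenario via run_stage.
ensemble_run <- function() {
  memo("ensemble_run", function() {
    sc <- make_ensemble_scenario(seed = 1L)
    dir <- file.path(tempdir(), "overlayset_ens_scenario")
    unlink(dir, recursive = TRUE)
    write_scenario(sc, dir)
    out <- file.path(dir, "run")
    cfg <- run_config(
      input_dir = file.path(dir, "pdb"),
      activity_tsv = file.path(dir, "activity.tsv"),
      edia_tsv = file.path(dir, "edia.tsv"),
      out_dir = out, seed = 1L
    )
    res <- suppressMessages(run_stage("all", cfg))
    list(scenario = sc, dir = dir, out = out, config = cfg, result = res)
  })
}

# Independent rigid-superposition oracle: Horn's quaternion method via an
# eigendecomposition (no SVD), used to cross-check the Kabsch fit.
quaternion_superpose_rmsd <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  r0 <- sweep(ref, 2, colMeans(ref)); m0 <- sweep(mov, 2, colMeans(mov))
  s <- t(m0) %*% r0
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n <- rbind(
    c(sxx + syy + szz, syz - szy, szx - sxz, sxy - syx),
    c(syz - szy, sxx - syy - szz, sxy + syx, szx + sxz),
    c(szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy),
    c(sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz)
  )
  lam <- max(eigen(n, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- sum(r0^2) + sum(m0^2) - 2 * lam
  sqrt(max(0, e2) / nrow(ref))
}

# Monte-Carlo volume oracle for two heavy-atom sphere sets: uniform points in
# the joint bounding box classified against both occupancies.
mc_tversky <- function(tc, qc, tr, qr, n = 2e5, seed = 7) {
  set.seed(seed)
  lo <- pmin(apply(tc, 2, min) - max(tr), apply(qc, 2, min) - max(qr))
  hi <- pmax(apply(tc, 2, max) + max(tr), apply(qc, 2, max) + max(qr))
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
               runif(n, lo[3], hi[3]))
  inside <- function(coords, radii) {
    hit <- rep(FALSE, n)
    for (i in seq_len(nrow(coords))) {
      d2 <- (pts[, 1] - coords[i, 1])^2 + (pts[, 2] - coords[i, 2])^2 +
        (pts[, 3] - coords[i, 3])^2
      hit <- hit | d2 <= radii[i]^2
    }
    hit
  }
  it <- inside(tc, tr); iq <- inside(qc, qr)
  sum(it & iq) / sum(it)
}

# Monte-Carlo surface-accessibility oracle (random sphere points, not the
# deterministic spiral used by the implementation).
mc_buriedness <- function(lig_xyz, lig_el, prot_xyz, prot_el, probe = 1.4,
                          n = 400, seed = 11) {
  set.seed(seed)
  rl <- overlayset:::vdw_radius(lig_el) + probe
  rp <- overlayset:::vdw_radius(prot_el) + probe
  area <- function(occluders, occ_radii) {
    tot <- 0
    for (i in seq_len(nrow(lig_xyz))) {
      v <- matrix(rnorm(3 * n), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      pts <- sweep(v * rl[i], 2, lig_xyz[i, ], "+")
      acc <- rep(TRUE, n)
      for (j in seq_len(nrow(lig_xyz))) {
        if (j == i) next
        acc <- acc & (pts[, 1] - lig_xyz[j, 1])^2 +
          (pts[, 2] - lig_xyz[j, 2])^2 +
          (pts[, 3] - lig_xyz[j, 3])^2 >= rl[j]^2
      }
      if (!is.null(occluders)) {
        for (j in seq_len(nrow(occluders))) {
          acc <- acc & (pts[, 1] - occluders[j, 1])^2 +
            (pts[, 2] - occluders[j, 2])^2 +
            (pts[, 3] - occluders[j, 3])^2 >= occ_radii[j]^2
        }
      }
      tot <- tot + 4 * pi * rl[i]^2 * mean(acc)
    }
    tot
  }
  free <- area(NULL, NULL)
  complexed <- area(prot_xyz, rp)
  1 - complexed / free
}
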