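test_that("Kabsch recovers exact and noisy rigid transforms", {
  set.seed(21)
  ref <- matrix(rnorm(30), ncol = 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  # 37-degree rotation about z plus a shift is inverted exactly
  th <- 37 * pi / 180
  rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mov <- sweep(ref %*% t(rz), 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose(ref, mov)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$transform(mov), ref, tolerance = 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # noisy point sets agree with an independent quaternion-eigen oracle
  for (k in 1:10) {
    a <- matrix(rnorm(36), ncol = 3)
    b <- a + matrix(rnorm(36, sd = 0.3), ncol = 3)
    expect_equal(kabsch_superpose(a, b)$rmsd,
                 quaternion_superpose_rmsd(a, b), tolerance = 1e-9)
  }

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("binding sites select residues by the any-atom 6.5 A rule", {
  # two residues: nearest atoms at 6.4 and 6.6 A from the ligand atom
  pdb <- paste(c(
    "HEADER    SYNTHETIC COMPLEX                       05-JAN-10   TST2",
    "REMARK   2 RESOLUTION.    1.50 ANGSTROMS.",
    sprintf("ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            1:8, rep(c("N", "CA", "C", "O"), 2), rep(c("GLY", "ALA"), each = 4),
            rep(1:2, each = 4),
            c(6.4, 7.4, 8.0, 9.0, 6.6, 7.6, 8.2, 9.2),
            rep(0, 8), rep(0, 8), rep(c("N", "C", "C", "O"), 2)),
    "TER",
    "HETATM    9  C1  LIG A  10       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ), collapse = "\n")
  e <- parse_structure(pdb, entry_id = "tst2")
  site <- extract_binding_site(e$ligand_candidates[[1]], e, radius = 6.5)
  expect_identical(site$residues$resno, 1L)
  expect_identical(site$signature, "G")
  # isolated ligand: no residue in range is an error
  expect_error(extract_binding_site(e$ligand_candidates[[1]], e, radius = 2),
               "no residue")
})

test_that("ensembles are named after the search ligand key", {
  expect_identical(ligand_key("5L2", "A", 302, "4zx0"), "5L2_A_302-4zx0")
})

test_that("identical-sequence matching groups the scenario families", {
  idx <- build_site_index(
    ensemble_entries()[c("e101", "e102", "e301")],
    c("LGA_A_201-e101", "LGB_A_201-e102", "SNG_A_101-e301")
  )
  q <- idx$sites[["LGA_A_201-e101"]]
  hits <- find_identical_sites(q, idx)
  expect_setequal(vapply(hits, function(s) s$ligand_key, character(1)),
                  c("LGA_A_201-e101", "LGB_A_201-e102"))
  # a different pocket sequence is never returned
  expect_false("SNG_A_101-e301" %in%
                 vapply(hits, function(s) s$ligand_key, character(1)))
})

test_that("member deduplication keeps the lowest backbone RMSD per SMILES", {
  mk <- function(key, smiles, rmsd) {
    list(key = key, smiles = smiles, backbone_rmsd = rmsd,
         entry_id = sub("^.*-", "", key))
  }
  ens <- structure(list(
    name = "X_A_1-aaaa", search_ligand = "X_A_1-aaaa",
    members = list(
      "X_A_1-aaaa" = mk("X_A_1-aaaa", "c1ccccc1", 0),
      "X_A_1-bbbb" = mk("X_A_1-bbbb", "CCO", 0.5),
      "X_A_1-cccc" = mk("X_A_1-cccc", "CCO", 0.2)
    ),
    complexes = c("X_A_1-aaaa", "X_A_1-bbbb", "X_A_1-cccc"),
    removed = FALSE
  ), class = "LigandEnsemble")
  d <- deduplicate_members(ens)
  expect_setequal(d$complexes, c("X_A_1-aaaa", "X_A_1-cccc"))
  expect_false(d$removed)
  # complexes set size equals member count after dedup
  expect_length(d$complexes, length(d$members))

  # RMSD tie: lexicographically smallest key is kept
  tie <- ens
  tie$members[["X_A_1-bbbb"]]$backbone_rmsd <- 0.2
  d2 <- suppressMessages(deduplicate_members(tie))
  expect_true("X_A_1-bbbb" %in% d2$complexes)

  # reduction to one member marks the ensemble removed
  solo <- ens
  solo$members <- ens$members[c(2, 3)]
  solo$members[[1]]$smiles <- "CCO"
  solo$search_ligand <- "X_A_1-bbbb"
  d3 <- deduplicate_members(solo)
  expect_true(d3$removed)
})

test_that("an exactly moved pocket copy superimposes back within 1e-6 A", {
  # full-precision rigid copy of a parsed entry (no file round trip)
  entry <- ensemble_entries()[["e201"]]
  set.seed(55)
  rot <- overlayset:::random_rotation()
  shift <- runif(3, -10, 10)
  move <- function(m) sweep(as.matrix(m) %*% t(rot), 2, shift, "+")
  copy <- entry
  copy$entry_id <- "e999"
  xyz <- move(entry$protein_atoms[, c("x", "y", "z")])
  copy$protein_atoms[, c("x", "y", "z")] <- xyz
  for (ch in names(copy$chains)) {
    bb <- copy$chains[[ch]]$backbone
    for (i in seq_len(dim(bb)[1])) bb[i, , ] <- move(bb[i, , ])
    copy$chains[[ch]]$backbone <- bb
  }
  for (k in names(copy$ligand_candidates)) {
    lig <- copy$ligand_candidates[[k]]
    lig$entry_id <- "e999"
    lig$atoms[, c("x", "y", "z")] <- move(lig$atoms[, c("x", "y", "z")])
    lig$mol$coords <- move(lig$mol$coords)
    copy$ligand_candidates[[k]] <- lig
  }
  names(copy$ligand_candidates) <- sub("-e201$", "-e999",
                                       names(copy$ligand_candidates))
  entries <- list(e201 = entry, e999 = copy)
  keys <- names(entries$e201$ligand_candidates)
  survivors <- c(keys, names(copy$ligand_candidates))
  idx <- build_site_index(entries, survivors)
  ens <- build_ensemble(keys[1], idx, entries)
  rmsds <- vapply(ens$members, function(m) m$backbone_rmsd, numeric(1))
  expect_true(all(rmsds < 1e-6))
  # the moved copy's ligand lands exactly on the original pose
  orig <- entries$e201$ligand_candidates[[keys[1]]]$mol$coords
  moved_key <- sub("-e201$", "-e999", keys[1])
  expect_lt(max(abs(ens$members[[moved_key]]$coords - orig)), 1e-6)
})

test_that("rigid-copy pockets recover ground truth at coordinate precision", {
  run <- ensemble_run()
  gt <- run$scenario$manifest$fam2_ground_truth
  ens <- run$result$ensembles$ensembles[["ANT_A_301-e202"]]
  tr <- gt$transforms[["e202"]]
  rmsds <- vapply(ens$members, function(m) m$backbone_rmsd, numeric(1))
  # entries carry 3-decimal coordinates, so recovery is exact to that scale
  expect_true(all(rmsds < 5e-3))
  for (key in names(gt$poses)) {
    truth <- sweep(gt$poses[[key]] %*% t(tr$rotation), 2, tr$shift, "+")
    got <- ens$members[[key]]$coords
    got_heavy <- got[!ens$members[[key]]$mol$is_h, , drop = FALSE]
    expect_lt(max(abs(unname(got_heavy) - unname(truth))), 5e-3)
  }
})
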