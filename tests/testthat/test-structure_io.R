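minimal_pdb <- function(het_lines = character(0),
                        resolution = "REMARK   2 RESOLUTION. 2.00 ANGSTROMS.") {
  paste(c(
    "HEADER    SYNTHETIC COMPLEX                       05-JAN-10   TST1",
    resolution,
    "REVDAT   1   05-JAN-10 TST1    0",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.010   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.230   1.540   0.000  1.00  0.00           O",
    "ATOM      5  N   CYS A   2       4.000   0.000   2.000  1.00  0.00           N",
    "ATOM      6  CA  CYS A   2       5.458   0.000   2.000  1.00  0.00           C",
    "ATOM      7  C   CYS A   2       6.010   1.420   2.000  1.00  0.00           C",
    "ATOM      8  O   CYS A   2       7.230   1.540   2.000  1.00  0.00           O",
    "ATOM      9  SG  CYS A   2       5.000  -1.500   3.500  1.00  0.00           S",
    "TER      10      CYS A   2",
    het_lines,
    "END"
  ), collapse = "\n")
}

het_line <- function(serial, name, het, resnum, x, y, z, el,
                     chain = "A") {
  sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    serial, name, het, chain, resnum, x, y, z, el
  )
}

test_that("header fields, candidates and the no-ligand flag are parsed", {
  e <- parse_structure(minimal_pdb(), entry_id = "tst1")
  expect_equal(e$resolution, 2.0)
  expect_equal(format(e$release_date), "2010-01-05")
  expect_identical(e$exclusion, "no_ligand")
  expect_length(e$ligand_candidates, 0)

  lig <- het_line(11, "C1", "LIG", 90, 10, 10, 10, "C")
  e2 <- parse_structure(minimal_pdb(lig), entry_id = "tst1")
  expect_null(e2$exclusion)
  expect_length(e2$ligand_candidates, 1)
  expect_identical(names(e2$ligand_candidates), "LIG_A_90-tst1")

  # waters are dropped before candidate listing
  wat <- het_line(12, "O1", "HOH", 95, 12, 12, 12, "O")
  e3 <- parse_structure(minimal_pdb(c(lig, wat)), entry_id = "tst1")
  expect_length(e3$ligand_candidates, 1)

  # unknown resolution is retained at parse time (rejected later)
  e4 <- parse_structure(minimal_pdb(lig, resolution = "REMARK   1 X"),
                        entry_id = "tst1")
  expect_true(is.na(e4$resolution))
})

test_that("malformed coordinate records and empty input are parse errors", {
  bad <- sub("       0.000", "      xx.000", minimal_pdb())
  expect_error(parse_structure(bad, entry_id = "tst1"), "line 4")
  expect_error(parse_structure("", entry_id = "tst1"), "empty")
})

test_that("fixture complexes parse back to their manifest ground truth", {
  tc <- make_toy_complex(pocket_seq = "GASLVTKF",
                         ligand_smiles = "c1ccccc1CCN", resolution = 1.8,
                         seed = 11, entry_id = "tc11")
  e <- parse_structure(paste(tc$pdb, collapse = "\n"), entry_id = "tc11")
  expect_equal(e$resolution, 1.8)
  expect_length(e$chains, tc$manifest$n_chains)
  expect_length(e$ligand_candidates, 1)
  expect_equal(nrow(e$ligand_candidates[[1]]$atoms),
               tc$manifest$n_ligand_atoms)
  # round trip preserves coordinates at PDB precision
  got <- as.matrix(e$ligand_candidates[[1]]$atoms[, c("x", "y", "z")])
  expect_equal(unname(got), unname(tc$manifest$ligand_pose),
               tolerance = 1e-3)
  # the generator's pocket ground truth matches the extraction rule
  e <- classify_candidates(e)
  site <- extract_binding_site(e$ligand_candidates[[1]], e)
  expect_equal(sort(site$residues$resno), tc$manifest$pocket_resnos)
  expect_identical(site$signature, "GASLVTKF")
})

test_that("candidate classification flags metals, covalent and polymer links", {
  zn <- het_line(11, "ZN", "ZN", 90, 10, 10, 10, "Zn")
  cov <- het_line(12, "C1", "COV", 91, 5.0, -1.5, 5.0, "C")   # 1.5 A from SG
  free <- c(
    het_line(13, "C1", "FRE", 92, 10, 6, 6, "C"),
    het_line(14, "C2", "FRE", 92, 11.4, 6, 6, "C")
  )
  e <- parse_structure(minimal_pdb(c(zn, cov, free)), entry_id = "tst1")
  e <- classify_candidates(e, covalent_cutoff = 1.9)
  expect_identical(e$ligand_candidates[["ZN_A_90-tst1"]]$skip_reason,
                   "metal_ion")
  expect_identical(e$ligand_candidates[["COV_A_91-tst1"]]$skip_reason,
                   "covalent")
  expect_null(e$ligand_candidates[["FRE_A_92-tst1"]]$skip_reason)

  # two HETATM groups bonded to each other are a polymer
  poly <- c(
    het_line(15, "C1", "PLA", 93, 20, 20, 20, "C"),
    het_line(16, "C1", "PLB", 94, 21.4, 20, 20, "C")
  )
  e2 <- classify_candidates(parse_structure(minimal_pdb(poly),
                                            entry_id = "tst1"))
  expect_identical(e2$ligand_candidates[["PLA_A_93-tst1"]]$skip_reason,
                   "polymer")
  expect_identical(e2$ligand_candidates[["PLB_A_94-tst1"]]$skip_reason,
                   "polymer")

  # idempotence: a second pass yields identical flags
  e3 <- classify_candidates(e, covalent_cutoff = 1.9)
  expect_identical(
    lapply(e$ligand_candidates, function(l) l$skip_reason),
    lapply(e3$ligand_candidates, function(l) l$skip_reason)
  )
})

test_that("ensemble SDF export round-trips and orders records by RMSD", {
  run <- ensemble_run()
  ens <- run$result$ensembles$ensembles[["ANT_A_301-e202"]]
  path <- tempfile(fileext = ".sdf")
  write_ensemble_sdf(ens, path)
  back <- read_ensemble_sdf(path)
  expect_identical(back$name, ens$name)
  expect_identical(back$members[[1]]$key, ens$search_ligand)
  rmsd <- unname(vapply(back$members, function(m) m$backbone_rmsd,
                        numeric(1)))
  expect_equal(rmsd[1], 0, tolerance = 1e-3)
  expect_true(all(diff(rmsd) >= 0))
  for (m in back$members) {
    orig <- ens$members[[m$key]]
    expect_equal(unname(m$coords), unname(orig$coords), tolerance = 1e-3)
  }
  # refuse to write a member without coordinates
  broken <- ens
  broken$members[[1]]$coords <- NULL
  expect_error(write_ensemble_sdf(broken, tempfile(fileext = ".sdf")),
               "coordinates")
})
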