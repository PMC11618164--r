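fake_lig <- function(entry, smiles, edia, chain = "A", resnum = 1L,
                     het = "LIG") {
  list(entry_id = entry, residue_name = het, chain_id = chain,
       residue_number = resnum, smiles = smiles, edia = edia)
}

test_that("duplicate removal keeps the best EDIA instance per entry+SMILES", {
  a <- fake_lig("aaaa", "c1ccccc1", 0.85, resnum = 1L)
  b <- fake_lig("aaaa", "c1ccccc1", 0.92, resnum = 2L)
  kept <- dedupe_by_edia(list(a, b))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$edia, 0.92)

  # same SMILES in different entries: both kept
  c2 <- fake_lig("bbbb", "c1ccccc1", 0.85)
  expect_length(dedupe_by_edia(list(a, c2)), 2)

  # single instance unchanged
  expect_length(dedupe_by_edia(list(a)), 1)

  # EDIA tie: lexicographically smallest (chain, resnum) wins
  t1 <- fake_lig("cccc", "CCO", 0.9, chain = "B", resnum = 5L)
  t2 <- fake_lig("cccc", "CCO", 0.9, chain = "A", resnum = 9L)
  kept <- suppressMessages(dedupe_by_edia(list(t1, t2)))
  expect_length(kept, 1)
  expect_identical(kept[[1]]$chain_id, "A")
})

test_that("buriedness matches trivial cases and the Monte-Carlo oracle", {
  lig <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  far <- data.frame(element = "C", x = 50, y = 50, z = 50)
  expect_equal(compute_buriedness(lig, far), 0)

  # dense synthetic cage around a single atom: nearly fully buried
  sph <- overlayset:::golden_spiral_points(200) * 4.0
  cage <- data.frame(element = "C", x = sph[, 1], y = sph[, 2], z = sph[, 3])
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  b_cage <- compute_buriedness(one, cage)
  expect_gte(b_cage, 0.95)
  mc <- mc_buriedness(as.matrix(one[, c("x", "y", "z")]), "C",
                      as.matrix(cage[, c("x", "y", "z")]),
                      rep("C", nrow(cage)))
  expect_lt(abs(b_cage - mc), 0.05)

  # half-exposed: planar wall below the ligand
  wall <- expand.grid(x = seq(-6, 6, 1.2), y = seq(-6, 6, 1.2), z = -3)
  wall <- data.frame(element = "C", wall)
  b_wall <- compute_buriedness(lig, wall)
  mc_wall <- mc_buriedness(as.matrix(lig[, c("x", "y", "z")]),
                           lig$element,
                           as.matrix(wall[, c("x", "y", "z")]),
                           wall$element)
  expect_lt(abs(b_wall - mc_wall), 0.05)
  expect_lt(b_wall, 0.6)

  # invariant under rigid transformation of the whole complex, up to the
  # angular resolution of the fixed surface-point set
  set.seed(8)
  r <- overlayset:::random_rotation(); t <- rnorm(3, sd = 10)
  rot <- function(df) {
    xyz <- sweep(as.matrix(df[, c("x", "y", "z")]) %*% t(r), 2, t, "+")
    data.frame(element = df$element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  expect_lt(abs(compute_buriedness(rot(lig), rot(wall)) - b_wall), 0.01)
})

test_that("the engineered scenario is filtered exactly as constructed", {
  run <- filter_run()
  sc <- run$scenario
  rep <- run$report
  expect_identical(rep$n_input, 12L)
  expect_identical(rep$report$entries_discarded,
                   unname(sc$manifest$expected_discarded))
  expect_identical(sort(rep$survivors), sc$manifest$expected_survivors)
  # conservation at every step
  before <- c(rep$n_input, rep$report$entries_remaining[-10])
  expect_identical(before - rep$report$entries_discarded,
                   rep$report$entries_remaining)
  # steps appear in cascade order
  expect_identical(rep$report$step, 3:12)
  # idempotence on survivors
  rep2 <- apply_cascade(rep$ligands, sc$activity, sc$edia,
                        filter_thresholds(), run$entries)
  expect_true(all(rep2$report$entries_discarded == 0))
  expect_identical(sort(rep2$survivors), sort(rep$survivors))
})

test_that("survivors are order-invariant and thresholds act monotonically", {
  run <- filter_run()
  sc <- run$scenario
  shuffled <- run$ligands[sample(length(run$ligands))]
  rep_a <- apply_cascade(shuffled, sc$activity, sc$edia, filter_thresholds(),
                         run$entries)
  expect_identical(sort(rep_a$survivors), sort(run$report$survivors))
  # tightening any threshold never increases the survivor count
  tighter <- list(
    filter_thresholds(max_resolution = 1.0),
    filter_thresholds(min_edia = 0.95),
    filter_thresholds(max_molecular_weight = 120),
    filter_thresholds(max_rotatable_bonds = 1L),
    filter_thresholds(allowed_elements = c("C", "O")),
    filter_thresholds(min_heavy_atoms = 12L),
    filter_thresholds(min_ligand_efficiency = 0.9),
    filter_thresholds(min_buriedness = 0.99)
  )
  for (th in tighter) {
    rep_t <- apply_cascade(run$ligands, sc$activity, sc$edia, th,
                           run$entries)
    expect_lte(length(rep_t$survivors), length(run$report$survivors))
    expect_true(all(rep_t$survivors %in% run$report$survivors))
  }
  # empty input: all rows zero
  rep_e <- apply_cascade(list(), sc$activity, sc$edia, filter_thresholds(),
                         run$entries)
  expect_true(all(rep_e$report$entries_discarded == 0))
  expect_length(rep_e$survivors, 0)
})
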