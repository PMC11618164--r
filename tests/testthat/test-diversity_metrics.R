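test_that("Bemis-Murcko scaffolds keep rings and linkers only", {
  expect_identical(bemis_murcko_scaffold(fixture_mol("Cc1ccccc1")),
                   overlayset:::canonical_smiles("c1ccccc1"))
  expect_identical(bemis_murcko_scaffold(fixture_mol("CCCCCC")), "")
  expect_identical(
    bemis_murcko_scaffold(fixture_mol("c1ccc(Cc2ccccc2)cc1")),
    overlayset:::canonical_smiles("c1ccc(Cc2ccccc2)cc1")
  )
  # acetophenone: the whole acyl side chain is pruned
  expect_identical(bemis_murcko_scaffold(fixture_mol("CC(=O)c1ccccc1")),
                   overlayset:::canonical_smiles("c1ccccc1"))
  # ring-attached carbonyl survives via the multiple-bond restore rule
  expect_identical(bemis_murcko_scaffold(fixture_mol("O=C1CCCCC1")),
                   overlayset:::canonical_smiles("O=C1CCCCC1"))
})

test_that("scaffold recovery AUC matches hand-computed curves", {
  expect_equal(as.numeric(scaffold_auc(letters[1:10])), 0.5)
  labels <- c(rep("common", 99), "rare")
  expect_equal(as.numeric(scaffold_auc(labels)), 0.745)
  one <- scaffold_auc(rep("only", 5))
  expect_equal(as.numeric(one), 0.5)
  expect_true(isTRUE(attr(one, "degenerate")))
  expect_error(scaffold_auc(character(0)), "empty")

  # brute-force curve oracle on random label sets
  set.seed(31)
  brute_auc <- function(labels) {
    counts <- sort(table(labels), decreasing = TRUE)
    ns <- length(counts); total <- sum(counts)
    xs <- seq_len(ns) / ns
    ys <- cumsum(as.numeric(counts)) / total
    auc <- xs[1] * ys[1] / 2
    if (ns > 1) {
      for (i in 2:ns) auc <- auc + (xs[i] - xs[i - 1]) * (ys[i] + ys[i - 1]) / 2
    }
    auc
  }
  for (k in 1:25) {
    labels <- sample(letters[1:sample(2:8, 1)], sample(5:60, 1),
                     replace = TRUE)
    labels <- c(labels, letters[1:2])   # ensure >= 2 classes
    expect_equal(as.numeric(scaffold_auc(labels)), brute_auc(labels),
                 tolerance = 1e-12)
    expect_gte(as.numeric(scaffold_auc(labels)), 0.5 - 1e-12)
    expect_lte(as.numeric(scaffold_auc(labels)), 1)
  }
})

test_that("median pairwise MACCS similarity behaves at its fixed points", {
  m <- fixture_mol("c1ccc2ccccc2c1")
  expect_equal(median_pairwise_similarity(list(m, m, m)), 1.0)
  expect_true(is.na(median_pairwise_similarity(list(m))))

  mols <- list(fixture_mol("c1ccc2ccccc2c1"), fixture_mol("CCO"),
               fixture_mol("CC(=O)Nc1ccccc1"))
  got <- median_pairwise_similarity(mols)
  # independent oracle: set arithmetic on the raw structural-key indices
  sdfset <- overlayset:::as_sdfset(lapply(mols, function(m) m$sdf))
  bits <- ChemmineR::fingerprintOB(sdfset, "MACCS")@fpma
  keysets <- lapply(seq_len(nrow(bits)), function(i) which(bits[i, ] != 0))
  set_tanimoto <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  sims <- c(set_tanimoto(keysets[[1]], keysets[[2]]),
            set_tanimoto(keysets[[1]], keysets[[3]]),
            set_tanimoto(keysets[[2]], keysets[[3]]))
  expect_equal(got, median(sims), tolerance = 1e-12)
  expect_gte(got, 0); expect_lte(got, 1)
  # permutation invariance
  expect_equal(median_pairwise_similarity(mols[c(3, 1, 2)]), got)
})

test_that("ensemble HAC statistics use the sample standard deviation", {
  s <- ensemble_stats(c(18, 43))
  expect_equal(round(s$hac_sd, 2), 17.68)
  expect_equal(ensemble_stats(c(20, 20, 20))$hac_sd, 0)
  expect_equal(ensemble_stats(c(10, 20, 30))$hac_sd, 10)
  # two-pass textbook formula oracle on random inputs
  set.seed(17)
  for (k in 1:20) {
    hacs <- sample(10:60, sample(2:12, 1), replace = TRUE)
    m <- mean(hacs)
    twopass <- sqrt(sum((hacs - m)^2) / (length(hacs) - 1))
    expect_equal(ensemble_stats(hacs)$hac_sd, twopass, tolerance = 1e-12)
  }
})

test_that("property summaries match a sort-based quantile oracle", {
  mk <- function(mw) list(molecular_weight = mw, slogp = 1, hbd = 0, hba = 1,
                          rotatable_bonds = 2)
  one <- property_distribution_summary(list(mk(180)))
  row <- one[one$property == "molecular_weight", ]
  expect_true(all(row[c("min", "q25", "median", "q75", "max")] == 180))

  mws <- c(151, 320, 208, 275, 199, 430, 310)
  tab <- property_distribution_summary(lapply(mws, mk))
  row <- tab[tab$property == "molecular_weight", ]
  expect_equal(row$min, min(mws)); expect_equal(row$max, max(mws))
  expect_equal(row$median, sort(mws)[4])
  expect_equal(as.numeric(row[c("q25", "q75")]),
               as.numeric(quantile(mws, c(0.25, 0.75))))
})

test_that("release growth counts pairs in the later entry's year", {
  pairs <- data.frame(
    template_key = c("A_A_1-aaaa", "A_A_1-aaaa", "B_A_1-bbbb"),
    query_key = c("B_A_1-bbbb", "C_A_1-cccc", "C_A_1-cccc"),
    stringsAsFactors = FALSE
  )
  dates <- list(aaaa = as.Date("1994-05-01"), bbbb = as.Date("2017-01-01"),
                cccc = as.Date("2005-07-07"))
  g <- release_growth(pairs, dates)
  expect_identical(g$year, c(2005L, 2017L))
  expect_identical(g$n_pairs, c(1L, 2L))
  expect_identical(g$cumulative, cumsum(g$n_pairs))
  expect_true(all(diff(g$cumulative) >= 0))
  # missing date: pair excluded with a log entry
  dates$cccc <- as.Date(NA)
  g2 <- suppressMessages(release_growth(pairs, dates))
  expect_identical(sum(g2$n_pairs), 1L)
  expect_identical(g2$year, 2017L)
})
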