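sphere_lens_volume <- function(r, d) {
  # intersection volume of two equal spheres of radius r at center distance d
  if (d >= 2 * r) return(0)
  pi * (4 * r + d) * (2 * r - d)^2 / 12
}

test_that("pair enumeration yields all ordered pairs", {
  mk <- function(n) {
    structure(list(name = "E", search_ligand = "k1",
                   members = setNames(lapply(seq_len(n), function(i)
                     list(key = paste0("k", i))), paste0("k", seq_len(n))),
                   complexes = paste0("k", seq_len(n)), removed = FALSE),
              class = "LigandEnsemble")
  }
  p3 <- enumerate_pairs(mk(3))
  expect_identical(nrow(p3), 6L)
  expect_true(all(p3$template_key != p3$query_key))
  p2 <- enumerate_pairs(mk(2))
  expect_identical(nrow(p2), 2L)
  expect_setequal(paste(p2$template_key, p2$query_key),
                  c("k1 k2", "k2 k1"))
  expect_error(enumerate_pairs(mk(1)), "at least 2")
  # n(n-1) scaling
  for (n in c(4, 7, 12)) expect_identical(nrow(enumerate_pairs(mk(n))),
                                          as.integer(n * (n - 1)))
})

test_that("grid volumes match trivial cases, the lens formula and MC", {
  one <- matrix(c(0, 0, 0), ncol = 3)
  r_c <- overlayset:::vdw_radius("C")

  # identical sets: no exclusive volume
  v <- volume_overlap(one, one, "C", "C")
  expect_equal(v$non_overlap_template, 0)
  expect_equal(v$non_overlap_query, 0)
  expect_gt(v$overlap, 0)

  # two atoms 10 A apart: disjoint
  v2 <- volume_overlap(one, matrix(c(10, 0, 0), ncol = 3), "C", "C")
  expect_equal(v2$overlap, 0)

  # spheres at center distance d = r: within 2 % of the analytic lens volume
  d <- r_c
  v3 <- volume_overlap(one, matrix(c(d, 0, 0), ncol = 3), "C", "C",
                       spacing = 0.25)
  expect_lt(abs(v3$overlap - sphere_lens_volume(r_c, d)) /
              sphere_lens_volume(r_c, d), 0.02)

  # sum rule: overlap + nonOverlap(T) is the template's own cell volume,
  # independent of the query (same lattice forced via shared extremes)
  frame <- rbind(c(4, 4, 4), c(-4, -4, -4))
  q_a <- rbind(c(1.1, 0.4, -0.2), frame)
  q_b <- rbind(c(0.5, 0, 0), frame)
  v_a <- volume_overlap(one, q_a, "C", rep("C", 3))
  v_b <- volume_overlap(one, q_b, "C", rep("C", 3))
  expect_identical(v_a$cells[["both"]] + v_a$cells[["template_only"]],
                   v_b$cells[["both"]] + v_b$cells[["template_only"]])

  expect_error(volume_overlap(one, one, "C", "C", spacing = 0),
               "spacing")
})

test_that("shape Tversky matches its fixed points and the MC oracle", {
  t_coords <- matrix(c(0, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(shape_tversky(t_coords, t_coords), 1.0)

  # template fully inside a larger query: forced to 1 by q = 0
  big <- rbind(t_coords, c(3, 0, 0), c(-1.5, 0, 0), c(0.7, 1.5, 0))
  expect_equal(shape_tversky(t_coords, big), 1.0)

  # disjoint: 0
  expect_equal(shape_tversky(t_coords, t_coords + 20), 0.0)

  # two-sphere suite against the Monte-Carlo oracle (0.25 A lattice: the
  # single-sphere fixture is the worst case for surface discretization)
  set.seed(99)
  for (d in c(1.0, 1.7, 2.5, 3.0)) {
    q_coords <- matrix(c(d, 0, 0), ncol = 3)
    one <- matrix(0, ncol = 3, nrow = 1)
    sti <- shape_tversky(one, q_coords, spacing = 0.25)
    mc <- mc_tversky(one, q_coords, overlayset:::vdw_radius("C"),
                     overlayset:::vdw_radius("C"))
    expect_lt(abs(sti - mc), 0.02)
  }

  # analytic value: query sphere covering exactly the lens fraction
  r_c <- overlayset:::vdw_radius("C")
  d <- r_c
  one <- matrix(0, ncol = 3, nrow = 1)
  expected <- sphere_lens_volume(r_c, d) / (4 / 3 * pi * r_c^3)
  expect_equal(shape_tversky(one, matrix(c(d, 0, 0), ncol = 3),
                             spacing = 0.25), expected, tolerance = 0.02)

  # grid convergence: halving the spacing moves the index by < 0.01
  q_coords <- matrix(c(1.3, 0.5, -0.4, 2.5, 0, 0), ncol = 3, byrow = TRUE)
  i1 <- shape_tversky(t_coords, q_coords, spacing = 0.2)
  i2 <- shape_tversky(t_coords, q_coords, spacing = 0.1)
  expect_lt(abs(i1 - i2), 0.01)

  # monotone in coverage: adding query atoms never decreases the index
  set.seed(5)
  grown <- t_coords
  prev <- shape_tversky(t_coords, grown)
  for (k in 1:5) {
    grown <- rbind(grown, runif(3, -2, 2))
    cur <- shape_tversky(t_coords, grown)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("subset binning is half-open with the top bin closed at 1.0", {
  expect_identical(assign_subset(0.80), "subset_80")
  expect_identical(assign_subset(0.7999), "subset_70")
  expect_identical(assign_subset(1.0), "subset_90")
  expect_identical(assign_subset(0), "subset_0")
  expect_identical(assign_subset(0.0999), "subset_0")
  expect_identical(assign_subset(c(0.15, 0.95)),
                   c("subset_10", "subset_90"))
  expect_error(assign_subset(1.2), "within")
  expect_error(assign_subset(-0.1), "within")
})
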