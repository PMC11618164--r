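#' Deterministic synthetic fixtures
#'
#' Generates toy protein-ligand complexes (peptide cages around placed 3D
#' ligand conformers), activity tables and EDIA tables with known ground
#' truth, so the whole workflow is testable without downloads. Cages are
#' geometric constructions, not physically realistic folds: every in-scope
#' operator depends only on geometry, sequence identity and chemistry.
#'
#' @name synthetic_fixtures
NULL

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
names(AA3) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

# Idealized backbone atom offsets (N, CA, C, O) in a local residue frame,
# centered at the atom centroid to minimize the placement footprint.
RESIDUE_TEMPLATE <- local({
  m <- rbind(
    N  = c(1.46, 0.00, 0.00),
    CA = c(0.00, 0.00, 0.00),
    C  = c(-0.73, 1.25, 0.00),
    O  = c(-1.90, 1.25, 0.35)
  )
  sweep(m, 2, colMeans(m))
})

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Center heavy-atom coordinates and rotate into principal axes with
# deterministic sign/handedness fixes.
canonicalize_coords <- function(xyz, elements, smiles = NA_character_) {
  xyz <- sweep(xyz, 2, colMeans(xyz))
  v <- svd(xyz)$v
  for (k in 1:3) if (v[which.max(abs(v[, k])), k] < 0) v[, k] <- -v[, k]
  if (det(v) < 0) v[, 3] <- -v[, 3]
  list(coords = xyz %*% v, elements = elements, smiles = smiles)
}

# Canonical conformer: heavy atoms of a generated 3D conformer. Only used
# for rigid molecules, where the generation is deterministic; flexible or
# exotic fixtures use the analytic builders below.
canonical_conformer <- function(smiles) {
  mol <- mol_from_smiles(smiles)
  canonicalize_coords(mol$coords[!mol$is_h, , drop = FALSE],
                      mol$elements[!mol$is_h], mol$smiles)
}

# Ideal all-anti zig-zag n-alkane chain (C-C 1.53 A, 111 degrees).
alkane_conformer <- function(n_carbons) {
  d <- 1.53; half <- (111 / 2) * pi / 180
  i <- seq_len(n_carbons) - 1
  xyz <- cbind(i * d * sin(half), (i %% 2) * d * cos(half), 0)
  canonicalize_coords(xyz, rep("C", n_carbons))
}

# In-plane direction pointing away from a ring atom's two ring neighbours.
substituent_directions <- function(mol) {
  heavy <- which(!mol$is_h)
  deg <- heavy_degree(mol)
  lapply(heavy, function(a) {
    nb <- unique(c(mol$bonds$a1[mol$bonds$a2 == a],
                   mol$bonds$a2[mol$bonds$a1 == a]))
    nb <- nb[!mol$is_h[nb]]
    v <- mol$coords[a, ] - colMeans(mol$coords[nb, , drop = FALSE])
    list(atom = a, degree = deg[a], dir = v / sqrt(sum(v^2)))
  })
}

# Naphthalene skeleton with every C-H position substituted by one atom of
# `element` at `bond_length`; with iodine this is the heavyweight fixture.
substituted_naphthalene_conformer <- function(element = "I",
                                              bond_length = 2.10) {
  mol <- mol_from_smiles("c1ccc2ccccc2c1")
  dirs <- substituent_directions(mol)
  xyz <- mol$coords[!mol$is_h, , drop = FALSE]
  el <- mol$elements[!mol$is_h]
  for (d in dirs) {
    if (d$degree != 2) next   # ring-fusion carbons carry no substituent
    xyz <- rbind(xyz, mol$coords[d$atom, ] + bond_length * d$dir)
    el <- c(el, element)
  }
  canonicalize_coords(xyz, el)
}

# Trimethylsilyl-benzene: benzene core plus a tetrahedral SiMe3 group.
tms_phenyl_conformer <- function() {
  mol <- mol_from_smiles("c1ccccc1")
  dirs <- substituent_directions(mol)
  d1 <- dirs[[1]]
  si <- mol$coords[d1$atom, ] + 1.87 * d1$dir
  u <- d1$dir
  # orthonormal frame around the Si-C(ipso) axis
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(u, e1)
  ang <- 109.47 * pi / 180
  methyls <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    si + 1.87 * (cos(ang) * (-u) + sin(ang) * (cos(phi) * e1 + sin(phi) * e2))
  }, numeric(3)))
  xyz <- rbind(mol$coords[!mol$is_h, , drop = FALSE], si, methyls)
  el <- c(mol$elements[!mol$is_h], "Si", rep("C", 3))
  canonicalize_coords(xyz, el)
}

# Rigid placement of a canonical conformer: rows %*% t(rotation) + shift.
place_conformer <- function(conf, rotation = diag(3), shift = c(0, 0, 0)) {
  conf$coords <- sweep(conf$coords %*% t(rotation), 2, shift, "+")
  conf
}

# Rotation mapping canonical axes (long, mid, normal) onto given global axes.
axes_rotation <- function(long = c(0, 1, 0), mid = c(0, 0, 1)) {
  long <- long / sqrt(sum(long^2))
  mid <- mid - sum(mid * long) * long
  mid <- mid / sqrt(sum(mid^2))
  cbind(long, mid, pracma_cross(long, mid))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place a peptide cage around ligand poses
#'
#' Rejection-samples rigidly oriented backbone residues so that every residue
#' atom lies within `radius - margin` of at least one atom of every pose in
#' `pocket_poses` (so each pose's pocket selects the full cage and all pocket
#' sequences coincide), keeps `clearance` from every atom of every pose in
#' `clearance_poses`, and does not clash with already placed residues.
#'
#' @param pocket_poses list of heavy-atom coordinate matrices
#' @param clearance_poses list of coordinate matrices to keep clear of
#'   (defaults to `pocket_poses`)
#' @param n_target residues to place
#' @param radius pocket radius the cage must satisfy
#' @param margin safety margin inside `radius`
#' @param clearance minimum residue-ligand atom distance
#' @param half_space optional function(ca) -> logical further restricting
#'   candidate CA positions (used for under-buried fixtures)
#' @param max_tries sampling budget
#' @return list of residue atom matrices (rows N, CA, C, O)
#' @keywords internal
place_cage <- function(pocket_poses, clearance_poses = NULL, n_target = 60L,
                       radius = 6.5, margin = 0.3, clearance = 2.6,
                       half_space = NULL, max_tries = 40000L) {
  clearance_poses <- clearance_poses %||% pocket_poses
  all_pocket <- do.call(rbind, pocket_poses)
  all_clear <- do.call(rbind, clearance_poses)
  # enumerate CA positions that can possibly host a residue: close enough to
  # every pose (leaving room for the backbone extent) and clear of all poses
  lo <- apply(all_pocket, 2, min) - radius
  hi <- apply(all_pocket, 2, max) + radius
  grid <- as.matrix(expand.grid(
    x = seq(lo[1], hi[1], by = 0.7),
    y = seq(lo[2], hi[2], by = 0.7),
    z = seq(lo[3], hi[3], by = 0.7)
  ))
  near_each <- vapply(pocket_poses, function(p)
    apply(cross_dist(grid, p), 1, min), numeric(nrow(grid)))
  d_clear <- apply(cross_dist(grid, all_clear), 1, min)
  feas <- apply(near_each, 1, max) <= radius - margin - 0.45 &
    d_clear >= clearance + 0.9
  if (!is.null(half_space)) {
    feas <- feas & vapply(seq_len(nrow(grid)), function(i)
      isTRUE(half_space(grid[i, ])), logical(1))
  }
  cand <- grid[feas, , drop = FALSE]
  if (!nrow(cand)) return(list())
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  placed <- list()
  placed_atoms <- NULL
  tries_per_site <- max(10L, as.integer(max_tries / nrow(cand)))
  for (i in seq_len(nrow(cand))) {
    if (length(placed) >= n_target) break
    ca <- cand[i, ] + stats::runif(3, -0.25, 0.25)
    for (k in seq_len(tries_per_site)) {
      atoms <- sweep(RESIDUE_TEMPLATE %*% t(random_rotation()), 2, ca, "+")
      if (min_dist(atoms, all_clear) < clearance) next
      ok <- all(vapply(pocket_poses, function(p) {
        d <- cross_dist(atoms, p)
        all(apply(d, 1, min) <= radius - margin)
      }, logical(1)))
      if (!ok) next
      if (!is.null(placed_atoms) && min_dist(atoms, placed_atoms) < 1.7) next
      placed[[length(placed) + 1L]] <- atoms
      placed_atoms <- rbind(placed_atoms, atoms)
      break
    }
  }
  placed
}

pdb_date <- function(date) {
  toupper(format(as.Date(date), "%d-%b-%y"))
}

# Assemble one PDB entry from residue atom matrices and ligand poses.
entry_pdb_text <- function(entry_id, residues, resnames, ligands,
                           resolution = 2.0, date = "2010-01-01",
                           chain = "A") {
  id <- toupper(entry_id)
  d <- pdb_date(date)
  lines <- c(
    sprintf("HEADER    SYNTHETIC COMPLEX                       %s   %s", d, id),
    sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution),
    sprintf("REVDAT   1   %s %s    0", d, id)
  )
  serial <- 0L
  atom_names <- c(" N  ", " CA ", " C  ", " O  ")
  elements <- c("N", "C", "C", "O")
  for (i in seq_along(residues)) {
    for (a in 1:4) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, atom_names[a], resnames[i], chain, i,
        residues[[i]][a, 1], residues[[i]][a, 2], residues[[i]][a, 3],
        elements[a]
      ))
    }
  }
  lines <- c(lines, sprintf("TER   %5d      %-3s %s%4d",
                            serial + 1L, resnames[length(resnames)], chain,
                            length(residues)))
  for (lig in ligands) {
    for (j in seq_len(nrow(lig$coords))) {
      serial <- serial + 1L
      el <- lig$elements[j]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial,
        substr(sprintf("%s%d", toupper(el), j), 1, 4),
        lig$het, lig$chain %||% chain, lig$resnum,
        lig$coords[j, 1], lig$coords[j, 2], lig$coords[j, 3], el
      ))
    }
  }
  c(lines, "END")
}

#' Generate one toy protein-ligand complex
#'
#' Builds a peptide cage of the requested pocket sequence around an embedded
#' 3D conformer of the ligand SMILES, writes PDB text with the requested
#' resolution and release date, and records ground truth (atom counts,
#' pocket residues, ligand pose) in the manifest row.
#'
#' @param pocket_seq one-letter pocket sequence (cage size = its length)
#' @param ligand_smiles ligand SMILES (`NULL` for a protein-only entry)
#' @param placement translation of the ligand conformer
#' @param resolution header resolution in Angstrom
#' @param date release date (anything `as.Date` accepts)
#' @param seed integer seed (cage sampling is deterministic in it)
#' @param entry_id 4-character entry id
#' @param het ligand het code
#' @return list with `pdb` (character lines) and `manifest`
#' @export
make_toy_complex <- function(pocket_seq = "GASLVTKF", ligand_smiles = "c1ccc2ccccc2c1",
                             placement = c(0, 0, 0), resolution = 1.8,
                             date = "2012-06-01", seed = 1L,
                             entry_id = "tc01", het = "LIG") {
  with_seed(seed, {
    resnames <- AA3[strsplit(pocket_seq, "")[[1]]]
    if (anyNA(resnames)) stop("pocket_seq must use standard one-letter codes")
    n <- length(resnames)
    if (is.null(ligand_smiles)) {
      # protein-only entry: residues on a ring
      ang <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
      residues <- lapply(ang, function(a) {
        sweep(RESIDUE_TEMPLATE %*% t(random_rotation()), 2,
              c(8 * cos(a), 8 * sin(a), 0), "+")
      })
      pdb <- entry_pdb_text(entry_id, residues, resnames, list(),
                            resolution = resolution, date = date)
      return(list(pdb = pdb, manifest = list(
        entry_id = entry_id, n_chains = 1L, n_ligand_atoms = 0L,
        n_residues = n, pocket_resnos = integer(0), seed = seed
      )))
    }
    conf <- place_conformer(canonical_conformer(ligand_smiles),
                            shift = placement)
    residues <- place_cage(list(conf$coords), n_target = n)
    if (length(residues) < n) {
      stop("cage placement failed for seed ", seed, ", SMILES ",
           ligand_smiles)
    }
    lig <- list(het = het, resnum = 301L, coords = conf$coords,
                elements = conf$elements)
    pdb <- entry_pdb_text(entry_id, residues, resnames, list(lig),
                          resolution = resolution, date = date)
    list(pdb = pdb, manifest = list(
      entry_id = entry_id, n_chains = 1L,
      n_ligand_atoms = nrow(conf$coords),
      n_residues = n,
      pocket_resnos = seq_len(n),   # by construction all residues qualify
      ligand_pose = conf$coords,
      ligand_smiles = conf$smiles,
      seed = seed
    ))
  })
}

scenario_tables <- function(rows) {
  activity <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$activity)) return(NULL)
    data.frame(entry_id = r$entry_id, het = r$het, type = r$activity$type,
               value = r$activity$value, unit = r$activity$unit,
               source = "synthetic", stringsAsFactors = FALSE)
  }))
  edia <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$edia)) return(NULL)
    data.frame(entry_id = r$entry_id, het = r$het, chain = r$chain,
               resnum = r$resnum, edia_m = r$edia, stringsAsFactors = FALSE)
  }))
  list(activity = activity, edia = edia)
}

#' Generate the filter-cascade scenario
#'
#' Twelve ligands across eleven entries: exactly one ligand violates each
#' cascade step (resolution, EDIA, molecular weight, rotatable bonds,
#' element filter, heavy atoms, duplicate removal, activity presence, ligand
#' efficiency, buriedness) and two survive. The manifest records the
#' expected per-step discard vector and the survivor keys.
#'
#' @param seed integer seed
#' @return a `ScenarioManifest`-style list: `entries_pdb` (named character
#'   vectors), `activity`, `edia`, `manifest`
#' @export
make_filter_scenario <- function(seed = 1L) {
  with_seed(seed, {
    specs <- list(
      list(entry = "f301", het = "MNA", smiles = "Cc1ccc2ccccc2c1",
           resolution = 3.0, edia = 0.92, act = 1e-2),         # resolution
      list(entry = "f302", het = "ANA", smiles = "Nc1ccc2ccccc2c1",
           resolution = 2.0, edia = 0.50, act = 1e-2),         # EDIA
      list(entry = "f303", het = "OIN",
           conf = substituted_naphthalene_conformer("I", 2.10),
           resolution = 2.0, edia = 0.92, act = 1e-2),         # MW > 975
      list(entry = "f304", het = "TDC", conf = alkane_conformer(14L),
           resolution = 2.0, edia = 0.92, act = 1e-2),         # rot bonds
      list(entry = "f305", het = "TMS", conf = tms_phenyl_conformer(),
           resolution = 2.0, edia = 0.92, act = 1e-2),         # element
      list(entry = "f306", het = "BNZ", smiles = "c1ccccc1",
           resolution = 2.0, edia = 0.92, act = 1e-2),         # heavy atoms
      list(entry = "f307", het = "CNA", smiles = "Clc1ccc2ccccc2c1",
           resolution = 2.0, edia = 0.92, act = NULL),         # no activity
      list(entry = "f308", het = "PHN", smiles = "c1ccc2c(c1)ccc1ccccc12",
           resolution = 2.0, edia = 0.92, act = 1e3),          # LE (1 mM)
      list(entry = "f309", het = "ANC", smiles = "c1ccc2cc3ccccc3cc2c1",
           resolution = 2.0, edia = 0.92, act = 1e-2,
           half_cage = TRUE),                                  # buriedness
      list(entry = "f310", het = "NPL", smiles = "Oc1ccc2ccccc2c1",
           resolution = 2.0, edia = 0.92, act = 1e-2,
           duplicate_edia = 0.85),                             # survivor + dup
      list(entry = "f311", het = "FNA", smiles = "Fc1ccc2ccccc2c1",
           resolution = 2.0, edia = 0.92, act = 1e-2)          # survivor
    )
    entries_pdb <- list()
    rows <- list()
    dates <- c("1998-03-14", "2001-07-02", "2004-11-23", "2006-02-05",
               "2008-09-17", "2011-04-30", "2013-12-12", "2015-08-08",
               "2017-05-19", "2019-10-01", "2021-01-26")
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      conf <- sp$conf %||% canonical_conformer(sp$smiles)
      half <- if (isTRUE(sp$half_cage)) {
        # one-sided wall: residues confined to a quarter-space off one end
        xcut <- min(conf$coords[, 1]) + 1.0
        function(ca) ca[1] < xcut && ca[2] < 0
      } else NULL
      n_res <- if (isTRUE(sp$half_cage)) 12L else 18L
      residues <- place_cage(list(conf$coords), n_target = n_res,
                             half_space = half)
      if (length(residues) < 6L) {
        stop("cage placement failed for entry ", sp$entry)
      }
      # construction check: the cage realizes the intended burial regime
      prot <- do.call(rbind, residues)
      bur <- compute_buriedness(
        data.frame(element = conf$elements, x = conf$coords[, 1],
                   y = conf$coords[, 2], z = conf$coords[, 3]),
        data.frame(element = rep(c("N", "C", "C", "O"), length(residues)),
                   x = prot[, 1], y = prot[, 2], z = prot[, 3]),
        n_points = 256L
      )
      if (isTRUE(sp$half_cage) && bur >= 0.45) {
        stop("under-buried fixture failed construction (buriedness ", bur, ")")
      }
      if (!isTRUE(sp$half_cage) && bur < 0.55) {
        stop("buried fixture failed construction (buriedness ", bur, ")")
      }
      resnames <- AA3[sample(names(AA3), length(residues), replace = TRUE)]
      ligands <- list(list(het = sp$het, resnum = 401L, coords = conf$coords,
                           elements = conf$elements))
      rows[[length(rows) + 1L]] <- list(
        entry_id = sp$entry, het = sp$het, chain = "A", resnum = 401L,
        edia = sp$edia,
        activity = if (!is.null(sp$act))
          list(type = "IC50", value = sp$act, unit = "uM") else NULL
      )
      if (!is.null(sp$duplicate_edia)) {
        # second instance of the same molecule, far outside the cage
        dup <- place_conformer(conf, shift = c(30, 0, 0))
        ligands[[2]] <- list(het = sp$het, resnum = 402L, coords = dup$coords,
                             elements = dup$elements)
        rows[[length(rows) + 1L]] <- list(
          entry_id = sp$entry, het = sp$het, chain = "A", resnum = 402L,
          edia = sp$duplicate_edia, activity = NULL
        )
      }
      entries_pdb[[sp$entry]] <- entry_pdb_text(
        sp$entry, residues, resnames, ligands,
        resolution = sp$resolution, date = dates[i]
      )
    }
    tables <- scenario_tables(rows)
    survivors <- c(
      ligand_key("NPL", "A", 401L, "f310"),
      ligand_key("FNA", "A", 401L, "f311")
    )
    manifest <- list(
      seed = seed,
      n_ligands = 12L,
      expected_discarded = stats::setNames(rep(1L, 10), CASCADE_STEPS$name),
      expected_survivors = sort(survivors)
    )
    list(entries_pdb = entries_pdb, activity = tables$activity,
         edia = tables$edia, manifest = manifest)
  })
}

#' Generate the ensemble/clustering/pair scenario
#'
#' Three pocket-sequence families with full ground truth:
#' * family 1 (five entries, two ligand chemotypes): backbone conformations
#'   lie on a one-dimensional displacement line, so each query's
#'   lowest-RMSD duplicate-SMILES choice is controlled exactly; the member
#'   choices found two disjoint clusters that a later ensemble bridges,
#'   forcing the multi-cluster merge.
#' * family 2 (four entries, rigid copies under random rigid motions): an
#'   anthracene member whose terminal-ring pair exactly covers a naphthalene
#'   member (Shape Tversky 1.0), and two elongated members (biphenyl and
#'   decane) crossed in projection but separated by more than two vdW
#'   diameters along z, giving a strictly volume-disjoint subset_0 pair.
#' * family 3: a singleton ensemble, removed by the singleton rule.
#'
#' @param seed integer seed
#' @return list: `entries_pdb`, `activity`, `edia`, `manifest` (expected
#'   ensembles, clusters, representatives, pair subsets, growth table)
#' @export
make_ensemble_scenario <- function(seed = 1L) {
  with_seed(seed, {
    # --- family 1: merge construction on a displacement line ---------------
    confA <- canonical_conformer("Cc1ccc2ccccc2c1")        # methylnaphthalene
    confB <- canonical_conformer("c1ccc2c(c1)ccc1ccccc12") # phenanthrene
    rot_flat <- axes_rotation(long = c(0, 1, 0), mid = c(0, 0, 1))
    poseA <- place_conformer(confA, rot_flat, c(0, 0, 0))
    poseB <- place_conformer(confB, rot_flat, c(0, 0, 0))
    cage1 <- place_cage(list(poseA$coords, poseB$coords), n_target = 55L)
    if (length(cage1) < 12L) stop("family-1 cage placement failed")
    seq1 <- sample(names(AA3), length(cage1), replace = TRUE)
    u1 <- lapply(cage1, function(r) {
      m <- matrix(stats::rnorm(12), 4, 3)
      m / sqrt(rowSums(m^2))
    })
    fam1 <- list(
      list(entry = "e101", het = "LGA", pose = poseA, t = 0.00, year = 1994),
      list(entry = "e102", het = "LGB", pose = poseB, t = 0.40, year = 2005),
      list(entry = "e103", het = "LGA", pose = poseA, t = 0.70, year = 2005),
      list(entry = "e104", het = "LGB", pose = poseB, t = 0.95, year = 2010),
      list(entry = "e105", het = "LGB", pose = poseB, t = 1.60, year = 2017)
    )
    # --- family 2: rigid copies with engineered pair overlaps --------------
    # naphthalene/anthracene lie in the x-y plane (exact substructure
    # coverage); the two elongated members cross in projection but sit at
    # z = +/- 2.7, farther apart than two vdW diameters, so their volumes
    # are strictly disjoint while all four poses stay central (common
    # pocket set, full burial).
    confAnth <- canonical_conformer("c1ccc2cc3ccccc3cc2c1")
    # naphthalene = the ten anthracene carbons away from one terminal ring
    ord <- order(confAnth$coords[, 1])
    naph_idx <- sort(ord[-(1:4)])
    naph_sub <- confAnth$coords[naph_idx, , drop = FALSE]
    shift0 <- colMeans(naph_sub)
    anth_pose <- list(coords = sweep(confAnth$coords, 2, shift0),
                      elements = confAnth$elements)
    naph_pose <- list(coords = anth_pose$coords[naph_idx, , drop = FALSE],
                      elements = anth_pose$elements[naph_idx])
    confBiph <- canonical_conformer("c1ccc(-c2ccccc2)cc1")
    biph_pose <- place_conformer(
      confBiph, axes_rotation(long = c(1, 0, 0), mid = c(0, 1, 0)),
      c(0, 0, 2.45)
    )
    confDec <- alkane_conformer(10L)
    dec_pose <- place_conformer(
      confDec, axes_rotation(long = c(0, 1, 0), mid = c(1, 0, 0)),
      c(0, 0, -2.45)
    )
    stopifnot(min_dist(biph_pose$coords, dec_pose$coords) > 3.55)
    fam2_poses <- list(naph_pose$coords, anth_pose$coords,
                       biph_pose$coords, dec_pose$coords)
    cage2 <- place_cage(fam2_poses, n_target = 26L, margin = 0.15)
    if (length(cage2) < 12L) stop("family-2 cage placement failed")
    # construction check: every member pose clears the buriedness gate
    prot2 <- do.call(rbind, cage2)
    pa2 <- data.frame(element = rep(c("N", "C", "C", "O"), length(cage2)),
                      x = prot2[, 1], y = prot2[, 2], z = prot2[, 3])
    for (po in fam2_poses) {
      b <- compute_buriedness(
        data.frame(element = rep("C", nrow(po)), x = po[, 1], y = po[, 2],
                   z = po[, 3]),
        pa2, n_points = 256L
      )
      if (b < 0.51) stop("family-2 pose under-buried (", round(b, 3), ")")
    }
    seq2 <- sample(names(AA3), length(cage2), replace = TRUE)
    fam2 <- list(
      list(entry = "e201", het = "NPH", pose = naph_pose, year = 1999),
      list(entry = "e202", het = "ANT", pose = anth_pose, year = 2008),
      list(entry = "e203", het = "BIP", pose = biph_pose, year = 2008),
      list(entry = "e204", het = "DEC", pose = dec_pose, year = 2021)
    )
    # e201/e202 share one crystal frame so the engineered exact-coverage
    # pair survives coordinate rounding bit-exactly; the other two entries
    # get arbitrary rigid motions
    fam2_transforms <- list(
      e201 = list(rotation = diag(3), shift = c(0, 0, 0)),
      e202 = list(rotation = diag(3), shift = c(0, 0, 0)),
      e203 = list(rotation = random_rotation(), shift = stats::runif(3, -15, 15)),
      e204 = list(rotation = random_rotation(), shift = stats::runif(3, -15, 15))
    )
    # --- family 3: singleton -----------------------------------------------
    confS <- canonical_conformer("c1ccc2ncccc2c1")
    poseS <- place_conformer(confS, rot_flat, c(0, 0, 0))
    cage3 <- place_cage(list(poseS$coords), n_target = 20L)
    if (length(cage3) < 8L) stop("family-3 cage placement failed")
    seq3 <- sample(names(AA3), length(cage3), replace = TRUE)

    entries_pdb <- list()
    rows <- list()
    add_row <- function(entry, het, resnum = 201L) {
      rows[[length(rows) + 1L]] <<- list(
        entry_id = entry, het = het, chain = "A", resnum = resnum,
        edia = 0.93,
        activity = list(type = "Ki", value = 10, unit = "nM")
      )
    }
    for (sp in fam1) {
      residues <- lapply(seq_along(cage1), function(i) {
        cage1[[i]] + sp$t * 0.25 * u1[[i]]
      })
      lig <- list(het = sp$het, resnum = 201L, coords = sp$pose$coords,
                  elements = sp$pose$elements)
      entries_pdb[[sp$entry]] <- entry_pdb_text(
        sp$entry, residues, AA3[seq1], list(lig), resolution = 1.9,
        date = sprintf("%d-06-15", sp$year)
      )
      add_row(sp$entry, sp$het)
    }
    for (sp in fam2) {
      tr <- fam2_transforms[[sp$entry]]
      residues <- lapply(cage2, function(r) {
        sweep(r %*% t(tr$rotation), 2, tr$shift, "+")
      })
      lig <- list(het = sp$het, resnum = 301L,
                  coords = sweep(sp$pose$coords %*% t(tr$rotation), 2,
                                 tr$shift, "+"),
                  elements = sp$pose$elements)
      entries_pdb[[sp$entry]] <- entry_pdb_text(
        sp$entry, residues, AA3[seq2], list(lig), resolution = 2.1,
        date = sprintf("%d-03-03", sp$year)
      )
      add_row(sp$entry, sp$het, 301L)
    }
    ligS <- list(het = "SNG", resnum = 101L, coords = poseS$coords,
                 elements = poseS$elements)
    entries_pdb[["e301"]] <- entry_pdb_text(
      "e301", cage3, AA3[seq3], list(ligS), resolution = 1.7,
      date = "2000-09-09"
    )
    add_row("e301", "SNG", 101L)

    tables <- scenario_tables(rows)

    k <- function(het, resnum, entry) ligand_key(het, "A", resnum, entry)
    a1 <- k("LGA", 201L, "e101"); b1 <- k("LGB", 201L, "e102")
    a2 <- k("LGA", 201L, "e103"); b2 <- k("LGB", 201L, "e104")
    b3 <- k("LGB", 201L, "e105")
    n2 <- k("NPH", 301L, "e201"); t2 <- k("ANT", 301L, "e202")
    d2 <- k("BIP", 301L, "e203"); p2 <- k("DEC", 301L, "e204")
    s3 <- k("SNG", 101L, "e301")

    # expected subset labels for the rigid-copy family, from ground truth
    fam2_keys <- c(ligand_key("NPH", "A", 301L, "e201"),
                   ligand_key("ANT", "A", 301L, "e202"),
                   ligand_key("BIP", "A", 301L, "e203"),
                   ligand_key("DEC", "A", 301L, "e204"))
    fam2_els <- lapply(list(naph_pose, anth_pose, biph_pose, dec_pose),
                       function(p) p$elements)
    pair_rows <- list()
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      sti <- shape_tversky(fam2_poses[[i]], fam2_poses[[j]],
                           template_elements = fam2_els[[i]],
                           query_elements = fam2_els[[j]])
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        template_key = fam2_keys[i], query_key = fam2_keys[j],
        subset = assign_subset(sti), stringsAsFactors = FALSE
      )
    }
    expected_pair_subsets <- do.call(rbind, pair_rows)

    expected_ensembles <- list()
    expected_ensembles[[a1]] <- sort(c(a1, b1))
    expected_ensembles[[b1]] <- sort(c(b1, a2))
    expected_ensembles[[a2]] <- sort(c(a2, b2))
    expected_ensembles[[b2]] <- sort(c(b2, a2))
    expected_ensembles[[b3]] <- sort(c(b3, a2))
    for (key in c(n2, t2, d2, p2)) {
      expected_ensembles[[key]] <- sort(c(n2, t2, d2, p2))
    }

    manifest <- list(
      seed = seed,
      expected_survivors = sort(c(a1, b1, a2, b2, b3, n2, t2, d2, p2, s3)),
      expected_ensembles = expected_ensembles,
      expected_removed_singletons = s3,
      expected_clusters = list(
        sort(c(a1, b1, a2, b2, b3)),
        sort(c(n2, t2, d2, p2))
      ),
      expected_representatives = sort(c(b1, t2)),
      covering_pair = c(template = n2, query = t2),   # Tversky exactly 1.0
      disjoint_pair = c(d2, p2),                      # zero overlap, subset_0
      expected_pair_subsets = expected_pair_subsets,
      expected_pair_count = 14L,
      entry_years = c(e101 = 1994, e102 = 2005, e103 = 2005, e104 = 2010,
                      e105 = 2017, e201 = 1999, e202 = 2008, e203 = 2008,
                      e204 = 2021, e301 = 2000),
      fam2_ground_truth = list(
        poses = stats::setNames(fam2_poses, c(n2, t2, d2, p2)),
        transforms = fam2_transforms
      )
    )
    list(entries_pdb = entries_pdb, activity = tables$activity,
         edia = tables$edia, manifest = manifest)
  })
}

#' Write a generated scenario to disk
#'
#' Materializes the PDB entries plus activity and EDIA TSV tables in the same
#' dialects the pipeline consumes, and the manifest as JSON.
#'
#' @param scenario result of [make_filter_scenario()] or
#'   [make_ensemble_scenario()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(file.path(dir, "pdb"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(scenario$entries_pdb)) {
    writeLines(scenario$entries_pdb[[id]], file.path(dir, "pdb",
                                                     paste0(id, ".pdb")))
  }
  write_tsv(scenario$activity, file.path(dir, "activity.tsv"))
  write_tsv(scenario$edia, file.path(dir, "edia.tsv"))
  manifest <- scenario$manifest
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "fam2_ground_truth")],
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
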