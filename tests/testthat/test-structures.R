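test_that("read_structure parses minimal files and MODEL blocks", {
  mods <- read_structure(tiny_pdb())
  expect_length(mods, 1L)
  expect_equal(nrow(mods[[1]]$atoms), 2L)
  expect_equal(mods[[1]]$atoms$res_num, c(1L, 2L))

  multi <- write_pdb_fixture(c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CB", "ALA", "A", 1, 1, 1, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "ALA", "A", 1, 0.5, 0, 0),
    pdb_line(2, "CB", "ALA", "A", 1, 1.5, 1, 0),
    "ENDMDL"))
  mods <- read_structure(multi)
  expect_length(mods, 2L)
  expect_identical(mods[[1]]$atoms$atom_name, mods[[2]]$atoms$atom_name)
  expect_equal(mods[[2]]$atoms$x[1], 0.5)
})

test_that("sanitization: altlocs, MSE, waters, hydrogens, chains", {
  p <- write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4, alt = "B"),
    pdb_line(3, "SD", "MSE", "A", 2, 2, 0, 0, elem = "S"),
    pdb_line(4, "O", "HOH", "A", 90, 5, 5, 5) |>
      sub(pattern = "^ATOM  ", replacement = "HETATM"),
    pdb_line(5, "H", "ALA", "A", 1, 0.1, 0, 0, elem = "H"),
    pdb_line(6, "CA", "GLY", "B", 3, 4, 0, 0)
  ))
  m <- read_structure(p)[[1]]
  # highest-occupancy altloc kept
  expect_equal(sum(m$atoms$atom_name == "CA" & m$atoms$res_num == 1), 1L)
  expect_equal(m$atoms$x[m$atoms$atom_name == "CA" & m$atoms$res_num == 1], 0)
  # MSE relabelled MET, atoms retained
  expect_true(any(m$atoms$res_name == "MET"))
  expect_false(any(m$atoms$res_name == "MSE"))
  # water and hydrogens dropped
  expect_false(any(m$atoms$res_name == "HOH"))
  expect_false(any(toupper(m$atoms$element) == "H"))
  # heteroatoms kept on request
  mh <- read_structure(p, keep_het = TRUE)[[1]]
  expect_true(any(mh$atoms$res_name == "HOH"))
  # chain selection
  mb <- read_structure(p, chain = "B")[[1]]
  expect_equal(unique(mb$atoms$chain_id), "B")
  expect_error(read_structure(p, chain = "Z"), "absent")

  # altloc occupancy tie: alphabetically first wins
  tie <- write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.5, alt = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 2, 0, 0, occ = 0.5, alt = "A")))
  mt <- read_structure(tie)[[1]]
  expect_equal(mt$atoms$alt_loc, "A")
})

test_that("get_reference_atom enforces the lysine default and allows overrides", {
  p <- write_pdb_fixture(c(
    pdb_line(1, "CA", "LYS", "A", 167, 0, 0, 0),
    pdb_line(2, "NZ", "LYS", "A", 167, 1, 2, 2, elem = "N"),
    pdb_line(3, "CA", "VAL", "A", 102, 4, 0, 0),
    pdb_line(4, "CB", "VAL", "A", 102, 5, 0, 0),
    pdb_line(5, "CA", "LYS", "A", 200, 8, 0, 0)
  ))
  m <- read_structure(p)[[1]]
  ref <- get_reference_atom(m, atom_selector("A", 167))
  expect_equal(ref$atom_name, "NZ")
  expect_equal(c(ref$x, ref$y, ref$z), c(1, 2, 2))
  # lysine missing its NZ
  expect_error(get_reference_atom(m, atom_selector("A", 200)),
               "reference atom absent")
  # default selector on a non-lysine refuses
  expect_error(get_reference_atom(m, atom_selector("A", 102)),
               "not lysine")
  # explicit atom name overrides the lysine requirement
  cb <- get_reference_atom(m, atom_selector("A", 102, "CB"))
  expect_equal(cb$atom_name, "CB")
})

test_that("select_region boundary is inclusive and order-independent", {
  p <- write_pdb_fixture(c(
    pdb_line(1, "CA", "ALA", "A", 1, 5.9, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 6.1, 0, 0),
    pdb_line(3, "CA", "SER", "A", 3, 0, 0, 0)
  ))
  m <- read_structure(p)[[1]]
  spec <- region_spec(center = c(0, 0, 0), radius = 6)
  reg <- select_region(m, spec)
  expect_setequal(reg$res_num, c(1L, 3L))   # 5.9 in, 6.1 out
  expect_equal(reg$distance[reg$res_num == 3], 0)  # center atom included
  # idempotent / order independent membership
  m2 <- m
  m2$atoms <- m2$atoms[rev(seq_len(nrow(m2$atoms))), ]
  reg2 <- select_region(m2, spec)
  expect_setequal(reg2$res_num, reg$res_num)
  # empty region warns
  expect_warning(select_region(m, region_spec(c(100, 100, 100), 1)),
                 "empty region")
})

test_that("kabsch_superpose recovers exact transforms", {
  set.seed(42)
  a <- matrix(rnorm(15), 5, 3)
  s <- kabsch_superpose(a, a)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)

  b <- sweep(a, 2, c(5, 0, 0), "+")
  s <- kabsch_superpose(a, b)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(a[1:2, ], b[1:2, ]), "at least 3")
  col <- cbind(1:5, 2 * (1:5), -1 * (1:5))  # collinear
  expect_error(kabsch_superpose(col, col), "degenerate")
})

test_that("kabsch rmsd matches a rotation-grid oracle on noised data", {
  set.seed(7)
  a <- matrix(rnorm(15), 5, 3)
  axis <- c(1, 2, 0.5); axis <- axis / sqrt(sum(axis^2))
  rot_about <- function(theta) {
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  }
  true_theta <- 0.8
  b <- a %*% t(rot_about(true_theta))
  b <- sweep(b, 2, c(1, -2, 3), "+") + matrix(rnorm(15, sd = 0.01), 5, 3)

  # independent oracle: scan the rotation angle about the known axis at
  # 0.5 degree resolution (optimal translation = centroid match), then
  # refine the best bracket
  rmsd_at <- function(theta) {
    fit <- a %*% t(rot_about(theta))
    fit <- sweep(fit, 2, colMeans(b) - colMeans(fit), "+")
    rmsd_between(fit, b)
  }
  grid <- seq(0, 2 * pi, by = 0.5 * pi / 180)
  vals <- vapply(grid, rmsd_at, numeric(1))
  i <- which.min(vals)
  refined <- stats::optimize(rmsd_at, grid[c(max(i - 1, 1),
                                             min(i + 1, length(grid)))])
  s <- kabsch_superpose(a, b)
  expect_lte(s$rmsd, refined$objective + 1e-9)   # kabsch is optimal
  expect_lt(abs(s$rmsd - refined$objective), 1e-3)  # absolute, angstrom
})

test_that("superposition invariants hold on random inlier sets", {
  for (sd_seed in 1:5) {
    set.seed(sd_seed)
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    s1 <- kabsch_superpose(a, b)
    # pre-translation invariance
    s2 <- kabsch_superpose(sweep(a, 2, c(10, -4, 2), "+"), b)
    expect_equal(s1$rmsd, s2$rmsd, tolerance = 1e-9)
    # fitting never increases the rmsd
    fitted <- apply_superposition(s1, a)
    expect_lte(rmsd_between(fitted, b), rmsd_between(a, b) + 1e-12)
    expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  }
})

test_that("rmsd_between evaluates the formula", {
  a <- matrix(0, 2, 3)
  expect_equal(rmsd_between(a, a), 0)
  b <- rbind(c(2, 0, 0), c(0, 0, 0))
  one <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(rmsd_between(one, matrix(c(2, 0, 0), 1, 3)), 2)
  expect_equal(rmsd_between(a, b), sqrt(2))
  expect_error(rmsd_between(a, b[1, , drop = FALSE]), "differ in size")
})
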