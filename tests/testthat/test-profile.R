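ref_lys_lines <- function() c(
  pdb_line(1, "NZ", "LYS", "A", 100, 0, 0, 0, elem = "N"),
  pdb_line(2, "CA", "LYS", "A", 100, 0, 0, -3, elem = "C")
)

test_that("load_ensemble turns models into snapshots and checks atom sets", {
  block <- function(i, x) c(
    sprintf("MODEL %8d", i),
    ref_lys_lines(),
    pdb_line(3, "CA", "ALA", "A", 1, x, 0, 0),
    "ENDMDL")
  p3 <- write_pdb_fixture(c(block(1, 4), block(2, 4.2), block(3, 3.8)))
  ens <- load_ensemble(p3)
  expect_s3_class(ens, "Ensemble")
  expect_equal(n_snapshots(ens), 3L)

  p1 <- write_pdb_fixture(c(ref_lys_lines(),
                            pdb_line(3, "CA", "ALA", "A", 1, 4, 0, 0)))
  expect_equal(n_snapshots(load_ensemble(p1)), 1L)

  # model 2 missing an atom: error names it
  bad <- write_pdb_fixture(c(
    "MODEL        1", ref_lys_lines(),
    pdb_line(3, "CA", "ALA", "A", 1, 4, 0, 0), "ENDMDL",
    "MODEL        2", ref_lys_lines(), "ENDMDL"))
  expect_error(load_ensemble(bad), "A:1::CA")
})

test_that("distance_profile computes per-atom mean and sample SD", {
  p1 <- write_pdb_fixture(c(ref_lys_lines(),
                            pdb_line(3, "CA", "ALA", "A", 1, 4, 0, 0)))
  spec <- region_spec(center = c(0, 0, 0), radius = 6,
                      reference_atom = atom_selector("A", 100))
  prof <- distance_profile(load_ensemble(p1), spec)
  row <- prof[prof$res_num == 1, ]
  expect_equal(row$mean, 4.0)
  expect_equal(row$sd, 0.0)

  # two snapshots at 3 and 5 angstrom: mean 4, sample sd sqrt(2)
  p2 <- write_pdb_fixture(c(
    "MODEL        1", ref_lys_lines(),
    pdb_line(3, "CA", "ALA", "A", 1, 3, 0, 0), "ENDMDL",
    "MODEL        2", ref_lys_lines(),
    pdb_line(3, "CA", "ALA", "A", 1, 5, 0, 0), "ENDMDL"))
  prof <- distance_profile(load_ensemble(p2), spec)
  row <- prof[prof$res_num == 1, ]
  expect_equal(row$mean, 4.0)
  expect_equal(row$sd, sqrt(2), tolerance = 1e-12)
})

test_that("profile agrees with an independent resampling oracle", {
  # static geometry: one atom at 7 angstrom from the lysine NZ
  atoms <- data.frame(
    serial = 1:3, atom_name = c("NZ", "CA", "CA"), alt_loc = "",
    res_name = c("LYS", "LYS", "ALA"), chain_id = "A",
    res_num = c(100L, 100L, 1L), ins_code = "",
    x = c(0, 0, 7), y = 0, z = c(0, -3, 0),
    occupancy = 1, b_factor = 0, element = c("N", "C", "C"))
  base <- structure_model("toy", 1L, atoms)
  spec <- region_spec(center = c(7, 0, 0), radius = 2,
                      reference_atom = atom_selector("A", 100))
  ens <- sample_ensemble(base, sigma = 0.3, n_snapshots = 10000, seed = 7)
  prof <- distance_profile(ens, spec)
  # oracle: an independent batch from the same generative model
  set.seed(999)
  n <- 10000
  d_oracle <- sqrt(rowSums((matrix(rnorm(3 * n, 0, 0.3), n) + c(7, 0, 0) -
                              matrix(rnorm(3 * n, 0, 0.3), n))^2))
  se <- sqrt(prof$sd[1]^2 / prof$n_snapshots[1] + var(d_oracle) / n)
  expect_lt(abs(prof$mean[1] - mean(d_oracle)), 3 * se)
})

test_that("profile equals a naive double-loop oracle on random ensembles", {
  for (s in 0:2) {
    set.seed(s)
    n_atoms <- 30; n_snap <- 40
    atoms <- data.frame(
      serial = seq_len(n_atoms), atom_name = "CA", alt_loc = "",
      res_name = "GLY", chain_id = "A", res_num = seq_len(n_atoms),
      ins_code = "", x = rnorm(n_atoms, sd = 3), y = rnorm(n_atoms, sd = 3),
      z = rnorm(n_atoms, sd = 3), occupancy = 1, b_factor = 0,
      element = "C")
    atoms$atom_name[1] <- "NZ"; atoms$res_name[1] <- "LYS"
    atoms$x[1] <- 0; atoms$y[1] <- 0; atoms$z[1] <- 0
    arr <- array(rnorm(n_atoms * 3 * n_snap, sd = 2),
                 dim = c(n_atoms, 3, n_snap))
    ens <- ensemble(atoms, arr, source_id = "rand")
    spec <- region_spec(center = c(0, 0, 0), radius = 1e6,
                        reference_atom = atom_selector("A", 1))
    prof <- distance_profile(ens, spec)
    # naive oracle
    for (i in c(2, 11, 27)) {
      d <- numeric(n_snap)
      for (t in seq_len(n_snap))
        d[t] <- sqrt(sum((arr[i, , t] - arr[1, , t])^2))
      row <- prof[prof$serial == i, ]
      expect_equal(row$mean, mean(d), tolerance = 1e-9)
      expect_equal(row$sd, sd(d), tolerance = 1e-9)
    }
  }
})

test_that("profile is snapshot-order invariant and scales linearly", {
  set.seed(1)
  atoms <- data.frame(
    serial = 1:4, atom_name = c("NZ", "CA", "CB", "CA"), alt_loc = "",
    res_name = c("LYS", "GLY", "GLY", "ALA"), chain_id = "A",
    res_num = c(9L, 1L, 1L, 2L), ins_code = "",
    x = c(0, 3, 4, 5), y = 0, z = 0, occupancy = 1, b_factor = 0,
    element = c("N", "C", "C", "C"))
  arr <- array(rnorm(4 * 3 * 20), dim = c(4, 3, 20))
  spec <- region_spec(center = c(0, 0, 0), radius = 1e6,
                      reference_atom = atom_selector("A", 9))
  p1 <- distance_profile(ensemble(atoms, arr), spec)
  p2 <- distance_profile(ensemble(atoms, arr[, , sample(20)]), spec)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-12)
  expect_equal(p1$sd, p2$sd, tolerance = 1e-12)
  p3 <- distance_profile(ensemble(atoms, arr * 2.5), spec)
  expect_equal(p3$mean, 2.5 * p1$mean, tolerance = 1e-9)
  expect_equal(p3$sd, 2.5 * p1$sd, tolerance = 1e-9)
})

test_that("aggregate_by_residue uses the closest-approach convention", {
  prof <- data.frame(
    serial = c(1L, 2L, 3L, 4L, 5L),
    atom_name = c("CA", "CB", "CA", "CA", "CB"),
    res_name = c("GLY", "GLY", "ALA", "SER", "SER"),
    chain_id = "A", res_num = c(1L, 1L, 2L, 3L, 3L), ins_code = "",
    mean = c(6.0, 4.0, 5.0, 2.0, 2.0), sd = c(0.1, 0.2, 0.3, 0.4, 0.5),
    n_snapshots = 10L)
  class(prof) <- c("DistanceProfile", "data.frame")
  rp <- aggregate_by_residue(prof)
  expect_equal(rp$mean[rp$res_num == 1], 4.0)   # smallest mean wins
  expect_equal(rp$n_atoms[rp$res_num == 1], 2L)
  expect_equal(rp$mean[rp$res_num == 2], 5.0)   # one-atom passthrough
  # equal means: lower serial wins
  expect_equal(rp$sd[rp$res_num == 3], 0.4)
})

test_that("ensembles round-trip through multi-model PDB and TSV table", {
  pair <- make_homolog_pair(n_residues = 5, seed = 3)
  ens <- sample_ensemble(pair$model_a, 0.2, 4, seed = 3)
  pdb <- tempfile(fileext = ".pdb")
  write_structure_pdb(lapply(1:4, function(i) snapshot_model(ens, i)), pdb)
  back <- load_ensemble(pdb)
  expect_equal(n_snapshots(back), 4L)
  expect_equal(back$snapshots, ens$snapshots, tolerance = 5e-4)

  tsv <- tempfile(fileext = ".tsv")
  tb <- do.call(rbind, lapply(1:4, function(t)
    data.frame(snapshot = t, atom = seq_len(nrow(ens$atom_index)),
               x = ens$snapshots[, 1, t], y = ens$snapshots[, 2, t],
               z = ens$snapshots[, 3, t])))
  write.table(tb, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- load_ensemble_table(tsv, ens$atom_index)
  expect_equal(back2$snapshots, ens$snapshots, tolerance = 1e-6)
})
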