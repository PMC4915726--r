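#' Derive an independent seed stream from a root seed
#'
#' Every generator in this package draws from its own stream, derived
#' from the single root seed by a fixed counter scheme, so adding a new
#' generator never perturbs fixtures produced by existing ones. Streams:
#' 1 = homolog pair, 2 = ensemble, 3 = MSA, 4 = peak areas,
#' 5 = kinetics. Derived seeds stay below 2^31.
#'
#' @param seed root seed (non-negative integer).
#' @param stream small positive integer stream id.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %% 2147483587)
}

# deterministic near-uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a toy homologous structure pair with planted divergences
#'
#' Builds two single-conformer toy structures sharing a scaffold: a
#' central catalytic lysine whose `NZ` sits at the reference point, and
#' `n_residues` residues, each a C-alpha plus one sidechain-proxy atom
#' (`CB`), placed on distinct rays at radii inside the analysis sphere.
#' The backbone (CA) is identical in both homologs, mirroring the
#' alignable fold of real homolog pairs, while structure B's planted
#' residues carry their sidechain proxy displaced radially by the
#' stated offset - so the planted signal shows up in closest-approach
#' residue profiles but never breaks the structural correspondence.
#' Structure B is renumbered (+7) and rigidly moved by a random
#' rotation/translation; the true residue correspondence, the transform
#' and the planted offsets are stored as ground truth. Offsets are
#' realized exactly (to 1e-9 angstrom) in the static structures.
#'
#' @param n_residues number of scaffold residues.
#' @param planted data frame with columns `res_num` (A-side numbering)
#'   and `offset` (angstrom), or `NULL`.
#' @param seed root seed (stream 1 is used).
#' @param res_num_shift B-side renumbering shift (default 7).
#' @return an object of class `HomologPairTruth`: list with `model_a`,
#'   `model_b`, `correspondence` (true pairing), `planted`,
#'   `reference_a`/`reference_b` ([atom_selector]s for the lysine NZ),
#'   `transform` and `seed`.
#' @export
make_homolog_pair <- function(n_residues = 20L, planted = NULL, seed = 1L,
                              res_num_shift = 7L) {
  if (!is.null(planted)) {
    stopifnot(all(c("res_num", "offset") %in% names(planted)))
    if (any(planted$res_num < 1L | planted$res_num > n_residues))
      stop("planted residue out of range 1..", n_residues)
  }
  set.seed(derive_seed(seed, 1L))
  rot_scaffold <- random_rotation()
  dirs <- fibonacci_sphere(n_residues) %*% t(rot_scaffold)
  radii <- stats::runif(n_residues, 3.8, 5.6)

  # backbone (CA) is shared between the homologs so that structural
  # pairing stays intact; the geometric signal lives on the sidechain
  # proxy (CB), seated inward of the CA so it is the residue's
  # closest-approach atom. Planted residues have B's CB displaced
  # radially by the stated offset.
  cb_radii_a <- radii - 0.8
  cb_radii_b <- cb_radii_a
  if (!is.null(planted)) {
    if (any(planted$offset <= 0))
      stop("planted offsets must be positive")
    cb_radii_b[planted$res_num] <- cb_radii_a[planted$res_num] -
      planted$offset
    if (any(cb_radii_b[planted$res_num] < 0.4))
      stop("planted offsets place atoms atop the reference (sidechain ",
           "radius would drop below 0.4 angstrom)")
  }

  build_atoms <- function(radii_use, cb_radii_use) {
    n <- length(radii_use)
    ca <- dirs * radii_use
    cb <- dirs * cb_radii_use
    atoms <- data.frame(
      serial = seq_len(2L * n),
      atom_name = c(rbind(rep("CA", n), rep("CB", n)))[seq_len(2L * n)],
      alt_loc = "",
      res_name = "GLY",
      chain_id = "A",
      res_num = rep(seq_len(n), each = 2L),
      ins_code = "",
      x = 0, y = 0, z = 0,
      occupancy = 1, b_factor = 0, element = "C",
      stringsAsFactors = FALSE
    )
    xyz <- matrix(NA_real_, nrow = 2L * n, ncol = 3L)
    xyz[seq(1L, 2L * n, by = 2L), ] <- ca
    xyz[seq(2L, 2L * n, by = 2L), ] <- cb
    # catalytic lysine: NZ at the origin (reference), CA off to one side
    lys <- data.frame(
      serial = 2L * n + 1:2, atom_name = c("NZ", "CA"), alt_loc = "",
      res_name = "LYS", chain_id = "A", res_num = 1000L, ins_code = "",
      x = 0, y = 0, z = 0, occupancy = 1, b_factor = 0,
      element = c("N", "C"), stringsAsFactors = FALSE)
    xyz <- rbind(xyz, c(0, 0, 0), c(1.2, 1.1, -3.4))
    atoms <- rbind(atoms, lys)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    atoms
  }

  atoms_a <- build_atoms(radii, cb_radii_a)
  atoms_b <- build_atoms(radii, cb_radii_b)

  # distinct rigid frame for B
  R0 <- random_rotation()
  t0 <- stats::runif(3, -8, 8)
  xyz_b <- as.matrix(atoms_b[, c("x", "y", "z")]) %*% t(R0)
  xyz_b <- sweep(xyz_b, 2, t0, "+")
  atoms_b$x <- xyz_b[, 1]; atoms_b$y <- xyz_b[, 2]; atoms_b$z <- xyz_b[, 3]
  atoms_b$res_num <- atoms_b$res_num + res_num_shift

  # sanity: no two atoms on top of each other
  for (atoms in list(atoms_a, atoms_b)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.25)
      stop("planted offsets place atoms atop one another (min distance ",
           format(dmin, digits = 3), " angstrom)")
  }

  corr <- data.frame(
    chain_a = "A", res_num_a = c(seq_len(n_residues), 1000L),
    res_name_a = c(rep("GLY", n_residues), "LYS"),
    chain_b = "A", res_num_b = c(seq_len(n_residues), 1000L) + res_num_shift,
    res_name_b = c(rep("GLY", n_residues), "LYS"),
    distance = 0)
  attr(corr, "method") <- "truth"
  class(corr) <- c("Correspondence", "data.frame")

  structure(list(
    model_a = structure_model("homolog_A", 1L, atoms_a),
    model_b = structure_model("homolog_B", 1L, atoms_b),
    correspondence = corr,
    planted = planted,
    reference_a = atom_selector("A", 1000L),
    reference_b = atom_selector("A", 1000L + res_num_shift),
    transform = list(rotation = R0, translation = t0),
    seed = seed
  ), class = "HomologPairTruth")
}

#' Sample a Gaussian-perturbed conformational ensemble
#'
#' Each snapshot adds i.i.d. isotropic Gaussian displacement (per-atom,
#' per-coordinate SD `sigma`) to the base coordinates. This emulates
#' only the statistical structure the distance-profile analysis assumes
#' (stationary fluctuation about a mean structure); it is explicitly
#' *not* a physical molecular-dynamics surrogate (no covariance, modes,
#' or kinetics).
#'
#' @param model base [structure_model].
#' @param sigma per-coordinate fluctuation SD, angstrom (>= 0).
#' @param n_snapshots number of snapshots (the emulated default
#'   elsewhere is 10000: a 10 ns run saved every 1 ps).
#' @param dt snapshot spacing, ps.
#' @param seed root seed (stream 2 is used).
#' @return an [ensemble].
#' @export
sample_ensemble <- function(model, sigma, n_snapshots, dt = 1, seed = 1L) {
  stopifnot(sigma >= 0, n_snapshots >= 1)
  set.seed(derive_seed(seed, 2L))
  base <- coords(model)
  n <- nrow(base)
  arr <- array(rep(as.numeric(base), n_snapshots),
               dim = c(n, 3L, n_snapshots))
  if (sigma > 0)
    arr <- arr + array(stats::rnorm(n * 3L * n_snapshots, 0, sigma),
                       dim = c(n, 3L, n_snapshots))
  ensemble(model$atoms, arr, dt = dt,
           source_id = paste0(model$structure_id, "_ens"))
}

#' Simulate a homolog-family alignment with per-column conservation
#'
#' Sequences are drawn independently per column from stated
#' distributions: either fully conserved (`list(aa = "V")`) or a
#' mixture (`list(freqs = c(I = 0.5, V = 0.5))`). Gaps are overlaid
#' uniformly at `gap_rate`.
#'
#' @param n_sequences number of sequences.
#' @param columns list of per-column specs (see above).
#' @param gap_rate per-symbol gap probability in \[0, 1\].
#' @param seed root seed (stream 3 is used).
#' @return named character vector of aligned sequences.
#' @export
make_msa <- function(n_sequences, columns, gap_rate = 0, seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  mat <- matrix("", nrow = n_sequences, ncol = length(columns))
  for (j in seq_along(columns)) {
    spec <- columns[[j]]
    if (!is.null(spec$aa)) {
      mat[, j] <- spec$aa
    } else if (!is.null(spec$freqs)) {
      f <- spec$freqs
      if (abs(sum(f) - 1) > 1e-9)
        stop("column ", j, ": frequencies must sum to 1")
      mat[, j] <- sample(names(f), n_sequences, replace = TRUE, prob = f)
    } else stop("column ", j, ": spec needs $aa or $freqs")
  }
  if (gap_rate > 0) {
    gaps <- matrix(stats::runif(length(mat)) < gap_rate, nrow = n_sequences)
    mat[gaps] <- "-"
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- paste0("seq_", seq_len(n_sequences))
  out
}

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate replicate enantiomer peak areas at a stated true ee
#'
#' Reference/other areas are `total_area * (1 +/- true_ee) / 2`, each
#' multiplied by positivity-preserving lognormal noise of coefficient
#' of variation `cv` (mean 1).
#'
#' @param true_ee true signed ee fraction in \[-1, 1\].
#' @param total_area mean total area (arbitrary units).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param n_reps number of replicate runs.
#' @param seed root seed (stream 4 is used).
#' @return data frame: `run_id`, `area_ref`, `area_other`.
#' @export
simulate_peak_areas <- function(true_ee, total_area = 100, cv = 0.02,
                                n_reps = 3L, seed = 1L) {
  stopifnot(abs(true_ee) <= 1, total_area > 0, cv >= 0, n_reps >= 1)
  set.seed(derive_seed(seed, 4L))
  a_ref <- total_area * (1 + true_ee) / 2 * lognormal_factor(n_reps, cv)
  a_oth <- total_area * (1 - true_ee) / 2 * lognormal_factor(n_reps, cv)
  data.frame(run_id = seq_len(n_reps), area_ref = a_ref, area_other = a_oth)
}

#' Simulate Michaelis-Menten rate data
#'
#' `v = k_cat * S / (K_M + S)` times lognormal noise of coefficient of
#' variation `noise_cv` (emulating a photometric rate readout).
#'
#' @param K_M Michaelis constant, mM.
#' @param k_cat turnover number, 1/s.
#' @param S_grid substrate concentrations, mM.
#' @param noise_cv multiplicative noise CV (0 for noiseless).
#' @param seed root seed (stream 5 is used).
#' @return data frame: `S`, `rate`.
#' @export
simulate_kinetics <- function(K_M, k_cat, S_grid, noise_cv = 0.01,
                              seed = 1L) {
  stopifnot(K_M > 0, k_cat > 0, all(S_grid > 0), noise_cv >= 0)
  set.seed(derive_seed(seed, 5L))
  v <- mm_rate(S_grid, K_M, k_cat) * lognormal_factor(length(S_grid), noise_cv)
  data.frame(S = S_grid, rate = v)
}

#' Write a fixture with its JSON ground-truth sidecar
#'
#' Standard formats only: structures/ensembles as (multi-model) PDB,
#' alignments as FASTA, tables as TSV; the ground truth goes to a JSON
#' sidecar written losslessly (`digits = NA`).
#'
#' @param truth a list of ground-truth values (seeds, planted offsets,
#'   true parameters, ...).
#' @param path sidecar path (`.json`).
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
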