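#' Construct a conformational ensemble
#'
#' An ensemble is an ordered set of snapshots of a fixed atom set, e.g.
#' frames saved along a molecular-dynamics production run (the emulated
#' default elsewhere in this package is a 10 ns run sampled every 1 ps).
#'
#' @param atom_index data frame of atom identities (columns as in a
#'   [structure_model] atoms table, coordinates ignored).
#' @param snapshots numeric array `n_atoms x 3 x n_snapshots`, angstrom.
#' @param dt snapshot spacing in picoseconds (metadata only).
#' @param source_id identifier string.
#' @return an object of class `Ensemble`.
#' @export
ensemble <- function(atom_index, snapshots, dt = 1, source_id = "ensemble") {
  stopifnot(is.array(snapshots), length(dim(snapshots)) == 3L,
            dim(snapshots)[2] == 3L)
  if (dim(snapshots)[1] != nrow(atom_index))
    stop("snapshot atom count does not match atom_index")
  if (dim(snapshots)[3] < 1L) stop("ensemble needs at least one snapshot")
  structure(list(atom_index = atom_index, snapshots = snapshots,
                 dt = dt, source_id = source_id),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble", x$source_id, "-", dim(x$snapshots)[1], "atoms x",
      dim(x$snapshots)[3], "snapshots (dt =", x$dt, "ps)\n")
  invisible(x)
}

#' Number of snapshots in an ensemble
#' @param ens an [ensemble].
#' @return integer snapshot count.
#' @export
n_snapshots <- function(ens) dim(ens$snapshots)[3]

atom_key <- function(atoms) {
  paste(atoms$chain_id, atoms$res_num, atoms$ins_code, atoms$atom_name,
        sep = ":")
}

#' Load a conformational ensemble from a multi-model PDB file
#'
#' Every model must contain the same atoms in the same order; the first
#' mismatching atom is named in the error. Models become snapshots in
#' file order.
#'
#' @inheritParams read_structure
#' @param atom_filter optional predicate `function(atoms_df) -> logical
#'   vector` applied to the atom table of every model (e.g. to restrict
#'   to C-alpha atoms).
#' @param dt snapshot spacing in picoseconds (metadata).
#' @return an [ensemble].
#' @export
load_ensemble <- function(path, atom_filter = NULL, chain = NULL,
                          keep_het = FALSE, keep_hydrogens = FALSE, dt = 1) {
  models <- read_structure(path, chain = chain, keep_het = keep_het,
                           keep_hydrogens = keep_hydrogens)
  if (!is.null(atom_filter)) {
    models <- lapply(models, function(m) {
      m$atoms <- m$atoms[atom_filter(m$atoms), , drop = FALSE]
      m
    })
  }
  ensemble_from_models(models, dt = dt,
                       source_id = models[[1]]$structure_id)
}

#' Assemble an ensemble from a list of structure models
#' @param models list of [structure_model] objects sharing one atom set.
#' @inheritParams ensemble
#' @return an [ensemble].
#' @export
ensemble_from_models <- function(models, dt = 1, source_id = "ensemble") {
  ref_key <- atom_key(models[[1]]$atoms)
  for (k in seq_along(models)) {
    kk <- atom_key(models[[k]]$atoms)
    if (!identical(kk, ref_key)) {
      missing_atom <- setdiff(ref_key, kk)
      extra <- setdiff(kk, ref_key)
      off <- if (length(missing_atom)) missing_atom[1] else extra[1]
      stop("atom-set mismatch between models 1 and ", k,
           ": first offending atom ", off)
    }
  }
  arr <- array(NA_real_, dim = c(length(ref_key), 3L, length(models)))
  for (k in seq_along(models)) arr[, , k] <- coords(models[[k]])
  ensemble(models[[1]]$atoms, arr, dt = dt, source_id = source_id)
}

#' Read an ensemble from a plain-text trajectory table
#'
#' Accepts the simple TSV dialect used for generated fixtures: columns
#' `snapshot`, `atom` (index into `atom_index`), `x`, `y`, `z`.
#'
#' @param path TSV path.
#' @param atom_index atom identity table (as in [ensemble()]).
#' @inheritParams ensemble
#' @return an [ensemble].
#' @export
load_ensemble_table <- function(path, atom_index, dt = 1,
                                source_id = "ensemble") {
  tb <- utils::read.table(path, header = TRUE, sep = "\t")
  snaps <- sort(unique(tb$snapshot))
  arr <- array(NA_real_, dim = c(nrow(atom_index), 3L, length(snaps)))
  for (i in seq_along(snaps)) {
    s <- tb[tb$snapshot == snaps[i], , drop = FALSE]
    s <- s[order(s$atom), , drop = FALSE]
    if (nrow(s) != nrow(atom_index))
      stop("snapshot ", snaps[i], " has ", nrow(s), " atoms, expected ",
           nrow(atom_index))
    arr[, , i] <- cbind(s$x, s$y, s$z)
  }
  ensemble(atom_index, arr, dt = dt, source_id = source_id)
}

#' Extract one snapshot of an ensemble as a structure model
#' @param ens an [ensemble].
#' @param i snapshot index (default 1, the designated reference
#'   conformer).
#' @return a [structure_model].
#' @export
snapshot_model <- function(ens, i = 1L) {
  a <- ens$atom_index
  a$x <- ens$snapshots[, 1, i]
  a$y <- ens$snapshots[, 2, i]
  a$z <- ens$snapshots[, 3, i]
  structure_model(ens$source_id, i, a)
}

#' Per-atom distance statistics over a conformational ensemble
#'
#' For every atom of the stereoselectivity-determining region, computes
#' the mean and standard deviation of its distance to the reference atom
#' (catalytic-lysine `NZ` by default) across all snapshots:
#' `d_i(t) = || x_i(t) - x_ref(t) ||`. The region membership is fixed
#' once, on the reference conformer (snapshot `reference_snapshot`), and
#' kept even if atoms drift beyond the radius mid-trajectory. The SD is
#' the sample standard deviation (n - 1 denominator), treating snapshots
#' as a sample of the conformational distribution.
#'
#' @param ens an [ensemble].
#' @param spec a [region_spec]; its center and reference atom are
#'   resolved on the reference conformer.
#' @param reference_snapshot index of the conformer defining the region.
#' @return a `DistanceProfile`: data frame with atom identity columns,
#'   `mean`, `sd` and `n_snapshots`; attributes `reference` (atom
#'   identity row) and `radius`.
#' @export
distance_profile <- function(ens, spec, reference_snapshot = 1L) {
  stopifnot(inherits(ens, "Ensemble"), inherits(spec, "RegionSpec"))
  refmod <- snapshot_model(ens, reference_snapshot)
  ref_rec <- get_reference_atom(refmod, spec)
  region <- select_region(refmod, spec)
  if (nrow(region) == 0L) stop("empty region: nothing to profile")
  all_keys <- atom_key(ens$atom_index)
  reg_idx <- match(atom_key(region), all_keys)
  ref_idx <- match(atom_key(ref_rec), all_keys)
  nt <- n_snapshots(ens)
  # distances per region atom per snapshot
  dmat <- matrix(NA_real_, nrow = length(reg_idx), ncol = nt)
  for (t in seq_len(nt)) {
    snap <- matrix(ens$snapshots[, , t], ncol = 3L)
    rel <- snap[reg_idx, , drop = FALSE] -
      matrix(snap[ref_idx, ], nrow = length(reg_idx), ncol = 3L,
             byrow = TRUE)
    dmat[, t] <- sqrt(rowSums(rel^2))
  }
  means <- rowMeans(dmat)
  sds <- if (nt > 1L) apply(dmat, 1L, stats::sd) else rep(0, length(reg_idx))
  out <- ens$atom_index[reg_idx, c("serial", "atom_name", "res_name",
                                   "chain_id", "res_num", "ins_code"),
                        drop = FALSE]
  out$mean <- means
  out$sd <- sds
  out$n_snapshots <- nt
  rownames(out) <- NULL
  attr(out, "reference") <- ref_rec
  attr(out, "radius") <- spec$radius
  class(out) <- c("DistanceProfile", "data.frame")
  out
}

#' Aggregate an atom-level distance profile to residue level
#'
#' The representative statistic per residue follows the closest-approach
#' convention: the atom with the smallest mean distance speaks for the
#' residue (ties broken by lower atom serial). A mean-over-atoms
#' alternative is available via `stat = "mean"`.
#'
#' @param profile a `DistanceProfile` from [distance_profile()].
#' @param stat `"closest"` (default) or `"mean"`.
#' @return a `ResidueProfile` data frame: `chain_id`, `res_num`,
#'   `ins_code`, `res_name`, `mean`, `sd`, `n_atoms`.
#' @export
aggregate_by_residue <- function(profile, stat = c("closest", "mean")) {
  stat <- match.arg(stat)
  stopifnot(nrow(profile) > 0L)
  key <- paste(profile$chain_id, profile$res_num, profile$ins_code,
               sep = ":")
  split_idx <- split(seq_len(nrow(profile)), key)
  rows <- lapply(split_idx, function(ix) {
    p <- profile[ix, , drop = FALSE]
    if (stat == "closest") {
      best <- ix[order(profile$mean[ix], profile$serial[ix])][1]
      data.frame(chain_id = profile$chain_id[best],
                 res_num = profile$res_num[best],
                 ins_code = profile$ins_code[best],
                 res_name = profile$res_name[best],
                 mean = profile$mean[best], sd = profile$sd[best],
                 n_atoms = length(ix))
    } else {
      data.frame(chain_id = p$chain_id[1], res_num = p$res_num[1],
                 ins_code = p$ins_code[1], res_name = p$res_name[1],
                 mean = mean(p$mean), sd = sqrt(mean(p$sd^2)),
                 n_atoms = length(ix))
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_id, out$res_num, out$ins_code), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ResidueProfile", "data.frame")
  out
}

#' Write a distance profile as TSV
#'
#' Columns mirror an atom-level mean/SD distance plot: atom, residue,
#' mean and SD in angstrom.
#'
#' @param profile a `DistanceProfile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- data.frame(atom = profile$atom_name,
                    residue = paste0(profile$res_name, profile$res_num),
                    chain = profile$chain_id,
                    mean_A = profile$mean, sd_A = profile$sd)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
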