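#' Specify the stereoselectivity-determining region around a reference point
#'
#' The region is defined as all atoms within `radius` angstrom (inclusive
#' boundary) of a center point: either explicit coordinates (e.g. the
#' newly formed stereogenic center of the bound substrate) or an atom
#' selector resolved on a structure. Distances throughout the analysis
#' are measured to a reference atom, by default the epsilon-amino
#' nitrogen (`NZ`) of the catalytic, Schiff-base-forming lysine.
#'
#' @param center either a numeric length-3 coordinate (angstrom) or an
#'   [atom_selector].
#' @param radius region radius in angstrom (> 0); the default 6
#'   corresponds to a 12-angstrom-diameter sphere.
#' @param reference_atom [atom_selector] for the distance reference atom;
#'   when its `atom_name` is left at the default `"NZ"` the residue is
#'   required to be a lysine.
#' @return an object of class `RegionSpec`.
#' @export
region_spec <- function(center, radius = 6.0,
                        reference_atom = atom_selector(NULL, NULL, "NZ")) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  if (is.numeric(center)) {
    if (length(center) != 3L || !all(is.finite(center)))
      stop("numeric center must be a finite 3-vector")
  } else if (!inherits(center, "AtomSelector")) {
    stop("center must be a 3-vector or an atom_selector()")
  }
  structure(list(center = center, radius = radius,
                 reference_atom = reference_atom),
            class = "RegionSpec")
}

#' Select a single atom by chain, residue number and atom name
#'
#' @param chain chain identifier (or `NULL` to match any single chain).
#' @param res_num author residue number.
#' @param atom_name PDB atom name, default `"NZ"` (the catalytic-lysine
#'   epsilon-amino nitrogen). Setting any other name overrides the
#'   lysine requirement in [get_reference_atom()].
#' @param ins_code insertion code, default empty.
#' @return an object of class `AtomSelector`.
#' @export
atom_selector <- function(chain, res_num, atom_name = "NZ", ins_code = "") {
  structure(list(chain = chain, res_num = res_num,
                 atom_name = atom_name, ins_code = ins_code,
                 default_nz = missing(atom_name)),
            class = "AtomSelector")
}

resolve_atom <- function(model, sel, what = "atom") {
  stopifnot(inherits(model, "StructureModel"), inherits(sel, "AtomSelector"))
  a <- model$atoms
  hit <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) hit <- hit & a$chain_id == sel$chain
  if (!is.null(sel$res_num)) hit <- hit & a$res_num == sel$res_num
  hit <- hit & a$ins_code == (sel$ins_code %||% "")
  if (!any(hit))
    stop(what, ": residue ", sel$chain %||% "*", ":",
         sel$res_num %||% "*", " not found in ", model$structure_id)
  res <- a[hit, , drop = FALSE]
  if (isTRUE(sel$default_nz) && !all(res$res_name %in% c("LYS", "K")))
    stop(what, ": residue ", sel$chain %||% "*", ":", sel$res_num,
         " is ", res$res_name[1],
         ", not lysine; name the atom explicitly to override")
  res <- res[res$atom_name == sel$atom_name, , drop = FALSE]
  if (nrow(res) == 0L)
    stop(what, ": reference atom absent - no '", sel$atom_name,
         "' in residue ", sel$chain %||% "*", ":", sel$res_num)
  res[1, , drop = FALSE]
}

#' Locate the distance-reference atom of a structure
#'
#' By default this is the `NZ` atom of the specified lysine (the
#' epsilon-amino group that forms the catalytic Schiff base); the residue
#' must then actually be a lysine. Selecting any other atom name is an
#' explicit override and skips that check.
#'
#' @param model a [structure_model].
#' @param spec a [region_spec] (its `reference_atom` selector is used) or
#'   an [atom_selector].
#' @return one-row data frame: the matching atom record.
#' @export
get_reference_atom <- function(model, spec) {
  sel <- if (inherits(spec, "RegionSpec")) spec$reference_atom else spec
  resolve_atom(model, sel, what = "reference atom")
}

resolve_center <- function(model, spec) {
  if (is.numeric(spec$center)) return(as.numeric(spec$center))
  rec <- resolve_atom(model, spec$center, what = "region center")
  c(rec$x, rec$y, rec$z)
}

#' Select all atoms within the region radius of the center
#'
#' Membership uses an inclusive boundary (Euclidean distance <= radius)
#' and preserves input atom order. An empty region is legal and produces
#' a warning, mirroring the behaviour wanted for sparse toy systems.
#'
#' @param model a [structure_model].
#' @param spec a [region_spec].
#' @return data frame of member atom records with an extra `distance`
#'   column (angstrom from the center).
#' @export
select_region <- function(model, spec) {
  stopifnot(inherits(model, "StructureModel"), inherits(spec, "RegionSpec"))
  ctr <- resolve_center(model, spec)
  xyz <- coords(model)
  d <- sqrt(colSums((t(xyz) - ctr)^2))
  keep <- d <= spec$radius
  if (!any(keep)) warning("empty region: no atoms within ", spec$radius,
                          " angstrom of the center")
  out <- model$atoms[keep, , drop = FALSE]
  out$distance <- d[keep]
  rownames(out) <- NULL
  out
}

#' Write region membership as TSV
#'
#' Columns: chain, res_num, res_name, atom_name, distance (angstrom).
#'
#' @param region data frame from [select_region()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(region, path) {
  out <- data.frame(chain = region$chain_id, res_num = region$res_num,
                    res_name = region$res_name, atom_name = region$atom_name,
                    distance_A = region$distance)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `R %*% mobile + t` and `target` over paired points. A
#' reflection arising from the SVD is corrected by flipping the sign of
#' the smallest singular direction, so the returned rotation always has
#' determinant +1.
#'
#' @param mobile,target n x 3 matrices of paired coordinates, n >= 3.
#' @return an object of class `Superposition`: list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stop("mobile and target must have identical dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("need at least 3 paired points, got ", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)          # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set: superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ct - as.numeric(R %*% cm)
  fitted <- sweep(mobile %*% t(R), 2, t_vec, "+")
  structure(list(rotation = R, translation = t_vec,
                 rmsd = rmsd_between(fitted, target), n_pairs = n),
            class = "Superposition")
}

#' Apply a superposition to coordinates
#' @param sup a `Superposition` from [kabsch_superpose()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  stopifnot(inherits(sup, "Superposition"))
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @export
print.Superposition <- function(x, ...) {
  cat("Superposition:", x$n_pairs, "pairs, rmsd",
      format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' No re-fitting is performed; the deviation is measured in the given
#' frames.
#'
#' @param a,b n x 3 matrices of paired coordinates.
#' @return RMSD in angstrom.
#' @export
rmsd_between <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}
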