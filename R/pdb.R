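#' Read a protein structure from a PDB file
#'
#' Parses PDB v3.3 `ATOM`/`HETATM`/`MODEL`/`ENDMDL` records into one
#' [structure_model] per `MODEL` block (a file without `MODEL` records
#' yields a single implicit model). Reading is gzip-transparent.
#'
#' Sanitization mirrors common structure-preparation practice:
#' \itemize{
#'   \item alternate locations are collapsed to the highest-occupancy
#'     conformer (ties broken alphabetically by altloc id);
#'   \item waters and other heteroatoms are dropped unless `keep_het`;
#'   \item selenomethionine (`MSE`) is relabelled `MET` with its atoms
#'     retained, regardless of `keep_het`;
#'   \item hydrogens (and deuteriums) are dropped unless `keep_hydrogens`.
#' }
#' Author residue numbering and insertion codes are preserved verbatim.
#'
#' @param path path to a PDB file (optionally gzip-compressed).
#' @param chain optional single chain identifier; all other chains are
#'   discarded. An error is raised if the chain is absent.
#' @param keep_het keep heteroatom records (including waters)?
#' @param keep_hydrogens keep hydrogen/deuterium atoms?
#' @return a list of [structure_model] objects, one per model.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C"
#' ), pdb)
#' mods <- read_structure(pdb)
#' length(mods)        # 1
#' nrow(mods[[1]]$atoms)  # 2
#' @export
read_structure <- function(path, chain = NULL, keep_het = FALSE,
                           keep_hydrogens = FALSE) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read PDB file '", path,
                                             "': ", conditionMessage(e)))
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(rec == "ATOM  "))
    stop("no ATOM records found in '", path, "'")

  # assign model ids by scanning MODEL/ENDMDL
  model_of <- integer(length(lines))
  cur <- 0L
  seen_model_rec <- any(startsWith(lines, "MODEL"))
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "MODEL")) {
      mid <- suppressWarnings(as.integer(substr(lines[i], 7, 20)))
      cur <- if (is.na(mid)) cur + 1L else mid
    }
    model_of[i] <- if (seen_model_rec) cur else 1L
  }
  keep <- is_atom & model_of > 0L
  if (!seen_model_rec) keep <- is_atom
  lines <- lines[keep]
  model_of <- model_of[keep]
  rec <- rec[keep]

  atoms <- data.frame(
    record    = trimws(rec),
    serial    = suppressWarnings(as.integer(substr(lines, 7, 11))),
    atom_name = trimws(substr(lines, 13, 16)),
    alt_loc   = trimws(substr(lines, 17, 17)),
    res_name  = trimws(substr(lines, 18, 20)),
    chain_id  = trimws(substr(lines, 22, 22)),
    res_num   = suppressWarnings(as.integer(substr(lines, 23, 26))),
    ins_code  = trimws(substr(lines, 27, 27)),
    x         = as.numeric(substr(lines, 31, 38)),
    y         = as.numeric(substr(lines, 39, 46)),
    z         = as.numeric(substr(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    b_factor  = suppressWarnings(as.numeric(substr(lines, 61, 66))),
    element   = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$b_factor[is.na(atoms$b_factor)] <- 0
  # element fallback from atom name when columns 77-78 are blank
  blank <- atoms$element == ""
  atoms$element[blank] <- sub("^[0-9]*", "", atoms$atom_name[blank])
  atoms$element[blank] <- substr(atoms$element[blank], 1, 1)

  if (!is.null(chain)) {
    if (!chain %in% atoms$chain_id)
      stop("requested chain '", chain, "' absent from '", path, "'")
    sel <- atoms$chain_id == chain
    atoms <- atoms[sel, , drop = FALSE]
    model_of <- model_of[sel]
  }

  # MSE -> MET, retained even when heteroatoms are dropped
  is_mse <- atoms$res_name == "MSE"
  atoms$res_name[is_mse] <- "MET"
  atoms$record[is_mse] <- "ATOM"

  if (!keep_het) {
    sel <- atoms$record == "ATOM"
    atoms <- atoms[sel, , drop = FALSE]
    model_of <- model_of[sel]
  }
  if (!keep_hydrogens) {
    elem <- toupper(atoms$element)
    sel <- !(elem %in% c("H", "D"))
    atoms <- atoms[sel, , drop = FALSE]
    model_of <- model_of[sel]
  }
  if (nrow(atoms) == 0L)
    stop("zero atoms remain after filtering '", path, "'")

  sid <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  out <- lapply(sort(unique(model_of)), function(m) {
    a <- atoms[model_of == m, , drop = FALSE]
    a <- collapse_altlocs(a)
    a$record <- NULL
    rownames(a) <- NULL
    structure_model(sid, m, a)
  })
  out
}

# keep, per (chain, res_num, ins_code, atom_name), the altloc with the
# highest occupancy; equal occupancies resolved alphabetically by altloc
collapse_altlocs <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_num, atoms$ins_code,
               atoms$atom_name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$alt_loc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Construct a single-conformer structure model
#'
#' @param structure_id identifier string (e.g. a PDB id or fixture name).
#' @param model_id integer model number.
#' @param atoms data frame with columns `serial`, `atom_name`, `alt_loc`,
#'   `res_name`, `chain_id`, `res_num`, `ins_code`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `element`.
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(structure_id, model_id, atoms) {
  needed <- c("atom_name", "res_name", "chain_id", "res_num", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure model must contain atoms")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in structure model")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- ""
  if (is.null(atoms$ins_code)) atoms$ins_code <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b_factor)) atoms$b_factor <- 0
  if (is.null(atoms$element))
    atoms$element <- substr(sub("^[0-9]*", "", atoms$atom_name), 1, 1)
  key <- paste(atoms$chain_id, atoms$res_num, atoms$ins_code,
               atoms$atom_name, atoms$alt_loc)
  if (anyDuplicated(key))
    stop("duplicate atom identity after cleaning: ", key[duplicated(key)][1])
  structure(list(structure_id = structure_id, model_id = as.integer(model_id),
                 atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$structure_id, "model", x$model_id, "-",
      nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$res_num, x$atoms$ins_code))),
      "residues\n")
  invisible(x)
}

#' Extract the coordinate matrix of a structure model
#' @param model a [structure_model].
#' @return numeric matrix, one row per atom, columns x/y/z (angstrom).
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  m <- cbind(x = model$atoms$x, y = model$atoms$y, z = model$atoms$z)
  m
}

format_pdb_atom_line <- function(a) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L,
          ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name), a$atom_name),
          ifelse(a$alt_loc == "", " ", a$alt_loc),
          a$res_name, a$chain_id, a$res_num,
          ifelse(a$ins_code == "", " ", a$ins_code),
          a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
}

#' Write one or more structure models as a (multi-model) PDB file
#'
#' Coordinates are quantized to the PDB fixed-width precision (3 decimal
#' places); round-trips through this writer are therefore exact only to
#' 5e-4 angstrom.
#'
#' @param models a [structure_model] or list of them (written as
#'   `MODEL`/`ENDMDL` blocks when more than one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(models, path) {
  if (inherits(models, "StructureModel")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1L
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m$model_id), con)
    writeLines(format_pdb_atom_line(m$atoms), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
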