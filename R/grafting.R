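#' Create a substitution or deletion edit
#'
#' Edits are always expressed in the *original* numbering of the target
#' sequence; renumbering happens only when a mutated sequence is emitted
#' by [apply_edits()]. Names follow the conventional grammar:
#' `"T18S"` for substitutions, `"\u0394G204"` for deletions.
#'
#' @param kind `"substitution"` or `"deletion"`.
#' @param res_num 1-based position in the original target numbering.
#' @param from_aa wild-type 1-letter amino acid at that position.
#' @param to_aa replacement 1-letter amino acid (substitutions only).
#' @return one-row data frame of class `Edit`.
#' @export
edit <- function(kind = c("substitution", "deletion"), res_num, from_aa,
                 to_aa = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "substitution") {
    if (is.na(to_aa)) stop("substitution needs to_aa")
    if (identical(to_aa, from_aa))
      stop("substitution must change the residue (", from_aa, res_num, ")")
  }
  out <- data.frame(kind = kind, res_num = as.integer(res_num),
                    from_aa = from_aa, to_aa = to_aa,
                    stringsAsFactors = FALSE)
  class(out) <- c("Edit", "data.frame")
  out
}

#' Parse an edit string
#'
#' Understands `"T18S"` (substitution) and `"\u0394G204"` or `"dG204"`
#' (deletion).
#'
#' @param s a single edit string.
#' @return an [edit()].
#' @export
parse_edit <- function(s) {
  s <- trimws(s)
  if (grepl("^(\u0394|d)[A-Z][0-9]+$", s)) {
    body <- sub("^(\u0394|d)", "", s)
    edit("deletion", res_num = as.integer(substr(body, 2, nchar(body))),
         from_aa = substr(body, 1, 1))
  } else if (grepl("^[A-Z][0-9]+[A-Z]$", s)) {
    edit("substitution",
         res_num = as.integer(substr(s, 2, nchar(s) - 1)),
         from_aa = substr(s, 1, 1), to_aa = substr(s, nchar(s), nchar(s)))
  } else {
    stop("cannot parse edit '", s, "'")
  }
}

edit_name <- function(e) {
  ifelse(e$kind == "deletion", paste0("\u0394", e$from_aa, e$res_num),
         paste0(e$from_aa, e$res_num, e$to_aa))
}

#' Bundle edits into a named variant
#'
#' @param name variant name; defaults to the edit names joined by `"/"`.
#' @param edits an `Edit` data frame (rows are edits) or list of
#'   [edit()]s / parseable strings.
#' @return an object of class `VariantSpec`: list with `name` and the
#'   edits sorted by residue number.
#' @export
variant_spec <- function(edits, name = NULL) {
  if (!is.data.frame(edits)) {
    edits <- if (length(edits) == 0L) {
      data.frame(kind = character(), res_num = integer(),
                 from_aa = character(), to_aa = character(),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(edits, function(e)
        if (is.character(e)) parse_edit(e) else e))
    }
  }
  if (nrow(edits) == 0L && is.null(name)) name <- "wt"
  if (anyDuplicated(edits$res_num))
    stop("two edits at the same residue: ",
         edits$res_num[duplicated(edits$res_num)][1])
  if (is.null(name)) name <- paste(edit_name(edits), collapse = "/")
  edits <- edits[order(edits$res_num), , drop = FALSE]
  rownames(edits) <- NULL
  structure(list(name = name, edits = edits), class = "VariantSpec")
}

#' @export
print.VariantSpec <- function(x, ...) {
  cat("VariantSpec", x$name, "(", nrow(x$edits), "edit(s) )\n")
  invisible(x)
}

#' Map divergent candidate sites onto a target enzyme
#'
#' Given candidate sites in a source homolog and a correspondence whose
#' A side is the source and B side is the target, returns the target
#' positions with their wild-type residues verified against the target
#' sequence.
#'
#' @param candidates data frame with column `res_num` (source numbering)
#'   and optionally `label` and `expected_wt` (1-letter; checked against
#'   the target sequence when present).
#' @param corr_target a `Correspondence` with the source on side A and
#'   the target on side B.
#' @param target_seq target protein sequence (1-letter string).
#' @return a `SiteMap` data frame: `label`, `source_res`, `res_num`
#'   (target numbering), `wt_aa`.
#' @export
map_sites <- function(candidates, corr_target, target_seq) {
  tseq <- strsplit(toupper(target_seq), "")[[1]]
  idx <- match(candidates$res_num, corr_target$res_num_a)
  if (any(is.na(idx)))
    stop("candidate site(s) without a target partner: ",
         paste(candidates$res_num[is.na(idx)], collapse = ", "))
  tgt <- corr_target$res_num_b[idx]
  if (any(tgt < 1L | tgt > length(tseq)))
    stop("target position out of range: ",
         paste(tgt[tgt < 1L | tgt > length(tseq)], collapse = ", "))
  wt <- tseq[tgt]
  if (!is.null(candidates$expected_wt)) {
    bad <- !is.na(candidates$expected_wt) & candidates$expected_wt != wt
    if (any(bad))
      stop("wild-type mismatch at target position ", tgt[bad][1],
           ": expected ", candidates$expected_wt[bad][1], ", sequence has ",
           wt[bad][1])
  }
  out <- data.frame(
    label = candidates$label %||% paste0("site_", candidates$res_num),
    source_res = candidates$res_num, res_num = tgt, wt_aa = wt,
    stringsAsFactors = FALSE)
  class(out) <- c("SiteMap", "data.frame")
  out
}

.IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand a degenerate codon under the standard genetic code
#'
#' Enumerates every concrete codon matching the 3-letter IUPAC pattern
#' and translates them with the standard genetic code (table 1). Stop
#' codons are counted and excluded from the amino-acid set. The
#' workhorse case is `"NDT"`, the 12-codon set encoding 12 chemically
#' diverse amino acids with no stops, used for site-saturation
#' libraries.
#'
#' @param codon 3 IUPAC nucleotide letters.
#' @return an object of class `CodonExpansion`: list with `codon`,
#'   `codons` (character vector), `amino_acids` (sorted unique 1-letter
#'   set, stops excluded) and `stops` (count of stop codons).
#' @examples
#' expand_degenerate_codon("NDT")$amino_acids
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must have 3 letters")
  letters3 <- strsplit(codon, "")[[1]]
  if (!all(letters3 %in% names(.IUPAC_NT)))
    stop("invalid IUPAC nucleotide letter: ",
         paste(setdiff(letters3, names(.IUPAC_NT)), collapse = ", "))
  grid <- expand.grid(.IUPAC_NT[[letters3[3]]], .IUPAC_NT[[letters3[2]]],
                      .IUPAC_NT[[letters3[1]]], stringsAsFactors = FALSE)
  codons <- sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  structure(list(codon = codon, codons = codons,
                 amino_acids = sort(unique(aa[aa != "*"])),
                 stops = sum(aa == "*")),
            class = "CodonExpansion")
}

#' @export
print.CodonExpansion <- function(x, ...) {
  cat("CodonExpansion", x$codon, "-", length(x$codons), "codons,",
      length(x$amino_acids), "amino acids (",
      paste(x$amino_acids, collapse = ","), "),", x$stops, "stop(s)\n")
  invisible(x)
}

#' Single-substitution variants of one site over an amino-acid set
#'
#' Emits one single-edit variant per amino acid in `aa_set`, minus the
#' wild type (a variant must differ) and minus `exclusions`. Names
#' follow the `"X{n}Y"` grammar.
#'
#' @param site one-row `SiteMap` entry (or list with `res_num`,
#'   `wt_aa`).
#' @param aa_set candidate amino acids, e.g.
#'   `expand_degenerate_codon("NDT")$amino_acids`.
#' @param exclusions amino acids to skip; accepts plain letters
#'   (`"N"`) or full variant names (`"L20N"`).
#' @return list of [variant_spec()]s (empty with a warning if nothing
#'   remains).
#' @export
design_point_variants <- function(site, aa_set, exclusions = character()) {
  if (length(aa_set) == 0L) stop("aa_set must be nonempty")
  excl <- ifelse(nchar(exclusions) > 1L,
                 substr(exclusions, nchar(exclusions), nchar(exclusions)),
                 exclusions)
  aa <- setdiff(aa_set, c(site$wt_aa, excl))
  if (length(aa) == 0L) {
    warning("no variants remain for site ", site$wt_aa, site$res_num)
    return(list())
  }
  lapply(aa, function(to)
    variant_spec(edit("substitution", site$res_num, site$wt_aa, to)))
}

#' Build a named multi-edit motif swap (e.g. a beta-strand chimera)
#'
#' All edits are validated against the target sequence before the
#' variant is accepted.
#'
#' @param name variant name (e.g. `"chim_beta1"`).
#' @param edits edit strings or `Edit` rows.
#' @param target_seq target protein sequence (1-letter string).
#' @return a [variant_spec()].
#' @export
design_motif_swap <- function(name, edits, target_seq) {
  v <- variant_spec(edits, name = name)
  validate_edits(v$edits, target_seq)
  v
}

validate_edits <- function(edits, target_seq) {
  tseq <- strsplit(toupper(target_seq), "")[[1]]
  if (any(edits$res_num < 1L | edits$res_num > length(tseq)))
    stop("edit position out of range: ",
         edits$res_num[edits$res_num < 1L | edits$res_num > length(tseq)][1])
  have <- tseq[edits$res_num]
  bad <- have != edits$from_aa
  if (any(bad))
    stop("wild-type mismatch at position ", edits$res_num[bad][1],
         ": edit expects ", edits$from_aa[bad][1], ", sequence has ",
         have[bad][1])
  invisible(TRUE)
}

#' Combine variants into residue-disjoint higher-order variants
#'
#' Produces every `arity`-wise combination of the input variants whose
#' edit sets touch disjoint residues; conflicting combinations (two
#' edits at one residue) are dropped and reported via a message and the
#' `"dropped"` attribute. Combined names join the component names with
#' `"/"` in input-list order (matching the conventional naming of e.g.
#' `"A203G/\u0394G204/\u0394G205/T18S"`).
#'
#' @param variants list of [variant_spec()]s.
#' @param arity combination order (>= 2).
#' @return list of combined `VariantSpec`s, with attribute `dropped`
#'   naming the rejected combinations.
#' @export
combine_edits <- function(variants, arity = 2L) {
  if (arity < 2L) stop("arity must be >= 2")
  if (length(variants) < arity) return(structure(list(), dropped = character()))
  combos <- utils::combn(length(variants), arity, simplify = FALSE)
  kept <- list(); dropped <- character()
  for (cc in combos) {
    parts <- variants[cc]
    all_edits <- do.call(rbind, lapply(parts, `[[`, "edits"))
    nm <- paste(vapply(parts, `[[`, "", "name"), collapse = "/")
    if (anyDuplicated(all_edits$res_num)) {
      dropped <- c(dropped, nm)
    } else {
      kept[[length(kept) + 1L]] <- variant_spec(all_edits, name = nm)
    }
  }
  if (length(dropped))
    message("dropped ", length(dropped), " conflicting combination(s): ",
            paste(dropped, collapse = ", "))
  structure(kept, dropped = dropped)
}

#' Apply a variant's edits to the target sequence
#'
#' Substitutions are applied in place; deletions remove positions. Edit
#' positions always refer to the ORIGINAL numbering; the returned
#' sequence is renumbered contiguously (so after `\u0394G204
#' \u0394G205` the residue originally at 206 sits at 204).
#'
#' @param spec a [variant_spec()].
#' @param target_seq original target sequence (1-letter string).
#' @return the mutated sequence as a single string.
#' @export
apply_edits <- function(spec, target_seq) {
  stopifnot(inherits(spec, "VariantSpec"))
  validate_edits(spec$edits, target_seq)
  tseq <- strsplit(toupper(target_seq), "")[[1]]
  subs <- spec$edits[spec$edits$kind == "substitution", , drop = FALSE]
  tseq[subs$res_num] <- subs$to_aa
  dels <- spec$edits$res_num[spec$edits$kind == "deletion"]
  if (length(dels)) tseq <- tseq[-dels]
  paste(tseq, collapse = "")
}

#' Write variants as TSV and per-variant FASTA
#'
#' @param variants list of [variant_spec()]s.
#' @param target_seq original target sequence.
#' @param tsv_path output TSV path (name, edits, mutated sequence).
#' @param fasta_path optional FASTA output path.
#' @return `tsv_path`, invisibly.
#' @export
write_variants <- function(variants, target_seq, tsv_path,
                           fasta_path = NULL) {
  seqs <- vapply(variants, apply_edits, "", target_seq = target_seq)
  names(seqs) <- vapply(variants, `[[`, "", "name")
  out <- data.frame(
    name = names(seqs),
    edits = vapply(variants, function(v)
      paste(edit_name(v$edits), collapse = ","), ""),
    sequence = unname(seqs))
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta_path)
  invisible(tsv_path)
}
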