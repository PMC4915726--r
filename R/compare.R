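#' Pair residues of two homologs by structural superposition
#'
#' After applying `sup` to model A's coordinates, C-alpha atoms of the
#' two structures are paired by mutual nearest neighbour within `cutoff`
#' angstrom. The result is one-to-one by construction.
#'
#' @param model_a,model_b [structure_model] objects.
#' @param sup a `Superposition` mapping A onto B's frame (e.g. from
#'   [kabsch_superpose()] on anchor atoms).
#' @param cutoff maximum C-alpha distance for a pair, angstrom.
#' @param ca_name atom name used for pairing (default `"CA"`).
#' @return a `Correspondence` data frame: `chain_a`, `res_num_a`,
#'   `res_name_a`, `chain_b`, `res_num_b`, `res_name_b`, `distance`.
#' @export
build_correspondence <- function(model_a, model_b, sup, cutoff = 2.5,
                                 ca_name = "CA") {
  a <- model_a$atoms[model_a$atoms$atom_name == ca_name, , drop = FALSE]
  b <- model_b$atoms[model_b$atoms$atom_name == ca_name, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("no '", ca_name, "' atoms to pair")
  xa <- apply_superposition(sup, cbind(a$x, a$y, a$z))
  xb <- cbind(b$x, b$y, b$z)
  # pairwise distances (small n: dense matrix is fine)
  dd <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  dd[dd < 0] <- 0
  dd <- sqrt(dd)
  nn_ab <- apply(dd, 1L, which.min)
  nn_ba <- apply(dd, 2L, which.min)
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab] == i & dd[cbind(i, nn_ab)] <= cutoff
  if (!any(mutual)) stop("no residue pairs within ", cutoff, " angstrom")
  j <- nn_ab[mutual]
  out <- data.frame(chain_a = a$chain_id[mutual], res_num_a = a$res_num[mutual],
                    res_name_a = a$res_name[mutual],
                    chain_b = b$chain_id[j], res_num_b = b$res_num[j],
                    res_name_b = b$res_name[j],
                    distance = dd[cbind(which(mutual), j)])
  out <- out[order(out$chain_a, out$res_num_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- "structural"
  class(out) <- c("Correspondence", "data.frame")
  out
}

#' Configuration for divergence calling
#'
#' The underlying study reports only that homologous positions showed
#' "significantly different" distances; the numeric criterion here is a
#' declared convention of this package, with both knobs exposed: a site
#' is a candidate when its mean-distance difference is at least
#' `score_threshold` pooled-SD units *and* at least `min_delta` angstrom
#' in absolute terms, and it is not on the mechanistic exclusion list.
#'
#' @param score_threshold pooled-SD multiple `k` (default 2).
#' @param min_delta minimum absolute mean-distance difference, angstrom.
#' @param exclusions data frame with columns `side` ("A" or "B"),
#'   `res_num` and `reason`; mechanistic removals (e.g. proton-shuttle
#'   glutamates) are always explicit user input, never inferred.
#' @return an object of class `CompareConfig`.
#' @export
compare_config <- function(score_threshold = 2.0, min_delta = 1.0,
                           exclusions = NULL) {
  if (score_threshold <= 0 || min_delta <= 0)
    stop("thresholds must be positive")
  if (!is.null(exclusions))
    stopifnot(all(c("side", "res_num", "reason") %in% names(exclusions)))
  structure(list(score_threshold = score_threshold, min_delta = min_delta,
                 exclusions = exclusions),
            class = "CompareConfig")
}

#' Cross-homolog divergence of residue distance profiles
#'
#' Joins two residue-level profiles through a correspondence and scores
#' each pair: `delta = |mean_A - mean_B|`, `pooled_sd =
#' sqrt(sd_A^2 + sd_B^2)`, `score = delta / pooled_sd` (infinite when the
#' pooled SD is zero but the means differ). Pairs missing from either
#' profile are skipped with a warning.
#'
#' @param profile_a,profile_b `ResidueProfile` objects (A and B sides of
#'   the correspondence).
#' @param corr a `Correspondence` from [build_correspondence()] (or an
#'   equivalent user-supplied table).
#' @param cfg a [compare_config()].
#' @return a `DivergenceTable` data frame: pair identity columns,
#'   `pair_label` (1-letter residue codes, A side first), `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `delta`, `pooled_sd`, `score`,
#'   `candidate`, `excluded_reason`.
#' @export
divergence_table <- function(profile_a, profile_b, corr,
                             cfg = compare_config()) {
  ka <- paste(profile_a$chain_id, profile_a$res_num)
  kb <- paste(profile_b$chain_id, profile_b$res_num)
  ia <- match(paste(corr$chain_a, corr$res_num_a), ka)
  ib <- match(paste(corr$chain_b, corr$res_num_b), kb)
  miss <- is.na(ia) | is.na(ib)
  if (all(miss)) stop("no correspondence pair present in both profiles")
  if (any(miss))
    warning(sum(miss), " correspondence pair(s) missing from a profile; skipped")
  corr <- corr[!miss, , drop = FALSE]
  ia <- ia[!miss]; ib <- ib[!miss]
  delta <- abs(profile_a$mean[ia] - profile_b$mean[ib])
  pooled <- sqrt(profile_a$sd[ia]^2 + profile_b$sd[ib]^2)
  score <- ifelse(pooled > 0, delta / pooled, ifelse(delta > 0, Inf, 0))
  out <- data.frame(
    chain_a = corr$chain_a, res_num_a = corr$res_num_a,
    res_name_a = profile_a$res_name[ia],
    chain_b = corr$chain_b, res_num_b = corr$res_num_b,
    res_name_b = profile_b$res_name[ib],
    mean_a = profile_a$mean[ia], sd_a = profile_a$sd[ia],
    mean_b = profile_b$mean[ib], sd_b = profile_b$sd[ib],
    delta = delta, pooled_sd = pooled, score = score,
    stringsAsFactors = FALSE
  )
  out$pair_label <- paste0(aa_one(out$res_name_a), out$res_num_a, "/",
                           aa_one(out$res_name_b), out$res_num_b)
  out$excluded_reason <- NA_character_
  excl <- cfg$exclusions
  if (!is.null(excl)) {
    for (r in seq_len(nrow(excl))) {
      hit <- if (excl$side[r] == "A") out$res_num_a == excl$res_num[r]
             else out$res_num_b == excl$res_num[r]
      out$excluded_reason[hit] <- excl$reason[r]
    }
  }
  out$candidate <- out$score >= cfg$score_threshold &
    out$delta >= cfg$min_delta & is.na(out$excluded_reason)
  class(out) <- c("DivergenceTable", "data.frame")
  out
}

#' Write a divergence table as TSV
#' @param div a `DivergenceTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_divergence_tsv <- function(div, path) {
  utils::write.table(as.data.frame(div), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path aligned FASTA path.
#' @return uppercase character vector of equal-length sequences, named
#'   by FASTA headers.
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  if (length(unique(nchar(out))) != 1L)
    stop("ragged alignment: sequences differ in length")
  out
}

#' Write an alignment as aligned FASTA
#' @param msa character vector of aligned sequences (optionally named).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  if (is.null(names(msa))) names(msa) <- paste0("seq_", seq_along(msa))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(msa), path)
  invisible(path)
}

#' Per-column conservation statistics of an alignment
#'
#' For each column, amino-acid frequencies are computed over non-gap
#' symbols, the Shannon entropy `H = -sum f_a log2 f_a` (bits) and the
#' information content `IC = log2(20) - H` follow the standard
#' sequence-logo convention: the stack height is IC and each letter's
#' height is `f_a * IC`. No small-sample correction is applied by
#' default (alignments of thousands of sequences make it negligible);
#' `small_sample_correction = TRUE` subtracts the usual
#' `e(n) = (20 - 1) / (2 ln(2) n)` term.
#'
#' Columns that are entirely gaps get `IC = NA` and `all_gap = TRUE`;
#' columns with more than 50% gaps are flagged `unreliable`.
#'
#' @param msa character vector of equal-length aligned sequences
#'   (uppercase; `-` and `.` are gaps) or a path handled by
#'   [read_msa()].
#' @param small_sample_correction apply the `e(n)` correction?
#' @return a `ColumnStats` data frame with columns `column`, `entropy`,
#'   `ic`, `gap_fraction`, `n_effective`, `all_gap`, `unreliable`;
#'   attributes `freq` (20 x n_columns frequency matrix) and `heights`.
#' @export
column_stats <- function(msa, small_sample_correction = FALSE) {
  if (length(msa) == 1L && file.exists(msa)) msa <- read_msa(msa)
  L <- unique(nchar(msa))
  if (length(L) != 1L) stop("ragged alignment: sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  ncol_aln <- ncol(mat)
  freq <- matrix(0, nrow = 20L, ncol = ncol_aln,
                 dimnames = list(.AA20, NULL))
  entropy <- ic <- gapf <- neff <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- mat[, j]
    gap <- col %in% c("-", ".")
    gapf[j] <- mean(gap)
    res <- col[!gap]
    neff[j] <- length(res)
    if (length(res) == 0L) {
      entropy[j] <- NA_real_; ic[j] <- NA_real_
      next
    }
    counts <- table(factor(res, levels = .AA20))
    f <- as.numeric(counts) / sum(counts)
    freq[, j] <- f
    p <- f[f > 0]
    entropy[j] <- -sum(p * log2(p))
    corr <- if (small_sample_correction) 19 / (2 * log(2) * length(res)) else 0
    ic[j] <- max(log2(20) - entropy[j] - corr, 0)
  }
  out <- data.frame(column = seq_len(ncol_aln), entropy = entropy, ic = ic,
                    gap_fraction = gapf, n_effective = neff,
                    all_gap = neff == 0L, unreliable = gapf > 0.5)
  heights <- sweep(freq, 2L, ic, "*")
  attr(out, "freq") <- freq
  attr(out, "heights") <- heights
  class(out) <- c("ColumnStats", "data.frame")
  out
}

#' Information content accessor
#'
#' Returns per-column IC in bits with its bounds checked
#' (`0 <= IC <= log2(20)`; `NA` for all-gap columns).
#'
#' @param stats a `ColumnStats` from [column_stats()].
#' @return numeric vector of IC values (bits).
#' @export
information_content <- function(stats) {
  ic <- stats$ic
  ok <- is.na(ic) | (ic >= -1e-12 & ic <= log2(20) + 1e-12)
  if (!all(ok)) stop("information content out of [0, log2(20)] bounds")
  ic
}

#' Letter heights of a sequence logo in long format
#' @param stats a `ColumnStats`.
#' @return data frame `column`, `aa`, `height` (bits); per-column
#'   heights sum to the column IC.
#' @export
letter_heights <- function(stats) {
  h <- attr(stats, "heights")
  data.frame(column = rep(seq_len(ncol(h)), each = nrow(h)),
             aa = rep(rownames(h), ncol(h)),
             height = as.numeric(h))
}

#' Write a logo matrix as TSV (column, aa, height)
#' @param stats a `ColumnStats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(stats, path) {
  lh <- letter_heights(stats)
  utils::write.table(lh[lh$height > 0, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter divergent candidates by conservation in both families
#'
#' Retains divergence candidates whose alignment columns are (virtually)
#' fully conserved in *both* homolog families: information content at
#' least `ic_min` bits on each side.
#'
#' @param div a `DivergenceTable` from [divergence_table()].
#' @param stats_a,stats_b `ColumnStats` for the A- and B-family
#'   alignments.
#' @param map_a,map_b named integer vectors mapping residue number (as
#'   character names) to alignment column, for sides A and B.
#' @param ic_min minimum IC in bits (default 3.0).
#' @return the candidate rows of `div` that survive, with `ic_a` and
#'   `ic_b` columns appended.
#' @export
conserved_divergent_sites <- function(div, stats_a, stats_b, map_a, map_b,
                                      ic_min = 3.0) {
  cand <- div[div$candidate, , drop = FALSE]
  col_a <- map_a[as.character(cand$res_num_a)]
  col_b <- map_b[as.character(cand$res_num_b)]
  if (any(is.na(col_a)) || any(is.na(col_b))) {
    bad <- cand$pair_label[is.na(col_a) | is.na(col_b)]
    stop("unmapped site(s): ", paste(bad, collapse = ", "))
  }
  cand$ic_a <- information_content(stats_a)[col_a]
  cand$ic_b <- information_content(stats_b)[col_b]
  keep <- !is.na(cand$ic_a) & !is.na(cand$ic_b) &
    cand$ic_a >= ic_min & cand$ic_b >= ic_min
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
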