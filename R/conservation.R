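#' Classify a nonapeptide against the motif hierarchy
#'
#' Returns `"stringent"` if the nonapeptide satisfies the stringent
#' grammar, else `"relaxed"` if it satisfies the relaxed grammar, else
#' `"none"`. Vectorized.
#'
#' @param nonapeptide Character vector of 9-residue strings.
#' @return Character vector in `{"stringent", "relaxed", "none"}`.
#' @export
classify_nonapeptide <- function(nonapeptide) {
  if (any(nchar(nonapeptide) != 9L)) {
    input_error("classify_nonapeptide expects 9-residue strings")
  }
  nonapeptide <- toupper(nonapeptide)
  s_re <- paste0("^", motif_regex(compile_motif("stringent")), "$")
  r_re <- paste0("^", motif_regex(compile_motif("relaxed")), "$")
  ifelse(grepl(s_re, nonapeptide), "stringent",
         ifelse(grepl(r_re, nonapeptide), "relaxed", "none"))
}

#' Summarize PTS2 conservation across an ortholog set
#'
#' Scans every ortholog with the relaxed grammar (a superset of the
#' stringent one), takes the earliest in-window match per sequence as
#' its best match, classifies its nonapeptide on the
#' stringent/relaxed/none hierarchy and co-reports the PTS1 call so a
#' "PTS2 lost, PTS1 gained" transition (as in diatoms) is visible.
#'
#' @param orthologs Protein set or FASTA path (at least one sequence).
#' @param config A [screen_config()]; its `window`, `enforce_pos5`,
#'   `hydrophobic_set` and `extended_pts1` entries apply. Detection uses
#'   the relaxed preset regardless of `motif_mode` so relaxed-only
#'   nonapeptides are classified rather than missed.
#' @return Object of class `conservation_profile`: list with `calls`
#'   (per-sequence `data.frame`), `fraction_stringent`,
#'   `fraction_any_pts2`, `pos5_hydrophobic_fraction` (over
#'   match-bearing sequences; `NA` if none) and `msa_concordant`
#'   (`NA` until [msa_anchor_check()] is consulted).
#' @export
conservation_summary <- function(orthologs, config = screen_config()) {
  proteins <- as_protein_set(orthologs)
  if (nrow(proteins) == 0L) input_error("conservation needs at least one sequence")
  motif <- compile_motif("relaxed",
                         enforce_pos5_hydrophobic = config$enforce_pos5,
                         hydrophobic_set = config$hydrophobic_set)
  matches <- scan_pts2(proteins, motif)
  matches <- n_terminal_filter(matches, config$window)
  best <- matches[!duplicated(matches$protein_id), , drop = FALSE]
  idx <- match(proteins$id, best$protein_id)
  pts1 <- classify_pts1(proteins, config$extended_pts1)

  calls <- data.frame(protein_id = proteins$id,
                      start = best$start[idx],
                      end = best$end[idx],
                      nonapeptide = best$nonapeptide[idx],
                      pos5_residue = best$pos5_residue[idx],
                      pos5_hydrophobic = best$pos5_hydrophobic[idx],
                      class = "none",
                      pts1_tripeptide = pts1$tripeptide,
                      pts1_category = pts1$category,
                      stringsAsFactors = FALSE)
  has <- !is.na(calls$nonapeptide)
  calls$class[has] <- classify_nonapeptide(calls$nonapeptide[has])

  structure(list(calls = calls,
                 fraction_stringent = mean(calls$class == "stringent"),
                 fraction_any_pts2 = mean(calls$class %in% c("stringent", "relaxed")),
                 pos5_hydrophobic_fraction =
                   if (any(has)) mean(calls$pos5_hydrophobic[has]) else NA_real_,
                 msa_concordant = NA),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(paste0("PTS2 conservation over %d sequences: %.0f%% stringent, ",
                     "%.0f%% any PTS2"),
              nrow(x$calls), 100 * x$fraction_stringent,
              100 * x$fraction_any_pts2))
  if (!is.na(x$pos5_hydrophobic_fraction)) {
    cat(sprintf(", %.0f%% hydrophobic position 5", 100 * x$pos5_hydrophobic_fraction))
  }
  cat("\n")
  invisible(x)
}

# Column indices of the residues (non-gap characters) of one aligned row.
alignment_columns <- function(aligned) {
  which(!strsplit(aligned, "")[[1]] %in% c("-", "."))
}

read_alignment <- function(msa, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    aln <- Biostrings::readAAMultipleAlignment(msa, format = format)
    out <- as.character(aln)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(msa) && !is.null(names(msa))) return(msa)
  input_error("MSA must be an alignment file path or a named character vector")
}

#' Check that motif matches occupy homologous alignment columns
#'
#' Maps each sequence's best in-window match to the columns of a
#' supplied multiple sequence alignment and tests whether every
#' match-bearing sequence shares at least `min_overlap` columns with the
#' reference's match. Gap characters `-` and `.` are equivalent. The
#' alignment rows, once ungapped, must be identical to the raw
#' sequences they stand for (checked when `proteins` is supplied).
#'
#' @param msa Aligned FASTA/Clustal path, or named character vector of
#'   aligned rows.
#' @param reference_id Identifier of the reference sequence; it must be
#'   present and carry a match.
#' @param config A [screen_config()] (window, motif options).
#' @param min_overlap Minimum shared columns for concordance (default 5
#'   of 9, a majority of the nonapeptide).
#' @param proteins Optional raw protein set to verify against.
#' @param format Alignment file format.
#' @return List with `concordant` (logical) and `spans`, a per-sequence
#'   `data.frame` of alignment column spans and overlaps with the
#'   reference.
#' @export
msa_anchor_check <- function(msa, reference_id, config = screen_config(),
                             min_overlap = 5L, proteins = NULL,
                             format = c("fasta", "clustal")) {
  rows <- read_alignment(msa, format)
  ungapped <- gsub("[-.]", "", rows)
  if (!is.null(proteins)) {
    proteins <- as_protein_set(proteins)
    idx <- match(names(rows), proteins$id)
    if (anyNA(idx)) input_error("alignment row(s) missing from raw sequences")
    if (!all(toupper(ungapped) == proteins$sequence[idx])) {
      input_error("alignment rows are not ungapped-identical to the raw sequences")
    }
  }
  if (!reference_id %in% names(rows)) {
    input_error("reference id '%s' absent from the alignment", reference_id)
  }
  prof <- conservation_summary(ungapped, config)
  calls <- prof$calls
  motif_cols <- lapply(seq_along(rows), function(i) {
    if (is.na(calls$start[i])) return(NULL)
    alignment_columns(rows[[i]])[calls$start[i]:calls$end[i]]
  })
  names(motif_cols) <- names(rows)
  ref_cols <- motif_cols[[reference_id]]
  if (is.null(ref_cols)) {
    input_error("reference '%s' has no in-window PTS2 match", reference_id)
  }
  spans <- data.frame(
    protein_id = names(rows),
    has_match = !vapply(motif_cols, is.null, TRUE),
    col_start = vapply(motif_cols, function(cc) if (is.null(cc)) NA_integer_
                       else min(cc), 1L),
    col_end = vapply(motif_cols, function(cc) if (is.null(cc)) NA_integer_
                     else max(cc), 1L),
    overlap = vapply(motif_cols, function(cc) if (is.null(cc)) NA_integer_
                     else length(intersect(cc, ref_cols)), 1L),
    stringsAsFactors = FALSE)
  rownames(spans) <- NULL
  concordant <- all(spans$overlap[spans$has_match] >= min_overlap)
  list(concordant = concordant, spans = spans)
}
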