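BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Homology significance thresholds
#'
#' All three comparisons are strict: a hit passes with
#' `evalue < e_max` AND `pident > id_min` AND `coverage > cov_min`.
#'
#' @param e_max Maximum E-value (exclusive), default `0.001`.
#' @param id_min Minimum percent identity (exclusive), default `30`.
#' @param cov_min Minimum query coverage as a fraction (exclusive),
#'   default `0.5`.
#' @return Object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(e_max = 0.001, id_min = 30, cov_min = 0.5) {
  if (e_max <= 0 || id_min <= 0 || cov_min <= 0) {
    input_error("all homology thresholds must be positive")
  }
  structure(list(e_max = e_max, id_min = id_min, cov_min = cov_min),
            class = "filter_thresholds")
}

empty_hit_frame <- function() {
  df <- as.data.frame(matrix(nrow = 0, ncol = length(BLAST6_COLS)))
  names(df) <- BLAST6_COLS
  df$query_length <- integer(0)
  df$query_coverage <- numeric(0)
  df$coverage_flag <- logical(0)
  df
}

#' Parse a BLAST tabular hit file
#'
#' Accepts the standard 12-column `outfmt 6` dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`) or a 13-column dialect with `qlen` appended.
#' With 12 columns, query lengths are joined from `query_fasta`.
#' Comment lines (`#`) are skipped. Query coverage is
#' `alignment_length / query_length` by default; `coverage_mode =
#' "query_span"` uses `(qend - qstart + 1) / query_length` instead
#' (gap-free query-span coverage). Coverage above 1.5 is flagged as a
#' suspicious join in the `coverage_flag` column.
#'
#' @param path Hit file path.
#' @param query_fasta Optional query FASTA path or protein set, required
#'   for the 12-column dialect.
#' @param coverage_mode `"alignment_length"` (default) or `"query_span"`.
#' @return `data.frame` of hits with derived `query_length`,
#'   `query_coverage` and `coverage_flag` columns.
#' @export
parse_blast_tab <- function(path, query_fasta = NULL,
                            coverage_mode = c("alignment_length", "query_span")) {
  coverage_mode <- match.arg(coverage_mode)
  if (!file.exists(path)) input_error("BLAST hit file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hit_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || !ncols %in% c(12L, 13L)) {
    input_error("BLAST tabular file must have 12 or 13 columns uniformly (saw: %s)",
                paste(ncols, collapse = ", "))
  }
  m <- do.call(rbind, fields)
  df <- data.frame(m, stringsAsFactors = FALSE)
  names(df) <- c(BLAST6_COLS, if (ncols == 13L) "qlen")
  num_cols <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore", if (ncols == 13L) "qlen")
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  if (any(df$evalue < 0)) input_error("negative E-value in %s", path)

  if (ncols == 13L) {
    df$query_length <- as.integer(df$qlen)
    df$qlen <- NULL
  } else {
    if (is.null(query_fasta)) {
      input_error("12-column hit file needs query_fasta to resolve query lengths")
    }
    q <- as_protein_set(query_fasta)
    idx <- match(df$qseqid, q$id)
    if (anyNA(idx)) {
      input_error("query id(s) absent from FASTA: %s",
                  paste(unique(df$qseqid[is.na(idx)]), collapse = ", "))
    }
    df$query_length <- nchar(q$sequence)[idx]
  }
  aligned <- if (coverage_mode == "alignment_length") df$length
             else df$qend - df$qstart + 1
  df$query_coverage <- aligned / df$query_length
  df$coverage_flag <- df$query_coverage > 1.5
  df
}

#' Filter hits under the significance thresholds
#'
#' Keeps hits with `evalue < e_max` AND `pident > id_min` AND
#' `query_coverage > cov_min` (strict inequalities); order is preserved
#' and the operation is idempotent.
#'
#' @param hits Hits from [parse_blast_tab()].
#' @param thresholds A [filter_thresholds()].
#' @return The passing rows of `hits`.
#' @export
filter_homologs <- function(hits, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  keep <- hits$evalue < thresholds$e_max &
    hits$pident > thresholds$id_min &
    hits$query_coverage > thresholds$cov_min
  hits[keep, , drop = FALSE]
}

#' Assign homology classes to screen candidates
#'
#' A candidate is a `known_family_homolog` iff at least one passing hit
#' links it (as query) to a subject in the known PTS2 family set;
#' otherwise it is `novel`. When no hit set is supplied
#' (`passing_hits = NULL`) candidates stay `unassigned`.
#'
#' @param candidates Candidates `data.frame` (or a `pts2_screen`).
#' @param passing_hits Hits that survived [filter_homologs()], or `NULL`.
#' @param known_family_subjects Character vector of subject ids
#'   belonging to known PTS2 protein families.
#' @return The candidates with `homology_class` filled.
#' @export
assign_homology_class <- function(candidates, passing_hits = NULL,
                                  known_family_subjects = character(0)) {
  screen <- NULL
  if (inherits(candidates, "pts2_screen")) {
    screen <- candidates
    candidates <- screen$candidates
  }
  if (is.null(passing_hits)) {
    candidates$homology_class <- "unassigned"
  } else {
    known <- vapply(candidates$protein_id, function(id) {
      subj <- passing_hits$sseqid[passing_hits$qseqid == id]
      any(subj %in% known_family_subjects)
    }, TRUE)
    candidates$homology_class <- ifelse(known, "known_family_homolog", "novel")
  }
  if (!is.null(screen)) {
    screen$candidates <- candidates
    return(screen)
  }
  candidates
}
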