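#' Screen configuration
#'
#' Bundles the tunable parameters of the candidate screen.
#'
#' @param window N-terminal window in residues; a match qualifies iff
#'   its start position is `<= window` (default 40).
#' @param motif_mode Motif preset, `"stringent"` or `"relaxed"`.
#' @param cys_window How many residues downstream of the nonapeptide end
#'   to search for the cleavage-site cysteine (default 10).
#' @param extended_pts1 Extended PTS1 tripeptide list.
#' @param enforce_pos5 Require a hydrophobic residue at nonapeptide
#'   position 5 during scanning.
#' @param hydrophobic_set Residues counted as hydrophobic at position 5.
#' @param ascii Use ASCII `-` instead of the en-dash in position spans.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(window = 40L, motif_mode = "stringent",
                          cys_window = 10L,
                          extended_pts1 = default_extended_pts1(),
                          enforce_pos5 = FALSE,
                          hydrophobic_set = DEFAULT_HYDROPHOBIC,
                          ascii = FALSE) {
  window <- as.integer(window)
  cys_window <- as.integer(cys_window)
  if (is.na(window) || window < 9L) input_error("window must be >= 9")
  if (is.na(cys_window) || cys_window < 1L) input_error("cys_window must be >= 1")
  structure(list(window = window, motif_mode = motif_mode,
                 cys_window = cys_window,
                 extended_pts1 = toupper(extended_pts1),
                 enforce_pos5 = isTRUE(enforce_pos5),
                 hydrophobic_set = toupper(hydrophobic_set),
                 ascii = isTRUE(ascii)),
            class = "screen_config")
}

config_motif <- function(config) {
  compile_motif(config$motif_mode,
                enforce_pos5_hydrophobic = config$enforce_pos5,
                hydrophobic_set = config$hydrophobic_set)
}

#' Keep matches starting inside the N-terminal window
#'
#' A match qualifies iff `start <= window`; order is preserved. The
#' start-based rule keeps a nonapeptide whose tail extends past the
#' window boundary (e.g. a 35–43 match under a 40-residue window).
#'
#' @param matches Match `data.frame` from [scan_pts2()].
#' @param window Window size in residues.
#' @return The qualifying rows of `matches`.
#' @export
n_terminal_filter <- function(matches, window = 40L) {
  matches[matches$start <= window, , drop = FALSE]
}

#' Find the cleavage-site cysteine downstream of a match
#'
#' The processing site of PTS2 proteins carries a conserved Cys shortly
#' downstream of the nonapeptide. Returns the smallest offset `k >= 1`
#' such that the residue at `end + k` is `C` and `k <= cys_window`, or
#' `NA` if none (the search is truncated at the sequence end).
#'
#' @param sequence Protein sequence(s), or a protein set.
#' @param end Nonapeptide end position(s), 1-based.
#' @param cys_window Search window in residues (default 10).
#' @return Integer vector of offsets (`NA` where absent).
#' @export
find_cleavage_cys <- function(sequence, end, cys_window = 10L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  n <- nchar(sequence)
  region <- substr(sequence, end + 1L, pmin(end + cys_window, n))
  pos <- regexpr("C", region, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos), NA_integer_)
}

empty_candidate_frame <- function() {
  data.frame(protein_id = character(0), annotation = character(0),
             homology_class = character(0), pattern = character(0),
             start = integer(0), end = integer(0),
             nonapeptide = character(0), pos5_residue = character(0),
             pos5_hydrophobic = logical(0), cys_offset = integer(0),
             pts1_tripeptide = character(0), pts1_category = character(0),
             first_exon = logical(0), stringsAsFactors = FALSE)
}

#' Screen a proteome for PTS2 candidate proteins
#'
#' Runs the full candidate screen: motif scan over every sequence,
#' N-terminal window filter, cleavage-site Cys detection on the primary
#' match, and PTS1 co-classification. A protein becomes a candidate iff
#' it has at least one match starting inside the window; its primary
#' match is the earliest such match. The homology class is filled later
#' by [assign_homology_class()] and starts as `"unassigned"`.
#'
#' @param x Proteome: FASTA path or protein set.
#' @param config A [screen_config()].
#' @return Object of class `pts2_screen`: a list with `candidates` (one
#'   row per candidate protein, in input order), `matches` (every match
#'   anywhere, with `in_window` flag), `summary` (`n_proteins`,
#'   `n_with_motif_anywhere`, `n_candidates_in_window`) and `config`.
#' @export
scan_proteome <- function(x, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  proteins <- as_protein_set(x)
  motif <- config_motif(config)
  matches <- scan_pts2(proteins, motif)
  matches$in_window <- matches$start <= config$window

  pts1 <- classify_pts1(proteins, config$extended_pts1)
  cand <- empty_candidate_frame()
  inw <- matches[matches$in_window, , drop = FALSE]
  if (nrow(inw) > 0L) {
    first <- inw[!duplicated(inw$protein_id), , drop = FALSE]  # earliest start
    ord <- match(first$protein_id, proteins$id)
    seqs <- proteins$sequence[ord]
    cand <- data.frame(protein_id = first$protein_id,
                       annotation = proteins$description[ord],
                       homology_class = "unassigned",
                       pattern = first$pattern,
                       start = first$start, end = first$end,
                       nonapeptide = first$nonapeptide,
                       pos5_residue = first$pos5_residue,
                       pos5_hydrophobic = first$pos5_hydrophobic,
                       cys_offset = find_cleavage_cys(seqs, first$end,
                                                      config$cys_window),
                       pts1_tripeptide = pts1$tripeptide[ord],
                       pts1_category = pts1$category[ord],
                       first_exon = NA,
                       stringsAsFactors = FALSE)
    cand <- cand[order(match(cand$protein_id, proteins$id)), , drop = FALSE]
    rownames(cand) <- NULL
  }
  summary <- list(n_proteins = nrow(proteins),
                  n_with_motif_anywhere = length(unique(matches$protein_id)),
                  n_candidates_in_window = nrow(cand))
  structure(list(candidates = cand, matches = matches,
                 summary = summary, config = config),
            class = "pts2_screen")
}

#' @export
print.pts2_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("PTS2 screen (%s motif, window %d aa): %d proteins, ",
                     "%d with a motif anywhere, %d in-window candidates\n"),
              x$config$motif_mode, x$config$window, s$n_proteins,
              s$n_with_motif_anywhere, s$n_candidates_in_window))
  invisible(x)
}

format_span <- function(start, end, ascii = FALSE) {
  if (length(start) == 0L) return(character(0))
  paste0(start, if (ascii) "-" else "–", end)
}

#' Write a candidate report as TSV
#'
#' Columns: `protein_id`, `annotation`, `homology_class`, `pattern`,
#' `position` (formatted `start–end`; en-dash by default, ASCII `-`
#' with `ascii = TRUE`), `nonapeptide`, `pos5_hydrophobic`,
#' `cys_offset`, `pts1_tripeptide`, `pts1_category`, `first_exon`.
#' Header row always present; rows keep input order.
#'
#' @param x A `pts2_screen` or a candidates `data.frame`.
#' @param path Output path.
#' @param ascii Use ASCII hyphen in position spans.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path, ascii = FALSE) {
  cand <- if (inherits(x, "pts2_screen")) x$candidates else x
  out <- data.frame(protein_id = cand$protein_id,
                    annotation = cand$annotation,
                    homology_class = cand$homology_class,
                    pattern = cand$pattern,
                    position = format_span(cand$start, cand$end, ascii),
                    nonapeptide = cand$nonapeptide,
                    pos5_hydrophobic = cand$pos5_hydrophobic,
                    cys_offset = cand$cys_offset,
                    pts1_tripeptide = cand$pts1_tripeptide,
                    pts1_category = cand$pts1_category,
                    first_exon = cand$first_exon,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    # keep a header-only file even with zero candidates
    out <- out[0, , drop = FALSE]
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a candidate report
#'
#' Parses a TSV written by [write_candidates()], splitting the position
#' span (en-dash or hyphen) back into integer `start`/`end`.
#'
#' @param path Report path.
#' @return Candidates `data.frame`.
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", na.strings = "")
  if (nrow(df) > 0L) {
    parts <- strsplit(df$position, "–|-")
    df$start <- vapply(parts, function(p) as.integer(p[1]), 1L)
    df$end <- vapply(parts, function(p) as.integer(p[2]), 1L)
  } else {
    df$start <- integer(0)
    df$end <- integer(0)
  }
  df
}

#' Does the nonapeptide lie in the first coding exon?
#'
#' Many PTS2 proteins carry the nonapeptide in a short first exon. Given
#' the CDS segments of one transcript (1-based inclusive genomic
#' coordinates, GFF3 convention), the match lies in the first exon iff
#' `3 * match_end` nucleotides fit in the first CDS segment in
#' translation order (minus-strand transcripts translate from the
#' highest-coordinate segment). The CDS `phase` attribute is ignored:
#' the first segment is assumed to start in frame.
#'
#' @param cds `data.frame` with columns `start`, `end`, `strand`
#'   (one transcript; all features on one strand), e.g. one element of
#'   [read_gff_cds()].
#' @param match_end Nonapeptide end position in protein coordinates, or
#'   a match row from [scan_pts2()].
#' @return Logical.
#' @export
pts2_in_first_exon <- function(cds, match_end) {
  if (is.data.frame(match_end)) match_end <- match_end$end
  if (is.null(cds) || nrow(cds) == 0L) input_error("no CDS features supplied")
  strand <- unique(as.character(cds$strand))
  if (length(strand) != 1L || !strand %in% c("+", "-")) {
    input_error("CDS features must lie on a single strand ('+' or '-')")
  }
  ord <- order(cds$start, decreasing = (strand == "-"))
  first_nt <- cds$end[ord[1]] - cds$start[ord[1]] + 1L
  3L * match_end <= first_nt
}

#' Read CDS segments per transcript from a GFF3 file
#'
#' @param path GFF3 path.
#' @return Named list (by `Parent` attribute) of `data.frame`s with
#'   columns `start`, `end`, `strand`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) input_error("GFF3 file not found: %s", path)
  g <- rtracklayer::readGFF(path)
  g <- g[as.character(g$type) == "CDS", , drop = FALSE]
  if (nrow(g) == 0L) return(list())
  parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  df <- data.frame(start = as.integer(g$start), end = as.integer(g$end),
                   strand = as.character(g$strand), parent = parent,
                   stringsAsFactors = FALSE)
  split(df[c("start", "end", "strand")], df$parent)
}
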