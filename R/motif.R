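# PTS2 nonapeptide grammars. Positions are 1..9; a constrained position
# holds a set of admissible residues, every other position is free.
# Ambiguity codes (X/B/Z/U, ...) satisfy free positions only: a
# constrained position demands evidence of a specific residue.

MOTIF_PRESETS <- list(
  stringent = list(`1` = c("R", "K"),
                   `2` = c("L", "V", "I"),
                   `8` = c("H", "Q"),
                   `9` = c("L", "A", "F")),
  relaxed   = list(`1` = c("R", "K"),
                   `2` = c("L", "V", "I", "M"),
                   `8` = c("H", "Q"),
                   `9` = c("L", "A", "F", "M", "V"))
)

#' Compile a PTS2 nonapeptide motif
#'
#' Builds the positional residue-class grammar used by [scan_pts2()].
#' The `"stringent"` preset is \[RK\]-\[LVI\]-x5-\[HQ\]-\[LAF\]; the
#' `"relaxed"` preset additionally admits Met at position 2 and Met/Val
#' at position 9, variants observed in stramenopile orthologs. A custom
#' grammar is given as a table mapping positions (1..9) to residue sets;
#' unmapped positions are unconstrained.
#'
#' @param mode `"stringent"`, `"relaxed"`, `"custom"`, or directly a
#'   position-class table (a named list, names in 1..9, each element a
#'   character vector of residues or a single string such as `"RK"`).
#' @param position_classes Position-class table when `mode = "custom"`.
#' @param enforce_pos5_hydrophobic If `TRUE`, position 5 is treated as a
#'   constrained class equal to `hydrophobic_set` (intersected with any
#'   explicit position-5 class).
#' @param hydrophobic_set Residues counted as hydrophobic at position 5.
#' @return An object of class `motif_spec`.
#' @examples
#' compile_motif("stringent")
#' compile_motif(list(`1` = "R"))  # any 9-mer starting with R
#' @export
compile_motif <- function(mode = "stringent", position_classes = NULL,
                          enforce_pos5_hydrophobic = FALSE,
                          hydrophobic_set = DEFAULT_HYDROPHOBIC) {
  if (is.list(mode)) {
    position_classes <- mode
    mode <- "custom"
  }
  if (!is.character(mode) || length(mode) != 1L) {
    input_error("motif mode must be a single string or a position-class table")
  }
  if (mode == "custom") {
    if (is.null(position_classes)) {
      input_error("custom motif needs a position-class table")
    }
    classes <- lapply(position_classes, function(cl) {
      cl <- toupper(as.character(cl))
      if (length(cl) == 1L && nchar(cl) > 1L) cl <- strsplit(cl, "")[[1]]
      cl
    })
    pos <- suppressWarnings(as.integer(names(classes)))
    if (any(is.na(pos)) || any(pos < 1L | pos > 9L)) {
      input_error("motif positions must be integers in 1..9")
    }
    if (anyDuplicated(pos)) input_error("duplicate motif position")
    if (any(vapply(classes, length, 1L) == 0L) ||
        any(!vapply(classes, function(cl) all(grepl("^[A-Z]$", cl)), TRUE))) {
      input_error("each motif residue class must be a non-empty set of residue letters")
    }
    names(classes) <- as.character(pos)
    classes <- classes[order(pos)]
  } else if (mode %in% names(MOTIF_PRESETS)) {
    classes <- MOTIF_PRESETS[[mode]]
  } else {
    input_error("unknown motif preset '%s' (known: %s)", mode,
                paste(names(MOTIF_PRESETS), collapse = ", "))
  }
  structure(list(name = mode,
                 position_classes = classes,
                 enforce_pos5_hydrophobic = isTRUE(enforce_pos5_hydrophobic),
                 hydrophobic_set = toupper(hydrophobic_set)),
            class = "motif_spec")
}

# Position classes with the optional position-5 hydrophobicity constraint
# folded in. Returns a named list, names "1".."9" (subset).
effective_classes <- function(motif) {
  classes <- motif$position_classes
  if (isTRUE(motif$enforce_pos5_hydrophobic)) {
    cl5 <- if ("5" %in% names(classes)) {
      intersect(classes[["5"]], motif$hydrophobic_set)
    } else {
      motif$hydrophobic_set
    }
    if (length(cl5) == 0L) {
      input_error("position-5 class and hydrophobic set are disjoint")
    }
    classes[["5"]] <- cl5
    classes <- classes[order(as.integer(names(classes)))]
  }
  classes
}

# Regex over the 9 positions; free positions match any single letter.
motif_regex <- function(motif) {
  classes <- effective_classes(motif)
  paste(vapply(as.character(1:9), function(p) {
    if (p %in% names(classes)) {
      paste0("[", paste(classes[[p]], collapse = ""), "]")
    } else "[A-Z]"
  }, character(1)), collapse = "")
}

#' @export
print.motif_spec <- function(x, ...) {
  cls <- vapply(x$position_classes, paste, character(1), collapse = "")
  cat(sprintf("PTS2 motif '%s': %s\n", x$name,
              paste(sprintf("pos%s=[%s]", names(cls), cls), collapse = " ")))
  if (x$enforce_pos5_hydrophobic) {
    cat(sprintf("  position 5 restricted to hydrophobic set [%s]\n",
                paste(x$hydrophobic_set, collapse = "")))
  }
  invisible(x)
}

empty_match_frame <- function() {
  data.frame(protein_id = character(0), start = integer(0), end = integer(0),
             nonapeptide = character(0), pattern = character(0),
             pos5_residue = character(0), pos5_hydrophobic = logical(0),
             stringsAsFactors = FALSE)
}

#' Scan proteins for PTS2 nonapeptide matches
#'
#' Slides a 9-residue window along each sequence (step 1, overlaps
#' allowed) and reports every window whose constrained positions all lie
#' in their residue classes. Coordinates are 1-based inclusive with the
#' initiator Met as residue 1, so a match satisfies `end - start == 8`.
#' No N-terminal window filter is applied here; see
#' [n_terminal_filter()].
#'
#' @param proteins Protein set (anything [as_protein_set()] accepts).
#' @param motif A `motif_spec` from [compile_motif()].
#' @return `data.frame` with one row per match: `protein_id`, `start`,
#'   `end`, `nonapeptide`, `pattern` (reduced, e.g. `"RLx5HL"`),
#'   `pos5_residue`, `pos5_hydrophobic`; sorted by protein input order
#'   then ascending `start`. Sequences shorter than 9 yield no rows.
#' @export
scan_pts2 <- function(proteins, motif = compile_motif("stringent")) {
  stopifnot(inherits(motif, "motif_spec"))
  proteins <- as_protein_set(proteins)
  re <- paste0("(?=", motif_regex(motif), ")")
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    m <- gregexpr(re, s, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts <- starts[starts > 0L]
    if (length(starts) == 0L) return(NULL)
    nona <- substring(s, starts, starts + 8L)
    pos5 <- substr(nona, 5L, 5L)
    data.frame(protein_id = proteins$id[i],
               start = starts, end = starts + 8L,
               nonapeptide = nona,
               pattern = reduced_pattern(nona),
               pos5_residue = pos5,
               pos5_hydrophobic = pos5 %in% motif$hydrophobic_set,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty_match_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reduced nonapeptide pattern
#'
#' Collapses a nonapeptide to its four informative residues:
#' positions 1, 2 then `"x5"` then positions 8, 9 (e.g. `"RIAAAAAHL"`
#' becomes `"RIx5HL"`), the compact notation used in candidate reports.
#'
#' @param nonapeptide Character vector of 9-residue strings.
#' @return Character vector of reduced patterns.
#' @export
reduced_pattern <- function(nonapeptide) {
  if (any(nchar(nonapeptide) != 9L)) {
    input_error("reduced_pattern expects 9-residue strings")
  }
  paste0(substr(nonapeptide, 1L, 2L), "x5", substr(nonapeptide, 8L, 9L))
}

#' Default extended PTS1 tripeptide list
#'
#' Non-canonical C-terminal tripeptides treated as predicted PTS1 in
#' addition to the canonical consensus; replace via the `extended_pts1`
#' configuration entry.
#' @return Character vector of tripeptides.
#' @export
default_extended_pts1 <- function() c("AHL", "SHL", "SLL", "SSL", "SAL")

#' Classify the C-terminal PTS1 tripeptide
#'
#' Examines exactly the C-terminal three residues of each protein (after
#' trailing-`*` stripping). A tripeptide matching the plant consensus
#' \[SA\]-\[KR\]-\[LMI\] position-wise is `canonical` (12 tripeptides);
#' otherwise membership in the extended list makes it
#' `listed_noncanonical`; anything else (including sequences shorter
#' than 3, whose tripeptide is `NA`) is `none`.
#'
#' @param proteins Protein set, or a character vector of sequences.
#' @param extended_list Extended tripeptide set
#'   (default [default_extended_pts1()]).
#' @return `data.frame` with columns `protein_id`, `tripeptide`,
#'   `category`.
#' @export
classify_pts1 <- function(proteins, extended_list = default_extended_pts1()) {
  proteins <- as_protein_set(proteins)
  n <- nchar(proteins$sequence)
  tri <- ifelse(n >= 3L, substr(proteins$sequence, n - 2L, n), NA_character_)
  canonical <- !is.na(tri) & grepl("^[SA][KR][LMI]$", tri)
  listed <- !is.na(tri) & !canonical & tri %in% toupper(extended_list)
  data.frame(protein_id = proteins$id,
             tripeptide = tri,
             category = ifelse(canonical, "canonical",
                               ifelse(listed, "listed_noncanonical", "none")),
             stringsAsFactors = FALSE)
}

#' Position-5 hydrophobicity of matches
#'
#' Reports whether the middle (5th) residue of each match's nonapeptide
#' belongs to the motif's hydrophobic set. This never filters matches;
#' to make hydrophobicity a scan requirement, compile the motif with
#' `enforce_pos5_hydrophobic = TRUE`.
#'
#' @param matches Match `data.frame` from [scan_pts2()].
#' @param motif The `motif_spec` used for scanning.
#' @return Logical vector, one element per match.
#' @export
hydrophobic_pos5 <- function(matches, motif = compile_motif("stringent")) {
  substr(matches$nonapeptide, 5L, 5L) %in% motif$hydrophobic_set
}
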