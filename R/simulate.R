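PLANT_KINDS <- c("pts2_in_window", "pts2_out_of_window", "broken_pts2",
                 "pts1_tail", "pts2_plus_cys")

#' Describe one planted signal or decoy
#'
#' @param kind One of `"pts2_in_window"`, `"pts2_out_of_window"`,
#'   `"broken_pts2"`, `"pts1_tail"`, `"pts2_plus_cys"`.
#' @param protein 1-based index of the target protein.
#' @param start Start position for PTS2 kinds (1-based; required there,
#'   ignored for `pts1_tail` which always occupies the C-terminus).
#' @param peptide Planted string: a nonapeptide for PTS2 kinds (default
#'   `"RLDSLGQHL"`, a stringent motif; `"RLDSLGQRG"` for `broken_pts2`,
#'   whose positions 8 and 9 violate every preset) or a tripeptide for
#'   `pts1_tail` (default `"SKL"`).
#' @param cys_offset For `pts2_plus_cys`: offset of the planted Cys
#'   downstream of the nonapeptide end (default 3).
#' @return A `sim_plant` list.
#' @export
plant <- function(kind, protein, start = NULL, peptide = NULL,
                  cys_offset = 3L) {
  kind <- match.arg(kind, PLANT_KINDS)
  if (is.null(peptide)) {
    peptide <- switch(kind,
                      pts1_tail = "SKL",
                      broken_pts2 = "RLDSLGQRG",
                      "RLDSLGQHL")
  }
  peptide <- toupper(peptide)
  want <- if (kind == "pts1_tail") 3L else 9L
  if (nchar(peptide) != want) {
    input_error("plant kind '%s' needs a %d-residue peptide", kind, want)
  }
  if (kind != "pts1_tail" && is.null(start)) {
    input_error("plant kind '%s' needs a start position", kind)
  }
  structure(list(kind = kind, protein = as.integer(protein),
                 start = if (is.null(start)) NA_integer_ else as.integer(start),
                 peptide = peptide, cys_offset = as.integer(cys_offset)),
            class = "sim_plant")
}

#' Configuration of a synthetic proteome
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer min/max of the uniform length
#'   distribution (default 100–600 aa).
#' @param composition Named probability vector over the 20 standard
#'   residues (default uniform, 0.05 each); must sum to 1 within 1e-9.
#' @param plants List of [plant()] specifications.
#' @param seed Integer seed; fully determines the output.
#' @param motif_mode Motif preset the truth oracle scans with.
#' @param window N-terminal window used to label in-window truth.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 100L, length_range = c(100L, 600L),
                       composition = NULL, plants = list(), seed = 1L,
                       motif_mode = "stringent", window = 40L) {
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (is.null(names(composition)) ||
      !setequal(names(composition), AA_STANDARD)) {
    input_error("composition must be named over the 20 standard residues")
  }
  composition <- composition[AA_STANDARD]
  if (abs(sum(composition) - 1) > 1e-9 || any(composition < 0)) {
    input_error("composition must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 9L) {
    input_error("length_range must be c(min, max) with 9 <= min <= max")
  }
  if (!all(vapply(plants, inherits, TRUE, "sim_plant"))) {
    input_error("plants must be a list of plant() specifications")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = length_range,
                 composition = composition,
                 plants = plants, seed = as.integer(seed),
                 motif_mode = motif_mode, window = as.integer(window)),
            class = "sim_config")
}

# Run expr under a private RNG stream, leaving the caller's stream alone.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Per-protein substream seed: plants are applied after generation, so the
# background of protein i never depends on other proteins or plant order.
protein_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 7919) %% 2147483587
}

plant_span <- function(p, len) {
  if (p$kind == "pts1_tail") {
    c(len - 2L, len)
  } else if (p$kind == "pts2_plus_cys") {
    c(p$start, p$start + 8L + p$cys_offset)
  } else {
    c(p$start, p$start + 8L)
  }
}

#' Exhaustive window scan (ground-truth oracle)
#'
#' Checks every 9-residue window by direct per-position set membership,
#' a code path independent of the regex scanner in [scan_pts2()]. Used
#' to derive the truth ledger of simulated proteomes.
#'
#' @param proteins Protein set.
#' @param motif A `motif_spec`.
#' @return Match `data.frame` in the same shape as [scan_pts2()].
#' @export
scan_pts2_exhaustive <- function(proteins, motif = compile_motif("stringent")) {
  proteins <- as_protein_set(proteins)
  classes <- effective_classes(motif)
  pos <- as.integer(names(classes))
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    L <- nchar(s)
    if (L < 9L) return(NULL)
    chars <- strsplit(s, "")[[1]]
    starts <- seq_len(L - 8L)
    ok <- rep(TRUE, length(starts))
    for (k in seq_along(pos)) {
      ok <- ok & chars[starts + pos[k] - 1L] %in% classes[[k]]
    }
    starts <- starts[ok]
    if (length(starts) == 0L) return(NULL)
    nona <- substring(s, starts, starts + 8L)
    pos5 <- substr(nona, 5L, 5L)
    data.frame(protein_id = proteins$id[i], start = starts,
               end = starts + 8L, nonapeptide = nona,
               pattern = reduced_pattern(nona), pos5_residue = pos5,
               pos5_hydrophobic = pos5 %in% motif$hydrophobic_set,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty_match_frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic proteome with planted signals
#'
#' Background residues are drawn i.i.d. from the configured composition;
#' planted segments overwrite the background at their stated coordinates
#' (lengths are unchanged). The truth ledger records the plants and, by
#' post-hoc exhaustive scanning ([scan_pts2_exhaustive()]), every motif
#' occurrence — so accidental background motifs are truthfully labeled.
#' Identical seeds give byte-identical output.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_proteome`: list with `proteins` (protein
#'   set), `truth` (list: `plants` ledger `data.frame`, `oracle_matches`
#'   with `in_window` flag, `candidates` = ids with an in-window oracle
#'   match) and `config`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  lr <- config$length_range
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- with_local_seed(protein_seed(config$seed, i), {
      len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
      paste(sample(AA_STANDARD, len, replace = TRUE,
                   prob = config$composition), collapse = "")
    })
  }
  ids <- sprintf("SIM%05d", seq_len(n))

  ledger <- list()
  by_protein <- split(config$plants,
                      vapply(config$plants, function(p) p$protein, 1L))
  for (pi in names(by_protein)) {
    i <- as.integer(pi)
    if (i < 1L || i > n) input_error("plant targets protein %d of %d", i, n)
    len <- nchar(seqs[i])
    spans <- lapply(by_protein[[pi]], plant_span, len = len)
    for (k in seq_along(spans)) {
      if (spans[[k]][1] < 1L || spans[[k]][2] > len) {
        input_error("plant in protein %d overlaps the sequence end (span %d-%d, length %d)",
                    i, spans[[k]][1], spans[[k]][2], len)
      }
    }
    if (length(spans) > 1L) {
      for (a in seq_len(length(spans) - 1L)) for (b in (a + 1L):length(spans)) {
        if (spans[[a]][1] <= spans[[b]][2] && spans[[b]][1] <= spans[[a]][2]) {
          input_error("two plants overlap in protein %d", i)
        }
      }
    }
    for (p in by_protein[[pi]]) {
      if (p$kind == "pts1_tail") {
        substr(seqs[i], len - 2L, len) <- p$peptide
        st <- len - 2L; en <- len
      } else {
        substr(seqs[i], p$start, p$start + 8L) <- p$peptide
        st <- p$start; en <- p$start + 8L
        if (p$kind == "pts2_plus_cys") {
          substr(seqs[i], en + p$cys_offset, en + p$cys_offset) <- "C"
        }
      }
      ledger[[length(ledger) + 1L]] <-
        data.frame(protein_id = ids[i], kind = p$kind, start = st, end = en,
                   planted_string = p$peptide, stringsAsFactors = FALSE)
    }
  }
  plants_df <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(protein_id = character(0), kind = character(0),
               start = integer(0), end = integer(0),
               planted_string = character(0), stringsAsFactors = FALSE)
  rownames(plants_df) <- NULL

  proteins <- data.frame(id = ids, description = paste("synthetic protein", ids),
                         sequence = seqs, stringsAsFactors = FALSE)
  motif <- compile_motif(config$motif_mode)
  oracle <- scan_pts2_exhaustive(proteins, motif)
  oracle$in_window <- oracle$start <= config$window
  structure(list(proteins = proteins,
                 truth = list(plants = plants_df,
                              oracle_matches = oracle,
                              candidates = unique(oracle$protein_id[oracle$in_window])),
                 config = config),
            class = "sim_proteome")
}

#' Write a simulated proteome to disk
#'
#' Writes `proteome.faa` (FASTA), `truth.tsv` (plant ledger) and
#' `summary.json` (counts) into `dir`.
#'
#' @param sim A `sim_proteome` from [generate_proteome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_proteome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteins(sim$proteins, file.path(dir, "proteome.faa"))
  utils::write.table(sim$truth$plants, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_proteins = nrow(sim$proteins),
                            n_plants = nrow(sim$truth$plants),
                            n_oracle_matches = nrow(sim$truth$oracle_matches),
                            n_truth_candidates = length(sim$truth$candidates),
                            seed = sim$config$seed),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a plant table from TSV
#'
#' Expected columns: `kind`, `protein`, `start`, `peptide`,
#' `cys_offset` (the last three may be empty where not applicable).
#'
#' @param path TSV path.
#' @return List of [plant()] specifications.
#' @export
read_plant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  lapply(seq_len(nrow(df)), function(i) {
    plant(kind = df$kind[i], protein = df$protein[i],
          start = if (is.na(df$start[i])) NULL else df$start[i],
          peptide = if (is.na(df$peptide[i])) NULL else df$peptide[i],
          cys_offset = if ("cys_offset" %in% names(df) &&
                           !is.na(df$cys_offset[i])) df$cys_offset[i] else 3L)
  })
}

#' Analytic per-window motif match probability
#'
#' Under i.i.d. residues with the given composition, the probability
#' that one 9-residue window matches the motif is the product, over
#' constrained positions, of the composition mass of that position's
#' class (position 5 included when hydrophobicity is enforced). The
#' per-protein probability for a window of `W` start positions,
#' `1 - (1 - p)^W`, ignores the dependence between overlapping windows
#' and is an approximation.
#'
#' @param composition Named probability vector over residues (default
#'   uniform over the 20 standard residues).
#' @param motif A `motif_spec`.
#' @param window Number of eligible window start positions `W`.
#' @return List with `per_window`, `per_protein`, `window`.
#' @export
analytic_match_rate <- function(composition = NULL,
                                motif = compile_motif("stringent"),
                                window = 40L) {
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  classes <- effective_classes(motif)
  masses <- vapply(classes, function(cl) {
    sum(composition[intersect(cl, names(composition))])
  }, numeric(1))
  p <- prod(masses)
  list(per_window = p, per_protein = 1 - (1 - p)^window, window = window)
}

#' Empirical per-window motif match rate
#'
#' Draws `n_windows` independent 9-residue windows (fresh residues each,
#' no overlap dependence) from the composition and reports the fraction
#' matching the motif together with its binomial standard error.
#'
#' @param n_windows Number of windows to draw.
#' @param composition Named probability vector (default uniform).
#' @param motif A `motif_spec`.
#' @param seed Integer seed.
#' @return List with `fraction`, `se`, `n_windows`.
#' @export
empirical_match_rate <- function(n_windows, composition = NULL,
                                 motif = compile_motif("stringent"),
                                 seed = 1L) {
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  composition <- composition[AA_STANDARD]
  composition[is.na(composition)] <- 0
  classes <- effective_classes(motif)
  pos <- as.integer(names(classes))
  frac <- with_local_seed(seed, {
    idx <- matrix(sample.int(20L, n_windows * 9L, replace = TRUE,
                             prob = composition),
                  nrow = n_windows, ncol = 9L)
    ok <- rep(TRUE, n_windows)
    for (k in seq_along(pos)) {
      cls_idx <- match(classes[[k]], AA_STANDARD)
      cls_idx <- cls_idx[!is.na(cls_idx)]
      ok <- ok & idx[, pos[k]] %in% cls_idx
    }
    mean(ok)
  })
  list(fraction = frac, se = sqrt(frac * (1 - frac) / n_windows),
       n_windows = n_windows)
}
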