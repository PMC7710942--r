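#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

# 20 standard amino acids, alphabetical one-letter codes
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DEFAULT_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W")

input_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("pts2screen_input_error", "error")))
}

# Uppercase, strip one trailing stop symbol, reject internal stops and
# non-letter characters. `id` only decorates error messages.
normalize_sequence <- function(sequence, id = "<sequence>") {
  s <- toupper(sequence)
  s <- sub("\\*$", "", s)
  if (grepl("*", s, fixed = TRUE)) {
    input_error("protein '%s': internal stop symbol '*' (truncated gene model?)", id)
  }
  if (!nzchar(s)) {
    input_error("protein '%s': empty sequence after normalization", id)
  }
  if (grepl("[^A-Z]", s)) {
    input_error("protein '%s': sequence contains non-letter characters", id)
  }
  s
}

#' Coerce to a protein set
#'
#' A protein set is a plain `data.frame` with columns `id`, `description`
#' and `sequence` (uppercase, single trailing `*` stripped). Accepts a
#' FASTA path, a named or unnamed character vector of sequences, an
#' `AAStringSet`, or a data frame that already has `id` and `sequence`
#' columns. Duplicate identifiers are an error.
#'
#' @param x FASTA path, character vector, `AAStringSet`, or data frame.
#' @return `data.frame` with columns `id`, `description`, `sequence`.
#' @export
as_protein_set <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("id", "sequence") %in% names(x))) {
      input_error("protein data frame needs 'id' and 'sequence' columns")
    }
    df <- data.frame(id = as.character(x$id),
                     description = if ("description" %in% names(x))
                       as.character(x$description) else "",
                     sequence = as.character(x$sequence),
                     stringsAsFactors = FALSE)
  } else if (inherits(x, "XStringSet")) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(x))
    df <- data.frame(id = sub("\\s.*$", "", nm),
                     description = ifelse(grepl("\\s", nm),
                                          sub("^\\S+\\s+", "", nm), ""),
                     sequence = as.character(x),
                     stringsAsFactors = FALSE)
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             !grepl("^[A-Za-z*]+$", x)) {
    # anything that cannot be a raw sequence is taken as a FASTA path
    return(read_proteins(x))
  } else if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- paste0("seq", seq_along(x))
    df <- data.frame(id = nm, description = "", sequence = unname(x),
                     stringsAsFactors = FALSE)
  } else {
    input_error("cannot interpret object of class '%s' as proteins", class(x)[1])
  }
  df$sequence <- vapply(seq_len(nrow(df)),
                        function(i) normalize_sequence(df$sequence[i], df$id[i]),
                        character(1))
  if (anyDuplicated(df$id)) {
    input_error("duplicate protein identifiers: %s",
                paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read a protein FASTA file
#'
#' The identifier is the first whitespace-delimited token of the header;
#' the rest of the header becomes the description. Multi-line (wrapped)
#' records are supported. Sequences are normalized (uppercased, one
#' trailing `*` stripped); malformed records raise an error naming the
#' offending record.
#'
#' @param path Path to a FASTA file. An empty file yields a 0-row set.
#' @return Protein set `data.frame` (`id`, `description`, `sequence`).
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) input_error("FASTA file not found: %s", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) input_error("malformed FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  as_protein_set(aa)
}

#' Write a protein set as FASTA
#'
#' @param proteins Protein set (anything [as_protein_set()] accepts).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path, width = 60L) {
  proteins <- as_protein_set(proteins)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$id, proteins$description),
                      proteins$id)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}
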