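# Independent brute-force window oracle, deliberately re-implemented here
# (plain loops, no shared code with the package's scanners).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# classes: named list, names "1".."9" (subset), values residue vectors
oracle_scan <- function(sequence, classes) {
  starts <- integer(0)
  L <- nchar(sequence)
  if (L >= 9) {
    for (i in seq_len(L - 8)) {
      window <- substr(sequence, i, i + 8)
      ok <- TRUE
      for (p in names(classes)) {
        if (!substr(window, as.integer(p), as.integer(p)) %in% classes[[p]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

STRINGENT_CLASSES <- list(`1` = c("R", "K"), `2` = c("L", "V", "I"),
                          `8` = c("H", "Q"), `9` = c("L", "A", "F"))
RELAXED_CLASSES <- list(`1` = c("R", "K"), `2` = c("L", "V", "I", "M"),
                        `8` = c("H", "Q"), `9` = c("L", "A", "F", "M", "V"))

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

extdata <- function(...) system.file("extdata", ..., package = "pts2screen")
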