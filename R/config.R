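# Config files are YAML with up to three sections:
#   screen:   window, mode, cys_window, enforce_pos5, extended_pts1, ascii
#   homology: evalue, min_identity, min_coverage, coverage_mode, known_subjects
#   sim:      n_proteins, length_min, length_max, seed, mode, window
# Unknown sections or keys are rejected outright so typos cannot
# silently fall back to defaults.

CONFIG_KEYS <- list(
  screen = c("window", "mode", "cys_window", "enforce_pos5",
             "extended_pts1", "ascii", "hydrophobic_set"),
  homology = c("evalue", "min_identity", "min_coverage", "coverage_mode",
               "known_subjects"),
  sim = c("n_proteins", "length_min", "length_max", "seed", "mode", "window")
)

#' Read and validate a configuration file
#'
#' @param path YAML config path; `NULL` yields an empty config.
#' @return Nested list of validated sections.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) input_error("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) return(list())
  bad <- setdiff(names(cfg), names(CONFIG_KEYS))
  if (length(bad)) input_error("unknown config section(s): %s",
                               paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    badk <- setdiff(names(cfg[[sec]]), CONFIG_KEYS[[sec]])
    if (length(badk)) input_error("unknown key(s) in [%s]: %s", sec,
                                  paste(badk, collapse = ", "))
  }
  cfg
}

# File value unless the caller supplied the flag explicitly.
pick <- function(flag_value, file_value, supplied) {
  if (supplied || is.null(file_value)) flag_value else file_value
}

screen_config_from <- function(cfg, window = 40L, mode = "stringent",
                               cys_window = 10L, enforce_pos5 = FALSE,
                               ascii = FALSE, supplied = character(0)) {
  s <- cfg$screen
  screen_config(
    window = pick(window, s$window, "window" %in% supplied),
    motif_mode = pick(mode, s$mode, "mode" %in% supplied),
    cys_window = pick(cys_window, s$cys_window, "cys_window" %in% supplied),
    extended_pts1 = if (is.null(s$extended_pts1)) default_extended_pts1()
                    else s$extended_pts1,
    enforce_pos5 = pick(enforce_pos5, s$enforce_pos5,
                        "enforce_pos5" %in% supplied),
    hydrophobic_set = if (is.null(s$hydrophobic_set)) DEFAULT_HYDROPHOBIC
                      else s$hydrophobic_set,
    ascii = pick(ascii, s$ascii, "ascii" %in% supplied))
}
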