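# Synthetic proteome generation, truth ledger and match-rate calculus.

test_that("generate_proteome plants signals at exact coordinates", {
  sim <- generate_proteome(sim_config(
    n_proteins = 1, length_range = c(60, 60), seed = 3,
    plants = list(plant("pts2_in_window", 1, start = 12,
                        peptide = "RLQSTLSHL"))))
  expect_equal(substr(sim$proteins$sequence, 12, 20), "RLQSTLSHL")
  tr <- sim$truth$oracle_matches
  expect_true(any(tr$start == 12 & tr$end == 20 & tr$pattern == "RLx5HL"))

  # broken plant (positions 8,9 violated) leaves no oracle match at its span
  simb <- generate_proteome(sim_config(
    n_proteins = 1, length_range = c(60, 60), seed = 3,
    plants = list(plant("broken_pts2", 1, start = 12, peptide = "RLQSTLSRG"))))
  expect_false(any(simb$truth$oracle_matches$start == 12))

  # pts2_plus_cys also writes the downstream cysteine
  simc <- generate_proteome(sim_config(
    n_proteins = 1, length_range = c(60, 60), seed = 3,
    plants = list(plant("pts2_plus_cys", 1, start = 10, cys_offset = 4))))
  expect_equal(substr(simc$proteins$sequence, 22, 22), "C")
  expect_equal(find_cleavage_cys(simc$proteins$sequence, 18L), 4L)

  # pts1_tail overwrites the C-terminus
  simt <- generate_proteome(sim_config(
    n_proteins = 1, length_range = c(60, 60), seed = 3,
    plants = list(plant("pts1_tail", 1, peptide = "SRL"))))
  expect_equal(classify_pts1(simt$proteins)$category, "canonical")
})

test_that("plant validation rejects out-of-bounds and overlapping plants", {
  expect_error(generate_proteome(sim_config(
    n_proteins = 1, length_range = c(50, 50), seed = 1,
    plants = list(plant("pts2_in_window", 1, start = 48)))),
    "overlaps the sequence end")
  expect_error(generate_proteome(sim_config(
    n_proteins = 1, length_range = c(50, 50), seed = 1,
    plants = list(plant("pts2_in_window", 1, start = 10),
                  plant("pts2_in_window", 1, start = 15)))),
    "overlap")
  expect_error(plant("pts2_in_window", 1), "start")
  expect_error(plant("pts1_tail", 1, peptide = "SKLX"), "3-residue")
  expect_error(sim_config(composition = c(A = 1)), "20 standard")
  bad <- stats::setNames(rep(0.06, 20), pts2screen:::AA_STANDARD)
  expect_error(sim_config(composition = bad), "sum to 1")
})

test_that("the same seed reproduces byte-identical output", {
  cfg <- sim_config(n_proteins = 20, length_range = c(80, 200), seed = 7,
                    plants = list(plant("pts2_in_window", 3, start = 9)))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(generate_proteome(cfg), d1)
  write_simulation(generate_proteome(cfg), d2)
  for (f in c("proteome.faa", "truth.tsv", "summary.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # a different seed changes the background
  cfg2 <- sim_config(n_proteins = 20, length_range = c(80, 200), seed = 8,
                     plants = list(plant("pts2_in_window", 3, start = 9)))
  expect_false(identical(generate_proteome(cfg2)$proteins$sequence,
                         generate_proteome(cfg)$proteins$sequence))
})

test_that("plants are order-independent across proteins", {
  p1 <- list(plant("pts2_in_window", 2, start = 10),
             plant("pts2_out_of_window", 5, start = 60))
  p2 <- rev(p1)
  s1 <- generate_proteome(sim_config(n_proteins = 6, length_range = c(80, 120),
                                     seed = 9, plants = p1))
  s2 <- generate_proteome(sim_config(n_proteins = 6, length_range = c(80, 120),
                                     seed = 9, plants = p2))
  expect_identical(s1$proteins$sequence, s2$proteins$sequence)
})

test_that("every planted in-window signal appears in the oracle truth", {
  set.seed(2)
  plants <- lapply(1:10, function(i) plant("pts2_in_window", i,
                                           start = sample(1:30, 1)))
  sim <- generate_proteome(sim_config(n_proteins = 10,
                                      length_range = c(100, 200),
                                      seed = 21, plants = plants))
  tr <- sim$truth$oracle_matches
  pl <- sim$truth$plants
  for (i in seq_len(nrow(pl))) {
    expect_true(any(tr$protein_id == pl$protein_id[i] &
                      tr$start == pl$start[i] & tr$end == pl$end[i]))
  }
  expect_true(all(pl$protein_id %in% sim$truth$candidates))
})

test_that("analytic match rates reproduce the class-size products", {
  expect_equal(analytic_match_rate()$per_window, (2 * 3 * 2 * 3) / 20^4)
  expect_equal(analytic_match_rate(motif = compile_motif("relaxed"))$per_window,
               (2 * 4 * 2 * 5) / 20^4)
  # degenerate composition with zero mass on R and K
  comp <- stats::setNames(rep(1 / 18, 20), pts2screen:::AA_STANDARD)
  comp[c("R", "K")] <- 0
  expect_equal(analytic_match_rate(comp)$per_window, 0)
  # per-protein approximation
  a <- analytic_match_rate(window = 40)
  expect_equal(a$per_protein, 1 - (1 - a$per_window)^40)
  # enforcing position 5 multiplies in the hydrophobic class mass
  a5 <- analytic_match_rate(motif = compile_motif("stringent",
                                                  enforce_pos5_hydrophobic = TRUE))
  expect_equal(a5$per_window, analytic_match_rate()$per_window * 7 / 20)
})

test_that("empirical match rates behave at the degenerate corners", {
  # motif constraining position 1 to all 20 residues matches everything
  all20 <- compile_motif(list(`1` = paste(AA20, collapse = "")))
  expect_equal(empirical_match_rate(1e4, motif = all20, seed = 4)$fraction, 1)
  # composition without H and Q can never satisfy position 8
  comp <- stats::setNames(rep(1 / 18, 20), pts2screen:::AA_STANDARD)
  comp[c("H", "Q")] <- 0
  expect_equal(empirical_match_rate(1e4, comp, seed = 4)$fraction, 0)
  # moderate n: within 4 SE of the analytic value
  e <- empirical_match_rate(2e5, seed = 12)
  p <- analytic_match_rate()$per_window
  expect_lt(abs(e$fraction - p), 4 * sqrt(p * (1 - p) / 2e5))
})
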