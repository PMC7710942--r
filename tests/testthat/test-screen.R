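# Window filtering, cleavage-site Cys, proteome screen and report I/O.

make_screen_fixture <- function() {
  # 5 in-window signals, 2 signals planted after position 40, 1 broken motif
  plants <- c(lapply(1:5, function(i) plant("pts2_in_window", i, start = 5 + i)),
              lapply(6:7, function(i) plant("pts2_out_of_window", i, start = 60)),
              list(plant("broken_pts2", 8, start = 10)))
  generate_proteome(sim_config(n_proteins = 8, length_range = c(100, 150),
                               plants = plants, seed = 20))
}

test_that("n_terminal_filter keeps matches by start position", {
  m <- data.frame(protein_id = "p", start = c(35L, 40L, 41L),
                  end = c(43L, 48L, 49L))
  kept <- n_terminal_filter(m, 40L)
  expect_equal(kept$start, c(35L, 40L))   # 35-43 and the boundary case stay
})

test_that("find_cleavage_cys returns the smallest in-window offset", {
  s <- paste0(strrep("A", 22), "C", strrep("A", 10))
  expect_equal(find_cleavage_cys(s, end = 20L), 3L)
  expect_true(is.na(find_cleavage_cys(strrep("A", 40), end = 20L)))
  # search truncated at the sequence end, no error
  expect_true(is.na(find_cleavage_cys("AAAA", end = 3L)))
  # first of several Cys
  s2 <- paste0(strrep("A", 21), "CC")
  expect_equal(find_cleavage_cys(s2, end = 20L), 2L)
})

test_that("scan_proteome separates in-window candidates from decoys", {
  sim <- make_screen_fixture()
  screen <- scan_proteome(sim$proteins)
  truth_planted <- sim$truth$plants
  inw <- truth_planted[truth_planted$kind == "pts2_in_window", ]
  expect_true(all(inw$protein_id %in% screen$candidates$protein_id))
  # candidate set equals the oracle truth (accidental matches included)
  expect_setequal(screen$candidates$protein_id, sim$truth$candidates)
  expect_equal(screen$summary$n_proteins, 8L)
  expect_gte(screen$summary$n_with_motif_anywhere, 7L)
  # summary ordering invariant
  s <- screen$summary
  expect_lte(s$n_candidates_in_window, s$n_with_motif_anywhere)
  expect_lte(s$n_with_motif_anywhere, s$n_proteins)
})

test_that("empty FASTA gives an empty report and all-zero summary", {
  f <- withr::local_tempfile(fileext = ".faa")
  file.create(f)
  screen <- scan_proteome(f)
  expect_equal(nrow(screen$candidates), 0L)
  expect_equal(unlist(screen$summary),
               c(n_proteins = 0L, n_with_motif_anywhere = 0L,
                 n_candidates_in_window = 0L))
})

test_that("raising the window never decreases the candidate count", {
  sim <- generate_proteome(sim_config(n_proteins = 60,
                                      length_range = c(100, 200), seed = 33))
  counts <- vapply(c(9L, 20L, 40L, 80L, 160L), function(w) {
    scan_proteome(sim$proteins, screen_config(window = w))$summary$n_candidates_in_window
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})

test_that("candidate report round-trips through TSV with parseable spans", {
  sim <- make_screen_fixture()
  screen <- scan_proteome(sim$proteins)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_candidates(screen, f)
  back <- read_candidates(f)
  expect_equal(back$protein_id, screen$candidates$protein_id)
  expect_equal(back$start, screen$candidates$start)
  expect_equal(back$end, screen$candidates$end)
  expect_true(all(back$end - back$start == 8L))
  expect_true(all(grepl("–", readLines(f, warn = FALSE)[-1])))
  # ascii mode switches the span separator
  write_candidates(screen, f, ascii = TRUE)
  expect_false(any(grepl("–", readLines(f, warn = FALSE))))
  # zero records still produce a header-only file
  write_candidates(scan_proteome(data.frame(id = "x", sequence = strrep("G", 50))), f)
  expect_equal(length(readLines(f, warn = FALSE)), 1L)
})

test_that("first-exon check is strand-invariant and follows translation order", {
  plus <- data.frame(start = c(101L, 501L), end = c(220L, 900L), strand = "+")
  expect_true(pts2_in_first_exon(plus, 18L))    # 54 <= 120
  expect_false(pts2_in_first_exon(plus, 43L))   # 129 > 120
  # mirrored minus-strand gene: first translated segment is the
  # higher-coordinate feature, same segment lengths
  minus <- data.frame(start = c(1101L, 2001L), end = c(1500L, 2120L), strand = "-")
  expect_true(pts2_in_first_exon(minus, 18L))
  expect_false(pts2_in_first_exon(minus, 43L))
  expect_error(pts2_in_first_exon(plus[0, ], 18L), "no CDS")
  mixed <- data.frame(start = c(1L, 50L), end = c(20L, 80L), strand = c("+", "-"))
  expect_error(pts2_in_first_exon(mixed, 5L), "single strand")
})

test_that("GFF3 CDS features are grouped by transcript", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t101\t900\t.\t+\t.\tID=t1",
               "chr1\tsrc\tCDS\t101\t220\t.\t+\t0\tParent=t1",
               "chr1\tsrc\tCDS\t501\t900\t.\t+\t0\tParent=t1",
               "chr1\tsrc\tmRNA\t1101\t2120\t.\t-\t.\tID=t2",
               "chr1\tsrc\tCDS\t1101\t1500\t.\t-\t0\tParent=t2",
               "chr1\tsrc\tCDS\t2001\t2120\t.\t-\t0\tParent=t2"), gff)
  cds <- read_gff_cds(gff)
  expect_setequal(names(cds), c("t1", "t2"))
  expect_true(pts2_in_first_exon(cds$t1, 18L))
  expect_true(pts2_in_first_exon(cds$t2, 18L))
  expect_false(pts2_in_first_exon(cds$t2, 43L))
})
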