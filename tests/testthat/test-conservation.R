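test_that("entropy conservation scores match hand-computed values", {
  aln <- msa(c(a = "LLA", b = "LLC", c = "LVD", d = "LVE",
               e = "LLF", f = "LVG", g = "LLH", h = "LVI",
               i = "LLK", j = "LVM"))
  prof <- column_conservation(aln)
  expect_equal(prof$score[1], 1)                       # invariant column
  expect_equal(prof$score[2], 1 - log(2) / log(20))    # 5 L + 5 V
  expect_equal(prof$score[3], 1 - log(10) / log(20))   # 10 distinct
  expect_equal(prof$category[1], 9L)
})

test_that("gap handling: gap-only columns are NA, gappy columns flagged", {
  aln <- msa(c("A-A-", "A-C-", "A---", "A---"))
  prof <- column_conservation(aln)
  expect_true(prof$gap_only[2])
  expect_true(is.na(prof$score[2]))
  expect_true(prof$low_confidence[4])   # 100% gaps
  expect_false(prof$low_confidence[3])  # exactly 50% gaps: not flagged
  expect_false(prof$low_confidence[1])
  expect_true(is.na(prof$category[2]))
})

test_that("conservation is invariant to row order and rewards duplication correctly", {
  aln <- make_msa(n_rows = 12L, length = 40L,
                  conserved_columns = c(3L, 7L), seed = 8L)
  prof <- column_conservation(aln)
  perm <- msa(setNames(aln$seqs[c(5:12, 1:4)], aln$ids[c(5:12, 1:4)]))
  expect_equal(column_conservation(perm)$score, prof$score)
  # duplicating every row leaves column frequencies, hence scores, unchanged
  dup <- msa(setNames(rep(aln$seqs, 2), paste0("s", 1:24)))
  expect_equal(column_conservation(dup)$score, prof$score)
  # planted conserved columns score 1
  expect_equal(prof$score[c(3, 7)], c(1, 1))
})

test_that("sum-of-pairs scoring ranks invariant above mixed columns", {
  aln <- make_msa(n_rows = 10L, length = 30L, conserved_columns = 4L,
                  seed = 9L)
  prof <- column_conservation(aln, method = "sop_blosum")
  expect_equal(prof$score[4], max(prof$score, na.rm = TRUE))
  expect_true(all(prof$score >= 0 & prof$score <= 1, na.rm = TRUE))
})

test_that("motif scan agrees with an exhaustive window oracle", {
  set.seed(10)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  # bias toward motif letters so matches are not vanishingly rare
  pool <- c(aa, rep(c("D", "N", "S", "T"), 6))
  for (i in 1:200) {
    s <- paste0(sample(pool, 40, replace = TRUE), collapse = "")
    expect_equal(scan_fj_motif(s)$start, brute_motif_starts(s))
  }
})

test_that("motif scan handles overlaps, edges and bad input", {
  hit <- scan_fj_motif("DANDAAAAAAAT")
  expect_equal(hit$start, 1L)
  expect_equal(hit$phospho_site_position, 12L)
  expect_equal(hit$matched_span, "DANDAAAAAAAT")
  # two overlapping windows: starts 1 and 4 share residues
  s2 <- "DANDANDAAAASAAT"
  expect_equal(scan_fj_motif(s2)$start, brute_motif_starts(s2))
  expect_equal(nrow(scan_fj_motif("DANDAAAAAAA")), 0L)   # 11 residues
  expect_error(scan_fj_motif("DANDAAAAAAAZ"), "invalid")
})

test_that("planted motifs are found at the planted position in every row", {
  aln <- make_msa(n_rows = 6L, length = 50L, motif_plant = 17L, seed = 13L)
  for (s in aln$seqs)
    expect_true(17L %in% scan_fj_motif(s)$start)
})

test_that("interface painting maps alignment columns through the reference row", {
  toy <- make_toy_complex(domains_per_chain = 2L,
                          residues_per_domain = 10L, seed = 14L)
  n_res <- 20L
  ref <- paste0(rep("A", n_res), collapse = "")
  other <- paste0(sample(c("A", "C", "D"), n_res, replace = TRUE),
                  collapse = "")
  aln <- msa(c(ref = ref, o1 = other, o2 = other))
  prof <- column_conservation(aln)
  painting <- paint_interface(prof, toy$structure, chain = "A",
                              buried_resno = c(3L, 4L))
  expect_equal(nrow(painting), n_res)
  expect_equal(painting$is_interface, seq_len(n_res) %in% c(3L, 4L))
  expect_equal(painting$score, prof$score)
  # an offset shifting the map off the structure is an error
  expect_error(paint_interface(prof, toy$structure, chain = "A",
                               offset = 1000L), "offset")
})

test_that("MSA input validation and FASTA round trip", {
  expect_error(msa(c("AC", "A")), "differ in length")
  expect_error(msa("ACDE"), "at least 2")
  expect_error(msa(c("AB", "CD")), "invalid")
  aln <- make_msa(n_rows = 5L, length = 25L, seed = 15L)
  fp <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), fp)
  back <- read_msa(fp)
  expect_equal(back$seqs, aln$seqs)
  expect_equal(back$ids, aln$ids)
})
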