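test_that("FASTA round trip preserves taxa and codons", {
  aln <- codon_alignment(c(sp1 = "ATGAAACCC", sp2 = "ATGAAGCCA"))
  f <- tempfile(fileext = ".fasta")
  write_codon_fasta(aln, f, width = 6)  # force wrapping
  back <- read_codon_fasta(f)
  expect_identical(back$taxa, aln$taxa)
  expect_identical(back$codons, aln$codons)
  # headers are taken up to the first whitespace
  writeLines(c(">sp1 some description", "atgaaa", ">sp2", "ATGAAG"), f)
  expect_identical(read_codon_fasta(f)$taxa, c("sp1", "sp2"))
})

test_that("construction rejects malformed alignments", {
  expect_error(codon_alignment(c(a = "ATGAAA", b = "ATG")), "unequal")
  expect_error(codon_alignment(c(a = "ATGAAAC", b = "ATGAAAC")), "divisible by 3")
  expect_error(codon_alignment(c(a = "ATGAAA", a = "ATGCCC")), "duplicate")
})

test_that("validation reports stops, bad characters and clean inputs", {
  gc <- genetic_code()
  clean <- codon_alignment(c(a = "ATGAAA", b = "ATGCCC"))
  expect_identical(nrow(validate_cds_alignment(clean, gc)), 0L)

  with_stop <- codon_alignment(c(a = "ATGTAA", b = "ATGCCC"))
  rep <- validate_cds_alignment(with_stop, gc)
  expect_identical(rep$type, "stop_codon")
  expect_identical(rep$codon_index, 2L)
  expect_match(rep$message, "terminal")

  internal <- codon_alignment(c(a = "TGACCCAAA", b = "ATGCCCAAA"))
  expect_match(validate_cds_alignment(internal, gc)$message, "internal")

  weird <- codon_alignment(c(a = "ATGXYZ", b = "ATGCCC"))
  expect_identical(validate_cds_alignment(weird, gc)$type, "invalid_character")
})

test_that("terminal stop stripping is explicit and conservative", {
  aln <- codon_alignment(c(a = "ATGAAATAA", b = "ATGCCCTGA"))
  stripped <- strip_terminal_stops(aln)
  expect_identical(ncol(stripped$codons), 2L)
  # not stripped when any sequence ends in a sense codon
  mixed <- codon_alignment(c(a = "ATGAAATAA", b = "ATGCCCAAA"))
  expect_identical(ncol(strip_terminal_stops(mixed)$codons), 3L)
})

test_that("gap codons are removed column-wise with a faithful column map", {
  aln <- codon_alignment(c(a = "ATG---AAA", b = "ATGCCCAAA"))
  res <- remove_gap_codons(aln)
  expect_identical(res$column_map, c(1L, 3L))
  expect_identical(unname(res$alignment$codons["a", ]), c("ATG", "AAA"))
  expect_identical(unname(res$alignment$codons["b", ]), c("ATG", "AAA"))
  # composing the map reproduces the original columns
  expect_identical(res$alignment$codons, aln$codons[, res$column_map])
  # idempotence and identity on gap-free input
  again <- remove_gap_codons(res$alignment)
  expect_identical(again$alignment$codons, res$alignment$codons)
  expect_identical(again$column_map, seq_len(2L))
  # codons containing N are treated as gap codons
  withn <- codon_alignment(c(a = "ATGANAAAA", b = "ATGCCCAAA"))
  expect_identical(remove_gap_codons(withn)$column_map, c(1L, 3L))
  # frame-breaking partial gaps are a hard error
  expect_error(remove_gap_codons(codon_alignment(c(a = "ATGA--AAA", b = "ATGCCCAAA"))),
               "frame-breaking")
})

test_that("F3x4 frequencies match hand-computed products and normalize", {
  # two sequences, 2 codons: position-wise nucleotide counts are easy to
  # track by hand
  aln <- codon_alignment(c(a = "ATGAAA", b = "ATGCCC"))
  fr <- f3x4_frequencies(aln)
  expect_s3_class(fr, "codon_frequencies")
  expect_equal(sum(fr), 1)
  # position 1: A x2, A x1, C... counts: pos1 {A,A,A,C}, pos2 {T,A,T,C},
  # pos3 {G,A,G,C}
  p1 <- c(T = 0, C = .25, A = .75, G = 0)
  p2 <- c(T = .5, C = .25, A = .25, G = 0)
  p3 <- c(T = 0, C = .25, A = .25, G = .5)
  raw <- p1["A"] * p2["T"] * p3["G"]  # ATG before renormalization
  sense <- genetic_code()$sense_codons
  norm <- sum(vapply(sense, function(cd)
    p1[substr(cd, 1, 1)] * p2[substr(cd, 2, 2)] * p3[substr(cd, 3, 3)],
    numeric(1)))
  expect_equal(unname(fr["ATG"]), unname(raw / norm))

  # duplicating all sequences leaves the estimate unchanged
  dup <- codon_alignment(c(a = "ATGAAA", b = "ATGCCC",
                           a2 = "ATGAAA", b2 = "ATGCCC"))
  expect_equal(as.numeric(f3x4_frequencies(dup)), as.numeric(fr))
})

test_that("equal frequencies give 1/61 per sense codon", {
  fr <- codon_frequencies(estimator = "equal")
  expect_equal(as.numeric(fr), rep(1 / 61, 61))
})
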