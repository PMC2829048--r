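test_that("FASTA reading normalizes case, RNA and ids", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 some description", "acgu", ">s2", "TTNN", "ACGT"), tmp)
  fa <- read_fasta(tmp)
  expect_equal(names(fa), c("s1", "s2"))
  expect_equal(as.character(fa[["s1"]]), "ACGT")
  expect_equal(as.character(fa[["s2"]]), "TTNNACGT")
  expect_equal(attr(fa, "descriptions")[1], "some description")
})

test_that("malformed FASTA (sequence before header) is a format error", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">s1", "ACGT"), tmp)
  expect_error(read_fasta(tmp), "line 1")
  tmp2 <- withr::local_tempfile(fileext = ".fa")
  file.create(tmp2)
  fa <- read_fasta(tmp2)
  expect_length(fa, 0)
})

test_that("FASTA write/read round-trip is the identity on 100 records", {
  set.seed(42)
  seqs <- vapply(sample(1:200, 100, replace = TRUE), function(n)
    paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- sprintf("rec%03d", 1:100)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, tmp, width = 37)
  back <- read_fasta(tmp)
  expect_equal(names(back), names(seqs))
  expect_equal(unname(unclass(back)[seq_along(seqs)]), unname(seqs))
})

test_that("revcomp is an involution and handles N", {
  expect_equal(revcomp("ACGTN"), "NACGT")
  set.seed(7)
  for (i in 1:25) {
    s <- random_dna_str(sample(1:80, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("extract_region is 1-based inclusive and strand-aware", {
  fa <- c(s1 = "ACGTAC")
  expect_equal(extract_region(fa, "s1", 2, 4), "CGT")
  # start > end encodes the minus strand
  expect_equal(extract_region(fa, "s1", 4, 2), "ACG")
  expect_equal(extract_region(fa, "s1", 2, 4, strand = "-"), "ACG")
  expect_error(extract_region(fa, "nope", 1, 2), "unknown scaffold")
  expect_error(extract_region(fa, "s1", 1, 9), "out of bounds")
  # length law on random intervals
  set.seed(11)
  big <- c(x = random_dna_str(500))
  for (i in 1:20) {
    ab <- sample(500, 2)
    expect_equal(nchar(extract_region(big, "x", ab[1], ab[2])),
                 abs(ab[2] - ab[1]) + 1)
  }
})

test_that("translation uses table 1, emits * for stops and X for N codons", {
  expect_equal(translate_nt("ATGTAA"), "M*")
  expect_equal(translate_nt("ATGNTAA"), "MX")  # trailing A dropped
  expect_equal(translate_nt(""), "")
  expect_equal(nchar(translate_nt(random_dna_str(300))), 100)
  # frames shift the codon grid
  expect_equal(translate_nt("AATGTAA", 1), "M*")
  # cross-check against Biostrings on clean sequence
  set.seed(3)
  s <- random_dna_str(300)
  ref <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_equal(translate_nt(s), ref)
})

test_that("six_frame returns all six conceptual translations", {
  s <- "ATGGCCTAA"
  fr <- six_frame(s)
  expect_named(fr, c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_equal(fr[["+1"]], "MA*")
  expect_equal(fr[["-1"]], translate_nt(revcomp(s), 0))
})
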