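test_that("Smith-Waterman matches hand-computed and symmetric cases", {
  sch <- scoring_scheme("protein")
  expect_equal(sw_align("AAAA", "AAAA", sch)$score, 16)  # 4 x BLOSUM62 A/A
  set.seed(21)
  for (i in 1:20) {
    a <- random_peptide_str(sample(3:15, 1))
    b <- random_peptide_str(sample(3:15, 1))
    expect_equal(sw_align(a, b, sch)$score, sw_align(b, a, sch)$score)
  }
  expect_error(sw_align("ACGT", "AC1T", scoring_scheme("nucleotide")),
               "alphabet")
})

test_that("alignment scores equal the brute-force quadratic DP oracle", {
  set.seed(77)
  sch <- scoring_scheme("protein")
  for (i in 1:200) {
    a <- random_peptide_str(sample(2:12, 1))
    b <- random_peptide_str(sample(2:12, 1))
    expect_equal(sw_align(a, b, sch)$score, sw_brute_score(a, b, sch))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  sch <- scoring_scheme("protein")
  set.seed(31)
  for (i in 1:25) {
    a <- random_peptide_str(sample(10:60, 1))
    b <- random_peptide_str(sample(10:60, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(sw_align(a, b, sch)$score, max(ref, 0))
  }
})

test_that("local score never decreases when a sequence is extended", {
  set.seed(13)
  sch <- scoring_scheme("protein")
  for (i in 1:20) {
    a <- random_peptide_str(sample(5:20, 1))
    b <- random_peptide_str(sample(5:20, 1))
    s0 <- sw_align(a, b, sch)$score
    s1 <- sw_align(paste0(a, random_peptide_str(5)), b, sch)$score
    expect_gte(s1, s0)
  }
})

test_that("Karlin-Altschul conversions follow the closed forms", {
  sch <- scoring_scheme("protein")
  expect_equal(bit_score(40, sch), (0.267 * 40 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(bit_score(40, sch), 2), 20.02)
  # E is linear in n and strictly decreasing in bits
  expect_equal(e_value(30, 100, 2e5), 2 * e_value(30, 100, 1e5))
  bits <- seq(1, 100, by = 0.5)
  ev <- e_value(bits, 300, 1e6)
  expect_true(all(diff(ev) < 0))
  expect_lt(e_value(1e4, 300, 1e6), 1e-300)
})

test_that("search reports self-hits, frame symmetry and sorted output", {
  set.seed(41)
  db <- stats::setNames(vapply(1:10, function(i) random_peptide_str(80),
                               character(1)), paste0("p", 1:10))
  hits <- search_hits(db["p3"], db, "prot-prot", bits_min = 30)
  expect_equal(hits$subject_id[1], "p3")
  expect_equal(hits$pident[1], 100)
  # translated-query: reverse complement finds the same top hit
  cds <- paste0("ATG", random_dna_str(300), "TAA")
  names(cds) <- "q"
  h1 <- best_hits(search_hits(c(q = cds[[1]]), db, "translated-query",
                              bits_min = 0))
  h2 <- best_hits(search_hits(c(q = revcomp(cds[[1]])), db,
                              "translated-query", bits_min = 0))
  if (nrow(h1) > 0 && nrow(h2) > 0) {
    expect_equal(h1$subject_id, h2$subject_id)
    expect_equal(h1$bit_score, h2$bit_score)
  }
  expect_warning(search_hits(db["p1"], character(0), "prot-prot"), "empty")
})

test_that("search equals an exhaustive all-pairs alignment at threshold", {
  set.seed(55)
  sch <- scoring_scheme("protein")
  qs <- stats::setNames(vapply(1:15, function(i)
    random_peptide_str(sample(20:50, 1)), character(1)), paste0("q", 1:15))
  db <- stats::setNames(vapply(1:15, function(i)
    random_peptide_str(sample(20:50, 1)), character(1)), paste0("s", 1:15))
  db[["s7"]] <- paste0(substr(qs[["q2"]], 1, 30), random_peptide_str(10))
  thr <- 18
  got <- search_hits(qs, db, "prot-prot", bits_min = thr,
                     prefilter = "none")
  want <- list()
  for (q in names(qs)) {
    for (s in names(db)) {
      sc <- sw_align(qs[[q]], db[[s]], sch)$score
      if (sc > 0 && bit_score(sc, sch) >= thr)
        want[[paste(q, s)]] <- sc
    }
  }
  expect_setequal(paste(got$query_id, got$subject_id), names(want))
  expect_equal(got$raw_score[order(got$query_id, got$subject_id)],
               unname(unlist(want[order(names(want))])))
})

test_that("lowering the threshold only adds hits (monotonicity)", {
  set.seed(66)
  qs <- stats::setNames(vapply(1:8, function(i) random_peptide_str(40),
                               character(1)), paste0("q", 1:8))
  db <- stats::setNames(vapply(1:8, function(i) random_peptide_str(40),
                               character(1)), paste0("s", 1:8))
  hi <- search_hits(qs, db, "prot-prot", bits_min = 15, prefilter = "none")
  lo <- search_hits(qs, db, "prot-prot", bits_min = 8, prefilter = "none")
  expect_true(all(paste(hi$query_id, hi$subject_id) %in%
                    paste(lo$query_id, lo$subject_id)))
})

test_that("the external tabular adapter round-trips and validates", {
  set.seed(88)
  qs <- stats::setNames(c(random_peptide_str(60)), "qA")
  db <- stats::setNames(c(paste0(qs[[1]], "WWW"), random_peptide_str(50)),
                        c("sA", "sB"))
  hits <- search_hits(qs, db, "prot-prot", bits_min = 10,
                      prefilter = "none")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, tmp)
  back <- read_hit_table(tmp, db_tag = "external")
  expect_equal(nrow(back), nrow(hits))
  for (col in c("query_id", "subject_id", "q_start", "q_end",
                "s_start", "s_end")) {
    expect_equal(back[[col]], hits[[col]])
  }
  expect_equal(back$bit_score, hits$bit_score, tolerance = 1e-6)
  # comments skipped, column mismatch named by line
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", readLines(tmp)), tmp2)
  expect_equal(nrow(read_hit_table(tmp2)), nrow(hits))
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t90.0", tmp3)
  expect_error(read_hit_table(tmp3), "line 1")
})

test_that("seeded diagonal fast path agrees with full alignment", {
  set.seed(99)
  base <- random_peptide_str(120)
  qs <- stats::setNames(c(base), "q")
  mut <- strsplit(base, "")[[1]]
  idx <- sample(120, 18)
  for (i in idx) mut[i] <- sample(setdiff(LETTERS[c(1,3:9,11:14,16:20,22,23,25)],
                                          mut[i]), 1)
  db <- stats::setNames(c(paste(mut, collapse = "")), "s")
  slow <- search_hits(qs, db, "prot-prot", bits_min = 20,
                      prefilter = "none")
  fast <- search_hits(qs, db, "prot-prot", bits_min = 20,
                      prefilter = "kmer", diag_fast = TRUE)
  expect_equal(fast$raw_score, slow$raw_score)
  expect_equal(fast$q_start, slow$q_start)
  expect_equal(fast$q_end, slow$q_end)
})
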