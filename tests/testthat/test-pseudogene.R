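test_that("an exact reverse-translated locus annotates as intact", {
  set.seed(301)
  prot <- random_peptide_str(250)
  cds <- reverse_translate(prot, 0.3)
  r <- annotate_locus(cds, prot)
  expect_equal(r$n_frameshifts, 0)
  expect_equal(r$n_internal_stops, 0)
  expect_equal(r$truncation_fraction, 1, tolerance = 0.01)
  expect_true(r$intact)
  expect_equal(r$identity_aa, 1)
  # reverse-complemented input is annotated on the other orientation
  r2 <- annotate_locus(revcomp(cds), prot)
  expect_equal(r2$orientation, "-")
  expect_true(r2$intact)
  expect_error(annotate_locus(cds, "SHORT"), "30 aa")
  r3 <- annotate_locus(random_dna_str(600), prot)
  expect_equal(r3$reason, "no_alignment")
})

test_that("constructed frameshifts, stops and truncation are recovered", {
  set.seed(302)
  prot <- random_peptide_str(300)
  cds <- reverse_translate(prot, 0.3)
  # truncate to 180 codons, stop at codon 60, 1-nt deletion at codon 120
  mut <- substr(cds, 1, 540)
  substr(mut, 178, 180) <- "TAA"
  mut <- paste0(substr(mut, 1, 357), substr(mut, 359, 540))
  r <- annotate_locus(mut, prot)
  expect_equal(r$n_internal_stops, 1)
  expect_equal(r$n_frameshifts, 1)
  expect_equal(r$truncation_fraction, 0.6, tolerance = 0.02)
  expect_false(r$intact)
})

test_that("generator lesions are re-derived exactly on fresh datasets", {
  for (s in c(2, 13)) {
    ds <- generate_synthetic_dataset(generator_config(seed = s))
    rl <- recover_truth_lesions(ds)
    expect_equal(rl$ann_fs, rl$true_fs)
    expect_equal(rl$ann_stops, rl$true_stops)
    expect_true(all(abs(rl$ann_trunc - rl$true_trunc) <= 0.02))
  }
})

test_that("intron structure is recovered at canonical boundaries", {
  set.seed(303)
  prot <- random_peptide_str(260)
  cds <- reverse_translate(prot, 0.3)
  ilen <- 180
  intron <- paste0("GT", random_dna_str(ilen - 4, 0.3), "AG")
  cut <- 3 * 130
  locus <- paste0(substr(cds, 1, cut), intron,
                  substr(cds, cut + 1, nchar(cds)))
  st <- infer_intron_structure(locus, prot)
  expect_false(st$single_exon)
  expect_equal(nrow(st$introns), 1)
  expect_true(st$introns$canonical[1])
  expect_equal(st$introns$start[1], cut + 1)
  expect_equal(st$introns$end[1], cut + ilen)
  expect_equal(st$exons$end[1], cut)
  expect_equal(st$exons$start[2], cut + ilen + 1)
  # intronless locus: single exon
  st2 <- infer_intron_structure(cds, prot)
  expect_true(st2$single_exon)
  # non-canonical donor site is flagged, not forced
  locus3 <- locus
  substr(locus3, cut + 1, cut + 2) <- "CC"
  st3 <- infer_intron_structure(locus3, prot)
  expect_false(st3$single_exon)
  expect_false(any(st3$introns$canonical &
                     st3$introns$start == cut + 1))
})

test_that("in-silico PCR computes amplicons and is strand-invariant", {
  set.seed(304)
  fwd <- random_dna_str(20, 0.5)
  rev <- random_dna_str(22, 0.5)
  mid <- random_dna_str(40, 0.3)
  template <- paste0(random_dna_str(100, 0.3), fwd, mid, revcomp(rev),
                     random_dna_str(100, 0.3))
  amp <- insilico_pcr(template, fwd, rev)
  expect_equal(amp$product_length, 20 + 40 + 22)
  # template reverse complement with swapped primers: same product
  amp2 <- insilico_pcr(revcomp(template), rev, fwd)
  expect_equal(amp2$product_length, amp$product_length)
  expect_null(insilico_pcr(random_dna_str(300), fwd, rev))
  expect_error(insilico_pcr(template, "ACGT", rev), "15-35")
  # smallest product reported when the forward primer recurs
  t2 <- paste0(fwd, random_dna_str(200, 0.3), fwd, mid, revcomp(rev))
  expect_equal(insilico_pcr(t2, fwd, rev)$product_length, 20 + 40 + 22)
  # one mismatch tolerated only when allowed
  fwd_mm <- fwd
  substr(fwd_mm, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                    substr(fwd, 10, 10))[1]
  expect_null(insilico_pcr(template, fwd_mm, rev))
  expect_equal(insilico_pcr(template, fwd_mm, rev,
                            mismatch_max = 1)$product_length, 82)
})
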