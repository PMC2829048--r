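test_that("bacterial screen keeps only items reaching the bit threshold", {
  set.seed(201)
  db <- stats::setNames(vapply(1:5, function(i) random_peptide_str(200),
                               character(1)), paste0("bac", 1:5))
  qs <- c(hit = substr(db[[2]], 20, 140),   # strong genuine match
          miss = random_peptide_str(80))
  out <- bacterial_screen(qs, db, "prot-prot")
  expect_true(out$verdicts$pass[out$verdicts$id == "hit"])
  expect_false(out$verdicts$pass[out$verdicts$id == "miss"])
  expect_equal(out$verdicts$reason[out$verdicts$id == "miss"],
               "no_bacterial_hit")
  # a vacuous threshold keeps anything with any positive-scoring hit
  out0 <- bacterial_screen(qs, db, "prot-prot", bits_min = 0)
  expect_true(all(out0$verdicts$pass))
})

mk_hit <- function(id, bits, q1, q2, e = 1e-10, subject = "s") {
  data.frame(query_id = id, subject_id = subject, subject_db = "db",
             pident = 50, aln_len = q2 - q1 + 1, q_start = q1, q_end = q2,
             s_start = 1, s_end = q2 - q1 + 1, frame = 0L,
             raw_score = bits, bit_score = bits, e_value = e,
             stringsAsFactors = FALSE)
}

test_that("invertebrate comparison applies margin, ties and overlap", {
  bac <- rbind(mk_hit("a", 100, 1, 50), mk_hit("b", 60, 1, 50),
               mk_hit("c", 60, 1, 50), mk_hit("d", 80, 1, 50))
  inv <- rbind(mk_hit("a", 60, 1, 50), mk_hit("b", 100, 5, 45),
               mk_hit("c", 60, 200, 260))
  v <- invertebrate_comparison(bac, inv, margin_bits = 0)
  expect_true(v$pass[v$id == "a"])                       # clear margin
  expect_equal(v$reason[v$id == "b"], "conserved_gene")  # shared region
  expect_false(v$pass[v$id == "c"])                      # tie, disjoint
  expect_equal(v$reason[v$id == "c"], "invertebrate_better")
  expect_true(v$pass[v$id == "d"])                       # no invertebrate hit
})

test_that("full-protein recheck enforces the 13-bit margin", {
  set.seed(202)
  prot <- random_peptide_str(300)
  bac_db <- c(bac1 = mutate_protein(prot, 0.25))
  # animal ortholog slightly more diverged: difference under 13 bits
  ani_db <- c(ani1 = mutate_protein(prot, 0.28))
  r <- full_protein_recheck(prot, bac_db, ani_db)
  expect_lt(abs(r$bac_bits - r$animal_bits), 50)
  expect_equal(r$pass, r$animal_bits < r$bac_bits - 13)
  # no animal hit passes
  r2 <- full_protein_recheck(prot, bac_db, c(x = random_peptide_str(100)))
  expect_true(r2$pass)
  # far closer animal protein fails as animal origin
  r3 <- full_protein_recheck(prot, c(b = mutate_protein(prot, 0.45)),
                             c(a = mutate_protein(prot, 0.05)))
  expect_false(r3$pass)
  expect_equal(r3$reason, "animal_origin")
})

test_that("weak rule is the printed conjunction; repeats are caught", {
  pep <- random_peptide_str(100)
  expect_equal(weak_and_repeat_filter(pep, mk_hit("x", 44, 1, 60,
                                                  e = 0.01))$reason, "weak")
  expect_true(weak_and_repeat_filter(pep, mk_hit("x", 44, 1, 60,
                                                 e = 1e-6))$pass)
  expect_true(weak_and_repeat_filter(pep, mk_hit("x", 60, 1, 60,
                                                 e = 0.01))$pass)
  rep_pep <- strrep("QA", 40)
  expect_equal(weak_and_repeat_filter(rep_pep, mk_hit("x", 60, 1, 80))$reason,
               "repeat")
  low <- strrep("A", 80)
  f <- weak_and_repeat_filter(low, mk_hit("x", 60, 1, 80))
  expect_false(f$pass)
  expect_equal(weak_and_repeat_filter(pep, mk_hit("x", 60, 1, 100))$pass,
               TRUE)
})

test_that("entropy and autocorrelation detectors behave as designed", {
  expect_equal(tandem_repeat_fraction(strrep("QA", 30)), 1)
  expect_lt(tandem_repeat_fraction(random_peptide_str(200)), 0.5)
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy("ACGT"), 2)
  expect_lt(min_window_entropy(paste0(random_peptide_str(50),
                                      strrep("A", 30))), 0.5)
})

test_that("scaffold classification separates host, contaminant, chimera", {
  set.seed(203)
  donor <- random_dna_str(12000, gc = 0.45)
  host1 <- random_dna_str(5000, gc = 0.3)
  contam <- substr(donor, 100, 5099)           # pure donor fragment
  shorty <- random_dna_str(1500, gc = 0.3)     # short, no host evidence
  chim <- paste0(random_dna_str(4000, gc = 0.3), substr(donor, 6000, 6399),
                 random_dna_str(3800, gc = 0.3))
  asm <- c(host = host1, contam = contam, shorty = shorty, chim = chim)
  v <- classify_scaffolds(asm, c(donorG = donor),
                          read_support = function(sc, s, e) 1)
  expect_equal(v$class[v$scaffold == "host"], "host")
  expect_equal(v$class[v$scaffold == "contam"], "contaminant")
  expect_gt(v$bac_coverage[v$scaffold == "contam"], 0.9)
  expect_equal(v$class[v$scaffold == "shorty"], "contaminant")
  expect_equal(v$class[v$scaffold == "chim"], "chimeric_scaffold")
  # multi-read support rescues the chimeric segment
  v2 <- classify_scaffolds(asm, c(donorG = donor),
                           read_support = function(sc, s, e) 3)
  expect_equal(v2$class[v2$scaffold == "chim"], "host")
  # host evidence vetoes the short rule
  v3 <- classify_scaffolds(asm, c(donorG = donor),
                           host_hits = c(shorty = TRUE))
  expect_equal(v3$class[v3$scaffold == "shorty"], "host")
})

test_that("chimeric reads need two exclusive regions and junction support", {
  set.seed(204)
  host <- c(hostA = random_dna_str(9000, gc = 0.3))
  donor <- c(donorG = random_dna_str(6000, gc = 0.45))
  mk_chim <- function(hpos) paste0(substr(host[[1]], hpos, hpos + 399),
                                   substr(donor[[1]], 2000, 2399))
  reads <- c(
    chim1 = mk_chim(3000), chim2 = mk_chim(3000), chim3 = mk_chim(3000),
    solo = mk_chim(6000),
    plain = substr(host[[1]], 1000, 1799),
    vec = paste0(substr(host[[1]], 500, 899), random_dna_str(300)),
    poly = strrep("AT", 350))
  vec_db <- c(vec1 = substr(reads[["vec"]], 380, 700))
  res <- detect_chimeric_reads(reads, donor, host, vector_db = vec_db)
  expect_equal(res$class[res$read_id %in% c("chim1", "chim2", "chim3")],
               rep("chimera_lgt", 3))
  expect_equal(res$class[res$read_id == "solo"], "chimera_artifact")
  expect_equal(res$class[res$read_id == "plain"], "host_only")
  expect_equal(res$class[res$read_id == "vec"], "vector")
  expect_equal(res$class[res$read_id == "poly"], "low_complexity")
  # a single region matching both databases is a conserved gene, not LGT
  shared <- random_dna_str(700, gc = 0.4)
  host2 <- c(hostA = paste0(substr(host[[1]], 1, 4000), shared,
                            substr(host[[1]], 4001, 9000)))
  donor2 <- c(donorG = paste0(donor[[1]], shared))
  res2 <- detect_chimeric_reads(c(r = shared), donor2, host2)
  expect_equal(res2$class, "conserved")
})

test_that("symbiont screen reports implanted fragments, not contaminants", {
  set.seed(205)
  symb <- c(symb = random_dna_str(8000, gc = 0.45))
  frag <- substr(symb[[1]], 3000, 3499)
  host <- c(h1 = paste0(random_dna_str(2000, 0.3), frag,
                        random_dna_str(2000, 0.3)),
            h2 = random_dna_str(3000, 0.3),
            cont = substr(symb[[1]], 5000, 7000))
  verd <- data.frame(scaffold = c("h1", "h2", "cont"),
                     class = c("host", "host", "contaminant"))
  loci <- symbiont_nt_screen(symb, host, scaffold_verdicts = verd)
  expect_true(any(loci$scaffold == "h1" & loci$start < 2100 &
                    loci$end > 2400))
  expect_false(any(loci$scaffold == "cont"))
  none <- symbiont_nt_screen(symb, c(h2 = host[["h2"]]))
  expect_equal(nrow(none), 0)
})

test_that("paralog expansion finds tandem copies and respects overlap", {
  set.seed(206)
  prot <- random_peptide_str(220)
  cds <- reverse_translate(prot, 0.3)
  copy2 <- reverse_translate(mutate_protein(prot, 0.05), 0.3)
  copy3 <- reverse_translate(mutate_protein(prot, 0.05), 0.3)
  asm <- c(sc1 = paste0(random_dna_str(800, 0.3), cds,
                        random_dna_str(1500, 0.3), copy2,
                        random_dna_str(800, 0.3)),
           sc2 = paste0(random_dna_str(500, 0.3), copy3,
                        random_dna_str(500, 0.3)))
  seed_cand <- data.frame(id = "seed", peptide = prot, scaffold = "sc1",
                          start = 801, end = 800 + nchar(cds),
                          stringsAsFactors = FALSE)
  par <- expand_paralogs(seed_cand, asm, bits_min = 40)
  expect_equal(nrow(par), 2)
  expect_setequal(par$scaffold, c("sc1", "sc2"))
  expect_true(all(par$seed_id == "seed"))
  # no paralogs implanted: nothing beyond the seed
  asm2 <- c(sc1 = paste0(random_dna_str(500, 0.3), cds,
                         random_dna_str(500, 0.3)))
  seed2 <- data.frame(id = "seed", peptide = prot, scaffold = "sc1",
                      start = 501, end = 500 + nchar(cds),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(expand_paralogs(seed2, asm2, bits_min = 40)), 0)
})
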