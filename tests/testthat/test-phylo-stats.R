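test_that("pairwise distances drop gap columns and follow closed forms", {
  base <- strrep("A", 100)
  v <- strsplit(base, "")[[1]]
  v[1:10] <- "R"
  aln <- c(x = base, y = paste(v, collapse = ""))
  D <- pairwise_distances(aln, "p-distance")
  expect_equal(D["x", "y"], 0.10)
  Dp <- pairwise_distances(aln, "poisson")
  expect_equal(Dp["x", "y"], -log(0.9))
  # a gap column in any row is excluded from the site count
  v2 <- v; v2[50] <- "-"
  aln2 <- c(x = base, y = paste(v2, collapse = ""))
  D2 <- pairwise_distances(aln2, "p-distance")
  expect_equal(D2["x", "y"], 10 / 99)
  expect_equal(diag(D), c(x = 0, y = 0))
  expect_error(pairwise_distances(c(a = "--", b = "A-")), "length|gap")
})

test_that("NJ recovers topology and branch lengths on additive input", {
  # distances generated by the tree ((A:1,B:2):1,C:3,D:4) with internal
  # branch joining (A,B) to (C,D)
  lab <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 6
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 7
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  # additive: path lengths on the tree reproduce D exactly
  expect_equal(unname(cophenetic(tr)[lab, lab]), unname(D),
               tolerance = 1e-10)
  # topology AB | CD
  spl <- ape::prop.part(tr)
  expect_error(neighbor_joining(D[1:2, 1:2]), "3 taxa")
  # permuting the taxa leaves the unrooted topology unchanged
  perm <- c("C", "A", "D", "B")
  tr2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
})

test_that("negative NJ branch lengths are clamped to zero", {
  lab <- c("a", "b", "c", "d")
  D <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4, dimnames = list(lab, lab))
  D["a", "c"] <- D["c", "a"] <- 2  # break additivity hard
  expect_message(tr <- neighbor_joining(D), "clamping")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support is seeded, bounded and signal-responsive", {
  set.seed(401)
  anc <- random_peptide_str(120)
  cladeA <- mutate_protein(anc, 0.35)
  cladeB <- mutate_protein(anc, 0.35)
  aln <- c(a1 = mutate_protein(cladeA, 0.03), a2 = mutate_protein(cladeA, 0.03),
           a3 = mutate_protein(cladeA, 0.03), b1 = mutate_protein(cladeB, 0.03),
           b2 = mutate_protein(cladeB, 0.03), b3 = mutate_protein(cladeB, 0.03))
  bs <- bootstrap_support(aln, B = 200, seed = 7)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  # the two-clade split is overwhelmingly supported
  expect_gt(max(bs$support), 95)
  bs2 <- bootstrap_support(aln, B = 200, seed = 7)
  expect_identical(bs$support, bs2$support)
  b1 <- bootstrap_support(aln, B = 1, seed = 3)
  expect_true(all(b1$support %in% c(0, 100)))
})

test_that("relative-rate test follows the chi-square closed form", {
  base <- strsplit(strrep("A", 300), "")[[1]]
  out <- paste(base, collapse = "")
  i2 <- base; i2[1:5] <- "C"        # 5 sites unique to ingroup 2
  i1 <- base; i1[10:29] <- "W"      # 20 sites unique to ingroup 1
  r <- relative_rate_test(paste(i1, collapse = ""),
                          paste(i2, collapse = ""), out)
  expect_equal(r$m1, 20)
  expect_equal(r$m2, 5)
  expect_equal(r$chi2, (20 - 5)^2 / 25)
  expect_equal(r$p, stats::pchisq(9, 1, lower.tail = FALSE))
  expect_equal(round(r$p, 4), 0.0027)
  # swapping the ingroups swaps the counts, not the statistic
  r2 <- relative_rate_test(paste(i2, collapse = ""),
                           paste(i1, collapse = ""), out)
  expect_equal(r2$m1, 5)
  expect_equal(r2$chi2, r$chi2)
  # identical ingroups: no signal
  r3 <- relative_rate_test(out, out, paste(i1, collapse = ""))
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p, 1)
})

test_that("relaxed PHYLIP export writes a parsable alignment", {
  aln <- c(taxonA = "MKV-LI", taxonB = "MKVQLI")
  tmp <- withr::local_tempfile(fileext = ".phy")
  write_phylip(aln, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "2 6")
  expect_equal(lines[2], "taxonA MKV-LI")
  expect_error(write_phylip(c(a = "AA", b = "AAA"), tmp), "equal length")
})

test_that("placement attributes candidates to the generating lineage", {
  set.seed(402)
  anc <- random_peptide_str(250)
  linA <- mutate_protein(anc, 0.15)
  linB <- mutate_protein(anc, 0.15)
  refs <- c(A1 = mutate_protein(linA, 0.05), A2 = mutate_protein(linA, 0.05),
            B1 = mutate_protein(linB, 0.05), B2 = mutate_protein(linB, 0.05))
  lin <- c(A1 = "donorA", A2 = "donorA", B1 = "donorB", B2 = "donorB")
  cand <- mutate_protein(linA, 0.10)
  pl <- placement_report(cand, refs, lin, B = 200, seed = 5)
  expect_equal(pl$call, "donorA")
  expect_gte(pl$support, 70)
  # truncated candidate is projected onto the reference alignment
  pl2 <- placement_report(substr(cand, 40, 200), refs, lin, B = 200,
                          seed = 5)
  expect_equal(pl2$call, "donorA")
  # single-lineage reference set: trivially that lineage, low information
  pl3 <- placement_report(cand, refs[1:2], lin[1:2], B = 50, seed = 1)
  expect_true(pl3$low_information)
  # a candidate without affinity to either lineage stays unresolved
  far <- random_peptide_str(250)
  pl4 <- placement_report(far, refs, lin, B = 200, seed = 5)
  expect_true(pl4$call %in% c("unresolved", NA_character_) ||
                is.na(pl4$support) || pl4$support < 100)
})
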