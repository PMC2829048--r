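cfg_small <- function(seed = 1, ...) {
  generator_config(seed = seed, n_scaffolds = 4, scaffold_len_mean = 6000,
                   n_families = 30, n_decoy_extra = 10, ...)
}

test_that("identical configurations give byte-identical datasets", {
  ds1 <- generate_synthetic_dataset(generator_config(seed = 3))
  ds2 <- generate_synthetic_dataset(generator_config(seed = 3))
  expect_identical(ds1$assembly, ds2$assembly)
  expect_identical(ds1$reads, ds2$reads)
  expect_identical(ds1$truth, ds2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(ds1, d1)
  write_synthetic_dataset(ds2, d2)
  f1 <- file.path(d1, "assembly.fasta"); f2 <- file.path(d2, "assembly.fasta")
  expect_identical(readLines(f1), readLines(f2))
  ds3 <- generate_synthetic_dataset(generator_config(seed = 4))
  expect_false(identical(ds1$assembly, ds3$assembly))
})

test_that("host GC and gap-run counts match the configuration", {
  cfg <- generator_config(seed = 5, n_gap_runs = 5)
  host <- generate_host_assembly(cfg)
  expect_equal(nrow(host$gaps), 5)
  seqs <- paste(host$assembly, collapse = "")
  tab <- table(strsplit(seqs, "")[[1]])
  acgt <- sum(tab[c("A", "C", "G", "T")])
  gc <- sum(tab[c("G", "C")]) / acgt
  expect_lt(abs(gc - 0.30), 0.01)
  expect_true(all(mapply(function(sc, s, e)
    substr(host$assembly[[sc]], s, e) == strrep("N", e - s + 1),
    host$gaps$scaffold, host$gaps$start, host$gaps$end)))
  expect_error(generate_host_assembly(generator_config(seed = 1,
                                                       n_scaffolds = 0)))
})

test_that("divergence tiers behave like per-site substitution rates", {
  set.seed(8)
  p <- random_peptide_str(300)
  expect_identical(mutate_protein(p, 0), p)
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  ids <- replicate(20, ident(p, mutate_protein(p, 0.35)))
  expect_lt(abs(mean(ids) - 0.65), 0.05)
})

test_that("decoy proteome shares the configured conserved fraction", {
  cfg <- generator_config(seed = 6, n_families = 40, conserved_frac = 0.2,
                          n_decoy_extra = 12)
  donors <- evolve_donor_proteomes(cfg)
  expect_length(donors$conserved_families, 8)
  expect_length(donors$decoy, 8 + 12)
  expect_length(donors$bacterial_db, 4 * 40)
  # conserved decoys are recognizably similar to their donor twins
  fam <- donors$conserved_families[1]
  al <- sw_align(donors$decoy[[paste0("decoy_", fam)]],
                 donors$donorA1[[paste0("donorA1_", fam)]])
  expect_gt(bit_score(al$score, scoring_scheme("protein")), 100)
})

test_that("implants have the declared lesion structure by construction", {
  ds <- generate_synthetic_dataset(generator_config(seed = 2))
  expect_equal(nrow(ds$truth), 12)
  expect_setequal(unique(ds$truth$class),
                  c("functional_LGT", "chimeric_fusion", "paralog_cluster",
                    "pseudogene_LGT", "buchnera_fragment"))
  # functional events: spliced CDS translates without stops
  for (eid in unique(ds$exons$event_id)) {
    e <- ds$exons[ds$exons$event_id == eid, ]
    cds <- paste(mapply(function(s, en, st)
      extract_region(ds$assembly, e$scaffold[1], s, en, st),
      e$start, e$end, e$strand), collapse = "")
    expect_false(grepl("*", translate_nt(cds), fixed = TRUE))
    # introns are canonical GT..AG
    if (nrow(e) > 1) {
      ev <- ds$truth[ds$truth$event_id == eid, ]
      if (nrow(ev) == 0) next
    }
  }
  # pseudogene/fragment classes carry at least one lesion
  psi <- ds$truth[ds$truth$class %in% c("pseudogene_LGT",
                                        "buchnera_fragment"), ]
  expect_true(all(psi$n_frameshifts + psi$n_internal_stops >= 1 |
                    psi$truncation_fraction < 1))
  # functional events carry none
  fun <- ds$truth[ds$truth$class %in% c("functional_LGT",
                                        "paralog_cluster",
                                        "chimeric_fusion"), ]
  expect_true(all(fun$n_frameshifts == 0 & fun$n_internal_stops == 0))
  # truth loci never overlap assembly gap runs for functional events
  for (i in seq_len(nrow(fun))) {
    g <- ds$gaps[ds$gaps$scaffold == fun$scaffold[i], ]
    if (nrow(g) == 0) next
    lo <- min(fun$start[i], fun$end[i]); hi <- max(fun$start[i], fun$end[i])
    expect_true(all(g$end < lo | g$start > hi))
  }
})

test_that("paralog cluster members sit on one scaffold at high identity", {
  ds <- generate_synthetic_dataset(generator_config(seed = 9))
  cl <- ds$truth[ds$truth$cluster_id == "rlpA" &
                   !is.na(ds$truth$cluster_id), ]
  expect_equal(nrow(cl), 5)
  expect_equal(length(unique(cl$scaffold)), 1)
  seqs <- vapply(seq_len(nrow(cl)), function(i)
    extract_region(ds$assembly, cl$scaffold[i], cl$start[i], cl$end[i],
                   cl$strand[i]), character(1))
  al <- sw_align(seqs[1], seqs[2], scoring_scheme("nucleotide"))
  expect_gt(al$identity, 0.94)
})

test_that("read pool matches the coverage model", {
  cfg <- generator_config(seed = 10, chimeric_read_rate = 0)
  ds <- generate_synthetic_dataset(cfg)
  G <- sum(nchar(ds$assembly))
  expected <- cfg$coverage * G / cfg$read_len_mean
  expect_lt(abs(length(ds$reads) - expected) / expected, 0.1)
  expect_false(any(ds$read_truth$type == "chimeric_artifact"))
  cfg2 <- generator_config(seed = 10, chimeric_read_rate = 0.02)
  ds2 <- generate_synthetic_dataset(cfg2)
  expect_gt(sum(ds2$read_truth$type == "chimeric_artifact"), 0)
})

test_that("contaminant scaffolds are near-identical donor fragments", {
  cfg <- generator_config(seed = 11, contaminant_identity = 1.0)
  ds <- generate_synthetic_dataset(cfg)
  expect_length(ds$contaminants, cfg$n_contaminant_scaffolds)
  genomes <- c(ds$donors$donorA_genome$seq, ds$donors$donorB_genome$seq)
  for (cs in ds$contaminants) {
    expect_true(any(vapply(genomes, function(g)
      grepl(cs, g, fixed = TRUE), logical(1))))
  }
})

test_that("qPCR simulation separates genomic and contaminant loci", {
  loci <- data.frame(locus = c("g1", "c1"), type = c("genomic",
                                                     "contaminant"))
  cfg0 <- generator_config(seed = 12, sigma_genomic = 0)
  q0 <- simulate_qpcr(loci[1, ], cfg0)
  expect_true(all(q0$ratio == 1))
  expect_equal(nrow(q0), (3 + 4) * 3)  # batches x technical replicates
  cv <- function(x) stats::sd(x) / mean(x)
  wins <- 0
  for (s in 1:20) {
    q <- simulate_qpcr(loci, generator_config(seed = s))
    if (cv(q$ratio[q$locus == "c1"]) > cv(q$ratio[q$locus == "g1"]))
      wins <- wins + 1
  }
  expect_gt(wins, 15)
})
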