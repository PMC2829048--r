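mk_qpcr <- function(vals_by_sample, locus = "g", strains = NULL) {
  n <- length(vals_by_sample)
  if (is.null(strains)) strains <- rep(c("LSR1", "ISO"), length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(locus = locus, strain = strains[i],
               sample = paste0("s", i),
               replicate = seq_along(vals_by_sample[[i]]),
               ratio = vals_by_sample[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("ratio summaries give textbook means and standard errors", {
  t1 <- mk_qpcr(list(1, 1, 1))
  s1 <- summarize_ratios(t1)
  pooled <- s1[s1$strain == "pooled", ]
  expect_equal(pooled$mean_R, 1)
  expect_equal(pooled$se_R, 0)
  t2 <- mk_qpcr(list(0.9, 1.1))
  s2 <- summarize_ratios(t2)
  expect_equal(s2$mean_R[s2$strain == "pooled"], 1.0)
  expect_equal(s2$se_R[s2$strain == "pooled"], 0.1)
  # single-sample strains are flagged
  expect_true(all(s2$flagged[s2$strain != "pooled"]))
})

test_that("ANOVA/Tukey handles degenerate and clear-cut cases", {
  a0 <- anova_tukey(rep(1, 9), rep(c("x", "y", "z"), each = 3))
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  expect_true(all(a0$tukey$p_adj == 1))
  a1 <- anova_tukey(c(1, 1.001, 1, 2, 2.001, 2), rep(c("x", "y"), each = 3))
  expect_lt(a1$p, 0.001)
  expect_lt(a1$tukey$p_adj[1], 0.001)
  expect_warning(anova_tukey(c(1, 2, 3, 4, 5), c("x", "x", "y", "y", "z")),
                 "one observation")
})

test_that("Tukey-Kramer p-values are conservative vs unadjusted t-tests", {
  set.seed(501)
  for (i in 1:10) {
    vals <- rnorm(24)
    grp <- rep(c("a", "b", "c"), each = 8)
    tk <- anova_tukey(vals, grp)$tukey
    pt <- stats::pairwise.t.test(vals, grp, p.adjust.method = "none",
                                 pool.sd = TRUE)$p.value
    unadj <- c(pt["b", "a"], pt["c", "a"], pt["c", "b"])
    adj <- tk$p_adj[match(c("b-a", "c-a", "c-b"), tk$pair)]
    expect_true(all(adj >= unadj - 1e-10))
  }
})

test_that("copy-number calls formalize 'constant and centred at 1'", {
  # degenerate noiseless replicates
  t0 <- mk_qpcr(list(c(1, 1), c(1, 1)))
  v0 <- copy_number_call(t0)
  expect_equal(v0$call, "single_copy_genomic")
  # mean far outside the band is variable titer
  t1 <- mk_qpcr(lapply(1:7, function(i) rnorm(3, 8, 0.1)))
  expect_equal(copy_number_call(t1)$call, "variable_titer")
  # verdicts depend only on the ratios (scale cancels in R)
  set.seed(502)
  t2 <- mk_qpcr(lapply(1:7, function(i) rnorm(3, 1, 0.05)))
  expect_equal(copy_number_call(t2)$call,
               copy_number_call(transform(t2, ratio = ratio))$call)
})

test_that("simulated genomic and contaminant loci are separated", {
  loci <- data.frame(locus = c("g", "c"),
                     type = c("genomic", "contaminant"))
  ok_g <- 0; ok_c <- 0
  for (s in 1:40) {
    q <- simulate_qpcr(loci, generator_config(seed = 600 + s))
    v <- copy_number_call(q)
    if (v$call[v$locus == "g"] != "variable_titer") ok_g <- ok_g + 1
    if (v$call[v$locus == "c"] == "variable_titer") ok_c <- ok_c + 1
  }
  expect_gte(ok_g / 40, 0.9)
  expect_gte(ok_c / 40, 0.9)
})

test_that("fold changes are ratios of tissue means with Tukey flags", {
  set.seed(503)
  expr <- rbind(
    data.frame(locus = "LdcA1", tissue = "whole_body", replicate = 1:6,
               copies = rnorm(6, 1, 0.01)),
    data.frame(locus = "LdcA1", tissue = "bacteriocyte", replicate = 1:6,
               copies = rnorm(6, 11.6, 0.01)),
    data.frame(locus = "LdcA1", tissue = "midgut", replicate = 1:6,
               copies = rnorm(6, 1, 0.01)))
  fc <- fold_change(expr)
  expect_equal(fc$fold[fc$tissue == "bacteriocyte"], 11.6,
               tolerance = 0.01)
  expect_lt(fc$p_adj_vs_reference[fc$tissue == "bacteriocyte"], 0.001)
  expect_equal(fc$fold[fc$tissue == "midgut"], 1, tolerance = 0.01)
  expect_gt(fc$p_adj_vs_reference[fc$tissue == "midgut"], 0.05)
  # zero reference mean is undefined and flagged
  expr0 <- transform(expr, copies = ifelse(tissue == "whole_body", 0,
                                           copies))
  expect_warning(fc0 <- fold_change(expr0), "zero reference")
  expect_true(all(is.na(fc0$fold)))
  # missing reference tissue skips the locus with a warning
  expect_warning(fold_change(expr[expr$tissue != "whole_body", ]),
                 "absent")
})
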