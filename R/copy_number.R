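# Replicate qPCR copy-number verdicts: a locus is host-genomic when its
# target/standard ratio is statistically constant across samples and
# centred at 1; bacterial contaminants fluctuate in titer among samples.

# per-locus sample means (one value per biological sample)
.sample_means <- function(df) {
  if (!"sample" %in% names(df)) {
    df$sample <- paste(df$strain, df$replicate, sep = "_")
  }
  agg <- stats::aggregate(ratio ~ locus + strain + sample, data = df,
                          FUN = mean)
  agg
}

#' Summarize qPCR ratios per locus
#'
#' Mean and standard error of the per-sample ratios, per strain and pooled.
#'
#' @param table data.frame with columns `locus, strain, replicate, ratio`
#'   (and optionally `sample`; without it each row is one sample).
#' @return data.frame `locus, strain, n, mean_R, se_R` including a
#'   `"pooled"` strain row per locus.  With a single sample the SE is `NA`
#'   and the row is flagged.
#' @export
summarize_ratios <- function(table) {
  sm <- .sample_means(table)
  one <- function(vals, locus, strain) {
    n <- length(vals)
    data.frame(locus = locus, strain = strain, n = n,
               mean_R = mean(vals),
               se_R = if (n >= 2) stats::sd(vals) / sqrt(n) else NA_real_,
               flagged = n < 2, stringsAsFactors = FALSE)
  }
  out <- list()
  for (loc in unique(sm$locus)) {
    s <- sm[sm$locus == loc, ]
    for (st in unique(s$strain)) {
      out[[length(out) + 1L]] <- one(s$ratio[s$strain == st], loc, st)
    }
    out[[length(out) + 1L]] <- one(s$ratio, loc, "pooled")
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Standard one-way F test followed by Tukey's honest significant
#' differences (the Tukey-Kramer studentized-range procedure, which handles
#' unequal group sizes).  Groups with a single observation are excluded with
#' a warning; a completely constant response returns `F = 0, p = 1` by
#' convention.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @return List `F, p, tukey` (`tukey` is a data.frame `pair, diff, p_adj`,
#'   `NULL` when fewer than 2 usable groups remain).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  tab <- table(groups)
  if (any(tab < 2)) {
    warning("excluding ", sum(tab < 2), " group(s) with one observation")
    keep <- groups %in% names(tab)[tab >= 2]
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) {
    return(list(F = NA_real_, p = NA_real_, tukey = NULL))
  }
  if (stats::var(values) == 0 || all(is.nan(values))) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2, FUN = paste, collapse = "-")
    return(list(F = 0, p = 1,
                tukey = data.frame(pair = pairs, diff = 0, p_adj = 1,
                                   stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }
  tk <- stats::TukeyHSD(fit)$groups
  list(F = Fv, p = pv,
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Copy-number verdict per locus
#'
#' Formalizes the "constant and centred at 1" criterion: a locus is called
#' `single_copy_genomic` when (i) one-way ANOVA among samples followed by
#' Tukey-Kramer comparisons finds no significant variation (among-sample
#' variation counts as significant only when the ANOVA rejects *and* some
#' Tukey-adjusted pairwise comparison rejects, which is the
#' "ANOVA followed by Tukey-Kramer" procedure), (ii) a two-sample t-test
#' between strains finds no difference (`p > alpha`), (iii) the pooled
#' mean ratio lies within `band`, and (iv) 1 lies within `mean +/- t SE`.
#' It is `variable_titer` when among-sample variation is significant or
#' the mean leaves the band, and `indeterminate` otherwise.
#'
#' @param table data.frame `locus, strain, sample, replicate, ratio`
#'   (`sample` optional: without technical replicates the ANOVA groups by
#'   strain).
#' @param alpha Significance level (default 0.05).
#' @param band Acceptable pooled-mean band (default `c(0.5, 2)`).
#' @return data.frame (`CopyNumberVerdict`): `locus, mean_R, se_R, anova_p,
#'   strain_t_p, call`.
#' @export
copy_number_call <- function(table, alpha = 0.05, band = c(0.5, 2.0)) {
  has_sample <- "sample" %in% names(table)
  sm <- .sample_means(table)
  out <- list()
  for (loc in unique(table$locus)) {
    raw <- table[table$locus == loc, ]
    s <- sm[sm$locus == loc, ]
    # among-sample ANOVA on technical replicates (or among strains when no
    # technical replication exists)
    grp <- if (has_sample) raw$sample else raw$strain
    a <- suppressWarnings(anova_tukey(raw$ratio, grp))
    anova_p <- a$p
    variation_sig <- !is.na(anova_p) && anova_p <= alpha &&
      !is.null(a$tukey) && any(a$tukey$p_adj <= alpha)
    # between-strain t-test on sample means
    st <- unique(s$strain)
    t_p <- if (length(st) == 2 &&
               all(table(s$strain) >= 2) &&
               stats::var(s$ratio) > 0) {
      stats::t.test(ratio ~ strain, data = s, var.equal = TRUE)$p.value
    } else if (length(st) < 2) NA_real_ else 1
    n <- nrow(s)
    mean_R <- mean(s$ratio)
    se_R <- if (n >= 2) stats::sd(s$ratio) / sqrt(n) else NA_real_
    ci_half <- if (n >= 2) stats::qt(0.975, n - 1) * se_R else Inf
    in_ci <- abs(mean_R - 1) <= ci_half ||
      (!is.na(se_R) && se_R == 0 && mean_R == 1)
    in_band <- mean_R >= band[1] && mean_R <= band[2]
    t_ok <- is.na(t_p) || t_p > alpha
    call <- if (!variation_sig && t_ok && in_band && in_ci) {
      "single_copy_genomic"
    } else if (variation_sig || !in_band) {
      "variable_titer"
    } else {
      "indeterminate"
    }
    out[[length(out) + 1L]] <- data.frame(
      locus = loc, mean_R = mean_R, se_R = se_R, anova_p = anova_p,
      strain_t_p = t_p, call = call, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Tissue fold-change summary
#'
#' Fold change of each tissue relative to the whole-body reference, with
#' Tukey-Kramer significance flags across tissues.
#'
#' @param expr data.frame `locus, tissue, replicate, copies` (normalized
#'   copies).
#' @param reference Reference tissue name (default `"whole_body"`).
#' @return data.frame `locus, tissue, fold, p_adj_vs_reference` (fold is
#'   `NA`, with a warning, when the reference mean is zero; the reference
#'   tissue itself is omitted).
#' @export
fold_change <- function(expr, reference = "whole_body") {
  out <- list()
  for (loc in unique(expr$locus)) {
    e <- expr[expr$locus == loc, ]
    if (!reference %in% e$tissue) {
      warning("locus ", loc, ": reference tissue absent; skipped")
      next
    }
    ref_mean <- mean(e$copies[e$tissue == reference])
    if (ref_mean == 0) warning("locus ", loc, ": zero reference mean")
    a <- anova_tukey(e$copies, e$tissue)
    for (ti in setdiff(unique(e$tissue), reference)) {
      fold <- if (ref_mean == 0) NA_real_ else
        mean(e$copies[e$tissue == ti]) / ref_mean
      p <- NA_real_
      if (!is.null(a$tukey)) {
        pair <- a$tukey$pair %in% c(paste0(ti, "-", reference),
                                    paste0(reference, "-", ti))
        if (any(pair)) p <- a$tukey$p_adj[pair][1]
      }
      out[[length(out) + 1L]] <- data.frame(
        locus = loc, tissue = ti, fold = fold, p_adj_vs_reference = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(locus = character(0), tissue = character(0),
                      fold = numeric(0), p_adj_vs_reference = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
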