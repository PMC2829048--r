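# End-to-end orchestration: generate (or accept) inputs, run the PPP and
# six-frame window screening arms through the filter cascade, the read and
# symbiont screens, paralog expansion, pseudogene annotation, placement and
# copy-number verdicts, and score recovery against the synthetic truth.

#' Pipeline configuration
#'
#' Bundles the generator configuration with every cascade threshold.  The
#' defaults are the screen's printed operating points: PPPs of at least 60
#' aa; protein/translated bit threshold 40 and nucleotide 55; the weak rule
#' `bits <= 45 and E >= 0.001`; the full-protein margin of 13 bits; 1,000 nt
#' windows overlapping by 200; symbiont-screen `E < 1e-5`; the short-
#' scaffold rule at 2 kb.
#'
#' @param seed Master seed.
#' @param generator A [generator_config()]; defaults to
#'   `generator_config(seed)`.
#' @param dataset Optional pre-generated dataset (bypasses the generator).
#' @param ppp_min_len Minimum PPP length (aa).
#' @param window_len,window_overlap Window screen geometry (nt).
#' @param prot_bits_min,nt_bits_min Bacterial-screen thresholds (bits).
#' @param inv_bits_min Report threshold for invertebrate comparison hits.
#' @param margin_bits Required bacterial-minus-invertebrate margin.
#' @param weak_bits_max,weak_e_min Weak-similarity rule.
#' @param delta_min Full-protein recheck margin (bits).
#' @param e_max_symbiont Symbiont nucleotide screen E ceiling.
#' @param short_len,contaminant_identity_min,contaminant_coverage_min,chimera_seg_max
#'   Scaffold classification thresholds.
#' @param region_min,junction_overlap_max,min_support Chimeric-read rules.
#' @param locus_bits_min Sub-threshold hits above this level extend a
#'   surviving item's locus (locus construction only).
#' @param merge_gap Candidate loci closer than this are merged (nt).
#' @param paralog_bits_min Paralog expansion threshold (bits).
#' @param support_min,b_boot Placement support threshold and bootstrap
#'   replicates.
#' @param alpha,band Copy-number verdict parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, generator = generator_config(seed),
                            dataset = NULL,
                            ppp_min_len = 60,
                            window_len = 1000, window_overlap = 200,
                            prot_bits_min = 40, nt_bits_min = 55,
                            inv_bits_min = 20, margin_bits = 0,
                            weak_bits_max = 45, weak_e_min = 0.001,
                            delta_min = 13,
                            e_max_symbiont = 1e-5,
                            short_len = 2000,
                            contaminant_identity_min = 0.90,
                            contaminant_coverage_min = 0.50,
                            chimera_seg_max = 1000,
                            region_min = 100, junction_overlap_max = 30,
                            min_support = 2,
                            locus_bits_min = 25, merge_gap = 600,
                            paralog_bits_min = 40,
                            support_min = 70, b_boot = 200,
                            alpha = 0.05, band = c(0.5, 2.0)) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.family_of <- function(subject_id) sub("^.*_(fam[0-9]+)$", "\\1", subject_id)

# extract the candidate-side peptide of a locus by chained frame alignment
.candidate_peptide <- function(locus_nt, homolog, scheme) {
  best <- NULL
  for (orient in c("+", "-")) {
    nt <- if (orient == "+") locus_nt else revcomp(locus_nt)
    chain <- .chain_hsps(.frame_hsps(nt, homolog, scheme, 22))
    if (length(chain) == 0) next
    tot <- sum(vapply(chain, `[[`, numeric(1), "score"))
    if (is.null(best) || tot > best$tot)
      best <- list(chain = chain, tot = tot, nt = nt)
  }
  if (is.null(best)) return(NA_character_)
  segs <- vapply(best$chain, function(h) {
    translate_nt(substr(best$nt, h$nt_start, h$nt_end),
                 (h$nt_start - 1L) %% 3L * 0L)
  }, character(1))
  chartr("*", "X", paste(segs, collapse = ""))
}

#' Run the full screening pipeline
#'
#' Stages run in screening order: scaffold classification; PPP extraction
#' and the PPP cascade (bacterial screen, invertebrate comparison,
#' contaminant exclusion, weak/repeat exclusion); the six-frame window arm;
#' chimeric-read screening of the read pool; the symbiont nucleotide
#' screen; paralog expansion; then pseudogene annotation, donor-lineage
#' placement and qPCR copy-number verdicts for the final candidates.  Runs
#' are deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return An `lgt_report` list: `funnel`, `candidates`, `contaminant_calls`,
#'   `scaffold_verdicts`, `read_screen`, `pseudogene_reports`, `placement`,
#'   `copy_number`, `recovery`, `dataset`.
#' @export
run_pipeline <- function(config) {
  ds <- if (!is.null(config$dataset)) config$dataset else
    generate_synthetic_dataset(config$generator)
  psch <- scoring_scheme("protein")
  bac_prot <- ds$donors$bacterial_db
  inv_db <- ds$donors$decoy
  bac_nt <- c(donorA_genome = ds$donors$donorA_genome$seq,
              donorB_genome = ds$donors$donorB_genome$seq)
  symbionts <- c(symbiont_B = ds$donors$donorB_genome$seq)
  funnel <- list()
  note <- function(arm, stage, n_in, n_out, info = "") {
    funnel[[length(funnel) + 1L]] <<- data.frame(
      arm = arm, stage = stage, n_in = n_in, n_out = n_out, info = info,
      stringsAsFactors = FALSE)
  }

  verdicts <- classify_scaffolds(
    ds$assembly, bac_nt,
    contaminant_identity_min = config$contaminant_identity_min,
    contaminant_coverage_min = config$contaminant_coverage_min,
    short_len = config$short_len,
    chimera_seg_max = config$chimera_seg_max,
    bits_min = config$nt_bits_min)
  bad_sc <- verdicts$scaffold[verdicts$class != "host"]

  # ---- PPP arm ------------------------------------------------------------
  ppps <- extract_ppps(ds$assembly, min_len = config$ppp_min_len)
  peptides <- stats::setNames(ppps$peptide, ppps$ppp_id)
  note("ppp", "census", NA, nrow(ppps))
  bs <- bacterial_screen(peptides, bac_prot, "prot-prot",
                         bits_min = config$prot_bits_min,
                         prefilter = "kmer", diag_fast = TRUE)
  surv <- bs$verdicts$id[bs$verdicts$pass]
  note("ppp", "bacterial_screen", nrow(ppps), length(surv))
  contam_items <- list()
  if (length(surv) > 0) {
    inv_hits <- search_hits(peptides[surv], inv_db, "prot-prot",
                            bits_min = config$inv_bits_min,
                            db_tag = "invertebrate",
                            prefilter = "kmer", diag_fast = TRUE)
    iv <- invertebrate_comparison(
      bs$best[bs$best$query_id %in% surv, , drop = FALSE],
      best_hits(inv_hits), margin_bits = config$margin_bits)
    surv2 <- iv$id[iv$pass]
  } else surv2 <- character(0)
  note("ppp", "invertebrate_comparison", length(surv), length(surv2))
  note("ppp", "nr_top_hit", length(surv2), length(surv2),
       "approximated by the combined bacterial+invertebrate comparison")
  on_bad <- ppps$scaffold[match(surv2, ppps$ppp_id)] %in% bad_sc
  if (any(on_bad)) {
    for (id in surv2[on_bad]) {
      sc <- ppps$scaffold[match(id, ppps$ppp_id)]
      contam_items[[length(contam_items) + 1L]] <- data.frame(
        id = id, scaffold = sc,
        final_call = verdicts$class[match(sc, verdicts$scaffold)],
        stringsAsFactors = FALSE)
    }
  }
  surv3 <- surv2[!on_bad]
  note("ppp", "contaminant_exclusion", length(surv2), length(surv3))
  surv4 <- character(0)
  for (id in surv3) {
    wr <- weak_and_repeat_filter(
      peptides[[id]], bs$best[bs$best$query_id == id, , drop = FALSE],
      weak_bits_max = config$weak_bits_max,
      weak_e_min = config$weak_e_min)
    if (wr$pass) surv4 <- c(surv4, id)
  }
  note("ppp", "weak_repeat_filter", length(surv3), length(surv4))
  note("ppp", "full_protein_recheck", length(surv4), length(surv4),
       "skipped: no external gene models supplied")

  # ---- window (six-frame) arm --------------------------------------------
  wins <- make_windows(ds$assembly, config$window_len, config$window_overlap)
  wseqs <- stats::setNames(wins$seq, wins$window_id)
  whits <- search_hits(wseqs, bac_prot, "translated-query",
                       bits_min = config$locus_bits_min,
                       db_tag = "bacterial",
                       prefilter = "kmer", diag_fast = TRUE)
  wbest <- best_hits(whits)
  wsurv <- wbest$query_id[wbest$bit_score >= config$prot_bits_min]
  note("window", "bacterial_screen", nrow(wins), length(wsurv))
  if (length(wsurv) > 0) {
    winv <- search_hits(wseqs[wsurv], inv_db, "translated-query",
                        bits_min = config$inv_bits_min,
                        db_tag = "invertebrate",
                        prefilter = "kmer", diag_fast = TRUE)
    wiv <- invertebrate_comparison(
      wbest[wbest$query_id %in% wsurv, , drop = FALSE],
      best_hits(winv), margin_bits = config$margin_bits)
    wsurv2 <- wiv$id[wiv$pass]
  } else wsurv2 <- character(0)
  note("window", "invertebrate_comparison", length(wsurv), length(wsurv2))
  w_sc <- wins$scaffold[match(wsurv2, wins$window_id)]
  wsurv3 <- wsurv2[!w_sc %in% bad_sc]
  note("window", "contaminant_exclusion", length(wsurv2), length(wsurv3))

  # ---- candidate locus construction --------------------------------------
  items <- list()
  for (id in surv4) {
    i <- match(id, ppps$ppp_id)
    b <- bs$best[bs$best$query_id == id, , drop = FALSE]
    # the candidate locus is the aligned region of the PPP, not the whole
    # stop-to-stop stretch (which can read through far into flanking DNA)
    if (ppps$start[i] <= ppps$end[i]) {
      g1 <- ppps$start[i] + 3L * (b$q_start[1] - 1L)
      g2 <- ppps$start[i] + 3L * b$q_end[1] - 1L
    } else {
      g1 <- ppps$start[i] - 3L * b$q_end[1] + 1L
      g2 <- ppps$start[i] - 3L * (b$q_start[1] - 1L)
    }
    items[[length(items) + 1L]] <- data.frame(
      scaffold = ppps$scaffold[i], start = min(g1, g2), end = max(g1, g2),
      source = "ppp", id = id, bits = b$bit_score[1],
      subject = b$subject_id[1], peptide = ppps$peptide[i],
      strong = TRUE, stringsAsFactors = FALSE)
  }
  for (id in wsurv3) {
    i <- match(id, wins$window_id)
    b <- wbest[wbest$query_id == id, , drop = FALSE]
    fam <- .family_of(b$subject_id[1])
    h <- whits[whits$query_id == id &
                 .family_of(whits$subject_id) == fam, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      items[[length(items) + 1L]] <- data.frame(
        scaffold = wins$scaffold[i],
        start = wins$start[i] - 1L + min(h$q_start[r], h$q_end[r]),
        end = wins$start[i] - 1L + max(h$q_start[r], h$q_end[r]),
        source = "window", id = id, bits = h$bit_score[r],
        subject = b$subject_id[1], peptide = NA_character_,
        strong = h$bit_score[r] >= config$prot_bits_min,
        stringsAsFactors = FALSE)
    }
  }
  loci <- .build_loci(items, config$merge_gap)
  note("merge", "candidate_loci",
       length(surv4) + length(wsurv3), nrow(loci))

  # ---- read screen --------------------------------------------------------
  read_screen <- detect_chimeric_reads(
    ds$reads, bac_nt, ds$assembly,
    region_min = config$region_min,
    junction_overlap_max = config$junction_overlap_max,
    min_support = config$min_support, bits_min = config$nt_bits_min)
  chim_lgt <- read_screen[read_screen$class == "chimera_lgt", , drop = FALSE]
  if (nrow(chim_lgt) > 0) {
    for (i in seq_len(nrow(chim_lgt))) {
      s <- max(1, chim_lgt$junction[i] - config$region_min)
      e <- chim_lgt$junction[i] + config$region_min
      if (!.overlaps_any(loci, chim_lgt$scaffold[i], s, e)) {
        loci <- rbind(loci, data.frame(
          locus_id = paste0(chim_lgt$scaffold[i], ":", s, "-", e),
          scaffold = chim_lgt$scaffold[i], start = s, end = e,
          best_bits = NA_real_, best_subject = NA_character_,
          peptide = NA_character_, sources = "read_chimera",
          n_items = 1L, stringsAsFactors = FALSE))
      }
    }
  }
  note("read", "chimera_screen", length(ds$reads), nrow(chim_lgt),
       paste0(sum(read_screen$class == "chimera_artifact"),
              " singleton artifacts removed"))

  # ---- symbiont nucleotide screen ----------------------------------------
  symb <- symbiont_nt_screen(symbionts, ds$assembly,
                             e_max = config$e_max_symbiont,
                             scaffold_verdicts = verdicts,
                             animal_nt_db = c(invertebrate_genome =
                                                ds$donors$decoy_genome$seq),
                             bits_min = config$nt_bits_min)
  n_new_symb <- 0L
  if (nrow(symb) > 0) {
    for (i in seq_len(nrow(symb))) {
      if (!.overlaps_any(loci, symb$scaffold[i], symb$start[i],
                         symb$end[i])) {
        n_new_symb <- n_new_symb + 1L
        loci <- rbind(loci, data.frame(
          locus_id = paste0(symb$scaffold[i], ":", symb$start[i], "-",
                            symb$end[i]),
          scaffold = symb$scaffold[i], start = symb$start[i],
          end = symb$end[i], best_bits = symb$best_bits[i],
          best_subject = NA_character_, peptide = NA_character_,
          sources = "symbiont_nt", n_items = 1L, stringsAsFactors = FALSE))
      }
    }
  }
  note("symbiont", "nt_screen", nrow(symb), n_new_symb,
       "loci not already found by the protein arms")

  # ---- paralog expansion --------------------------------------------------
  seeds <- loci[!is.na(loci$peptide), , drop = FALSE]
  # one expansion sweep per gene family is enough
  seeds <- seeds[!duplicated(.family_of(seeds$best_subject)), , drop = FALSE]
  n_par <- 0L
  if (nrow(seeds) > 0) {
    par <- expand_paralogs(
      data.frame(id = seeds$locus_id, peptide = seeds$peptide,
                 scaffold = seeds$scaffold, start = seeds$start,
                 end = seeds$end, stringsAsFactors = FALSE),
      ds$host_assembly, bits_min = config$paralog_bits_min)
    if (nrow(par) > 0) {
      par <- par[!par$scaffold %in% bad_sc, , drop = FALSE]
      for (i in seq_len(nrow(par))) {
        s <- min(par$start[i], par$end[i]); e <- max(par$start[i],
                                                     par$end[i])
        if (.overlaps_any(loci, par$scaffold[i], s, e)) next
        n_par <- n_par + 1L
        loci <- rbind(loci, data.frame(
          locus_id = paste0(par$scaffold[i], ":", s, "-", e),
          scaffold = par$scaffold[i], start = s, end = e,
          best_bits = par$bit_score[i],
          best_subject = loci$best_subject[match(par$seed_id[i],
                                                 loci$locus_id)],
          peptide = NA_character_, sources = "paralog_expansion",
          n_items = 1L, stringsAsFactors = FALSE))
      }
    }
  }
  note("paralog", "tblastn_expansion", nrow(seeds), n_par,
       "additional paralog loci")

  # ---- per-candidate annotation ------------------------------------------
  pg <- list(); placement <- list()
  for (i in seq_len(nrow(loci))) {
    subj <- loci$best_subject[i]
    if (is.na(subj) || !subj %in% names(bac_prot)) next
    homolog <- bac_prot[[subj]]
    pad <- 30L
    L <- nchar(ds$assembly[[loci$scaffold[i]]])
    nt <- extract_region(ds$assembly, loci$scaffold[i],
                         max(1, loci$start[i] - pad),
                         min(L, loci$end[i] + pad))
    rep_i <- annotate_locus(nt, homolog)
    rep_i$locus_id <- loci$locus_id[i]
    rep_i$homolog_id <- subj
    pg[[length(pg) + 1L]] <- rep_i
    fam <- .family_of(subj)
    refs <- bac_prot[paste0(c("donorA1_", "donorA2_", "donorB1_",
                              "donorB2_"), fam)]
    refs <- refs[!is.na(names(refs))]
    lin <- stats::setNames(ifelse(grepl("^donorA", names(refs)),
                                  "donorA", "donorB"), names(refs))
    cand_pep <- if (!is.na(loci$peptide[i])) loci$peptide[i] else
      .candidate_peptide(nt, homolog, psch)
    pl <- if (is.na(cand_pep)) {
      list(call = NA_character_, support = NA_real_)
    } else {
      placement_report(cand_pep, refs, lin,
                       support_min = config$support_min,
                       B = config$b_boot, seed = config$seed)
    }
    placement[[length(placement) + 1L]] <- data.frame(
      locus_id = loci$locus_id[i], family = fam, call = pl$call,
      support = pl$support, stringsAsFactors = FALSE)
  }
  pg <- if (length(pg)) do.call(rbind, pg) else NULL
  placement <- if (length(placement)) do.call(rbind, placement) else NULL

  # ---- qPCR verdicts ------------------------------------------------------
  contam_calls <- if (length(contam_items)) do.call(rbind, contam_items)
    else NULL
  qloci <- data.frame(locus = loci$locus_id,
                      type = rep("genomic", nrow(loci)),
                      stringsAsFactors = FALSE)
  if (!is.null(contam_calls)) {
    take <- utils::head(unique(contam_calls$id), 3)
    qloci <- rbind(qloci, data.frame(locus = take, type = "contaminant",
                                     stringsAsFactors = FALSE))
  }
  qpcr <- simulate_qpcr(qloci, config$generator)
  if (nrow(qpcr) > 0) {
    cn <- copy_number_call(qpcr, alpha = config$alpha, band = config$band)
    cn$truth_type <- qloci$type[match(cn$locus, qloci$locus)]
  } else cn <- NULL

  recovery <- compare_to_truth(loci, ds$truth,
                               contaminant_scaffolds =
                                 names(ds$contaminants))
  funnel <- do.call(rbind, funnel)
  structure(list(funnel = funnel, candidates = loci,
                 contaminant_calls = contam_calls,
                 scaffold_verdicts = verdicts, read_screen = read_screen,
                 pseudogene_reports = pg, placement = placement,
                 copy_number = cn, recovery = recovery, dataset = ds,
                 config = config),
            class = "lgt_report")
}

.overlaps_any <- function(loci, sc, s, e) {
  k <- loci[loci$scaffold == sc, , drop = FALSE]
  nrow(k) > 0 && any(pmin(e, k$end) - pmax(s, k$start) >= 0)
}

# Candidate loci: cores are merged from threshold-passing (strong)
# evidence; sub-threshold locus-extension hits only widen a core when they
# lie within `weak_ext` nt of it, so distant chance hits cannot inflate a
# locus boundary.
.build_loci <- function(items, merge_gap, weak_ext = 150) {
  empty <- data.frame(locus_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      best_bits = numeric(0), best_subject = character(0),
                      peptide = character(0), sources = character(0),
                      n_items = integer(0), stringsAsFactors = FALSE)
  if (length(items) == 0) return(empty)
  df <- do.call(rbind, items)
  if (!"strong" %in% names(df)) df$strong <- TRUE
  if (!any(df$strong)) return(empty)
  out <- list()
  for (sc in unique(df$scaffold)) {
    d <- df[df$scaffold == sc, , drop = FALSE]
    dstrong <- d[d$strong, , drop = FALSE]
    if (nrow(dstrong) == 0) next
    m <- .merge_intervals(dstrong$start, dstrong$end, gap = merge_gap)
    dweak <- d[!d$strong, , drop = FALSE]
    for (r in seq_len(nrow(m))) {
      lo <- m$start[r]; hi <- m$end[r]
      # grow by nearby weak evidence until stable
      repeat {
        near <- dweak$start <= hi + weak_ext & dweak$end >= lo - weak_ext
        if (!any(near)) break
        nlo <- min(lo, dweak$start[near]); nhi <- max(hi, dweak$end[near])
        if (nlo == lo && nhi == hi) break
        lo <- nlo; hi <- nhi
        dweak <- dweak[!near, , drop = FALSE]
      }
      sel <- d$start <= hi & d$end >= lo
      dd <- d[sel, , drop = FALSE]
      best <- which.max(dd$bits)
      peps <- dd$peptide[!is.na(dd$peptide)]
      out[[length(out) + 1L]] <- data.frame(
        locus_id = paste0(sc, ":", lo, "-", hi),
        scaffold = sc, start = lo, end = hi,
        best_bits = dd$bits[best], best_subject = dd$subject[best],
        peptide = if (length(peps)) peps[which.max(nchar(peps))] else
          NA_character_,
        sources = paste(sort(unique(dd$source)), collapse = "+"),
        n_items = nrow(dd), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  # merging by weak extension can make cores collide; unify overlaps
  df <- df[!duplicated(df$locus_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Score candidate loci against a synthetic truth table
#'
#' Loci match truth events by at least 50% reciprocal overlap.  Sensitivity
#' is the fraction of truth events matched; precision the fraction of
#' candidate loci matching a truth event; contaminant precision the
#' fraction of candidates lying on host (non-contaminant) scaffolds.
#'
#' @param candidates Candidate loci data.frame (`scaffold, start, end`).
#' @param truth Truth table from the generator.
#' @param contaminant_scaffolds Ids of contaminant scaffolds (for the
#'   contaminant-precision figure).
#' @return List `sensitivity, precision, contaminant_precision, per_class`
#'   (data.frame of truth classes with matched counts) and `matches`.
#' @export
compare_to_truth <- function(candidates, truth,
                             contaminant_scaffolds = character(0)) {
  matched <- logical(nrow(truth))
  cand_matched <- logical(nrow(candidates))
  matches <- list()
  for (i in seq_len(nrow(truth))) {
    t1 <- min(truth$start[i], truth$end[i])
    t2 <- max(truth$start[i], truth$end[i])
    for (j in seq_len(nrow(candidates))) {
      if (candidates$scaffold[j] != truth$scaffold[i]) next
      c1 <- candidates$start[j]; c2 <- candidates$end[j]
      ov <- min(t2, c2) - max(t1, c1) + 1
      if (ov >= 0.5 * (t2 - t1 + 1) && ov >= 0.5 * (c2 - c1 + 1)) {
        matched[i] <- TRUE
        cand_matched[j] <- TRUE
        matches[[length(matches) + 1L]] <- data.frame(
          event_id = truth$event_id[i],
          locus_id = candidates$locus_id[j], overlap = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_class <- stats::aggregate(matched ~ class,
                                data = cbind(truth, matched = matched),
                                FUN = function(x) c(n = length(x),
                                                    matched = sum(x)))
  per_class <- data.frame(class = per_class$class,
                          n = per_class$matched[, "n"],
                          matched = per_class$matched[, "matched"],
                          stringsAsFactors = FALSE)
  on_contam <- candidates$scaffold %in% contaminant_scaffolds
  list(sensitivity = mean(matched),
       precision = if (nrow(candidates)) mean(cand_matched) else NA_real_,
       contaminant_precision = if (nrow(candidates))
         1 - mean(on_contam) else NA_real_,
       per_class = per_class,
       matches = if (length(matches)) do.call(rbind, matches) else NULL)
}

#' Write a run report to disk
#'
#' Emits the candidate inventory and per-stage funnel as TSV, candidate
#' loci as GFF3, and the verification tables (pseudogene reports,
#' placement calls, copy-number verdicts) as TSV where present.
#'
#' @param report An `lgt_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0)
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  tsv(report$candidates, "candidates.tsv")
  tsv(report$funnel, "funnel.tsv")
  tsv(report$scaffold_verdicts, "scaffold_verdicts.tsv")
  tsv(report$pseudogene_reports, "pseudogene_reports.tsv")
  tsv(report$placement, "placement.tsv")
  tsv(report$copy_number, "copy_number.tsv")
  tsv(report$read_screen, "read_screen.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(funnel = report$funnel, recovery = report$recovery[
        c("sensitivity", "precision", "contaminant_precision")]),
      file.path(dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  cand <- report$candidates
  if (nrow(cand) > 0) {
    write_gff3(data.frame(
      seqid = cand$scaffold, type = "lgt_candidate",
      start = pmin(cand$start, cand$end),
      end = pmax(cand$start, cand$end), strand = ".",
      attributes = paste0("ID=", cand$locus_id, ";sources=",
                          cand$sources),
      stringsAsFactors = FALSE), file.path(dir, "candidates.gff3"))
  }
  invisible(dir)
}

#' @export
print.lgt_report <- function(x, ...) {
  cat("LGT screening report\n")
  cat("  final candidate loci:", nrow(x$candidates), "\n")
  cat("  funnel:\n")
  f <- x$funnel
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %-9s %-26s %6s -> %-6s %s\n", f$arm[i], f$stage[i],
                ifelse(is.na(f$n_in[i]), "", f$n_in[i]), f$n_out[i],
                f$info[i]))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: sensitivity %.3f, precision %.3f, contaminant precision %.3f\n",
                x$recovery$sensitivity, x$recovery$precision,
                x$recovery$contaminant_precision))
  }
  invisible(x)
}
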