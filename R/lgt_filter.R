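# The candidate filter cascade: bacterial screen, invertebrate score
# comparison, contaminant-scaffold and chimeric-read exclusions, weak-hit
# and repeat exclusions, the full-protein recheck, the symbiont nucleotide
# screen and paralog expansion.  Every verdict carries a machine-readable
# reason so the per-stage funnel can be reconstructed.

#' Shannon entropy of a sequence (bits per symbol)
#'
#' @param s Sequence string.
#' @return Entropy of the symbol frequency distribution.
#' @export
shannon_entropy <- function(s) {
  if (nchar(s) == 0) return(0)
  cnt <- tabulate(as.integer(charToRaw(s)), nbins = 256)
  p <- cnt[cnt > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Minimum sliding-window entropy
#'
#' Low-complexity detector: the smallest Shannon entropy over sliding
#' windows (stride 10).
#'
#' @param s Sequence string.
#' @param window Window length (default 20).
#' @return Minimum entropy in bits/symbol; the whole-sequence entropy when
#'   shorter than `window`.
#' @export
min_window_entropy <- function(s, window = 20) {
  n <- nchar(s)
  if (n <= window) return(shannon_entropy(s))
  starts <- unique(c(seq(1, n - window + 1, by = 10), n - window + 1))
  min(vapply(starts, function(i) shannon_entropy(substr(s, i, i + window - 1)),
             numeric(1)))
}

#' Tandem-repeat fraction by autocorrelation
#'
#' The largest fraction of positions matching themselves at a lag of
#' 1..`max_period` symbols; near 1 for tandem repeats with a short unit.
#'
#' @param s Sequence string.
#' @param max_period Largest repeat unit considered (default 12).
#' @return Fraction in `[0, 1]` (0 for sequences shorter than 2 symbols).
#' @export
tandem_repeat_fraction <- function(s, max_period = 12) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) return(0)
  best <- 0
  for (p in seq_len(min(max_period, n - 1))) {
    f <- mean(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])
    if (f > best) best <- f
  }
  best
}

#' Bacterial similarity screen
#'
#' An item survives iff its best bacterial hit reaches the mode's bit
#' threshold (protein and translated searches 40 bits, nucleotide 55 bits).
#'
#' @param seqs Named character vector of query sequences.
#' @param bacterial_db Named character vector (protein or nucleotide).
#' @param mode `"prot-prot"`, `"translated-query"` or `"nt-nt"`.
#' @param bits_min Bit threshold; defaults to 40 (protein/translated) or 55
#'   (nucleotide).
#' @param ... Passed to [search_hits()].
#' @return List with `hits` (all hits at the threshold), `best` (best hit
#'   per surviving query) and `verdicts` (data.frame `id, pass, reason`).
#' @export
bacterial_screen <- function(seqs, bacterial_db,
                             mode = c("prot-prot", "translated-query",
                                      "nt-nt"),
                             bits_min = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(bits_min)) bits_min <- if (mode == "nt-nt") 55 else 40
  hits <- search_hits(seqs, bacterial_db, mode = mode, bits_min = bits_min,
                      db_tag = "bacterial", ...)
  bh <- best_hits(hits)
  pass <- names(seqs) %in% bh$query_id
  verdicts <- data.frame(
    id = names(seqs), pass = pass,
    reason = ifelse(pass, "", "no_bacterial_hit"),
    stringsAsFactors = FALSE)
  list(hits = hits, best = bh, verdicts = verdicts)
}

.interval_overlap <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1) + 1L)
}

#' Bacterial-versus-invertebrate score comparison
#'
#' A candidate passes when its best bacterial bit score exceeds its best
#' invertebrate bit score by more than `margin_bits` (no invertebrate hit
#' passes trivially).  When the two best hits cover one common query region
#' and the invertebrate score is at least `bacterial - margin_bits`, the
#' candidate is an evolutionarily conserved gene rather than a transfer
#' candidate.
#'
#' @param bac_best Best bacterial hit per query (one row per query).
#' @param inv_best Best invertebrate hit per query.
#' @param margin_bits Required margin in bits (default 0: strictly better).
#' @return data.frame `id, pass, reason` with reason `conserved_gene` or
#'   `invertebrate_better` on failure.
#' @export
invertebrate_comparison <- function(bac_best, inv_best, margin_bits = 0) {
  out <- lapply(seq_len(nrow(bac_best)), function(i) {
    qid <- bac_best$query_id[i]
    j <- match(qid, inv_best$query_id)
    if (is.na(j)) {
      return(data.frame(id = qid, pass = TRUE, reason = "",
                        stringsAsFactors = FALSE))
    }
    bb <- bac_best$bit_score[i]; ib <- inv_best$bit_score[j]
    if (bb - ib > margin_bits) {
      return(data.frame(id = qid, pass = TRUE, reason = "",
                        stringsAsFactors = FALSE))
    }
    b1 <- min(bac_best$q_start[i], bac_best$q_end[i])
    b2 <- max(bac_best$q_start[i], bac_best$q_end[i])
    i1 <- min(inv_best$q_start[j], inv_best$q_end[j])
    i2 <- max(inv_best$q_start[j], inv_best$q_end[j])
    ov <- .interval_overlap(b1, b2, i1, i2)
    shared <- ov >= 0.5 * min(b2 - b1 + 1L, i2 - i1 + 1L)
    data.frame(id = qid, pass = FALSE,
               reason = if (shared) "conserved_gene" else
                 "invertebrate_better",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Full-length protein recheck
#'
#' When a surviving candidate is part of a predicted full-length protein,
#' the whole protein is re-searched: it fails (animal origin) when the best
#' animal bit score comes within `delta_min` bits of the best bacterial one.
#'
#' @param protein Full-length protein sequence (single string).
#' @param bacterial_db,animal_db Named protein databases.
#' @param delta_min Required bacterial-minus-animal margin (default 13).
#' @param scheme Protein scoring scheme.
#' @return List `pass, reason, bac_bits, animal_bits`.
#' @export
full_protein_recheck <- function(protein, bacterial_db, animal_db,
                                 delta_min = 13,
                                 scheme = scoring_scheme("protein")) {
  q <- c(full_protein = protein)
  bb <- best_hits(search_hits(q, bacterial_db, "prot-prot", scheme,
                              db_tag = "bacterial"))
  ab <- best_hits(search_hits(q, animal_db, "prot-prot", scheme,
                              db_tag = "animal"))
  bac <- if (nrow(bb)) bb$bit_score[1] else NA_real_
  ani <- if (nrow(ab)) ab$bit_score[1] else NA_real_
  if (is.na(bac)) {
    return(list(pass = FALSE, reason = "no_bacterial_hit",
                bac_bits = bac, animal_bits = ani))
  }
  if (is.na(ani)) {
    return(list(pass = TRUE, reason = "", bac_bits = bac,
                animal_bits = ani))
  }
  if (ani >= bac - delta_min) {
    list(pass = FALSE, reason = "animal_origin", bac_bits = bac,
         animal_bits = ani)
  } else {
    list(pass = TRUE, reason = "", bac_bits = bac, animal_bits = ani)
  }
}

#' Weak-similarity, tandem-repeat and low-complexity exclusion
#'
#' Fails `weak` when the best bacterial hit has bit score <= 45 *and*
#' E-value >= 0.001 (the rule is a conjunction); fails `repeat` when the
#' aligned query region is dominated by a short-period tandem repeat; fails
#' `low_complexity` when the aligned region's sliding-window entropy is
#' below `entropy_min`.
#'
#' @param query_seq The candidate's sequence.
#' @param best_hit One-row hit table with the best bacterial hit.
#' @param weak_bits_max,weak_e_min The weak rule thresholds (45, 0.001).
#' @param repeat_frac_min Tandem-repeat fraction threshold (default 0.75).
#' @param entropy_min Entropy threshold in bits/symbol (default 1.5).
#' @return List `pass, reason`.
#' @export
weak_and_repeat_filter <- function(query_seq, best_hit,
                                   weak_bits_max = 45, weak_e_min = 0.001,
                                   repeat_frac_min = 0.75,
                                   entropy_min = 1.5) {
  if (nrow(best_hit) == 0)
    return(list(pass = FALSE, reason = "no_hit"))
  bits <- best_hit$bit_score[1]
  ev <- best_hit$e_value[1]
  if (bits <= weak_bits_max && ev >= weak_e_min)
    return(list(pass = FALSE, reason = "weak"))
  q1 <- min(best_hit$q_start[1], best_hit$q_end[1])
  q2 <- max(best_hit$q_start[1], best_hit$q_end[1])
  region <- substr(query_seq, q1, q2)
  if (tandem_repeat_fraction(region) >= repeat_frac_min)
    return(list(pass = FALSE, reason = "repeat"))
  if (min_window_entropy(region) < entropy_min)
    return(list(pass = FALSE, reason = "low_complexity"))
  list(pass = TRUE, reason = "")
}

# ---- seeded mapping ------------------------------------------------------

# optimal gapless local alignment restricted to one diagonal (exact when
# the true alignment has no indels): vectorized maximum-subarray scan.
# `diag` is the 0-based offset b_index - a_index.
.diag_local <- function(a, b, diag, scheme) {
  la <- nchar(a); lb <- nchar(b)
  i1 <- max(1L, 1L - diag); i2 <- min(la, lb - diag)
  if (i2 - i1 + 1L < 1L) return(NULL)
  ca <- strsplit(substr(a, i1, i2), "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(b, i1 + diag, i2 + diag), "", fixed = TRUE)[[1]]
  sc <- scheme$matrix[cbind(ca, cb)]
  P <- cumsum(sc)
  low <- cummin(c(0, P[-length(P)]))
  gains <- P - low
  score <- max(gains)
  if (score <= 0) return(NULL)
  e <- which.max(gains)
  s <- which(c(0, P[-length(P)]) == low[e])
  s <- s[s <= e][1]
  rng <- s:e
  list(score = as.integer(score),
       a_start = i1 + s - 1L, a_end = i1 + e - 1L,
       b_start = i1 + diag + s - 1L, b_end = i1 + diag + e - 1L,
       n_ident = sum(ca[rng] == cb[rng]), n_cols = length(rng),
       aln_len = length(rng),
       identity = sum(ca[rng] == cb[rng]) / length(rng))
}

# Map queries onto a set of (possibly long) subject sequences: exact-word
# seeding (word size `word`), seed clusters turned into bounded
# Smith-Waterman problems.  Returns a hit table; both query orientations
# are searched and hit q_start > q_end encodes a minus-strand hit.
.nt_map <- function(queries, subjects, scheme = scoring_scheme("nucleotide"),
                    bits_min = 55, word = 16L, pad = 300L,
                    cluster_gap = 2000L) {
  if (length(subjects) == 0 || length(queries) == 0) return(.empty_hits())
  concat <- paste(subjects, collapse = ".")
  offsets <- cumsum(c(0L, nchar(subjects) + 1L))[seq_along(subjects)]
  n_db <- sum(nchar(subjects))
  min_raw <- .raw_for_bits(bits_min, scheme)
  orient <- list(`+` = queries, `-` = stats::setNames(revcomp(queries),
                                                      names(queries)))
  rows <- list()
  for (strand in names(orient)) {
    qs <- orient[[strand]]
    seeds <- cpp_seed_hits(qs, concat, word)
    for (qi in seq_along(qs)) {
      sp <- seeds[[qi]]$s
      if (length(sp) == 0) next
      qp <- seeds[[qi]]$q
      qlen <- nchar(qs[[qi]])
      # which subject each seed falls in
      sub_idx <- findInterval(sp, offsets)
      for (si in unique(sub_idx)) {
        sel <- sub_idx == si
        o <- order(sp[sel])
        pos <- (sp[sel] - offsets[si])[o]  # 0-based within subject
        qpos <- qp[sel][o]
        # split into clusters separated by > cluster_gap
        grp <- cumsum(c(1L, diff(pos) > cluster_gap))
        for (g in unique(grp)) {
          p <- pos[grp == g]
          diag <- p - qpos[grp == g]
          if (length(unique(diag)) == 1L) {
            # gapless case: exact diagonal-restricted alignment
            al <- .diag_local(qs[[qi]], subjects[[si]], diag[1], scheme)
            if (is.null(al) || al$score < min_raw) next
            w1 <- 1L
          } else {
            # the subject window implied by the seed diagonals, plus slack
            w1 <- max(1L, min(diag) + 1L - pad)
            w2 <- min(nchar(subjects[[si]]),
                      max(diag) + qlen + word + pad)
            al <- sw_align(qs[[qi]], substr(subjects[[si]], w1, w2), scheme)
            if (al$score < min_raw) next
          }
          bits <- bit_score(al$score, scheme)
          if (strand == "+") {
            q_start <- al$a_start; q_end <- al$a_end
          } else {
            q_start <- qlen - al$a_start + 1L
            q_end <- qlen - al$a_end + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = names(qs)[qi], subject_id = names(subjects)[si],
            subject_db = "nt", pident = 100 * al$identity,
            aln_len = al$aln_len, q_start = q_start, q_end = q_end,
            s_start = w1 + al$b_start - 1L, s_end = w1 + al$b_end - 1L,
            frame = 0L, raw_score = al$score, bit_score = bits,
            e_value = e_value(bits, qlen, n_db),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(.empty_hits())
  out <- do.call(rbind, rows)
  # deduplicate overlapping windows: keep best per (query, subject, region)
  out <- out[order(out$query_id, out$subject_id, -out$bit_score), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$query_id == out$query_id[i] &
                 out$subject_id == out$subject_id[i])
    if (length(j) == 0) next
    qi1 <- pmin(out$q_start[j], out$q_end[j])
    qi2 <- pmax(out$q_start[j], out$q_end[j])
    a1 <- min(out$q_start[i], out$q_end[i])
    a2 <- max(out$q_start[i], out$q_end[i])
    ov <- pmin(a2, qi2) - pmax(a1, qi1) + 1
    keep[j[ov > 0.5 * (qi2 - qi1 + 1)]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.merge_intervals <- function(starts, ends, gap = 0L) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + gap + 1L) {
      me <- max(me, ends[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  data.frame(start = vapply(out, `[`, numeric(1), 1),
             end = vapply(out, `[`, numeric(1), 2))
}

#' Classify assembly scaffolds as host, contaminant or chimeric
#'
#' A scaffold is a bacterial contaminant when near-identical bacterial
#' nucleotide hits (identity >= `contaminant_identity_min`) cover at least
#' `contaminant_coverage_min` of its length and it has no host evidence, or
#' when it is shorter than `short_len` with no host evidence.  A scaffold
#' carrying a short (< `chimera_seg_max` nt) near-identical bacterial
#' segment inside otherwise host sequence is a chimeric assembly artifact
#' when the segment has single-read support.
#'
#' @param assembly Named character vector of scaffolds.
#' @param bacterial_nt_db Named nucleotide database (donor genomes).
#' @param host_hits Named logical: whether each scaffold has a significant
#'   hit to host/animal evidence (absent names are treated as `FALSE`).
#' @param read_support Optional function `(scaffold, start, end) ->` number
#'   of reads covering the segment; used for the chimeric-scaffold rule.
#' @param contaminant_identity_min,contaminant_coverage_min Near-identity
#'   and coverage thresholds (defaults 0.90 and 0.50).
#' @param short_len Short-scaffold rule length (default 2000).
#' @param chimera_seg_max Maximum chimeric segment length (default 1000).
#' @param bits_min Nucleotide hit threshold in bits (default 55).
#' @return data.frame `scaffold, length, bac_coverage, host_hit, class`
#'   with class in `{host, contaminant, chimeric_scaffold}`.
#' @export
classify_scaffolds <- function(assembly, bacterial_nt_db,
                               host_hits = NULL, read_support = NULL,
                               contaminant_identity_min = 0.90,
                               contaminant_coverage_min = 0.50,
                               short_len = 2000, chimera_seg_max = 1000,
                               bits_min = 55) {
  hh <- function(sc) {
    !is.null(host_hits) && !is.na(host_hits[sc]) && isTRUE(host_hits[[sc]])
  }
  # chunk scaffolds so alignment problems stay bounded
  chunks <- make_windows(assembly, window_len = 1000, overlap = 0)
  qs <- stats::setNames(chunks$seq, chunks$window_id)
  hits <- .nt_map(qs, bacterial_nt_db, bits_min = bits_min)
  hits <- hits[hits$pident >= 100 * contaminant_identity_min, , drop = FALSE]
  out <- list()
  for (sc in names(assembly)) {
    L <- nchar(assembly[[sc]])
    sel <- chunks$scaffold == sc
    ids <- chunks$window_id[sel]
    h <- hits[hits$query_id %in% ids, , drop = FALSE]
    cov <- 0; segs <- NULL
    if (nrow(h) > 0) {
      off <- chunks$start[match(h$query_id, chunks$window_id)] - 1L
      s1 <- off + pmin(h$q_start, h$q_end)
      s2 <- off + pmax(h$q_start, h$q_end)
      segs <- .merge_intervals(s1, s2, gap = 50L)
      cov <- sum(segs$end - segs$start + 1) / L
    }
    class <- "host"
    if (cov >= contaminant_coverage_min && !hh(sc)) {
      class <- "contaminant"
    } else if (L < short_len && !hh(sc)) {
      class <- "contaminant"
    } else if (!is.null(segs) && cov > 0 &&
               sum(segs$end - segs$start + 1) < chimera_seg_max) {
      support <- if (is.null(read_support)) 1L else
        min(vapply(seq_len(nrow(segs)), function(i)
          read_support(sc, segs$start[i], segs$end[i]), numeric(1)))
      if (support <= 1) class <- "chimeric_scaffold"
    }
    out[[sc]] <- data.frame(scaffold = sc, length = L, bac_coverage = cov,
                            host_hit = hh(sc), class = class,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Detect chimeric host-bacteria reads
#'
#' Vector-matching and low-complexity reads are excluded first.  A read is
#' chimeric when it carries a bacterial-only and a host-only aligned region,
#' each at least `region_min` nt, overlapping each other by at most
#' `junction_overlap_max` nt.  Chimeric reads sharing a junction (same host
#' scaffold, host-side position within `junction_tol`) with at least
#' `min_support` reads are lateral-transfer evidence; singletons are
#' cloning/sequencing artifacts.
#'
#' @param reads Named character vector of reads.
#' @param bacterial_nt_db Named nucleotide donor/symbiont database.
#' @param host_db Named nucleotide host database (assembly scaffolds).
#' @param vector_db Optional named vector-sequence database (e.g. cloning
#'   vectors).
#' @param region_min Minimum length of each region (default 100 nt).
#' @param junction_overlap_max Maximum overlap between the two regions
#'   (default 30 nt).
#' @param min_support Reads required at a junction for transfer evidence
#'   (default 2).
#' @param junction_tol Positional tolerance when grouping junctions
#'   (default 50 nt).
#' @param entropy_min Low-complexity threshold in bits/symbol (default
#'   1.2: homopolymers score 0 and short tandem repeats about 1, while
#'   ordinary AT-rich genomic sequence stays near 1.9).
#' @param bits_min Nucleotide hit threshold (default 55 bits).
#' @return data.frame `read_id, class, scaffold, junction` with class in
#'   `{vector, low_complexity, no_hit, host_only, bacterial_only,
#'   conserved, chimera_artifact, chimera_lgt}`.
#' @export
detect_chimeric_reads <- function(reads, bacterial_nt_db, host_db,
                                  vector_db = NULL, region_min = 100,
                                  junction_overlap_max = 30,
                                  min_support = 2, junction_tol = 50,
                                  entropy_min = 1.2, bits_min = 55) {
  res <- data.frame(read_id = names(reads), class = "no_hit",
                    scaffold = NA_character_, junction = NA_real_,
                    stringsAsFactors = FALSE)
  active <- rep(TRUE, length(reads))
  if (!is.null(vector_db) && length(vector_db) > 0) {
    vh <- .nt_map(reads, vector_db, bits_min = bits_min)
    hit <- res$read_id %in% vh$query_id
    res$class[hit] <- "vector"
    active[hit] <- FALSE
  }
  lowc <- vapply(reads, function(r) min_window_entropy(r, 40) < entropy_min,
                 logical(1))
  res$class[active & lowc] <- "low_complexity"
  active[lowc] <- FALSE

  act_reads <- reads[active]
  if (length(act_reads) > 0) {
    bh <- .nt_map(act_reads, bacterial_nt_db, bits_min = bits_min)
    hh <- .nt_map(act_reads, host_db, bits_min = bits_min)
    for (rid in names(act_reads)) {
      b <- bh[bh$query_id == rid, , drop = FALSE]
      h <- hh[hh$query_id == rid, , drop = FALSE]
      i <- match(rid, res$read_id)
      if (nrow(b) == 0 && nrow(h) == 0) next
      if (nrow(b) == 0) { res$class[i] <- "host_only"; next }
      if (nrow(h) == 0) { res$class[i] <- "bacterial_only"; next }
      breg <- .merge_intervals(pmin(b$q_start, b$q_end),
                               pmax(b$q_start, b$q_end), gap = 20L)
      hreg <- .merge_intervals(pmin(h$q_start, h$q_end),
                               pmax(h$q_start, h$q_end), gap = 20L)
      found <- FALSE
      for (bi in seq_len(nrow(breg))) {
        if (breg$end[bi] - breg$start[bi] + 1 < region_min) next
        # the bacterial region must not itself be host-similar
        ov_h <- max(0, max(vapply(seq_len(nrow(hreg)), function(hi)
          .interval_overlap(breg$start[bi], breg$end[bi],
                            hreg$start[hi], hreg$end[hi]), numeric(1))))
        if (ov_h > junction_overlap_max) next
        for (hi in seq_len(nrow(hreg))) {
          if (hreg$end[hi] - hreg$start[hi] + 1 < region_min) next
          ov_b <- max(0, max(vapply(seq_len(nrow(breg)), function(bj)
            .interval_overlap(hreg$start[hi], hreg$end[hi],
                              breg$start[bj], breg$end[bj]), numeric(1))))
          if (ov_b > junction_overlap_max) next
          # host-side anchor of the junction
          hrow <- h[which.max(h$bit_score), , drop = FALSE]
          host_inner <- if (hreg$start[hi] < breg$start[bi])
            max(hrow$s_start, hrow$s_end) else min(hrow$s_start, hrow$s_end)
          res$class[i] <- "chimera_artifact"  # upgraded below by support
          res$scaffold[i] <- hrow$subject_id
          res$junction[i] <- host_inner
          found <- TRUE
          break
        }
        if (found) break
      }
      if (!found) res$class[i] <- "conserved"
    }
  }
  # junction support among chimeric reads
  chim <- which(res$class == "chimera_artifact")
  if (length(chim) > 0) {
    for (i in chim) {
      same <- chim[res$scaffold[chim] == res$scaffold[i] &
                     abs(res$junction[chim] - res$junction[i]) <=
                     junction_tol]
      if (length(same) >= min_support) res$class[i] <- "chimera_lgt"
    }
  }
  res
}

#' Nucleotide screen with symbiont genomes
#'
#' Symbiont genome chunks are searched against the assembly; hit loci below
#' `e_max` are merged and reported as candidate non-coding transfer loci,
#' after removing loci on scaffolds classified as contaminant or chimeric.
#' When an animal nucleotide database is supplied, each locus is re-searched
#' against it and dropped when its best animal hit reaches its symbiont
#' score: such loci are evolutionarily conserved sequence, not transfers.
#'
#' @param symbiont_genomes Named nucleotide sequences (symbiont genomes).
#' @param assembly Named character vector of scaffolds.
#' @param e_max E-value ceiling (default 1e-5).
#' @param scaffold_verdicts Optional output of [classify_scaffolds()].
#' @param animal_nt_db Optional named nucleotide database for the
#'   back-search exclusion.
#' @param bits_min Seed-stage bit threshold (default 55).
#' @return data.frame `scaffold, start, end, best_bits` of candidate loci.
#' @export
symbiont_nt_screen <- function(symbiont_genomes, assembly, e_max = 1e-5,
                               scaffold_verdicts = NULL,
                               animal_nt_db = NULL, bits_min = 55) {
  chunks <- make_windows(symbiont_genomes, window_len = 2000, overlap = 200)
  qs <- stats::setNames(chunks$seq, chunks$window_id)
  hits <- .nt_map(qs, assembly, bits_min = bits_min)
  hits <- hits[hits$e_value < e_max, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), best_bits = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(scaffold_verdicts)) {
    bad <- scaffold_verdicts$scaffold[scaffold_verdicts$class != "host"]
    hits <- hits[!hits$subject_id %in% bad, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), best_bits = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (sc in unique(hits$subject_id)) {
    h <- hits[hits$subject_id == sc, , drop = FALSE]
    m <- .merge_intervals(pmin(h$s_start, h$s_end),
                          pmax(h$s_start, h$s_end), gap = 100L)
    for (i in seq_len(nrow(m))) {
      sel <- pmin(h$s_start, h$s_end) <= m$end[i] &
        pmax(h$s_start, h$s_end) >= m$start[i]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc, start = m$start[i], end = m$end[i],
        best_bits = max(h$bit_score[sel]), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  if (!is.null(animal_nt_db) && nrow(df) > 0) {
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      seg <- substr(assembly[[df$scaffold[i]]], df$start[i], df$end[i])
      # diverged animal homologs share only short exact words: seed the
      # back-search at word 11 so a conserved gene is not missed
      ah <- .nt_map(stats::setNames(seg, "locus"), animal_nt_db,
                    bits_min = bits_min, word = 11L)
      if (nrow(ah) > 0 && max(ah$bit_score) >= df$best_bits[i])
        keep[i] <- FALSE
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

# iteratively collect HSPs of `query` against `subject`, masking the
# subject region of each accepted HSP; returns a list of sw_align records
.iterate_hsps <- function(query, subject, scheme, bits_min = 22,
                          max_hsps = 40) {
  min_raw <- .raw_for_bits(bits_min, scheme)
  out <- list()
  for (k in seq_len(max_hsps)) {
    al <- tryCatch(sw_align(query, subject, scheme), error = function(e) NULL)
    if (is.null(al) || al$score < min_raw) break
    out[[k]] <- al
    substr(subject, al$b_start, al$b_end) <-
      strrep(.MASK_CHAR, al$b_end - al$b_start + 1L)
  }
  out
}

#' Expand confirmed candidates to further paralogous loci
#'
#' A translated search of each confirmed candidate peptide against the
#' assembly (the in-package analogue of a TBLASTN paralog sweep): every
#' non-overlapping locus reaching `bits_min` that does not overlap an
#' already-known candidate locus is reported as an additional paralog,
#' linked to its seed.
#'
#' @param candidates data.frame with columns `id, peptide, scaffold, start,
#'   end` (the confirmed candidates and their loci).
#' @param assembly Named character vector of scaffolds.
#' @param bits_min Bit threshold for paralog loci (default 40).
#' @param scheme Protein scoring scheme.
#' @return data.frame `seed_id, scaffold, start, end, bit_score` of new
#'   paralog loci (strand encoded by `start > end`).
#' @export
expand_paralogs <- function(candidates, assembly, bits_min = 40,
                            scheme = scoring_scheme("protein")) {
  known <- data.frame(scaffold = candidates$scaffold,
                      start = pmin(candidates$start, candidates$end),
                      end = pmax(candidates$start, candidates$end))
  found <- list()
  overlaps_known <- function(sc, s, e) {
    k <- known[known$scaffold == sc, , drop = FALSE]
    nrow(k) > 0 && any(pmin(e, k$end) - pmax(s, k$start) + 1 >
                         0.25 * (e - s + 1))
  }
  for (ci in seq_len(nrow(candidates))) {
    pep <- candidates$peptide[ci]
    if (is.na(pep) || nchar(pep) < 30) next
    for (sc in names(assembly)) {
      frames <- six_frame(assembly[[sc]])
      L <- nchar(assembly[[sc]])
      for (fname in names(frames)) {
        faa <- frames[[fname]]
        if (nchar(faa) < 20) next
        off <- abs(as.integer(fname)) - 1L
        minus <- startsWith(fname, "-")
        hsps <- .iterate_hsps(pep, faa, scheme, bits_min = bits_min,
                              max_hsps = 8)
        for (al in hsps) {
          nt1 <- off + 3L * (al$b_start - 1L) + 1L
          nt2 <- off + 3L * al$b_end
          if (minus) {
            g1 <- L - nt1 + 1L; g2 <- L - nt2 + 1L
          } else {
            g1 <- nt1; g2 <- nt2
          }
          s <- min(g1, g2); e <- max(g1, g2)
          if (overlaps_known(sc, s, e)) next
          found[[length(found) + 1L]] <- data.frame(
            seed_id = candidates$id[ci], scaffold = sc, start = g1,
            end = g2, bit_score = bit_score(al$score, scheme),
            stringsAsFactors = FALSE)
          known <- rbind(known, data.frame(scaffold = sc, start = s,
                                           end = e))
        }
      }
    }
  }
  if (length(found) == 0) {
    return(data.frame(seed_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, found)
  rownames(df) <- NULL
  df
}
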