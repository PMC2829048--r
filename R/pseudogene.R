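# Pseudogene annotation: a candidate locus is aligned to its donor homolog
# by three-frame local-alignment stitching.  Frame segments are chained at
# minimal-cost junctions; a junction whose nucleotide offset is not a
# multiple of three (and too short to be an intron) counts one frameshift;
# stop codons inside aligned spans are internal stops; the aligned homolog
# span gives the truncation fraction.

# the annotation scheme: high-stringency matrix and prohibitive gap
# penalties, so alignments never extend across non-homologous sequence and
# every indel becomes a stitching junction
.annotation_scheme <- function() {
  scoring_scheme("protein-strict", gap_open = 10000, gap_extend = 10)
}

# decompose one pairwise alignment into sub-segments separated by score
# drops of at least `drop` (raw score units), trimming each segment to its
# maximal-scoring span.  Returns a list of column ranges.
.split_alignment <- function(al, scheme, drop) {
  acols <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
  bcols <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
  n <- length(acols)
  sc <- numeric(n)
  in_gap <- FALSE
  for (c in seq_len(n)) {
    if (acols[c] == "-" || bcols[c] == "-") {
      sc[c] <- -(if (in_gap) scheme$gap_extend else
        scheme$gap_open + scheme$gap_extend)
      in_gap <- TRUE
    } else {
      sc[c] <- scheme$matrix[acols[c], bcols[c]]
      in_gap <- FALSE
    }
  }
  segs <- list()
  cur_start <- 1L; run <- 0; peak <- 0; peak_end <- 0L
  flush <- function() {
    if (peak > 0 && peak_end >= cur_start)
      segs[[length(segs) + 1L]] <<- c(cur_start, peak_end, peak)
  }
  for (c in seq_len(n)) {
    if (run == 0 && sc[c] < 0) { cur_start <- c + 1L; next }
    run <- run + sc[c]
    if (run > peak) { peak <- run; peak_end <- c }
    if (run < 0 || peak - run >= drop) {
      flush()
      run <- 0; peak <- 0; cur_start <- c + 1L; peak_end <- c
    }
  }
  flush()
  segs
}

# collect HSPs of homolog vs all three forward-frame translations,
# decomposed at score drops so each HSP is one homologous segment
.frame_hsps <- function(locus_nt, homolog, scheme, hsp_bits_min,
                        drop_split = 35) {
  min_raw <- .raw_for_bits(hsp_bits_min, scheme)
  hsps <- list()
  for (off in 0:2) {
    faa <- translate_nt(locus_nt, off)
    if (nchar(faa) < 8) next
    for (al in .iterate_hsps(homolog, faa, scheme,
                             bits_min = hsp_bits_min)) {
      acols <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      bcols <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      # cumulative residue positions per column
      apos <- al$a_start - 1L + cumsum(acols != "-")
      bpos <- al$b_start - 1L + cumsum(bcols != "-")
      for (seg in .split_alignment(al, scheme, drop_split)) {
        c1 <- seg[1]; c2 <- seg[2]
        if (seg[3] < min_raw) next
        cols <- c1:c2
        match_cols <- cols[acols[cols] != "-" & bcols[cols] != "-"]
        if (length(match_cols) == 0) next
        stops <- bpos[match_cols][bcols[match_cols] == "*"]
        hsps[[length(hsps) + 1L]] <- list(
          frame = off, score = seg[3],
          p_start = apos[match_cols[1]], p_end = apos[match_cols[length(match_cols)]],
          nt_start = off + 3L * (bpos[match_cols[1]] - 1L) + 1L,
          nt_end = off + 3L * bpos[match_cols[length(match_cols)]],
          n_ident = sum(acols[match_cols] == bcols[match_cols]),
          n_cols = length(match_cols),
          stop_pos = off + 3L * (stops - 1L) + 1L)
      }
    }
  }
  hsps
}

# chain HSPs colinearly (increasing protein and nt coordinates, small
# overlaps tolerated), maximizing total raw score
.chain_hsps <- function(hsps, aa_slop = 10L, nt_slop = 30L) {
  if (length(hsps) == 0) return(list())
  o <- order(vapply(hsps, `[[`, numeric(1), "p_start"))
  hsps <- hsps[o]
  n <- length(hsps)
  dp <- vapply(hsps, `[[`, numeric(1), "score")
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- hsps[[j]]$p_end <= hsps[[i]]$p_start + aa_slop &&
        hsps[[j]]$p_start < hsps[[i]]$p_start &&
        hsps[[j]]$nt_end <= hsps[[i]]$nt_start + nt_slop &&
        hsps[[j]]$nt_start < hsps[[i]]$nt_start
      if (ok && dp[j] + hsps[[i]]$score > dp[i]) {
        dp[i] <- dp[j] + hsps[[i]]$score
        prev[i] <- j
      }
    }
  }
  i <- which.max(dp)
  chain <- integer(0)
  while (!is.na(i)) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  hsps[chain]
}

#' Annotate a candidate locus against a donor homolog
#'
#' @param locus_nt Nucleotide sequence of the locus (both orientations are
#'   tried by default; the better-scoring one is annotated).
#' @param homolog Donor homolog protein sequence (>= 30 aa).
#' @param scheme Protein scoring scheme.
#' @param hsp_bits_min Bit threshold for individual frame segments
#'   (default 22).
#' @param bits_min Minimum total chained bit score for a report
#'   (default 25).
#' @param intron_min Junction gaps of at least this many nt are treated as
#'   intron-like gaps, never as frameshifts (default 40).
#' @param intact_min Minimum truncation fraction for an intact call
#'   (default 0.9).
#' @return A one-row data.frame (`PseudogeneReport`): `n_frameshifts,
#'   n_internal_stops, truncation_fraction, identity_aa, intact, n_segments,
#'   orientation, total_bits` — or, when no alignment reaches `bits_min`, a
#'   row of `NA`s with `reason = "no_alignment"`.
#' @export
annotate_locus <- function(locus_nt, homolog,
                           scheme = .annotation_scheme(),
                           hsp_bits_min = 22, bits_min = 25,
                           intron_min = 40, intact_min = 0.9) {
  if (nchar(homolog) < 30) stop("homolog shorter than 30 aa")
  empty <- data.frame(n_frameshifts = NA_integer_,
                      n_internal_stops = NA_integer_,
                      truncation_fraction = NA_real_,
                      identity_aa = NA_real_, intact = NA,
                      n_segments = 0L, orientation = NA_character_,
                      total_bits = NA_real_, reason = "no_alignment",
                      stringsAsFactors = FALSE)
  best <- NULL
  for (orient in c("+", "-")) {
    nt <- if (orient == "+") locus_nt else revcomp(locus_nt)
    chain <- .chain_hsps(.frame_hsps(nt, homolog, scheme, hsp_bits_min))
    if (length(chain) == 0) next
    tot <- sum(vapply(chain, `[[`, numeric(1), "score"))
    if (is.null(best) || tot > best$tot)
      best <- list(chain = chain, tot = tot, orient = orient)
  }
  if (is.null(best) || bit_score(best$tot, scheme) < bits_min) return(empty)
  chain <- best$chain
  nt_used <- if (best$orient == "+") locus_nt else revcomp(locus_nt)
  n_fs <- 0L
  junction_stops <- integer(0)
  if (length(chain) > 1) {
    for (i in seq_along(chain)[-1]) {
      d_nt <- chain[[i]]$nt_start - chain[[i - 1]]$nt_end - 1L
      d_aa <- chain[[i]]$p_start - chain[[i - 1]]$p_end - 1L
      if (d_nt >= intron_min) next  # intron-like gap
      if ((d_nt - 3L * d_aa) %% 3L != 0L) {
        n_fs <- n_fs + 1L
      } else if (d_nt > 0 && d_aa <= 2 && d_nt <= 9) {
        # frame-preserving short junction: stops in the skipped stretch
        # (segments break at stop codons the aligner refuses to cross)
        gap_nt <- substr(nt_used, chain[[i - 1]]$nt_end + 1L,
                         chain[[i]]$nt_start - 1L)
        aa <- translate_nt(gap_nt, 0)
        hit <- gregexpr("*", aa, fixed = TRUE)[[1]]
        if (hit[1] != -1) {
          junction_stops <- c(junction_stops,
                              chain[[i - 1]]$nt_end + 3L * (hit - 1L) + 1L)
        }
      }
    }
  }
  stop_pos <- unique(c(unlist(lapply(chain, `[[`, "stop_pos")),
                       junction_stops))
  span <- max(vapply(chain, `[[`, numeric(1), "p_end")) -
    min(vapply(chain, `[[`, numeric(1), "p_start")) + 1
  trunc <- span / nchar(homolog)
  ident <- sum(vapply(chain, `[[`, numeric(1), "n_ident")) /
    sum(vapply(chain, `[[`, numeric(1), "n_cols"))
  data.frame(n_frameshifts = n_fs,
             n_internal_stops = length(stop_pos),
             truncation_fraction = trunc, identity_aa = ident,
             intact = n_fs == 0L && length(stop_pos) == 0L &&
               trunc >= intact_min,
             n_segments = length(chain), orientation = best$orient,
             total_bits = bit_score(best$tot, scheme), reason = "",
             stringsAsFactors = FALSE)
}

#' Infer exon/intron structure of a locus from a homolog
#'
#' Chained homolog alignments give approximate exons; junction gaps of at
#' least `intron_min` nt are introns.  Boundaries are refined by scanning
#' nearby canonical `GT`..`AG` dinucleotide pairs and keeping the pair whose
#' spliced product aligns best to the homolog; introns without a canonical
#' pair keep the alignment boundaries and are flagged non-canonical.  When
#' no intron-scale gap exists, the single-exon chain is returned.
#'
#' @param locus_nt Locus nucleotide sequence, 5' to 3' on the coding strand.
#' @param homolog Homolog protein (or conceptual translation of a
#'   transcript).
#' @param scheme Protein scoring scheme.
#' @param intron_min Minimum intron length (default 40 nt).
#' @param hsp_bits_min Frame-segment bit threshold (default 22).
#' @return List with `exons` (data.frame `start, end`), `introns`
#'   (data.frame `start, end, canonical`), and `single_exon` flag.
#' @export
infer_intron_structure <- function(locus_nt, homolog,
                                   scheme = .annotation_scheme(),
                                   intron_min = 40, hsp_bits_min = 22) {
  chain <- .chain_hsps(.frame_hsps(locus_nt, homolog, scheme,
                                   hsp_bits_min))
  if (length(chain) == 0) {
    return(list(exons = data.frame(start = 1L, end = nchar(locus_nt)),
                introns = data.frame(start = integer(0), end = integer(0),
                                     canonical = logical(0)),
                single_exon = TRUE, reason = "no_alignment"))
  }
  ex_start <- vapply(chain, `[[`, numeric(1), "nt_start")
  ex_end <- vapply(chain, `[[`, numeric(1), "nt_end")
  introns <- list()
  exons <- data.frame(start = ex_start[1], end = ex_end[1])
  for (i in seq_along(chain)[-1]) {
    gap <- ex_start[i] - ex_end[i - 1] - 1L
    if (gap < intron_min) {
      # same exon (frameshift or small indel): extend
      exons$end[nrow(exons)] <- ex_end[i]
      next
    }
    e1 <- exons$end[nrow(exons)]     # approximate exon end
    s2 <- ex_start[i]                # approximate next exon start
    dcand <- integer(0); acand <- integer(0)
    for (p in max(1, e1 - 12):min(nchar(locus_nt) - 1, e1 + 24)) {
      if (substr(locus_nt, p, p + 1) == "GT") dcand <- c(dcand, p)
    }
    for (q in max(2, s2 - 24):min(nchar(locus_nt), s2 + 12)) {
      if (substr(locus_nt, q - 1, q) == "AG") acand <- c(acand, q)
    }
    best <- NULL
    for (d in dcand) {
      for (a in acand) {
        if (a - d + 1 < intron_min) next
        spliced <- paste0(substr(locus_nt, max(1, d - 150), d - 1),
                          substr(locus_nt, a + 1,
                                 min(nchar(locus_nt), a + 150)))
        sc <- 0
        for (off in 0:2) {
          aa <- translate_nt(spliced, off)
          if (nchar(aa) < 5) next
          al <- tryCatch(sw_align(homolog, aa, scheme),
                         error = function(e) NULL)
          if (!is.null(al)) sc <- max(sc, al$score)
        }
        if (is.null(best) || sc > best$sc ||
            (sc == best$sc && abs(d - e1) < abs(best$d - e1))) {
          best <- list(d = d, a = a, sc = sc)
        }
      }
    }
    if (is.null(best)) {
      introns[[length(introns) + 1L]] <- data.frame(
        start = e1 + 1L, end = s2 - 1L, canonical = FALSE)
      exons <- rbind(exons, data.frame(start = s2, end = ex_end[i]))
    } else {
      introns[[length(introns) + 1L]] <- data.frame(
        start = best$d, end = best$a, canonical = TRUE)
      exons$end[nrow(exons)] <- best$d - 1L
      exons <- rbind(exons, data.frame(start = best$a + 1L,
                                       end = ex_end[i]))
    }
  }
  introns <- if (length(introns)) do.call(rbind, introns) else
    data.frame(start = integer(0), end = integer(0),
               canonical = logical(0))
  list(exons = exons, introns = introns,
       single_exon = nrow(exons) == 1, reason = "")
}

#' Re-derive implanted lesion parameters from a synthetic dataset
#'
#' For every truth event, the implanted locus is extracted from the
#' assembly and annotated against the event's own transferred protein,
#' closing the generator/annotator loop: frameshift and internal-stop
#' counts should match the truth exactly and the truncation fraction to
#' within a small tolerance.
#'
#' @param ds Output of [generate_synthetic_dataset()].
#' @param classes Truth classes to annotate (default: all).
#' @return data.frame with true and annotated `n_frameshifts,
#'   n_internal_stops, truncation_fraction` per event.
#' @export
recover_truth_lesions <- function(ds,
                                  classes = c("functional_LGT",
                                              "pseudogene_LGT",
                                              "paralog_cluster",
                                              "chimeric_fusion",
                                              "buchnera_fragment")) {
  tr <- ds$truth[ds$truth$class %in% classes, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    ev <- tr[i, ]
    nt <- extract_region(ds$assembly, ev$scaffold, ev$start, ev$end,
                         ev$strand)
    rep_i <- annotate_locus(nt, ds$proteins[[ev$event_id]])
    out[[i]] <- data.frame(
      event_id = ev$event_id, class = ev$class,
      true_fs = ev$n_frameshifts, ann_fs = rep_i$n_frameshifts,
      true_stops = ev$n_internal_stops, ann_stops = rep_i$n_internal_stops,
      true_trunc = ev$truncation_fraction,
      ann_trunc = rep_i$truncation_fraction,
      identity_aa = rep_i$identity_aa, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

.primer_sites <- function(template, primer, mismatch_max) {
  lp <- nchar(primer)
  n <- nchar(template)
  if (n < lp) return(integer(0))
  if (mismatch_max == 0) {
    g <- gregexpr(primer, template, fixed = TRUE)[[1]]
    return(if (g[1] == -1) integer(0) else as.integer(g))
  }
  pr <- strsplit(primer, "", fixed = TRUE)[[1]]
  tp <- strsplit(template, "", fixed = TRUE)[[1]]
  out <- integer(0)
  for (i in seq_len(n - lp + 1)) {
    if (sum(tp[i:(i + lp - 1)] != pr) <= mismatch_max)
      out <- c(out, i)
  }
  out
}

#' In-silico PCR
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer on the template (both template orientations are scanned) and
#' reports the amplicon: product length is the distance from the forward
#' primer's 5' start to the reverse primer's 5' start on the opposite
#' strand, inclusive.  The smallest product is reported; multiple products
#' of equal smallest length are all returned with a warning.
#'
#' @param template Template nucleotide sequence.
#' @param primer_fwd,primer_rev Primer sequences, 5' to 3', 15-35 nt.
#' @param mismatch_max Maximum mismatches per primer site (default 0).
#' @param max_product Largest product considered (default 10000 nt).
#' @return `NULL` when no product; otherwise a data.frame with
#'   `product_length, fwd_start, rev_start, strand` (one row per
#'   equal-smallest product).
#' @export
insilico_pcr <- function(template, primer_fwd, primer_rev,
                         mismatch_max = 0, max_product = 10000) {
  for (p in c(primer_fwd, primer_rev)) {
    if (nchar(p) < 15 || nchar(p) > 35)
      stop("primers must be 15-35 nt")
  }
  template <- toupper(template)
  products <- list()
  scan <- function(tmpl, strand) {
    f <- .primer_sites(tmpl, toupper(primer_fwd), mismatch_max)
    r <- .primer_sites(tmpl, revcomp(toupper(primer_rev)), mismatch_max)
    lr <- nchar(primer_rev)
    for (i in f) {
      for (j in r) {
        if (j < i) next
        len <- (j + lr - 1) - i + 1
        if (len > max_product || len < nchar(primer_fwd) + lr) next
        products[[length(products) + 1L]] <<- data.frame(
          product_length = len, fwd_start = i, rev_start = j + lr - 1,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  scan(template, "+")
  scan(revcomp(template), "-")
  if (length(products) == 0) return(NULL)
  df <- do.call(rbind, products)
  df <- df[df$product_length == min(df$product_length), , drop = FALSE]
  # the same amplicon is found once per strand; keep unique lengths/loci
  df <- unique(df[order(df$strand), , drop = FALSE])
  plus <- df[df$strand == "+", , drop = FALSE]
  if (nrow(plus) > 0) df <- plus
  if (nrow(df) > 1) warning("multiple products of equal smallest length")
  rownames(df) <- NULL
  df
}
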