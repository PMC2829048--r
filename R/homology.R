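# Local-alignment search engine and Karlin-Altschul score statistics.
# Every screening stage converts raw Smith-Waterman scores to bit scores
# S' = (lambda * S - ln K) / ln 2 and E-values E = m * n * 2^-S', so the
# internal engine and an external tabular report are threshold-compatible.

.MASK_CHAR <- "#"  # scores -10000 against everything; used to mask HSPs

#' Build a scoring scheme
#'
#' Protein schemes use BLOSUM62 with affine gap penalties 11/1 and the
#' standard gapped Karlin-Altschul parameters (lambda = 0.267, K = 0.041).
#' Nucleotide schemes use match +5 / mismatch -4 (N is neutral), gaps 10/6,
#' lambda = 0.192, K = 0.176.  The `"protein-strict"` scheme (PAM30, gaps
#' 9/1) is used where alignments must not extend across non-homologous
#' sequence, as in pseudogene lesion annotation.
#'
#' @param type `"protein"`, `"protein-strict"` or `"nucleotide"`.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul scale and prefactor.
#' @return A `scoring_scheme` list with the substitution matrix, an internal
#'   character map, gap penalties and statistical parameters.
#' @export
scoring_scheme <- function(type = c("protein", "protein-strict",
                                    "nucleotide"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  type <- match.arg(type)
  if (type == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
  } else if (type == "protein-strict") {
    e <- new.env()
    utils::data("PAM30", package = "Biostrings", envir = e)
    mat <- e$PAM30
    if (is.null(gap_open)) gap_open <- 9
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(lambda)) lambda <- 0.294
    if (is.null(K)) K <- 0.11
  } else {
    ab <- c("A", "C", "G", "T", "N")
    mat <- matrix(-4L, 5, 5, dimnames = list(ab, ab))
    diag(mat) <- 5L
    mat["N", ] <- 0L
    mat[, "N"] <- 0L
    if (is.null(gap_open)) gap_open <- 10
    if (is.null(gap_extend)) gap_extend <- 6
    if (is.null(lambda)) lambda <- 0.192
    if (is.null(K)) K <- 0.176
  }
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  # append the mask character
  mat <- rbind(cbind(mat, `#` = -10000L), `#` = -10000L)
  mat[nrow(mat), ] <- -10000L
  storage.mode(mat) <- "integer"
  charmap <- rep(-1L, 256)
  idx <- as.integer(charToRaw(paste(rownames(mat), collapse = "")))
  charmap[idx + 1L] <- seq_len(nrow(mat)) - 1L
  structure(list(type = type, matrix = mat, charmap = charmap,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Optimal pairwise local (or global) alignment
#'
#' Affine-gap Smith-Waterman; intervals are 1-based inclusive on both
#' sequences; identity is matches over aligned (non-gap) columns.
#'
#' @param a,b Sequences (single strings) over the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param type `"local"` (default) or `"global"`.
#' @return List with `score`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `a_aln`, `b_aln`, `identity`, `aln_len`.
#' @export
sw_align <- function(a, b, scheme = scoring_scheme("protein"),
                     type = c("local", "global")) {
  type <- match.arg(type)
  bad <- function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    ch[!ch %in% rownames(scheme$matrix)]
  }
  miss <- unique(c(bad(a), bad(b)))
  if (length(miss) > 0)
    stop("sequence characters not in scoring alphabet: ",
         paste(miss, collapse = " "))
  r <- cpp_align(a, b, scheme$matrix, scheme$charmap,
                 as.integer(scheme$gap_open), as.integer(scheme$gap_extend),
                 type == "local")
  r$identity <- if (r$n_cols > 0) r$n_ident / r$n_cols else NA_real_
  r
}

#' Convert a raw alignment score to a bit score
#'
#' @param raw Raw alignment score.
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Bit score `(lambda * raw - ln K) / ln 2`.
#' @export
bit_score <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Karlin-Altschul E-value from a bit score
#'
#' @param bits Bit score.
#' @param m Query length (residues).
#' @param n Database length (residues).
#' @return Expected number of chance hits `m * n * 2^-bits`.
#' @export
e_value <- function(bits, m, n) {
  m * n * 2^(-bits)
}

# smallest raw score whose bit score reaches `bits`
.raw_for_bits <- function(bits, scheme) {
  ceiling((bits * log(2) + log(scheme$K)) / scheme$lambda)
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             subject_db = character(0), pident = numeric(0),
             aln_len = integer(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0), frame = integer(0),
             raw_score = numeric(0), bit_score = numeric(0),
             e_value = numeric(0), stringsAsFactors = FALSE)
}

#' Search queries against a sequence database
#'
#' The internal analogue of a protein, translated, or nucleotide similarity
#' search.  `"prot-prot"` aligns peptides directly; `"translated-query"`
#' translates each nucleotide query in all six frames (stops retained as
#' `*`, so alignments may extend across them) and reports the best-scoring
#' frame per query/subject pair with coordinates mapped back to the forward
#' strand (minus-frame hits have `q_start > q_end`); `"nt-nt"` aligns
#' nucleotides.  One best local alignment is reported per pair; per query,
#' hits are sorted by descending bit score with ties broken by subject id.
#'
#' @param queries,database Named character vectors.
#' @param mode `"prot-prot"`, `"translated-query"` or `"nt-nt"`.
#' @param scheme Scoring scheme; defaults to protein (BLOSUM62) except for
#'   `"nt-nt"`, which defaults to the nucleotide scheme.
#' @param bits_min Report threshold in bits (default 0: everything with a
#'   positive score).
#' @param e_max Optional E-value ceiling applied in addition to `bits_min`.
#' @param db_tag Label stored in `subject_db`.
#' @param prefilter `"auto"`, `"none"` or `"kmer"`: whether to require
#'   exact shared words (two distinct protein 4-mers, or one nucleotide
#'   12-mer) before aligning a pair.  `"auto"` uses seeding only when the
#'   number of pairs is large.
#' @param diag_fast When seeding is active and all seeds of a pair fall on
#'   one diagonal, score the pair by exact gapless diagonal alignment
#'   instead of full Smith-Waterman (identical for alignments without
#'   indels; used by the pipeline for speed).
#' @return A hit table data.frame (the `HitTable` layout).
#' @export
search_hits <- function(queries, database,
                        mode = c("prot-prot", "translated-query", "nt-nt"),
                        scheme = NULL, bits_min = 0, e_max = NULL,
                        db_tag = "db", prefilter = c("auto", "none", "kmer"),
                        diag_fast = FALSE) {
  mode <- match.arg(mode)
  prefilter <- match.arg(prefilter)
  if (is.null(scheme))
    scheme <- scoring_scheme(if (mode == "nt-nt") "nucleotide" else "protein")
  if (length(database) == 0) {
    warning("empty database")
    return(.empty_hits())
  }
  if (length(queries) == 0) return(.empty_hits())
  word <- if (scheme$type == "nucleotide") 12L else 4L
  min_seeds <- if (scheme$type == "nucleotide") 1L else 2L
  use_kmer <- switch(prefilter,
    none = FALSE, kmer = TRUE,
    auto = length(queries) * length(database) > 5000)
  n_db <- sum(nchar(database))
  min_raw <- .raw_for_bits(bits_min, scheme)

  # frame sets per query (a single pseudo-frame outside translated mode)
  frames_of <- lapply(seq_along(queries), function(qi) {
    if (mode == "translated-query") {
      fr <- six_frame(queries[[qi]])
      fr[nchar(fr) > 0]
    } else {
      stats::setNames(queries[qi], "0")
    }
  })
  seed_of <- NULL
  if (use_kmer) {
    flat <- unlist(lapply(seq_along(queries), function(qi) {
      fr <- frames_of[[qi]]
      stats::setNames(fr, paste0(qi, "|", names(fr)))
    }))
    seed_of <- cpp_seed_hits_db(unname(flat), database, word)
    names(seed_of) <- names(flat)
  }

  rows <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qlen <- nchar(queries[[qi]])
    frames <- frames_of[[qi]]
    qrows <- list()
    if (use_kmer) {
      frame_seeds <- lapply(names(frames), function(fname)
        seed_of[[paste0(qi, "|", fname)]])
      names(frame_seeds) <- names(frames)
      subjects <- sort(unique(unlist(lapply(frame_seeds, `[[`, "si"))))
    } else {
      frame_seeds <- NULL
      subjects <- seq_along(database)
    }
    for (si in subjects) {
      best <- NULL
      for (fname in names(frames)) {
        fseq <- frames[[fname]]
        if (nchar(fseq) == 0 || nchar(database[[si]]) == 0) next
        al <- NULL
        if (use_kmer) {
          sd <- frame_seeds[[fname]]
          sel <- sd$si == si
          if (!any(sel)) next
          diags <- sort(sd$s[sel] - sd$q[sel])
          if (min_seeds > 1L) {
            # protein pairs must show two seeds on nearly one diagonal;
            # scattered single word matches are chance
            if (length(diags) < 2L || !any(diff(diags) <= 6L)) next
          }
          udiag <- unique(diags)
          if (diag_fast) {
            # score on the dominant diagonal when the seed evidence is
            # unambiguous (one diagonal, or one diagonal holding every
            # repeated seed while the rest are scattered singletons)
            tab <- table(diags)
            multi <- as.integer(names(tab)[tab >= 2L])
            dmain <- if (length(udiag) == 1L) udiag else
              if (length(multi) == 1L) multi else NULL
            if (!is.null(dmain)) {
              al <- .diag_local(fseq, database[[si]], dmain, scheme)
              if (is.null(al)) next
            }
          }
        }
        if (is.null(al))
          al <- sw_align(fseq, database[[si]], scheme, type = "local")
        if (al$score < min_raw || al$score <= 0) next
        if (is.null(best) || al$score > best$al$score)
          best <- list(al = al, frame = fname)
      }
      if (is.null(best)) next
      al <- best$al
      if (mode == "translated-query") {
        off <- abs(as.integer(best$frame)) - 1L
        minus <- startsWith(best$frame, "-")
        nt1 <- off + 3L * (al$a_start - 1L) + 1L
        nt2 <- off + 3L * al$a_end
        if (minus) {
          q_start <- qlen - nt1 + 1L
          q_end <- qlen - nt2 + 1L
        } else {
          q_start <- nt1; q_end <- nt2
        }
        frame_code <- if (minus) -(off + 1L) else off + 1L
      } else {
        q_start <- al$a_start; q_end <- al$a_end; frame_code <- 0L
      }
      bits <- bit_score(al$score, scheme)
      ev <- e_value(bits, qlen, n_db)
      if (bits < bits_min) next
      if (!is.null(e_max) && ev > e_max) next
      qrows[[length(qrows) + 1L]] <- data.frame(
        query_id = qid, subject_id = names(database)[si],
        subject_db = db_tag, pident = 100 * al$identity,
        aln_len = al$aln_len, q_start = q_start, q_end = q_end,
        s_start = al$b_start, s_end = al$b_end, frame = frame_code,
        raw_score = al$score, bit_score = bits, e_value = ev,
        stringsAsFactors = FALSE)
    }
    if (length(qrows) > 0) {
      df <- do.call(rbind, qrows)
      df <- df[order(-df$bit_score, df$subject_id), , drop = FALSE]
      rows[[qi]] <- df
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(.empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best hit per query from a hit table
#'
#' @param hits A hit table.
#' @return One row per query: the highest bit score, ties broken by subject
#'   id (lexicographic).
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$subject_id), ,
               drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse an external 12-column tabular alignment report
#'
#' Accepts the common tab-separated layout (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, E-value, bit score); `#` comment lines are skipped.
#' Raw scores are back-computed from the bit scores under `scheme`, so that
#' external and internal hits share thresholds.
#'
#' @param path Path to the report.
#' @param db_tag Label stored in `subject_db`.
#' @param scheme Scoring scheme used for the raw-score back-conversion.
#' @return A hit table data.frame.
#' @export
read_hit_table <- function(path, db_tag = "external",
                           scheme = scoring_scheme("protein")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12)) {
    stop("line ", which(nc != 12)[1],
         ": expected 12 tab-separated columns, found ", nc[nc != 12][1])
  }
  m <- do.call(rbind, parts)
  bits <- as.numeric(m[, 12])
  data.frame(
    query_id = m[, 1], subject_id = m[, 2], subject_db = db_tag,
    pident = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    frame = 0L,
    raw_score = (bits * log(2) + log(scheme$K)) / scheme$lambda,
    bit_score = bits, e_value = as.numeric(m[, 11]),
    stringsAsFactors = FALSE)
}

#' Write a hit table in the 12-column tabular layout
#'
#' @param hits A hit table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  mism <- round(hits$aln_len * (1 - hits$pident / 100))
  df <- data.frame(hits$query_id, hits$subject_id, hits$pident,
                   hits$aln_len, mism, 0L, hits$q_start, hits$q_end,
                   hits$s_start, hits$s_end, hits$e_value, hits$bit_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
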