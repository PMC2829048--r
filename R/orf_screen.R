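# Enumeration of screening units: stop-to-stop potential polypeptides (PPPs)
# over all six frames, and fixed-length overlapping windows for the
# translated (six-frame) search arm.

#' Extract all potential polypeptides (PPPs) from an assembly
#'
#' A PPP is the conceptual translation of a stop-to-stop DNA stretch,
#' regardless of the presence of an initiation codon: it begins with the
#' first codon after the previous stop and ends at the next stop (or at the
#' scaffold edge).  All six frames are scanned and overlaps between frames
#' are permitted.  Translations containing `X` (gap codons) are retained;
#' stretches are split only at stop codons.
#'
#' @param assembly Named character vector of scaffold sequences.
#' @param min_len Minimum peptide length in amino acids (default 60).
#' @param require_stop If `TRUE`, only stretches terminated by a stop codon
#'   are reported; by default stretches running into the scaffold edge are
#'   reported too, flagged `terminal = TRUE`.
#' @return data.frame with columns `ppp_id, scaffold, frame, start, end,
#'   length, terminal, peptide`.  `start`/`end` are 1-based genomic
#'   coordinates of the codon span; `start > end` encodes the minus strand.
#' @export
extract_ppps <- function(assembly, min_len = 60, require_stop = FALSE) {
  out <- list()
  for (sc in names(assembly)) {
    nt <- assembly[[sc]]
    L <- nchar(nt)
    trans <- six_frame(nt)
    for (fname in names(trans)) {
      aa <- trans[[fname]]
      n_aa <- nchar(aa)
      if (n_aa == 0) next
      off <- abs(as.integer(fname)) - 1L
      minus <- startsWith(fname, "-")
      # maximal runs of non-stop residues
      is_stop <- strsplit(aa, "", fixed = TRUE)[[1]] == "*"
      r <- rle(is_stop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- !r$values & r$lengths >= min_len
      if (!any(keep)) next
      for (k in which(keep)) {
        i1 <- starts[k]; i2 <- ends[k]
        terminal <- (i2 == n_aa)
        if (require_stop && terminal) next
        nt1 <- off + 3L * (i1 - 1L) + 1L
        nt2 <- off + 3L * i2
        if (minus) {
          g_start <- L - nt1 + 1L   # 5' end on minus strand
          g_end <- L - nt2 + 1L
        } else {
          g_start <- nt1; g_end <- nt2
        }
        out[[length(out) + 1L]] <- data.frame(
          ppp_id = paste(sc, fname, g_start, sep = ":"),
          scaffold = sc, frame = fname, start = g_start, end = g_end,
          length = i2 - i1 + 1L, terminal = terminal,
          peptide = substr(aa, i1, i2),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ppp_id = character(0), scaffold = character(0),
                      frame = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      terminal = logical(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  frame_order <- c("+1", "+2", "+3", "-1", "-2", "-3")
  df <- df[order(match(df$scaffold, names(assembly)),
                 match(df$frame, frame_order), pmin(df$start, df$end)), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Divide an assembly into overlapping windows
#'
#' Consecutive windows overlap by exactly `overlap` nucleotides (stride
#' `window_len - overlap`); the final window of a scaffold may be shorter.
#' Every base is covered at least once.
#'
#' @param assembly Named character vector of scaffold sequences.
#' @param window_len Window length in nt (default 1000).
#' @param overlap Overlap between consecutive windows in nt (default 200).
#' @return data.frame with columns `window_id, scaffold, start, end, seq`.
#' @export
make_windows <- function(assembly, window_len = 1000, overlap = 200) {
  if (window_len <= overlap) stop("window_len must exceed overlap")
  out <- list()
  stride <- window_len - overlap
  for (sc in names(assembly)) {
    L <- nchar(assembly[[sc]])
    if (L == 0) next
    n <- ceiling(max(L - overlap, 1) / stride)
    starts <- 1L + (seq_len(n) - 1L) * as.integer(stride)
    ends <- pmin(starts + window_len - 1L, L)
    out[[sc]] <- data.frame(
      window_id = paste(sc, starts, sep = ":"),
      scaffold = sc, start = starts, end = ends,
      seq = substring(assembly[[sc]], starts, ends),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(window_id = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
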