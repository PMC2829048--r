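#' @useDynLib lgtscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`.  The record id is
#' the first whitespace-delimited token of the header line; the remainder of
#' the header is retained in the `"descriptions"` attribute but is never used
#' for joins.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, with a `descriptions`
#'   attribute parallel to the ids.  An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    out <- character(0)
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence before header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", headers)
  names(seqs) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @param descriptions Optional vector of header descriptions appended after
#'   the id.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70, descriptions = NULL) {
  if (is.null(names(seqs)) && length(seqs) > 0)
    stop("sequences must be named")
  if (is.null(descriptions)) descriptions <- attr(seqs, "descriptions")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    if (!is.null(descriptions) && nzchar(descriptions[i]))
      hdr <- paste(hdr, descriptions[i])
    writeLines(paste0(">", hdr), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Handles the `{A,C,G,T,N}` alphabet (plus lower case).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract a genomic region, strand-aware
#'
#' Coordinates are 1-based inclusive.  A minus-strand region may be given
#' either as `start > end` (the convention used by locus tables) or
#' explicitly via `strand = "-"`; the returned sequence is then the reverse
#' complement of the forward-strand slice.
#'
#' @param assembly Named character vector of scaffold sequences.
#' @param scaffold_id Scaffold identifier.
#' @param start,end 1-based inclusive positions; `start > end` implies the
#'   minus strand.
#' @param strand Optional explicit strand, `"+"` or `"-"`.
#' @return The extracted nucleotide string, of length `abs(end - start) + 1`.
#' @export
extract_region <- function(assembly, scaffold_id, start, end, strand = NULL) {
  if (!scaffold_id %in% names(assembly))
    stop("unknown scaffold id: ", scaffold_id)
  s <- assembly[[scaffold_id]]
  if (is.null(strand)) strand <- if (start > end) "-" else "+"
  lo <- min(start, end); hi <- max(start, end)
  if (lo < 1 || hi > nchar(s))
    stop("region ", lo, "..", hi, " out of bounds for scaffold ",
         scaffold_id, " (length ", nchar(s), ")")
  region <- substr(s, lo, hi)
  if (strand == "-") region <- revcomp(region) else region
}

#' Conceptual translation of a nucleotide string
#'
#' Uses the standard genetic code (translation table 1).  Internal stop
#' codons are emitted as `*` so that translation proceeds across them, as
#' required when inspecting pseudogenized loci; any codon containing a
#' character outside `{A,C,G,T}` (assembly gap `N`s in particular) is emitted
#' as `X`.  A trailing partial codon is dropped.
#'
#' @param nt Nucleotide string.
#' @param frame Frame offset 0, 1 or 2.
#' @return Amino-acid string over the 20 residues plus `*` and `X`.
#' @export
translate_nt <- function(nt, frame = 0) {
  stopifnot(frame %in% 0:2)
  nt <- toupper(nt)
  n <- nchar(nt) - frame
  n_codons <- n %/% 3
  if (n_codons <= 0) return("")
  starts <- frame + 1 + 3 * (seq_len(n_codons) - 1)
  codons <- substring(nt, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate all six reading frames
#'
#' Frames `+1,+2,+3` translate the forward strand at offsets 0..2; frames
#' `-1,-2,-3` translate the reverse complement at offsets 0..2.
#'
#' @param nt Nucleotide string.
#' @return Named character vector of six translations, names
#'   `"+1","+2","+3","-1","-2","-3"`.
#' @export
six_frame <- function(nt) {
  rc <- revcomp(nt)
  out <- c(
    "+1" = translate_nt(nt, 0), "+2" = translate_nt(nt, 1),
    "+3" = translate_nt(nt, 2),
    "-1" = translate_nt(rc, 0), "-2" = translate_nt(rc, 1),
    "-3" = translate_nt(rc, 2))
  out
}

#' Write a simple GFF3 feature table
#'
#' @param features data.frame with columns `seqid, source, type, start, end,
#'   score, strand, attributes` (missing optional columns are filled).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) > 0) {
    df <- data.frame(
      seqid = features$seqid,
      source = if ("source" %in% names(features)) features$source else "lgtscreen",
      type = features$type,
      start = features$start,
      end = features$end,
      score = if ("score" %in% names(features)) features$score else ".",
      strand = if ("strand" %in% names(features)) features$strand else ".",
      phase = ".",
      attributes = features$attributes,
      stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
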