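# Independent oracles used across the suite.  They deliberately avoid the
# package's own algorithmic shortcuts: the alignment oracle is a plain
# quadratic DP that re-derives affine gap costs by scanning all gap
# lengths, and the PPP oracle re-scans all six frames by string splitting.

# brute-force affine-gap local alignment score: H[i,j] considers every gap
# length explicitly (no Gotoh state machine)
sw_brute_score <- function(a, b, scheme) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  gap <- function(L) scheme$gap_open + L * scheme$gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- H[i, j] + scheme$matrix[av[i], bv[j]]
      for (k in seq_len(i)) s <- max(s, H[i - k + 1, j + 1] - gap(k))
      for (k in seq_len(j)) s <- max(s, H[i + 1, j - k + 1] - gap(k))
      H[i + 1, j + 1] <- max(0, s)
    }
  }
  as.integer(max(H))
}

# six-frame stop-to-stop re-scan by string splitting
ppp_brute <- function(assembly, min_len = 60, require_stop = FALSE) {
  out <- list()
  for (sc in names(assembly)) {
    L <- nchar(assembly[[sc]])
    for (fname in c("+1", "+2", "+3", "-1", "-2", "-3")) {
      off <- abs(as.integer(fname)) - 1L
      minus <- startsWith(fname, "-")
      nt <- if (minus) revcomp(assembly[[sc]]) else assembly[[sc]]
      aa <- translate_nt(nt, off)
      if (nchar(aa) == 0) next
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      ends_with_stop <- substr(aa, nchar(aa), nchar(aa)) == "*"
      pos <- 1L
      for (k in seq_along(parts)) {
        pep <- parts[k]
        terminal <- (k == length(parts)) && !ends_with_stop
        if (nchar(pep) >= min_len && !(require_stop && terminal)) {
          nt1 <- off + 3L * (pos - 1L) + 1L
          nt2 <- off + 3L * (pos + nchar(pep) - 1L)
          if (minus) {
            g1 <- L - nt1 + 1L; g2 <- L - nt2 + 1L
          } else {
            g1 <- nt1; g2 <- nt2
          }
          out[[length(out) + 1L]] <- data.frame(
            scaffold = sc, frame = fname, start = g1, end = g2,
            peptide = pep, stringsAsFactors = FALSE)
        }
        pos <- pos + nchar(pep) + 1L
      }
    }
  }
  if (length(out) == 0) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$scaffold, df$frame, df$start), ]
}

random_dna_str <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_peptide_str <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
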