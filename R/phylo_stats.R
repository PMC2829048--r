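# Donor-lineage attribution: pairwise distances with gap-column removal,
# neighbor joining with bootstrap support, a Tajima one-degree-of-freedom
# relative-rate test, and a nearest-lineage placement call.

.aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  L <- unique(nchar(aln))
  if (length(L) != 1)
    stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

.drop_gap_columns <- function(m) {
  gap <- apply(m == "-" | m == ".", 2, any)
  m[, !gap, drop = FALSE]
}

#' Pairwise distances from an alignment
#'
#' Columns containing an alignment gap in any row are omitted before
#' counting.  `p` is the proportion of differing sites; the
#' Poisson-corrected distance is `-ln(1 - p)` (infinite, and flagged
#' saturated, when `p` reaches 1).
#'
#' @param aln Named character vector of equal-length aligned sequences, or
#'   a character matrix.
#' @param model `"p-distance"` or `"poisson"`.
#' @return Symmetric distance matrix with a `"saturated"` attribute (logical
#'   matrix of flagged pairs).
#' @export
pairwise_distances <- function(aln, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  m <- .drop_gap_columns(.aln_matrix(aln))
  if (ncol(m) == 0) stop("no gap-free columns to compare")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(m[i, ] != m[j, ])
      d <- if (model == "p-distance") p else {
        if (p >= 1) { sat[i, j] <- sat[j, i] <- TRUE; Inf }
        else -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree
#'
#' Canonical NJ agglomeration; negative branch lengths are clamped to zero
#' (with a message).  Requires at least three taxa.
#'
#' @param D Symmetric distance matrix with taxon labels.
#' @return An `ape::phylo` unrooted tree.
#' @export
neighbor_joining <- function(D) {
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0),
            " negative branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `B` times; the support
#' of each internal node of the point-estimate tree is the percentage of
#' replicates containing that split.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed for the resampling.
#' @param model Distance model (see [pairwise_distances()]).
#' @return List with `tree` (point-estimate `phylo`), `support` (per
#'   internal node, percent), and `B`.
#' @export
bootstrap_support <- function(aln, B = 1000, seed = 1,
                              model = "poisson") {
  m <- .drop_gap_columns(.aln_matrix(aln))
  if (ncol(m) < 2) stop("alignment needs at least 2 columns")
  dist_of <- function(mm) {
    n <- nrow(mm)
    D <- matrix(0, n, n, dimnames = list(rownames(mm), rownames(mm)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        p <- mean(mm[i, ] != mm[j, ])
        D[i, j] <- D[j, i] <-
          if (model == "poisson") -log(max(1 - p, 1e-9)) else p
      }
    }
    D
  }
  tree <- neighbor_joining(dist_of(m))
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- suppressMessages(neighbor_joining(dist_of(
      m[, cols, drop = FALSE])))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tree, support = 100 * counts / B, B = B)
}

#' Tajima one-degree-of-freedom relative-rate test
#'
#' With two ingroups and an outgroup, `m1` counts sites where ingroup 1
#' differs while ingroup 2 matches the outgroup, and `m2` the converse;
#' under equal rates `m1` and `m2` have equal expectation, and
#' `chi2 = (m1 - m2)^2 / (m1 + m2)` is chi-square with 1 df.  Gap columns
#' are removed first.
#'
#' @param in1,in2,outgroup Aligned sequences of equal length.
#' @return data.frame `m1, m2, chi2, p` (`chi2 = 0`, `p = 1` when
#'   `m1 + m2 == 0`).
#' @export
relative_rate_test <- function(in1, in2, outgroup) {
  m <- .drop_gap_columns(.aln_matrix(c(in1 = in1, in2 = in2,
                                       out = outgroup)))
  a <- m[1, ]; b <- m[2, ]; o <- m[3, ]
  m1 <- sum(a != b & b == o)
  m2 <- sum(a != b & a == o)
  if (m1 + m2 == 0) {
    return(data.frame(m1 = m1, m2 = m2, chi2 = 0, p = 1))
  }
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  data.frame(m1 = m1, m2 = m2, chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# align a candidate into a reference set that is already mutually aligned
# (equal lengths): global alignment to the closest reference, whose gap
# pattern is projected onto all rows
.align_to_references <- function(candidate, refs, scheme) {
  L <- unique(nchar(refs))
  if (length(L) != 1)
    stop("reference set must be pre-aligned (equal lengths)")
  if (nchar(candidate) == L) {
    return(c(candidate = candidate, refs))
  }
  bits <- vapply(refs, function(r)
    sw_align(candidate, r, scheme)$score, numeric(1))
  anchor <- refs[[which.max(bits)]]
  g <- sw_align(candidate, anchor, scheme, type = "global")
  a_aln <- strsplit(g$a_aln, "", fixed = TRUE)[[1]]  # candidate
  b_aln <- strsplit(g$b_aln, "", fixed = TRUE)[[1]]  # anchor
  # columns where the anchor has a gap are candidate insertions: drop them
  keep <- b_aln != "-"
  cand_row <- a_aln[keep]  # one symbol per anchor position
  out <- c(candidate = paste(cand_row, collapse = ""), refs)
  out
}

#' Write an alignment in relaxed PHYLIP format
#'
#' For export to external tree-inference tools; names are written in full
#' (relaxed format), one sequence per line.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(aln, path) {
  L <- unique(nchar(aln))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln), L), con)
  writeLines(paste(names(aln), aln), con)
  invisible(path)
}

#' Place a candidate peptide among lineage-tagged references
#'
#' Builds an NJ tree with bootstrap support for the candidate plus the
#' references and calls the lineage of the smallest supported clade
#' containing the candidate whose references all share one lineage tag.
#'
#' @param candidate Candidate peptide.
#' @param refs Named character vector of reference proteins (pre-aligned or
#'   equal-length; otherwise the candidate is projected onto its closest
#'   reference).
#' @param lineages Named character vector: lineage tag per reference.
#' @param support_min Minimum bootstrap support (percent, default 70).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @param scheme Protein scoring scheme.
#' @return List `call` (lineage tag or `"unresolved"`), `support`,
#'   `low_information` (single-lineage reference set), `tree`.
#' @export
placement_report <- function(candidate, refs, lineages, support_min = 70,
                             B = 1000, seed = 1,
                             scheme = scoring_scheme("protein")) {
  aln <- tryCatch(.align_to_references(candidate, refs, scheme),
                  error = function(e) NULL)
  if (is.null(aln)) return(list(call = NA_character_, support = NA_real_,
                                low_information = NA, tree = NULL))
  gsub_x <- function(s) chartr("*", "X", s)
  aln <- vapply(aln, gsub_x, character(1))
  if (length(unique(lineages)) == 1) {
    return(list(call = unique(lineages), support = NA_real_,
                low_information = TRUE, tree = NULL))
  }
  bs <- suppressMessages(bootstrap_support(aln, B = B, seed = seed))
  tree <- bs$tree
  rooted <- ape::root(tree, outgroup = names(refs)[length(refs)],
                      resolve.root = TRUE)
  n_tip <- length(tree$tip.label)
  # support per internal node of the unrooted point tree, matched by split
  node_support <- function(tips) {
    # find the internal node of `tree` whose clade is `tips` (unrooted
    # sense): accept the complement too
    for (nd in (n_tip + 1):(n_tip + tree$Nnode)) {
      cl <- ape::extract.clade(tree, nd)$tip.label
      if (setequal(cl, tips) ||
          setequal(cl, setdiff(tree$tip.label, tips))) {
        return(bs$support[nd - n_tip])
      }
    }
    NA_real_
  }
  best <- NULL
  for (nd in (n_tip + 1):(n_tip + rooted$Nnode)) {
    tips <- ape::extract.clade(rooted, nd)$tip.label
    if (!"candidate" %in% tips) next
    others <- setdiff(tips, "candidate")
    if (length(others) == 0) next
    lins <- unique(lineages[others])
    if (length(lins) != 1) next
    sup <- node_support(tips)
    if (is.na(sup) || sup < support_min) next
    if (is.null(best) || length(tips) < best$size) {
      best <- list(call = lins, size = length(tips), support = sup)
    }
  }
  if (is.null(best)) {
    list(call = "unresolved", support = NA_real_, low_information = FALSE,
         tree = tree)
  } else {
    list(call = best$call, support = best$support,
         low_information = FALSE, tree = tree)
  }
}
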