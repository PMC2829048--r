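# Seeded generator of truth-tagged synthetic inputs.  It emulates the data
# the screen was designed for: an AT-rich gapped host assembly, bacterial
# donor proteomes at several divergence tiers (two lineages, two strains
# each, so placement has phylogenetic signal), an invertebrate decoy
# proteome sharing conserved proteins with the donors, implanted transfer
# events (functional with introns, pseudogenized, tandem-duplicated,
# host-donor fusions, heavily truncated symbiont fragments), contaminant
# scaffolds nearly identical to donor genomes, Sanger-style reads with rare
# chimeric artifacts, and replicate qPCR copy-number ratios.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
.AA_FREQ <- c(7, 5, 4.5, 5.5, 2, 4, 6, 7, 2, 6, 9, 6, 2, 4, 5, 7, 5.5,
              1.5, 3.5, 7)
.AA_FREQ <- .AA_FREQ / sum(.AA_FREQ)

.random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.random_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE, prob = .AA_FREQ), collapse = "")
}

#' Diverge a protein by random amino-acid substitution
#'
#' Each site is substituted independently with probability `rate` to a
#' uniformly chosen different residue, so expected identity to the source is
#' `1 - rate` (the divergence-tier model used for donors and implants).
#'
#' @param protein Amino-acid string.
#' @param rate Per-site substitution probability in `[0, 1]`.
#' @return Diverged protein string.
#' @export
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(aa)) < rate
  for (i in which(hit)) {
    aa[i] <- sample(setdiff(.AA20, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

# per-amino-acid codon sampling weights from base composition at a given GC
.codon_weights <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  gcode <- Biostrings::GENETIC_CODE
  sense <- gcode[gcode != "*"]
  w <- vapply(names(sense), function(cod) {
    b <- strsplit(cod, "", fixed = TRUE)[[1]]
    p[b[1]] * p[b[2]] * p[b[3]]
  }, numeric(1))
  split(data.frame(codon = names(sense), w = unname(w),
                   stringsAsFactors = FALSE),
        unname(sense))
}

#' Reverse-translate a protein with composition-biased codon choice
#'
#' Synonymous codons are sampled with weights proportional to the base
#' composition implied by `gc`, so implants are not trivially detectable by
#' composition alone.
#'
#' @param protein Amino-acid string (no stops).
#' @param gc Target GC fraction of the coding sequence.
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, gc = 0.3) {
  tabs <- .codon_weights(gc)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  cods <- vapply(aa, function(a) {
    t <- tabs[[a]]
    if (is.null(t)) stop("cannot reverse-translate residue ", a)
    sample(t$codon, 1, prob = t$w)
  }, character(1))
  paste(cods, collapse = "")
}

#' Generator configuration
#'
#' All knobs of the synthetic-data module with defaults chosen to match the
#' study conditions the screen assumes: an AT-rich assembly (GC 0.30),
#' roughly 6x Sanger coverage with ~800 nt reads, contaminant scaffolds
#' mostly under 10 kb and >= 95% identical to donor genomes, tandem paralog
#' copies ~97% identical, and qPCR ratios centred at 1 for genomic loci.
#'
#' @param seed Integer seed; mandatory.  The full output set is
#'   byte-identical for identical configurations.
#' @param host_gc Host genomic GC fraction.
#' @param n_scaffolds,scaffold_len_mean,scaffold_len_sd Host scaffold count
#'   and length distribution (lengths clipped below at 3 kb).
#' @param n_gap_runs Number of assembly-gap (`N`) runs.
#' @param gap_len_range Length range of gap runs.
#' @param n_families Number of ancestral donor protein families.
#' @param protein_len_range Donor protein length range (aa).
#' @param lineage_div Ancestor-to-lineage divergence (per-site substitution
#'   probability) for each donor lineage.
#' @param strain_div Within-lineage strain divergence.
#' @param conserved_frac Fraction of families with an invertebrate
#'   (decoy) ortholog.
#' @param decoy_div Ancestor-to-decoy divergence for conserved families.
#' @param n_decoy_extra Unrelated decoy proteins.
#' @param n_host_conserved_genes Conserved-family genes implanted as
#'   ordinary host genes (they exercise the conserved-gene exclusion).
#' @param intron_len_range Intron length range (canonical GT..AG ends).
#' @param paralog_identity Nucleotide identity of tandem paralog copies.
#' @param spacer_range Intergenic spacer range within a paralog cluster.
#' @param n_contaminant_scaffolds,contaminant_identity,contaminant_len_range
#'   Contaminant scaffold count, nucleotide identity to the donor genome and
#'   length range.
#' @param read_len_mean,read_len_sd,coverage,chimeric_read_rate Sanger-style
#'   read model; chimeric artifact reads join host and donor sequence at a
#'   junction covered exactly once.
#' @param sigma_genomic qPCR measurement noise (SD of ratios) for genomic
#'   single-copy loci.
#' @param contaminant_sdlog Among-sample log-SD of contaminant titers.
#' @param n_batches_lsr1,n_batches_iso,n_techrep qPCR replicate structure:
#'   biological batches per strain and technical replicates per batch.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed,
                             host_gc = 0.30,
                             n_scaffolds = 8,
                             scaffold_len_mean = 9000,
                             scaffold_len_sd = 2000,
                             n_gap_runs = 6,
                             gap_len_range = c(50, 300),
                             n_families = 40,
                             protein_len_range = c(180, 360),
                             lineage_div = 0.15,
                             strain_div = 0.05,
                             conserved_frac = 0.2,
                             decoy_div = 0.25,
                             n_decoy_extra = 20,
                             n_host_conserved_genes = 3,
                             intron_len_range = c(60, 400),
                             paralog_identity = 0.97,
                             spacer_range = c(1200, 2000),
                             n_contaminant_scaffolds = 4,
                             contaminant_identity = 0.97,
                             contaminant_len_range = c(1500, 8000),
                             read_len_mean = 800,
                             read_len_sd = 80,
                             coverage = 6.2,
                             chimeric_read_rate = 0.005,
                             sigma_genomic = 0.1,
                             contaminant_sdlog = 1.0,
                             n_batches_lsr1 = 3,
                             n_batches_iso = 4,
                             n_techrep = 3) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$host_gc > 0, cfg$host_gc < 1, cfg$coverage > 0,
            cfg$chimeric_read_rate >= 0, cfg$chimeric_read_rate <= 1,
            cfg$conserved_frac >= 0, cfg$conserved_frac <= 1,
            cfg$n_scaffolds >= 1)
  class(cfg) <- "generator_config"
  cfg
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file with `generator_config()` fields; `seed` mandatory.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  vals <- yaml::read_yaml(path)
  do.call(generator_config, vals)
}

#' Generate the host assembly
#'
#' Scaffolds of i.i.d. nucleotides at the configured GC, with `N` gap runs
#' overwritten at random positions.
#'
#' @param cfg A [generator_config()].
#' @return List with `assembly` (named character vector) and `gaps`
#'   (data.frame `scaffold, start, end`).
#' @export
generate_host_assembly <- function(cfg) {
  if (cfg$n_scaffolds < 1) stop("config error: need at least one scaffold")
  set.seed(cfg$seed)
  lens <- pmax(3000L, as.integer(round(
    stats::rnorm(cfg$n_scaffolds, cfg$scaffold_len_mean,
                 cfg$scaffold_len_sd))))
  assembly <- stats::setNames(
    vapply(lens, function(L) .random_dna(L, cfg$host_gc), character(1)),
    sprintf("host_%02d", seq_len(cfg$n_scaffolds)))
  gaps <- list()
  if (cfg$n_gap_runs > 0) {
    for (g in seq_len(cfg$n_gap_runs)) {
      sc <- sample(names(assembly), 1, prob = lens)
      L <- nchar(assembly[[sc]])
      glen <- sample(cfg$gap_len_range[1]:cfg$gap_len_range[2], 1)
      start <- sample(seq(200, L - glen - 200), 1)
      substr(assembly[[sc]], start, start + glen - 1) <-
        strrep("N", glen)
      gaps[[g]] <- data.frame(scaffold = sc, start = start,
                              end = start + glen - 1,
                              stringsAsFactors = FALSE)
    }
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(scaffold = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  list(assembly = assembly, gaps = gaps)
}

# concatenate reverse-translated CDSs with short spacers into a "genome"
.donor_genome <- function(proteome, gc = 0.45) {
  parts <- character(0)
  genes <- list()
  pos <- 0L
  for (i in seq_along(proteome)) {
    spacer <- .random_dna(sample(50:150, 1), gc)
    cds <- reverse_translate(proteome[[i]], gc)
    parts <- c(parts, spacer, cds)
    start <- pos + nchar(spacer) + 1L
    end <- start + nchar(cds) - 1L
    genes[[i]] <- data.frame(gene = names(proteome)[i], start = start,
                             end = end, stringsAsFactors = FALSE)
    pos <- end
  }
  list(seq = paste(parts, collapse = ""), genes = do.call(rbind, genes))
}

#' Evolve donor proteomes and the invertebrate decoy
#'
#' An ancestral family set is diverged into two donor lineages (two strains
#' each, giving placement a within-lineage reference pair) and, for a
#' configurable conserved fraction of families, into invertebrate decoy
#' orthologs.  Donor "genomes" (concatenated coding sequences with short
#' spacers) are also built for the nucleotide screens and contaminants.
#'
#' @param cfg A [generator_config()].
#' @return List with `ancestors`, strain proteomes `donorA1, donorA2,
#'   donorB1, donorB2`, `decoy`, `conserved_families` (family ids with decoy
#'   twins), `bacterial_db` (all strains combined), and `donorA_genome`,
#'   `donorB_genome` (each `list(seq, genes)`).
#' @export
evolve_donor_proteomes <- function(cfg) {
  set.seed(cfg$seed + 1L)
  fam_ids <- sprintf("fam%02d", seq_len(cfg$n_families))
  lens <- sample(cfg$protein_len_range[1]:cfg$protein_len_range[2],
                 cfg$n_families, replace = TRUE)
  ancestors <- stats::setNames(
    vapply(lens, .random_protein, character(1)), fam_ids)
  diverge_set <- function(set, rate, prefix) {
    stats::setNames(
      vapply(set, mutate_protein, character(1), rate = rate),
      paste0(prefix, "_", names(set)))
  }
  lineageA <- diverge_set(ancestors, cfg$lineage_div, "A")
  lineageB <- diverge_set(ancestors, cfg$lineage_div, "B")
  donorA1 <- diverge_set(stats::setNames(lineageA, names(ancestors)),
                         cfg$strain_div, "donorA1")
  donorA2 <- diverge_set(stats::setNames(lineageA, names(ancestors)),
                         cfg$strain_div, "donorA2")
  donorB1 <- diverge_set(stats::setNames(lineageB, names(ancestors)),
                         cfg$strain_div, "donorB1")
  donorB2 <- diverge_set(stats::setNames(lineageB, names(ancestors)),
                         cfg$strain_div, "donorB2")
  n_cons <- round(cfg$conserved_frac * cfg$n_families)
  conserved <- fam_ids[seq_len(n_cons)]
  decoy <- character(0)
  if (n_cons > 0) {
    decoy <- diverge_set(ancestors[conserved], cfg$decoy_div, "decoy")
  }
  if (cfg$n_decoy_extra > 0) {
    extra_len <- sample(cfg$protein_len_range[1]:cfg$protein_len_range[2],
                        cfg$n_decoy_extra, replace = TRUE)
    extra <- stats::setNames(
      vapply(extra_len, .random_protein, character(1)),
      sprintf("decoy_only%02d", seq_len(cfg$n_decoy_extra)))
    decoy <- c(decoy, extra)
  }
  gA <- .donor_genome(donorA1)
  gB <- .donor_genome(donorB1)
  gD <- .donor_genome(decoy, gc = 0.35)
  list(ancestors = ancestors,
       donorA1 = donorA1, donorA2 = donorA2,
       donorB1 = donorB1, donorB2 = donorB2,
       decoy = decoy, conserved_families = conserved,
       bacterial_db = c(donorA1, donorA2, donorB1, donorB2),
       donorA_genome = gA, donorB_genome = gB, decoy_genome = gD)
}

#' Default implant roster
#'
#' Twelve events mirroring the composition of the real candidate inventory:
#' a five-copy tandem paralog cluster, a three-member gene family with one
#' frameshift-riddled pseudogene, one functional singleton with an intron,
#' one host-donor fusion gene, and two heavily truncated symbiont-derived
#' (donor B) pseudogene fragments.
#'
#' @return data.frame roster consumed by [implant_events()].
#' @export
default_roster <- function() {
  data.frame(
    event_id = c("amiD", "bLys", paste0("rlpA", 1:5),
                 "ldcA1", "ldcA2", "psi_ldcA", "psi_dnaE", "psi_atpH"),
    class = c("functional_LGT", "chimeric_fusion",
              rep("paralog_cluster", 5),
              "functional_LGT", "functional_LGT", "pseudogene_LGT",
              "buchnera_fragment", "buchnera_fragment"),
    donor_lineage = c(rep("donorA", 10), "donorB", "donorB"),
    tier = c(0.30, 0.28, rep(0.30, 5), 0.25, 0.25, 0.25, 0.30, 0.30),
    n_frameshifts = c(0, 0, rep(0, 5), 0, 0, 11, 2, 0),
    n_internal_stops = c(0, 0, rep(0, 5), 0, 0, 0, 0, 3),
    truncation_fraction = c(1, 1, rep(1, 5), 1, 1, 1, 0.30, 0.55),
    cluster_id = c(NA, NA, rep("rlpA", 5), "ldcA", "ldcA", "ldcA",
                   NA, NA),
    n_introns = c(1, 1, rep(1, 5), 1, 1, 0, 0, 0),
    stringsAsFactors = FALSE)
}

# mutate a nucleotide cassette to a target identity without creating
# in-frame stops inside exons or touching intron GT/AG dinucleotides.
# exons: data.frame(start, end) in cassette coordinates, in gene order.
.mutate_cassette <- function(cassette, rate, exons) {
  nt <- strsplit(cassette, "", fixed = TRUE)[[1]]
  in_exon <- rep(FALSE, length(nt))
  for (i in seq_len(nrow(exons)))
    in_exon[exons$start[i]:exons$end[i]] <- TRUE
  protected <- rep(FALSE, length(nt))
  if (nrow(exons) > 1) {
    for (i in seq_len(nrow(exons) - 1)) {
      is <- exons$end[i] + 1L; ie <- exons$start[i + 1] - 1L
      protected[c(is, is + 1L, ie - 1L, ie)] <- TRUE
    }
  }
  # map exon positions to spliced CDS positions
  cds_pos <- integer(length(nt))
  cds_pos[in_exon] <- seq_len(sum(in_exon))
  spliced <- nt[in_exon]
  hit <- which(stats::runif(length(nt)) < rate & !protected)
  for (i in hit) {
    new <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1)
    if (in_exon[i]) {
      k <- cds_pos[i]
      cstart <- 3L * ((k - 1L) %/% 3L) + 1L
      cod <- spliced[cstart:(cstart + 2L)]
      cod[k - cstart + 1L] <- new
      if (Biostrings::GENETIC_CODE[paste(cod, collapse = "")] == "*") next
      spliced[k] <- new
    }
    nt[i] <- new
  }
  paste(nt, collapse = "")
}

# build a gene cassette from a protein: optional introns at codon
# boundaries; returns list(seq, exons (cassette coords), cds)
.build_gene_cassette <- function(protein, cfg, n_introns = 1) {
  cds <- reverse_translate(protein, cfg$host_gc)
  L_aa <- nchar(protein)
  if (n_introns == 0) {
    return(list(seq = cds,
                exons = data.frame(start = 1L, end = nchar(cds)),
                cds = cds))
  }
  lo <- max(65L, ceiling(0.3 * L_aa))
  hi <- min(L_aa - 65L, floor(0.7 * L_aa))
  if (hi <= lo) { lo <- floor(L_aa / 3); hi <- floor(2 * L_aa / 3) }
  cuts <- sort(sample(lo:hi, n_introns))
  parts <- character(0)
  exons <- list()
  pos <- 0L
  prev <- 0L
  for (i in seq_along(cuts)) {
    ex <- substr(cds, 3L * prev + 1L, 3L * cuts[i])
    ilen <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], 1)
    intron <- paste0("GT", .random_dna(ilen - 4L, cfg$host_gc), "AG")
    parts <- c(parts, ex, intron)
    exons[[i]] <- data.frame(start = pos + 1L, end = pos + nchar(ex))
    pos <- pos + nchar(ex) + nchar(intron)
    prev <- cuts[i]
  }
  ex <- substr(cds, 3L * prev + 1L, nchar(cds))
  parts <- c(parts, ex)
  exons[[length(exons) + 1L]] <- data.frame(start = pos + 1L,
                                            end = pos + nchar(ex))
  list(seq = paste(parts, collapse = ""), exons = do.call(rbind, exons),
       cds = cds)
}

# pseudogenize a CDS: truncation, internal stop substitutions, then 1-2 nt
# frameshift indels.  Stops and frameshifts are kept clear of each other and
# of the segment start so that each lesion is independently recoverable.
.pseudogenize <- function(cds, n_stops, n_fs, truncation) {
  L_aa <- nchar(cds) %/% 3L
  keep <- max(30L, round(truncation * L_aa))
  cds <- substr(cds, 1L, 3L * keep)
  L_aa <- keep
  clean_head <- min(90L, floor(0.5 * L_aa))
  usable <- (clean_head + 1L):(L_aa - 5L)
  picks <- integer(0)
  if (n_stops + n_fs > 0) {
    n_les <- n_stops + n_fs
    span <- length(usable)
    step <- span / n_les
    # evenly spaced with bounded jitter, so every inter-lesion segment
    # stays long enough to align on its own
    picks <- usable[pmin(span, pmax(1, round((seq_len(n_les) - 0.5) * step +
                                             stats::runif(n_les, -step / 6,
                                                          step / 6))))]
    picks <- sort(unique(picks))
    while (length(picks) < n_les) {
      cand <- sample(usable, 1)
      if (all(abs(cand - picks) >= 10)) picks <- sort(c(picks, cand))
    }
  }
  stop_codons_at <- if (n_stops > 0) sample(picks, n_stops) else integer(0)
  fs_at <- setdiff(picks, stop_codons_at)
  for (k in stop_codons_at) {
    substr(cds, 3L * (k - 1L) + 1L, 3L * k) <- "TAA"
  }
  # apply frameshifts 3' -> 5' so positions stay valid
  for (k in sort(fs_at, decreasing = TRUE)) {
    p <- 3L * (k - 1L) + 1L  # first nt of codon k
    for (try in 1:20) {
      type <- sample(c("del1", "ins1", "del2", "ins2"), 1)
      cand <- switch(type,
        del1 = paste0(substr(cds, 1, p - 1), substr(cds, p + 1, nchar(cds))),
        del2 = paste0(substr(cds, 1, p - 1), substr(cds, p + 2, nchar(cds))),
        ins1 = paste0(substr(cds, 1, p - 1), .random_dna(1, 0.5),
                      substr(cds, p, nchar(cds))),
        ins2 = paste0(substr(cds, 1, p - 1), .random_dna(2, 0.5),
                      substr(cds, p, nchar(cds))))
      # reject if a stop codon appears near the junction in either the old
      # or the new downstream frame (keeps the lesion counts exact)
      lo <- max(1L, p - 9L)
      win <- substr(cand, lo, min(nchar(cand), p + 11L))
      ok <- TRUE
      for (f in 0:2) {
        if (grepl("\\*", translate_nt(win, f))) { ok <- FALSE; break }
      }
      if (ok || try == 20) { cds <- cand; break }
    }
  }
  list(seq = cds, n_stops = length(stop_codons_at),
       n_fs = length(fs_at), n_codons = L_aa)
}

#' Implant truth-tagged transfer events into a host assembly
#'
#' Donor proteins are diverged by each event's tier, reverse-translated with
#' host-like codon bias, given spliceosomal-type (GT..AG) introns when
#' functional, pseudogenized (frameshifts, internal stops, truncation) when
#' not, duplicated in tandem for paralog clusters, or fused downstream of a
#' eukaryotic domain for chimeric events.  Cassettes are inserted at random
#' positions (never inside gap runs) with coordinates tracked exactly.
#'
#' @param host Output of [generate_host_assembly()].
#' @param donors Output of [evolve_donor_proteomes()].
#' @param cfg A [generator_config()].
#' @param roster Event roster; defaults to [default_roster()].
#' @return List with the modified `assembly`, shifted `gaps`, `truth`
#'   (one row per event: locus, class, lesions, homolog id), `exons`
#'   (genomic exon intervals for intron-bearing events), `proteins`
#'   (the transferred proteins, for reference), and `host_genes`
#'   (conserved-family genes implanted as ordinary host genes).
#' @export
implant_events <- function(host, donors, cfg, roster = default_roster()) {
  set.seed(cfg$seed + 2L)
  assembly <- host$assembly
  gaps <- host$gaps
  scaffolds <- names(assembly)
  n_fam <- length(donors$ancestors)
  free_fams <- setdiff(names(donors$ancestors), donors$conserved_families)

  # choose one family per gene family (cluster members share theirs)
  fam_for <- list()
  needed <- unique(ifelse(is.na(roster$cluster_id), roster$event_id,
                          roster$cluster_id))
  if (length(free_fams) < length(needed) + cfg$n_host_conserved_genes)
    stop("placement error: not enough donor families for the roster")
  # lesion-rich and heavily truncated events draw the longest families
  # (their real counterparts, e.g. DNA polymerase III alpha, are long
  # genes), so inter-lesion segments and truncated fragments stay alignable
  lesioned <- unique(c(
    roster$cluster_id[roster$n_frameshifts + roster$n_internal_stops > 0 |
                        roster$truncation_fraction < 1],
    roster$event_id[is.na(roster$cluster_id) &
                      (roster$n_frameshifts + roster$n_internal_stops > 0 |
                         roster$truncation_fraction < 1)]))
  lesioned <- lesioned[!is.na(lesioned) & lesioned %in% needed]
  by_len <- free_fams[order(-nchar(donors$ancestors[free_fams]))]
  fams <- character(0)
  fams[lesioned] <- by_len[seq_along(lesioned)]
  rest <- setdiff(needed, lesioned)
  fams[rest] <- sample(setdiff(free_fams, fams), length(rest))

  # --- build cassettes -----------------------------------------------------
  cassettes <- list()   # per insertion unit
  add_unit <- function(unit) cassettes[[length(cassettes) + 1L]] <<- unit

  pick_protein <- function(lineage, fam) {
    src <- if (lineage == "donorA") donors$donorA1 else donors$donorB1
    src[[paste0(if (lineage == "donorA") "donorA1_" else "donorB1_", fam)]]
  }
  homolog_id <- function(lineage, fam) {
    paste0(if (lineage == "donorA") "donorA1_" else "donorB1_", fam)
  }

  rows_single <- roster[is.na(roster$cluster_id) |
                          roster$cluster_id == "ldcA", , drop = FALSE]
  # ldcA family: ldcA1 built first, ldcA2 is a ~97% nt copy of it,
  # psi_ldcA an independently diverged, frameshifted copy
  ldca_protein <- NULL
  ldca_cassette <- NULL
  for (i in seq_len(nrow(rows_single))) {
    ev <- rows_single[i, ]
    fam <- fams[[if (is.na(ev$cluster_id)) ev$event_id else ev$cluster_id]]
    src <- pick_protein(ev$donor_lineage, fam)
    prot <- mutate_protein(src, ev$tier)
    if (ev$event_id == "ldcA2" && !is.null(ldca_cassette)) {
      cas_seq <- .mutate_cassette(ldca_cassette$seq,
                                  1 - cfg$paralog_identity,
                                  ldca_cassette$exons)
      unit <- list(events = data.frame(
        event_id = ev$event_id, class = ev$class,
        donor_lineage = ev$donor_lineage, family = fam,
        homolog_id = homolog_id(ev$donor_lineage, fam),
        tier = ev$tier, n_frameshifts = 0L, n_internal_stops = 0L,
        truncation_fraction = 1, cluster_id = ev$cluster_id,
        n_introns = ev$n_introns, off_start = 1L,
        off_end = nchar(cas_seq), stringsAsFactors = FALSE),
        seq = cas_seq, exons = ldca_cassette$exons,
        exon_event = ev$event_id, protein = ldca_protein)
      add_unit(unit)
      next
    }
    if (ev$class %in% c("pseudogene_LGT", "buchnera_fragment")) {
      cds <- reverse_translate(prot, cfg$host_gc)
      ps <- .pseudogenize(cds, ev$n_internal_stops, ev$n_frameshifts,
                          ev$truncation_fraction)
      unit <- list(events = data.frame(
        event_id = ev$event_id, class = ev$class,
        donor_lineage = ev$donor_lineage, family = fam,
        homolog_id = homolog_id(ev$donor_lineage, fam),
        tier = ev$tier, n_frameshifts = ps$n_fs,
        n_internal_stops = ps$n_stops,
        truncation_fraction = ps$n_codons / nchar(prot),
        cluster_id = ev$cluster_id, n_introns = 0L,
        off_start = 1L, off_end = nchar(ps$seq),
        stringsAsFactors = FALSE),
        seq = ps$seq, exons = NULL, protein = prot)
      add_unit(unit)
    } else if (ev$class == "chimeric_fusion") {
      # eukaryotic domain (a decoy-only protein) + donor domain, the two
      # domains on separate exons
      host_dom <- mutate_protein(
        donors$decoy[[grep("^decoy_only", names(donors$decoy))[1]]], 0.1)
      host_dom <- substr(host_dom, 1, 150)
      ex1 <- reverse_translate(host_dom, cfg$host_gc)
      ex2 <- reverse_translate(prot, cfg$host_gc)
      ilen <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2], 1)
      intron <- paste0("GT", .random_dna(ilen - 4L, cfg$host_gc), "AG")
      seqs <- paste0(ex1, intron, ex2)
      exons <- data.frame(start = c(1L, nchar(ex1) + nchar(intron) + 1L),
                          end = c(nchar(ex1), nchar(seqs)))
      # the transferred material is the donor-domain exon; the truth locus
      # records it (the eukaryotic domain is host sequence, not LGT)
      unit <- list(events = data.frame(
        event_id = ev$event_id, class = ev$class,
        donor_lineage = ev$donor_lineage, family = fam,
        homolog_id = homolog_id(ev$donor_lineage, fam),
        tier = ev$tier, n_frameshifts = 0L, n_internal_stops = 0L,
        truncation_fraction = 1, cluster_id = ev$cluster_id,
        n_introns = 1L, off_start = exons$start[2],
        off_end = exons$end[2],
        stringsAsFactors = FALSE),
        seq = seqs, exons = exons, exon_event = ev$event_id,
        protein = prot)
      add_unit(unit)
    } else {  # functional_LGT
      cas <- .build_gene_cassette(prot, cfg, ev$n_introns)
      if (ev$event_id == "ldcA1") {
        ldca_protein <- prot
        ldca_cassette <- cas
      }
      unit <- list(events = data.frame(
        event_id = ev$event_id, class = ev$class,
        donor_lineage = ev$donor_lineage, family = fam,
        homolog_id = homolog_id(ev$donor_lineage, fam),
        tier = ev$tier, n_frameshifts = 0L, n_internal_stops = 0L,
        truncation_fraction = 1, cluster_id = ev$cluster_id,
        n_introns = ev$n_introns, off_start = 1L,
        off_end = nchar(cas$seq), stringsAsFactors = FALSE),
        seq = cas$seq, exons = cas$exons, exon_event = ev$event_id,
        protein = prot)
      add_unit(unit)
    }
  }

  # tandem paralog cluster (all members in one cassette on one scaffold)
  clus <- roster[!is.na(roster$cluster_id) & roster$cluster_id != "ldcA", ,
                 drop = FALSE]
  if (nrow(clus) > 0) {
    cid <- clus$cluster_id[1]
    fam <- fams[[cid]]
    src <- pick_protein(clus$donor_lineage[1], fam)
    prot <- mutate_protein(src, clus$tier[1])
    proto <- .build_gene_cassette(prot, cfg, clus$n_introns[1])
    parts <- character(0)
    evrows <- list()
    exon_rows <- list()
    pos <- 0L
    for (i in seq_len(nrow(clus))) {
      cas_seq <- if (i == 1) proto$seq else
        .mutate_cassette(proto$seq, 1 - cfg$paralog_identity, proto$exons)
      spacer <- if (i < nrow(clus))
        .random_dna(sample(cfg$spacer_range[1]:cfg$spacer_range[2], 1),
                    cfg$host_gc) else ""
      evrows[[i]] <- data.frame(
        event_id = clus$event_id[i], class = clus$class[i],
        donor_lineage = clus$donor_lineage[i], family = fam,
        homolog_id = homolog_id(clus$donor_lineage[i], fam),
        tier = clus$tier[i], n_frameshifts = 0L, n_internal_stops = 0L,
        truncation_fraction = 1, cluster_id = cid,
        n_introns = clus$n_introns[i],
        off_start = pos + 1L, off_end = pos + nchar(cas_seq),
        stringsAsFactors = FALSE)
      exon_rows[[i]] <- data.frame(event_id = clus$event_id[i],
                                   start = pos + proto$exons$start,
                                   end = pos + proto$exons$end,
                                   stringsAsFactors = FALSE)
      parts <- c(parts, cas_seq, spacer)
      pos <- pos + nchar(cas_seq) + nchar(spacer)
    }
    add_unit(list(events = do.call(rbind, evrows),
                  seq = paste(parts, collapse = ""),
                  exons = do.call(rbind, exon_rows), exon_event = NA,
                  protein = prot))
  }

  # conserved-family genes implanted as ordinary host genes
  host_gene_units <- list()
  if (cfg$n_host_conserved_genes > 0 &&
      length(donors$conserved_families) > 0) {
    cons <- donors$conserved_families[
      seq_len(min(cfg$n_host_conserved_genes,
                  length(donors$conserved_families)))]
    for (fam in cons) {
      decoy_twin <- donors$decoy[[paste0("decoy_", fam)]]
      prot <- mutate_protein(decoy_twin, 0.05)
      host_gene_units[[fam]] <- list(
        events = data.frame(event_id = paste0("hostgene_", fam),
                            class = "host_conserved", family = fam,
                            off_start = 1L,
                            off_end = 3L * nchar(prot),
                            stringsAsFactors = FALSE),
        seq = reverse_translate(prot, cfg$host_gc))
    }
  }

  # --- place cassettes -----------------------------------------------------
  units <- c(cassettes, unname(host_gene_units))
  n_units <- length(units)
  # round-robin over shuffled scaffolds so no scaffold is overloaded
  shuffled <- sample(scaffolds)
  target_sc <- shuffled[(seq_len(n_units) - 1L) %% length(scaffolds) + 1L]
  # the cluster cassette is long: give it the longest scaffold
  lens <- nchar(assembly)
  clus_idx <- which(vapply(units, function(u)
    any(!is.na(u$events$cluster_id) & u$events$cluster_id == "rlpA" &
          u$events$class == "paralog_cluster"), logical(1)))
  if (length(clus_idx) == 1) target_sc[clus_idx] <- names(which.max(lens))

  truth <- list(); exons_out <- list(); host_genes <- list()
  proteins <- list()
  for (sc in unique(target_sc)) {
    idx <- which(target_sc == sc)
    L <- nchar(assembly[[sc]])
    # insertion points outside gap runs, away from scaffold ends
    scgaps <- gaps[gaps$scaffold == sc, , drop = FALSE]
    ok_point <- function(p) {
      p >= 500 && p <= L - 500 &&
        (nrow(scgaps) == 0 ||
           all(p < scgaps$start - 10 | p > scgaps$end + 10))
    }
    # distinct insertion points stay well separated (> 1.5 kb) so
    # independent events are never adjacent by accident; intended
    # adjacency (the tandem cluster) is a single cassette
    pts <- integer(0)
    tries <- 0L
    min_sep <- 1500L
    while (length(pts) < length(idx)) {
      cand <- sample(500:(L - 500), 1)
      tries <- tries + 1L
      if (tries > 2000L) min_sep <- 800L
      if (ok_point(cand) && all(abs(cand - pts) > min_sep))
        pts <- c(pts, cand)
    }
    pts <- sort(pts)
    ord <- idx[order(pts)]  # arbitrary stable pairing
    shift <- 0L
    newseq <- assembly[[sc]]
    for (k in seq_along(pts)) {
      u <- units[[ord[k]]]
      p <- pts[k] + shift
      strand <- sample(c("+", "-"), 1)
      cas <- if (strand == "+") u$seq else revcomp(u$seq)
      newseq <- paste0(substr(newseq, 1, p), cas,
                       substr(newseq, p + 1, nchar(newseq)))
      G <- p
      Lc <- nchar(cas)
      map <- function(a, b) {
        if (strand == "+") c(G + a, G + b) else c(G + Lc - a + 1L,
                                                  G + Lc - b + 1L)
      }
      ev <- u$events
      for (r in seq_len(nrow(ev))) {
        se <- map(ev$off_start[r], ev$off_end[r])
        row <- ev[r, setdiff(names(ev), c("off_start", "off_end")),
                  drop = FALSE]
        row$scaffold <- sc
        row$start <- se[1]; row$end <- se[2]; row$strand <- strand
        if (identical(row$class, "host_conserved")) {
          host_genes[[length(host_genes) + 1L]] <- row
        } else {
          truth[[length(truth) + 1L]] <- row
        }
      }
      if (!is.null(u$exons)) {
        exdf <- u$exons
        ev_id <- if ("event_id" %in% names(exdf)) exdf$event_id else
          rep(u$exon_event, nrow(exdf))
        for (r in seq_len(nrow(exdf))) {
          se <- map(exdf$start[r], exdf$end[r])
          exons_out[[length(exons_out) + 1L]] <- data.frame(
            event_id = ev_id[r], scaffold = sc, start = se[1],
            end = se[2], strand = strand, stringsAsFactors = FALSE)
        }
      }
      if (!is.null(u$protein)) {
        for (eid in u$events$event_id)
          proteins[[eid]] <- u$protein
      }
      # shift gap coordinates on this scaffold
      if (nrow(gaps) > 0) {
        sel <- gaps$scaffold == sc & gaps$start > p
        gaps$start[sel] <- gaps$start[sel] + Lc
        gaps$end[sel] <- gaps$end[sel] + Lc
      }
      shift <- shift + Lc
    }
    assembly[[sc]] <- newseq
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth <- truth[order(match(truth$event_id,
                             default_roster()$event_id)), , drop = FALSE]
  rownames(truth) <- NULL
  list(assembly = assembly, gaps = gaps, truth = truth,
       exons = if (length(exons_out)) do.call(rbind, exons_out) else NULL,
       proteins = proteins,
       host_genes = if (length(host_genes)) do.call(rbind, host_genes)
       else NULL)
}

#' Add contaminant scaffolds and simulate a Sanger-style read pool
#'
#' Contaminant scaffolds are donor-genome fragments at the configured
#' identity (mostly short); reads are drawn uniformly from the combined
#' assembly at the configured coverage, and with probability
#' `chimeric_read_rate` a read is replaced by a host/donor junction artifact
#' whose junction is covered exactly once.
#'
#' @param assembly Host assembly (post-implant).
#' @param donors Output of [evolve_donor_proteomes()].
#' @param cfg A [generator_config()].
#' @return List with `contaminants` (named character vector),
#'   `contaminant_truth`, `reads` (named character vector) and `read_truth`
#'   (`read_id, type, scaffold, start, end`).
#' @export
make_contaminants_and_reads <- function(assembly, donors, cfg) {
  set.seed(cfg$seed + 3L)
  gA <- donors$donorA_genome$seq
  gB <- donors$donorB_genome$seq
  contaminants <- character(0)
  ctruth <- list()
  for (i in seq_len(cfg$n_contaminant_scaffolds)) {
    src <- if (i %% 2 == 1) gA else gB
    lineage <- if (i %% 2 == 1) "donorA" else "donorB"
    len <- sample(cfg$contaminant_len_range[1]:cfg$contaminant_len_range[2], 1)
    len <- min(len, nchar(src) - 1)
    start <- sample(seq_len(nchar(src) - len), 1)
    frag <- substr(src, start, start + len - 1)
    if (cfg$contaminant_identity < 1) {
      nt <- strsplit(frag, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(nt)) < 1 - cfg$contaminant_identity)
      for (k in hit) nt[k] <- sample(setdiff(c("A","C","G","T"), nt[k]), 1)
      frag <- paste(nt, collapse = "")
    }
    id <- sprintf("contam_%02d", i)
    contaminants[[id]] <- frag
    ctruth[[i]] <- data.frame(scaffold = id, donor = lineage,
                              length = nchar(frag),
                              stringsAsFactors = FALSE)
  }
  combined <- c(assembly, contaminants)
  total <- sum(nchar(combined))
  n_reads <- round(cfg$coverage * total / cfg$read_len_mean)
  sc_prob <- nchar(combined) / total
  reads <- character(n_reads)
  rtruth <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    rid <- sprintf("read_%05d", r)
    rl <- as.integer(round(stats::rnorm(1, cfg$read_len_mean,
                                        cfg$read_len_sd)))
    rl <- max(300L, min(1500L, rl))
    if (stats::runif(1) < cfg$chimeric_read_rate) {
      # cloning/sequencing artifact: host half + donor half
      hsc <- sample(names(assembly), 1)
      hl <- rl %/% 2L
      hstart <- sample(seq_len(max(1L, nchar(assembly[[hsc]]) - hl)), 1)
      dsrc <- if (stats::runif(1) < 0.5) gA else gB
      dl <- rl - hl
      dstart <- sample(seq_len(nchar(dsrc) - dl), 1)
      reads[r] <- paste0(substr(assembly[[hsc]], hstart, hstart + hl - 1L),
                         substr(dsrc, dstart, dstart + dl - 1L))
      rtruth[[r]] <- data.frame(read_id = rid, type = "chimeric_artifact",
                                scaffold = hsc, start = hstart,
                                end = hstart + hl - 1L,
                                stringsAsFactors = FALSE)
    } else {
      sc <- sample(names(combined), 1, prob = sc_prob)
      L <- nchar(combined[[sc]])
      rl2 <- min(rl, L)
      start <- sample(seq_len(L - rl2 + 1L), 1)
      frag <- substr(combined[[sc]], start, start + rl2 - 1L)
      if (stats::runif(1) < 0.5) frag <- revcomp(frag)
      reads[r] <- frag
      rtruth[[r]] <- data.frame(read_id = rid, type = "genomic",
                                scaffold = sc, start = start,
                                end = start + rl2 - 1L,
                                stringsAsFactors = FALSE)
    }
    names(reads)[r] <- rid
  }
  list(contaminants = contaminants,
       contaminant_truth = do.call(rbind, ctruth),
       reads = reads, read_truth = do.call(rbind, rtruth))
}

#' Simulate replicate qPCR copy-number ratios
#'
#' Genomic single-copy loci yield target/standard ratios distributed
#' `Normal(1, sigma_genomic)` truncated above 0 (pure measurement noise, no
#' batch effect); contaminant loci have a log-normal among-sample titer, so
#' their among-replicate variation greatly exceeds the genomic noise.
#'
#' @param loci data.frame with columns `locus` and `type`
#'   (`"genomic"`/`"contaminant"`), or a truth table with a `class` column
#'   (every class but `contaminant` is treated as genomic).
#' @param cfg A [generator_config()].
#' @param seed Optional seed override (defaults to `cfg$seed + 4`).
#' @return data.frame `locus, strain, sample, replicate, ratio`.
#' @export
simulate_qpcr <- function(loci, cfg, seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 4L else seed)
  if (!"type" %in% names(loci)) {
    loci <- data.frame(locus = loci$event_id,
                       type = ifelse(loci$class == "contaminant",
                                     "contaminant", "genomic"),
                       stringsAsFactors = FALSE)
  }
  if (nrow(loci) == 0) {
    return(data.frame(locus = character(0), strain = character(0),
                      sample = character(0), replicate = integer(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  }
  batches <- rbind(
    data.frame(strain = "LSR1", batch = seq_len(cfg$n_batches_lsr1)),
    data.frame(strain = "ISO", batch = seq_len(cfg$n_batches_iso)))
  out <- list()
  for (i in seq_len(nrow(loci))) {
    for (b in seq_len(nrow(batches))) {
      if (loci$type[i] == "contaminant") {
        titer <- stats::rlnorm(1, 0, cfg$contaminant_sdlog)
        vals <- titer * pmax(1e-6, stats::rnorm(cfg$n_techrep, 1,
                                                cfg$sigma_genomic))
      } else {
        vals <- stats::rnorm(cfg$n_techrep, 1, cfg$sigma_genomic)
        while (any(vals <= 0))
          vals[vals <= 0] <- stats::rnorm(sum(vals <= 0), 1,
                                          cfg$sigma_genomic)
      }
      out[[length(out) + 1L]] <- data.frame(
        locus = loci$locus[i], strain = batches$strain[b],
        sample = paste0(batches$strain[b], "_", batches$batch[b]),
        replicate = seq_len(cfg$n_techrep), ratio = vals,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Generate the complete synthetic dataset
#'
#' Runs [generate_host_assembly()], [evolve_donor_proteomes()],
#' [implant_events()] and [make_contaminants_and_reads()] under one seed and
#' assembles their outputs.  The same configuration always yields a
#' byte-identical dataset.
#'
#' @param cfg A [generator_config()].
#' @param roster Event roster; defaults to [default_roster()].
#' @return List with `assembly` (host + contaminants), `host_assembly`,
#'   `gaps`, `donors`, `truth`, `exons`, `proteins`, `host_genes`,
#'   `contaminants`, `contaminant_truth`, `reads`, `read_truth`, `cfg`.
#' @export
generate_synthetic_dataset <- function(cfg, roster = default_roster()) {
  host <- generate_host_assembly(cfg)
  donors <- evolve_donor_proteomes(cfg)
  imp <- implant_events(host, donors, cfg, roster)
  cr <- make_contaminants_and_reads(imp$assembly, donors, cfg)
  list(assembly = c(imp$assembly, cr$contaminants),
       host_assembly = imp$assembly, gaps = imp$gaps, donors = donors,
       truth = imp$truth, exons = imp$exons, proteins = imp$proteins,
       host_genes = imp$host_genes, contaminants = cr$contaminants,
       contaminant_truth = cr$contaminant_truth, reads = cr$reads,
       read_truth = cr$read_truth, cfg = cfg)
}

#' Write a synthetic dataset to disk
#'
#' Emits the assembly, read pool and proteome FASTAs, the truth table as
#' TSV, implanted features as GFF3, and (if supplied) a qPCR CSV.
#'
#' @param ds Output of [generate_synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @param qpcr Optional qPCR table from [simulate_qpcr()].
#' @return Invisibly, `dir`.
#' @export
write_synthetic_dataset <- function(ds, dir, qpcr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(ds$assembly, file.path(dir, "assembly.fasta"))
  write_fasta(ds$reads, file.path(dir, "reads.fasta"))
  write_fasta(ds$donors$bacterial_db, file.path(dir, "bacterial_db.fasta"))
  write_fasta(ds$donors$decoy, file.path(dir, "invertebrate_db.fasta"))
  utils::write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- ds$truth
  feats <- data.frame(
    seqid = tr$scaffold, type = "lgt_event",
    start = pmin(tr$start, tr$end), end = pmax(tr$start, tr$end),
    strand = tr$strand,
    attributes = paste0("ID=", tr$event_id, ";class=", tr$class),
    stringsAsFactors = FALSE)
  if (nrow(ds$gaps) > 0) {
    feats <- rbind(feats, data.frame(
      seqid = ds$gaps$scaffold, type = "gap", start = ds$gaps$start,
      end = ds$gaps$end, strand = ".",
      attributes = paste0("ID=gap", seq_len(nrow(ds$gaps))),
      stringsAsFactors = FALSE))
  }
  write_gff3(feats, file.path(dir, "truth.gff3"))
  if (!is.null(qpcr)) {
    utils::write.csv(qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE)
  }
  invisible(dir)
}
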