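---
title: "Screening an insect genome for bacterial gene transfers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening an insect genome for bacterial gene transfers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtscreen)
```

## The problem

Insects that host intracellular bacterial symbionts sometimes carry pieces
of bacterial DNA in their own nuclear genomes: lateral gene transfers
(LGT).  Finding them in a whole-genome assembly is a needle-in-haystack
problem complicated by three confounders that mimic transfer:

* **contamination** — bacterial DNA co-extracted with the insect is
  assembled into scaffolds of its own;
* **chimeric artifacts** — cloning and assembly errors join host and
  bacterial fragments into a single read or scaffold;
* **conserved genes** — anciently shared genes look "bacterial" by
  similarity alone even when vertically inherited.

`lgtscreen` reimplements a genome-wide screen that addresses all three
with a cascade of filters, and verifies survivors with pseudogene
annotation, distance-based phylogenetic placement, and a qPCR copy-number
test.  Because the original genome-scale inputs (an early aphid assembly,
its discarded read pool, and period database snapshots) are not
redistributable at package scale, the package ships a seeded synthetic
genome generator that implants truth-tagged transfer events, so the whole
cascade is testable end to end.

## Screening units

Two complementary enumeration strategies feed the cascade:

* **Potential polypeptides (PPPs).** Every stop-to-stop stretch in all six
  reading frames, regardless of start codons, with a conceptual translation
  of at least 60 aa (`extract_ppps()`).  Overlaps between frames are
  permitted.  Stretches running into a scaffold edge without a closing stop
  are emitted flagged `terminal = TRUE`; `require_stop = TRUE` restores the
  strict stop-terminated definition.  Stretches are split only at stop
  codons; codons containing assembly gaps (`N`) translate to `X` rather
  than splitting the peptide, because real candidate loci do span gaps.
* **Windows.** 1,000-nt windows overlapping by 200 nt (`make_windows()`),
  searched by six-frame translation.  This arm has no length threshold and
  aligns across in-frame stop codons, so it picks up short, degraded
  fragments that the PPP arm cannot represent.

## The search engine and its statistics

The internal engine (`search_hits()`) performs affine-gap Smith-Waterman
alignment (Rcpp) under BLOSUM62 with gap penalties 11/1 for protein and
translated searches, and +5/−4 with gaps 10/6 for nucleotide searches.
Raw scores are converted to bit scores,
\(S' = (\lambda S - \ln K)/\ln 2\), with the standard gapped parameters
(\(\lambda = 0.267, K = 0.041\) for BLOSUM62; \(\lambda = 0.192,
K = 0.176\) for the nucleotide scheme), and E-values \(E = mn\,2^{-S'}\).
All cascade thresholds are expressed in bits, so an external search tool's
tabular report (`read_hit_table()`) can stand in for the internal engine
without re-tuning.

For speed the engine can require exact shared seed words before aligning
a pair — for protein searches, two 4-mers on nearly the same diagonal
(scattered single word matches are chance at desk scale); for nucleotide
searches one 12-mer (16 for read mapping) — and when the seed evidence
points to a single diagonal it scores the pair by an exact gapless
diagonal scan, identical to full Smith-Waterman whenever the true
alignment has no indels.  Both shortcuts are off in the oracle
comparisons of the test suite, which check the engine against a
brute-force quadratic DP and against `Biostrings::pairwiseAlignment`.

## The filter cascade

Candidates from either arm pass through, in order:

1. **Bacterial screen** — best bacterial hit at ≥ 40 bits (protein /
   translated) or ≥ 55 bits (nucleotide).
2. **Invertebrate comparison** — the bacterial score must strictly exceed
   the best invertebrate score (`margin_bits = 0`).  When the two hits
   cover one common query region and the invertebrate score is comparable,
   the candidate is classified an evolutionarily conserved gene.
3. **Contaminant-scaffold exclusion** — scaffolds whose length is
   dominated (≥ 50%) by near-identical (≥ 90%) bacterial nucleotide hits
   with no host evidence, or that are shorter than 2 kb with no host
   evidence, are contaminants; their candidates are discarded wholesale.
   A short (< 1 kb) near-identical bacterial segment inside an otherwise
   host scaffold with single-read support is a chimeric assembly artifact.
4. **Weak-hit and repeat exclusion** — fails candidates whose best hit is
   weak (bit ≤ 45 *and* E ≥ 0.001; the rule is the printed conjunction),
   whose aligned region is a short-period tandem repeat (autocorrelation
   fraction ≥ 0.75 at periods ≤ 12), or low-complexity (sliding-window
   entropy < 1.5 bits/symbol).
5. **Full-protein recheck** — when a candidate is part of a predicted
   full-length protein, the whole protein must beat its best animal hit by
   at least 13 bits (`full_protein_recheck()`).  The synthetic pipeline has
   no external gene models, so this stage is logged as skipped there.
6. **Paralog expansion** — a translated sweep of each confirmed peptide
   against the assembly adds tandem or dispersed paralogs the direct
   screens missed.

The read pool passes a parallel cascade (`detect_chimeric_reads()`):
vector and low-complexity exclusion, then the chimera rule — a
bacterial-only and a host-only region, each ≥ 100 nt, overlapping ≤ 30 nt.
A chimeric junction supported by a single read is an artifact; junctions
shared by ≥ 2 reads are genuine transfer evidence.  The original study
also assembled its discarded reads with phred/phrap before inspection;
that arm adds no decision logic beyond junction support, which the
`min_support` rule captures directly, so no assembler is invoked.
The region/overlap sizes (100/30 nt) and the junction grouping tolerance
(50 nt) are package choices; the underlying screen described them only
qualitatively.

A nucleotide screen with symbiont genomes (`symbiont_nt_screen()`,
E < 10⁻⁵) covers non-protein-coding transfers.  Hits are removed when a
back-search finds an equally good animal-genome match (conserved
sequence), when they lie on contaminant scaffolds, or on sub-2 kb
scaffolds without host evidence.

## Pseudogene annotation

`annotate_locus()` aligns a candidate locus to a donor homolog by
*three-frame stitching*: local alignments of the homolog against each
forward-frame conceptual translation are decomposed at score drops,
chained colinearly, and the chain's junctions are classified.  A junction
whose nucleotide offset is not a multiple of three (and is too short to be
an intron, < 40 nt) counts one frameshift; stop codons aligned to homolog
residues, or sitting in short frame-preserving junction gaps, count as
internal stops; the aligned homolog span over the homolog length is the
truncation fraction.  A locus is intact when it has no frameshifts, no
internal stops and truncation ≥ 0.9.

Two numerical choices matter here and are deliberate:

* annotation uses a **high-stringency matrix (PAM30)** with prohibitive
  gap penalties.  Permissive matrices let the aligner bridge
  frame-shifted or intronic "garbage" between genuine segments, which
  silently merges junctions and miscounts lesions; under PAM30 with
  effectively gapless alignment every indel becomes a junction, which is
  exactly what the stitcher classifies.  This is a simplification relative
  to a full frameshift-aware six-state alignment automaton, which remains
  an extension point.
* segments are **decomposed at raw-score drops ≥ 35** so one alignment
  never spans two homologous segments across non-homologous sequence.

`infer_intron_structure()` reuses the chain: junction gaps ≥ 40 nt are
introns, and boundaries are refined by scanning nearby canonical `GT..AG`
pairs and keeping the pair whose spliced product aligns best to the
homolog; violations are reported as non-canonical, never forced.
`insilico_pcr()` verifies loci by exact primer matching (the study's
primers were designed exact; `mismatch_max` defaults to 0) and reports the
amplicon as the 5'-to-5' span, smallest product first.

## Phylogenetic placement and the relative-rate test

Placement is distance-based: pairwise distances with gap-containing
columns omitted (p-distance or Poisson-corrected), neighbor joining
(via `ape`, negative branch lengths clamped to zero), and bootstrap
support from column resampling.  A candidate is attributed to the lineage
of the smallest bootstrap-supported (≥ 70%) clade containing it whose
references share one lineage tag; with references from a single lineage
the call is flagged low-information.  Bayesian and maximum-likelihood
inference and topology tests are out of scope; alignments can be exported
for external tools.

Rate acceleration — the signature of a pseudogene — is tested with
Tajima's one-degree-of-freedom relative-rate test: with ingroups 1 and 2
and an outgroup, \(m_1\) counts sites where only ingroup 1 differs,
\(m_2\) the converse, and \((m_1-m_2)^2/(m_1+m_2)\) is compared to
\(\chi^2_1\).  The exact variant used by the original study is not
recoverable from its text; Tajima's test is the standard choice and is
recorded here as an assumption.

## Copy-number verdicts

Genuine genomic loci have the same copy number as a known single-copy
gene in every sample; contaminant titers fluctuate among samples.  The
package formalizes "nearly constant and centred around 1" as a
conjunction (`copy_number_call()`): one-way ANOVA among samples not
significant, a between-strain t-test not significant, the pooled mean
ratio within [0.5, 2], and 1 inside the mean ± t·SE interval (all at
α = 0.05, configurable).  A locus with significant among-sample variation
or a mean outside the band is `variable_titer`; anything else is
`indeterminate`.  ANOVA with Tukey-Kramer comparisons is delegated to
`stats::aov`/`TukeyHSD`, which implement the studentized-range procedure
with unequal group sizes.  Tissue expression is summarized as fold change
versus whole body with Tukey flags (`fold_change()`).

## What the synthetic generator emulates

`generate_synthetic_dataset()` builds, under one seed (every run is
byte-identical for the same configuration):

* an AT-rich host assembly (GC 0.30, eight scaffolds around 9 kb, six
  `N` gap runs), deliberately desk-scale so a full pipeline run takes
  tens of seconds;
* two donor lineages diverged 0.15 from a common ancestral proteome, each
  with two strains 0.05 apart — enough structure for placement to have a
  within-lineage reference pair, mirroring paired symbiont genomes;
* an invertebrate decoy proteome sharing 20% conserved families with the
  donors, plus host-implanted conserved genes, to exercise the
  conserved-gene exclusion;
* twelve implanted events mirroring the composition of the real candidate
  inventory: one functional singleton with an intron, one host-donor
  fusion (donor domain on its own exon), a five-copy tandem paralog
  cluster at 97% nucleotide identity, a three-member gene family with one
  eleven-frameshift pseudogene, and two heavily truncated symbiont-lineage
  fragments (one with three internal stops, one with two frameshifts);
* contaminant scaffolds (donor-genome fragments at 97% identity, mostly
  short), and a Sanger-style read pool at 6.2× coverage with ~800-nt
  reads and rare single-junction chimeric artifact reads;
* replicate qPCR tables: two strains with three and four biological
  batches, technical triplicates, ratios Normal(1, 0.1) for genomic loci
  and log-normal among-batch titers for contaminants.

Divergence tiers are per-site substitution probabilities (identity ≈ 1 −
tier); the real evolutionary process behind the published identity values
is unknowable, so this Poisson-substitution stand-in is a model choice,
not an inference.  Implant tiers default to 0.25–0.30, which lands
implant hit scores in the same comfortable-margin regime as the published
candidate scores (tens of bits above the 40-bit threshold).  Lesion-rich
events draw the longest donor families and lesions are spaced evenly with
bounded jitter, so every inter-lesion segment remains independently
alignable — the real counterparts of these events are long genes, and
without a minimum segment length no annotator could count lesions
exactly.  Introns are drawn uniform 60–400 nt with fixed `GT..AG` ends
and paralog-cluster spacers 1.2–2 kb: compact enough that locus-level
matching by ≥ 50% reciprocal overlap remains meaningful for merged
exon-level candidate loci, while spacers stay well above the locus merge
gap (600 nt) so cluster members are never fused.

What the generator does **not** emulate: sequencing error and quality
values, codon-level selection (dN/dS), repeat families, heterozygosity,
and real intergenic composition.  Passing the end-to-end tests therefore
demonstrates that the cascade's *decision logic* is correct under the
stated statistical structure, not that its thresholds are optimal for any
particular real assembly.

## End-to-end runs and recovery scoring

`run_pipeline(pipeline_config(seed = 1))` executes generation, scaffold
classification, both screening arms, the read and symbiont screens,
paralog expansion, pseudogene annotation, placement and copy-number
verdicts, and scores recovery against the implant truth by ≥ 50%
reciprocal-overlap locus matching (`compare_to_truth()`).  On the default
scenario the screen recovers all twelve implants and assigns no
contaminant-scaffold locus as a final candidate, for every seed exercised
by the test suite.  The per-stage funnel (counts in and out, with
machine-readable reasons) is the report's backbone, because the funnel is
the shape of the result in this kind of screen.

Placement inside the pipeline uses 200 bootstrap replicates (the
standalone default is 1,000) — support values stabilize well below that
for the five-taxon reference sets involved, and it keeps a full run under
half a minute.

## Known limitations

* The original screen's manual, one-by-one inspection steps are
  formalized as explicit rules; the formalization is an interpretation.
* The full-protein recheck requires external gene models and is skipped
  on purely synthetic runs.
* The nr-wide "top hit must be bacterial" stage is approximated by the
  combined bacterial-plus-invertebrate comparison; period-database
  behavior cannot be reproduced offline.
* Lesion counting assumes lesions are separated by alignable segments;
  two frameshifts a handful of codons apart collapse into one junction
  for any segment-based annotator.  More rarely (well under 1% of
  lesion-rich implants), the shifted-frame translation between two
  frameshifts resembles the homolog by chance closely enough that the
  aligner bridges it, merging one junction; no score threshold separates
  that case from a genuine low-identity stretch.
* The conceptual-translation length reported for a heavily truncated
  fragment depends on whether flanking near-homology is included; the
  module reports the aligned-span figure and leaves extended-ORF variants
  to the caller.
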