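---
title: "Integrated trio filtering and RNA validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated trio filtering and RNA validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triosplice)
```

This vignette documents the models and design decisions behind
`triosplice`: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions adopted where several were
defensible.

## The diagnostic problem

A trio exome in a suspected Mendelian case yields tens of thousands of
annotated variants; prioritization must reduce them to a handful of
candidates, and for loss-of-function (LoF) candidates in novel genes, DNA
evidence alone is rarely conclusive. RNA sequencing of an accessible tissue
adds three orthogonal tests: does a splice-region variant actually change
junction usage, does it create a transcript absent from deep multi-tissue
junction catalogs, and is the mutant allele depleted in mRNA as expected if
the premature termination codon triggers nonsense-mediated decay (NMD)?
`triosplice` implements that chain as composable stages with a single
orchestrator, `run_pipeline()`.

## Filter cascade

Rules are applied in a fixed order (frequency → ClinVar category →
inheritance) and the first rule to remove a variant is recorded, making the
cascade deterministic and auditable. Decisions that were genuinely open:

* **Threshold inequalities.** The frequency rule is stated as "below
  threshold passes"; removal therefore uses `af >= threshold`, and the
  borderline band of the benign rule is the closed interval [0.01, 0.05].
* **Dual-annotated genes.** A gene annotated both dominant and recessive
  uses the stricter dominant threshold (0.01). Treating it leniently would
  make the cascade's output depend on rule order in a way that is hard to
  audit; conservative retention is instead handled by the inheritance rules.
* **De novo calling thresholds.** "Absent from the parents" is
  operationalized as: each parent covered at ≥ 10 reads with ≤ 1
  alternate read, thresholds chosen so that a 30x-minimum exome renders
  essentially every site decidable while tolerating one stray error read;
  both are arguments of `detect_de_novo()`. Parents below the depth floor
  yield `"unresolvable"`, never a silent negative.
* **Missing population frequency** is treated as 0 (absent from the
  population database), which is the semantics of "not seen in gnomAD".
* **Classification precedence.** A survivor that is de novo is labeled
  `de_novo` even if it would also qualify as homozygous-recessive; de novo
  status is the rarer, more actionable signal. Two recessive-gene
  heterozygotes carried by *both* parents cannot be phased from genotypes
  alone; they are retained with a `phase_unknown` note rather than dropped,
  because silent removal of a possible compound heterozygote is the worse
  error.

## Consequence engine

Coordinates follow one convention internally (0-based half-open genomic;
1-based transcript/CDS; conversions centralized in the transcript model),
with VCF and HGVS adapters at the boundaries.

* **Equivalent deletions.** A deletion in a repeat context has several
  equivalent representations. `normalize_deletion()` implements both
  canonical forms — maximally left-shifted (VCF) and maximally right-shifted
  on the transcript strand (HGVS 3' rule) — by sliding the deletion window
  while the flanking base matches. Splice-site assignment happens *after*
  right-normalization, which is what places a G deletion anywhere inside a
  GGG run spanning an exon/donor boundary at the intronic +1 position.
* **Frameshift naming.** The first altered residue is the first amino acid
  at which the mutant translation differs from the reference protein
  (standard HGVS practice), and `fs*N` counts the new stop with that residue
  as 1. Translation continues through the 3' UTR; if no stop is reached the
  consequence is tagged `fs_no_stop` rather than inventing an offset. A
  shifted frame whose first altered codon is itself a stop is reported as
  nonsense. The standard genetic code (table 1) is used, without
  selenocysteine handling.
* **Aberrant transcripts.** The engine never guesses a cryptic donor
  position: the junction module observes the novel junction, and
  `predict_exon_extension()` then models the transcript retaining the first
  k intronic nucleotides. This division of labor keeps DNA-side and RNA-side
  evidence independent.
* **Distance reporting.** The distance between a deletion and a nearby
  acceptor can be measured edge-to-edge or inclusively; the package reports
  coordinates and leaves distance conventions to the caller rather than
  asserting one.

## Junction analytics

Junctions are intron intervals in 0-based half-open coordinates
(`donor_pos` = first intronic base), matching BED directly. Extraction uses
`GenomicAlignments::junctions()` over primary, non-duplicate, non-secondary
alignments — every `N` CIGAR operation contributes one observation, so a
two-intron read contributes two. No MAPQ filter is applied by default (an
aligner-specific choice), but `min_mapq` is exposed. Usage ratios are
reported to one decimal, half-up. Novel-junction matching is exact by
default (`slop = 0`): comparison against a deep multi-tissue catalog is a
categorical absence call, and coordinate tolerance would blur precisely the
signal of interest; a `slop` option exists for noisier catalogs.

## ASE and mosaicism

Inspection-based zygosity calls are formalized as an exact binomial test of
the alternate count against 0.5 (two-sided, default `alpha` 0.05). A site
rejecting 0.5 is mosaic only when its VAF falls in the band
[`lod` = 0.05, 0.35]: below the band it is a homozygous-reference artifact
regime, above 0.35-but-significant it is an ambiguous skew and stays
`indeterminate`. The 0.35 ceiling sits halfway between the germline
expectation and the ~0.30 regime where blood mosaicism is typically called;
the band is a config parameter, not a constant. Depth below 20 never errors
— it yields `indeterminate`, since low-depth binomial tests are
uninformative rather than wrong.

NMD evidence is a one-sided Fisher exact test of the DNA vs RNA 2×2 allele
table, alternative: RNA alternate fraction lower. A zero margin (e.g. no
alternate reads anywhere) makes the table degenerate; the test returns p = 1
with a note instead of a spurious rejection. RNA genotyping at indel sites
(`count_rna_alleles()`) requires a read to span the full allele interval
with an exact reference or alternate match; near-miss reads are counted as
ambiguous and excluded from both counts, because mapping artifacts at indels
otherwise masquerade as allelic signal.

Percent values are rounded half-up to one decimal everywhere (29/96 →
30.2%), implemented explicitly since base R rounds half to even.

## Splice-site models

Window conventions are fixed to the MaxEntScan standard: donors are 9-mers
(3 exonic + 6 intronic), acceptors 23-mers (20 intronic + 3 exonic). Two
model families are trained in-package — WMM (independent positions) and MM1
(first-order Markov) — with scores as log2 odds against a background
(default uniform 0.25, overridable). The pseudocount default of 0.25 per
base keeps every ACGT window finitely scored at small training sizes. The
full maximum-entropy model is deliberately *not* re-estimated: its
parameters belong to a separate published procedure, so `MAXENT_TABLE`
accepts an external k-mer score table and errors loudly on missing k-mers.
Maximum Dependence Decomposition is out of scope for the same reason. The
pipeline's interpretive rule is conservative: a variant is called
splice-weakening only when the delta is negative under **all** available
models.

## The synthetic study generator

`simulation_config()` defines the study conditions; the defaults are the
regimes the pipeline is designed around, chosen once:

| parameter | default | rationale |
|---|---|---|
| `mosaic_fraction` | 0.30 | blood-mosaicism regime for a post-zygotic variant |
| `depth_dna` / `depth_rna` | 96 / 100 | ~100x clinical exome/transcriptome; the germline study uses 44/138 explicitly |
| `nmd_factor` | 0.5 | per-read survival of the mutant transcript; at a het site this centers the RNA alternate fraction on 1/3 (≈ 45 alt / 93 ref at 138x) |
| `usage_parent` | (0.45, 0.55) | balanced competing acceptors in carriers of the reference allele |
| `usage_proband` (exonic-deletion study) | (0.38, 0.62) | the shift a pyrimidine-tract deletion induces at the affected acceptor |
| `aberrant_fraction` | 0.13 | cryptic-donor junction usage in the mosaic proband |
| `n_junction_reads` | 2000 | split-read depth at a well-expressed junction |
| `n_background_variants` | 100 | enough to exercise every cascade rule; the cascade is O(n) so the count is not load-bearing |

The fixed synthetic locus is a five-exon, plus-strand transcript: exon 1
carries 57 coding nt and ends GG|GTAAGT, so the exonic GG plus intronic +1 G
form the homopolymer that exercises deletion normalization at a donor; a
cryptic donor 4 nt into intron 1 produces a +4 exon extension, hence a
frameshift from residue 20; exon 3's donor splices to a long and a short
exon-4 acceptor 21 nt apart; the planted exonic deletion sits 7 bp upstream
of the short acceptor inside its pyrimidine tract. RNA depletion is modeled
as binomial thinning of alternate reads — the simplest mechanism consistent
with NMD — giving `p_rna = p·nmd / (1 − p + p·nmd)`.

What the generator does **not** emulate: sequencing error profiles, GC and
fragment-length bias, UMI structure, mapping ambiguity, multi-gene
transcriptomes, or annotation errors. Passing tests therefore demonstrate
the correctness and calibration of the *statistical machinery* on clean
reads, not robustness to upstream artifacts — on real data, the alignment
and annotation steps feeding this package carry their own error modes.

## Verification design and problem sizes

The test suite checks every computational claim against an independent
route: frameshifts against a hand-rolled codon-table mutate-and-translate
oracle (200 random CDSs up to 300 codons); junction extraction against a
manual CIGAR walk; binomial and Fisher p-values against direct
density-summation oracles (agreement to 1e-10 over a stratified grid of
~1,200 tables with margins ≤ 60 — the full enumeration of such tables is
~3.6 million, so the grid covers all margin strata and boundary cells
instead); the filter cascade against per-rule set operations composed in
order, on random trios up to 200 variants. Calibration checks use 1,000
replicates for the heterozygous call rate at depth 100, 500 for mosaic
power at f = 0.30/depth 96, 200 replicates of 2,000 reads for usage-ratio
recovery, and 500 replicates for NMD-imbalance power at 44x DNA / 138x RNA.
These sizes keep the full suite under two minutes on one core while leaving
Monte-Carlo noise well below each test's margin.

## Known limitations

* Single-transcript consequence calls: overlapping transcripts must be
  scored one model at a time.
* Phasing uses parental genotypes only; read-backed phasing is not
  attempted, so double-parent carriers stay `phase_unknown`.
* The HGVS implementation covers deletions, insertions (exon extensions)
  and substitution classification — not inversions, complex delins, or
  repeat notation.
* ACMG-style tags (`PVS1_like`, `PS2_like`, `PM2_like`) are informational
  mirrors of the evidence fields, not a scored classification.
* The ranking heuristic (de novo > LoF > RNA-support count) is a
  transparent ordering for review, not a claim about pathogenicity.
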