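---
title: "Methods: TIP detection, genotyping and mobilome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIP detection, genotyping and mobilome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`mobilomekit`, the assumptions behind them, the parameters a user may
want to tune, and the choices we made where the design was genuinely
open. It states no empirical claim that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The detection model

A non-reference TE insertion leaves two footprints in paired-end data
aligned to a reference that lacks the insertion:

* **split reads** spanning an insertion breakpoint fail to align
  end-to-end; one part matches the flanking genome, the remainder
  matches a TE;
* **discordant pairs** with one mate in the flank and one mate inside
  the inserted TE body; the TE-side mate aligns to TE sequence elsewhere
  (or nowhere), so the pair looks unmapped-mate or aberrant.

Detection therefore proceeds in four steps per accession:

1. *Candidate extraction.* Reads that are unmapped (SAM flag 4) or whose
   pairs map to different contigs or to positions separated by more than
   ten times the mean library size (`estimate_insert_metrics()` measures
   the mean from up to 10,000 proper pairs; at least 100 are required).
2. *TE-library alignment* (`align_to_te()`). Candidates are aligned
   locally against every copy of the family library on both strands. The
   built-in aligner seeds with exact 20-mers sampled every 10 bases,
   extends along the modal diagonal with an exact maximal-scoring-segment
   computation under match +2 / mismatch −3, and falls back to a full
   Smith–Waterman (gap open −5, gap extend −2) only when seeds disagree
   on the diagonal, i.e. when an indel is plausible. The default score
   threshold 2 × 20 is met exactly by a perfect 20-mer, aligning the
   reporting floor with the evidence threshold below. An
   `external_adapter` mode ingests SAM from any user-run local aligner
   instead.
3. *Evidence selection and anchoring.* A read is split evidence when its
   TE segment is ≥ 20 nt **and** its non-TE remainder is ≥ 20 nt (the
   remainder must be long enough to anchor uniquely); it is discordant
   evidence when it aligns to the TE essentially full-length (both clips
   < 20 nt) and its mate is not itself TE-derived. Anchors are placed by
   exact occurrence search in the reference, escalating the allowed
   mismatch count (0, 1, 2) until a hit exists; an anchor with more than
   one hit at its best level is dropped as multimapped and tallied. This
   occurrence-count uniqueness stands in for an aligner mapping-quality
   floor (MAPQ ≥ 10): both demand a clear best locus.
4. *Clustering and intersection* (`call_clusters()`,
   `intersect_sites()`). Oriented evidence kinds are `softclip_3p`
   (anchor ends at the left breakpoint), `softclip_5p` (anchor starts at
   the right breakpoint), `discordant_plus` and `discordant_minus`
   (mate anchors pointing toward the insertion from the left and right).
   A locus becomes a cluster when it holds ≥ 2 reads in valid
   orientation order: no downstream-type element (5′ clip, minus
   discordant) may lie left of an upstream-type element (3′ clip, plus
   discordant), comparing anchor starts. Clusters from all accessions
   within 100 bp are merged, and a site is emitted when at least one
   accession supports it with ≥ 3 reads including ≥ 1 upstream and ≥ 1
   downstream read.

Breakpoints: the left breakpoint estimate is the maximal end of 3′-clip
anchors (else of plus-discordant anchors), the right breakpoint the
minimal start of 5′-clip anchors (else of minus-discordant anchors). A
target-site duplication (TSD) makes the right breakpoint *smaller* than
the left by the TSD length; we accept overlaps up to 25 bp (LTR-element
TSDs are ≤ ~6 bp; the margin absorbs clip jitter) and reject clusters
overlapping further as incoherent. When clip evidence is absent on one
side the cluster is imprecise and its position is the breakpoint-interval
midpoint.

Orientation-rule semantics deserve a note: the rule is enforced as a
*no-violating-pair* condition, so a cluster whose evidence is all
upstream-type (e.g. 2-up/0-down) is ordering-consistent and is kept as a
candidate locus; such loci can never seed a site on their own (the
≥ 1-up/≥ 1-down site filter removes them) but their support still counts
for accessions at sites seeded by better-balanced clusters. The
exhaustive subset test in the suite pins this behaviour against a
brute-force evaluation of the rule.

### Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_copy_len` | 1000 | bp | family retention: at least one annotated copy this long |
| `copy_floor` | 200 | bp | copies shorter than this add alignment noise, not anchoring power |
| `min_partial` | 20 | nt | minimal TE segment and minimal anchoring remainder |
| discordance distance | 10 × mean insert | bp | pairs separated further are discordant |
| `max_span` | mean + 3 sd of insert | bp | evidence grouping span |
| `merge_window` | 100 | bp | cross-accession site merging (≈ one read length) |
| `tsd_tol` | 25 | bp | maximal breakpoint overlap before a cluster is incoherent |
| `negcov_threshold` | 5 | reads | noncarrier requires negative coverage > 5 |
| `flank` | 50 | bp | negative-coverage fetch window and contig-edge guard |
| `support_window` | 600 | bp | per-accession support recount around a site (covers the discordant reach) |

## Genotyping by negative coverage

For each accession and site, supporting evidence reads are recounted in a
window around the site. Accessions with support are carriers. Without
support the call depends on *negative coverage*: the minimum over the two
breakpoints of the number of well-mapped reads spanning the breakpoint
with at least one base on each side. More than five spanning reads make a
confident noncarrier; five or fewer leave the call missing. The boundary
value five itself is treated as missing — asserting absence is the risky
direction, and a conservative tie-break costs only missingness. Genuine
carriers sequenced at very low depth therefore drift to the missing
channel, never to noncarrier: their breakpoints interrupt spanning
coverage, so negative coverage stays at or below threshold.

MAF is computed over non-missing calls and folded; sites that end up with
zero carriers are dropped with a log message.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the benchmark condition used throughout
the tests: a 1 Mb genome in two contigs, five TE families spanning the
six superfamilies (GYPSY/COPIA/LINE of Class I, MuDR/hAT/CACTA of
Class II), two planted, ~2%-degenerate ancestral copies per family (the
library source), ten accessions, fifty insertion events, 20× depth,
100 bp error-free reads, 400 ± 40 bp inserts. Insertion events carry a
uniform 0–6 bp TSD; carrier counts follow P(k) ∝ k⁻² truncated at the
panel size, so most insertions are private — the rare-skewed spectrum
that real mobilome surveys observe; placement biases put COPIA and the
Class II superfamilies near genes and GYPSY/LINE in the pericentromeric
third of each contig. Accessions are homozygous throughout: inbred
panels are the target use case, so no heterozygotes are simulated.

In perfect-alignment mode each read's true origin is mapped through the
accession-to-reference liftover: reads fully inside reference-derived
segments become mapped records; reads touching inserted TE sequence
become **unmapped** records (flag 4) with their sequence and their mate's
placement. This emulates an end-to-end aligner, under which
boundary-spanning reads fail to map — exactly the population the flag-4
extraction rule retrieves; their clip structure is then *discovered* by
the TE-alignment and anchoring stages rather than asserted by the
simulator.

Events are resampled if they fall within 2,500 bp of another event or
1,500 bp of a contig end. The spacing floor exceeds the evidence-grouping
span, so distinct events always yield separable clusters; real genomes
contain nested and clustered insertions that this generator deliberately
does not produce (see Limitations).

What passing tests on this generator do **not** show: robustness to
indel sequencing errors, PCR duplicates, aligner-specific soft-clip
conventions, heterozygous dosage, nested insertions, or reference TE
deletions. The generator's substitution-only error model and uniform
coverage are idealisations; the external-adapter path exists so real
aligner output can replace the hermetic path without touching the
downstream contracts.

## Population statistics

* **PCA** codes carrier = 1 / noncarrier = 0, imputes missing calls to
  the site mean, centres sites and uses `prcomp` (SVD).
* **Family accumulation** counts families detected in growing accession
  subsets. Subsets are nested within each bootstrap replicate (a random
  accession ordering is accumulated — `vegan::specaccum(method =
  "random")`), which makes every replicate curve, hence the mean curve,
  non-decreasing by construction; independent subsets per size would
  leave the mean monotone only in expectation. The 95% interval is the
  percentile interval over replicates.
* **Group richness** compares groups at the common subsample size (the
  smallest group). The displayed uncertainty is bootstrap; the pairwise
  test permutes group labels (default 1,000 permutations) on the *exact*
  rarefied richness E[S_m] = Σ_f (1 − C(n−n_f, m)/C(n, m)), removing
  bootstrap noise from the test statistic.
* **LD** uses r² = squared Pearson correlation of 0/1 genotype vectors,
  equal to D²/(p₁q₁p₂q₂) under inbred coding; each pair is complete-case
  and pairs monomorphic in their complete-case subset are skipped and
  counted. Per TIP the nearest `n_flank` SNPs on each side enter; the
  background is all pairs among those same SNPs.
* **Mappability** tiles pseudo-reads (default 100 bp every 10 bp); a
  pseudo-read is unique when its sequence occurs exactly once in the
  genome across both strands. This exact-occurrence proxy is
  deterministic and aligner-free; it diverges from an operational
  "fraction of reads with MAPQ ≥ 10" definition by ignoring base errors
  and near-duplicates that an aligner might still resolve.

## Expression impact

Position classes follow the precedence UTR > exon > intron inside genes;
outside, upstream/downstream within 1 kb are strand-aware, the boundary
inclusive at exactly 1 kb. Sites equidistant from two genes are assigned
to both and flagged. Expression effects are
log₂((mean carriers + 1)/(mean noncarriers + 1)) on library-normalized
counts — the pseudo-count of one normalized unit handles zeros — with
2-fold classes at |log₂FC| ≥ 1; genes must be expressed in at least one
sample, and both groups need ≥ 2 accessions. The elongation statistic
compares per-accession (downstream + 1)/(upstream + 1) read-count ratios
between carrier and noncarrier groups via the **median** (the ratio
distribution the metric produces is skewed; the median is robust), takes
|log₂| of the ratio of medians and bins it into
≤0.5, (0.5–1.5], (1.5–2.5], (2.5–3.5], (3.5–4.5], >4.5. The (2.5–3.5]
bin is included so the bins partition the half-line; downstream flank
windows default to 500 bp per side, excluding the TE itself.

## The mixed-model scan

The association model is the classical two-step approximation: variance
components of *y = Xβ + u + ε*, *u* ~ N(0, σ²g·K), *ε* ~ N(0, σ²e·I) are
estimated once on the null model by REML, then every marker is tested by
GLS under the fixed covariance σ²g·K + σ²e·I.

REML maximises over δ = σ²e/σ²g. After projecting out the fixed effects,
the spectral decomposition of the projected kinship makes the restricted
likelihood closed-form in δ; we evaluate it on a 100-point log₁₀ grid
over [−5, 5] and refine the best grid cell with golden-section
(`optimize`). The grid guards against the rare multimodal profile; the
refinement gives the smooth optimum. K must be positive semi-definite
(tolerance 10⁻⁶ relative); the error message suggests the standard
K + 10⁻⁶ I regularization.

Per-marker missing genotypes are handled complete-case (mean imputation
is available as a flag): the covariance is subset to the complete rows
and re-factorized per marker. With no missing data the scan uses a
whitening transform computed once, so 5,000 markers at n = 300 take
seconds. With K = I the GLS reduces exactly to OLS — coefficient,
standard error and p-value — which the suite asserts at 10⁻⁸.

Binary phenotypes are analysed with the linear model (as is conventional
for EMMAX-style scans of case/control-coded traits); this is a
documented caveat, not a logistic model. The significance default is
Bonferroni over tested markers. The carrier-label permutation test
permutes the marker among accessions and reports
(1 + #{perm p ≤ observed p})/(n_perm + 1); for a single marker the
"scan minimum" is the marker's own p-value. We use the standard
empirical-p definition; published permutation thresholds phrased as "the
fraction of permuted datasets with associations" are compatible with it
up to the +1 correction.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed internally (the R/Bioconductor idiom);
  emitted VCF is 1-based, emitted bedGraph half-open 0-based.
* Family ties in clusters resolve by evidence count, then
  lexicographically smallest name, with a log message.
* Exactly-boundary values: MAF exactly 1% is retained; missingness
  exactly 20% is retained; negative coverage exactly 5 is missing;
  a 20-nt TE segment is kept; an elongation effect of exactly 1.5 falls
  in (0.5–1.5].
* Empty TE libraries, < 100 proper pairs, constant PCA matrices,
  single-group richness, zero-complete-marker kinship pairs and unknown
  configuration keys are hard errors with specific messages or condition
  classes.
* Detection contains no randomness: reruns on identical inputs are
  bit-identical. All simulator randomness derives from one integer seed.

## Problem sizes used by the tests

The hermetic end-to-end benchmark uses the generator defaults (1 Mb, 10
accessions, 50 events, 20×); module tests run a 200 kb, 4-accession,
8-event version of the same conditions. Calibration tests use n = 300
with 5,000 null markers (type-I error), 20 replicates at n = 200
(heritability recovery), and 50 repeats of 200 permutations (permutation
uniformity). These sizes were chosen to give the statistics enough
resolution (binomial error on a 5% rate at 5,000 markers is ±0.3%) while
keeping the suite comfortably interactive.

## Known limitations

* Reference (fixed) TE deletions, somatic or heterozygous dosage,
  excision footprints and nested insertions are out of scope.
* The built-in aligner is substitution-oriented; reads whose TE segment
  contains indels reach the Smith–Waterman fallback only when a second
  seed diagonal exists.
* IBS simple-matching kinship is the implemented estimator; centred
  (VanRaden-type) kinships change δ but usually not marker ranking.
* The mappability proxy understates ambiguity between near-identical
  (non-exact) repeats.
* SINE/MITE-scale elements are excluded by the library length filter by
  design: short, high-copy families are not reliably resolvable with
  short reads.
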