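---
title: "Demarcating putative ecological species from deep psaA amplicon data"
author: "EcotypeSeq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating putative ecological species from deep psaA amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EcotypeSeq)
```

## The scientific problem

Hot-spring cyanobacterial mats harbor *Synechococcus* populations that are
nearly identical at ribosomal loci yet occupy distinct niches along the
temperature gradient of the effluent channel and the sub-millimetre light
and O~2~ gradients within the mat. Under the Stable Ecotype Model of
bacterial speciation, such communities are collections of **ecotypes**:
long-lived, ecologically distinct populations whose members are
ecologically interchangeable, because recurrent selective sweeps (periodic
selection) purge diversity within an ecotype while new ecotypes arise by
niche invasion. A single-copy protein-coding marker (here a 324-bp segment
of *psaA*, encoding a Photosystem I reaction-centre subunit) sequenced to
great depth can then be used to *predict* ecological species — putative
ecotypes (PEs) — from sequence data alone, and those predictions can be
tested against the distribution of each PE over temperature and depth and
against its response to environmental perturbation.

EcotypeSeq re-implements that whole chain as a reproducible pipeline:

1. **synthio** — synthetic communities, haplotypes and pyrosequencing-style
   reads with homopolymer errors (ground truth for every later stage);
2. **readclean** — removal of homopolymer frameshift artifacts against an
   in-frame consensus reference;
3. **hfscount** — dereplication, per-sample counting, high-frequency
   sequence (HFS) selection and lineage assignment;
4. **demarc** — a Stable Ecotype Model coalescent, simulation-based
   likelihood fitting of (omega, sigma, npop), and tree-based PE
   demarcation (conservative and fine-scale);
5. **abundance** — low-frequency sequence (LFS) assignment and per-sample
   PE percentage profiles;
6. **ecostats** — canonical correspondence analysis (CCA) against
   temperature and depth, a permutation test for nonrandom clustering of a
   PE's variants in ordination space, G-tests, and trend models for
   perturbation time series;
7. **dieltx** — diel transcript assignment and two-stage normalization;
8. `runPipeline()` — orchestration of 2–6 from one master seed with a
   checksummed manifest.

## The synthetic data generator and what it emulates

The generator plants a known community so that every downstream claim can
be checked against truth.

* **Niche model.** Each ecotype has a Gaussian product niche over
  temperature and depth: abundance of ecotype $i$ at $(T, z)$ is
  proportional to
  $w_i \exp\{-(T-T_i)^2/2\sigma_T^2 - (z-z_i)^2/2\sigma_z^2\}$, normalized
  per sample. The field data constrain only empirical distributions, so a
  smooth unimodal niche is the simplest defensible choice; defaults
  ($\sigma_T = 2.5$ °C, $\sigma_z = 220$ µm, centres 3 °C and 200 µm
  apart) give strongly structured but overlapping distributions, as
  observed along the 60–68 °C channel and the upper-mat microgradient.
* **Haplotypes.** Each ecotype carries one dominant variant, `n_hfs - 1`
  further high-frequency variants at exactly `withinDistance` (default 2)
  substitutions from the dominant, and `n_lfs` low-frequency variants one
  further substitution away. Within-ecotype read frequencies default to
  70 % dominant / 25 % HFS / 5 % LFS, mimicking the dominant-variant
  structure of deep amplicon surveys. Dominant variants of different
  ecotypes carry disjoint private substitutions so that the minimum
  between-ecotype distance is `separation * withinDistance` (default
  5 × 2 = 10 substitutions) and always exceeds the maximum within-ecotype
  distance.
* **Unambiguous substitution sites.** Substitutions are planted only at
  reference positions whose flanking two base pairs on either side are
  run-free, at pairwise spacing of at least two sites, and with the new
  base differing from both reference neighbours. Without these
  constraints a homopolymer insertion adjacent to a planted polymorphism
  admits several optimal alignments, some of which erase the
  polymorphism — the ground truth would then be ill-defined. This is the
  one deliberate deviation from "uniformly random positions": it is what
  makes substitution-only haplotypes an *unambiguous* truth for
  frame-based cleaning.
* **Sequencing errors.** Per maximal run of identical bases of length
  $L$, one extra copy of the run base is inserted with probability
  $p_{ins} L^{e}$ or one base deleted with probability $p_{del} L^{e}$,
  at most one event per run (which keeps the fraction of error-free reads
  at the closed form $\prod_r (1 - p_{ins,r} - p_{del,r})$, used as a
  test oracle). The platform's error magnitudes are not characterized in
  the source data; the defaults $p_{ins} = 0.01$, $p_{del} = 0.005$,
  $e = 0$ are nominal and are recorded in the run manifest.
* **Not emulated:** chimeras, quality scores, PCR bias, paired ends, true
  biological indels. Passing tests therefore show correctness of the
  algorithms under this error model, not robustness to every artifact of
  real amplicon data.

## Read cleaning

Each raw read is aligned globally, in all four orientations (forward,
complement, reverse, reverse complement), against the in-frame consensus
reference; the best-scoring orientation wins, with ties resolved by a
fixed priority. Read bases that gap the reference frame are excised
(assumed erroneous homopolymer copies) and the read is trimmed to
reference length; reads that still leave gaps in the reference frame
(deletions, truncations) are rejected, as are reads with non-IUPAC
characters or less than half the reference length.

Two numerical choices matter:

* **Linear gap costs** (match +2, mismatch −3, 7 per gapped base, no
  opening penalty). Homopolymer indels are independent scattered events;
  an affine opening penalty makes the optimal alignment merge clustered
  single-base insertions into one gap block, paying a spurious mismatch
  to save gap-opens and thereby corrupting the excision.
* **Canonical excision.** Optimal alignments are not unique: an inserted
  copy of a base next to a true polymorphism can be explained equally
  well by excising the polymorphism. Among equal-score placements the
  cleaner prefers excising a base that duplicates a retained neighbour
  (a plausible homopolymer copy), via a bounded local repair search.
  Both choices are assessed by the round-trip property: on insertion-only
  corruptions, every cleaned read must equal its source haplotype
  exactly, and all deletion-corrupted reads must be rejected.

For cDNA mode, cleaned reads can be trimmed to a configurable window
(e.g. the 247-bp segment used for transcript matching).

## Dereplication, HFS selection and lineages

Cleaned reads are dereplicated into unique variants with exact per-sample
counts; ordering is deterministic (descending total, then lexicographic).
A variant is a **high-frequency sequence** when its total count across
all samples is *strictly greater* than the threshold (default 50; 10 as
a permissive alternative). Lineage labels (A, B-prime, A-prime) use
per-column identity in the shared reference frame: A or B-prime requires
at least 95 % identity to the respective genomic homolog and best-match
status; A-prime is assigned by best match into a reference set of
high-temperature metagenomic variants, with no identity floor by default
(configurable), since no genome exists for that lineage.

## The Stable Ecotype Model coalescent and demarcation

Observed HFS diversity within a clade is summarized as a **bin curve**:
the number of complete-linkage clusters at each criterion of a
sequence-identity ladder (default: strict identity followed by criteria
spaced 0.005 × 1.5 apart — the 1.5 "sorting" multiplier widens the ladder
spacing). Distances are Jukes–Cantor corrected; saturated pairs are an
error.

`simulateSES()` generates bin curves under the model: backward in time,
`nLineages` sampled lineages distributed over `npop` ecotypes experience

* **ecotype formation** (rate `omega` per substitution per lineage) — a
  random occupied ecotype merges into another, the time-reversal of
  niche-invasion budding;
* **periodic selection** (rate `sigma` per substitution per occupied
  multi-lineage ecotype) — all sampled lineages of the swept ecotype
  coalesce;
* **drift** (rate `drift` per within-ecotype lineage pair) — one pair
  coalesces.

Mutations are Poisson along branches (the clock is expected substitutions
per sequence). `maxDepth` is the *ecotype divergence depth*: lineages
still in distinct ecotypes star-join there, while a single remaining
ecotype coalesces on its own clock. This asymmetry matters: if a lone
ecotype were also truncated at `maxDepth`, every single-population
simulation would inherit the observed clade depth and mimic multi-ecotype
structure, destroying identifiability.

`fitSES()` estimates parameters by simulation-based likelihood: a
replicate *matches* the observed curve when its bin counts agree exactly
at all but at most `maxMiss = 3` criteria. Exact agreement (`slack = 0`)
is essential — whether a clade splits into one or two bins at a criterion
is precisely the demarcation question, and allowing ±1 bin of slack
erases that signal; the `maxMiss` allowance absorbs the one-criterion
jitter of each curve transition under Poisson mutation noise. The
likelihood surface is scanned over a small grid (omega ∈ {0.3, 1.5},
sigma ∈ {0.3, 1, 3}, four moment-matched drift values, npop = 1…6, 150
replicates each). The reported number of ecotypes is the smallest npop
whose profile likelihood is within 80 % of the grid maximum (a parsimony
rule: tight clades are equally consistent with one ecotype or several
micro-ecotypes, and the parsimonious reading resolves such plateaus
toward fewer ecotypes); the confidence set contains all npop within a
factor $e^{-2}$ of the maximum.

`demarcate()` walks the midpoint-rooted neighbor-joining tree of the HFS
from the root: a clade is accepted as one PE when its fitted ecotype
number is compatible with 1 — in **conservative** mode when the
confidence set contains 1 (the most inclusive clades), in **fine-scale**
mode when the parsimony-ML estimate itself equals 1. Rejected clades
recurse into their children; singletons are PEs. Since an ML of 1 implies
1 lies in the confidence set, every fine-scale PE nests inside a
conservative PE by construction.

### Known limitations

* A drift-only population (no periodic selection) often leaves deep
  two- or three-cluster genealogies whose bin curves are genuinely
  indistinguishable from multiple ecotypes; the single-population null is
  therefore calibrated under the model's own one-ecotype null with
  periodic selection at the rate scale reported for this marker
  (sigma ≈ 2.7 events per substitution), not under pure drift.
* The original demarcation software's exact binning rule, match
  tolerance, confidence-interval construction and traversal order are
  not published in usable detail; each corresponding knob here
  (`slack`, `maxMiss`, `parsimony`, ladder spacing and sorting factor,
  likelihood-ratio cutoff) is explicit, documented and configurable, but
  byte-compatibility with that program is not a goal.

## Abundance profiles

LFS variants are assigned by reference-framed Hamming distance to the
demarcated HFS: when the nearest and second-nearest HFS lie in the same
PE the LFS falls within that clade, otherwise it is tentatively assigned
to the nearest HFS's PE; exact distance ties go to the PE whose tied HFS
has the larger total count. Distances are leaf-to-leaf, not node-to-node —
simpler, and directly testable. Each PE's percentage in each sample is
(PE sequences in sample / all assigned sequences in sample) × 100,
decomposed into dominant, other-HFS and pooled-LFS components; replicate
samples are summarized as mean with range. Absolute abundances are out of
reach by design of the assay (proportional sampling only).

## Ecological statistics

* **CCA** (via `vegan::cca`) relates the variant × sample table to
  temperature and depth as linear predictors; scores are reported in
  species-conditional scaling ("scaling 2"), the convention consumed by
  the cluster test; per-predictor fractions are partial constrained
  inertias. The unit tests check the constrained eigenvalues against a
  dense ter Braak oracle (chi-square-standardized matrix, weighted
  projection, eigen-decomposition) to 1e-8 and the inertia decomposition
  exactly. Under a shuffled environment the expected constrained fraction
  is about (number of predictors)/(n − 1), not zero — a fact worth
  remembering when reading "variance explained" from small designs.
* **Ordination cluster test.** For each PE, the statistic is the mean
  squared Euclidean distance of its variants' ordination scores to their
  centroid (default: first two constrained axes); the null redistributes
  group membership at random among all variants (size-preserving);
  p = (1 + #{permuted ≤ observed}) / (nPerm + 1). PEs with fewer than two
  variants are not testable. Type-I error is verified by calibration at
  alpha = 0.05 over 500 null data sets.
* **G-tests** of distribution heterogeneity use the log-likelihood-ratio
  statistic G = 2 Σ O ln(O/E) with (r−1)(c−1) degrees of freedom;
  all-zero margins are dropped with a warning.
* **Perturbation trends.** Heterogeneity of PE responses over time is
  tested by the multinomial trend model in Poisson log-linear form
  (`count ~ pe + timepoint + pe:time`), the categorical generalization of
  a binomial share regression. The naive approach — independent binomial
  GLMs of each PE's share with a PE × time interaction — is
  anti-conservative on compositional count tables (measured ~11 % type-I
  at alpha = 0.05) because the shares are negatively coupled; the
  log-linear form restores calibration (~5 %) while keeping the same
  interaction-deviance logic. Per-PE slopes and up/down/flat labels come
  from binomial share regressions; an arcsine-square-root ANCOVA mode is
  provided as the alternate formulation. Within-PE interchangeability is
  tested by regressing each HFS's share of its PE, and the pooled
  LFS:HFS ratio, on time — flat slopes mean the membership moves in
  unison.
* **Diel transcripts.** cDNA reads are assigned to PEs by exact match
  over the shared window (reads matching variants of more than one PE
  after windowing are discarded as ambiguous); short reads are recruited
  to lineage gene sets by best ungapped Hamming distance up to 5
  mismatches on either strand, ties discarded. Counts are normalized by
  the per-timepoint total and then by each category's geometric mean over
  non-missing timepoints (zeros replaced by a 0.5 pseudocount first), so
  every normalized series has unit geometric mean and timing patterns are
  comparable across categories. Relative-abundance series use assigned
  reads only as the denominator. With two categories the *share* series
  peaks at the antiphase of the competitor; peak-hour recovery is
  therefore assessed against a stable background category.

## Reproducibility and problem sizes

All randomness flows from one master seed through deterministic per-stage
seeds; rerunning `runPipeline()` with the same configuration and seed
reproduces byte-identical outputs, verified by manifest checksums. The
test-suite problem sizes — 5,000-read cleaning round-trips, 20-community
HFS recovery, 50-trial demarcation and null-recovery experiments,
500-replicate calibrations of the permutation and deviance tests — were
chosen so the full suite completes in minutes on a single core while
keeping Monte-Carlo standard errors well inside the margins being
asserted.
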