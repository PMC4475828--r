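# EcotypeSeq

Demarcation of putative ecological species (ecotypes) of hot-spring
*Synechococcus* from deep single-locus amplicon sequencing, and tests of
their ecological distinctness and internal interchangeability.

## What it does, and for whom

Thermophilic *Synechococcus* populations in alkaline hot-spring mats are
nearly uniform at ribosomal markers yet partition finely along the
temperature gradient of the effluent channel and the sub-millimetre
light/O₂ gradient inside the mat. Under the **Stable Ecotype Model**,
such communities consist of ecotypes: long-lived populations of
ecologically interchangeable members, kept cohesive by periodic selection
(recurrent within-population selective sweeps, rate σ per nucleotide
substitution) and multiplied by ecotype formation (niche invasion, rate
ω). EcotypeSeq is for microbial ecologists who want to predict such
**putative ecotypes (PEs)** from deep amplicon data of a protein-coding
marker (here a 324-bp *psaA* segment) and then test the predictions
against habitat distributions and perturbation responses.

The pipeline:

* simulate synthetic communities, haplotypes and 454-style reads with
  homopolymer indel errors (`ecotypeSpec`, `simulateCommunity`,
  `simulateReads`) — every downstream claim is checked against this
  planted truth;
* remove homopolymer frameshift artifacts by four-orientation global
  alignment to an in-frame consensus reference, excising read bases that
  gap the reference frame and rejecting reads with residual gaps
  (`cleanReads`);
* dereplicate into exact variants, select high-frequency sequences
  (total count > 50 across all samples) and assign lineages
  (`dereplicateAndCount`, `selectHFS`, `assignLineage`);
* fit the Stable Ecotype Model by a backward-in-time coalescent with
  ecotype-formation, periodic-selection and drift events
  (`simulateSES`), estimate (ω, σ, npop) by simulation-based likelihood
  over sequence-identity bin curves (`fitSES`), and demarcate PEs on the
  neighbor-joining tree — conservative mode accepts a clade when the
  confidence set for the number of ecotypes includes 1, fine-scale mode
  when the ML estimate equals 1 (`demarcate`);
* assign low-frequency sequences and compute per-sample PE percentage
  profiles (`assignLFS`, `peAbundance`);
* test ecological structure: canonical correspondence analysis against
  temperature and depth, a permutation test for nonrandom clustering of
  a PE's variants in ordination space, G-tests of distribution
  heterogeneity, and multinomial/binomial trend models for perturbation
  series (`ccaOrdination`, `ordtestCluster`, `gTest`,
  `perturbationTrend`, `withinPEHomogeneity`);
* normalize diel transcript series by per-timepoint totals and each
  category's geometric mean (`matchTranscripts`, `recruitReads`,
  `normalizeDiel`).

`runPipeline()` chains everything from one master seed and writes a
checksummed JSON manifest; reruns are byte-identical. See the vignette
(`vignettes/ecotype-demarcation.Rmd`) for the models, parameter meanings
and design choices.

## Worked example

```r
library(EcotypeSeq)
res <- runPipeline(pipelineConfig(), seed = 11)
res$manifest[c("n_reads", "n_passed", "n_hfs", "n_pe")]
res$partitions$fine
round(res$profile$percent, 1)
```

With the default three-ecotype configuration (9 samples on a
60–65 °C × 200–600 µm grid, 600 reads each, p_ins = 0.01,
p_del = 0.005) this prints:

```
reads: 5400  passed: 1783
variants: 151  HFS: 8
PEPartition (fine): 3 PEs over 8 variants (sizes: 2,3,3)
     S01_T60_z200 S02_T63_z200 S03_T65_z200 S04_T60_z400 ...
PE01          3.2          9.5         29.7          7.1
PE02         22.4         60.5         56.4         34.3
PE03         74.4         30.0         13.8         58.6
```

Reading this: of 5,400 simulated reads, 1,783 survive cleaning — the
deletion-bearing two-thirds are rejected by the frameshift rule, as
intended for this error model. Dereplication finds 151 variants, 8 of
them high-frequency; fine-scale demarcation recovers the three planted
ecotypes as PEs, and their per-sample percentages track the planted
Gaussian niches (PE03 dominates the cool/shallow corner, PE01 the
hot/deep corner). The constrained ordination attributes 82 % of variant
inertia to temperature + depth (58 % / 22 % partial fractions), and the
G-test of PE × temperature counts is decisive (G = 440.3, df = 4).

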