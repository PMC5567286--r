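---
title: "From small-RNA reads and 3'UTR variants to muscle-trait associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From small-RNA reads and 3'UTR variants to muscle-trait associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrait)
```

## The problem

In selectively bred rainbow trout, growth and muscle-quality traits
(whole body weight, muscle yield, crude fat, shear force, fillet
whiteness) vary widely between full-sib families. Two regulatory
mechanisms plausibly contribute: differences in microRNA abundance in
muscle, and single-nucleotide polymorphisms in the 3'UTRs of target
genes that remove an existing microRNA recognition element seed site
(MRESS) or create a novel, illegitimate one. `mirtrait` implements the
full analysis chain for such a study on pooled family material:

1. **quantify** small-RNA reads per pooled library (adapter trimming,
   length filtering, tolerant annotation, isomiR collapsing);
2. **test** for differential miRNA expression between divergent
   high/low family pools;
3. **scan** 3'UTRs for seed sites under explicit pairing rules;
4. **classify** 3'UTR SNPs as site-destroying, site-creating or
   neutral, and screen pooled allele frequencies for high/low
   imbalance;
5. **associate** genotypes and qPCR expression with quantitative
   traits.

Because studies of this design rarely deposit raw data, the package
ships a synthetic-data generator that emulates the study layout with
planted ground truth, so every stage is verifiable end to end.

## Seed matching model

A seed of length 6, 7 or 8 nt is anchored at mature-miRNA position 2
(positions 2–7, 2–8, 2–9) and pairs antiparallel against a UTR window:
seed position $i$ pairs window position $L - 1 - i$ (0-based). Each
opposing pair is Watson–Crick, a G:U wobble (seed G against target T,
or seed U against target G), or a mismatch. Tolerances follow the
PITA-style parameterization used for salmonid target prediction:

| seed length | G:U wobbles | mismatches |
|---|---|---|
| 6 | 0 | 0 |
| 7 | ≤ 1 | 0 |
| 8 | ≤ 1 | ≤ 1 |

Gaps (loops) are never allowed. Seed lengths anchored at the same
mature position share their 3'-most UTR coordinate, so nested matches
are reported once, at the longest matching length; intervals always
satisfy `end - start = seed_len`. A direct consequence of the 8-mer
allowances worth knowing: any perfect 7-mer site is also a valid 8-mer
site (the extra position can at worst be the one allowed mismatch), so
reported sites at a given anchor carry the longest defensible length.

```{r}
scan_sites("mir-x", "AAGGCACUCAUCGAUCGAUCGA", "g1", "AAAAGTGCCTAAAA")
```

## Duplex energy

Each site is annotated with a nearest-neighbor hybridization energy:
the duplex is anchored at mature position 2 and extended 3'-ward along
the miRNA, without gaps, while consecutive pairs are Watson–Crick or
wobble; the energy is a duplex-initiation penalty plus the sum of
stacking terms (Turner 2004 values, shipped as an editable TSV in
`inst/extdata/stack_energies.tsv`; terminal-AU penalties and dangling
ends are omitted since the energy feeds a single reporting threshold,
−15 kcal/mol by default). Raising the threshold never removes a
passing site.

One modelling decision deserves emphasis. Under this gapless
seed-anchored extension, a site that a *single substitution* can
destroy must already have its extension blocked around mature position
8–9 — otherwise the 8-mer's one-mismatch allowance keeps the site
alive under the alternate allele. Such sites never reach −15 kcal/mol.
Published pipelines apply the energy threshold to full hybrids with
loops, a quantity this package deliberately does not model. SNP
classification therefore gates on seed-rule site presence by default
(`energy_cutoff = NULL` in `classify_snp()`), while energies and
`passes_energy` flags are always reported and a cutoff can be imposed
explicitly.

## SNP impact and imbalance screening

`classify_snp()` scans both allele variants of the hosting UTR,
restricted to windows overlapping the SNP (classification is provably
local), and compares site presence per miRNA: present→absent is
`destroyed`, absent→present is `created`, identical calls are `none`.
The effect allele is the allele whose state differs (without the site
for destroyed, with the novel site for created). A SNP destroying one
miRNA's site while creating another's yields two rows.

Pooled allele depths are screened with the coverage filters total
reads > 10, minor allele count > 4 and MAF > 0.05 (strict, as stated
in the source protocol's Methods), then the effect-allele frequency
ratio between high- and low-ranked family groups is flagged as
amplification (≥ 2.0) or loss of heterozygosity (≤ 0.5). The source
protocol states the thresholds inclusively in its Methods and
exclusively in its Results; both conventions are supported
(`strict = FALSE` is the default). Division-by-zero ratios are kept
distinguishable (`"0.25/0"` display form with a `low_freq_zero` flag)
rather than collapsed to infinity.

## Differential expression from single pooled libraries

With one pooled library per family group, biological dispersion is not
estimable. Differential expression is therefore assessed with the
conditional exact binomial test: conditional on the total count of a
miRNA across both pools, the high-pool count is Binomial with
proportion equal to the high pool's library-size share. Counts are
CPM-normalized for reporting; a miRNA is called DE when the BH-adjusted
p-value is below 0.05 and the signed fold change is below −2 or above
+2 (ratio convention: $r$ if $r \ge 1$, else $-1/r$; a 0.5 pseudocount
enters only when a group mean is zero).

Two caveats are documented rather than hidden. First, the exact test
models *technical* sampling only; with biological replication an
overdispersed count model (negative binomial) would be required, and
the package's calibration experiments are run at dispersion 0
accordingly. Second, normalized counts are relative abundances: a
large one-sided block of truly changed miRNAs shifts the apparent fold
change of every unchanged miRNA (composition effect). The recovery
experiments plant balanced up/down fold changes, which is both the
realistic case (observed DE lists run in both directions) and the
regime in which "unchanged" is well-defined on the normalized scale.

## Association stage

Quantitative traits are transformed with the rank-based inverse normal
(Blom) transform, $\Phi^{-1}\!\big((\text{rank} - 3/8)/(n + 1/4)\big)$,
which is invariant to monotone transforms of the input and passes
standard normality screens for continuous data. Association of a trait
with additive genotype dosage (0/1/2) or with qPCR ΔCt uses ordinary
least squares; results are reported as signed $r^2$ — the squared
Pearson correlation carrying the slope's sign — matching reporting
conventions in which negative table entries denote negative
correlations. BH adjustment is applied within each trait's predictor
panel. Supporting utilities: the whiteness index
$100 - \sqrt{(100-L)^2 + a^2 + b^2}$ from colorimeter L\*/a\*/b\*
readings; ΔΔCt fold changes $2^{-\Delta\Delta Ct}$ against a U6
reference; multi-predictor $R^2$; covariate-adjusted (conditional)
association for independence checks — implemented as linear regression
with covariate dosages, since logistic regression is not well-posed
for a quantitative outcome; and identity-by-state distances with
classical MDS for stratification diagnostics.

## The synthetic study and what it does (not) show

`make_truth_bundle()` plus the simulators generate every pipeline
input with planted truth:

- **miRNAs/UTRs** — random sequences (mature length 21–23 nt,
  pairwise-distinct 6-mer seeds; UTRs 250–350 nt).
- **Planted SNPs** — destroy segments host an 8-mer site whose
  position-9 pairing is a hard mismatch, so one further seed mismatch
  (the alternate allele) removes the site at every seed length; create
  segments are the mirror image. Every planted SNP is self-verified by
  `classify_snp()` against the full panel, with up to 1000 placement
  retries before a loud failure.
- **Counts** — negative binomial with variance $\mu + d\mu^2$
  (Poisson at $d = 0$, the single-pool regime); the expected high/low
  group-mean ratio equals the planted fold change.
- **Reads** — canonical mature sequences with 3' adapter appended and
  a 20% isomiR rate (end shifts ≤ 1 nt, occasional substitution),
  always within the annotation tolerance.
- **Pooled alleles** — binomial draws at the groups' true frequencies;
  effect SNPs get divergent frequencies (0.6 vs 0.1, half in each
  direction), neutral SNPs stay balanced at 0.35.
- **Phenotypes** — 98 families × 5 fish by default;
  trait = mean + sd × (family effect + planted effects + residual),
  with family and residual SDs 0.6 and 0.8 on the standardized scale
  and effect sizes planted as exact fractions of total variance.
  Genotypes are iid Hardy–Weinberg draws; whiteness is always derived
  from simulated L\*/a\*/b\*.

The generator does *not* emulate sequencing error profiles, mapping
bias, linkage disequilibrium, within-family genotype correlation, or
adapter-dimer artifacts. Passing tests therefore demonstrate the
correctness of the algorithms under the stated models, not robustness
to those real-data complications.

## Problem sizes and numerical choices

The shipped test-and-verification workloads use: 1000 random
(miRNA, UTR) pairs per seed length for exact oracle agreement; a
150-SNP bundle (50 per class) for impact recovery; 200 miRNAs with 20
planted 4-fold changes at 10^5 reads per pool for DE recovery; 5000
replicates for test-size calibration; 25 replicates of a 5%-variance
SNP at n = 786 for association recovery; and a 15-miRNA / 2000-read
synthetic study for end-to-end determinism. Tie-breaks and degenerate
inputs: ambiguous read assignments are dropped (counted, never
fractionally assigned); both-zero counts give p = 1; monomorphic SNPs
and zero-variance series are flagged untestable rather than erroring;
constant input to the rank transform is an error. All generators are
deterministic given their seed, and the orchestrated pipeline is
byte-identical across reruns with one seed.
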