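---
title: "Quantifying bisulfite-conversion quality from multiplex qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bisulfite-conversion quality from multiplex qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bisquer)
```

## The measurement problem

Bisulfite conversion — the chemical deamination of unmethylated cytosine to
uracil that underlies most DNA-methylation assays — damages the very sample
it prepares: DNA is fragmented by the acidic, high-temperature reaction,
part of it is lost during purification, and any cytosine that escapes
conversion is later misread as methylated. A laboratory choosing a
conversion kit, or deciding whether a precious low-input sample is still
usable downstream, therefore needs three numbers per converted sample:

* **conversion efficiency** — the fraction of convertible cytosines that
  actually converted;
* **degradation level** — how much the conversion step shifted the fragment
  size distribution;
* **recovery** — how much amplifiable material survived, relative to the
  genomic DNA (gDNA) that went in.

`bisquer` implements the computational side of a single multiplex TaqMan
qPCR assay that yields all three at once, plus the assay-design scans that
make such a system possible and a molecule-level simulator that makes every
stage testable without wet-lab data.

## Assay model

The assay interrogates two differently sized amplicons in multicopy
regions, a 104 bp "short" target and a 238 bp "long" target, both amplified
with **cytosine-free primers**: every primer footprint on the top strand
contains no C, so conversion cannot change the annealing site and a single
primer set amplifies gDNA and converted DNA (BS-DNA) identically. Four
fluorescence channels are read per well:

| channel | dye | detects |
|---|---|---|
| short-C | FAM | unconverted C at a single non-CpG site of the short amplicon |
| short-T | VIC | converted T at the same site |
| long-Cfree | NED | the long amplicon, with a probe containing no C |
| IPC | CY5 | a fixed dose of exogenous synthetic template (inhibition control) |

Quantification is by classical standard curves, Ct = *m*·log10(Q) + *b*,
fitted by ordinary least squares on a five-point genomic dilution series
(10, 2, 0.4, 0.08, 0.016 ng per 1 µl reaction). Human standard DNA produces
no short-T signal, so the short-T channel has no curve of its own. Instead,
synthetic **C/T indicator** oligos with a degenerate Y base at the
discrimination site — assumed to be 50 % C / 50 % T from synthesis — are run
at four dilutions (10^6^–10^3^ copies/µl), and the paired Cts of the two
short channels are regressed across the dilution series to give the
**transforming equation**

$$Ct_{C\text{-equiv}} = \alpha \, Ct_T + \beta,$$

which maps any short-T Ct onto the short-C scale so it can be read off the
short-C curve. Two modelling choices here were genuinely open and are worth
stating. First, the "relative ratio of Ct between short-C and short-T" is
implemented as a linear regression of paired Cts rather than a single Ct
ratio: only a regression generalises to arbitrary short-T Cts and produces
the R² that gates run reliability. Second, the regression direction is
short-C **on** short-T, because the transform consumes short-T Cts; under
noise the inverse fit is not the algebraic inverse. The fit's R² doubles as
a run-level quality gate: below 0.99 the whole run is flagged unreliable.
We fit one transform per run (the channels' relative efficiency is a
property of the run's chemistry); fitting one pooled transform across runs
would be the natural alternative if many runs of one lot are analysed
together.

## The three metrics

With per-sample amounts *q~C~* (short-C), *q~T~* (short-T, on the short-C
scale) and *q~L~* (long-Cfree), and a converted sample paired with its own
source gDNA:

$$\text{efficiency} = 100 \cdot \frac{q_T}{q_C + q_T} \qquad
\text{degradation} = \frac{(q_C^{BS} + q_T^{BS})/q_L^{BS}}
                          {q_C^{g}/q_L^{g}} \qquad
\text{recovery} = 100 \cdot 2 \cdot \frac{q_C^{BS}+q_T^{BS}}{q_C^{g}}
                  \cdot \frac{V_{elu}}{10}$$

The gDNA short amount uses the short-C channel only — gDNA has no short-T
signal. Pairing each converted sample with its own gDNA makes the
degradation level invariant to individual copy-number variation of the
multicopy targets: scaling all quantities of either sample by any constant
leaves it unchanged. A degradation level of 1 means the conversion step
preserved the short/long ratio; above 1, long fragments were preferentially
lost. The recovery's factor 2 exists because only the sense strand of
converted DNA is amplifiable while both gDNA strands are; the elution
factor (V~elu~/10 µl) compensates dilution when a kit elutes in a larger
volume. IPC Cts should be constant across a run; a sample more than 2
cycles (configurable) above the run median is flagged inhibited — the
threshold is our default, chosen as a clearly-abnormal shift on an
instrument whose replicate scatter is a few tenths of a cycle.

### Degenerate inputs

Undetermined Ct maps to amount 0 — no amplification within the protocol
means no detectable template, not missing data. Both short channels empty
leaves the efficiency undefined (`NA`). A converted sample with short
signal but no long signal gets degradation level `+Inf` with a flag:
severe degradation is a finding, and omitting such samples would bias kit
summaries toward their best samples. A gDNA partner with zero short-C or
long signal invalidates the pair (error): nothing can be normalised against
it.

### Replicate handling

Reactions run in duplicate. For *reporting* and QC the package collapses
replicates to the mean Ct; a pair with one undetermined well keeps the
numeric Ct and carries a dropout flag (discarding it would silently lose
exactly the low-copy samples the assay exists for), and a numeric spread
above 0.5 cycles raises a discordance flag. For *quantification*, however,
each well is converted to an amount first — undetermined contributing 0 —
and replicate amounts are averaged on the linear scale. The distinction
matters near the detection limit: with roughly one unconverted copy per
reaction (a near-perfectly converted sample), averaging Cts while dropping
undetermined wells conditions on detection and overestimates the
unconverted amount, visibly depressing the efficiency estimate; averaging
amounts that include zeros is unbiased at the Poisson level. This is also
how instrument software computes a "quantity mean" across replicate wells.

## Assay design scans

`bisulfite_convert()` applies the sequence consequence of conversion (C→T,
with C preserved in CpG context under the fully-CpG-methylated model) to a
reference; `scan_cfree_primers()` then enumerates *every* window of the
requested lengths whose top-strand footprint is C-free — exhaustive by
design, since the population of valid windows is the quantity of interest
and heuristic pruning belongs to downstream primer pickers. A footprint C
would read T after conversion and break annealing; consequently forward
primers contain no C and reverse primers (the footprint's reverse
complement) no G, which matches the published primer set of the assay.
`scan_discrimination_probes()` finds windows with exactly one C, in
non-CpG context, and emits the C/T probe pair. Melting temperatures use
the Wallace rule up to 14 nt and the basic GC formula above — a ranking
aid only, since such assays are tuned manually. `in_silico_pcr()` anneals
by exact match only (the primers are exact by construction; mismatch
models are out of scope) and reports products spanning both primer 5'
ends, the convention under which the assay's products measure 104, 238 and
147 bp. Coordinates are 0-based half-open throughout.

## What the simulator emulates

`simulate_run()` generates a complete plate — standards, indicators, NTC,
paired gDNA/BS-DNA wells in duplicate — from an explicit molecule-level
model:

1. each sample carries a lognormal per-individual copy-number factor
   (CV 0.15 by default) shared by both target loci;
2. a molecule of an *L*-nt amplicon survives fragmentation iff no break
   falls in its span: independent per-nucleotide breakage *b* gives
   survival (1−*b*)^(L−1)^ — the simplest model that produces
   size-dependent loss;
3. purification retains each molecule with probability *r*; only one
   strand is amplifiable (factor ½); the discrimination site converts per
   molecule with probability *p*;
4. template copies are Poisson-sampled into each 1 µl aliquot, so
   stochastic low-input effects are representable (`poisson_sampling =
   FALSE` gives the exact deterministic limit used by the float-precision
   tests);
5. channel Cts come from per-channel copy-scale curves plus Gaussian noise
   (0.15 cycles by default); zero copies or Ct > 40 is undetermined.

`expected_metrics()` states the closed forms the pipeline should recover:
efficiency 100·*p*, degradation level (1−*b*)^(104−238)^, and recovery
100·*r*·(1−*b*)^103^ (the elution correction cancels the eluate dilution by
construction). Defaults mirror the nominal study design: 20 sample pairs,
50 ng gDNA input measured at 5 ng/µl, 10 µl elution, duplicates, 40 cycles.
Values the design does not pin down were chosen once as field-realistic:
3300 locus copies per ng (≈10 copies per haploid genome for a multicopy
target), true curve slopes of −3.3219 (perfect doubling) with intercepts
placed so the 10 ng standard reads Ct ≈ 21.2 (short-C) and ≈ 22.6
(long-Cfree), a deliberately different short-T slope (−3.45) so the
transforming equation is non-trivial, conversion 0.995, breakage 0.00302/nt
(degradation level ≈ 1.5), retention 0.45, IPC Ct 27.

What the simulator does **not** model — and what passing tests therefore do
not establish about real data: sequence-context conversion biases,
probe cross-hybridisation between the C and T probes, PCR inhibitors
(IPC Cts are generated clean), inter-assay lot variation, and any
systematic error of the 50/50 indicator synthesis assumption
(`indicator_c_fraction` exposes it as a parameter so its effect can be
explored, but its true value in a physical oligo lot is unknowable from
within the assay).

## Statistical comparison of kits

Kit comparisons follow a two-gate cascade: Shapiro–Wilk per group, then
Levene's test (mean-centred, the classic form) across groups, both at
α = 0.05. Any non-normal group selects Kruskal–Wallis with
Bonferroni-corrected pairwise Wilcoxon tests; normal but heteroscedastic
data selects Welch's ANOVA with Games–Howell; normal homoscedastic data
selects one-way ANOVA with Tukey HSD. Failing the normality gate on *any*
group is the conservative reading of "test normality, then equal
variance". Games–Howell is computed from its studentized-range
formulation with Welch–Satterthwaite degrees of freedom per pair; for two
groups it reduces exactly to the Welch t-test, which the test suite uses
as an oracle. Results carry the conventional significance tiers (0.05,
0.01, 0.001).

## Problem sizes used by the test suite

The parameter-recovery tests run a 2×2×2 grid (conversion probability
0.94/0.999, degradation level 1.0/1.5, retention 0.2/0.5 — spanning the
ranges such assays report in practice) with 10 independent runs of 20
samples per cell. Because the fitted curves and transform are shared by
all samples of a run, per-run estimator means are correlated within a run;
the Monte-Carlo standard error is therefore taken across the replicate
runs, not across samples. Oracle-equivalence tests use random 500 nt
sequences for scans and 1 kb for conversion; regression fits are checked
against hand-written normal equations at 10^−9^.

## Known limitations

* Quantities are relative to the standard's calibration; no genome-size
  conversion between mass and copies is attempted, so cross-unit
  comparisons are forbidden by construction.
* Exact-match in-silico PCR will miss products a real polymerase would
  still make from mismatched primers.
* The reliability gate (transform R² ≥ 0.99) is a binary flag; it does not
  propagate transform uncertainty into the reported quantities.
* Kit summaries average per-sample metrics arithmetically (medians
  available); with `+Inf` degradation levels present, means are taken over
  finite values only, which is reported but can understate a kit's tail
  behaviour.
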