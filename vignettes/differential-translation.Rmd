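---
title: "Testing and classifying translational-efficiency changes with riboTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing and classifying translational-efficiency changes with riboTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

## The question riboTE answers

Ribosome profiling pairs two measurements of the same cells: mRNA-seq,
which counts transcripts, and ribosome-protected-fragment (RPF)
sequencing, which counts ribosomes sitting on those transcripts. When a
regulator is depleted, a gene's ribosome occupancy can change either
because its mRNA level changed (transcription/decay) or because its
*translational efficiency* (TE) — ribosomes per transcript — changed.
riboTE separates the two, classifies the affected genes by their joint
mRNA/TE behavior, and characterizes the resulting gene groups by
architecture (region lengths), 5'UTR structure, positional footprint
density, and mRNA synthesis-rate/half-life balance.

The motivating biology is the yeast 5'→3' exoribonuclease Xrn1, which —
beyond degrading mRNA — promotes the translation of a group of
membrane-protein mRNAs with long, structured 5'UTRs. The package's
generators therefore default to that regime: a `t0` (untreated) versus
`t30` (30 minutes of rapid regulator depletion) contrast with two
replicates per assay and condition.

## The interaction model

For each gene, counts across the $2\times2\times r$ samples are modeled
as negative binomial with a log link:

$$\log \mu_{j} \;=\; \log s_j + \beta_0 + \beta_A A_j + \beta_C C_j +
  \beta_I A_j C_j,$$

where $A_j=1$ for RPF samples, $C_j=1$ for the depleted condition, and
$s_j$ are median-of-ratios size factors computed once on the combined
mRNA+RPF matrix (one normalization per fitted matrix). The coefficients
decompose into the quantities of interest:

* `log2fc_mrna` $= \beta_C/\ln 2$ — mRNA abundance change;
* `log2fc_rpf` $= (\beta_C+\beta_I)/\ln 2$ — ribosome occupancy change;
* `delta_te` $= \beta_I/\ln 2$ — the TE change, the interaction term.

$\beta_I$ is tested with a Wald test ($z=\hat\beta_I/\mathrm{SE}$,
standard errors from the observed Fisher information) and controlled by
Benjamini–Hochberg FDR across tested genes. The GLM is fitted by
iteratively reweighted least squares at fixed dispersion; convergence is
declared when the largest coefficient change falls below $10^{-8}$
(at most 100 iterations; non-convergence is flagged and propagates as
missing statistics, never silently).

### Dispersion: per-gene moments, moderated

`estimate_dispersion()` is a transparent method-of-moments estimator:
size-factor-normalized counts are pooled *within* design cells
(deviations from each cell's mean, denominator $n-k$), and
$\hat\alpha = \max(10^{-8}, (s^2-\bar m)/\bar m^2)$. With two replicates
per cell this estimator has only four residual degrees of freedom, and
plugging it into a Wald test yields far too many small p-values — the
same reason dedicated RNA-seq engines shrink dispersions. `run_te_test()`
therefore moderates each gene's estimate toward the across-gene mean
with weight $d_g/(d_g+d_0)$, where $d_g$ is the residual df and $d_0$
(`dispersion_prior_df`, default 20) acts as prior degrees of freedom.
This is deliberately *not* a full empirical-Bayes treatment — no trend
on the mean, no posterior variances — just enough pooling that the
type-I error of the interaction test is nominal, which the acceptance
suite verifies on 2000 simulated null genes (rejection at $p<0.05$
within $0.05 \pm 0.015$). Setting `dispersion_prior_df = 0` recovers the
raw per-gene estimator.

### Classification

Significant genes (`fdr < 0.05`, strict) are classified by two axes:

* direction: `activated_*` when `delta_te < 0` (the gene *needed* the
  regulator: efficiency falls upon depletion), `repressed_*` when
  `delta_te > 0`;
* mRNA status: `buffered` when `|log2fc_mrna| < 0.433` (strictly),
  `decreased` / `increased` beyond that boundary. The default 0.433
  log2 units is `log2(1.35)` — a ±35% mRNA change.

All $2\times3$ combinations are representable; classification is total,
with missing statistics mapping to `not_regulated`. Boundary ties go
away from significance (`fdr` exactly at the cutoff is not significant)
and away from buffering (`log2fc_mrna` exactly at ±0.433 is not
buffered).

## Positional analyses

**RPF metagene.** The first 15 codons of each CDS are masked
(elongation-inhibitor artefacts concentrate there), genes with fewer
than 40 retained codons are excluded, and each retained codon count is
normalized observed/expected with
`expected = library_total / total retained codons` — uniform usage over
the *whole analysis set*, not just the profiled group, so a group-wide
footprint shift survives normalization while sequencing-depth
differences cancel exactly. Normalized values are averaged over
replicates, t30 values are divided per gene by that gene's linear mRNA
fold change, and codon positions are mapped to 100 equal-width relative
bins by overlap-weighted averaging (every bin is defined for any gene
length; a uniform gene maps to an exactly flat profile). The choice of
100 relative bins is a convention for "along the CDS"; absolute codon
indices would conflate length classes.

**TIS-anchored structure profile.** Per-nucleotide structure scores
(PARS-style: log-ratio of double- to single-strand-specific nuclease
cuts; higher = more structured) are aligned at the first CDS nucleotide.
Genes contribute upstream coordinates only as far as their 5'UTR extends
(up to 100 nt) and downstream only as far as their CDS extends (up to
300 nt); per-position means skip missing scores, and the number of
contributing genes is reported per position. Region averages over
5'UTR/CDS/3'UTR use the same skip-missing convention; zero-length
regions yield missing values rather than zeros.

**Group comparisons.** Feature distributions (lengths, region structure
scores, rate changes) are compared to the unregulated background with a
two-sided Wilcoxon–Mann–Whitney test: exact by enumeration of label
assignments for $n_1+n_2 \le 12$ (valid under ties), otherwise a normal
approximation with tie correction and a 0.5 continuity correction
(always applied — conservative at moderate n).

## Rates, translatability, and polysomes

Genomic run-on (GRO) records decompose steady-state mRNA abundance into
synthesis and decay: `SR = nTR / cell_volume` (nascent transcription
rate corrected by average cell volume) and `HL = RA / SR`, all in
arbitrary units — no calibration to minutes is attempted, and half-life
ratios between conditions are compared as raw per-gene log2 ratios
without further transcriptome-wide normalization. Translatability
(protein change over mRNA change, relative to a reference) and its
cap-corrected variant (`t × capped_wt / capped_mut`, reference fully
capped by default) reproduce reporter-assay arithmetic. Shut-off decay
fits are log-linear least squares (equivalent to a nonlinear exponential
fit for clean decays and standard for shut-off time courses); a
non-negative slope is reported as an infinite half-life, flagged rather
than silently dropped. Polysome gradients are normalized to unit total
signal and summed over the five canonical fraction groups (free 1–5,
subunits 6–11, monosomes 12–15, light 16–21, heavy 22–26).

## What the synthetic data emulates

The generator produces the full input universe with known ground truth:

* **Classes.** Five occupied regulated subgroups plus background. The
  default proportions (4% activated-buffered, 2.5% activated-decreased,
  3.5% + 3.5% + 1.5% repressed, 85% background) keep the
  activated:repressed balance near the genome-scale ratio; the exact
  split within directions is a free modeling choice, as only the totals
  are constrained by observation.
* **Architecture.** Region lengths are log-normal per class (median +
  log-scale 0.6, a typical spread for yeast transcript regions), with
  class medians encoding the observed contrasts: activated genes 80 nt
  5'UTR / 1555.5 nt CDS versus 52 / 1113 nt background, repressed
  classes shorter, and an extended 3'UTR only for the
  repressed-buffered class. CDS lengths are forced to positive
  multiples of 3.
* **Structure.** Profiles are per-region class baselines (5'UTR 0.16
  activated vs 0.06 background vs 0.03 repressed-decreased; CDS
  0.32–0.35 regulated vs 0.25) plus a per-gene offset, Gaussian noise
  (sd 0.5), 2% missing scores, and a TIS window `[-100, +50]`: every
  class except the activated ones gets a score *dip* in `[-20, 0]`
  (start sites are normally kept accessible), while activated
  transcripts keep — and slightly raise — their structure through the
  TIS. This reproduces the qualitative contrast the TIS metagene must
  detect, not a mechanistic folding model.
* **Counts.** NB draws with per-gene base mean (log-normal around 200),
  shared dispersion 0.1, mRNA effects applied at t30 and TE effects
  additionally to RPF samples; codon coverage is multinomial given the
  gene's RPF count (uniform, or a geometric 5' ramp on request).
* **Rates.** Baseline SR and HL are log-normal; at t30 the activated
  class loses synthesis (×0.5) and gains half-life (×2) with
  log-normal noise (sd 0.2), other classes are unchanged; `RA = SR×HL`
  and `nTR = SR × volume` hold exactly by construction.
* **Labels.** Membrane-protein probability 0.5 in activated classes vs
  0.25 elsewhere (giving a ~2-fold enrichment to recover), SRP-dependent
  and -independent routes equally likely among membrane genes.

Seeding is hierarchical: one master seed, per-component seeds derived
from the component name, so adding a generator never perturbs the
streams of existing ones, and every artifact is byte-reproducible.

What the generator does *not* emulate: sequence content (no nucleotides
are drawn, only lengths and scores), positional biases beyond the
optional 5' ramp, correlated replicates, batch effects,
mean-dependent dispersion trends, or the capture asymmetry between
oligo(dT) RNA-seq and footprint libraries. Passing tests therefore
certify the computations, and the calibration of the test under the
stated noise model — not robustness to every artefact of real libraries.

## Statistical reality of the two-replicate design

With two replicates per cell and dispersion $\alpha$, the interaction
estimator's standard deviation is bounded below by
$\sqrt{4\alpha/r}/\ln 2$ log2 units even at unbounded counts — about
0.65 log2 units at $\alpha=0.1$, $r=2$. A one-log2-unit TE change is
thus a ~1.5σ effect: its detection probability at FDR < 0.05 is a few
percent, and the acceptance suite reports exactly that (the recovery
fraction it computes is ~0.3% under those conditions, with direction
accuracy near 1 among nominally significant genes and estimator bias
within ±0.1 at base mean 500). This is a property of the design, not of
the implementation; the genome-scale experiment compensates with
thousands of genes, catching the strongest effects. Validation runs that
need high per-gene power (e.g. the classifier's label contract) use
8 replicates or lower dispersion instead; problem sizes throughout the
suite (2000–6000 genes, 300-gene pipeline runs) were chosen as the
smallest at which the measured quantities are stable across seeds.

Because median-of-ratios normalization anchors on the majority of genes,
bias measurements balance activated and repressed genes so that the
anchor stays on the unregulated majority — one-sided regulation of a
sizeable gene fraction is partially absorbed into size factors, in this
implementation as in any median-of-ratios engine.

## Numerical and degenerate-input conventions

* All readers reject malformed input with the offending line/cell;
  writers emit fixed six-significant-digit TSV, so equal inputs give
  byte-identical files (the structure-score writer keeps 7 digits and
  round-trips values of that precision exactly).
* All-zero genes, failed or non-converged fits: missing statistics,
  `not_regulated`, never an aborted run; counts of such genes are kept
  as attributes and in the run log.
* Empty regions, genes shorter than the mask, groups without profiles:
  excluded and counted, with hard errors reserved for inconsistent
  inputs (gene-id mismatches, zero library totals, empty groups).
* The run log contains parameters and soft-failure counts only; timing
  goes to the console, keeping result directories byte-comparable.

## Known limitations

* The NB fit serves the 2×2 interaction design; it is not a
  general-purpose GLM engine (no arbitrary contrasts, no quasi-
  likelihood, no LRT — the Wald convention matches the field's default
  reporting).
* Dispersion moderation uses a single prior df and a global center; a
  mean-dispersion trend would track real data better but is out of
  scope by design.
* GO-term enrichment and raw-read processing (alignment, codon
  assignment) are outside the package: the pipeline starts from count
  and coverage tables.
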