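---
title: "Methods: ARE-centric cistrome analysis with cistromere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ARE-centric cistrome analysis with cistromere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromere)
```

## Scope and model

`cistromere` re-implements, as a tested pipeline, a family of analyses
built around the canonical androgen response element (ARE) — the
palindromic full-site motif bound by the androgen receptor (AR) dimer —
in AR ChIP-seq cistromes:

1. **Motif content of peak sets.** Each peak is called ARE-positive when a
   position weight matrix (PWM) scan of the central window (100 bp total
   width by default) yields at least one hit above threshold. The
   per-sample statistic is the *fraction of peaks with a motif*; groups of
   samples are compared with the Mann–Whitney U test (unpaired cohorts) or
   the Wilcoxon signed-rank test (matched tumor/normal pairs).
2. **Motif density profiles.** Hits are counted in 10-bp bins across a
   2,400-bp window around peak centers and normalized to
   hits/bp/peak; two conditions are compared by bin-wise subtraction,
   optionally smoothed with a second-degree (Savitzky–Golay, 5-bin)
   filter. Values above zero read as enrichment, below zero as depletion.
3. **Chromatin-state segmentation.** Binarized histone-mark calls on
   200-bp bins are modelled with a hidden Markov model whose per-state
   emissions are independent Bernoullis per mark (the ChromHMM model
   class). States are ordered from heterochromatin-like (E1) to active
   promoter/enhancer-like (EK) and mapped to the numeric values 1..K.
4. **Gene-signature scoring.** A signature is a pair of up/down gene
   sets; a sample's score is `sum(z(up)) - sum(z(down))` with z-scores
   computed per gene across the scored cohort.
5. **Survival association.** Scores stratify cohorts into quartiles
   Q1–Q4; groups are compared with Kaplan–Meier curves and the log-rank
   test, and effects are estimated with Cox proportional-hazards models.

Everything is exercised end to end on synthetic data with planted ground
truth; no external genomics datasets are required or bundled.

## Motif scanning and the calibrated threshold

Windows of length L are scored on both strands with the log-odds sum
`sum_j log2(p_j(base_j) / bg(base_j))` in bits; windows containing `N`
score `-Inf`. When both strands hit at the same offset only the higher
score is kept, ties broken to `+`.

The tools this analysis style descends from apply per-motif log-odds
cutoffs that are not printed anywhere, so the package calibrates its own
default: the smallest score whose per-position false-positive rate under
the background model is at most `1e-4`. The score distribution is
computed by dynamic programming over positions on a 0.001-bit grid.
Per-position scores are rounded *up* onto the grid, which makes the grid
distribution stochastically dominate the true one and the returned
threshold a guaranteed FPR bound; the cost is a threshold conservative by
at most L/1000 bits. Because the calibration substitutes for an unknown
cutoff, absolute fractions on real data may differ from externally
reported values; all within-package comparisons are
internally consistent.

The "100 bp window" and "2,400 bp window" of the presence and density
analyses are read as *total* widths centered on the peak center; both are
arguments, since conventions differ between tools.

## Interval algebra

Coordinates are 0-based half-open (BED) throughout; 1-based formats
(GFF3) are converted at the boundary. Overlap means sharing >= 1 bp;
half-open abutment is not overlap. `consensus_peaks()` merges the
per-base union of all input intervals into maximal blocks (touching
intervals form one block) and keeps blocks overlapped by >= 2 distinct
input sets; peaks within one set are merged first so a set contributes at
most one vote. This reading of "shared among two or more datasets" is
pinned by a per-base counting oracle in the test suite. Strand is carried
but ignored by overlap math — AR binding sites are unstranded.

## The HMM and its fitting choices

Baum–Welch EM with scaled forward–backward (Rcpp) treats chromosomes as
independent sequences. Initialization is uniform-plus-jitter under a
fixed seed, with the best of `n_restarts` (default 5) runs kept by final
log-likelihood; convergence is a log-likelihood gain below `1e-4`.
Emissions are clamped to `[1e-4, 1 - 1e-4]` to keep the likelihood
finite; the clamp binds only in degenerate corners. The EM guarantee
(non-decreasing log-likelihood, within 1e-8) is asserted on every fit in
the tests. `K = 1` falls back to the closed form (emissions = column
means) with a warning; an all-false matrix is rejected.

State ordering uses the operational score
`sum(active-mark emissions) - sum(repressive-mark emissions)`, ascending,
ties broken by total emission mass. Annotation pipelines often refine
state naming with laminB1-LAD and CpG-island context; that is out of
scope here, so the numeric transform is exactly the rank 1..K.

## Signature scoring conventions

z-scores use the sample standard deviation (n − 1) across the scored
cohort; neither the divisor nor the reference population is dictated by
the scoring formula itself, so this choice is recorded here and in the
score attributes.
Signatures applied to an external cohort are z-scored *within* that
cohort. Genes absent from the matrix or with zero variance are dropped
with a reported count, never imputed. Signature derivation defaults to
`padj <= 0.05` and `|log2FC| >= 1`; "significant" admits many
operationalizations, so both are arguments. The surrogate DE engine is a per-gene Welch t-test
with BH adjustment — an explicitly labelled stand-in used to exercise
derivation on synthetic cohorts, not a count-model DE method.

## Survival analysis

Cox models use Efron tie handling and Wald confidence intervals; fits
with fewer than `covariates + 5` events are refused. Quartiles use
linear-interpolation quantile breaks with ties assigned to the lower
quartile, Q1 = lowest. p-values are reported unadjusted — the exploratory
clinical analyses this supports conventionally apply no multiplicity
correction, and any adjustment policy belongs to the caller.

## What the synthetic world emulates — and what it does not

The generators plant the statistical structure each stage assumes:

- `make_genome()`: i.i.d. bases, GC 0.41 (human-like average).
- `make_peak_sets()`: non-overlapping fixed-width peaks; exactly
  `round(n * fraction)` carry the consensus site at their center, and the
  central scan window of every other peak is rejection-sampled to be
  motif-free, so the planted fraction is recovered *exactly*. Real peaks
  have variable widths, motif offsets and co-occurring motifs; a green
  recovery test establishes correctness of the counting machinery, not
  realism of cistromes.
- `make_matched_cohort()`: per-patient (normal, tumor) fraction pairs
  with fixed depletion plus Gaussian noise. The default of n = 8 pairs is
  the smallest design whose fully concordant exact two-sided p reaches
  2/2^8 = 0.0078125; the size is configurable.
- `make_mark_tracks()`: states from the Markov chain, marks from the
  emission Bernoullis — exactly the fitted model class, so parameter
  recovery tests are well-posed. Real histone data violate conditional
  independence between marks.
- `make_expression_cohort()`: gene baselines ~ Normal(8, 2) log2 units
  (typical of log2 TPM), per-observation noise SD 0.5, planted ±effect
  shifts in the treated group. The exact-recovery acceptance test uses
  10 vs 10 samples so that a null gene reaching |log2FC| >= 1 is a > 4 sd
  event and exact signature recovery holds by design rather than by seed.
- `make_survival()`: exponential event times with hazard
  `h0 * exp(beta * z)`, independent exponential censoring calibrated to
  the target censored fraction under the null. No competing risks, no
  time-varying effects.

Every generator is deterministic given its seed, and seeds are recorded
in output headers and truth sidecars.

## Numerical choices

- Exact paired signed-rank p (n <= 25) by the shift-algorithm DP over all
  2^n sign assignments on doubled midranks, so tied |differences| are
  enumerated exactly; zero differences are dropped, all-zero pairs return
  p = 1 by convention. Unpaired comparisons use exact enumeration when
  the pooled n <= 25 and values are untied, otherwise the normal
  approximation with tie correction.
- Density-profile smoothing is the Savitzky–Golay quadratic kernel
  (-3, 12, 17, 12, -3)/35 applied circularly; the symmetric unit-sum
  kernel then preserves the profile mean exactly, which the tests assert.
  The flanks of a 2,400-bp profile are near-background on both ends, so
  circular wrap-around introduces no visible artifact.
- Signal windows clipped at chromosome edges are `NA`, excluded from
  profile means — zero-filling would bias edge profiles toward 0.
- PCA component signs are fixed by making each component's
  largest-magnitude loading positive, for cross-platform determinism.
- Peak centers use `floor((start + end) / 2)`; odd spans round down.

## Known limitations

- Motif presence calls depend on the calibrated threshold, which stands
  in for tool-specific per-motif cutoffs; absolute fractions on real
  cistromes are not directly comparable across scanners.
- bigWig is not read natively; tracks travel as bedGraph.
- The HMM assumes conditionally independent marks within a state and
  Bernoulli (presence/absence) observations; it does not model signal
  magnitude.
- Reproducing cohort-specific clinical effect sizes requires
  proprietary or controlled-access patient datasets and is intentionally
  out of scope; the survival stage demonstrates direction and
  calibration on synthetic cohorts only.
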