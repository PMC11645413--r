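# cistromere

Motif-centric analysis of androgen receptor (AR) cistromes: how much of a
ChIP-seq peak set carries the canonical androgen response element (ARE),
how motif density and enhancer signal distribute around peak centers, how
chromatin states organize around those sites, and whether gene signatures
derived from ARE modulation associate with patient survival.

The package is aimed at computational biologists studying AR biology in
prostate tissue, where a recurring observation is that canonical AREs are
depleted from the tumor AR cistrome relative to normal tissue. It
provides the full analysis chain as reusable, tested R functions, plus a
synthetic-data module that generates every input with planted ground
truth, so each stage can be validated end to end without any external
dataset.

## What it computes

- **PWM scanning** — log-odds scores in bits,
  `sum_j log2(p_j(b_j) / bg(b_j))`, both strands, with a scan threshold
  calibrated by dynamic programming to a background false-positive rate
  of 1e-4 per position.
- **Fraction of peaks with motif** — per-sample fraction of peaks whose
  central 100-bp window contains a hit; Mann–Whitney (unpaired) and
  exact Wilcoxon signed-rank (matched pairs) comparisons.
- **Motif density profiles** — hits/bp/peak in 10-bp bins over a 2,400-bp
  window around peak centers; differential profiles by subtraction with
  optional second-degree (Savitzky–Golay) smoothing.
- **Interval algebra** — BED I/O, >= 1 bp overlap tests, per-base
  subtraction, consensus peaks shared by >= 2 datasets.
- **Signal tracks** — bedGraph I/O on fixed bin grids, RPKM
  normalization, anchored signal matrices and profiles, sample PCA over
  consensus regions.
- **Chromatin states** — Bernoulli-emission hidden Markov model
  (Baum–Welch in Rcpp) on binarized histone-mark calls, Viterbi/posterior
  decoding, E1..EK state ordering by active-minus-repressive emissions.
- **Gene signatures** — `score = sum(z up-genes) - sum(z down-genes)`
  per sample; signature derivation from DE tables; Fisher
  over-representation tests; quartile stratification Q1–Q4.
- **Survival** — Kaplan–Meier curves, log-rank tests, Cox
  proportional-hazards fits (Efron ties, Wald CIs) via the survival
  package.

## Worked example

```r
library(cistromere)
are <- load_motif(system.file("extdata", "ARE_synthetic.pfm",
                              package = "cistromere"))
print(are)
#> PositionWeightMatrix 'ARE_synthetic': length 15, default threshold 9.010 bits

# two simulated cistromes with planted ARE fractions (normal vs tumor)
g1 <- make_genome(c(chr1 = 50000), seed = 1)
normal <- make_peak_sets(g1, n_peaks = 50, are_fraction = 0.40,
                         pwm = are, seed = 1)
fraction_with_motif(normal$peaks, normal$genome, are)
#> [1] 0.4

# matched tumor/normal pairs: exact paired Wilcoxon
m <- make_matched_cohort(8, normal_mean = 0.40, depletion = 0.15,
                         noise_sd = 0.02, seed = 1)
compare_fractions(m$normal, m$tumor, paired = TRUE)$p_value
#> [1] 0.0078125

# survival cohort driven by a signature score (planted beta = -0.75)
set.seed(1)
co <- make_survival(rnorm(400), beta = -0.75, seed = 1)
q <- quartile_stratify(co$score)
logrank(co, q)$chisq
#> [1] 118.7
cox_fit(co, "score")[, c("hr", "ci_lower", "ci_upper")]
#>     hr  ci_lower  ci_upper
#> 1 0.47      0.41      0.53
```

The planted fractions come back exactly (0.40), eight concordant matched
pairs give the smallest achievable exact two-sided p (2/2^8 = 0.0078125),
and the Cox hazard ratio per standardized score unit recovers the planted
effect (exp(-0.75) = 0.47): higher ARE-activation scores, lower hazard.

A full demo run — simulation through motif statistics, density profiles,
chromatin-state fitting, signature scoring and survival — is one call:

```r
run_pipeline(default_config(outdir = "demo_run", seed = 1))
```

or from the shell:

```sh
Rscript inst/cli/cistromere.R run-all --outdir demo_run --seed 1
```

Outputs are TSV/JSON/BED/bedGraph files plus `manifest.json` recording
the package version, seed, all parameters and per-file checksums; reruns
with the same seed are byte-identical.

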