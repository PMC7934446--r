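---
title: "Statistical model and design notes for atacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical model and design notes for atacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacsim)
```

`atacsim` simulates single-cell ATAC-seq bin-by-cell count matrices from
a profile estimated on one biological cell group. This vignette records
the model, its assumptions, the tunable parameters, the numerical
choices, and what the package's own tests do and do not demonstrate.

## The generative model

Let `M` be a `B x C` matrix of non-negative read counts, rows indexed by
fixed-width genomic windows (bins, 5 kbp by default) and columns by cells
of one group. The simulator draws, in order:

1. **Library sizes.** `log2(l'_i)` from the two-component Gaussian
   mixture `w N(mu1, sigma1^2) + (1 - w) N(mu2, sigma2^2)`. Library
   sizes are kept continuous — they act only as Poisson scale factors, so
   rounding would add bias for no benefit. The two-mode form reflects
   droplet platforms, where empty-ish and loaded droplets produce a
   bimodal depth distribution; plate-based data are usually unimodal and
   are represented by `w = 1` with both components equal, so one
   container type covers both regimes.

2. **Sparsity mask.** `X_ji ~ Bernoulli(p_j)` independently, where `p_j`
   is the estimated fraction of cells with a non-zero count in bin `j`.
   The simulated proportion `p'_j` is the realized row mean of `X` —
   an identity, not an estimate.

3. **Bin means.** `m'_j = beta0 + beta1 p'_j + beta2 p'_j^2`, evaluated
   at the *simulated* proportions so that the mean structure follows the
   realized sparsity of each run. Negative polynomial values are clamped
   to 0, and `m'_j` is forced to 0 where `p'_j = 0` so fully closed bins
   carry no Poisson mass.

4. **Counts.** `c_ji = X_ji * Poisson(gamma * l'_i * m'_j / sum_k m'_k)`.
   The ratio apportions each cell's depth across bins by relative mean
   accessibility; with a full mask and `gamma = 1` the expected per-cell
   total is exactly `l'_i`.

5. **Optional noise.** `c_ji + int(N(mean, sd))`, clamped at 0, applied
   to every entry including zeros. `int()` rounds half away from zero
   (the integerization is not otherwise pinned down by the model; this
   choice is symmetric around zero). Disabled by default.

### Model assumptions

- Entries are independent given the profile: no co-accessibility, no
  per-cell covariates beyond depth, no chromosomal covariance.
- A single profile describes one homogeneous cell group; heterogeneous
  datasets should be split by group and simulated per group.
- Masked-in entries may still be zero by Poisson chance, so realized
  sparsity is at least the Bernoulli sparsity. The alternative — forcing
  `X = 1` entries positive — would inflate the conditional mean and was
  rejected; the Poisson form is taken literally.

### A consequence worth knowing: library-size thinning

Because the Poisson mass in masked-out entries is discarded, the
expected realized library size is `l'_i * sum_j(p_j m'_j) / sum_j(m'_j)`,
which is below `l'_i` whenever accessible mass sits in bins with
`p_j < 1`. Estimating a profile from a simulated matrix therefore
recovers the mixture *shape* (weight, standard deviations, distance
between modes) while both means shift down by the same constant,
`log2(sum p m' / sum m')`. On heavily sparse groups — including the
package's default fixtures — this shift is material (about −2.6 log2
units at the defaults), and iterating simulate → estimate → simulate
shrinks library sizes at each round. The resemblance metrics on bin
means and non-zero proportions are unaffected; sorted-library-size
comparisons between an input matrix and a re-simulated one include this
systematic component.

## Estimation

- **Non-zero proportions** are exact counts: `p_j = #\{i: M_ji > 0\}/C`.
- **Normalization** divides each column by its library size and
  multiplies by the median library size, so every normalized column sums
  to the median; bin means are row means of this matrix.
- **The quadratic** is ordinary least squares over all bins, unweighted,
  including bins with `p_j = 0`. Excluding closed bins or weighting by
  coverage would change `beta` on sparse groups; the all-bins fit is the
  simplest defensible convention and is stated here so users can
  pre-filter if they prefer.
- **The mixture** is fitted by EM on `log2` column sums after dropping
  zero-library cells (they carry no depth information and would break
  the log transform; they are reported via a warning and excluded from
  `n_cells_source`).

### EM numerical choices

Responsibilities are initialized by a hard split of the sorted values at
the median — deterministic, so a fit is reproducible without any RNG.
Iteration stops when the log-likelihood moves by less than `1e-6`
(absolute), with a cap of 500 iterations and a warning (plus best-so-far
parameters) on non-convergence; non-convergence is common and benign
when two components chase a genuinely unimodal sample. Component
variances are floored at `1e-6` to prevent collapse onto point masses;
a constant input yields both means equal with the floored variance.
Components are reported sorted by mean so `(mu1, sigma1, w)` always
names the lower mode. With `platform_hint = "auto"`, one- and
two-component fits are compared by BIC (2 vs 5 parameters). On real
bin-by-cell matrices the realized depth distribution is Poisson-broadened
and left-skewed, so "auto" may legitimately prefer two components even
for nominally unimodal platforms; the hint exists precisely so users can
assert platform knowledge instead.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `bin_width` | 5000 | bp | genome tiling resolution; ~600k bins for the canonical human genome |
| `n_components` | 2 | — | library-size mixture modes (1 for plate-based platforms) |
| `gamma` | 1 | — | multiplies every Poisson mean; <1 sparser, >1 denser |
| `noise_mean`, `noise_sd` | 0, 0 | counts | optional additive integer Gaussian noise, clamped at 0 |
| `n_peaks` | — | bins | peak-by-cell conversion keeps the top bins by mean |

`gamma` perturbs sparsity smoothly: realized zero fraction is monotone
non-increasing in `gamma` (verified across 0.8–1.2 in the test suite).
Noise trades distributional fidelity for harder clustering benchmarks:
negative-mean noise erodes weak signals and raises sparsity, which is
why it is off by default.

## Evaluation metrics

Resemblance uses `MAD = median|R - S|`, `MAE = mean|R - S|`,
`RMSE = sqrt(mean((R - S)^2))` on sorted library sizes (a
distribution-level comparison; with unequal cell counts the simulated
sorted vector is mapped by linear quantile interpolation and the report
flags it), and bin-wise on bin means and non-zero proportions, plus
Pearson correlations of the two bin-wise summaries. Multi-run reports
average over independently seeded simulations (`seed, seed + 1, ...`).

Clustering agreement: NMI normalizes mutual information by
`max(H(gt), H(pred))`; AMI subtracts the exact expected MI under the
permutation (hypergeometric) model and divides by the *arithmetic mean*
of the entropies minus `E[MI]` (some references use the max; the
arithmetic-mean convention is deliberate here); ARI is the standard
pair-counting form. Entropies use natural logs — the base cancels in
every normalized score. Degenerate cases are defined explicitly: two
constant labelings score 1, exactly one constant labeling scores 0, and
a vanishing adjusted denominator returns 1 only when the two partitions
are identical. These conventions match scikit-learn's, and the test
suite pins them against frozen reference values plus brute-force
contingency, `dhyper`-based, and pair-enumeration oracles.

## Fixtures: what they emulate and what they do not

`make_fixture()` builds a synthetic "real" input with known ground
truth: 60% of bins fully closed, open-bin proportions from Beta(0.5, 8)
(median ≈ 0.03, mimicking the heavy zero-inflation of genome-wide 5-kbp
binning), the bimodal library model `0.4 N(11, 0.5^2) + 0.6 N(13.5,
0.6^2)` on the log2 scale, and a convex mean curve
`(beta0, beta1, beta2) = (0.02, 2.5, 6)`. These are documented synthetic
choices of plausible magnitude, not estimates from any published
dataset.

Because fixtures are drawn from the package's own generative model,
passing recovery and self-resemblance tests demonstrates *internal
consistency* — estimators invert the simulator — not that the model
captures everything in real chromatin data. Real matrices carry
co-accessibility structure, batch effects, per-cell GC/size biases and
doublets, none of which the model represents; profiles estimated from
real data inherit only the three modeled summaries.

## Problem sizes and determinism

The shipped tests and the acceptance script run the self-resemblance
loop at 1000 cells × 2000 bins with 20 simulation runs, mixture recovery
at 10,000 draws, and conservation checks at 1000 bins × 500 cells —
sizes chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo error far below the asserted tolerances. Every
stochastic step consumes a single seeded RNG stream in a fixed order
(library sizes → mask, bin-fastest → Poisson draws over mask entries in
column-major order → noise), so `simulate_matrix()` is bit-reproducible
for a given profile and settings, and distinct seeds give independent
runs.

## Known limitations

- No read-level output (fragments/BAM): the simulator produces count
  matrices only.
- Bin–region aggregation counts a bin fully toward every region it
  touches by ≥ 1 bp; partial overlaps are not length-weighted (pre-split
  regions at bin boundaries for proportional assignment).
- One profile per cell group; no joint multi-group estimation.
- The library-size thinning described above: simulated *realized* depth
  sits below the mixture draws in proportion to how much accessible
  mass lies in partially open bins.
- Additive noise changes library-size and sparsity distributions; it is
  a benchmarking difficulty dial, not part of the fitted model.
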