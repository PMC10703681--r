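---
title: "Imputing mixed-type phenotypes with a copy-masked denoising autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing mixed-type phenotypes with a copy-masked denoising autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocomplete)
```

## The problem

Population biobanks measure hundreds of phenotypes — laboratory assays,
questionnaire answers, diagnostic codes, derived disease definitions —
across hundreds of thousands of individuals, but most phenotypes are missing
for most people: questionnaires are administered to subsets, assays are
costly, and follow-up modules are optional. Missingness is rarely scattered
at random. When an individual skips a questionnaire, *every* answer in that
module is absent together, producing strongly block-structured missingness
whose per-phenotype rates can range from below 1% to above 99%.

Because phenotypes share genetic and environmental causes, the observed
phenotypes of an individual carry real information about the missing ones.
`phenocomplete` exploits this by fitting a denoising autoencoder to the
samples-by-phenotypes matrix and using it to fill in missing entries —
continuous traits on their measurement scale, binary traits as
probabilities — so that downstream analyses (association testing in
particular) can use all individuals rather than only the observed subset.

## The model

Let $\tilde X$ be the $N \times P$ phenotype matrix and $M$ the matching
observedness indicator ($M_{ij} = 1$ when phenotype $j$ is measured on
individual $i$). Columns are ordered so the first $C$ phenotypes are
continuous (ordinal traits are treated as continuous and counted in $C$)
and the remaining $P - C$ are binary.

A feed-forward network $h$ maps each (normalized, zero-filled) row through
hidden layers with a leaky-rectifier nonlinearity $\Phi$ and an affine
output layer; outputs $1..C$ are returned raw and outputs $C{+}1..P$ pass
through the sigmoid $s(x) = 1/(1+e^{-x})$, so binary reconstructions lie in
$(0,1)$. With one hidden layer,

$$h^{(1)} = \Phi(W^{(1)} \tilde X_{i,:} + b^{(1)}), \qquad
  h^{(2)} = W^{(2)} h^{(1)} + b^{(2)},$$
$$h(\tilde X_{i,:}) = \bigl(\{h^{(2)}_j\}_{j \le C},
  \{s(h^{(2)}_j)\}_{j > C}\bigr).$$

Training minimizes a joint reconstruction loss summed over **all originally
observed cells**: squared error for continuous positions and cross-entropy
for binary positions. Crucially, the loss also covers cells deliberately
hidden from the network's input, which is what makes the objective a
*denoising* one — the network is graded on values it could not see.

The final imputed matrix copies observed values through unchanged and takes
the network reconstruction elsewhere:
$\hat X_{i,:} = M_{i,:} \cdot \tilde X_{i,:} + (1 - M_{i,:}) \cdot
h(\tilde X_{i,:})$.

### Copy-masking

The augmentation that hides input cells does not mask uniformly at random.
Each epoch, with probability $\rho$ per individual, a missingness pattern
$\tilde m$ is drawn uniformly from the *rows of the data's own mask matrix*
and multiplied into that individual's input mask. Simulated missingness
therefore inherits the questionnaire-block structure of real missingness:
whole modules vanish together, exactly the situation the model faces at
imputation time. The same procedure generates evaluation masks — donor
patterns are applied to recipient rows until a target fraction of observed
cells is withheld — so measured accuracy reflects structured, not
uniformly scattered, missingness. Uniform masking is retained as an
explicit ablation (`mask_mode = "uniform"`, `simulate_missingness_uniform()`)
because it both trains worse on block-missing data and *inflates* apparent
accuracy when used for evaluation.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `rho` | 0.8 | probability a row is copy-masked each epoch; the single most influential tuning knob (0.8 suits sparse collections, ~0.3 denser ones) |
| `hidden` | `ceil(1.5P), ceil(0.7P)` | hidden widths; three weight layers carry most of the achievable accuracy |
| `leaky_slope` | 0.01 | negative-side slope of $\Phi$; fixed, not learned |
| `learning_rate` | 0.1 | initial SGD step; halved after `lr_patience = 10` stagnant epochs |
| `momentum` | 0.9 | SGD momentum |
| `batch_size` | 2048 | rows per mini-batch (assumes biobank-scale $N$; see below) |
| `epochs` | 500 | upper bound; the returned weights are the best-validation checkpoint |
| `validation_fraction` | 0.2 | held-out share of training rows used only for checkpointing |

Normalization is fitted on the non-validation training rows only
(population, divide-by-$N$ standard deviation) and applied to every other
split, so no test statistics leak into training. Binary inputs are encoded
$-0.5/+0.5$ with $0$ for missing, making zero-fill the neutral point
between classes; loss targets stay on the $0/1$ scale.

### Design choices where the design was open

* **Rectifier sign.** We use the conventional LeakyReLU
  $\Phi(x) = \max(0,x) + l_\Phi \min(0,x)$. The sign-flipped variant
  $\max(0,x) - l_\Phi \min(0,x)$, which maps negatives to small positive
  values, is available as `phi_variant = "printed"` for users who want
  that behaviour; in practice the two fit comparably at slope 0.01.
* **Validation objective.** The checkpointing loss is the joint loss on the
  validation rows under a *single, seed-frozen* copy-mask, so the
  validation objective matches the imputation task and is stable across
  epochs rather than bouncing with fresh mask draws.
* **Pattern source.** Training-time copy-masks are drawn from the training
  split's own mask rows only, never from test patterns.
* **Evaluation-mask stopping rule.** Donor patterns are applied in full and
  the loop stops at the first crossing of the target count, so the achieved
  fraction can overshoot by less than one pattern's worth; it is always
  recorded alongside the target.
* **Mini-batch scaling.** The loss is a sum (matching its definition) while
  gradients are scaled by the batch row count for step-size stability; the
  final short batch is used.
* **Numerical safety.** The training path evaluates cross-entropy from
  logits via the softplus identity, which is exact in the unsaturated
  regime and avoids overflow where a sigmoid would round to 0 or 1. The
  exported `joint_loss()` keeps its strict contract (errors on
  probabilities outside the open unit interval).
* **Divergence.** A non-finite batch loss aborts training with the epoch
  and last finite loss reported; with the default learning-rate schedule
  this occurs only under aggressive step sizes.

## Evaluation protocol

`run_accuracy_benchmark()` packages the standard protocol: a 50/50
individual split; fitting on the training half; copy-mask simulation of
missingness on the test half at a target fraction (10% by default, with
1–50% the conventional grid); imputation; and scoring at the withheld
cells. Metrics are per-phenotype squared Pearson correlation $r^2$ (for
binary phenotypes, between predicted probability and 0/1 truth), plus AUPR
and AUROC for binary phenotypes. AUROC uses the Mann–Whitney form with
ties counted one half; AUPR is the step-wise precision–recall area.
Uncertainty comes from resampling evaluated cells within phenotype: 50
bootstrap replicates for standard errors and 100 for percentile confidence
intervals (both configurable). Method comparisons use a two-tailed z-test
on the bootstrap standard errors with a Bonferroni threshold
$\alpha / P$.

Phenotypes whose truth or predictions are constant in an evaluation have
undefined $r^2$; they are excluded from (unweighted) aggregates and listed
by name in the report.

For real data, where no withheld truth exists, `variance_ratio_qc()`
compares the variance of a phenotype's imputed portion to its observed
portion — over-shrunk imputations score near zero — with 0.2 as the
recommended minimum, alongside simulated-missingness $r^2 > 0.2$ and a
missing fraction worth imputing (>10%).

## Downstream analysis

Imputation is an estimate, and downstream statistics should reflect its
uncertainty. `multiple_impute()` (or `simulate()` on a fit) refits the
model `m = 10` times, each on a bootstrap resample of individuals with
fresh initialization, shuffling and mask draws, and imputes the original
data with each refit. Observed cells are identical across the
imputations; imputed cells vary. Any downstream estimate computed per
imputation is then combined with `rubin_pool()`: with per-imputation
estimates $Q_r$ and variances $U_r$,

$$\bar Q = \tfrac1m \sum_r Q_r,\quad \bar W = \tfrac1m \sum_r U_r,\quad
  B = \mathrm{var}(Q_r),\quad T = \bar W + (1 + \tfrac1m) B,$$

with a $t$ reference on $(m-1)\bigl(1 + \bar W/((1+\tfrac1m)B)\bigr)^2$
degrees of freedom (normal when $B = 0$ or $m = 1$). The pooled standard
error $\sqrt T$ never falls below the within-imputation component.
`pool_association_files()` applies this per variant to PLINK-style summary
statistics.

Two further utilities summarize what imputation buys:
`effective_sample_size()` computes
$N_\mathrm{eff} = N_\mathrm{obs} + r^2 N_\mathrm{imp}$, discounting
imputed individuals by the simulation-estimated accuracy of the phenotype;
and `clump_loci()` reduces significant variants to independent loci by
iteratively taking the top remaining variant per chromosome and discarding
significant neighbours within 1 Mb (inclusive; p-value ties broken by
smaller position). `sign_concordance_test()` checks directional
replication of loci against an exact two-sided binomial null of one half.

## The synthetic generator

Real biobank phenotypes are access-controlled, so the package ships a
generator (`generate_phenotypes()`) that reproduces the *structure* the
method relies on: $k$ standard-normal latent factors per individual,
continuous columns as factor loadings plus Gaussian noise, and binary
columns as liability-threshold indicators on the same factors (so
cross-type dependence exists for the mixed loss to exploit, as pleiotropy
produces in real collections). Missingness is the union of questionnaire
block skips — all columns of a block missing together — and uniform
cellwise dropout.

Defaults are fixed at $N = 5{,}000$ individuals, $P = 40$ phenotypes (30
continuous, 10 binary at 20% prevalence), $k = 4$ factors, and equal
signal and noise variance (`loading_scale = 1`, `noise_sd = 1`), with four
blocks of ten columns skipped with probabilities 0.05/0.15/0.30/0.50 plus
2% cellwise dropout (~26% missing overall). These sizes keep a full fit
under a minute on one CPU while leaving metrics stable; the equal
signal/noise split means at most half of each phenotype's variance is
recoverable from the others, a deliberately non-trivial regime — a
Gaussian conditional-expectation oracle with access to the true covariance
reaches mean $r^2 \approx 0.25$ under the default masking, and the fitted
network recovers most of that. `default_benchmark_suite()` adds the
conventional 1/5/10/20/50% missingness grid and a high-structure
questionnaire design (block skip probabilities 0.1/0.3/0.6/0.9).

What the generator does *not* emulate: nonlinear phenotype dependencies
(its truth is linear-Gaussian, so it cannot demonstrate the advantage of
nonlinearity over linear imputers), missingness that depends on the
phenotype values themselves (an optional factor-dependent skip mechanism
is off by default), ordinal measurement scales, and biobank sample sizes.
Passing tests on this generator therefore certify the machinery —
masking, optimization, checkpointing, metrics, pooling — not the realized
accuracy on any particular biobank collection.

### Benchmark problem sizes

The bundled benchmark (`run_accuracy_benchmark()`) trains with mini-batches
of 512 rows, learning rate 0.05 and up to 400 epochs. These are the
package's chosen settings for the generator's 2,500-row training halves:
the biobank-scale defaults (batch 2,048, learning rate 0.1) take too few
gradient steps per epoch at this $N$ to converge within the epoch budget.
The multiple-imputation demonstrations run at $N = 800$, $P = 20$, 40
epochs, where the between-imputation spread is already clearly nonzero.

## Known limitations

* Training is plain R matrix arithmetic: ample for the tens of phenotypes
  and thousands of rows the generator targets, but biobank-scale runs
  (hundreds of thousands of rows, hundreds of phenotypes) call for an
  accelerator-backed implementation of the same model.
* Binary imputations are probabilities; downstream analyses that need hard
  labels must choose their own threshold.
* The copy-mask advantage over uniform masking is a property of structured
  missingness; on near-uniform missingness the two training modes perform
  alike, and the package makes no claim otherwise.
* Imputations are only as interpretable as the network; the variance-ratio
  and simulated-accuracy QC gates are coarse screens, not guarantees, and
  phenotypes failing them should not be imputed.
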