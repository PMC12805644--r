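---
title: "Multi-ancestry trait imputation from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ancestry trait imputation from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsimpute)
```

## The problem

A GWAS of a well-powered cohort (often of European ancestry) yields per-SNP
marginal effect estimates that are freely shared, while the individual-level
trait values of other cohorts are missing, expensive, or — as with
late-onset diseases in young cohorts — not yet observable. Given only
genotypes $X$ for $n_2$ new individuals and a vector of marginal effects
$\hat\beta^*$, least-squares trait imputation reconstructs trait values by
inverting the defining identity of marginal statistics. If $X$ is
standardized (column mean 0, unit sample variance) and $Y$ were observed,
the marginal estimates would be $\hat\beta = X'Y/(n_2-1)$. Treating the
external $\hat\beta^*$ as a stand-in for $\hat\beta$ and solving the
(underdetermined, $p \gg n_2$) system gives

$$\hat Y = (n_2-1)\,(XX')^{+}\,X\hat\beta^*,$$

with $(XX')^{+}$ the Moore–Penrose pseudoinverse of the sample Gram matrix,
realized here as a ridge-regularized solve $(XX' + \lambda I)^{-1}$ with
$\lambda = 10^{-6}$.

The imputed vector is a *genetic* prediction of the trait: its accuracy is
bounded by the trait's heritability and the GWAS sample size, and for a
small target cohort of a different ancestry than the GWAS, by the partial
transferability of effect sizes. The two multi-ancestry extensions address
exactly that regime: a large auxiliary-ancestry GWAS with biased (for the
target population) effects, and a small target-ancestry GWAS with unbiased
but noisy effects.

**Combined.** Blend the two summary-statistic systems with a weight
$\omega \in [0,1]$ on the auxiliary ancestry and solve in closed form:

$$\hat Y = (n_2-1)\left(\omega \tilde X \tilde X' + (1-\omega)
\tilde{\tilde X}\tilde{\tilde X}'\right)^{+}
\left(\omega \tilde X\tilde\beta_1^* + (1-\omega)
\tilde{\tilde X}\tilde\beta_2^*\right),$$

where $\tilde X$ and $\tilde{\tilde X}$ are the column subsets of the
target cohort's genotypes matching each ancestry's SNP panel. At
$\omega \in \{0, 1\}$ this reduces exactly to a single-ancestry run;
`select_omega()` picks $\omega$ on a validation split.

**Transfer.** Initialize $Y$ at the auxiliary-ancestry imputation and
refine it toward the target-ancestry statistics by stochastic gradient
descent on the convex quadratic
$f(Y) = \lVert \tilde\beta_2^* - \tilde{\tilde X}'Y/(n_2-1)\rVert^2$,
treating the $p_2$ SNP equations as the stochastic units. Run to
convergence this recovers the target-only solution and forgets the
initialization, so the method's value comes from *early stopping*: the
epoch with the best validation metric is selected and then applied to the
test cohort. The SGD path interpolates between the auxiliary and
target-only solutions, so early stopping plays the same role as $\omega$
does for the combined method, but along a different (curved) path.

## Assumptions

- Genotypes are biallelic dosages in $\{0,1,2\}$; effects are per
  standardized genotype. Summary statistics must be harmonized to the
  genotype panel's effect alleles first (`harmonize_sumstats()`), with
  strand-ambiguous (A/T, C/G) SNPs dropped.
- $p \gg n_2$ within each solved system; the functions warn otherwise.
- The genetic architecture is at least partially shared across ancestries;
  with no sharing, tuning drives $\omega \to 0$ and stops the SGD at epoch
  0, gracefully degrading to the target-only and auxiliary-only methods.
- Binary (case/control) GWAS effects on the log-odds scale are converted to
  the linear scale by `glm_to_lm()`: $\beta_{LM} = \mu(1-\mu)\, b_1$ with
  $\mu$ the baseline case probability, obtained from the cohort's
  case/control counts via `logit_baseline()`. Imputed values for binary
  traits are continuous risk scores, evaluated by AUC.

## What the trait scale means

Standardized genotypes determine $\hat Y$ only up to location and scale:
the Gram matrix of column-centered genotypes annihilates the constant
vector, so the system determines $Y$ up to an additive constant, and the
scale of $\hat Y$ follows the scale of the supplied $\hat\beta^*$ (the
package's simulator computes betas against a standardized phenotype, so
imputed values are on the standardized-trait scale). Every evaluation
metric used (Pearson correlation, AUC, rank-based association tests) is
invariant to this indeterminacy. All initial values produced by the
package's own imputers are centered; user-supplied initializations with a
nonzero mean keep that mean through SGD, harmlessly for the supported
metrics.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ridge_lambda` | `1e-6` | pseudoinverse ridge; dimensionless, relative to Gram eigenvalues of order $p$ |
| `omega` grid | `seq(0, 1, 0.01)` | mixing weight on the auxiliary ancestry; percent-level resolution matches the precision at which interior optima are typically reported |
| `learning_rate` | 0.1 | SGD step in calibrated units (below) |
| `max_epochs` | 100–150 | epoch budget; the selected epoch is usually far below it |
| `sgd_batch_snps` | 512 | SNP equations per mini-batch |
| `sample_batch_max` | 2000 | samples per block when a cohort is split (`split_batches()`); each block is re-standardized so its system is internally consistent |

**Learning-rate calibration.** The raw gradient of $f$ carries a factor
$1/(n_2-1)^2$ that would make any human-scale learning rate (0.1, 0.01,
0.001) inert. The package therefore takes the update in the normalized
variable $Y/(n_2-1)$ and calibrates the step so one epoch applies one
full-gradient-equivalent step of size proportional to `learning_rate`,
regardless of how many mini-batches the epoch is split into:

$$Y \leftarrow Y + \mathrm{lr}\cdot\frac{n_2-1}{10\,p}
\sum_{j\in B} x_j\left(\hat\beta_j - x_j'Y/(n_2-1)\right)$$

per batch $B$. The constant is chosen so that `learning_rate = 0.1`
reaches the validation optimum after roughly ten epochs under the default
benchmark conditions; the epoch budget then scales as `1/learning_rate`
(10 epochs at 0.1 behave like 100 at 0.01 and 1000 at 0.001). Learning-rate
units are arbitrary up to exactly this kind of calibration — the invariant
property, which the test suite asserts, is that the attainable validation
metric is the same across learning rates once budgets are scaled
inversely. A safe step keeps
$\mathrm{lr} < 20p/\lambda_{\max}(XX')$, roughly $\mathrm{lr} \lesssim 5$
for standardized genotypes; the SGD aborts with a divergence error if the
objective ever exceeds $10^6$ times its initial value.

**Early stopping.** The full objective is recorded after every epoch
(epoch 0 = the initialization), and the validation metric likewise when a
validation trait is supplied. `select_epochs()` takes the argmax (ties to
the earliest epoch, so cheaper models win ties); no rise-then-fall shape
is assumed. `select_omega()` breaks exact ties toward smaller $\omega$,
i.e. toward less reliance on the auxiliary ancestry.

## The synthetic two-ancestry benchmark

`simulate_cohorts()` generates everything the methods need without any
restricted data:

- **Allele frequencies**: Balding–Nichols divergence — ancestral
  $q \sim U(0.05, 0.95)$, population frequencies
  $\mathrm{Beta}(q(1-F)/F,\ (1-q)(1-F)/F)$ with $F$ = `fst`.
- **Effects**: a seeded causal subset of `n_causal` SNPs; auxiliary
  effects $\beta^{(1)} \sim N(0, h^2/n_\mathrm{causal})$; target effects
  $\beta^{(2)} = \rho\,\beta^{(1)} + \sqrt{1-\rho^2}\,\varepsilon$ with
  the same marginal variance, so $\rho$ = `rho_effects` is the
  cross-ancestry effect correlation.
- **Traits**: $Y = X_s\beta + e$ with the noise variance set to deliver
  heritability $h^2$; binary traits threshold the liability at the
  $1-\mathrm{prevalence}$ quantile.
- **GWAS summary statistics**: computed by an actual marginal GWAS on
  internally simulated panels of `n_aux_gwas` and `n_tgt_gwas` samples
  (betas on the correlation scale, p-values from the $t$ statistic), so
  the estimates carry realistic sampling noise.

The default configuration emulates the motivating asymmetry: `p = 5000`
SNPs, a 50,000-sample auxiliary GWAS versus a 1,000-sample target GWAS,
validation and test cohorts of 500, `fst = 0.01`, `rho_effects = 0.8`,
`h2 = 0.5`. `n_causal = 500` (10% of SNPs causal) is the package's own
choice of a realistically polygenic but sparse architecture. Both
ancestries use the full simulated SNP panel in the benchmark; the panel
selection recipes (`select_snps()`: all SNPs significant at 0.05 topped up
with a seeded random draw of nonsignificant ones) are exercised separately
and in the workflow driver.

Large GWAS panels (up to $5 \times 10^4 \times 5 \times 10^3$ genotypes
per replicate) are sampled and reduced in a byte-per-genotype C++ backend,
so the 20-seed benchmark runs in minutes within a few hundred MB of
memory.

**What the simulator does not emulate** — and what passing the benchmark
therefore does not establish about real data: linkage disequilibrium (an
optional AR(1) panel exists solely to exercise `ld_prune()`), admixture
and population structure within cohorts, genotyping error and
missing-data structure, covariate effects, binary-trait ascertainment, and
effect-size–frequency coupling. The benchmark's purpose is to verify the
estimators' *relative* behavior (interior $\omega$ optimum, transfer
tracking the best blend, robustness to the learning rate), not to predict
absolute accuracy on any real cohort.

With a shared SNP panel the combined solution is exactly the chord
$\omega \hat Y_\mathrm{aux} + (1-\omega)\hat Y_\mathrm{tgt}$ between the
two single-ancestry solutions, while the transfer path is a curved
interpolation between the same endpoints; their validation-selected
maxima therefore coincide up to selection noise, and the benchmark
asserts the qualitative ordering (transfer $\approx$ combined $\ge$
best single ancestry) with a small tolerance rather than a strict
inequality between the two multi-ancestry methods.

## Numerical choices

- The pseudoinverse is a Cholesky solve of $G + \lambda I$; because
  centered genotypes give $G$ a null constant-direction with eigenvalue
  $\lambda$ after regularization, round-off in that direction is amplified
  by $1/\lambda$. Right-hand sides produced by the package ($X\beta$) are
  orthogonal to it, keeping the error harmless; this is also why the ridge
  route tracks an SVD pseudoinverse only for in-range right-hand sides.
- Missing dosages are mean-imputed per SNP before standardization, keeping
  the downstream algebra exact on a complete matrix; SNPs with more than
  10% missingness should be removed by QC first.
- The Hardy–Weinberg exact test sums the conditional distribution of
  heterozygote counts in log space; no mid-p correction, matching standard
  genotype-QC tooling.
- LD pruning is greedy per sliding window (50 SNPs, step 5 by default,
  counted in SNPs, not kb): the worst pair above the $r^2$ threshold loses
  its lower-MAF member (ties: the later position) until the window is
  clean.
- DeLong's test uses per-observation placements; identical score vectors
  return $z = 0$, $p = 1$ by convention rather than 0/0.
- SGD shuffling and all simulation draw from R's RNG, so every result is
  bit-reproducible given the seeds carried in `impute_config()` /
  `sim_config()`.

## Problem sizes in the test suite

The suite verifies self-recovery on a $200 \times 3000$ system, SGD
convergence on $100 \times 2000$, the HWE test exhaustively for all
genotype tables of up to 50 individuals, DeLong's variance against a
10,000-replicate bootstrap at $n = 60$ and its size under 1,000 label
permutations, and the full benchmark over 20 simulation seeds — sizes
chosen to exercise the $p \gg n$ regime the method targets while keeping
a complete run in the minutes range on one CPU.

## Known limitations

- Only two ancestries per run; extending the blend to more ancestries is
  straightforward algebraically but untested here.
- Marginal statistics from linear-mixed-model GWAS are not supported; the
  inversion assumes OLS-style marginal effects.
- Only biallelic SNPs with integer dosages; no VCF/BGEN input.
- The logistic-to-linear conversion is a first-order approximation that
  degrades for large per-SNP odds ratios; it is validated in simulation
  for the small-effect regime GWAS traits live in.
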