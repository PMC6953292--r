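---
title: "Multiset sparse PLS path modeling: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiset sparse PLS path modeling: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`msplspm` estimates dependencies among $Q$ data sources
$\mathbf X_1, \dots, \mathbf X_Q$ (each $n \times p_q$, measured on the same
$n$ samples) through one latent variable (LV) per source,
$\boldsymbol\zeta_q = \mathbf X_q \mathbf w_q$. A binary connectivity matrix
$\mathbf C$ declares which source is a *response* for which
($c_{qq'} = 1$: source $q$ responds to source $q'$); a symmetric pair
models a CCA-like mutual relation, a one-sided entry an RDA-like directed
one. The outer weights $\mathbf w_q$ of sources that *have* responses are
estimated by penalized multivariate regression (mode B), so that only a
sparse subset of their variables contributes; response-free (terminal)
sources use per-variable simple regression (mode A).

The fitted model maximizes, per source $q'$, the objective

$$
OF_{q'} =
\begin{cases}
\sum_{r} \operatorname{Cor}(\boldsymbol\zeta_r, \boldsymbol\zeta_{q'})^2
 & \text{if } q' \text{ has response sources } r,\\[2pt]
\sum_{i=1}^{p_{q'}} \sum_{m}
\operatorname{Cor}(\boldsymbol\zeta_m, \mathbf x_{q'(i)})^2
 & \text{otherwise (explanatory LVs } m\text{)},
\end{cases}
$$

a sum of squared correlations bounded by $R_{q'}$ (number of responses) in
the first branch and by $p_{q'} M_{q'}$ in the second.

## The iterative algorithm

After centering and scaling every column (sample standard deviation,
denominator $n-1$), the engine repeats until convergence:

a. **LVs** $\boldsymbol\zeta_q \propto \mathbf X_q \mathbf w_q$, normalized
   to unit sample variance.
b. **Inner model.** For every source with explanatory sources, the incoming
   coefficients of $\boldsymbol\Theta$ are the multiple-regression
   coefficients of its LV on the column-bound explanatory LVs; afterwards,
   for every source with responses, those coefficients are *overwritten* by
   the plain correlations with each response LV. The sparsity pattern of
   $\boldsymbol\Theta$ always mirrors $\mathbf C$.
c. **Re-estimation** $\tilde{\mathbf Z} = \mathbf Z \boldsymbol\Theta$
   (not re-normalized).
d. **Outer weights.** Mode A: $\mathbf w_q = \mathbf X_q'
   \tilde{\boldsymbol\zeta}_q / \tilde{\boldsymbol\zeta}_q'
   \tilde{\boldsymbol\zeta}_q$. Mode B: the Elastic Net update
   $\arg\min_{\mathbf w} \; \mathbf w' \frac{\mathbf X' \mathbf X +
   \lambda_2 \mathbf I}{1+\lambda_2} \mathbf w - 2 \tilde{\boldsymbol
   \zeta}' \mathbf X \mathbf w + \lambda_1 \lVert \mathbf w \rVert_1$, or
   its $\lambda_2 \to \infty$ limit, univariate soft thresholding (UST):
   $w_j = \operatorname{sign}(c_j)\max(|c_j| - \lambda_1/2,\, 0)$ with
   $c_j = \mathbf x_j' \tilde{\boldsymbol\zeta}$. UST is the default for
   high-dimensional blocks; the full Elastic Net is solved by cyclic
   coordinate descent (sweep tolerance $10^{-8}$) and reserved for
   moderate dimensions, since it forms the $p \times p$ Gram matrix.
e. **Convergence.** $CRT = \sum_q \lVert \mathbf w_q^{(1)} -
   \mathbf w_q^{(0)} \rVert^2 < \gamma = 10^{-6}$.

Unpenalized mode B ($\lambda_1 = \lambda_2 = 0$) reduces to alternating
least squares: a symmetric two-block model reproduces the first canonical
correlation, and a single directed relation solves the redundancy-analysis
eigenproblem; both are verified against independent oracles in the test
suite. Unpenalized mode B is refused when $p > n$ (singular covariance) —
that regime is precisely what the penalties are for.

### Numerical conventions

* **Weight normalization and sign.** After every update each
  $\mathbf w_q$ is rescaled to unit Euclidean norm and flipped so its
  largest-magnitude entry is positive. The criterion $CRT$ is then
  invariant to the scale drift of penalized updates and cannot stall on
  sign flips; LV signs follow their weights.
* **Warm starts.** Penalized fits start from the converged *unpenalized*
  solution rather than the flat all-ones vector. The soft threshold
  compares $\lambda_1/2$ against $c_j = \mathbf x_j'\tilde{\boldsymbol
  \zeta}$, and the scale of $\tilde{\boldsymbol\zeta}$ only settles once
  the inner coefficients have converged; started cold, any useful
  $\lambda_1$ empties the model at the first iteration because the initial
  $c_j$ are an order of magnitude too small. The warm start makes every
  $\lambda_1$ act on scores at their converged scale and is deterministic.
* **Degenerate cases.** A penalty that thresholds *every* weight to zero is
  an error (`lambda1 too large: empty model`); collinear LVs make the inner
  regression singular and raise an error naming the blocks involved;
  constant data columns are refused during standardization (dropping them
  silently would desynchronize variable indices from any selection
  bookkeeping).
* **Non-convergence** at `max_iter` (default 500) returns the fit with a
  warning and the full CRT trace, not an exception.
* The iteration hot path for UST penalties is implemented in C++
  (RcppArmadillo), with an R reference implementation kept in the package;
  a test asserts both produce identical trajectories.

## Choosing the penalty, and inference

**Cross-validation.** `cross_validate()` partitions samples once (seeded)
into $k$ folds (default 10). Training folds are standardized with their own
means/SDs; held-out rows are standardized with the *training* parameters
and projected onto the trained weights, and the objective branch of a
reference block (default: the terminal block) is evaluated on the held-out
scores. The $\lambda_1$ grid defaults to 20 log-spaced values between
$0.01\,\lambda_{\max}$ and $\lambda_{\max} = 2\max_j |\mathbf x_j'
\tilde{\boldsymbol\zeta}|$, measured at the *converged* unpenalized fit
(measured earlier, the grid ceiling would sit far below the sparse regime).
The chosen $\lambda_1$ maximizes the mean held-out objective, ties going to
the largest (sparsest) value; fits are warm-started along the grid. A
$\lambda_1$ that empties the model in a fold scores 0 in that fold — the
natural held-out value of a model that captures no correlation — so
aggressive grid values are safe to include. We do not use a
one-standard-error rule: measured on synthetic data it changed selections
only marginally while breaking the "maximizer of the mean" contract.

**Permutation test.** The rows of *each* block are permuted independently,
destroying cross-source correlation while preserving each source's internal
structure; the model is refitted with the fixed (typically CV-chosen)
penalty and the objective recorded, `B` times. The p-value is
$(1 + \#\{OF^{null} \ge OF^{obs}\})/(B+1) \ge 1/(B+1)$. A permutation that
empties the model under the fixed penalty has captured no correlation and
contributes a null objective of 0 (counted and reported); this is common
and expected under the null at moderate dimensions, where the observed
penalty level is calibrated to genuine association.

**Bootstrap.** One index vector per replicate, drawn with replacement and
applied to *every* block (preserving cross-source correlation); the
resample is re-standardized, refitted with the original penalty, and
empirical (inverse-CDF) quantiles of the objective reported.

## Multiple latent variables

`extract_components()` obtains successive LV sets by residualization:
$\mathbf X^{res} = \mathbf X - \boldsymbol\zeta(\boldsymbol\zeta'
\boldsymbol\zeta)^{-1}\boldsymbol\zeta'\mathbf X$ for the blocks named in
`deflate_mask` (default: every block with responses; terminal blocks keep
their original data, so each round extracts a fresh explanatory set for the
same responses). Residuals are not re-standardized — the objective is
correlation-based and scale-free, while explained-variance bookkeeping
needs original-scale variances. Scores of a deflated block are exactly
orthogonal across components. Per block, the cumulative explained variance
after $a$ components is the mean multiple $R^2$ of the original
(standardized) columns on the first $a$ scores; for orthogonal scores this
is the running sum of per-component communalities, and it is non-decreasing
and bounded by 1 for any mask. The per-block scalar "variance explained by
one LV" is interpreted as the average squared LV-variable correlation
(communality), uniformly for mode A and mode B blocks.

## The synthetic-data generator

`simulate_dataset()` emulates a three-source design: two high-dimensional
explanatory sources in a symmetric relation and a response source driven by
both of their LVs.

* $\mathbf X_1, \mathbf X_2$ ($p_1 = p_2 = 1000$ by default) are drawn from
  $\mathcal N(\mathbf 0, \boldsymbol\Sigma)$ with $\boldsymbol\Sigma =
  \mathbf I_{2000}$ except for a $10 \times 10$ cross-block $\mathbf H$
  linking the first $k_1 = 10$ columns of $\mathbf X_1$ with the first
  $k_2 = 10$ of $\mathbf X_2$, entries i.i.d. $\mathcal N(0.3, 0.05)$
  (0.05 read as a standard deviation; the variance reading is available by
  configuration).
* Generative weights put $0.7$ / $0.6$ on the associated columns and 0
  elsewhere; $\boldsymbol\zeta_1 = \mathbf X_1\mathbf w_1$,
  $\boldsymbol\zeta_2 = \mathbf X_2\mathbf w_2$, deliberately left
  unnormalized.
* The first $k_3 = 10$ of $p_3 = 100$ response columns are
  $\mathcal N(0.8\,\zeta_1 + 0.7\,\zeta_2,\ \sqrt{1 - 0.3^2})$
  elementwise; the rest are standard normal. All blocks are centered and
  scaled before use.

**Positive-semidefiniteness repair.** With $\mathbf H \approx 0.3$ on a
$10\times10$ block, the dominant singular value of $\mathbf H$ is about
$10 \times 0.3 = 3 > 1$, so the nominal $\boldsymbol\Sigma$ is strongly
indefinite (its smallest eigenvalue is about $1 - \sigma_1(\mathbf H)$,
well below zero) and *cannot* be sampled as
written. The generator applies the smallest intervention that makes the
recipe samplable: eigenvalues are clipped at zero with eigenvectors fixed
(the same behavior as the common `eigen`-method multivariate-normal
samplers), and nothing is rescaled. The repair has real consequences that
`build_sigma()` and every simulated dataset report: the achieved mean
cross-block correlation drops from the nominal 0.3 to roughly 0.18, while
the two associated-column sums become almost perfectly correlated along the
dominant direction. Any result that depends on the absolute association
strength — in particular absolute objective-function levels — inherits this
choice, which is why the repair diagnostics are attached to the data
object.

The generator reproduces the *structure* of multi-omics data (shared
samples, a low-rank cross-source dependency, sparse relevant variables,
Gaussian noise) but not its messier features: heavy tails, skewed counts,
batch effects, block-internal correlation among irrelevant variables, or
missingness. Passing recovery tests on these data therefore demonstrates
correctness of the estimation machinery under the stated model, not
robustness on real omics data.

**Recovery metrics.** For a block with $k$ associated variables,
$TPR = \#\{\text{associated with } w_j \ne 0\} / \min(k, \#\{w_j \ne 0\})$
(an all-zero model scores 0) and
$TNR = \#\{\text{not associated with } w_j = 0\} / (p - k)$.
`run_study()` repeats simulate → CV (UST) → fit → score with per-replicate
child seeds drawn up front from the master seed, so studies are
reproducible and replicates independent of execution order.

## Problem sizes used by the packaged checks

The replicated study runs 200 replicates at each $n \in \{50, 100, 250\}$
with the default generator and the default 20-point grid under 10-fold CV;
single-dataset objective checks use one dataset per $n$; permutation
calibration under a null generator ($\mathbf H = 0$, inner coefficients 0)
uses 200 Monte-Carlo repetitions at $B = 99$, $n = 50$, a 10-point penalty
grid, and an iteration cap of 50 applied identically to observed and
permuted refits
(weak-signal fits converge slowly, and exchangeability only requires the
same procedure on both sides); the significance
check on associated data uses $B = 1000$ at $n = 100$. The $n = 37$,
$p_1 = 360{,}000$ configuration is accepted by `simulation_config()` but
not exercised by the default checks.

## Known limitations

* Only the regression/correlation inner-weighting scheme is implemented
  (no centroid/factorial schemes), and no orthogonality is enforced
  *across* blocks.
* The Elastic Net update materializes $\mathbf X'\mathbf X$; for
  $p \gtrsim 10^4$ use UST (the design intent) or cardinality targeting.
* Cross-validated penalties optimize held-out *objective*, not support
  recovery; on the synthetic design the held-out optimum sits at models a
  few times denser than the sparsest ones with equivalent objective, so
  specificity (TNR) of CV-selected models plateaus slightly below 1 at
  small $n$. Cardinality targeting (`penalty_cardinality()`) is the
  appropriate tool when a fixed variable budget is wanted.
* Missing values are rejected, not imputed; samples must arrive in the
  same order in every block (no joining).
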