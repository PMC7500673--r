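---
title: "The MTLC model: taxonomy-structured GEEs for longitudinal microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MTLC model: taxonomy-structured GEEs for longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlc)
```

## The problem

16S rRNA and shotgun metagenomic surveys summarize a community as relative
abundances (RAs) of operational taxonomic units (OTUs). Three features of
these data defeat standard regression: RAs are zero-inflated (an OTU is
often absent from a sample); the same subject is measured repeatedly (visits
over time, twins within a pedigree, multiple body sites); and the OTUs
themselves are correlated, with the taxonomy suggesting *which* correlations
should be equal. This package implements a marginal-model answer — the
Microbiome Taxonomic Longitudinal Correlation (MTLC) model — in which all
three features enter through one patterned working-correlation matrix inside
a pair of generalized estimating equations (GEEs).

## From taxonomy to a correlation pattern

The taxonomy of the analysed OTUs is trimmed to the informative range:
level 1 is the deepest rank at which all OTUs still share one taxon, level
$I$ the shallowest rank at which every OTU is distinct. Counting OTUs per
taxon per level gives the numeric representation $(n_1, \dots, n_I)$, from
which a symbolic $N \times N$ structure matrix $\Gamma$ is built: each OTU
pair is assigned one correlation class (uppercase Roman numeral) determined
entirely by the pair's *first common taxon* — the taxon at the deepest level
where the two lineages still agree. Pairs with the same first common taxon
share a class, hence a single correlation coefficient; this collapses up to
$\binom{N}{2}$ pairwise parameters into a handful of estimable ones.

Repeated measures are described the same way: an $l \times l$ time-point
structure $\Omega_T$ (exchangeable, Toeplitz or unstructured), an $s \times
s$ exchangeable structure $\Omega_S$ for repeated samples such as twins, and
their combination $\Omega$ over all $L = l \cdot s$ cells (samples outer,
time points inner), where every distinct pair (time class, sample class)
becomes one lowercase class. The integrative structure $R$ is the $J \times
J$ grid ($J = N \cdot L$, OTU-major) whose entry for cells $(a,u),(b,v)$ is
the label pair $\rho(\Gamma_{ab}, \Omega_{uv})$ with $D$ marking "same OTU"
or "same cell". Clusters with missing cells simply use the principal
sub-structure (`subset_structure()`); realization into numbers
(`realize_correlation()`) fills classes from a named coefficient vector,
defaulting unnamed classes to zero.

## The two-part estimator

Observed abundances $y_{kj}$ (cluster $k$, cell $j$) are split into a
prevalence indicator $y^{(0)}_{kj} = \mathbf{1}\{y_{kj} > 0\}$ and, where
positive, a continuous part $y^{(+)}_{kj} = \log_{10} y_{kj}$ (sign
configurable; the simulation convention uses $-\log_{10}$ so transformed RAs
are positive). Two GEEs share the symbolic structure but estimate separate
coefficient sets:

$$\operatorname{logit}(\mu^{(0)}_{kj}) = x_{kj}'\beta^{(0)}, \qquad
  \mu^{(+)}_{kj} = x_{kj}'\beta^{(+)}.$$

Each GEE solves $\sum_k D_k' V_k^{-1} (y_k - \mu_k) = 0$ with $V_k =
A_k^{1/2} R_k(\rho) A_k^{1/2}$, alternating a Fisher-scoring step for
$\beta$ with moment updates of the dispersion
$\hat\phi = \sum e_{kj}^2 / (\sum_k J_k - p)$ (fixed at 1 for the binomial
part) and of each free class coefficient
$$\hat\rho_c \;=\; \frac{\sum_k \sum_{(j,j') \in c} e_{kj} e_{kj'}}
                        {(N_c - p)\,\hat\phi},$$
where $e_{kj}$ are Pearson residuals and $N_c$ counts the class-$c$ pairs.
Coefficient covariance is the robust sandwich; hypotheses $C\beta = c$ are
tested by Wald statistics against $\chi^2_q$. The two part-wise p-values are
combined by the Cauchy combination test
$W = \tfrac12 \tan[(\tfrac12 - p^{(0)})\pi] + \tfrac12 \tan[(\tfrac12 -
p^{(+)})\pi]$, whose null distribution is standard Cauchy even under
dependence between the parts.

## Tunable parameters

* `time_structure`: `exchangeable` (default; one coefficient), `toeplitz`
  (one per lag), `unstructured` (one per pair). More classes cost degrees of
  freedom in the moment estimates, not in $\beta$.
* `pinned` / `pinned0` / `pinnedp`: classes held at a fixed value (usually
  0) instead of being estimated. Pinning cross classes such as $(I, i)$ does
  not bias the remaining estimates — the misspecification-robustness
  property of GEE, which the acceptance suite verifies empirically.
* `gee_control(tol = 1e-6, max_iter = 100)`: conventional values with no
  canonical alternative. Convergence is declared on the maximum absolute
  coefficient change.
* `transform`: `log10` for real RA data, `neglog10` for the simulation
  convention; the choice only flips the sign of $\beta^{(+)}$.

## The synthetic-data generator

`mtlc_scenario()` encodes the stated simulation world: $K = 1000$ clusters;
two OTUs sharing one taxonomic class and two exchangeable time points
($J = 4$); a binary predictor; prevalence drawn as correlated Bernoulli
variables with logit-linear means; $-\log_{10}$ abundances drawn as a
truncated multivariate normal with identity-linear means; the two parts
drawn independently and multiplied into a zero-inflated outcome; generating
correlations $\rho(D,i) = \rho(I,D) = 0.3$, $\rho(I,i) = 0$ in both parts
(0.5 / $-0.3$ in the correlation-recovery study).

Parameters the scenario definition leaves open were fixed once:

* **Intercepts** $\alpha^{(0)} = 0$, $\alpha^{(+)} = 3$, $\sigma = 1$. The
  normal part is truncated at zero; with mean 3 the per-vector truncation
  probability is below 0.2%, so the truncated moments match the untruncated
  ones — the only regime in which $\hat\beta^{(+)}$ and $\hat\rho^{(+)}$
  can be unbiased for the nominal generating values, which is what the
  recovery tests assert. The value 3 also makes the one-part
  zero-replacement study informative (replacing $-\log_{10} 0$ by 3, i.e.
  exactly the positive-part mean, collapses the prevalence signal;
  replacing it by 6 inflates residual variance and dilutes power).
* **Predictor law**: one $-1/+1$ value per cluster, shared by its cells —
  the analogue of a subject-level exposure such as obesity status. The
  choice matters: with a per-cell i.i.d. predictor the naive comparators'
  model-based variances are accidentally valid, so the comparison the
  harness is meant to exhibit (naive models with inflated size
  $2\Phi(-1.96/\sqrt{\mathbf 1'R\mathbf 1 / J}) = 0.121$ per part, GEE
  power driven by $\mathbf 1'R^{-1}\mathbf 1$) only exists under a
  cluster-level predictor. An `x_law = "cell_bernoulli"` option retains
  the per-cell variant.
* **Correlated Bernoulli sampling**: Gaussian-copula thresholding with
  pairwise latent correlations solved by bisection on the bivariate normal
  rectangle probability. The correlation-recovery setting (0.5 on the
  four-cycle, 0 on its diagonals) lies on the boundary of the feasible
  region and admits *no* Gaussian copula, so for small $J$ the generator
  switches automatically to an exact sampler: the joint pmf over the $2^J$
  atoms is solved from the linear moment constraints by alternating
  projections and sampled directly. Infeasible targets raise an error
  naming the violated bound.
* **Truncation mechanics**: whole-vector rejection (redraw a vector with
  any non-positive coordinate), erroring out below 1% acceptance.

What a green simulation test does **not** establish: the generator draws
balanced two-OTU, two-visit grids with Gaussian positive parts and a single
binary covariate. Real data have many OTUs, irregular missingness,
non-Gaussian positive parts and confounded covariates; the application
machinery handles the layout, but the operating characteristics measured by
the acceptance suite are statements about the stated synthetic world only.

## Numerical choices

* Indefinite working or latent correlation matrices are repaired by
  clipping eigenvalues at $10^{-6}$ and renormalizing to unit diagonal;
  repairs are flagged. GEE consistency of $\hat\beta$ tolerates such
  working-matrix perturbations.
* $\hat\rho$ estimates are clipped to $(-0.99, 0.99)$; classes with no
  observed pairs are set to 0 with a warning.
* p-values entering the Cauchy combination are clamped to
  $[10^{-15}, 1 - 10^{-15}]$; `cauchy_combine(p, p) = p` holds to about
  $10^{-6}$ relative error, limited by `tan()` near $\pi/2$.
* Initialization: $\beta$ from the pooled independence GLM, $\rho = 0$,
  $\phi = 1$.
* Degenerate parts (an outcome with no variation, or an empty positive
  part) are skipped; the combined test then falls back to the remaining
  part with a warning.

## Known limitations

* The combined test inherits the usual mild finite-sample
  anti-conservativity of sandwich-based Wald tests: at K = 1000 clusters
  the acceptance run measures a null rejection rate slightly above the
  nominal 0.05 (its t1 value). Bias-corrected small-sample sandwich
  variants are deliberately out of scope.
* Families are limited to binomial-logit and gaussian-identity — the two
  the model uses.
* No standard errors for $\hat\rho$ (an open problem in the underlying
  method); no high-dimensional ($p \ge K$) support; discrete time only.
* The exact Bernoulli sampler enumerates $2^J$ atoms and is restricted to
  $J \le 12$; beyond that only copula-attainable targets are available.
* The twin-study application benchmark requires the originating study's
  deposited dataset, which is not redistributable inside the package; the
  corresponding acceptance criterion is intentionally left failing when the
  file is absent, and the full pipeline is exercised on a synthetic
  twin-style fixture instead.
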