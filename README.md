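# mtlc — taxonomy-structured GEEs for longitudinal microbiome data

`mtlc` implements the **Microbiome Taxonomic Longitudinal Correlation
(MTLC)** model: a two-part marginal model for zero-inflated OTU relative
abundances with repeated measures, in which the working correlation of a
generalized estimating equation (GEE) is *derived from the taxonomy* of the
OTUs and the repeated-measure design, rather than assumed exchangeable or
left unstructured.

It is aimed at biostatisticians and microbiome analysts who need, from one
model: (i) predictor effects on OTU *prevalence* (presence/absence), (ii)
predictor effects on the *positive relative abundance* (log scale), (iii) an
overall test combining both, and (iv) interpretable estimates of the
correlations between OTUs, time points and repeated samples (e.g. twins).

## The model

For cluster $k$ (a subject or pedigree) and cell $j$ (an OTU × repeat-cell
combination, $J = N \cdot L$ cells), abundances $y_{kj}$ are split into
$y^{(0)}_{kj} = \mathbf 1\{y_{kj}>0\}$ and $y^{(+)}_{kj} = \log_{10} y_{kj}$
(where positive), and modelled marginally:

$$
\operatorname{logit}(\mu^{(0)}_{kj}) = x_{kj}'\beta^{(0)},
\qquad
\mu^{(+)}_{kj} = x_{kj}'\beta^{(+)} .
$$

Both GEEs use working covariance
$V_k = A_k^{1/2} R_k(\rho) A_k^{1/2}$, where the symbolic pattern of $R$
assigns one correlation class to every cell pair:

* taxonomic classes (I, II, …) — one per *first common taxon* of an OTU
  pair, built from the trimmed taxonomy via the numeric representation
  $(n_1,\dots,n_I)$;
* repeat classes (i, ii, …) — exchangeable/Toeplitz/unstructured time
  structure crossed with an exchangeable repeated-sample structure.

Coefficients $\rho_c$ are estimated per class by moment equations on
Pearson residuals, $\hat\rho_c = \sum e_{kj}e_{kj'} / ((N_c - p)\hat\phi)$;
$\hat\beta$ gets the robust sandwich covariance; $H_0\!: C\beta^{(0)} =
c,\ C\beta^{(+)} = c$ is tested per part by Wald statistics and overall by
the Cauchy combination test
$W = \tfrac12\tan[(\tfrac12 - p^{(0)})\pi] + \tfrac12\tan[(\tfrac12 -
p^{(+)})\pi] \sim \mathrm{Cauchy}(0,1)$ under the null.

## Worked example

```r
library(mtlc)

# 1. taxonomy -> symbolic structure matrix
lin <- c("c1;o1;f1;g1", "c1;o1;f1;g2", "c1;o1;f2;g3",
         "c1;o2;f3;g4", "c1;o2;f3;g5", "c1;o2;f3;g6")
gamma <- build_structure_matrix(parse_lineages(lin))
print(gamma)
#> taxonomic structure matrix (6 x 6), classes: I, II, III, IV
#>      OTU1 OTU2 OTU3 OTU4 OTU5 OTU6
#> OTU1 D    III  II   I    I    I
#> OTU2 III  D    II   I    I    I
#> OTU3 II   II   D    I    I    I
#> OTU4 I    I    I    D    IV   IV
#> OTU5 I    I    I    IV   D    IV
#> OTU6 I    I    I    IV   IV   D
```

Class I is the correlation of OTUs that only share the root class, II/III
of OTUs sharing an order or family, IV of genera within the last family —
six OTUs, four correlation parameters instead of fifteen.

```r
# 2. simulate a two-OTU, two-visit cohort and fit the two-part model
set.seed(1)
sc  <- mtlc_scenario(K = 400, beta0 = 0.3, betap = 0.2)
d   <- simulate_zero_inflated(sc)
fit <- fit_mtlc(d$y, d$x, gamma = sc$gamma, omega = sc$omega,
                transform = "neglog10")
print(fit)
#> Prevalence part (binomial, logit):
#>             Estimate Robust SE      z
#> (Intercept)   0.1091    0.0635 1.7190
#> x             0.3037    0.0635 4.7865
#> rho:     D,i     I,D     I,i
#>       0.3080  0.2776 -0.0155
#>
#> Positive-abundance part (gaussian, identity, neglog10):
#>             Estimate Robust SE       z
#> (Intercept)   3.0103    0.0406 74.0583
#> x             0.2608    0.0406  6.4165
#> rho:     D,i     I,D     I,i
#>       0.2562  0.3021 -0.0253
#>
#> Tests (H0: contrast = 0):
#>   prevalence: W = 22.9105, df = 1, p = 1.697e-06
#>   positive:   W = 41.1720, df = 1, p = 1.394e-10
#>   combined (Cauchy): p = 2.788e-10
```

Both generating effects (0.3 on prevalence, 0.2 on the $-\log_{10}$
abundance) are recovered within sampling error, the generating correlations
($\rho(D,i) = \rho(I,D) = 0.3$, $\rho(I,i) = 0$) appear in both parts'
`rho` maps, and the combined test rejects decisively.

Real data enter through TSV files:

```sh
inst/cli/mtlc fit --otu-table otu.tsv --taxonomy taxa.tsv --meta meta.tsv \
    --predictor obesity --subject-col family --sample-col twin \
    --time-col visit --time-structure exchangeable --transform log10 \
    --out report.json
```

(`mtlc_cli()` exposes the same subcommands — `build-structure`, `fit`,
`simulate` — in-process.)

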