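---
title: "Measuring the convergence of common- and rare-variant gene signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the convergence of common- and rare-variant gene signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corac)
```

## The question

Common variants (GWAS) and rare variants (exome sequencing) interrogate the
same genome with very different instruments. For a given complex trait, do
the two instruments implicate the *same genes*? `corac` quantifies that
convergence and provides the simulation machinery to study what drives it:
statistical power (effective sample size), polygenicity, negative selection,
and the linkage disequilibrium (LD) coupling between the two variant
classes.

## The convergence signature

Gene-level association signals from the two variant classes are first made
comparable:

1. **Per-gene p-values.** The common-variant path aggregates SNP-level
   linear-regression p-values within a gene into a single statistic
   $T=\sum_j -2\ln p_j$ referred to a scaled chi-square whose first two
   moments account for the LD between the SNPs (Brown's method; the
   covariance of $-2\ln p$ terms is a cubic polynomial in the absolute
   genotype correlation). The rare-variant path runs burden and SKAT-O
   (and optionally SKAT) per annotation category (pLoF, missense/LC,
   synonymous) and takes $P_\text{rare}$ as the minimum over the six
   (test × category) p-values, deliberately unadjusted; a Bonferroni-style
   variant is available for sensitivity analysis.
2. **Clumping.** Within each approximately independent LD block only the
   gene with the smallest product $P_\text{common}\cdot P_\text{rare}$
   (computed in log space) is retained, so the agreement unit is an
   effectively independent locus.
3. **Top-$k$ selection.** Both rankings are cut at the same $k$, which
   controls for the effect of sample size on the *number* of significant
   genes and yields a 2×2 table: $a$ genes top-ranked by both classes, $b$
   and $c$ by one class only, $d$ by neither.

The signature is Cohen's kappa on that table,

$$\kappa=\frac{p_\alpha-p_\epsilon}{1-p_\epsilon},\qquad
p_\alpha=\frac{a+d}{n},\quad
p_\epsilon=\frac{a+b}{n}\frac{a+c}{n}+\frac{c+d}{n}\frac{b+d}{n},$$

i.e. observed agreement corrected by the agreement expected from the two
margins at random. A companion statistic, Gwet's AC1, replaces
$p_\epsilon$ with $2\pi(1-\pi)$, $\pi=\tfrac12(p_{1.}+p_{.1})$; it is less
sensitive to the prevalence of associated genes and therefore better suited
to comparisons across traits. The odds ratio $ad/bc$ is reported for
completeness only: it is 1 at chance and diverges as errors vanish, which
makes its scale awkward as a measure of agreement.

Because both margins are fixed at $k$ by construction, $\hat\kappa$ is a
linear function of $a$, and its expectation under independent rankings is
exactly 0 — the property the null-calibration test exercises.

### Uncertainty

* **Bootstrap.** Clumped genes are the exchangeable unit: each replicate
  resamples them with replacement, re-ranks both p-value columns inside the
  resample, rebuilds the table, and recomputes $\kappa$ and AC1. This
  preserves the coupling between the two rankings. Replicates with an
  undefined $\kappa$ (degenerate margins) are dropped and counted.
* **Bayesian posterior.** The table is multinomial in
  $(p_{11},p_{10},p_{01},p_{00})$, parameterized by the margins
  $p_{1.},p_{.1}$ and the joint probability $p_{11}$, with likelihood
  $p_{11}^a(p_{1.}-p_{11})^b(p_{.1}-p_{11})^c(1-p_{1.}-p_{.1}+p_{11})^d$.
  The last factor is written here with $+p_{11}$, the form required for the
  four cell probabilities to sum to one. Margins get Beta priors
  (means $s,t$, concentrations $u,v$; default: observed margins with
  $u=v=2$) and $p_{11}$ a uniform prior *conditional on its feasible
  Fréchet range* $[\max(0,p_{1.}+p_{.1}-1),\min(p_{1.},p_{.1})]$, so that a
  zero-data posterior reproduces the prior margins exactly. The posterior is
  evaluated on a 101³ grid in log space with a global max-shift (robust to
  very large counts) and normalized by the trapezoid rule; MCMC would buy
  nothing for a 3-parameter bounded problem and would cost reproducibility.

## The synthetic cohort generator

Real biobank genotypes cannot ship with a package, so the generator
emulates the structural assumptions the analysis rests on:

* **Block-diagonal LD.** Within a block, a single latent Gaussian factor
  induces exchangeable correlation: common variants load
  $\sqrt{0.3}$ (pairwise latent correlation 0.3) and rare variants load so
  that their latent correlation with any other variant is 0.05. Two latent
  draws per individual are thresholded at the frequency-matched normal
  quantile and summed, giving Hardy–Weinberg dosages in $\{0,1,2\}$. Note
  the configured values are *latent* correlations; thresholding attenuates
  them, strongly so for rare variants (a latent 0.05 between a 0.5%-MAF
  rare variant and a common variant induces a dosage correlation of only
  ~0.008). Blocks are independent; there is no ancestry structure,
  genotyping error, or realistic human LD map.
* **Frequency spectra.** Common target MAFs are uniform on
  $[\text{split},0.5]$ and rare MAFs uniform on $[1/(2n),\text{split})$,
  with the split at 0.01 in simulation mode (0.05 is the conventional
  common-variant filter for empirical summary inputs). Monomorphic columns
  are flagged, never dropped, so indices stay aligned with the genome map.
* **Causal architecture.** Each path (common, rare) receives
  `round(prop_causal_genes * n_genes)` causal genes built from a shared
  core of `round(shared_causal_fraction * size)` genes plus disjoint
  remainders, so the realized overlap is exact. Within a causal gene, half
  of the class's polymorphic variants (configurable) carry effects.
* **Effect sizes.** Under the selection model, per-SD effects are drawn
  $\beta_i \sim N\!\big(0,\,C\,[p_i(1-p_i)]^{1+\alpha}(1/(1+\ell_i))^{r}\big)$
  with $C=h^2/N_\text{causal}$; the baseline model uses the
  frequency-independent variance $h^2/N_\text{causal}$. Negative $\alpha$
  flattens the per-variant heritability profile across the frequency
  spectrum — the signature of negative selection. We implement this model
  literally on SD-scaled genotypes and do not re-parameterize it.
* **Phenotype.** $y=G_s\beta+\varepsilon$; the noise is drawn, then
  orthogonalized against the genetic component and both parts are rescaled
  so the *realized* genetic variance share equals $h^2$ exactly (not just
  in expectation). This stabilizes desk-scale experiments, where the
  sampling variability of a realized $h^2$ would otherwise dominate
  between-replicate variance.
* **Decorrelation.** `decorrelate_rare()` permutes every rare column
  independently across individuals before the phenotype is generated:
  marginal allele counts are preserved exactly, and all correlation between
  the rare class and anything else is destroyed.

### What the defaults mean for the sweep experiments

The sweep defaults — 150 blocks × 2 genes, 4 common + 12 rare variants per
gene, $k=15$ of 150 clumped genes, $N\le 4000$, 20 replicates per
condition — are a desk-scale rendition of the study conditions
($h^2=0.30$, 10% causal genes, shared fraction 0.50, $N$ varied). They were
sized by a power calculation so that the rare-variant path, which is the
power-limiting path exactly as in empirical common/rare comparisons, has a
detection gradient across the $N$ grid on a single CPU. Full-scale
configurations (more blocks, genes, variants, individuals) are accepted by
every function; only runtime grows.

Two findings from the paper-scale analysis deserve an explicit caveat
because the synthetic conditions cannot reproduce them, and the package's
test suite reports them honestly rather than papering over them:

* **Selection dampening.** Empirically, traits under stronger negative
  selection show *less* convergence. In this generator the opposite
  happens: with per-SD effects, lowering $\alpha$ moves heritability from
  the common path into the rare path, and since the rare path is the
  bottleneck, convergence *rises*. The empirical dampening plausibly runs
  through a channel this generator deliberately lacks: on real genotypes,
  rare variants sit on common haplotype backgrounds, so rare-variant gene
  tests partially tag the common-variant signal, and that leakage — which
  scales with how strongly heritability concentrates in common variants —
  is removed here by the very weak induced rare/common dosage correlation
  (~0.008). The decorrelation experiment is the same story: shuffling rare
  genotypes removes a correlation that is already negligible, so the
  measured effect is near zero rather than clearly negative.
* **Conditional FDR under the global null.** The conditional FDR
  $\text{FDR}(p_R\mid p_C)=\pi_0(p_C)\,p_R/\hat F(p_R\mid p_C)$ equals
  $\approx\pi_0\approx 1$ for *every* $p$ when the data are globally null,
  because $\hat F(p)\approx p$; a null FDR curve that "tracks $p$" is not a
  property this estimator (or any Bayesian FDR) can have. The worked
  arithmetic (e.g. $\text{FDR}=1\times 0.2/(2/4)=0.4$ on a four-gene
  subset) and the enrichment behaviour under shared signal are the
  meaningful checks.

## Stratified (conditional) FDR

For gene pairs $(p_R,p_C)$, the estimator conditions on
$p_C\le\text{threshold}$, estimates $\pi_0$ on the subset with Storey's
method at $\lambda=0.5$ (the reference approach names no estimator; λ is
exposed), floors the empirical conditional CDF at $1/|S|$, and clamps the
FDR at 1. The mirrored direction swaps the two columns. The companion
stratified Q–Q summary reports expected versus observed $-\log_{10}$
quantiles per conditioning stratum (default thresholds 1, 0.1, 0.01,
0.001, nested by construction; strata under 20 genes are dropped with a
warning): with shared signal, tighter strata dominate the unconditional
curve.

## Selection-exponent inference from summary statistics

`fit_alpha()` models each per-SD marginal estimate as
$\hat\beta_i\sim N\!\big(0,\,C\,[p_i(1-p_i)]^{1+\alpha}(1/(1+\ell_i))^{r}+\text{se}_i^2\big)$,
treating variants as independent given their LD scores, profiles $C$ out by
an inner one-dimensional maximization at each $\alpha$ on a grid over
$[-1.5,1]$ (step 0.01), and refines the grid optimum by continuous local
search. Identifiability requires frequency contrast (at least a two-fold
spread in $p(1-p)$) and per-variant information: the companion generator
`simulate_summary_stats()` therefore fixes the *mean per-variant
noncentrality* (default 20, a modest value for ascertained causal variants
in biobank-scale studies) rather than splitting a trait $h^2$ over all
variants — at desk-scale $N$ the latter would leave $\alpha$ unidentifiable
regardless of estimator, while fixing the noncentrality preserves the
information content of the real setting. Only causal variants are passed in
recovery experiments; a null/causal mixture is not modelled.

## Trend statistics

`trend_analysis()` relates convergence estimates to a driver with Spearman
and Kendall rank correlations, their partial versions given a covariate
(partial Kendall via
$\tau_{xy\cdot z}=(\tau_{xy}-\tau_{xz}\tau_{yz})/\sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}$,
partial Spearman via rank-residual correlation), and a generalized
least-squares fit with $\operatorname{Var}(\varepsilon_i)\propto
x_i^{2\theta}$. The exponent $\theta$ is chosen on a grid over $[-2,2]$
(step 0.05) by Gaussian profile likelihood, ties broken toward the smallest
$|\theta|$ so the homoskedastic fit is the default answer when the data
cannot distinguish.

## Numerical choices and degenerate inputs

* SKAT p-values use Ruben's chi-square series on the eigenvalues of the
  weighted genotype cross-product — exact up to a rigorously bounded
  truncation error — with a saddlepoint (Lugannani–Rice) and then Liu-type
  moment-matching fallback for pathological spectra. Moment matching alone
  carries a percent-scale systematic error in the bulk that a
  Kolmogorov–Smirnov calibration check can detect at a few thousand genes.
  The SKAT-O omnibus keeps the Liu machinery throughout (per-ρ p-values,
  quantile inversions, and the integration of the minimum-p envelope over
  the shared $\chi^2_1$ factor with the substitution $x=u^2$, which removes
  the density singularity at 0), falling back to a flagged Bonferroni
  correction over the ρ grid if the decomposition degenerates; a
  single-point ρ grid is computed with the exact quadratic form so the
  SKAT and burden limiting cases are exact.
* The covariance of $-2\ln p$ terms in the gene-level aggregation uses an
  even polynomial in the genotype correlation fitted for two-sided
  p-values ($3.9364 r^2 - 0.0407 r^4 + 0.1043 r^6$, constrained to the
  exact value 4 at $|r|=1$ so duplicated variants collapse exactly); the
  classical one-sided cubic in $|r|$ overstates the covariance and makes
  the test conservative.
* Clumping and top-$k$ ties are broken by lexicographic gene id and
  flagged; p-value products are summed in log space.
* Zero cells in the odds ratio trigger the Haldane–Anscombe +0.5
  correction, flagged.
* Every stochastic operation is a pure function of its inputs and an
  integer seed; pipeline stages derive child seeds deterministically from
  the master seed, so sweep tables are bit-reproducible.

## Worked example

```{r, eval = FALSE}
ar <- architecture_params(h2_trait = 0.3, prop_causal_genes = 0.1,
                          shared_causal_fraction = 0.5, alpha = -0.37)
co <- simulate_cohort(ar, n_individuals = 2000, seed = 1)
genes <- gene_assoc_table(co$panel, co$phenotype)
fit <- corac(genes, k = 15, bootstrap = 1000, seed = 1)
fit
plot(fit)
```

## Limitations

The generator's LD is exchangeable within blocks and absent between them;
there is no ancestry structure, no genotyping error, no realistic exome
site-frequency spectrum, and the rare/common coupling is far weaker than on
real haplotypes (see the caveats above). Gene length is deliberately not
adjusted for. Binary traits enter only through the effective-sample-size
convention $4/(1/\text{cases}+1/\text{controls})$; association tests are
linear-model based and assume a quantitative phenotype. Passing synthetic
tests here demonstrates internal correctness of the estimators and the
direction of power-driven effects, not that any particular empirical trait
will show a given convergence level.
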