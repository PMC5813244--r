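---
title: "Estimating EWAS significance thresholds by permutation and density extrapolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating EWAS significance thresholds by permutation and density extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasthresh)
```

## The problem

An epigenome-wide association study (EWAS) tests hundreds of thousands of
CpG sites for a difference in mean DNA methylation between conditions. Two
features complicate the choice of a significance threshold. First, nearby
CpGs are co-methylated: their Beta values (methylation fractions in (0,1))
are correlated at genomic distances up to 1–2 kb, so a Bonferroni
correction over the probe count over-corrects. Second, commercial arrays
such as the Illumina 450k interrogate under 2% of the ~28 million CpGs in
the genome, so a threshold tied to the probe count under-corrects relative
to the full methylome that a result implicitly makes claims about.

This package implements an empirical resolution of both problems:

1. a **label-permutation minimum-P (maxT) null** gives a family-wise 5%
   threshold $\alpha$ for the probe set actually tested;
2. the **effective number of independent tests** is read off as
   $m = 0.05/\alpha$ (Bonferroni inversion) and, as a model-based
   alternative, as the second shape parameter of a $\beta(1, b)$ fit to
   the minimum-P distribution (the Šidák law for $b$ independent tests);
3. **subsampling over a grid of CpG densities** traces $m$ as a function
   of coverage, and a **Monod (saturating growth) fit**
   $f(x) = u x/(k + x)$ extrapolates it to saturated genome-wide density,
   giving a genome-wide threshold $\alpha = 0.05/u$;
4. **non-central-t power machinery** converts thresholds into study sample
   sizes, re-deriving published EWAS design recommendations under the
   empirically estimated thresholds.

A synthetic 450k-like data generator ties the stages together so the whole
pipeline is testable without any external download.

## The permutation null

Beta values are converted to M values, $M = \log_2(\beta/(1-\beta))$,
before testing; the t-test is approximately valid on that scale. Labels
(`assign_labels()`) designate $\lfloor n/2\rfloor$ samples as cases. Each
permutation redraws the labels, computes the equal-variance two-sample t
statistic per CpG with $n-2$ degrees of freedom, records the maximum $|t|$
and converts it to a two-sided P value — the per-permutation minimum P.
Because labels are random by construction, the scheme is immune to
confounding structure in the data itself. `alpha_from_null()` takes the
empirical 5th percentile (type-7 quantile, linear interpolation between
order statistics) as $\alpha$.

Two choices are deliberately documented rather than inherited: label
permutations are drawn independently **with replacement** from the
permutation space (at $10^4$ draws from an astronomically large space,
collisions are irrelevant and streaming is simpler), and the quantile
estimator is fixed to the interpolation convention above. Taking the P
value of the maximum $|t|$ is equivalent to the minimum of the per-CpG P
values at fixed degrees of freedom; the equivalence is asserted in the
test suite against a naive two-loop reference implementation.

The permutation stream is drawn once from the master seed before probes
are processed, so results are reproducible and independent of the
chunking used to bound memory (`chunk_size` rows at a time, i.e.
O(chunk × permutations) memory). A CpG with zero pooled variance in some
permutation is skipped for that permutation and counted.

## Effective number of tests

`bonferroni_m()` inverts the threshold; `fit_beta_min_p()` fits
$\beta(1, b)$ to the minimum P values. The moment start is
$\hat b = (1-\bar x)/\bar x$ and the reported estimate maximises the
likelihood numerically on $\log b$ (relative tolerance $10^{-10}$) —
mirroring the original numerical-optimisation procedure — while the
closed-form MLE $-R/\sum \log(1-p_i)$ is computed alongside as a
cross-check. On real 450k data the two routes (Bonferroni inversion and
beta fit) disagree materially, which is evidence that no single "true"
effective test count exists; both numbers are therefore reported, and the
QQ diagnostic (`qq_expected()`) shows how far the observed minimum-P
distribution is from any $\beta(1, m)$ law.

Per-dataset estimates are combined by a sample-size-weighted mean of the
effective test counts, then inverted: `consensus_alpha()`. Weighting by
sample size reproduces both published consensus figures ($2.4\times10^{-7}$
for the 450k and $3.6\times10^{-8}$ genome-wide) from the published
per-dataset tables; an unweighted mean does not, so the weights are fixed
to sample sizes.

## Density subsampling and Monod extrapolation

`subsample_curve()` emulates sparser arrays: at density $d$ it draws
$\lceil d\,p\rceil$ probes without replacement, takes each permutation's
minimum P over the subset, and records the 5% point across permutations;
replicate draws (default 100) are averaged. Subsets are drawn
independently per (replicate, density) — the estimates at each density are
then unbiased and no nesting convention needs to be invented. The grid
default is $0.01, 0.02, \ldots, 1$; a density of exactly 0 is degenerate
(no probes) and excluded. The 5% point is taken per replicate and then
averaged, not the other way around.

At low density most subsampled probes are isolated, so
$m_\mathrm{eff}(d) = 0.05/\alpha(d)$ grows linearly; as density
saturates, correlated neighbours stop contributing independent
information and the curve bends. `fit_monod()` fits
$m_\mathrm{eff}(d) \approx u d/(k+d)$ by unweighted least squares
(Levenberg–Marquardt, start $u_0 = 2\,m_\mathrm{eff}(1)$, $k_0 = 1$, with
a multi-start fallback). The asymptote $u$ is the effective test count of
a hypothetical array of infinite density and $0.05/u$ the genome-wide
threshold. Failure to converge is a first-class result (`converged =
FALSE`) — with near-independent data the curve is a straight line, $u$ and
$k$ diverge together and no asymptote is identifiable; a fitted $k$ far
outside the observed density range (more than ten times the maximum
density) is likewise flagged `identifiable = FALSE`. That mirrors what
happens on real data when a dataset's minimum-P distribution is
ill-behaved: the failure is reported, not averaged in.

## Sample sizes under the new thresholds

Published EWAS power tables report, for mean methylation differences
$\delta$ of 7–15 percentage points, the sample size giving 80% power at
$P<0.05$ and $P<10^{-6}$ for two designs. `solve_sigma()` treats each
anchor as an equation in the unknown noise scale $\sigma$: power is
evaluated from the non-central t distribution and solved by bracketed
root finding (power is strictly monotone in $\sigma$). `solve_n()` then
re-solves for the sample size at a new threshold.

The design determines the distribution:

* discordant-twin (paired differences of $n$ twin pairs):
  $\mathrm{df} = n-1$, $\mathrm{ncp} = \sqrt{n}\,\delta/\sigma$;
* case-control ($n$ cases vs $n$ controls):
  $\mathrm{df} = 2n-2$, $\mathrm{ncp} = \sqrt{n/2}\,\delta/\sigma$.

Using the paired formula for both designs leaves five case-control cells
one sample off; with the design-specific forms, every published cell at
the re-derived thresholds is reproduced exactly. Integer conversion is
round-to-nearest by default because that is the convention the published
tables follow (`rounding = "up"` gives the smallest sample size whose
power meets the target, which is the conservative choice for prospective
design). $\sigma$ is anchored at the $10^{-6}$ column, the regime closest
to the genome-wide thresholds being substituted; the 0.05 column of the
published tables came from a different simulation regime and is not used
as an anchor. The inferred $\sigma$ (roughly 16 for twins, 13 per arm for
case-control, in percentage-point units) is validated indirectly: through
exact table reproduction and through a normal-approximation oracle
($\mathrm{ncp}_{req} \approx t_{crit} + z_{power}$ for df $\ge 60$).

```{r table, eval = FALSE}
rebuild_sample_size_table(new_alphas = c(2.4e-7, 3.6e-8))
```

## The synthetic data generator

`generate_manifest()` and `generate_beta()` emulate the features of
processed 450k data that the pipeline consumes:

* **spacing** — gaps between consecutive probes are a mixture of short
  within-cluster gaps (default 2–200 bp, probability 0.7) and long
  between-cluster gaps (2–20 kb), reproducing island-like clustering;
* **co-methylation** — a latent Gaussian field with correlation
  $\rho(d) = \rho_{bg} + (\rho_{max}-\rho_{bg})\,e^{-d/L}$. Defaults
  $\rho_{max} = 0.4$, $\rho_{bg} = 0.05$, $L = 1000$ bp sit in the middle
  of the per-bin correlation profiles observed across published blood,
  brain and cross-population 450k datasets (maxima ≈ 0.3–0.45 decaying to
  ≈ 0.04–0.07 beyond ~2 kb);
* **marginals** — the latent field is mapped probe-wise through a
  Gaussian copula to Beta distributions with a trimodal baseline (hypo-,
  intermediate, hypermethylated), concentration 50, matching the
  inter-individual spread of array data. Values are clipped to
  $[10^{-6}, 1-10^{-6}]$ so M values stay within roughly ±20.

The exponential kernel is realised *exactly* by an Ornstein–Uhlenbeck
recursion along the sorted positions — correlation between any two probes
is $e^{-d/L}$ by the Markov property — which makes generation
O(probes × samples) with no banded covariance factorisation at all; the
background floor is a shared per-sample factor. The copula makes the
Beta-scale Pearson correlation a monotone, near-identity function of the
latent correlation (attenuation under 1% at the default concentration,
measured by simulation), so the generator and `correlation_profile()`
serve as mutual oracles in the test suite.

What the generator deliberately does **not** emulate: probe-chemistry
(Infinium I/II) effects, batch structure, cell-type mixtures, methylation
QTLs, and — importantly — the *heterogeneity* of short-range correlation.
Real arrays mix near-duplicate probe pairs ($r \to 1$) with uncorrelated
close pairs averaging to the observed per-bin means; the Gaussian field
gives every close pair the same moderate correlation. Since maxT
multiplicity reduction is driven by the near-duplicates, the default
generator loses fewer effective tests than real 450k data does
(where $m/p \approx 0.3$–0.5). Pipeline tests that need a strongly
saturating density curve therefore use configurations with tight clusters
of highly correlated probes; conclusions about real-data thresholds rest
on the published per-dataset tables, not on the generator.

## Numerical conventions and edge cases

* Distances are absolute differences of 1-based manifest positions; no
  strand concept (CpGs are strand-symmetric).
* Correlation-profile bins are formed by equal occupancy (default 400
  pairs) after a stable sort on distance, so distance ties keep
  enumeration order; the last bin may be short. The published procedure
  does not say how uneven remainders are handled; equal occupancy with a
  short tail is this package's documented choice.
* Probe pairs with a zero-variance row are skipped and counted, never
  silently imputed.
* `beta_to_m()` refuses values at 0 or 1 rather than clipping silently;
  the caller owns the clipping policy.
* Power saturating at 1.0 in double precision bounds how far
  monotonicity-in-n can be asserted; solver tolerances are $10^{-12}$
  (sigma) and $10^{-9}$ (continuous n).
* Problem sizes in the test suite are scaled to desk hardware: the
  end-to-end run uses 5,000 probes × 60 samples × 1,000 permutations with
  20 subsampling replicates on a 0.05 density grid; the independence
  check uses 10,000 probes × 2,000 permutations. At these sizes the
  empirical 5% point carries ~10% Monte-Carlo error, which is what the
  corresponding test tolerances reflect.

## Limitations

The genome-wide extrapolation inherits the array's probe placement: the
450k targets islands and promoters, so "density → 1" extrapolates a
biased sample of genomic contexts. The effective-test concept itself is a
modelling convenience — Bonferroni inversion and the beta fit disagree on
real data — and the Monod form is one of several plausible saturating
curves, retained because it matched sequence-based and population-genetic
extrapolations in the GWAS setting where this approach originated. For
small samples (~20 arrays) the minimum-P distribution becomes unstable
and both the beta fit and the Monod fit can fail; the package surfaces
those failures explicitly.
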