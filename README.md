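# ltbayescpi

Joint Bayesian genomic prediction for one continuous and one binary
(threshold) trait.

Breeding programmes usually need genomic estimated breeding values (GEBVs)
for continuous traits (growth, yield) and categorical ones (disease status,
calving ease) at the same time, yet routine whole-genome regression is run
one trait at a time. For a binary trait with low heritability and a modest
training population, single-trait prediction discards the information
carried by genetically correlated continuous traits. This package is for
quantitative geneticists and breeding researchers who want to quantify — or
use — that information.

## The model

`lt_bayescpi` is a bivariate linear-threshold spike-and-slab regression.
With $y_1$ the continuous records and $l$ the latent liabilities behind the
binary records ($y_{2,i} = \mathbf{1}(l_i > 0)$),

$$
\begin{pmatrix} y_1 \\ l \end{pmatrix} =
\begin{pmatrix} X_1 \beta_1 \\ X_2 \beta_2 \end{pmatrix} +
\begin{pmatrix} Z g_1 \\ Z g_2 \end{pmatrix} +
\begin{pmatrix} e_1 \\ e_2 \end{pmatrix},
\qquad (e_{1i}, e_{2i})' \sim N_2(0, R_e),
$$

where $Z$ holds allele dosages (0/1/2). Each SNP has a *shared* inclusion
indicator: with probability $\pi$ the effect pair $(g_{1j}, g_{2j})$ is zero
for both traits, otherwise it is drawn from the bivariate-normal slab
$N_2(0, G_0)$. $\pi$, $G_0$ and $R_e$ are estimated from the data (uniform
and inverse-Wishart priors, flat by default); identifiability for the binary
trait is obtained by fixing its threshold at 0 and residual variance at 1,
with $R_e$ sampled from the corresponding conditional inverse-Wishart
(Korsgaard-type algorithm). The single-trait special cases are included:
`bayescpi` (continuous) and `bayestcpi` (binary via liabilities). Inference
is single-site Gibbs sampling with the effect pair integrated out of the
inclusion odds; everything is deterministic given a seed.

The package also ships the forward-in-time simulator of the validation
design (mutation-drift equilibrium history, Haldane recombination,
pleiotropic and trait-specific QTL groups, empirical-quantile thresholding),
the evaluation layer (accuracy $r_{TBV,GEBV}$, bias slope $b_{TBV,GEBV}$
with liability-scale rescaling, paired t-tests across replicates), and a
scenario-grid runner. See the vignette
(`vignettes/linear-threshold-bayescpi.Rmd`) for the full model and the
design decisions.

## Worked example

Simulate a small two-trait population, fit the joint model, and evaluate
prediction in the candidate generations (this is the desk-scale standard
scenario used by `scripts/acceptance.R`; about half a minute):

```r
library(ltbayescpi)

genome <- genome_config(n_markers_per_chrom = 200, chrom_length = 0.1)
dat <- simulate_dataset(genome, demography_config(), architecture_config(),
                        seed = 1)
fit <- ltbc_fit(dat$phenotypes, dat$genotypes, method = "lt_bayescpi",
                n_cycles = 8000, burn_in = 4000, seed = 101)
glance(fit)
evaluate_fit(fit, dat, generations = 3)
```

Output from the run above (via `Rscript scripts/acceptance.R --seed 1 ...`,
which fits all three methods on the same replicate):

```
        method      trait generation accuracy slope slope_rescaled
1     bayescpi continuous          3    0.741 0.946             NA
5    bayestcpi     binary          3    0.625 2.962          0.329
9  lt_bayescpi continuous          3    0.702 0.861             NA
13 lt_bayescpi     binary          3    0.589 2.594          0.288

Joint model: pi_hat = 0.9539 (prop. included 0.0452), r_g_hat = 0.028, r_e_hat = -0.089
Simulated truth: realized r_g = 0.151, v_e2 = 9.00
```

Reading this: `accuracy` is the correlation between true and estimated
breeding values in generation 3 (the first candidate generation); `slope`
is the regression of TBV on GEBV (1 = unbiased); for the binary trait the
slope is also rescaled by the true residual liability variance
(`slope_rescaled = slope / v_e2`) because the model's liability scale fixes
the residual variance at 1. `pi_hat` is the posterior probability of a zero
effect, `r_g_hat` / `r_e_hat` the estimated genetic and residual
correlations. In this particular replicate the realized genetic correlation
happens to be low (0.15), so joint analysis cannot beat single-trait
prediction; at the full design scale (10,000 markers, 50,000 cycles,
20 replicates — hours of CPU, via `run_scenario(scale_factor = 1)`) the
joint model's advantage on the binary trait grows with the genetic
correlation.

Per-SNP posterior summaries come from `tidy(fit)`, diagnostic plots from
`autoplot(fit, "effects")` and `autoplot(fit, "trace")`, GEBVs for new
genotypes from `predict_gebv(fit, Z)`. A thin CLI (`exec/ltbayes`) wraps
simulate / fit / evaluate for shell pipelines.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates one desk-scale standard-scenario replicate (1,000 markers at
the full design's marker spacing, 1,000 phenotyped training individuals),
fits all three methods, prints the per-generation accuracy/bias table and
the joint model's posterior summaries, and writes its JSON output to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Distributional correctness of the samplers themselves (conditional
inverse-Wishart vs a rejection oracle, factorisation of the joint chain,
a Geweke-style joint-distribution test, truncated-normal moments, and
reduced-scale parameter recovery) is covered in
`tests/testthat/test-acceptance.R`.
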