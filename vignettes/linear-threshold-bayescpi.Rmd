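---
title: "Joint genomic prediction of a continuous and a threshold trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint genomic prediction of a continuous and a threshold trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breeding programmes routinely select on a continuous trait (growth rate,
milk yield) together with a categorical one (calving ease, leg weakness,
disease status). Single-trait whole-genome regression wastes the information
carried by the genetic correlation between such traits, and a binary trait
with low heritability and modest training size is exactly the case where
borrowed information helps most. This package implements a bivariate
*linear-threshold* spike-and-slab regression — `lt_bayescpi` — together with
its single-trait special cases (`bayescpi` for the continuous trait,
`bayestcpi` for the binary trait via latent liabilities), a forward-in-time
simulator of the two-trait validation design, and the accuracy/bias
evaluation layer used to compare the methods.

## The model

Let $y_1$ be the continuous observations and $l$ the latent liabilities of
the binary trait, with $y_{2,i} = \mathbf{1}(l_i > t)$. Stacked,

$$
\begin{pmatrix} y_1 \\ l \end{pmatrix} =
\begin{pmatrix} X_1\beta_1 \\ X_2\beta_2 \end{pmatrix} +
\begin{pmatrix} Z g_1 \\ Z g_2 \end{pmatrix} +
\begin{pmatrix} e_1 \\ e_2 \end{pmatrix},
$$

where $Z$ is the $n \times q$ matrix of allele dosages (0/1/2) and residual
rows are iid $N_2(0, R_e)$. Each SNP $j$ carries a shared inclusion
indicator $\delta_j$: with probability $\pi$ the effect pair
$(g_{1j}, g_{2j})$ is $(0,0)$; with probability $1-\pi$ it is drawn from the
bivariate-normal slab $N_2(0, G_0)$. $G_0$ and $R_e$ carry inverse-Wishart
priors (flat by default: degrees of freedom $-3$, zero scale), $\pi$ is
uniform on $(0,1)$, fixed effects are bounded-uniform. A binary trait
cannot identify both a threshold and a residual variance, so the standard
parameterisation fixes the threshold at 0 and $\sigma^2_{e2} = 1$; with
$k \ge 3$ categories one fixes $t_1 = 0, t_2 = 1$ instead and samples the
remaining thresholds from their ordered-uniform conditional (exposed as
`sample_thresholds()`; the Gibbs engine itself targets the binary case the
validation design uses).

## The Gibbs sampler

Each cycle sweeps, in order: liabilities, fixed effects, the per-SNP
$(\delta_j, g_j)$ blocks, $G_0$, $R_e$, $\pi$ (and thresholds when free).
Liabilities are truncated-normal draws whose mean includes the regression
adjustment $(\sigma_{e12}/\sigma^2_{e1}) e_{1,i}$ on the continuous-trait
residual and whose variance is
$\sigma^2_{e2}(1 - \sigma_{e12}^2 / (\sigma^2_{e1}\sigma^2_{e2}))$. Location
parameters are single-site normal draws from the mixed-model-equation
conditionals, with residual vectors maintained incrementally so each
coordinate costs $O(n)$ (tests verify the incremental bookkeeping against a
from-scratch recomputation at $10^{-8}$).

**SNP inclusion odds.** The per-SNP indicator is drawn with the effect pair
integrated out. With the SNP's own contribution added back into the
residuals, let $v = (z_j'e_1^*, z_j'e_2^*)'$, $b = R_e^{-1} v$ and
$\Omega = (z_j'z_j) R_e^{-1} + G_0^{-1}$. The slab-over-spike marginal
likelihood ratio is

$$
\mathrm{BF}_j = |G_0|^{-1/2} |\Omega|^{-1/2}
  \exp\left(\tfrac{1}{2} b' \Omega^{-1} b\right),
\qquad
P(\delta_j = 1 \mid \cdot) = \frac{(1-\pi)\,\mathrm{BF}_j}
       {\pi + (1-\pi)\,\mathrm{BF}_j},
$$

and an included pair is drawn from $N_2(\Omega^{-1} b, \Omega^{-1})$. When
$G_0$ and $R_e$ are diagonal this log-odds factorises exactly into the sum
of the two single-trait BayesC-type odds; the test suite asserts the
identity at $10^{-10}$ and, at chain level, that the zero-covariance joint
model reproduces the two single-trait fits on a clear-signal fixture.

**Dispersion parameters.** $G_0$ is drawn from
$\mathrm{IW}_2((V_g^{-1}+S_g)^{-1}, v_g + m_1)$ where $S_g$ is the
cross-product of the currently included effect pairs and $m_1$ their count.
The degrees of freedom deserve a note: counting all $q$ SNPs instead of the
$m_1$ included ones is a plausible alternative reading, but only $v_g + m_1$
is consistent with the joint model in which excluded SNPs contribute no
effect to $S_g$ — the joint-distribution (Geweke-style) test fails under the
$q$ convention and passes under $m_1$. The $q$ convention remains available
via `df_mode = "all"` and is recorded in the fit settings. With the flat
prior the update needs $m_1 \ge 5$; rare sparser cycles fall back to a
ridge-stabilised draw (scale $S_g + 10^{-6}I$, df $\max(v_g+m_1, 4)$),
counted and reported in `glance()` as `n_fallback`.

For the bivariate model $R_e$ must respect $\sigma^2_{e2} = 1$, so it is
drawn from the *conditional* inverse-Wishart by the Korsgaard-type
algorithm: with $V = (V_e^{-1} + S_e)^{-1}$ partitioned as usual, draw
$x_1 \sim W_1(V_{11}, v_e + n)$ and
$x_2 \sim N(V_{11}^{-1}V_{12},\; x_1^{-1}V_{22.1})$, then
$T_{11} = x_1^{-1} + x_2^2$, $T_{12} = -x_2$, $T_{22} = 1$. The construction
guarantees positive definiteness ($T_{11} - T_{12}^2 = x_1^{-1} > 0$), and
an acceptance test matches its two free margins against a rejection oracle
built on `stats::rWishart` (unconstrained draws kept when
$|\sigma^2_{e2} - 1| < 0.005$) at Kolmogorov–Smirnov distance below 0.01.

$\pi$ (the probability of a *zero* effect) is conjugate:
$\pi \mid \delta \sim \mathrm{Beta}(q - m_1 + 1,\; m_1 + 1)$, with $q$
counted over informative (non-monomorphic) SNPs — a monomorphic column has
an improper effect conditional and is pinned out of the mixture, so it
carries no evidence about $\pi$ either.

**Numerical choices.** Truncated normals use inverse-CDF sampling, switching
to an exponential-proposal rejection beyond six standard deviations so the
chain stays stable at extreme incidences (e.g. 5% cases). Dosage columns are
centered before the sweep (the intercept absorbs the shift; reported
allele-substitution effects are unchanged). Residuals are refreshed from
scratch every 2000 cycles. A non-finite guard aborts with the cycle index.
Chains are deterministic given `seed`: one R-level RNG stream drives
everything, including the compiled core.

**Correctness.** The decisive evidence that the conditionals cohere is the
Geweke-style joint-distribution test (`geweke_joint_test()`): on a tiny
instance with proper priors, marginal moments of $\pi$, $G_0$, $R_e$ and
$\sum\delta$ from the successive-conditional simulator (Gibbs sweep
alternating with a fresh data draw) are compared with direct prior sampling.
The acceptance test runs $6\times10^4$ sweeps and requires all seven
checked moments to sit within three combined standard errors of their prior
values.

## The simulator

`simulate_dataset()` reproduces the validation design used for the method:
a base population of 100 at mutation–drift equilibrium after 1,000
generations of random mating (all loci start monomorphic; allele states flip
at $1.25\times10^{-3}$ per locus per gamete; Haldane-model meiosis without
interference), expansion to 1,000 in generation 1, then five more
generations bred from 50 random sires each mated to 10 dams with two
offspring per dam. Generations 1–2 (2,000 individuals) are the training
population; generations 3–6 are validation candidates carrying genotypes and
true breeding values only.

Markers are evenly spaced (default 2,000 per 1-Morgan chromosome, five
chromosomes); each interval between adjacent markers harbours one candidate
QTL at its midpoint, so prediction must act through linkage disequilibrium
rather than through the causal loci themselves. The alternative reading in
which candidate QTL coincide with markers is available as
`qtl_on_markers = TRUE`. Recent generations are simulated without new
mutation (the mutation phase exists to reach drift equilibrium), and markers
that end monomorphic are excluded from the inference panel.

QTL fall into a pleiotropic group and two single-trait groups (ratio
0.8:0.1:0.1; forced to 0:0.5:0.5 at $r_{AB}=0$). Pleiotropic effect pairs
are bivariate normal. Because the single-trait groups dilute the
breeding-value correlation below the pair correlation (by the factor
$n_1/\sqrt{(n_1+n_2)(n_1+n_3)}$, about 0.89 at the default ratio), the
default `target_correlation = "genetic"` inflates the pair correlation so
the *realized* genetic correlation targets $r_{AB}$; a 20-replicate test
asserts the realized mean within $\pm 0.06$ of the target.
`target_correlation = "effect"` keeps the literal pair correlation
$r_{AB}$. Effects are rescaled per trait so the realized training variance
of the true breeding values equals the targets (2.0 and 1.0), environmental
deviations have variance $\sigma^2_a (1-h^2)/h^2$, and the binary threshold
is the empirical $(1-\text{incidence})$ quantile of training liabilities —
guaranteeing the assigned incidence in every replicate, unlike a
normal-theory quantile.

What a green simulator test does and does not establish: the generator
emulates the drift-equilibrium allele-frequency spectrum, family structure
and LD decay of the stated design, but not sequence-level mutation models,
selection during breeding, epistasis or imprinting; conclusions transfer to
real data only insofar as marker–QTL LD behaves comparably.

## Evaluation

GEBVs are raw dosage sums of posterior-mean effects. Accuracy is the
Pearson correlation with the true breeding values per candidate generation.
Bias is the OLS slope of TBV on GEBV; for the binary trait the GEBV lives on
the model's liability scale (residual variance 1) while the simulated TBV
does not, so the slope is rescaled by the true residual liability variance
$v_{e2}$. The literal rescaling divides by the *variance*; since liability
scales differ by a factor proportional to the residual *standard deviation*,
the square-root alternative $b/\sqrt{v_{e2}}$ is reported alongside
(`slope_rescaled_sd`) without taking a position; the variance form is the
primary output. Method comparisons across replicates use a paired two-sided
t-test (each replicate yields both methods' accuracies on identical data —
pairing is the natural, maximally powered choice).

## Desk scale versus full scale

The headline experiment (10,000 markers, 2,000 training individuals, 50,000
cycles, 20 replicates, three methods) is several CPU-hours per scenario.
`run_scenario(scale_factor = 1)` reproduces it; smaller factors shrink
markers and phenotyped individuals proportionally and scale the chain with a
floor of 3,000 cycles / 1,500 burn-in. Two choices matter when shrinking:

* **Marker spacing.** Reducing marker count at fixed genome length weakens
  marker–QTL LD (QTL sit mid-interval); the reduced-scale acceptance runs
  therefore shrink chromosome length with the marker count, preserving the
  full design's 0.0005 Morgan spacing.
* **What reduced scale can and cannot recover.** At 1,000 markers and 1,000
  phenotyped individuals the joint model's genetic-correlation estimate is
  attenuated (three-replicate mean about 0.3 against a realized truth near
  0.4–0.5) — consistent in direction with the full-scale behaviour, where
  the estimate at $r_{AB}=0.8$ is also biased down, but stronger, because
  the binary trait at $h^2 = 0.1$ carries little information at this
  training size. The proportion of SNPs included stabilises at roughly
  twice the causal proportion at this scale (the corresponding acceptance
  assertion is left failing by design, with the measured value in the test
  output) and falls towards the causal proportion as the genome grows: with
  long LD blocks relative to genome length the indicator count tracks
  tagging blocks, not QTL. This is a property of the reduced-scale world,
  not of the sampler — on fixtures whose causal loci are markers themselves
  the included proportion matches the causal proportion closely.

## Known limitations

Two traits at most, one of them binary in the compiled chain (general $k$
only through the exposed threshold sampler); no polygenic/pedigree residual
term; single-chain inference (traces are exported for external diagnostics);
the simulator does not model selection, epistasis, imprinting or
sequence-level processes.
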