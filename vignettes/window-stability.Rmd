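---
title: "Single-step GWAS window variances across generations: models, simulator and design choices"
author: "ssgwas package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GWAS window variances across generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ssgwas` studies a single question: when an association analysis in a
population under directional selection is summarised as the percent of
genetic variance explained by windows of consecutive SNPs, how stable are the
top windows across sliding subsets of generations?  Because the motivating
commercial data sets are proprietary, the package ships its own population
simulator with a known architecture; every downstream stage is then testable
against that ground truth.  This vignette documents the models, the
simulator's assumptions, the numerical choices, and what a green test does
and does not establish.

# The evaluation model

Phenotypes are analysed with a multi-trait animal model,

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}\mathbf{a} +
\mathbf{W}\mathbf{m} + \mathbf{e},$$

with fixed sex and contemporary-group effects per trait, an additive genetic
effect $\mathbf{a} \sim N(0, \mathbf{H} \otimes \mathbf{G}_0)$ defined for
*every* pedigree animal (genotyped or not, phenotyped or not), and a maternal
permanent-environment effect $\mathbf{m} \sim N(0, \mathbf{I} \otimes
\mathbf{P}_0)$ attached to the dam of the recorded animal (animals with an
unknown dam simply contribute no PE term).  Records with missing traits are
handled record-wise: each record's residual covariance is
$\mathbf{R}_0$ restricted to its observed traits.

The single-step inverse relationship matrix is

$$\mathbf{H}^{-1} = \mathbf{A}^{-1} +
\begin{bmatrix} \mathbf{0} & \mathbf{0} \\
\mathbf{0} & \mathbf{G}^{*-1} - \mathbf{A}_{22}^{-1} \end{bmatrix},$$

with $\mathbf{A}^{-1}$ built by Henderson's rules with inbreeding
(Meuwissen–Luo coefficients), $\mathbf{A}_{22}$ extracted from the sparse
inverse by Colleau-style solves rather than by forming the dense
$\mathbf{A}$, and $\mathbf{G}$ the (optionally SNP-weighted) VanRaden matrix

$$\mathbf{G} = \frac{\mathbf{M}\mathbf{D}\mathbf{M}'}
{2\sum_i p_i(1-p_i)\,\bar d},$$

where $\mathbf{M}$ is the gene content centered by $2p_i$ and residual
missing calls are imputed to the column mean (centered zero).  $\mathbf{G}$
is tuned to $\mathbf{A}_{22}$ — scalars $(a, b)$ solve
$a + b\,\overline{\mathbf{G}} = \overline{\mathbf{A}_{22}}$ and
$a + b\,\overline{\mathrm{diag}\,\mathbf{G}} =
\overline{\mathrm{diag}\,\mathbf{A}_{22}}$ — which compensates for the
shifted allele frequencies of a selectively genotyped subset, and then
blended, $\mathbf{G}^* = 0.95\,(a + b\mathbf{G}) + 0.05\,\mathbf{A}_{22}$.
The blending fraction is the common default of single-step software; it is a
config knob (`blend`) because the original analyses never state theirs.
$\tau = \omega = 1$: no additional $\mathbf{H}^{-1}$ scaling parameters are
fitted.

The mixed model equations are solved by Jacobi-preconditioned conjugate
gradients (relative residual below `1e-10` by default in the pipeline,
`1e-12` in unit fixtures; non-convergence is an error carrying the residual
history), or by a direct sparse solve for small fixtures.  Fixed effects are
kept full rank by dropping the first level of every factor after the first,
and fixed-effect levels that receive no observation for some trait are
pinned to zero rather than left as zero rows.

# SNP back-solving and window decomposition

GEBV of the genotyped animals are converted to SNP effects by

$$\hat{\mathbf{u}} = \mathbf{D}\mathbf{Z}'
[\mathbf{Z}\mathbf{D}\mathbf{Z}']^{-1}\hat{\mathbf{a}}_g,
\qquad
\hat\sigma^2_{u,i} = \hat u_i^2 \, 2 p_i (1 - p_i).$$

Two numerical facts shape the implementation:

* With observed-frequency centering the columns of $\mathbf{Z}$ sum to zero,
  so $\mathbf{Z}\mathbf{D}\mathbf{Z}'$ is *always* singular (and also
  whenever SNPs outnumber animals).  The inverse is therefore taken through
  the same tuned, blended $\mathbf{G}^*$ used in the evaluation,
  $\mathbf{Z}\mathbf{D}\mathbf{Z}' = 2\sum p_i(1-p_i)\bar d \cdot
  \mathbf{G}$, rebuilt from the current weights at every iteration.  Small
  fixtures that center with known founder frequencies may invert
  $\mathbf{Z}\mathbf{D}\mathbf{Z}'$ directly (`A22 = NULL`).
* Weights are refined with GEBV computed once: iteration 0 uses
  $\mathbf{D} = \mathbf{I}$; iteration $k$ sets $d_i$ to the previous
  iteration's $\hat\sigma^2_{u,i}$, floors exact zeros at $10^{-12}$ of the
  mean positive weight (weights must stay positive), rescales so
  $\sum d_i = m$, and back-solves again.  Three refinements are run and the
  last is reported; in simulation the weights have effectively converged one
  iteration earlier (shares move by less than half a percent between the
  last two), so the exact count is not critical.

Per-SNP variances are summed over sliding windows of $n$ consecutive SNPs
(default 20, the size at which simulated peaks stand out without excessive
noise), never spanning a chromosome; then an exclusive tiling is chosen
greedily: repeatedly keep the highest-variance window that does not overlap
a kept one (ties broken leftmost — a deterministic rule), and let the
remaining sub-$n$ gaps between and flanking kept windows become short
windows.  The result is a disjoint, exhaustive tiling, so window variances
sum exactly to the per-SNP total and window percents sum to 100.  A
dynamic-programming "optimal" tiling was considered and rejected: the greedy
rule is the natural reading of keeping the highest-value exclusive windows,
both satisfy the conservation invariant, and on fixtures they differ only in
low-variance filler windows.  The percent denominator is the sum of all
per-SNP variances of that trait/scenario/iteration — the one choice that
makes the full tiling sum to 100%; using the model's total additive variance
instead would only rescale all percents by a common factor.

# Scenarios and the stability report

Four scenarios are canonical: the complete data and the three-generation
windows G1–G3, G2–G4, G3–G5.  The pedigree is always complete; phenotypes
and the genotyped set are filtered, and QC, allele frequencies,
$\mathbf{G}^*$, the mixed model and the weight iterations are re-run from
scratch per scenario.  Because per-scenario QC can drop SNPs (a QTL driven
to fixation becomes monomorphic), windows are identified positionally and
re-expressed in reference-map indices through their first/last SNP ids
before matching.  Two windows match when their index ranges overlap by at
least one SNP (a 50%-reciprocal rule is available); the persistence report
records, for every window ever in a scenario's top $k$, its matched percent
in every scenario, the number of scenarios where the matched window is
itself top-$k$, and a flag for windows that fall below 0.1% elsewhere.

The segment-count helper uses natural log, $q = 2N_eL/\ln(4N_eL)$: with
$N_e = 50$ and $L = 39$ this gives 435 (base-10 log would give roughly a
thousand, so the logarithm base is not a free choice).

# The simulator: what it emulates and what it does not

`simConfig()` describes a desk-scale analogue of a broiler sire line:

* **Structure.** Unrelated founders (generation G0) are random-mated to
  create the first cohort; thereafter the parents of each cohort are the top
  `selectionProportion` (default 0.2) of the previous cohort per sex, ranked
  on the selection trait's recorded phenotype.  Mating is random among
  selected parents — no assortative or factorial design, since none is
  documented for the motivating data.
* **Genome.** Evenly spaced SNPs on `nChromosomes` chromosomes of
  `chromosomeLengthMorgans` each; gametes carry Poisson($L$) crossovers
  placed uniformly on the genetic map (Haldane model, no interference).
* **Architecture.** QTL are placed *on* markers so window recovery is
  exactly testable against `SimTruth`; each receives a stated fraction of
  the selection trait's additive variance, with fully pleiotropic effects
  along the genetic regression on the selection trait, and the remainder of
  $\mathbf{G}_0$ is an infinitesimal polygenic background transmitted as
  mid-parent value plus Mendelian sampling (inbreeding's second-order effect
  on sampling variance is ignored at these pedigree depths).
* **Traits.** Latent phenotypic variance 1 per trait; default
  heritabilities 0.25/0.30/0.10 with genetic correlations 0.5/0.2/0.1.
  Trait 2 is recorded on 25.6% of animals (the recorded-fraction of the
  motivating carcass trait); trait 3 is a Gaussian liability thresholded at
  `qnorm(0.83)` and recorded as 1/2 — about 17% twos, hence a mean near 1.17
  and SD near 0.38 — and analysed linearly, as such leg scores are in
  practice.  Sex effects (0.5/0.3/0 SD), hatch-batch contemporary groups
  (4 per generation, variance 0.05) and a dam permanent-environment variance
  of 0.05 complete the phenotype.  Units are arbitrary: the simulator
  matches moments and structure, not the scales of any particular line.
* **Genotyping.** Counts per generation are configurable; in the default
  and in the motivating design the first two generations are genotyped by
  phenotype rank (selective) and later ones at random.

Not emulated: sequence-level variation, mutation, genotyping error,
overlapping generations, variance-component estimation (the true simulation
components are reused in the evaluation — REML is out of scope by design).
A green stability test therefore establishes that the *pipeline* orders and
matches windows correctly under a known architecture; it cannot establish
anything about a real line's architecture, and the published percentages
from proprietary data are deliberately not targets.

# Calibration checks the tests run

* Realized response per generation matches the breeder's equation
  $\Delta G = i\,h\,\sigma_a$ within 15% (the shortfall of roughly 10% is
  the Bulmer effect, visible and expected).
* Offspring–mid-parent regression recovers the configured $h^2$ within 20%.
* Without selection, mean breeding value does not drift (3-SE band over 20
  replicates) and a selected line raises the favorable QTL allele frequency.
* A five-QTL architecture (6% of additive variance each, 2000 genotyped,
  1000 SNPs) places at least 4 of 5 QTL inside the top-10 twenty-SNP windows
  in at least 8 of 10 seeds.
* A 20%-variance QTL without selection stays in all four scenario top-10s;
  a 30%-variance QTL driven toward fixation ($p \approx 0.97$ by G5) loses
  window variance in G3–G5 relative to G1–G3 — the $2p(1-p)$ collapse that
  motivates re-estimating SNP effects every generation.
* The weighting iterations concentrate variance: the QTL marker's share
  rises from the unweighted pass to the final iteration on average across
  seeds.  Per-replicate monotonicity is *not* asserted — occasional small
  dips occur when an LD neighbour absorbs part of the signal, which is a
  property of the estimator, not a bug.

# Known limitations

* Dense $\mathbf{A}$ construction is capped at 20k animals; the sparse
  inverse and the Colleau extraction carry the pipeline beyond that, but the
  package targets desk scale (pedigrees of tens of thousands), not the
  hundreds of thousands of a production evaluation.
* The quasi-categorical trait is analysed linearly, faithful to field
  practice but not to a threshold model.
* Exactly one record per animal; repeated records would need a separate
  permanent-environment design.
* The greedy tiling is deterministic but not provably optimal for the sum
  of kept window variances; see above for why this is acceptable.
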