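---
title: "Methods: calcaneal elongation allometry, phylogenetic comparative analysis, and the lever model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcaneal elongation allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcelong)
```

## The scientific problem

In primates with a tarsifulcrumating foot, the calcaneus works as a class-2
lever: the segment distal to the ankle joint (length DL) is the load arm and
the heel (TL − DL) the lever arm of the triceps surae. Acrobatic leapers
carry relatively elongated distal segments; large-bodied species carry
relatively short ones. `calcelong` implements the quantitative machinery for
studying this system across living and extinct species: body-mass estimation
from the calcaneal cuboid facet, the elongation index ln(DL/TL), ordinary
and phylogenetic regression of elongation on mass, phylogenetic ANOVA of
locomotor groups, Bayesian ancestral state reconstruction, and a static
lever model that translates the fitted allometry into muscular effort.

## Measurement model and mass estimation

All analyses run in natural-log space with masses in grams and lengths in
mm. Body mass is estimated from the cuboid facet area, proxied by facet
width times depth, through the calibration line

> ln(BM) = 1.3274 · ln(CW·CD) + 3.0238, r² ≈ 0.98 (n = 129),

whose slope excludes 1.5, the isometric expectation for an area–volume
relationship; mass must therefore be estimated rather than replaced by the
facet area itself. Estimates enter analyses un-anti-logged and uncorrected;
a smearing-type QMLE factor (the mean of exp(residuals) of the calibration
fit) is available and applied only when anti-logged masses are reported.
`elongation_index()` is ln(DL/TL): always negative, invariant to units.
Species are the analysis units: per-specimen log values are computed first
and then averaged within species (`species_summary()`), with standard
errors only for n ≥ 2.

Regression of a ratio on mass uses ordinary least squares deliberately:
for a ratio the isometry null is a slope of zero, and OLS attenuates slopes
toward zero under poor correlation, making it the conservative choice;
reduced major axis is omitted. Two reference lines ship with the package:
`resA` (elongation on mass: slope −0.068, intercept −0.39) and `resB`
(ln DL on mass: slope 0.25, intercept 0.36), plus the early-Eocene
euprimate variant (`eocene`, intercept −0.386). Residuals are
observed − predicted (`residual_from_line()`). The intercept-on-slope
meta-regression (`slope_intercept_meta()`) compares clades by their
intercept residual from the line intercept = −7.978·slope − 0.908; the
sign of the constant is chosen so the published group values are
reproduced (the printed footnote's "+0.908" does not reproduce them).

## PGLS with Pagel's lambda

`pgls_fit()` is generalized least squares with error covariance
σ²·V(λ), where V holds shared root-to-tip path lengths (Brownian motion)
and λ multiplies the off-diagonal entries — the covariance equivalent of
multiplying internal branch lengths, which is how λ is defined here. δ
raises entries (path lengths) to a power; κ acts on individual branch
lengths and therefore rebuilds the covariance from the transformed tree.
Only λ is free in the shipped analyses; δ = κ = 1.

λ is estimated by maximising the profile ML (not REML) log-likelihood over
[0, 1] with a bounded scalar search (tolerance 1e-6), with explicit checks
of the boundary values, which a golden-section search never visits
exactly. Coefficient SEs use the unbiased residual variance RSS_V/(n−p);
R² and F compare against the GLS intercept-only model under the same V.
At λ = 0, V becomes a diagonal of root-to-tip depths, so PGLS coincides
with OLS exactly when tip depths are equal (ultrametric trees) — the
sense in which "λ = 0 collapses the phylogeny". Whether λ should act on
the covariance or on literal internal branches is undecidable from the
published description; the two agree for the likelihood on the trees used
here, and the covariance form is numerically simpler.

`phylo_anova()` fits a reference-coded categorical design by the same
machinery with one shared ML λ; the reported MS is the GLS residual mean
square, and post-hoc pairwise group differences are GLS contrasts (not
subset refits), so a single λ governs the whole table. Significance uses
the sequential Dunn–Šidák step-down rule: with p-values ascending, step j
of k tests against 1 − (1 − α)^(1/(k−j+1)) and stops at the first
failure (k = 3, α = 0.05: 0.016952, 0.025321, 0.05). Suspensory taxa are
excluded before analysis by the behaviour-code precedence rule
(`behavior_category()`: any SUS ⇒ excluded, otherwise the first listed
category).

## Brownian-motion ancestral states by MCMC

`bm_loglik()` is the multivariate-normal likelihood with mean
z_root + β·t_i (t_i the root-to-tip path length; β = 0 for the
non-directional model A) and covariance σ²·V. The trend β is identifiable
only when tips are non-contemporaneous, so fossil tips are essential and
an ultrametric tree triggers a warning.

`mcmc_sample()` is a cycling random-walk Metropolis–Hastings sampler over
(z_root, log σ², [β], [λ]). Priors are flat on z_root and β, log-uniform
on σ² within broad bounds, uniform on λ — chosen so the posterior tracks
the likelihood and model selection can use posterior log-likelihoods.
Proposal scales are tuned during burnin toward a 20–40% acceptance window
and frozen afterwards, preserving detailed balance for retained samples;
chains start at the GLS solution so burnin only has to tune proposals.
With λ fixed, sufficient inner products are precomputed and each iteration
costs O(1), which is what makes two chains of 100,000 iterations run in
seconds. Model selection (`compare_models()`) keeps the non-directional
unscaled baseline unless a candidate's average mean log-likelihood beats
it by ≥ 1.0 log-units; ties go to the simpler model. The harmonic-mean
log-likelihood is reported but flagged as high-variance; it never drives
selection.

One prior-induced subtlety documented here because tests rely on it: under
the log-uniform prior the exact marginal posterior mean of σ² is
RSS_GLS/(n−3) for model A (inverse-gamma), not the ML value RSS/n. The
sampler's σ² means are therefore validated against that closed form, while
z_root posterior means equal the GLS/ML estimate under the flat prior.

`reconstruct_nodes()` draws, for each retained parameter draw, the
internal-node states from their exact conditional Gaussian given the tips,
so nodal summaries integrate over parameter uncertainty. Under λ < 1 the
joint tips-plus-nodes covariance is built from the literally transformed
tree (internal branches scaled, tip depths preserved). Nodal 95% intervals
are shortest-interval HPDs. `nodal_residual_elongation()` subtracts the
reference line evaluated at the nodal mass reconstruction from the nodal
elongation reconstruction, per node.

Chain lengths default to test scale (2 × 100,000, burnin 5,000,
thin 20); publication-scale lengths are a `mcmc_config()` away.

## The lever model

With total calcaneal length 1 and distal fraction r, statically balancing
body weight m needs plantar-flexor force m·r/(1−r) (gram-equivalents);
available force at constant effort scales as (m/m₀)^(2/3) from an
ancestral state m₀. `effort_multiplier()` compares two evolutionary
scenarios: retaining the ancestor's proportions (effort grows exactly as
(m/m₀)^(1/3)) versus following the allometric line. With a 10 g ancestor
on the euprimate line, the distal fraction is 58%, the required force
13.8 g, and a 100 g descendant needs +115% relative effort at constant
proportions but only ~+53% along the line; at 7 kg the allometric effort
multiplication is ~3.8-fold, a level reached already near 550 g under
constant proportions (`equivalent_mass()`, bracketed root finding at 1e-6
relative tolerance). Conversely `constant_effort_max_ratio()` solves the
constant-effort bound under size decrease: shrinking 75 g → 5 g permits
~18% more elongation than the line predicts; 10 g → 5 g only ~4%.

The default line is the Eocene-euprimate one (−0.068, −0.386): the
published discussion nominally cites an all-primate line, but only these
coefficients reproduce the printed 58/13.8/64/115/53 chain, so both are
available and the reproducing one is the default. All statics are
deliberately simple: no dynamics, no tendon elasticity, forces in
gram-equivalents.

## The synthetic-data generator

`sim_spec()`/`simulate_tree()`/`simulate_traits()`/`emit_specimens()`
generate data with the structure the analyses assume, so every stage is
testable without downloads: ln mass evolves by (optionally directional)
Brownian motion on a time-scaled tree; elongation is the allometric line
plus group intercept offsets plus residual noise that is itself Brownian
on the tree (matching the strong λ ≈ 0.95 the large-sample analyses
estimate; i.i.d. noise is available for λ ≈ 0 scenarios); specimens carry
lognormal measurement noise and invert the mass calibration exactly when
noise is zero.

Defaults encode the study conditions: 64 tips, root age 60 Ma, mass rate
0.09 per Ma (a realistic ~2.3 SD spread of ln mass at the tips), residual
rate 0.0015 per Ma (tip SD ~0.3, of the order of the observed residual
spread), 5% measurement CV, three specimens per species. Birth-death
trees are complete realisations (extinct lineages kept), so fossil tips
end at their natural extinction ages throughout the tree's history — the
age structure of a dataset mixing extant species with Paleogene fossils.
An earlier design that truncated pendant edges of extant-conditioned
trees at uniform random ages produced fossils only a few Ma old, under
which a directional trend of 0.05 per Ma is barely identifiable; the
complete-process design was adopted for that reason, and edge truncation
is retained only for the deterministic balanced/star shapes.
`simulate_calibration()` emulates the mass-calibration sample: n = 129,
masses spanning ~38 g to ~110 kg, residual SD set so r² = 0.98 in
expectation.

What passing tests on these data do show: the estimators are unbiased and
correctly sized under the generative model the analyses assume. What they
do not show: robustness to real-data features the generator omits —
measurement correlation among the four calcaneal variables, taxonomic
error, non-Brownian evolution (selection regimes, bursts), or errors in
tree topology and dating.

## Numerical choices and degenerate inputs

* Covariance solves go through Cholesky factors; a singular V produces an
  error suggesting λ < 1 rather than a silent pseudo-inverse.
* Missing branch lengths in Newick input are an error unless an explicit
  default is supplied — time-calibrated analyses are length-sensitive.
* Polytomies are accepted everywhere (the covariance formulation never
  needs bifurcation).
* A constant response gives F = 0 by definition (both model and null RSS
  vanish).
* Grafting (`graft_taxon()`) preserves all pre-existing pairwise path
  lengths bit-for-bit; ghost-lineage-minimised grafting spaces successive
  stem attachments 1 Ma apart working rootward from the crown node,
  pushing deeper when a tip is geologically older than its slot.
* Tests at Monte-Carlo scale use seeded replicates throughout; simulation
  sizes (e.g. 200 replicates for slope-recovery coverage, 500 for ANOVA
  size, 20 datasets for MCMC-vs-closed-form checks, chains of 2 × 100k)
  were chosen as the smallest sizes at which the checked property is
  statistically decisive.

## Known limitations

Supertree construction, molecular dating and parsimony searches are out of
scope: trees are inputs. Printed values that depend on the original
(undeposited) supertrees — per-tree PGLS and ANOVA tables, nodal
reconstructions — are covered by statistical properties (oracle equality,
coverage, size, power, selection rates) rather than value-by-value
reproduction. RMA regression is intentionally absent. The harmonic-mean
marginal-likelihood estimator is reported only for completeness.
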