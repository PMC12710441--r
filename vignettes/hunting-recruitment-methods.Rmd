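---
title: "Methods: hunting pressure, tree recruitment and community trait composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hunting pressure, tree recruitment and community trait composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huntRecruit)
```

## The scientific problem

Overhunting depletes the large frugivorous vertebrates that disperse most
woody-plant seeds in Neotropical forests. If seed dispersal collapses along a
hunting-pressure gradient, animal-dispersed (endozoochorous) tree species —
especially large-seeded ones — should recruit fewer saplings beneath their
conspecific adults, while abiotically dispersed and rodent scatter-hoarded
species gain ground. Whether such species-level shifts scale up to
community-wide changes in functional composition (wood density, leaf mass per
area, seed size) is a separate question, because community-weighted means are
dominated by a handful of hyperabundant species.

`huntRecruit` implements this analysis chain end to end for forest-inventory
data — and, because the headline inferences depend on mixed-model machinery
that is easy to get subtly wrong, it pairs the chain with a synthetic
inventory generator carrying known ground truth, so every inferential step
can be calibrated (type-I error, sign recovery, CI coverage) before it is
trusted on real data.

## Data model and study design

The sampling design mirrors a replicated Amazonian plot network: 15 sites,
each with two 0.25-ha tree plots (all stems ≥ 10 cm DBH) and a nested
0.05-ha sapling subplot (stems 1–5 cm diameter, ≥ 1 m tall) spanning the
full length of the tree plot. Inputs are three delimited tables — stems
(plot, life stage, taxon, diameter), species traits (dispersal mode, seed
length/width/mass, wood density, LMA), and plot covariates (HP, CEC, VDND,
areas) — plus an optional Newick phylogeny.

## The hunting-pressure index

For each plot the HP proxy sums population-to-distance ratios over the
nearest village and the two regional towns:

$$HP = \frac{S_{vil}}{d_{vil}} + \frac{S_{car}}{d_{car}} +
\frac{S_{ita}}{d_{ita}}$$

in persons/km, with Euclidean distances to villages and fluvial distances to
towns (the distance type is the data supplier's responsibility and is
carried as metadata). Only the single nearest village contributes. The index
is strictly increasing in every settlement population and strictly
decreasing in every distance. Distances of zero are rejected: a plot
coinciding with a settlement is outside the model.

## Recruitment metrics

For every species × plot combination with at least one conspecific adult we
record the number of adults (0.25 ha), the number of saplings in the nested
subplot (0.05 ha), a presence flag (≥ 1 sapling), and — where the species
occurs in both stages — the sapling-to-tree abundance log-ratio on
per-hectare densities:

$$S{:}T = \log_{10}(D_{sapling} / D_{tree})$$

Densities (not raw counts) enter the ratio; using counts would shift every
value by $\log_{10}(5)$ given the 5× area ratio between plot and subplot.
Conditioning the presence universe on adult occurrence (not on occurrence at
any stage) is deliberate: the question is recruitment *given* a local seed
source.

## Trait assembly

Stems receive trait values by a species → genus → family fallback. Genus and
family means are unweighted means over species-level values, never
stem-weighted, so locally abundant species do not leak extra weight into the
imputation. Every assignment carries a provenance label
(species/genus/family/missing) and the per-trait coverage ledger is a
first-class output. Seed length is the primary seed-size metric (it has the
broadest taxonomic coverage); a species is flagged as potentially
dispersal-limited when SL > 18 mm, falling back to SW > 12 mm when SL is
unavailable — strictly greater in both cases, so boundary values are not
limited. LMA is stored in g/cm² (leaf-section dry mass over the 4-cm²
section area). Ballistic dispersal is grouped with the abiotic syndromes:
no animal vector is involved.

## Community-weighted means

Per plot and life stage, $CWM = \sum_i BA_i T_i / \sum_i BA_i$ with
$BA = \pi (DBH/2)^2$; the sapling diameter at the point of measurement plays
the role of DBH. Only species- and genus-level trait values enter the CWM;
family-level imputations are considered too coarse and are excluded (they
remain in the coverage ledger). CWMs are invariant to rescaling all basal
areas and bounded by the included trait values — both properties are tested.

## The model suite

All continuous predictors (HP, CEC, VDND, adult count, SL) are centred and
scaled to unit SD before fitting; the data sources give no canonical scale,
and standardised coefficients make the recovery simulations scale-free
(raw-scale fitting is available by flag). Dispersal mode uses treatment
contrasts with the alphabetically first level (abiotic) as reference;
guild-specific HP slopes are always reported as derived contrasts with
delta-method SEs, so the coding is immaterial.

1. **Sapling presence** — binomial GLMM (logit link, Laplace approximation,
   bobyqa optimizer with one fallback refit):
   `presence ~ z(HP) × mode + z(CEC) + z(VDND) + z(n_adults) + (1 | species)`.
2. **S:T ratio** — Gaussian LMM (REML, Satterthwaite p-values) with the same
   fixed/random structure, restricted to records with a defined ratio.
3. **Seed size within endozoochory** — Gaussian LMM
   `S:T ~ z(HP) × z(SL) + z(CEC) + z(VDND) + (1 | family / species)`, with SL
   standardised over the distinct endozoochorous species entering the model.
   With a single family the nesting degenerates to a species intercept, with
   a warning.
4. **CWM models** — OLS per trait:
   `CWM ~ z(HP) × life stage + z(VDND) + z(CEC)`.

The joint HP × mode test is a 2-df Wald chi-square on the interaction terms.
Nakagawa R² is computed from variance components
($\sigma^2_{resid} = \pi^2/3$ on the logit scale for the binomial model).
Marginal effects are design-matrix predictions at covariate means with
random effects at zero and delta-method intervals; HP values outside the
fitted range are flagged as extrapolation rather than refused. Pairwise
guild comparisons use Welch t-tests with the conventional star bands
(`*` at p ≤ 0.05 through `****` at p ≤ 0.0001); no multiplicity adjustment
by default (Holm behind a flag). A non-convergent mixed model is surfaced as
`converged = FALSE`, never silently; singular (boundary) fits count as
converged, with the variance at zero.

## Phylogenetic signal in residuals

Pagel's λ is estimated on per-species means of the *marginal*
(fixed-effects-only, response-scale) residuals of each mixed model:
observation-level residuals are not tip-indexed, and conditional residuals
would subtract the species effects whose phylogenetic structure is exactly
what the diagnostic is looking for. The λ likelihood profiles the mean and
scale analytically, is maximised over λ ∈ [0, 1] by bounded scalar
optimisation (tolerance 10⁻⁶, both endpoints checked; an exhaustive-grid
oracle backs the optimizer in tests), and the λ = 0 test uses the
boundary-corrected ½χ²₁ mixture. λ is capped at 1 to keep the transformed
covariance positive semi-definite on arbitrary trees.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes, at
the study's stated conditions:

* **Guild shares** 12.1 % abiotic / 8.8 % scatter-hoarded / 79.1 %
  endozoochory over the species pool.
* **Trait structure**: per-guild distributions ordered as in field data
  (scatter-hoarded densest-wooded and highest-LMA; endozoochorous species
  smallest-seeded), with Gaussian copulas giving positive SL–WD–LMA
  correlations within endozoochory (ρ = 0.3) and a negative WD–SL
  correlation (−0.45) within the abiotic guild. Endozoochorous SL is
  lognormal with a mean slightly below the 18-mm threshold, so roughly 30 %
  of the guild classifies as dispersal-limited. Only these *qualitative*
  orderings are calibrated: no per-guild distribution parameters are
  published, so defaults were fixed once to plausible field magnitudes
  (WD ≈ 0.58–0.72 g/cm³, LMA ≈ 0.007–0.012 g/cm², SL medians 12–24 mm) and
  not revisited.
* **Landscape**: site HP targets log-spaced over 2.4–13.8 persons/km;
  settlement populations are drawn first and distances back-computed so the
  HP index evaluated on the settlement table reproduces the target exactly —
  the index, not the map, is what the analysis consumes. CEC is right-skewed
  lognormal (plot mean ≈ 0.8 cmol/kg); VDND gamma (mean ≈ 16.3 m).
* **Inventory**: adult abundances follow a lognormal species-abundance
  distribution (σ_log = 1.5) scaled to ≈ 160 trees per 0.25-ha plot, with
  negative-binomial (size 1) plot counts — deliberately independent of HP,
  so any fitted adult-side HP effect is spurious by construction and many
  species occur as adults without saplings (the presence universe needs
  this). Sapling counts are Poisson with log-mean equal to the adult
  per-hectare density (times a constant setting ≈ 200 saplings per subplot)
  plus the ground-truth effects: guild-specific HP slopes, an HP × SL
  interaction confined to endozoochory, CEC and VDND effects, and
  species/family random intercepts. At null effects the expected sapling
  density tracks adult density, giving S:T a meaningful null.

Not emulated: spatial point patterns within plots, temporal dynamics,
vertebrate communities, measurement error in diameters, and a phylogeny
that mirrors the genus/family taxonomy (the diagnostic tree is a pure-birth
tree with randomly assigned tips — residual λ on synthetic runs is
therefore expected to be ≈ 0). Passing calibration on these data shows the
*machinery* is sound; it cannot show that real forests satisfy the model's
assumptions.

A note on scales: the generator's effects act on the log sapling *density*,
while the presence GLMM estimates logit-scale coefficients; signs and
orderings transfer across scales but magnitudes do not. Sign-recovery checks
therefore run through the full generator, whereas CI-coverage checks inject
truth directly on the fitted model's own scale.

## Numerical and design choices

* One master seed; stage seeds derived by fixed offsets, all within 32-bit
  range, so each stage is independently reproducible and identical seeds
  give byte-identical tables.
* Default test/calibration scale: 30 plots × 100–300 species, chosen so a
  single mixed-model replicate takes about a second and full calibration
  suites (200 null replicates; 50 recovery replicates) complete in minutes.
  The full-scale pool (846 species) is a parameter away.
* Ties in nearest-village selection break by settlement name; equal-distance
  villages are otherwise indistinguishable to the index.
* Genus/family means use unweighted species means (abundance must not leak
  into imputation).
* The collinearity screen reports undefined correlations (constant
  covariates) as NA and never flags them.
* Degenerate inputs: a single dispersal mode drops the interaction with a
  warning; a single species makes the random variance unidentifiable, so the
  boundary fit (variance 0, a plain GLM) is returned with a warning; a
  single family collapses the nested intercept to species-only.

## Known limitations

* The presence/absence GLMM conditions on ≥ 1 conspecific adult; true
  colonisation from outside the plot is invisible to it.
* λ is estimated on species-averaged residuals; species observed in few
  plots contribute noisier tips, which the MVN likelihood does not
  down-weight.
* CWM models treat plots as independent; no spatial autocorrelation
  structure is fitted.
* The generator's adult layer is HP-independent by design; real defaunation
  gradients may already have altered the adult cohort, which would attenuate
  sapling-side contrasts.
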