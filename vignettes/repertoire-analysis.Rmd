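---
title: "Methods: customary repertoires, dyadic similarity and Poisson mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: customary repertoires, dyadic similarity and Poisson mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`signalrep` analyses per-act records of non-vocal communicative signals
(gestures, body postures, facial expressions) produced by immature
orangutans towards different partner classes in wild and captive study
populations. This vignette is the package's account of the statistical
machinery: what is modelled, which knobs matter, what the synthetic
generator does and does not emulate, and where the numerical and design
choices were genuinely open.

## From records to customary repertoires

The unit of observation is one communicative act: a signaller, its fixed
attributes (species, research setting, group, sex, age), the partner class
the act was directed at (mother, same-aged peer, or older non-mother), the
signal type from a fixed ethogram, and the observer's estimate of the
social goal (seven categories). Two filters turn acts into analysable
repertoires:

* **Eligibility.** An individual enters the analysis for a partner scope
  only with *more than 30* signal instances in that scope (strict
  inequality; `min_interactions = 30` in `select_eligible()`). Whether a
  count of exactly 30 should be included is not decidable from the
  wording alone; the strict reading is adopted, consistent with an
  observed-effort minimum of 32 in the data the analysis targets.
* **Customary use.** A signal type belongs to an individual's repertoire
  in a scope only if used *at least twice* there (`min_uses = 2` in
  `build_repertoire()`). The same occurrence rule is applied to social
  goals for consistency (the source analysis is silent on this point);
  `goal_min_uses = 1` recovers the count-every-observed-goal variant.

Both thresholds are applied per individual *and per scope*: the mother-
and other-directed repertoires of one individual are computed from
disjoint record subsets, which is what allows the follow-up analyses
splitting "other" into peer- and older-directed sub-scopes. The
inventory table (`inventory_counts()`) reports, per setting-by-species
cell, the number of distinct types in the union of the *filtered*
individual repertoires, matching the customary-repertoire framing; the
union of all observed types is available by rebuilding with
`min_uses = 1`.

## Dyadic similarity and permutation inference

Repertoire composition is compared between individuals with the Dice
coefficient, `D = 2|A ∩ B| / (|A| + |B|)`: 0 for disjoint repertoires, 1
for identical ones, undefined only if both are empty. Matrices are built
per species and scope (`build_dice_matrix()`); cross-species pairs are
never formed, and zoos are pooled within species so each individual
carries a single wild/captive label.

Every individual contributes to `n − 1` pairs, so the pair values are
non-independent row- and column-wise and no i.i.d. test applies. The
package's null distribution comes from **label permutations**: the
per-individual setting labels are randomly reassigned (group sizes
preserved — equivalent to jointly permuting rows and columns of the fixed
matrix) and the contrast statistic is recomputed each time. The source
analysis says only "matrix permutations"; permuting individual labels
rather than, say, raw pair values is the standard scheme that respects
the dyadic dependence, and it is the single most consequential
interpretive choice in this module. `exact_permutation_test()` enumerates
all `choose(n, n_captive)` assignments and acts as the internal referee:
the Monte-Carlo test must agree with it within binomial error on every
enumerable instance, and the test suite enforces that up to 8
individuals.

Two contrasts are implemented: mean within-setting minus mean
between-setting Dice (wild–wild and captive–captive pooled), and mean
captive–captive minus mean wild–wild. The reported p is the upper-tail
position of the observed statistic with the add-one correction,
`(#{null ≥ obs} + 1) / (n_perm + 1)`, so p is never 0 and ties count as
at least as extreme (conservative). Because the contrast can be extreme
in either direction and its null distribution need not be symmetric,
decisions use the asymmetric thresholds `p ≤ 0.025` (upper tail) and
`p ≥ 0.975` (lower tail) rather than a single two-sided cut-off; the
lower-tail position and the raw proportion are always reported alongside.
Defaults are 1000 permutations and an explicit seed (20180101), and a
result is bit-identical given its seed.

## Poisson mixed models of repertoire size and goal diversity

Repertoire size and the number of distinct social goals are per-individual
counts, modelled with a log-link Poisson mixed model fitted by maximum
likelihood through `lme4::glmer` (Laplace approximation by default;
adaptive Gauss–Hermite quadrature via `nAGQ` for verification — one
scalar random intercept makes this cheap). The full model is

```
count ~ age + age² + setting + species + sex + log_z_effort + (1 | group)
```

with age, age², setting and species as test predictors, sex and log-z
observation effort as controls, and a Gaussian random intercept for group
(zoo or field site). Observation effort is log-transformed then
standardised to mean 0, sd 1 (sample sd, computed on the analysis subset)
to approximate linearity on the link scale. Age enters squared
*uncentred* by default — the source is silent on centring — with a
`center_age` flag because centring changes the age/age² collinearity
(but not the model fit). Estimation is plain ML, never a REML-like
variant, so likelihood-ratio tests on fixed effects are valid.

Inference follows the full-vs-null convention: the null model keeps the
controls and the random intercept, so the combined test of the four test
predictors is a 4-df likelihood-ratio test (`lrt()`), and per-term tests
come from single-term deletion refits (`drop1_lrt()`, in which every
term — including linear age — is droppable on its own). Diagnostics:

* **Overdispersion** (`overdispersion()`): sum of squared Pearson
  residuals over `n − p_fixed − 1` (one variance component). The residual
  degrees-of-freedom convention inside such hand-written checks varies;
  this one is documented here and deliberately simple. Values near 1 are
  consistent with the Poisson assumption. Note that with small counts and
  many parameters the statistic sits well below 1 even for well-specified
  data at n ≈ 25.
* **Collinearity** (`vif_main_effects()`): VIFs computed from the design
  of fixed *main* effects only (no age², per the source's own
  procedure), as `1/(1 − R²_j)` from regressing each column on the
  others. A rank-deficient column reports `Inf`.
* **Stability** (`stability_by_group_deletion()`): the model is refitted
  once per group with that group excluded; per-coefficient min/max ranges
  and sign flips are reported. Covariates (including the standardised
  effort) are *not* recomputed on each deletion subset: the same model is
  refitted on reduced data.

Cohen's kappa (`cohen_kappa()`) is provided as the standalone
inter-coder agreement statistic for categorical codings.

## The synthetic generator

`synthetic_config()` defaults define the conditions the analyses assume:

* 27 immatures in 7 groups — 8 wild / 5 captive Bornean (one field site,
  three zoos), 7 wild / 7 captive Sumatran (one field site, two zoos);
* ages uniform on 1–9 years; observation effort uniform on 32–776
  instances per partner scope, with a 10% chance of a sub-threshold draw
  (5–30) so the eligibility filter has something to exclude;
* a 41-type global inventory of which only the first 35 can be directed
  at mothers (so some types are never mother-directed, as in the data the
  generator emulates);
* multiplicative effects of captivity (`exp(0.42)`) and Sumatran species
  (`exp(0.52)`) on the expected *other*-directed latent repertoire size
  only — mother-directed size carries no setting or species effect. The
  magnitudes mirror the reported effect sizes so end-to-end runs produce
  results of the right order;
* a group-level log-normal size effect (`sigma_group = 0.2`), a
  moderate, plausible between-group heterogeneity;
* a **setting core**: per setting (and scope), a deterministic core
  covering `core_fraction = 0.7` of the expected repertoire, with
  `core_overlap = 0.45` of the smaller core shared between the wild and
  captive cores. Individuals carry their cell's core plus private types
  drawn independently, so repertoires are more similar within than
  between settings. At `core_fraction = 1` all individuals of a cell are
  identical (expected within-setting Dice exactly 1);
  `expected_dice()` gives the first-order expectation under the inclusion
  model, and the expected within-minus-between gap is monotone in the
  core fraction;
* Zipf-skewed usage frequencies (exponent 1) within each latent
  repertoire, so rare types occur once and the customary-use filter does
  real work; with effort → ∞ the filtered repertoire converges to the
  latent truth;
* per-individual Dirichlet goal preferences (`goal_concentration = 3`)
  around a fixed population distribution, identical in expectation across
  settings and species — goal diversity varies between individuals but
  carries no planted effect, so the goal-count models are null-true;
* one master seed, with per-individual sub-seeds derived
  deterministically, so an individual's draws are stable under design
  edits elsewhere.

`null_scenario()` switches off every systematic contrast (setting and
species effects, the core structure, group effects), making individuals
exchangeable — the configuration under which permutation decision rates
and LRT p-value distributions are measured. `simulate_size_counts()`
draws counts directly from the fitted model family itself (the
data-generating model equals the fitted model) for estimator calibration;
its `assign` argument switches setting/species between group-level
assignment (each group is one zoo or site, as in the observational
design) and individual-level randomisation.

**What the generator does not emulate:** interaction sequencing,
partner-identity networks, persistence or response-waiting dynamics,
age-dependent repertoire growth, and observation-condition differences
between wild and captive settings. Passing tests therefore show that the
*pipeline* is correct and calibrated under the stated structure, not that
real observational data meet that structure.

## Numerical choices and degenerate inputs

* Dice with two empty repertoires raises; a single empty side returns 0.
* Permutation tests refuse degenerate label vectors (one setting) and
  empty contrast categories; exact enumeration refuses instances beyond
  `max_assignments` (default 1e5).
* `log_z_transform()` requires positive counts and non-zero variance.
* Mixed-model convergence failures are flagged (`converged`), never
  silent; variance estimates on the boundary are reported as `sigma2 = 0`
  with `singular = TRUE`. `lrt()` clamps tiny negative chi-squares to 0
  and returns p = 1 for identical specifications.
* Tie handling in permutation p values counts equals as at-least-as-
  extreme, the conservative convention.
* Leave-one-group-out refit failures are recorded per deletion, not
  fatal.

## Calibration findings and known limitations

The tests and `analysis/05_calibration.R` measure (sizes chosen to keep
the default suite in the tens of minutes on one CPU: 1000 null datasets
of 12 individuals for the permutation rate; 100–200 replicates at
n = 100–200 for the model studies):

* the two-tailed permutation decision rate under the exchangeable null
  sits at its nominal ~5%;
* full-vs-null LRT p values are uniform and Wald intervals cover at
  ~95% with negligible bias **when the test predictors vary within
  groups** (individual-level assignment);
* with *group-level* setting and species — the observational reality,
  where a zoo has one species in one setting — and only 7–10 groups, the
  naive LRT is anticonservative (measured rejection well above nominal)
  and Wald coverage for those contrasts drops to ~85%. This is the
  familiar few-random-effect-levels problem, and it applies to any
  analysis of this design, not to this implementation specifically. It
  is the main caveat to carry when reading setting/species inferences
  from designs with a handful of groups.

Other limitations: the Poisson assumption suits small counts but the
dispersion statistic is then a blunt instrument; the permutation scheme
conditions on the observed group sizes; and repertoire-size responses
inherit the filters' truncation, so end-to-end effect estimates on
filtered sizes are attenuated relative to the latent effects that
generated them.
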