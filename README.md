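# signalrep

Analysis of non-vocal signal repertoires of immature orangutans across
wild and captive study populations — for behavioural ecologists and
comparative communication researchers working with per-act interaction
records (one row per communicative act: signaller, partner class, signal
type, presumed social goal).

The package implements the full analysis chain:

1. **Customary repertoires.** An individual enters a partner scope
   (mother-, other-, peer- or older-directed) with more than 30 signal
   instances there, and its repertoire is the set of signal types used at
   least twice in that scope. Inventory tables count distinct types by
   setting × species.
2. **Dyadic similarity.** Repertoire composition is compared between
   individuals with the Dice coefficient

   *D* = 2|A ∩ B| / (|A| + |B|),

   assembled into per-species similarity matrices. Because each
   individual contributes to many pairs, inference uses **matrix
   permutation tests**: the per-individual wild/captive labels are
   permuted (1000 permutations), the within-vs-between-setting contrast
   recomputed each time, and decisions taken at the asymmetric thresholds
   *P* ≤ 0.025 / *P* ≥ 0.975. An exact enumeration test over all label
   assignments serves as the oracle for small groups.
3. **Poisson mixed models.** Repertoire size and social-goal diversity
   are modelled as `count ~ age + age² + setting + species + sex +
   log-z effort + (1 | group)` with a log link, fitted by maximum
   likelihood (`lme4`). The combined effect of the test predictors is a
   4-df full-vs-null likelihood-ratio test; per-term tests come from
   single-term deletion. VIF, overdispersion and leave-one-group-out
   stability diagnostics are built in, plus Cohen's kappa for coder
   agreement.
4. **Synthetic generator.** `synthetic_config()` / `generate_dataset()`
   emulate the study conditions (27 immatures in 7 groups, 41 signal
   types, effort 32–776 per scope, captive and Sumatran effects on
   other-directed repertoire size, within-setting repertoire cores) with
   known ground truth; `null_scenario()` switches every contrast off for
   calibration studies.

See `vignettes/repertoire-analysis.Rmd` for the methods account and
`analysis/01_simulate.R` … `analysis/05_calibration.R` for the end-to-end
workflow (each writes its tables under `results/`).

## Worked example

```r
library(signalrep)

ds   <- generate_dataset(synthetic_config(), seed = 42)   # 27 immatures
reps <- build_repertoires(ds$records, "other")            # >30 acts, >=2 uses
tbl  <- repertoire_table(reps)

# dyadic similarity, Bornean individuals, other-directed
bor <- Filter(function(r) r$species == "bornean", reps)
dm  <- build_dice_matrix(bor)
matrix_permutation_test(dm, "within_vs_between", seed = 20180101)
#> <perm_result> within_vs_between (monte_carlo, 1000 permutations)
#>   observed = 0.3248; upper-tail P = 0.002997 (lower-tail 1); significant_high

# repertoire-size mixed model
full <- fit_poisson_glmm(tbl, "size", "full")
null <- fit_poisson_glmm(tbl, "size", "null")
lrt(full, null)
#> LRT: chi-square(4) = 17.426, P = 0.001597
full
#> <glmm_fit> Poisson mixed model of size (full model, nAGQ=1)
#>   n = 24 individuals in 7 groups; logLik = -55.537; sigma2 = 0.0000 (singular)
#>                 estimate    se
#> (Intercept)        2.304 0.390
#> age_years          0.064 0.144
#> I(age_years^2)    -0.004 0.014
#> settingwild       -0.327 0.137
#> speciessumatran    0.554 0.130
#> sexmale            0.076 0.132
#> log_z_effort      -0.002 0.091
```

Reading the output: same-setting pairs share substantially more of their
other-directed repertoires than cross-setting pairs (mean Dice contrast
+0.32, upper-tail *P* ≈ 0.003 over 1000 label permutations), and
repertoire size varies with the test predictors (χ²₄ = 17.4): smaller in
the wild (−0.33 on the log scale, i.e. ×e^−0.33 ≈ 0.72) and larger in
Sumatrans (+0.55) — the generator planted −0.42 and +0.52. The group
variance estimate sits on the boundary (`sigma2 = 0`), flagged as a
singular fit.

`run_pipeline(out_dir = "...", seed = ...)` runs everything (validation,
profiles, repertoires per scope, inventories, Dice matrices, both
permutation contrasts per species × scope, size and goal models with
diagnostics) and writes plain CSV/JSON artifacts, a run manifest and a
human-readable `report.txt`.

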