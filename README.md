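# markqg — quantitative genetics of white leg markings in horses

White leg markings are scored at studbook registration on each limb of a
horse, either as affected/unaffected or on a four-class ordinal scale
(0 unaffected; 1 white below the fetlock; 2 above the fetlock; 3 up to the
cannon bone). In breeds where extensive markings are penalized, breeders
need to know the trait's heritability, how symmetric its genetic control is
across limbs, and which systematic factors (sex, coat color, inbreeding,
the dam) shift its expression. `markqg` is an R package plus a scripted
analysis workflow for exactly that question in pedigreed populations.

## What the package implements

* **Pedigree algebra** — validated pedigree ingestion with topological
  ordering, Meuwissen–Luo inbreeding coefficients F, the numerator
  relationship matrix A (tabular method, `diag(A) = 1 + F`), and the sparse
  inverse A⁻¹ assembled directly by Henderson's rules with the
  Mendelian-sampling variance adjustment `d_i = 0.5 − 0.25 (F_s + F_d)`.
* **Threshold animal models** — each limb score is an interval-censored
  Gaussian liability `l = x'b + u + m_dam + e` with pedigree-structured
  direct (`u`) and maternal (`m`) genetic effects,
  `(u, m) ~ N(0, Σ ⊗ A)`. Gibbs sampling with liability augmentation
  (C++ core), dichotomous (t = 0, σ²ₑ = 1) and four-class ordinal
  (t₁ = 0, t₂ = 1) identifications, univariate and multi-trait. Derived
  per-draw heritabilities `h² = σ²ᵤ / (σ²ᵤ + σ²ₘ + σ²ₑ)`, genetic
  correlations, and the classical liability-to-observed-scale
  transformation `h²·z²/(p(1−p))`.
* **Risk screening** — Bayesian proportional-odds model
  `logit P(Y ≤ j) = α_j − (x'β + d_dam)` with a dam random intercept,
  fitted by adaptive Metropolis-within-Gibbs; effects retained when the
  95% credible interval excludes zero.
* **Descriptive tables** — per-limb score distributions, prevalence of the
  seven limb combinations (bilateral pairs, sides, diagonals, all four
  legs), stratified by sex or coat.
* **Posterior utilities** — empirical shortest-window HPD intervals,
  summaries, Geweke diagnostic, CSV round-trip.
* **Synthetic data** — a seeded generator producing closed-population
  pedigrees and correlated four-limb ordinal phenotypes under a published
  "pre-like" truth preset (variances, genetic correlations, sex/coat
  frequencies, prevalence-calibrated thresholds), used by the tests,
  recovery studies, and the analysis scripts.

## Worked example

```r
library(markqg)

cfg <- sim_config(n_founders = 150, n_generations = 8, n_matings = 150,
                  offspring_per_mating = 2, phenotype_generations = 6,
                  seed = 21)
sim <- simulate_marking_data(cfg)
score_distribution(sim$phenotypes)[, c("limb", "pct_affected")]
#>   limb pct_affected
#> 1   lf     4.268293
#> 2   rf     3.824834
#> 3   lh    15.410200
#> 4   rh    11.917960

spec  <- threshold_model_spec("lh", scale = "dichotomous")
chain <- run_gibbs(sim$phenotypes, sim$pedigree, spec,
                   chain_config(iter = 15000, burnin = 5000, thin = 5,
                                seed = 9))
posterior_summary(list(h2_lh = heritability_samples(chain, "lh")))
#>   parameter      mean    median         sd   hpd_low  hpd_high
#> 1     h2_lh 0.3319821 0.3452972 0.09847245 0.1166139 0.4868215
```

The simulated prevalences sit near the generator's calibration targets
(5.3/4.6/17.9/14.5% affected in the reference tabulation) up to the drift
and sampling noise of a 1,800-record population, and the liability-scale
true left-hindleg heritability of 0.48 is covered by the wide 95% HPD a
binary trait of this size warrants (the parameter-recovery study in the
test suite runs the same experiment at a larger, calibrated scale). The numbered
scripts under `analysis/` run the full chain — simulate, describe, risk
screen, threshold models, report — writing their tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_describe.R
Rscript analysis/03_risk_screen.R 1
Rscript analysis/04_threshold_models.R 1
Rscript analysis/05_report.R
```

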