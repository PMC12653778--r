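---
title: "Threshold animal models for white leg markings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold animal models for white leg markings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

White markings on horses' legs are scored at registration on each limb,
either as affected/unaffected or on a four-class ordinal scale (0 =
unaffected, 1 = white below the fetlock, 2 = above the fetlock, 3 = up to
the cannon bone). Because extensive markings are penalized in several
breeding programs, breeders want to know how heritable the trait is, how
symmetric its genetic control is across limbs, and which systematic factors
(sex, coat color, inbreeding, the dam) shift its expression. `markqg`
implements that analysis chain end to end for pedigreed populations:
descriptive prevalence and symmetry tables, a Bayesian cumulative-logit
risk screen, and Bayesian threshold animal models fitted by Gibbs sampling
with liability augmentation, together with a synthetic-data generator so
the whole pipeline can be exercised, and its estimators validated, at desk
scale.

# The liability model

Each limb score is modelled through a latent Gaussian liability
$l = \mathbf{x}'\mathbf{b} + u + m_{\mathrm{dam}} + e$, where
$\mathbf{x}'\mathbf{b}$ collects sex, coat-color and inbreeding effects,
$u$ is the animal's direct additive genetic effect, $m_{\mathrm{dam}}$ the
maternal genetic effect of its dam, and $e$ a residual. The observed class
is the interval of the liability between ordered thresholds. Jointly over
the pedigree,
$(\mathbf{u}, \mathbf{m}) \sim N(0, \Sigma \otimes A)$ with $A$ the
numerator relationship matrix, and the mixed-model equations embed the
sparse $A^{-1}$ built directly from the pedigree by Henderson's rules with
the inbreeding (Mendelian-sampling variance) adjustment
$d_i = 0.5 - 0.25(F_s + F_d)$, $0.75 - 0.25F_k$ with one known parent, and
$1$ with none. Inbreeding coefficients use the Meuwissen–Luo
ancestor-tracing algorithm, which is exact and never forms $A$.

Heritability is reported on the liability scale as
$h^2 = \sigma_u^2 / (\sigma_u^2 + \sigma_m^2 + \sigma_e^2)$ — the maternal
variance belongs in the denominator; this is the definition that reproduces
the published dichotomous-model heritabilities from their printed variance
components. Per-draw ratios are summarized, never ratios of posterior
means. The observed-scale (0/1) heritability uses the classical
transformation $h^2_{obs} = h^2 z^2 / (p(1-p))$ with $z$ the standard
normal density at the threshold implied by prevalence $p$
(`dempster_lerner()`).

## Identifiability constraints

A threshold model identifies liabilities only up to an affine transform, so
constraints must pin location and scale. We use the standard choices:

* dichotomous: threshold fixed at 0 and residual variance fixed at 1
  (a free intercept carries location);
* four-class ordinal: first two thresholds fixed at 0 and 1, third
  threshold sampled, residual variance free.

`truth_on_model_scale()` maps generator truth onto either identification so
that recovery experiments compare like with like; $h^2$ and genetic
correlations are invariant under the mapping.

# The Gibbs sampler

`run_gibbs()` cycles, in fixed order: (1) liabilities from truncated-normal
full conditionals (inverse-CDF centrally, Robert-style exponential
rejection in far tails, guarded so a numerically empty interval still
returns a finite in-interval value); (2) fixed effects (flat priors) and
genetic effects from their normal full conditionals — the direct effects of
one animal are updated as a small multi-trait block, maternal effects
single-site with a diagonal maternal covariance; (3) variance components
from scaled-inverse-chi-square (univariate, default $\nu = -2$, $S = 0$,
i.e. flat on the variance) or inverse-Wishart (multi-trait, minimal proper
degrees of freedom $T+1$ and scale $10^{-3} I$) full conditionals via
$A^{-1}$ quadratic forms; (4) the free ordinal threshold from its uniform
full conditional (Albert–Chib style; its mixing is slow, which we accept
and flag via the Geweke diagnostic rather than hide). All randomness flows
through R's RNG, so a run is reproducible given the seed; sweep order is
fixed, which makes posterior summaries order-sensitive only through the
RNG stream.

The inner loops are written in C++ (Rcpp/RcppArmadillo) because a
single-site sampler over tens of thousands of equations per iteration is
not feasible in interpreted R; the per-animal block solves use hand-rolled
small-matrix Cholesky factorizations to avoid allocation churn.

An optional direct–maternal covariance (univariate models) updates the
joint $(u, m)$ pair per animal and its $2\times 2$ covariance by
inverse-Wishart; it is off by default since the motivating analysis reports
no such estimate.

# The risk screen

The per-limb risk model is a proportional-odds regression,
$\mathrm{logit}\, P(Y \le j) = \alpha_j - (\mathbf{x}'\beta + d)$, with a
dam random intercept $d \sim N(0, \tau^2)$. We parameterize on the latent
severity scale (note the minus sign), so a positive coefficient means more
extensive markings — this matches how the factors are described
substantively (e.g. inbreeding positively associated with markings).
Sampling is Metropolis-within-Gibbs with random-walk proposals, cutpoint
ordering enforced by rejection, per-parameter step sizes adapted towards a
0.44 acceptance rate during burn-in only (so the post-burn-in chain is a
valid fixed-kernel MCMC). Priors are weakly informative: $N(0, 5^2)$ on
coefficients and cutpoints, half-normal(5) on $\tau$. Screening retains an
effect when its 95% equal-tailed credible interval excludes zero; an
interval touching zero does not count as exclusion. The dam SD is reported
as an SD (the scale of such published intervals is ambiguous; we document
our choice rather than guess another).

# The synthetic-data generator

`sim_config()` defaults are the "pre-like" preset: direct, maternal and
residual variances from the published four-class analysis of 38,825 PRE
horses; between-limb genetic correlations from the published table,
projected to the nearest PSD matrix by eigenvalue clipping (the printed,
rounded table need not be PSD; the projection is ours); maternal covariance
diagonal; direct–maternal covariance zero (no published estimate); sex
ratio 0.339 male and coat frequencies 0.404/0.387/0.085/0.124
(grey/bay/chestnut/black) from the same study's counts. Thresholds are
calibrated by solving the mixture-normal CDF equation per limb
(`calibrate_thresholds()`) so that the marginal probabilities of score
$\ge 1$, $\ge 2$ and $= 3$ match the published per-limb distribution
(5.3/4.6/17.9/14.5% affected and the class shares among affected).

Fixed-effect sizes are not published, so the preset chooses liability-scale
values a field scientist would call realistic and keeps them fixed: males
+1.0 (fore) / +0.6 (hind), chestnut +1.2, black −1.2, bay −0.4 against a
grey reference, and an inbreeding slope of 4 (fore) / 0.5 (hind) per unit
F — directions and relative limb patterns follow the published
descriptions (male and chestnut excess, inbreeding acting on forelegs).
Against a total liability SD of 3–4 these produce stratified prevalences of
the published order.

Demography is a discrete-generation closed population: default 30 founders,
10 generations, 20 matings per generation (sires drawn with replacement,
dams without), litter $1 + \mathrm{Poisson}(1)$. These defaults make mean
pedigree inbreeding land near the published mean of 0.074 (desk runs give
$\bar F \approx 0.08$, range up to $\approx 0.35$). Breeding values descend
the pedigree by Mendelian sampling, $u_i = \tfrac12(u_s + u_d) + \phi_i$
with $\mathrm{Var}(\phi_i) = d_i \Sigma$, so drift, assortativity and
inbreeding depression of Mendelian variance are all emulated. Coat is
assigned independently of genetics: the generator emulates covariate
structure, not pigmentation genetics (no KIT/MC1R-style loci), no
non-genetic maternal environment distinct from the maternal genetic effect,
and no overlapping generations. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated model, not
robustness to real-data features such as scorer effects, non-normal
liabilities, or genotype-driven coat–marking dependence.

# Problem sizes, and what is and is not recoverable at desk scale

All shipped analyses and tests run at reduced scale; the sizes are the
package's own choices balancing statistical identifiability against
turnaround:

* descriptive and calibration checks: populations of 5,000–15,000 founders
  (closed-form properties need no pedigree depth);
* risk-screen calibration: 100 null replicates of n = 500, 8,000
  iterations each;
* parameter recovery: replicate populations of roughly 5,400 pedigree
  animals with 3,200 phenotyped, dichotomous chains of 20,000 iterations
  (burn-in 5,000, every second draw stored — empirical shortest-window HPD
  endpoints are narrow-biased when computed from sparse draws, so coverage
  checks need dense storage). At substantially smaller sizes the flat
  variance priors dominate the weakly informative binary data and the
  maternal variance (truth ≈ 0.05 on the residual scale) is overestimated,
  so its interval coverage degrades; at the stated size coverage is
  nominal for $\sigma_u^2$, $\sigma_m^2$ and $h^2$.

Two quantities are documented as not desk-recoverable, with the behavior
left visible rather than patched:

* **Raw ordinal-scale variance components.** With thresholds fixed at 0
  and 1, the global liability scale is identified only by the occupancy of
  the narrow class-1 band; at desk scale the posterior of that scale is
  extremely diffuse and all components drift up and down together.
  Heritabilities and genetic correlations, being scale-free, are estimated
  stably. Recovery experiments therefore use the dichotomous
  identification, whose fixed residual variance pins the scale.
* **Interval coverage for near-unity genetic correlations.** The
  augmented-data sampler's genetic-covariance draws are attracted to the
  boundary $r = 1$ when the truth is close to it (0.995 for the hind
  pair): point recovery is accurate to a few thousandths, but the HPD
  interval is degenerately narrow (width $\sim 10^{-3}$) and need not
  contain the truth. A Gaussian fit on the same pedigree recovers both the
  point value and calibrated intervals, isolating the effect in the
  binary-data augmentation. We therefore check the genetic correlation by
  point accuracy, not interval coverage.

# Numerical choices

* HPD intervals are empirical shortest windows over sorted draws
  (`ceiling(mass * n)` points; ties broken to the lowest window) — the
  standard post-Gibbs practice and deterministic.
* Percentages use half-up rounding; tables print one decimal, text-style
  values two.
* Degenerate truncation intervals (liability mass below double precision)
  return the clipped interval midpoint; far tails use one-sided
  exponential rejection. A stored draw outside its category interval
  would be reported by the chain's `liability_in_interval` flag.
* Variance draws above $10^{12}$ abort the chain with a diagnostic.
* The dense relationship matrix refuses pedigrees beyond a configurable
  size (default 5,000); the model path never forms $A$.
* Unknown parents are unique unrelated founders ("0" and empty string both
  parse as unknown); a phenotyped animal with an unknown dam gets a
  phantom-founder dam in maternal models.
* Kahn topological ordering with input-order tie-breaking makes pedigree
  ingestion deterministic; cycles are reported with an offending animal.

# Known limitations

* Single-chain inference (matching common practice with these samplers);
  the Geweke z-score is reported, not enforced.
* The multivariate maternal structure is diagonal by default; a full
  maternal covariance is out of scope at desk scale because the
  reduced-size system becomes ill-conditioned.
* The free ordinal threshold mixes slowly (uniform full conditional);
  treat ordinal $t_3$ summaries from short chains with caution.
* Screening calibration is exact only asymptotically; with 100 replicates
  the acceptance band (5% ± 4%) reflects binomial noise, not a claim of
  exact nominal coverage.
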