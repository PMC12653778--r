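#' Parameter-recovery study for the threshold animal model
#'
#' Simulates replicate populations under the pre-like truth preset at a
#' stated scale, fits the dichotomous threshold animal model to one limb
#' per replicate, and records whether the truth (mapped to the model's
#' identification scale) falls inside the 95% HPD interval of each
#' parameter. The dichotomous scale is used because its residual-variance
#' constraint pins the liability scale, making the raw variance components
#' well identified at this problem size.
#'
#' @param n_rep number of replicate populations.
#' @param trait limb fitted in each replicate.
#' @param n_founders,n_generations,n_matings,phenotype_generations
#'   demography of each replicate population (defaults give roughly a
#'   5,400-animal pedigree with 3,200 phenotyped animals).
#' @param chain a `chain_config`; its seed is re-derived per replicate from
#'   `base_seed`. The default stores every second post-burn-in draw:
#'   empirical shortest-window HPD endpoints are narrow-biased when
#'   estimated from few draws, so coverage checks need dense storage.
#' @param base_seed integer; replicate r uses `base_seed + r` for the
#'   simulation and `base_seed + 500 + r` for the chain.
#' @return Data frame with one row per replicate: truth and HPD bounds for
#'   `sigma_u2`, `sigma_m2`, `h2`, posterior means, and coverage flags.
#' @export
recovery_study <- function(n_rep = 10L, trait = "lh",
                           n_founders = 300L, n_generations = 8L,
                           n_matings = 320L, phenotype_generations = 5L,
                           chain = chain_config(iter = 20000L, burnin = 5000L,
                                                thin = 2L),
                           base_seed = 2000L) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                      n_matings = n_matings, offspring_per_mating = 2,
                      phenotype_generations = phenotype_generations,
                      seed = base_seed + r)
    sim <- simulate_marking_data(cfg)
    spec <- threshold_model_spec(trait, scale = "dichotomous")
    cc <- chain_config(chain$iter, chain$burnin, chain$thin,
                       seed = base_seed + 500L + r)
    ch <- run_gibbs(sim$phenotypes, sim$pedigree, spec, cc)
    tr <- truth_on_model_scale(cfg, trait, "dichotomous")
    h_su <- hpd_interval(ch$sigma_u[, 1])
    h_sm <- hpd_interval(ch$sigma_m[, 1])
    h2d <- heritability_samples(ch, trait)
    h_h2 <- hpd_interval(h2d)
    rows[[r]] <- data.frame(
      rep = r,
      su2_truth = tr$sigma_u[1, 1], su2_mean = mean(ch$sigma_u[, 1]),
      su2_low = h_su[[1]], su2_high = h_su[[2]],
      su2_covered = tr$sigma_u[1, 1] >= h_su[[1]] & tr$sigma_u[1, 1] <= h_su[[2]],
      sm2_truth = tr$sigma_m[1, 1], sm2_mean = mean(ch$sigma_m[, 1]),
      sm2_low = h_sm[[1]], sm2_high = h_sm[[2]],
      sm2_covered = tr$sigma_m[1, 1] >= h_sm[[1]] & tr$sigma_m[1, 1] <= h_sm[[2]],
      h2_truth = tr$h2, h2_mean = mean(h2d),
      h2_low = h_h2[[1]], h2_high = h_h2[[2]],
      h2_covered = tr$h2 >= h_h2[[1]] & tr$h2 <= h_h2[[2]])
  }
  do.call(rbind, rows)
}

#' Genetic-correlation recovery for a limb pair
#'
#' Simulates one pre-like population and fits the bivariate dichotomous
#' threshold model to a limb pair, returning the genetic-correlation draws
#' and the truth. Point recovery of near-unity genetic correlations is
#' accurate at desk scale; their HPD intervals are degenerately narrow
#' because the augmented-data sampler is absorbed near the boundary r = 1,
#' so interval coverage is not a meaningful check for this parameter (see
#' the methods vignette).
#'
#' @param pair character vector of two limbs.
#' @inheritParams recovery_study
#' @param seed simulation seed; the chain uses `seed + 500`.
#' @return List with `r_truth`, `r_mean`, `draws`, and the fitted chain's
#'   HPD interval.
#' @export
correlation_recovery <- function(pair = c("lh", "rh"),
                                 n_founders = 300L, n_generations = 8L,
                                 n_matings = 320L, phenotype_generations = 5L,
                                 chain = chain_config(iter = 10000L,
                                                      burnin = 3000L,
                                                      thin = 5L),
                                 seed = 2100L) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_matings = n_matings, offspring_per_mating = 2,
                    phenotype_generations = phenotype_generations, seed = seed)
  sim <- simulate_marking_data(cfg)
  spec <- threshold_model_spec(pair, scale = "dichotomous")
  cc <- chain_config(chain$iter, chain$burnin, chain$thin, seed = seed + 500L)
  ch <- run_gibbs(sim$phenotypes, sim$pedigree, spec, cc)
  r <- genetic_correlation_samples(ch, pair)
  tr <- truth_on_model_scale(cfg, pair, "dichotomous")
  list(r_truth = tr$r_g[1, 2], r_mean = mean(r), draws = as.numeric(r),
       hpd = hpd_interval(r))
}

#' Credible-interval screening calibration under the null
#'
#' Repeatedly simulates data with no fixed effects at all, fits the
#' cumulative-logit risk model, and records how often each effect's 95%
#' credible interval excludes zero. Under the null this should happen for
#' about 5% of replicates.
#'
#' @param n_rep replicates.
#' @param n records per replicate.
#' @param effects fixed effects fitted (and simulated as null).
#' @param iter,burnin,thin chain settings per fit.
#' @param base_seed replicate r uses `base_seed + r`.
#' @return Matrix of logical exclusion flags, replicates x effects.
#' @export
screening_calibration <- function(n_rep = 100L, n = 500L,
                                  effects = c("sex", "F"),
                                  iter = 8000L, burnin = 2000L, thin = 3L,
                                  base_seed = 3000L) {
  out <- NULL
  for (r in seq_len(n_rep)) {
    set.seed(base_seed + r)
    d <- data.frame(animal = as.character(seq_len(n)),
                    sex = sample(c("male", "female"), n, TRUE),
                    coat = sample(c("grey", "bay", "chestnut", "black"), n, TRUE),
                    F = runif(n, 0, 0.3), dam = "",
                    lf = rbinom(n, 1, 0.2), rf = 0L, lh = 0L, rh = 0L,
                    stringsAsFactors = FALSE)
    class(d) <- c("marking_dataset", "data.frame")
    fit <- fit_cumulative_logit(d, "lf", fixed = effects, dam_effect = FALSE,
                                iter = iter, burnin = burnin, thin = thin,
                                seed = base_seed + r)
    scr <- screen_effects(fit)
    flags <- scr$retained[scr$effect != "dam_sd"]
    names(flags) <- scr$effect[scr$effect != "dam_sd"]
    out <- rbind(out, flags)
  }
  rownames(out) <- NULL
  out
}
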