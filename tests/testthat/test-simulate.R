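test_that("pedigree simulation is reproducible and structurally sound", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 4)
  set.seed(1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))

  cfg2 <- sim_config(seed = 9)
  set.seed(cfg2$seed); p1 <- simulate_pedigree(cfg2)
  set.seed(cfg2$seed); p2 <- simulate_pedigree(cfg2)
  expect_identical(p1, p2)
})

test_that("mean inbreeding rises across generations under finite founders", {
  # per-generation mean F averaged over replicates: a single small
  # population fluctuates, the expectation is strictly increasing
  M <- sapply(1:8, function(seed) {
    cfg <- sim_config(n_founders = 60, n_generations = 5, n_matings = 80,
                      seed = seed)
    set.seed(cfg$seed)
    ped <- simulate_pedigree(cfg)
    tapply(unname(inbreeding_coefficients(ped)), ped$birth_year, mean)
  })
  mean_by_gen <- rowMeans(M)
  expect_equal(unname(mean_by_gen[["0"]]), 0)
  expect_equal(unname(mean_by_gen[["1"]]), 0)   # founders unrelated
  late <- mean_by_gen[as.integer(names(mean_by_gen)) >= 2]
  expect_true(all(diff(late) > 0))
})

test_that("breeding values follow the configured covariance structure", {
  cfg <- sim_config(seed = 1)
  cfg$sigma_u <- matrix(0, 4, 4)
  cfg$sigma_m <- matrix(0, 4, 4)
  set.seed(1)
  ped <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 2, seed = 1))
  bv <- simulate_breeding_values(ped, cfg)
  expect_true(all(bv$u == 0) && all(bv$m == 0))

  # founder sample variance close to the configured variance (3 SE of var)
  cfg2 <- sim_config(n_founders = 2000, n_generations = 0, seed = 5)
  set.seed(5)
  ped2 <- simulate_pedigree(cfg2)
  bv2 <- simulate_breeding_values(ped2, cfg2)
  v <- var(bv2$u[, "lh"])
  truth <- cfg2$sigma_u["lh", "lh"]
  se <- truth * sqrt(2 / (2000 - 1))
  expect_lt(abs(v - truth), 3 * se)
  # hind-pair genetic correlation close to its configured value
  r <- cor(bv2$u[, "lh"], bv2$u[, "rh"])
  r_truth <- cov2cor(cfg2$sigma_u)["lh", "rh"]
  expect_lt(abs(r - r_truth), 3 * (1 - r_truth^2) / sqrt(2000))
})

test_that("offspring breeding values regress on mid-parent with slope one", {
  cfg <- sim_config(n_founders = 250, n_generations = 3, n_matings = 250,
                    offspring_per_mating = 2, seed = 8)
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, cfg)
  kid <- which(!is.na(ped$sire))
  mid <- 0.5 * (bv$u[match(ped$sire[kid], ped$animal), "lf"] +
                bv$u[match(ped$dam[kid], ped$animal), "lf"])
  fit <- lm(bv$u[kid, "lf"] ~ mid)
  expect_lt(abs(unname(coef(fit)[2]) - 1), 3 * summary(fit)$coefficients[2, 2])
})

test_that("phenotype generation respects thresholds and fixed effects", {
  # all variances zero, b = 0, thresholds (0,1,2): every liability 0, score 0
  cfg <- sim_config(seed = 3)
  cfg$sigma_u[] <- 0; cfg$sigma_m[] <- 0; cfg$sigma_e[] <- 0
  cfg$b_sex[] <- 0; cfg$b_coat[] <- 0; cfg$b_f[] <- 0
  cfg$thresholds <- matrix(rep(c(0, 1, 2), each = 4), 4, 3)
  set.seed(3)
  ped <- simulate_pedigree(sim_config(n_founders = 10, n_generations = 2,
                                      n_matings = 8, seed = 3))
  bv <- simulate_breeding_values(ped, cfg)
  ph <- simulate_phenotypes(ped, bv, cfg)
  expect_true(all(as.matrix(ph[, c("lf", "rf", "lh", "rh")]) == 0L))
  expect_true(all(attr(ph, "truth")$liability == 0))

  # very low thresholds: saturation at score 3
  cfg$thresholds <- matrix(c(-9, -8, -7), 4, 3, byrow = TRUE)
  ph2 <- simulate_phenotypes(ped, bv, cfg)
  expect_true(all(as.matrix(ph2[, c("lf", "rf", "lh", "rh")]) == 3L))

  # positive male liability shift raises male prevalence at large n
  cfg3 <- sim_config(n_founders = 4000, n_generations = 0, sex_ratio = 0.5,
                     seed = 12)
  cfg3$phenotype_generations <- 1L   # founders are the records here
  set.seed(12)
  ped3 <- simulate_pedigree(cfg3)
  ped3$birth_year <- 1L  # mark founders as the phenotyped generation
  bv3 <- simulate_breeding_values(ped3, cfg3)
  ph3 <- simulate_phenotypes(ped3, bv3, cfg3)
  by_sex <- prevalence_by_factor(ph3, "sex")
  m <- by_sex[by_sex$level == "male" & by_sex$limb == "lf", "pct_affected"]
  f <- by_sex[by_sex$level == "female" & by_sex$limb == "lf", "pct_affected"]
  expect_gt(m, f)
})

test_that("marginal prevalence matches the normal-CDF prediction", {
  # large founder-only population: no drift, closed form applies
  cfg <- sim_config(n_founders = 10000, n_generations = 1, n_matings = 5000,
                    offspring_per_mating = 1, phenotype_generations = 1,
                    seed = 31)
  s <- simulate_marking_data(cfg)
  ph <- s$phenotypes
  n <- nrow(ph)
  thr <- attr(ph, "truth")$thresholds
  # generator target = mixture-CDF closed form used by the calibration
  for (limb in c("lf", "lh")) {
    p_target <- cfg$target_prevalence[limb, "ge1"]
    p_hat <- mean(ph[[limb]] > 0)
    se <- sqrt(p_target * (1 - p_target) / n)
    expect_lt(abs(p_hat - p_target), 3 * se + 0.005)
  }
})

test_that("generator is exchangeable across limbs under symmetric truth", {
  cfg <- sim_config(n_founders = 3000, n_generations = 1, n_matings = 1500,
                    phenotype_generations = 1, seed = 17)
  cfg$b_sex[] <- 0; cfg$b_coat[] <- 0; cfg$b_f[] <- 0
  v <- mean(diag(cfg$sigma_u))
  R <- cov2cor(cfg$sigma_u)
  cfg$sigma_u <- v * R
  cfg$sigma_m <- diag(rep(mean(diag(cfg$sigma_m)), 4))
  cfg$sigma_e <- diag(rep(mean(diag(cfg$sigma_e)), 4))
  cfg$thresholds <- matrix(rep(qnorm(0.9, sd = sqrt(v + mean(diag(cfg$sigma_m)) +
                                                     mean(diag(cfg$sigma_e)))) +
                                 c(0, 0.5, 1), each = 4), 4, 3)
  s <- simulate_marking_data(cfg)
  prev <- score_distribution(s$phenotypes)$pct_affected
  n <- nrow(s$phenotypes)
  se <- 100 * sqrt(0.1 * 0.9 / n)
  expect_lt(max(prev) - min(prev), 6 * se)
})

test_that("phenotype files round-trip and validate", {
  s <- desk_sim(22, n_founders = 20, n_generations = 3, n_matings = 10,
                phenotype_generations = 3)$data
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(s$phenotypes, path)
  back <- load_phenotypes(path)
  expect_equal(as.data.frame(back),
               as.data.frame(s$phenotypes)[, names(back)],
               ignore_attr = TRUE, tolerance = 1e-12)

  # adapter renames deposit-style headers
  dep <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(s$phenotypes)
  names(df) <- c("id", "sexo", "capa", "consang", "madre",
                 "LF", "RF", "LH", "RH")
  write.csv(df, dep, row.names = FALSE)
  back2 <- load_phenotypes(dep, columns = list(
    animal = "id", sex = "sexo", coat = "capa", F = "consang", dam = "madre",
    lf = "LF", rf = "RF", lh = "LH", rh = "RH"))
  expect_equal(back2$lh, s$phenotypes$lh)

  # out-of-range score rejected with row id
  bad <- df; names(bad) <- names(as.data.frame(s$phenotypes))
  bad$lf[3] <- 7L
  badp <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, badp, row.names = FALSE)
  expect_error(load_phenotypes(badp), "row 3")
})
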