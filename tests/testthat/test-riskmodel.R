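# fixed 500-row covariate layout reused across risk-model tests
risk_fixture <- function(seed = 42, n = 500) {
  set.seed(seed)
  data.frame(
    sex = sample(c("male", "female"), n, TRUE),
    coat = sample(COATS <- c("grey", "bay", "chestnut", "black"), n, TRUE,
                  prob = c(.4, .4, .1, .1)),
    F = runif(n, 0, 0.3),
    stringsAsFactors = FALSE)
}

risk_dataset <- function(cov, y) {
  d <- data.frame(animal = as.character(seq_len(nrow(cov))), sex = cov$sex,
                  coat = cov$coat, F = cov$F, dam = "",
                  lf = as.integer(y), rf = 0L, lh = 0L, rh = 0L,
                  stringsAsFactors = FALSE)
  class(d) <- c("marking_dataset", "data.frame")
  d
}

test_that("two-category fit matches the maximum-likelihood logistic oracle", {
  cov <- risk_fixture()
  eta <- 0.8 * (cov$sex == "male") + 1.0 * (cov$coat == "chestnut") -
    0.5 * (cov$coat == "black") + 2 * cov$F - 1.5
  set.seed(1)
  y <- rbinom(nrow(cov), 1, plogis(eta))
  fit <- fit_cumulative_logit(risk_dataset(cov, y), "lf", dam_effect = FALSE,
                              iter = 12000, burnin = 3000, thin = 3, seed = 5)
  gl <- glm(y ~ I(sex == "male") + I(coat == "bay") + I(coat == "chestnut") +
              I(coat == "black") + F, family = binomial, data = cov)
  post <- colMeans(fit$beta)
  ml <- coef(gl)[-1]
  se <- summary(gl)$coefficients[-1, 2]
  # agreement judged against the ML standard error: weak priors shrink the
  # posterior mean by far less than a fifth of the sampling uncertainty
  expect_true(all(abs(unname(post) - unname(ml)) < 0.2 * se))
  # severity orientation: alpha1 corresponds to minus the glm intercept
  expect_lt(abs(mean(fit$alpha[, 1]) - (-coef(gl)[[1]])),
            0.2 * summary(gl)$coefficients[1, 2])
})

test_that("cutpoints stay ordered and category probabilities form a simplex", {
  s <- desk_sim(26, n_founders = 60, n_generations = 4, n_matings = 60,
                phenotype_generations = 3)$data
  fit <- fit_cumulative_logit(s$phenotypes, "lh", iter = 2000, burnin = 500,
                              thin = 2, seed = 3)
  expect_true(all(apply(fit$alpha, 1, function(a) all(diff(a) > 0))))
  for (eta in c(-2, 0, 3)) {
    pr <- category_probabilities(fit, eta)
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, nrow(pr)))
  }
  # reproducible given the seed
  fit2 <- fit_cumulative_logit(s$phenotypes, "lh", iter = 2000, burnin = 500,
                               thin = 2, seed = 3)
  expect_identical(fit$beta, fit2$beta)
})

test_that("screening retains effects whose interval excludes zero", {
  fit <- list(beta = cbind(pos = abs(rnorm(400)) + 0.1,
                           null = rnorm(400)),
              tau = NULL, limb = "lf")
  class(fit) <- "risk_fit"
  scr <- screen_effects(fit)
  expect_true(scr$retained[scr$effect == "pos"])
  expect_false(scr$retained[scr$effect == "null"])
  expect_match(scr$interval[1], "^\\(-?[0-9.]+, -?[0-9.]+\\)$")
})

test_that("F-slope recovery: credible intervals cover a true slope", {
  cov <- risk_fixture(seed = 9, n = 1500)
  hits <- 0L
  n_rep <- 6L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    eta <- 1.2 * scale(cov$F)[, 1] - 1
    y <- rbinom(nrow(cov), 1, plogis(eta))
    d <- risk_dataset(cov, y)
    d$F <- scale(cov$F)[, 1]
    fit <- fit_cumulative_logit(d, "lf", fixed = "F", dam_effect = FALSE,
                                iter = 4000, burnin = 1000, thin = 2,
                                seed = r)
    q <- quantile(fit$beta[, "F"], c(0.025, 0.975))
    if (q[[1]] <= 1.2 && 1.2 <= q[[2]]) hits <- hits + 1L
  }
  expect_gte(hits, n_rep - 1L)
})

test_that("degenerate inputs are rejected", {
  cov <- risk_fixture(n = 50)
  expect_error(fit_cumulative_logit(risk_dataset(cov, rep(0L, 50)), "lf"),
               "single observed category")
  s <- desk_sim(27, n_founders = 30, n_generations = 3, n_matings = 15,
                phenotype_generations = 2)$data
  expect_error(fit_cumulative_logit(s$phenotypes, "lh", iter = 100,
                                    burnin = 200), "burnin")
})
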