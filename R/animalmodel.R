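#' Threshold animal model specification
#'
#' Declares one model fit: which limbs, the response scale, fixed effects,
#' and random structure. Identifiability constraints follow standard
#' threshold-model practice: the dichotomous model fixes the single
#' threshold at 0 and the residual variance at 1; the four-class ordinal
#' model fixes the first two thresholds at 0 and 1, samples the third, and
#' estimates the residual variance. A `"gaussian"` scale treats the scores
#' (or any numeric response) as observed liabilities, which turns the
#' sampler into a conventional linear animal model.
#'
#' @param traits character vector of limbs (subset of `lf, rf, lh, rh`).
#' @param scale `"dichotomous"`, `"ordinal4"` or `"gaussian"`.
#' @param fixed fixed-effect terms, subset of `c("sex", "coat", "F")`;
#'   an intercept is always included.
#' @param maternal include the pedigree-structured maternal effect?
#' @param direct_maternal_covariance sample a direct-maternal covariance
#'   (univariate models only; off by default — the joint 2x2 covariance is
#'   then updated by inverse-Wishart).
#' @param reference_coat coat level absorbed into the intercept.
#' @param priors optional list overriding `nu_u, S_u, nu_m, s_m, nu_e, s_e`
#'   (defaults: flat scaled-inverse-chi-square, `nu = -2, S = 0`, for
#'   univariate variances; inverse Wishart with minimal proper degrees of
#'   freedom `T + 1` and scale `0.001 I` for the multivariate genetic
#'   covariance).
#' @return Object of class `threshold_model_spec`.
#' @export
threshold_model_spec <- function(traits,
                                 scale = c("ordinal4", "dichotomous", "gaussian"),
                                 fixed = c("sex", "coat", "F"),
                                 maternal = TRUE,
                                 direct_maternal_covariance = FALSE,
                                 reference_coat = "grey",
                                 priors = list()) {
  scale <- match.arg(scale)
  stopifnot(length(traits) >= 1L)
  if (scale != "gaussian") stopifnot(all(traits %in% LIMBS))
  if (direct_maternal_covariance && (length(traits) > 1L || !maternal)) {
    stop("direct-maternal covariance is supported for univariate maternal models only")
  }
  spec <- list(traits = traits, scale = scale, fixed = fixed,
               maternal = maternal,
               direct_maternal_covariance = direct_maternal_covariance,
               reference_coat = reference_coat, priors = priors)
  class(spec) <- "threshold_model_spec"
  spec
}

#' Gibbs chain settings
#'
#' @param iter total iterations; @param burnin discarded iterations
#'   (`burnin < iter`); @param thin keep every `thin`-th post-burn-in draw;
#' @param seed integer seed.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(iter = 20000L, burnin = 4000L, thin = 10L, seed = 1L) {
  iter <- as.integer(iter); burnin <- as.integer(burnin); thin <- as.integer(thin)
  if (burnin >= iter) stop("burnin must be smaller than total iterations")
  if (thin < 1L) stop("thinning must be >= 1")
  structure(list(iter = iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed)), class = "chain_config")
}

# Fixed-effect design with intercept; drops constant non-intercept columns,
# errors on rank deficiency beyond the declared reference levels.
.fixed_design <- function(data, fixed, reference_coat) {
  n <- nrow(data)
  cols <- list(intercept = rep(1, n))
  if ("sex" %in% fixed) cols$sex_male <- as.numeric(data$sex == "male")
  if ("coat" %in% fixed) {
    for (ct in setdiff(COATS, reference_coat)) {
      cols[[paste0("coat_", ct)]] <- as.numeric(data$coat == ct)
    }
  }
  if ("F" %in% fixed) cols$F <- as.numeric(data$F)
  X <- do.call(cbind, cols)
  if (ncol(X) > 1L) {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(col) length(unique(col)) > 1L))
    X <- X[, keep, drop = FALSE]
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  X
}

# Maps records to pedigree rows; augments the pedigree with phantom
# founders for phenotyped animals whose dam is unknown (maternal models).
.mme_frame <- function(data, ped, spec) {
  if (!all(data$animal %in% ped$animal)) {
    stop("phenotyped animal missing from pedigree: ",
         setdiff(data$animal, ped$animal)[1L])
  }
  dam <- as.character(data$dam)
  dam[is.na(dam) | dam == "0"] <- ""
  if (spec$maternal && any(dam == "")) {
    phantom <- paste0(".phantom_dam_", data$animal[dam == ""])
    dam[dam == ""] <- phantom
    add <- data.frame(animal = phantom, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    base <- as.data.frame(ped)[, c("animal", "sire", "dam")]
    ped <- pedigree_table(c(base$animal, add$animal),
                          c(base$sire, add$sire), c(base$dam, add$dam))
  }
  if (spec$maternal && !all(dam %in% ped$animal)) {
    stop("dam missing from pedigree: ", setdiff(dam, ped$animal)[1L])
  }
  list(ped = ped,
       animal_idx = match(data$animal, ped$animal) - 1L,
       dam_idx = if (spec$maternal) match(dam, ped$animal) - 1L
                 else rep(-1L, nrow(data)),
       X = .fixed_design(data, spec$fixed, spec$reference_coat))
}

#' Build the mixed-model equations at fixed variance components
#'
#' Assembles the sparse Henderson system for the Gaussian (observed
#' liability) case of one trait: fixed effects, direct genetic effects over
#' `A^-1 / sigma_u2`, and optionally maternal effects over
#' `A^-1 / sigma_m2`. Animals without records contribute through `A^-1`
#' only. Mainly used to initialize and cross-check the Gibbs sampler.
#'
#' @param data a `marking_dataset` (or any data frame with the covariate
#'   columns and a numeric response given via `response`).
#' @param ped a `pedigree_table` containing all phenotyped animals.
#' @param spec a `threshold_model_spec` (single trait).
#' @param varcomp list with `sigma_u2`, `sigma_e2` and, if maternal,
#'   `sigma_m2`.
#' @param response numeric response vector (defaults to the trait's score).
#' @return List with sparse `LHS`, `RHS`, the effect-block sizes and the
#'   (possibly phantom-augmented) pedigree.
#' @export
build_mme <- function(data, ped, spec, varcomp, response = NULL) {
  stopifnot(length(spec$traits) == 1L)
  fr <- .mme_frame(data, ped, spec)
  ped <- fr$ped
  n_ped <- nrow(ped)
  n_rec <- nrow(data)
  if (is.null(response)) response <- as.numeric(data[[spec$traits]])
  X <- fr$X
  p <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(n_rec), j = fr$animal_idx + 1L,
                            x = 1, dims = c(n_rec, n_ped))
  Ainv <- a_inverse(ped)
  lambda_u <- varcomp$sigma_e2 / varcomp$sigma_u2
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  blocks <- list(fixed = colnames(X), n_ped = n_ped,
                 maternal = isTRUE(spec$maternal))
  if (spec$maternal) {
    W <- Matrix::sparseMatrix(i = seq_len(n_rec), j = fr$dam_idx + 1L,
                              x = 1, dims = c(n_rec, n_ped))
    lambda_m <- varcomp$sigma_e2 / varcomp$sigma_m2
    LHS <- rbind(
      cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z), Matrix::crossprod(Xs, W)),
      cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + lambda_u * Ainv,
            Matrix::crossprod(Z, W)),
      cbind(Matrix::crossprod(W, Xs), Matrix::crossprod(W, Z),
            Matrix::crossprod(W) + lambda_m * Ainv))
    RHS <- c(as.numeric(Matrix::crossprod(Xs, response)),
             as.numeric(Matrix::crossprod(Z, response)),
             as.numeric(Matrix::crossprod(W, response)))
  } else {
    LHS <- rbind(
      cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
      cbind(Matrix::crossprod(Z, Xs), Matrix::crossprod(Z) + lambda_u * Ainv))
    RHS <- c(as.numeric(Matrix::crossprod(Xs, response)),
             as.numeric(Matrix::crossprod(Z, response)))
  }
  list(LHS = LHS, RHS = RHS, blocks = blocks, pedigree = ped, p = p)
}

#' Solve mixed-model equations
#'
#' @param mme output of [build_mme()].
#' @return Named list with `fixed`, `u` and (if present) `m` solution
#'   vectors (BLUE/BLUP at the given variance components).
#' @export
solve_mme <- function(mme) {
  sol <- as.numeric(Matrix::solve(mme$LHS, mme$RHS))
  p <- mme$p
  n <- mme$blocks$n_ped
  out <- list(fixed = stats::setNames(sol[seq_len(p)], mme$blocks$fixed),
              u = stats::setNames(sol[p + seq_len(n)], mme$pedigree$animal))
  if (mme$blocks$maternal) {
    out$m <- stats::setNames(sol[p + n + seq_len(n)], mme$pedigree$animal)
  }
  out
}

#' Fit a Bayesian threshold animal model by Gibbs sampling
#'
#' Gibbs sampling with liability augmentation over the sparse inverse
#' numerator relationship matrix. Each cycle draws (1) liabilities from
#' their truncated-normal full conditionals, (2) fixed effects and the
#' direct (block per animal, multivariate) and maternal (single-site)
#' genetic effects from normal full conditionals, (3) variance components
#' from scaled-inverse-chi-square / inverse-Wishart full conditionals using
#' `A^-1` quadratic forms, and (4) the free ordinal threshold from its
#' uniform full conditional. Deterministic given the seed.
#'
#' @param data a `marking_dataset` (numeric responses for gaussian scale).
#' @param ped a `pedigree_table`.
#' @param spec a `threshold_model_spec`.
#' @param chain a `chain_config`.
#' @param start optional list overriding start values
#'   (`sigma_u` matrix, `sigma_m`, `sigma_e`, `t3` vectors).
#' @param fix_sigma_e force the residual variance(s) to stay at their start
#'   value (defaults to TRUE for the dichotomous scale, FALSE otherwise).
#' @return Object of class `gibbs_chain` with draw matrices `b`, `sigma_u`
#'   (columns `t1.t2` of the genetic covariance), `sigma_m`, `sigma_um`,
#'   `sigma_e`, `t3`, posterior-mean breeding values, and bookkeeping.
#' @export
run_gibbs <- function(data, ped, spec, chain = chain_config(),
                      start = list(), fix_sigma_e = NULL) {
  stopifnot(inherits(spec, "threshold_model_spec"),
            inherits(chain, "chain_config"))
  traits <- spec$traits
  n_tr <- length(traits)
  fr <- .mme_frame(data, ped, spec)
  n_rec <- nrow(data)

  if (spec$scale == "gaussian") {
    ymat <- as.matrix(data[, traits, drop = FALSE])
    storage.mode(ymat) <- "double"
    yint <- matrix(0L, 1, n_tr)
    scale_code <- 0L
    if (is.null(fix_sigma_e)) fix_sigma_e <- FALSE
  } else {
    yint <- as.matrix(data[, traits, drop = FALSE])
    storage.mode(yint) <- "integer"
    if (spec$scale == "dichotomous") {
      yint <- matrix(as.integer(yint > 0L), n_rec, n_tr, dimnames = dimnames(yint))
      scale_code <- 2L
      if (is.null(fix_sigma_e)) fix_sigma_e <- TRUE
    } else {
      scale_code <- 4L
      if (is.null(fix_sigma_e)) fix_sigma_e <- FALSE
      for (t in seq_len(n_tr)) {
        seen <- tabulate(yint[, t] + 1L, 4L)
        if (any(seen == 0L)) {
          stop("ordinal4 scale requires all four classes observed for trait ",
               traits[t])
        }
      }
    }
    ymat <- matrix(0, 1, n_tr)
  }

  pr <- spec$priors
  nu_u <- pr$nu_u %||% if (n_tr == 1L) -2 else n_tr + 1
  S_u <- pr$S_u %||% if (n_tr == 1L) matrix(0, 1, 1) else diag(1e-3, n_tr)
  if (!is.matrix(S_u)) S_u <- diag(S_u, n_tr)
  nu_m <- pr$nu_m %||% -2
  s_m <- pr$s_m %||% 0
  nu_e <- pr$nu_e %||% -2
  s_e <- pr$s_e %||% 0

  Su_start <- start$sigma_u %||% diag(1, n_tr)
  if (!is.matrix(Su_start)) Su_start <- diag(Su_start, n_tr)
  sm_start <- rep_len(start$sigma_m %||% 0.1, n_tr)
  se_start <- rep_len(start$sigma_e %||% 1, n_tr)
  t3_start <- rep_len(start$t3 %||% 1.5, n_tr)

  Ainv <- a_inverse(fr$ped)
  set.seed(chain$seed)
  res <- gibbs_threshold_cpp(
    yint, fr$X, fr$animal_idx, fr$dam_idx, Ainv,
    scale_code, ymat, spec$maternal, spec$direct_maternal_covariance,
    fix_sigma_e, nu_u, S_u, nu_m, s_m, nu_e, s_e,
    Su_start, sm_start, se_start, t3_start,
    chain$iter, chain$burnin, chain$thin)

  bnames <- as.vector(outer(colnames(fr$X), traits,
                            function(b, t) paste0(t, ".", b)))
  colnames(res$b) <- bnames
  colnames(res$sigma_u) <- as.vector(outer(traits, traits,
                                           function(a, b) paste0(a, ".", b)))
  if (spec$maternal) colnames(res$sigma_m) <- traits
  colnames(res$sigma_e) <- traits
  if (scale_code == 4L) colnames(res$t3) <- traits
  rownames(res$u_mean) <- rownames(res$m_mean) <- fr$ped$animal
  colnames(res$u_mean) <- colnames(res$m_mean) <- traits

  out <- list(traits = traits, scale = spec$scale, spec = spec,
              chain = chain, b = res$b, sigma_u = res$sigma_u,
              sigma_m = if (spec$maternal) res$sigma_m else NULL,
              sigma_um = if (spec$direct_maternal_covariance) res$sigma_um else NULL,
              sigma_e = res$sigma_e,
              t3 = if (scale_code == 4L) res$t3 else NULL,
              thresholds_fixed = switch(spec$scale, dichotomous = c(t1 = 0),
                                        ordinal4 = c(t1 = 0, t2 = 1), NULL),
              u_mean = res$u_mean, m_mean = res$m_mean,
              n_stored = res$n_stored,
              liability_in_interval = res$liability_in_interval,
              pedigree = fr$ped)
  class(out) <- "gibbs_chain"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-draw heritability
#'
#' `h2 = sigma_u2 / (sigma_u2 + sigma_m2 + sigma_e2)` per stored draw (the
#' maternal term is part of the denominator; it is dropped automatically
#' for models without it). Ratios are taken per draw and then summarized,
#' never as a ratio of summaries.
#'
#' @param chain a `gibbs_chain`.
#' @param trait one of the chain's traits.
#' @return Numeric vector of h2 draws.
#' @export
heritability_samples <- function(chain, trait) {
  stopifnot(trait %in% chain$traits)
  su <- chain$sigma_u[, paste0(trait, ".", trait)]
  sm <- if (!is.null(chain$sigma_m)) chain$sigma_m[, trait] else 0
  se <- chain$sigma_e[, trait]
  su / (su + sm + se)
}

#' Per-draw genetic correlation
#'
#' `sigma_u[i,j] / sqrt(sigma_u[i,i] * sigma_u[j,j])` per stored draw of
#' the multivariate genetic covariance; draws with a zero variance are
#' excluded (their count is reported as an attribute).
#'
#' @param chain a multivariate `gibbs_chain`.
#' @param trait_pair character vector of two traits.
#' @return Numeric vector of correlation draws in `[-1, 1]`, attribute
#'   `n_excluded`.
#' @export
genetic_correlation_samples <- function(chain, trait_pair) {
  stopifnot(length(trait_pair) == 2L, all(trait_pair %in% chain$traits))
  i <- trait_pair[1L]; j <- trait_pair[2L]
  vij <- chain$sigma_u[, paste0(i, ".", j)]
  vii <- chain$sigma_u[, paste0(i, ".", i)]
  vjj <- chain$sigma_u[, paste0(j, ".", j)]
  ok <- vii > 0 & vjj > 0
  r <- vij[ok] / sqrt(vii[ok] * vjj[ok])
  attr(r, "n_excluded") <- sum(!ok)
  r
}

#' Liability-to-observed-scale heritability
#'
#' The classical transformation between the heritability on the underlying
#' (liability) scale and on the observed binary scale at prevalence `p`:
#' `h2_obs = h2 * z^2 / (p (1 - p))` with `z` the standard-normal density
#' at the threshold `qnorm(1 - p)`.
#'
#' @param h2_liability heritability on the liability scale, in `[0, 1]`.
#' @param prevalence trait prevalence, strictly inside (0, 1).
#' @return Observed-scale heritability.
#' @export
dempster_lerner <- function(h2_liability, prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1)) {
    stop("prevalence must be strictly inside (0, 1)")
  }
  if (any(h2_liability < 0 | h2_liability > 1)) {
    stop("h2 must be in [0, 1]")
  }
  z <- dnorm(qnorm(1 - prevalence))
  h2_liability * z^2 / (prevalence * (1 - prevalence))
}

#' Map generator truth onto the model's identification scale
#'
#' The threshold model identifies liabilities only up to an affine
#' transform. The dichotomous model fixes the threshold at 0 and the
#' residual variance at 1, so true (co)variances are divided by the true
#' residual SDs; the ordinal model fixes t1 = 0 and t2 = 1, so liabilities
#' are rescaled by `1 / (t2 - t1)`. Heritabilities and genetic correlations
#' are invariant. Needed to compare simulation truth with posterior draws.
#'
#' @param cfg the `sim_config` used to simulate.
#' @param traits traits of the fitted model.
#' @param scale `"dichotomous"` or `"ordinal4"`.
#' @return List with matrices/vectors `sigma_u`, `sigma_m`, `sigma_e`,
#'   `t3`, `h2` and `r_g` on the model scale.
#' @export
truth_on_model_scale <- function(cfg, traits, scale = c("ordinal4", "dichotomous")) {
  scale <- match.arg(scale)
  idx <- match(traits, LIMBS)
  thr <- .sim_thresholds(cfg)
  s <- if (scale == "dichotomous") {
    1 / sqrt(diag(cfg$sigma_e)[idx])
  } else {
    1 / (thr[idx, 2] - thr[idx, 1])
  }
  Su <- cfg$sigma_u[idx, idx, drop = FALSE] * tcrossprod(s)
  Sm <- cfg$sigma_m[idx, idx, drop = FALSE] * tcrossprod(s)
  Se <- cfg$sigma_e[idx, idx, drop = FALSE] * tcrossprod(s)
  h2 <- diag(Su) / (diag(Su) + diag(Sm) + diag(Se))
  Rg <- stats::cov2cor(cfg$sigma_u[idx, idx, drop = FALSE])
  t3 <- (thr[idx, 3] - thr[idx, 1]) * s
  list(sigma_u = Su, sigma_m = Sm, sigma_e = Se, t3 = t3, h2 = h2, r_g = Rg)
}

#' Posterior summary of a fitted chain
#'
#' Summaries (mean, median, SD, HPD95) for all stored variance components,
#' thresholds, fixed effects and the derived heritabilities and genetic
#' correlations.
#'
#' @param chain a `gibbs_chain`.
#' @param mass HPD mass.
#' @return Data frame in the [posterior_summary()] layout.
#' @export
summarize_chain <- function(chain, mass = 0.95) {
  draws <- list()
  for (nm in colnames(chain$b)) draws[[paste0("b.", nm)]] <- chain$b[, nm]
  for (t in chain$traits) {
    draws[[paste0("sigma_u2.", t)]] <- chain$sigma_u[, paste0(t, ".", t)]
    if (!is.null(chain$sigma_m)) draws[[paste0("sigma_m2.", t)]] <- chain$sigma_m[, t]
    draws[[paste0("sigma_e2.", t)]] <- chain$sigma_e[, t]
    if (!is.null(chain$t3)) draws[[paste0("t3.", t)]] <- chain$t3[, t]
    draws[[paste0("h2.", t)]] <- heritability_samples(chain, t)
  }
  if (length(chain$traits) > 1L) {
    prs <- utils::combn(chain$traits, 2, simplify = FALSE)
    for (pr in prs) {
      draws[[paste0("r_g.", pr[1L], ".", pr[2L])]] <-
        as.numeric(genetic_correlation_samples(chain, pr))
    }
  }
  posterior_summary(draws, mass = mass)
}
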