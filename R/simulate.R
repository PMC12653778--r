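#' Project a correlation matrix to the nearest positive semidefinite one
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Published
#' correlation tables rounded to three decimals need not be exactly PSD;
#' this projection makes them usable as simulation truth.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps smallest eigenvalue allowed after clipping.
#' @return A PSD correlation matrix.
#' @export
nearest_psd_correlation <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE)
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  dimnames(out) <- dimnames(R)
  (out + t(out)) / 2
}

.cov_from_cor <- function(R, variances) {
  sds <- sqrt(variances)
  out <- R * tcrossprod(sds)
  dimnames(out) <- dimnames(R)
  out
}

LIMBS <- c("lf", "rf", "lh", "rh")
COATS <- c("grey", "bay", "chestnut", "black")

#' Simulation configuration
#'
#' Bundles the demographic and genetic parameters of the synthetic-data
#' generator: a discrete-generation random-mating pedigree and four
#' correlated ordinal limb traits generated under the liability-threshold
#' model `l = x'b + u + m_dam + e` with pedigree-structured direct (`u`) and
#' maternal (`m`) genetic effects.
#'
#' Defaults are the "pre-like" preset: direct, maternal and residual
#' variances from the published ordinal four-class analysis; genetic
#' correlations from the published between-limb table projected to the
#' nearest PSD matrix; sex ratio and coat frequencies from the studbook
#' counts; thresholds calibrated so marginal prevalences approximate the
#' published per-limb score distribution (see [calibrate_thresholds()]).
#'
#' @param n_founders number of unrelated founder animals (>= 2).
#' @param n_generations number of discrete offspring generations.
#' @param n_matings matings per generation.
#' @param offspring_per_mating mean litter size; litter = 1 + Poisson(mean-1).
#' @param sex_ratio probability that an animal is male.
#' @param coat_frequencies probabilities of grey/bay/chestnut/black; sum 1.
#' @param b_sex per-trait liability shift for males (females reference).
#' @param b_coat 3 x 4 matrix of liability shifts for bay/chestnut/black
#'   (grey reference), columns = limbs.
#' @param b_f per-trait liability slope on the inbreeding coefficient.
#' @param sigma_u 4 x 4 direct-genetic covariance matrix.
#' @param sigma_m 4 x 4 maternal-genetic covariance matrix (diagonal by
#'   default).
#' @param sigma_um per-trait direct-maternal covariance (default 0).
#' @param sigma_e 4 x 4 residual covariance (diagonal).
#' @param thresholds 4 x 3 matrix of ascending per-trait cut points, or
#'   `NULL` to calibrate them from `target_prevalence`.
#' @param target_prevalence per-limb target probabilities of score at least
#'   1, at least 2, and equal to 3, used when `thresholds` is `NULL`.
#' @param phenotype_generations generations that receive phenotype records,
#'   counted backwards from the last (default: all non-founder generations).
#' @param seed integer seed; all randomness flows from this one seed.
#' @return A list of class `sim_config` (validated).
#' @export
sim_config <- function(n_founders = 30L,
                       n_generations = 10L,
                       n_matings = 20L,
                       offspring_per_mating = 2,
                       sex_ratio = 0.339,
                       coat_frequencies = c(grey = 0.404, bay = 0.387,
                                            chestnut = 0.085, black = 0.124),
                       b_sex = NULL,
                       b_coat = NULL,
                       b_f = NULL,
                       sigma_u = NULL,
                       sigma_m = NULL,
                       sigma_um = rep(0, 4),
                       sigma_e = NULL,
                       thresholds = NULL,
                       target_prevalence = NULL,
                       phenotype_generations = n_generations,
                       seed = 1L) {
  comp <- pre_reference_components()$ordinal4
  if (is.null(sigma_u)) {
    R <- nearest_psd_correlation(pre_reference_correlations("ordinal4"))
    sigma_u <- .cov_from_cor(R, comp$sigma_u2)
  }
  if (is.null(sigma_m)) sigma_m <- diag(comp$sigma_m2)
  if (is.null(sigma_e)) sigma_e <- diag(comp$sigma_e2)
  dimnames(sigma_u) <- dimnames(sigma_m) <- dimnames(sigma_e) <- list(LIMBS, LIMBS)
  # liability-scale fixed effects (total liability SD is ~3-4 per limb):
  # males and chestnuts shifted towards more white, blacks towards less,
  # inbreeding acting mainly on the forelegs
  if (is.null(b_sex)) b_sex <- c(lf = 1.0, rf = 1.0, lh = 0.6, rh = 0.6)
  if (is.null(b_coat)) {
    b_coat <- rbind(bay = c(-0.4, -0.4, -0.4, -0.4),
                    chestnut = c(1.2, 1.2, 1.2, 1.2),
                    black = c(-1.2, -1.2, -1.2, -1.2))
    colnames(b_coat) <- LIMBS
  }
  if (is.null(b_f)) b_f <- c(lf = 4, rf = 4, lh = 0.5, rh = 0.5)
  if (is.null(target_prevalence)) {
    cnt <- pre_reference_counts()$limbs
    tot <- pre_reference_counts()$n_total
    target_prevalence <- cbind(
      ge1 = cnt$n_affected / tot,
      ge2 = (cnt$n2 + cnt$n3) / tot,
      eq3 = cnt$n3 / tot
    )
    rownames(target_prevalence) <- cnt$limb
  }
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_matings = as.integer(n_matings),
              offspring_per_mating = offspring_per_mating,
              sex_ratio = sex_ratio,
              coat_frequencies = coat_frequencies,
              b_sex = b_sex, b_coat = b_coat, b_f = b_f,
              sigma_u = sigma_u, sigma_m = sigma_m,
              sigma_um = sigma_um, sigma_e = sigma_e,
              thresholds = thresholds,
              target_prevalence = target_prevalence,
              phenotype_generations = as.integer(phenotype_generations),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_founders >= 2L, cfg$n_generations >= 0L,
            cfg$sex_ratio > 0, cfg$sex_ratio < 1)
  if (abs(sum(cfg$coat_frequencies) - 1) > 1e-8) {
    stop("coat frequencies must sum to 1")
  }
  for (nm in c("sigma_u", "sigma_m", "sigma_e")) {
    S <- cfg[[nm]]
    if (!isSymmetric(unname(S), tol = 1e-8)) stop(nm, " must be symmetric")
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(nm, " must be positive semidefinite")
    }
  }
  # the joint (u, m) covariance must itself be PSD when sigma_um is nonzero
  if (any(cfg$sigma_um != 0)) {
    C <- rbind(cbind(cfg$sigma_u, diag(cfg$sigma_um)),
               cbind(diag(cfg$sigma_um), cfg$sigma_m))
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("joint direct-maternal covariance is not positive semidefinite")
    }
  }
  if (!is.null(cfg$thresholds)) {
    thr <- cfg$thresholds
    stopifnot(is.matrix(thr), nrow(thr) == 4, ncol(thr) == 3)
    if (any(thr[, 2] <= thr[, 1]) || any(thr[, 3] <= thr[, 2])) {
      stop("thresholds must be strictly ascending per trait")
    }
  }
  invisible(cfg)
}

#' Calibrate liability thresholds to target prevalences
#'
#' Solves, per limb, for the cut points (t1, t2, t3) at which the marginal
#' probabilities of score >= 1, >= 2 and == 3 match the configured targets,
#' given the fixed-effect structure. The marginal liability is a finite
#' normal mixture over the sex-by-coat cells (inbreeding held at its
#' population mean) with cell variance `sigma_u + sigma_m + sigma_e`.
#'
#' @param cfg a `sim_config`.
#' @param mean_f mean inbreeding coefficient used for the F covariate term.
#' @return 4 x 3 matrix of ascending thresholds (rows = limbs).
#' @export
calibrate_thresholds <- function(cfg, mean_f = 0.074) {
  p_sex <- c(male = cfg$sex_ratio, female = 1 - cfg$sex_ratio)
  p_coat <- cfg$coat_frequencies
  thr <- matrix(NA_real_, 4, 3, dimnames = list(LIMBS, c("t1", "t2", "t3")))
  for (t in seq_along(LIMBS)) {
    limb <- LIMBS[t]
    sdt <- sqrt(cfg$sigma_u[t, t] + cfg$sigma_m[t, t] + cfg$sigma_e[t, t])
    ce <- c(grey = 0, cfg$b_coat[, limb])
    names(ce) <- c("grey", rownames(cfg$b_coat))
    mu <- outer(c(male = cfg$b_sex[[limb]], female = 0), ce[COATS], "+") +
      mean_f * cfg$b_f[[limb]]
    w <- outer(p_sex, p_coat[COATS])
    exceed <- function(x) sum(w * (1 - pnorm((x - mu) / sdt)))
    solve_t <- function(target) {
      uniroot(function(x) exceed(x) - target, c(-60, 60), tol = 1e-10)$root
    }
    thr[t, ] <- c(solve_t(cfg$target_prevalence[limb, "ge1"]),
                  solve_t(cfg$target_prevalence[limb, "ge2"]),
                  solve_t(cfg$target_prevalence[limb, "eq3"]))
  }
  thr
}

.sim_thresholds <- function(cfg) {
  if (!is.null(cfg$thresholds)) cfg$thresholds else calibrate_thresholds(cfg)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are unrelated; each later generation is produced by random
#' mating within the previous generation (sires drawn with replacement from
#' its males, dams without replacement from its females, recycling when
#' exhausted). Litter sizes are 1 + Poisson(mean - 1). Uses the current RNG
#' state; seed via `set.seed()` or [simulate_marking_data()].
#'
#' @param cfg a `sim_config`.
#' @return A `pedigree_table` with `birth_year` (= generation) and `sex`.
#' @export
simulate_pedigree <- function(cfg) {
  n0 <- cfg$n_founders
  sex <- ifelse(runif(n0) < cfg$sex_ratio, "male", "female")
  # a generation without both sexes cannot reproduce
  if (cfg$n_generations > 0L) {
    if (!any(sex == "male")) sex[1L] <- "male"
    if (!any(sex == "female")) sex[1L] <- "female"
  }
  animal <- sprintf("G0_%04d", seq_len(n0))
  ped <- data.frame(animal = animal, sire = NA_character_, dam = NA_character_,
                    birth_year = 0L, sex = sex, stringsAsFactors = FALSE)
  prev <- ped
  counter <- n0
  for (g in seq_len(cfg$n_generations)) {
    males <- prev$animal[prev$sex == "male"]
    females <- prev$animal[prev$sex == "female"]
    if (!length(males) || !length(females)) {
      stop("generation ", g - 1L, " has a single sex; cannot mate")
    }
    sires <- sample(males, cfg$n_matings, replace = TRUE)
    dams <- if (length(females) >= cfg$n_matings) {
      sample(females, cfg$n_matings, replace = FALSE)
    } else {
      sample(rep(females, length.out = cfg$n_matings))
    }
    litters <- 1L + rpois(cfg$n_matings, max(cfg$offspring_per_mating - 1, 0))
    n_off <- sum(litters)
    off_sex <- ifelse(runif(n_off) < cfg$sex_ratio, "male", "female")
    if (g < cfg$n_generations) {
      if (!any(off_sex == "male")) off_sex[1L] <- "male"
      if (!any(off_sex == "female")) off_sex[1L] <- "female"
    }
    off <- data.frame(
      animal = sprintf("G%d_%04d", g, counter + seq_len(n_off)),
      sire = rep(sires, litters), dam = rep(dams, litters),
      birth_year = g, sex = off_sex, stringsAsFactors = FALSE)
    counter <- counter + n_off
    ped <- rbind(ped, off)
    prev <- off
  }
  out <- pedigree_table(ped$animal, ped$sire, ped$dam,
                        birth_year = ped$birth_year, sex = ped$sex)
  out
}

# draw n rows from N(0, S) via Cholesky with PSD-tolerant pivoting
.rmvn <- function(n, S) {
  d <- nrow(S)
  ev <- eigen(S, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  matrix(rnorm(n * d), n, d) %*% t(L)
}

#' Simulate direct and maternal breeding values down a pedigree
#'
#' Founders draw `(u, m)` from the joint normal with covariance
#' `[[sigma_u, diag(sigma_um)], [diag(sigma_um), sigma_m]]`; descendants get
#' the parent average plus a Mendelian-sampling deviation with covariance
#' `d_i` times the same matrix, where `d_i` is the Mendelian-sampling
#' variance from parental inbreeding and the parent-knowledge pattern.
#'
#' @param ped an ordered `pedigree_table`.
#' @param cfg a `sim_config`.
#' @param f optional precomputed inbreeding coefficients.
#' @return List with matrices `u` and `m` (animals x 4) in pedigree order.
#' @export
simulate_breeding_values <- function(ped, cfg, f = NULL) {
  if (is.null(f)) f <- inbreeding_coefficients(ped)
  n <- nrow(ped)
  C <- rbind(cbind(cfg$sigma_u, diag(cfg$sigma_um)),
             cbind(diag(cfg$sigma_um), cfg$sigma_m))
  p <- .parent_index(ped)
  d <- mendelian_variance(p$sire, p$dam, unname(f))
  G <- matrix(0, n, 8)
  phi <- .rmvn(n, C)
  for (i in seq_len(n)) {
    pa <- numeric(8)
    if (p$sire[i] > 0L) pa <- pa + 0.5 * G[p$sire[i], ]
    if (p$dam[i] > 0L) pa <- pa + 0.5 * G[p$dam[i], ]
    G[i, ] <- pa + sqrt(d[i]) * phi[i, ]
  }
  u <- G[, 1:4, drop = FALSE]
  m <- G[, 5:8, drop = FALSE]
  dimnames(u) <- dimnames(m) <- list(ped$animal, LIMBS)
  list(u = u, m = m)
}

#' Simulate four-limb ordinal marking phenotypes
#'
#' Generates, for each phenotyped animal, the liability
#' `l = x'b + u_animal + m_dam + e` per limb and the ordinal score as the
#' number of thresholds below the liability. Coat is assigned independently
#' of genetics; the F covariate is the pedigree inbreeding coefficient.
#' Animals with an unknown dam use that animal's own phantom maternal value
#' (an independent founder draw by construction of the pedigree).
#'
#' @param ped ordered `pedigree_table` (with `sex`, `birth_year`).
#' @param bv output of [simulate_breeding_values()].
#' @param cfg a `sim_config`.
#' @param f optional precomputed inbreeding coefficients.
#' @return A `data.frame` of class `marking_dataset` with columns
#'   `animal, sex, coat, F, dam, lf, rf, lh, rh`; latent truth (`u`, `m`,
#'   `liability`, `thresholds`) is kept in `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(ped, bv, cfg, f = NULL) {
  if (is.null(f)) f <- inbreeding_coefficients(ped)
  thr <- .sim_thresholds(cfg)
  first_pheno_gen <- cfg$n_generations - cfg$phenotype_generations + 1L
  keep <- ped$birth_year >= max(first_pheno_gen, 1L)
  rec <- ped[keep, , drop = FALSE]
  n <- nrow(rec)
  if (n == 0L) stop("no animals in the phenotyped generations")
  coat <- sample(COATS, n, replace = TRUE, prob = cfg$coat_frequencies[COATS])
  idx <- match(rec$animal, ped$animal)
  dam_idx <- match(rec$dam, ped$animal)

  liab <- matrix(NA_real_, n, 4, dimnames = list(rec$animal, LIMBS))
  score <- matrix(NA_integer_, n, 4, dimnames = list(rec$animal, LIMBS))
  ee <- .rmvn(n, cfg$sigma_e)
  for (t in seq_along(LIMBS)) {
    limb <- LIMBS[t]
    xb <- ifelse(rec$sex == "male", cfg$b_sex[[limb]], 0) +
      c(grey = 0, bay = cfg$b_coat["bay", limb],
        chestnut = cfg$b_coat["chestnut", limb],
        black = cfg$b_coat["black", limb])[coat] +
      unname(f[idx]) * cfg$b_f[[limb]]
    m_dam <- ifelse(is.na(dam_idx), bv$m[idx, t], bv$m[dam_idx, t])
    liab[, t] <- xb + bv$u[idx, t] + m_dam + ee[, t]
    score[, t] <- rowSums(outer(liab[, t], thr[t, ], ">"))
  }
  out <- data.frame(animal = rec$animal, sex = rec$sex, coat = coat,
                    F = unname(f[idx]),
                    dam = ifelse(is.na(rec$dam), "", rec$dam),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(score))
  rownames(out) <- NULL
  attr(out, "truth") <- list(u = bv$u, m = bv$m, liability = liab,
                             thresholds = thr)
  class(out) <- c("marking_dataset", "data.frame")
  out
}

#' Simulate a complete marking dataset
#'
#' Runs the whole generator under `cfg$seed`: pedigree, inbreeding, breeding
#' values, phenotypes.
#'
#' @param cfg a `sim_config`.
#' @return List with `pedigree`, `phenotypes` (a `marking_dataset`) and `f`.
#' @export
simulate_marking_data <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  f <- inbreeding_coefficients(ped)
  bv <- simulate_breeding_values(ped, cfg, f = f)
  dat <- simulate_phenotypes(ped, bv, cfg, f = f)
  list(pedigree = ped, phenotypes = dat, f = f)
}

#' Read and write phenotype files
#'
#' The phenotype CSV schema is `animal,sex,coat,F,dam,lf,rf,lh,rh` with
#' scores in 0..3 and `dam` empty or `"0"` for unknown. `columns` renames
#' nonstandard headers (adapter for externally deposited datasets), e.g.
#' `columns = list(animal = "id", lf = "score_LF")`.
#'
#' @param path file path.
#' @param columns optional named list mapping standard names to file headers.
#' @return A `marking_dataset`.
#' @export
load_phenotypes <- function(path, columns = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      hit <- match(columns[[std]], names(dt))
      if (is.na(hit)) stop("column '", columns[[std]], "' not found in ", path)
      names(dt)[hit] <- std
    }
  }
  need <- c("animal", "sex", "coat", "F", "dam", LIMBS)
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "))
  dt <- dt[, need]
  dt$animal <- as.character(dt$animal)
  dt$dam <- .as_parent(dt$dam)
  dt$dam[is.na(dt$dam)] <- ""
  for (l in LIMBS) {
    bad <- !dt[[l]] %in% 0:3
    if (any(bad)) {
      stop("score out of range 0..3 for limb ", l, " at row ", which(bad)[1L])
    }
    dt[[l]] <- as.integer(dt[[l]])
  }
  class(dt) <- c("marking_dataset", "data.frame")
  dt
}

#' @rdname load_phenotypes
#' @param data a `marking_dataset`.
#' @export
write_phenotypes <- function(data, path) {
  data.table::fwrite(as.data.frame(data), path)
  invisible(path)
}
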