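#' Published reference tabulations for PRE white leg markings
#'
#' Reference values from a published studbook-scale analysis of white leg
#' markings in 38,825 Pura Raza Espanola horses (83,334-animal pedigree).
#' These are used as the truth preset of the synthetic-data generator and as
#' inputs for arithmetic cross-checks; the package does not refit them.
#'
#' `pre_reference_counts()` returns the per-limb score counts and the
#' multi-limb combination counts. Limb rows carry the count of unaffected
#' horses (`n0`) and counts per ordinal class (`n1` below fetlock, `n2`
#' above fetlock, `n3` up to the cannon bone); combination rows carry the
#' count affected on every limb of the combination.
#'
#' @return A list with elements `limbs` and `combinations` (data frames) and
#'   `n_total` (number of scored horses).
#' @seealso [pre_reference_components()], [pre_reference_correlations()]
#' @export
pre_reference_counts <- function() {
  limbs <- data.frame(
    limb = c("lf", "rf", "lh", "rh"),
    n0 = c(36771L, 37021L, 31857L, 33191L),
    n1 = c(332L, 305L, 846L, 714L),
    n2 = c(1359L, 1172L, 4451L, 3594L),
    n3 = c(363L, 327L, 1671L, 1326L),
    stringsAsFactors = FALSE
  )
  limbs$n_affected <- limbs$n1 + limbs$n2 + limbs$n3
  combinations <- data.frame(
    combination = c("A", "B", "C", "D", "E", "F", "G"),
    n_affected = c(897L, 3552L, 1363L, 1089L, 1181L, 1204L, 484L),
    stringsAsFactors = FALSE
  )
  list(limbs = limbs, combinations = combinations, n_total = 38825L)
}

#' @rdname pre_reference_counts
#' @details `pre_reference_components()` returns posterior-mean variance
#'   components and heritabilities per limb for the dichotomous threshold
#'   model (`dichotomous`; residual variance fixed at 1 on the liability
#'   scale) and the four-class ordinal model (`ordinal4`).
#' @export
pre_reference_components <- function() {
  dichotomous <- data.frame(
    limb = c("lf", "rf", "lh", "rh"),
    sigma_u2 = c(1.540, 1.945, 1.223, 1.150),
    sigma_m2 = c(0.059, 0.067, 0.043, 0.037),
    sigma_e2 = c(1.000, 1.000, 1.000, 1.000),
    h2 = c(0.591, 0.645, 0.539, 0.525),
    h2_observed = c(0.187, 0.180, 0.515, 0.418),
    stringsAsFactors = FALSE
  )
  ordinal4 <- data.frame(
    limb = c("lf", "rf", "lh", "rh"),
    sigma_u2 = c(4.877, 4.772, 7.904, 5.659),
    sigma_m2 = c(0.185, 0.130, 0.398, 0.273),
    sigma_e2 = c(4.000, 3.420, 8.046, 5.898),
    h2 = c(0.514, 0.539, 0.574, 0.488),
    stringsAsFactors = FALSE
  )
  list(dichotomous = dichotomous, ordinal4 = ordinal4)
}

#' @rdname pre_reference_counts
#' @details `pre_reference_correlations()` returns the posterior-mean
#'   genetic correlation matrix between the four limbs for the requested
#'   model scale. The printed table need not be exactly positive
#'   semidefinite after rounding; consumers that need a valid covariance
#'   matrix should project it (see [nearest_psd_correlation()]).
#' @param scale `"ordinal4"` or `"dichotomous"`.
#' @export
pre_reference_correlations <- function(scale = c("ordinal4", "dichotomous")) {
  scale <- match.arg(scale)
  limbs <- c("lf", "rf", "lh", "rh")
  R <- diag(4)
  dimnames(R) <- list(limbs, limbs)
  fill <- function(R, i, j, v) { R[i, j] <- v; R[j, i] <- v; R }
  if (scale == "ordinal4") {
    R <- fill(R, "lf", "rf", 0.991)
    R <- fill(R, "lf", "lh", 0.907)
    R <- fill(R, "lf", "rh", 0.886)
    R <- fill(R, "rf", "lh", 0.887)
    R <- fill(R, "rf", "rh", 0.863)
    R <- fill(R, "lh", "rh", 0.995)
  } else {
    R <- fill(R, "lf", "rf", 0.988)
    R <- fill(R, "lf", "lh", 0.887)
    R <- fill(R, "lf", "rh", 0.883)
    R <- fill(R, "rf", "lh", 0.866)
    R <- fill(R, "rf", "rh", 0.858)
    R <- fill(R, "lh", "rh", 0.986)
  }
  R
}
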