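#' Limb combinations for symmetry analysis
#'
#' Named list of the multi-limb combinations studied for laterality,
#' symmetry and diagonality: A = both forelegs, B = both hindlegs,
#' C = left legs, D = right legs, E/F = diagonals, G = all four legs.
#' A horse is "affected" on a combination when every listed limb has a
#' nonzero score.
#'
#' @export
limb_combinations <- list(
  A = c("lf", "rf"), B = c("lh", "rh"), C = c("lf", "lh"), D = c("rf", "rh"),
  E = c("lf", "rh"), F = c("rf", "lh"), G = c("lf", "rf", "lh", "rh")
)

.check_scores <- function(data) {
  for (l in LIMBS) {
    bad <- !(data[[l]] %in% 0:3)
    if (any(bad)) {
      stop("score out of range 0..3 for limb ", l, " at row ",
           rownames(data)[which(bad)[1L]])
    }
  }
  invisible(data)
}

# half-up rounding (R's round() is banker's)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-limb score distribution
#'
#' Tabulates, per limb, the number and percentage of unaffected horses
#' (score 0) and of affected horses (score > 0), and the distribution of
#' the affected over the three severity classes (below fetlock, above
#' fetlock, cannon bone). Affected percentages are of the whole dataset;
#' class percentages are of the affected animals only, reported as `NA`
#' when no animal is affected.
#'
#' @param data a `marking_dataset`.
#' @return Data frame with one row per limb: counts `n0, n_affected,
#'   n1, n2, n3` and percentages `pct_affected, pct_unaffected,
#'   pct_class1, pct_class2, pct_class3`.
#' @export
score_distribution <- function(data) {
  .check_scores(data)
  n <- nrow(data)
  out <- do.call(rbind, lapply(LIMBS, function(l) {
    s <- data[[l]]
    cnt <- tabulate(s + 1L, nbins = 4L)
    aff <- sum(cnt[2:4])
    data.frame(limb = l, n = n, n0 = cnt[1L], n_affected = aff,
               n1 = cnt[2L], n2 = cnt[3L], n3 = cnt[4L],
               pct_unaffected = 100 * cnt[1L] / n,
               pct_affected = 100 * aff / n,
               pct_class1 = if (aff > 0) 100 * cnt[2L] / aff else NA_real_,
               pct_class2 = if (aff > 0) 100 * cnt[3L] / aff else NA_real_,
               pct_class3 = if (aff > 0) 100 * cnt[4L] / aff else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combination prevalences
#'
#' For each combination in [limb_combinations], counts horses affected on
#' every listed limb (dichotomized score > 0) and the complement.
#'
#' @param data a `marking_dataset`.
#' @return Data frame with one row per combination: `n_affected`,
#'   `n_unaffected`, `pct_affected`, `pct_unaffected`.
#' @export
combination_prevalence <- function(data) {
  .check_scores(data)
  n <- nrow(data)
  out <- do.call(rbind, lapply(names(limb_combinations), function(cmb) {
    limbs <- limb_combinations[[cmb]]
    aff <- sum(Reduce(`&`, lapply(limbs, function(l) data[[l]] > 0L)))
    data.frame(combination = cmb, n = n, n_affected = aff,
               n_unaffected = n - aff,
               pct_affected = 100 * aff / n,
               pct_unaffected = 100 * (n - aff) / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Prevalence stratified by a systematic factor
#'
#' Per-level, per-limb unaffected and affected percentages for `sex` or
#' `coat`.
#'
#' @param data a `marking_dataset`.
#' @param factor `"sex"` or `"coat"`.
#' @return Data frame with columns `level, limb, n, n_affected,
#'   pct_affected, pct_unaffected`.
#' @export
prevalence_by_factor <- function(data, factor = c("sex", "coat")) {
  factor <- match.arg(factor)
  .check_scores(data)
  known <- if (factor == "sex") c("male", "female") else COATS
  levels_seen <- unique(as.character(data[[factor]]))
  bad <- setdiff(levels_seen, known)
  if (length(bad)) stop("unknown ", factor, " level: ", bad[1L])
  out <- do.call(rbind, lapply(intersect(known, levels_seen), function(lv) {
    sub <- data[data[[factor]] == lv, , drop = FALSE]
    do.call(rbind, lapply(LIMBS, function(l) {
      aff <- sum(sub[[l]] > 0L)
      data.frame(level = lv, limb = l, n = nrow(sub), n_affected = aff,
                 pct_affected = 100 * aff / nrow(sub),
                 pct_unaffected = 100 * (nrow(sub) - aff) / nrow(sub),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Prevalence table from published-style counts
#'
#' Recomputes the percentage columns of a limb/combination count table
#' (such as [pre_reference_counts()]) from its count columns: affected and
#' unaffected as a share of the total, class shares among the affected.
#' Percentages use half-up rounding; tables print 1 decimal, text-style
#' reports 2.
#'
#' @param counts list as returned by [pre_reference_counts()].
#' @param digits decimals for the rounded columns (1 = table style,
#'   2 = text style).
#' @return List of data frames `limbs` and `combinations` with exact and
#'   rounded percentages.
#' @export
prevalence_from_counts <- function(counts, digits = 1) {
  n <- counts$n_total
  lb <- counts$limbs
  lb$pct_affected <- 100 * lb$n_affected / n
  lb$pct_unaffected <- 100 * lb$n0 / n
  lb$pct_class1 <- 100 * lb$n1 / lb$n_affected
  lb$pct_class2 <- 100 * lb$n2 / lb$n_affected
  lb$pct_class3 <- 100 * lb$n3 / lb$n_affected
  cb <- counts$combinations
  cb$pct_affected <- 100 * cb$n_affected / n
  cb$pct_unaffected <- 100 * (n - cb$n_affected) / n
  for (col in grep("^pct_", names(lb), value = TRUE)) {
    lb[[paste0(col, "_r")]] <- round_half_up(lb[[col]], digits)
  }
  for (col in grep("^pct_", names(cb), value = TRUE)) {
    cb[[paste0(col, "_r")]] <- round_half_up(cb[[col]], digits)
  }
  list(limbs = lb, combinations = cb)
}
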