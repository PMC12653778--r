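# Shared fixtures, built in code.

# full-sib mating pedigree: E = C x D with C, D full sibs
fullsib_ped <- function() {
  pedigree_table(c("A", "B", "C", "D", "E"),
                 c(NA, NA, "A", "A", "C"),
                 c(NA, NA, "B", "B", "D"))
}

trio_ped <- function() {
  pedigree_table(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
}

# random pedigree with n animals: founders then random earlier parents
random_ped <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  animal <- sprintf("X%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    sire[i] <- animal[sample.int(i - 1L, 1L)]
    repeat {
      d <- animal[sample.int(i - 1L, 1L)]
      if (d != sire[i]) break
    }
    dam[i] <- d
  }
  pedigree_table(animal, sire, dam)
}

# small marking dataset with given score matrix (4 cols: lf rf lh rh)
scores_dataset <- function(scores, sex = NULL, coat = NULL, F = NULL,
                           dam = NULL) {
  n <- nrow(scores)
  out <- data.frame(
    animal = sprintf("H%03d", seq_len(n)),
    sex = sex %||% rep("female", n),
    coat = coat %||% rep("grey", n),
    F = F %||% rep(0, n),
    dam = dam %||% rep("", n),
    lf = as.integer(scores[, 1]), rf = as.integer(scores[, 2]),
    lh = as.integer(scores[, 3]), rh = as.integer(scores[, 4]),
    stringsAsFactors = FALSE)
  class(out) <- c("marking_dataset", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reduced-scale pre-like simulation shared across model tests
desk_sim <- function(seed, n_founders = 150L, n_generations = 8L,
                     n_matings = 150L, phenotype_generations = 6L) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_matings = n_matings, offspring_per_mating = 2,
                    phenotype_generations = phenotype_generations, seed = seed)
  list(cfg = cfg, data = simulate_marking_data(cfg))
}
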