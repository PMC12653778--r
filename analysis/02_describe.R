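#!/usr/bin/env Rscript
# Stage 2: descriptive prevalence and symmetry tables.
#
# Produces the score distribution per limb (unaffected/affected, class
# shares among the affected), the seven multi-limb combination prevalences
# (bilateral pairs, left/right sides, diagonals, all four), and prevalence
# stratified by sex and coat. Also recomputes the same quantities from the
# published reference counts for side-by-side comparison.
suppressPackageStartupMessages(library(markqg))

dir.create("results", showWarnings = FALSE)
phen <- load_phenotypes("results/phenotypes.csv")

limbs <- score_distribution(phen)
combos <- combination_prevalence(phen)
write.csv(limbs, "results/prevalence_limbs.csv", row.names = FALSE)
write.csv(combos, "results/prevalence_combinations.csv", row.names = FALSE)
write.csv(prevalence_by_factor(phen, "sex"), "results/prevalence_by_sex.csv",
          row.names = FALSE)
write.csv(prevalence_by_factor(phen, "coat"), "results/prevalence_by_coat.csv",
          row.names = FALSE)

ref <- prevalence_from_counts(pre_reference_counts(), digits = 1)
write.csv(ref$limbs, "results/reference_prevalence_limbs.csv", row.names = FALSE)
write.csv(ref$combinations, "results/reference_prevalence_combinations.csv",
          row.names = FALSE)

message("simulated affected % per limb:   ",
        paste(sprintf("%.1f", limbs$pct_affected), collapse = " / "))
message("reference affected % per limb:   ",
        paste(sprintf("%.1f", ref$limbs$pct_affected), collapse = " / "))
message("all-four-legs (G) affected %:    ",
        sprintf("simulated %.2f vs reference %.2f",
                combos$pct_affected[combos$combination == "G"],
                ref$combinations$pct_affected[7]))
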