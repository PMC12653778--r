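#!/usr/bin/env Rscript
# Stage 3: cumulative-logit risk screening per limb.
#
# Fits the Bayesian proportional-odds model with sex, coat and inbreeding
# fixed effects and a dam random intercept to each limb's 0-3 score, and
# retains the effects whose 95% equal-tailed credible interval excludes
# zero. Effects are reported on the latent severity scale (positive =
# more extensive white markings).
suppressPackageStartupMessages(library(markqg))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)
phen <- load_phenotypes("results/phenotypes.csv")

all_screens <- list()
for (limb in c("lf", "rf", "lh", "rh")) {
  fit <- fit_cumulative_logit(phen, limb, iter = 6000, burnin = 1500,
                              thin = 3, seed = seed + match(limb, c("lf", "rf", "lh", "rh")))
  scr <- screen_effects(fit)
  scr$limb <- limb
  all_screens[[limb]] <- scr
  message(sprintf("%s: retained {%s}; dam SD interval %s", limb,
                  paste(scr$effect[scr$retained & scr$effect != "dam_sd"],
                        collapse = ", "),
                  scr$interval[scr$effect == "dam_sd"]))
}
out <- do.call(rbind, all_screens)
write.csv(out, "results/risk_screening.csv", row.names = FALSE)
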