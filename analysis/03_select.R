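#!/usr/bin/env Rscript
# Bayes-factor model selection over the asymmetric candidate set for a
# subset of pairs: bridge-sampling marginal likelihoods, nested-network
# navigation, and the per-pair selection report.

suppressPackageStartupMessages(library(metakin))
dir.create("results", showWarnings = FALSE)

if (file.exists("scratch/population/trajectories.csv")) {
  trajs <- read_trajectories("scratch/population/trajectories.csv")
} else {
  pop <- generate_population(read_generator_config("results/data/config.yaml"))
  trajs <- do.call(c, lapply(pop$cells, `[[`, "pairs"))
}
truth <- read.csv("results/data/ground_truth.csv")
keep <- which(!truth$qc_fail)[1:8]

light <- sampler_config(chains = 2, warmup = 800, draws = 800)
sels <- list()
for (i in keep) {
  tr <- trajs[[i]]
  sel <- select_for_pair(tr, candidates = asym_candidates(), config = light,
                         seed = 500 + i, retry_on_nonconvergence = FALSE)
  sels[[tr$pair_id]] <- sel
  dv <- abs(truth$v_minus_1[i] - truth$v_minus_2[i])
  message(sprintf("%s: preferred %s (generating |dv-| = %.3f um/s)",
                  tr$pair_id, sel$preferred, dv))
}
rep <- selection_report(sels, "results/model_selection.csv")
message(sprintf("%d/%d pairs prefer a sister-asymmetric model",
                sum(sapply(sels, `[[`, "preferred") != "M0"), length(sels)))
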