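#!/usr/bin/env Rscript
# Population-level spatial and temporal analyses on the generated cells:
# radial partitioning of the mechanical parameters, the drag-scaling
# consistency check, the randomised-pairing null for sister asymmetry, the
# two-factor variance decomposition, transverse organisation, and the
# tuning regression toward the anaphase-ready set point.

suppressPackageStartupMessages(library(metakin))
dir.create("results", showWarnings = FALSE)

truth <- read.csv("results/data/ground_truth.csv")
if (file.exists("scratch/population/trajectories.csv")) {
  trajs <- read_trajectories("scratch/population/trajectories.csv")
} else {
  pop <- generate_population(read_generator_config("results/data/config.yaml"))
  trajs <- do.call(c, lapply(pop$cells, `[[`, "pairs"))
}
ok <- !truth$qc_fail
truth <- truth[ok, ]; trajs <- trajs[ok]

## radial organisation -----------------------------------------------------
rp <- radial_partition(truth$r_um, k = 5,
                       pair_ids = paste(truth$cell_id, truth$pair_id))
med_by_group <- do.call(rbind, lapply(1:5, function(g) {
  i <- rp$group == g
  data.frame(group = g, r_max = rp$boundaries[g + 1],
             v_minus = median((truth$v_minus_1[i] + truth$v_minus_2[i]) / 2),
             v_plus = median((truth$v_plus_1[i] + truth$v_plus_2[i]) / 2),
             kappa = median(truth$kappa[i]), alpha = median(truth$alpha[i]),
             tau = median(truth$tau[i]), n = sum(i))
}))
write.csv(med_by_group, "results/radial_medians.csv", row.names = FALSE)
chk <- drag_consistency_check(med_by_group[, c("v_minus", "v_plus", "kappa",
                                               "alpha", "tau")], tol = 0.1)
message("centre-to-periphery changes (fraction): ",
        paste(sprintf("%s %.2f", names(chk$changes), chk$changes),
              collapse = ", "))
message(sprintf("single drag profile %s explain the trends (spread %.2f)",
                if (chk$consistent) "CAN" else "CANNOT", chk$spread))

## sister asymmetry is a continuum ----------------------------------------
nul <- randomized_pairing_null(truth$v_minus_1, truth$v_minus_2, rp$group,
                               n_perm = 200, seed = 11)
message(sprintf("sister vs randomised pairing |dv-|: p_MW = %.3f, p_KS = %.3f",
                nul$p_mw, nul$p_ks))

## variance decomposition --------------------------------------------------
vm_pair <- (truth$v_minus_1 + truth$v_minus_2) / 2
vd <- tryCatch(variance_decomposition(vm_pair, truth$cell_id, rp$group),
               error = function(e) NULL)
if (!is.null(vd)) {
  out <- data.frame(parameter = "v_minus", t(vd$components),
                    cell_over_location = vd$ratio,
                    total_sd_over_mean = vd$total_sd_over_mean, n = vd$n_used)
  write.csv(out, "results/variance_components.csv", row.names = FALSE)
  message(sprintf("v-: between-cell/between-location variance ratio %.2f",
                  vd$ratio))
} else {
  message("variance decomposition skipped (insufficient per-cell coverage)")
}

## transverse organisation -------------------------------------------------
dv <- abs(truth$v_minus_1 - truth$v_minus_2)
calls <- data.frame(pair_id = sapply(trajs, function(p) p$pair_id),
                    asymmetric = dv > quantile(dv, 0.75),
                    stronger = ifelse(abs(truth$v_minus_1) >=
                                        abs(truth$v_minus_2), 1, 2))
org <- transverse_organisation(trajs, calls)
write.csv(org$kt, "results/transverse_organisation.csv", row.names = FALSE)
message(sprintf(paste0("displacement toward own pole (um): stronger %.3f, ",
                       "symmetric %.3f, weaker %.3f"),
                org$medians[["stronger"]], org$medians[["symmetric"]],
                org$medians[["weaker"]]))

## temporal tuning ---------------------------------------------------------
tuned <- truth$tuned
if (sum(tuned) >= 5) {
  reg <- tuning_regression((truth$v_minus_1[tuned] + truth$v_minus_2[tuned]) / 2,
                           truth$v_minus_rate[tuned])
  message(sprintf("anaphase-ready set point v-* = %.4f um/s (s.e. %.4f)",
                  reg$set_point, reg$se_set_point))
  write.csv(data.frame(parameter = "v_minus", a = reg$a, b = reg$b,
                       set_point = reg$set_point, se = reg$se_set_point),
            "results/tuning_regression.csv", row.names = FALSE)
}
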