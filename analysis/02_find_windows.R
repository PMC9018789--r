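# Exhaustive sliding-window search with randomization-based false-positive
# control, one population at a time: all 66,795 windows up to 365 days
# before June 1, weighted linear fits, AICc vs the intercept-only baseline,
# and P_deltaAICc from 100 phenology-to-year permutations.

source("analysis/00_config.R")

sim <- regenerate_study()
phen_all <- study_phenology(sim)

rows <- list()
for (j in seq_len(nrow(sim$truth))) {
  tr <- sim$truth[j, ]
  phen <- phen_all[phen_all$population_id == tr$population_id &
                     phen_all$species == tr$species, ]
  te <- population_temps(sim, tr$population_id)
  res <- randomization_test(phen, te, window_config(), n_rand = 100,
                            seed = MASTER_SEED + j)
  rows[[j]] <- data.frame(
    population_id = tr$population_id, species = tr$species,
    n_years = res$n_years,
    open = res$best$open, close = res$best$close,
    duration = res$best$duration, midpoint_doy = res$best$midpoint_doy,
    slope = res$best$slope, delta_aicc = res$best$delta_aicc,
    p_delta_aicc = res$p_delta_aicc, is_cue = res$is_cue,
    true_midpoint = tr$midpoint_doy)
}
windows <- do.call(rbind, rows)
write_csv_table(windows, file.path(RESULTS_DIR, "window_results.csv"))

n_cue <- sum(windows$is_cue)
cat(sprintf("Temperature cue identified in %d/%d populations (P_deltaAICc <= 0.05, duration > 14 d).\n",
            n_cue, nrow(windows)))
cat(sprintf("All detected slopes negative (earlier laying when warmer): %s.\n",
            all(windows$slope[windows$is_cue] < 0)))
cat(sprintf("Window midpoint recovery: MAE %.1f days vs generating truth.\n",
            mean(abs(windows$midpoint_doy[windows$is_cue] -
                       windows$true_midpoint[windows$is_cue]))))
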