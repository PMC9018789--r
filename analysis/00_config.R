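# Shared configuration for the analysis workflow.
#
# The study is fully synthetic and deterministic given MASTER_SEED: each
# numbered script regenerates the metapopulation from this configuration
# rather than passing multi-megabyte daily temperature tables around.
# All outputs land under results/.

library(phenowin)

MASTER_SEED <- 20260927L
N_POPULATIONS <- 20L

# Study conditions: 40 breeding seasons, 20 first clutches per year with
# 2-day clutch noise, generating sensitivities between 2 and 6 days/C,
# daily temperature from 1949 so exposure can use the standard 1950-2017
# period.
DESIGN <- metapop_design(sensitivity_range = c(2, 6))

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

regenerate_study <- function() {
  simulate_metapopulation(N_POPULATIONS, DESIGN, seed = MASTER_SEED)
}

study_phenology <- function(sim) {
  suppressWarnings(annual_phenology(sim$clutches))
}

population_temps <- function(sim, population_id) {
  sim$temperature[sim$temperature$population_id == population_id, ]
}
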