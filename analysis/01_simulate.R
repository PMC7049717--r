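#!/usr/bin/env Rscript
# Stage 1: generate the synthetic SMT cohort.
#
# A cohort of spherocylindrical cells with lognormal total dimer
# concentrations; each molecule switches between FD/NB/TB states, diffuses
# with the state's D, and is observed stroboscopically (40 ms lapse, 20 nm
# precision) until photobleaching. The per-cell unbinding rate follows the
# biphasic law, so the downstream stages have a known truth to recover.

library(smtkinetics)

cfg <- default_config(seed = 20260926L)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(cfg)
write_tracks(cohort$tracks, "results/data/tracks.csv")
write_cells(cohort$cells, "results/data/cells.csv")
data.table::fwrite(cohort$truth, "results/data/truth.csv")
jsonlite::write_json(cfg, "results/data/config.json", auto_unbox = TRUE)

cat(sprintf("simulated %d cells, %d tracks, %d localizations\n",
            nrow(cohort$cells),
            nrow(unique(cohort$tracks[, c("cell_id", "track_id")])),
            nrow(cohort$tracks)))
cat(sprintf("true concentrations: %.0f-%.0f nM (median %.0f)\n",
            min(cohort$truth$conc_nM), max(cohort$truth$conc_nM),
            median(cohort$truth$conc_nM)))
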