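#!/usr/bin/env Rscript
# Stage 4: residence times, bleaching correction, and the biphasic fit.
#
# Sub-threshold (r < r0 = 0.2 um) runs give per-group residence-time sets;
# the track on-time distribution gives the photobleach/blink rate; the
# three-state dwell model deconvolutes FD/NB passages and corrects for
# bleaching, yielding the apparent unbinding rate constant k_minus1 per
# group, which is then fitted against the free dimer concentration with
# the biphasic (impeded-then-facilitated) rate law.

library(smtkinetics)

cfg <- jsonlite::read_json("results/data/config.json", simplifyVector = TRUE)
tracks <- read_tracks("results/data/tracks.csv")
cells <- data.table::fread("results/cells_quantified.csv")
groups <- data.table::fread("results/groups.tsv")
fr <- data.table::fread("results/fractions.tsv")
dj <- jsonlite::read_json("results/diffusion.json", simplifyVector = TRUE)
D <- unlist(dj$D)

img <- cfg$imaging
track_len <- tracks[, .N, by = c("cell_id", "track_id")]
bleach <- fit_on_times(track_len$N, img$t_lapse,
                       n_boot = cfg$thresholds$n_boot,
                       seed = cfg$seed + 2L)
cat(sprintf("photobleach/blink rate: %.2f +/- %.2f s^-1 (true %.2f)\n",
            bleach$k_bleach, bleach$sd, img$k_bleach))

disp <- merge(displacements(tracks), cells[, c("cell_id", "group")],
              by = "cell_id")
taus <- merge(extract_tau(disp, cfg$thresholds$r0, img$t_lapse),
              cells[, c("cell_id", "group")], by = "cell_id")

k_table <- data.table::rbindlist(lapply(sort(unique(fr$group)), function(g) {
  fg <- unlist(fr[fr$group == g, c("FD", "NB", "TB")])
  dw <- fit_dwell_distribution(taus[taus$group == g], D, fg,
                               bleach$k_bleach, cfg$thresholds$r0,
                               img$t_lapse, img$sigma_loc,
                               n_boot = cfg$thresholds$n_boot,
                               seed = cfg$seed + 10L + g)
  mean_p <- groups$mean_nM[groups$group == g]
  data.table::data.table(group = g, P_cell = mean_p,
                         P_FD = fg[["FD"]] * mean_p,
                         k_minus1 = dw$k_minus1, sd = dw$sd,
                         n_events = dw$n_events)
}))
data.table::fwrite(k_table, "results/k_table.tsv", sep = "\t")
print(k_table)

fit <- fit_unbinding(k_table[, c("P_FD", "k_minus1", "sd")],
                     n_o = cfg$n_o, n_boot = cfg$thresholds$n_boot,
                     seed = cfg$seed + 3L)
print(fit)
jsonlite::write_json(
  list(k_o_off = fit$params$k_o_off, k_r = fit$params$k_r,
       k_f = fit$params$k_f, K_m = fit$params$K_m, sd = as.list(fit$sd),
       P_min_free = fit$P_min, prefers_biphasic = fit$prefers_biphasic,
       k_bleach = bleach$k_bleach),
  "results/unbinding.json", auto_unbox = TRUE, digits = NA)
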