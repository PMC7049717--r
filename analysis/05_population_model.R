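#!/usr/bin/env Rscript
# Stage 5: equilibrium site-binding fit of the state populations.
#
# The per-group FD/NB/TB fractions versus total concentration are fitted
# with the site-depletion mass-action model, giving the tight-site and
# nonspecific-site dissociation constants (K_d1, K_d2) and capacities.
# K_d1 should agree with k_o_off / k_1 from the kinetic route; the ratio
# is reported as a cross-check.

library(smtkinetics)

cfg <- jsonlite::read_json("results/data/config.json", simplifyVector = TRUE)
fr <- data.table::fread("results/fractions.tsv")
ub <- jsonlite::read_json("results/unbinding.json", simplifyVector = TRUE)

fit <- fit_population_model(
  data.frame(P_total = fr$mean_nM, f_FD = fr$FD, f_NB = fr$NB,
             f_TB = fr$TB),
  n_boot = cfg$thresholds$n_boot, seed = cfg$seed + 4L)
print(fit)

truth <- cfg$simulation$equilibrium
cat(sprintf("generating values were K_d1 = %g, K_d2 = %g, D0_NB = %g, D0_TB*n_o = %g\n",
            truth$K_d1, truth$K_d2, truth$D0_NB, truth$D0_TB_no))
cat(sprintf("kinetic/thermodynamic cross-check: k_o_off / K_d1 = %.2f nM^-1 s^-1 (an estimate of k_1)\n",
            ub$k_o_off / fit$model$K_d1))

jsonlite::write_json(
  list(K_d1 = fit$model$K_d1, K_d2 = fit$model$K_d2,
       D0_NB = fit$model$D0_NB, D0_TB_no = fit$model$D0_TB_no,
       sd = as.list(fit$sd), rss = fit$rss,
       k1_implied = ub$k_o_off / fit$model$K_d1),
  "results/population.json", auto_unbox = TRUE, digits = NA)
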