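#!/usr/bin/env Rscript
## The trajectory analysis stack on scripted growth/binding runs.
##
## Three scripted trajectories (front growing at 0.5 A/ns, probe binding at
## 60 ns, growth slowing to 10% afterwards) are generated and pushed through
## the full pipeline: phase classification, front tracking and growth rate,
## solvation census and binding detection, the disulfide torsion series and
## the torsion-hydration map. The desk-scale profile (3 trajectories x 90
## frames x ~580 waters) replaces long production simulations; the point is
## ground-truth recovery, not thermodynamics.

suppressPackageStartupMessages(library(icebindr))
dir.create("results", showWarnings = FALSE)

cfg <- trajectory_config(seeds = 1:3, out_dir = "results/trajectory_run")
res <- run_trajectory_pipeline(cfg)
agg <- res$aggregate

cat(sprintf("Scripted growth rate %.2f A/ns; mean recovered pre-binding rate %.3f A/ns\n",
            agg$scripted_rate, agg$mean_recovered_rate))
cat(sprintf("Scripted binding at %.0f ns; detected at %s ns\n",
            agg$scripted_t_bind, paste(agg$binding_times, collapse = ", ")))

tr1 <- res$trajectories[[1]]
cen <- tr1$census
cat(sprintf("Trajectory 1 shell census: %.1f liquid waters pre-binding; %.1f liquid + %.1f ice-like post-binding\n",
            mean(cen$n_liquid[cen$time < tr1$binding_time_ns]),
            mean(cen$n_liquid[cen$time > tr1$binding_time_ns]),
            mean(cen$n_icelike[cen$time > tr1$binding_time_ns])))
cat("The solvation shell loses liquid waters to the ice front on binding -",
    "the desolvation signature.\n")

## torsion-hydration coupling over the pre-binding window
map <- tr1$map
neg <- sum(map$density[map$phi_mid < 0, ])
cat(sprintf("Torsion-hydration map mass at phi < 0: %.2f (two-conformer schedule)\n", neg))

write.csv(tr1$front, "results/traj1_front_series.csv", row.names = FALSE)
write.csv(tr1$rate, "results/traj1_growth_rate.csv", row.names = FALSE)
cat("wrote results/trajectory_run/* and results/traj1_front_series.csv, results/traj1_growth_rate.csv\n")
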