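#!/usr/bin/env Rscript
# Synthetic umbrella campaigns on the two reference landscapes: biased
# overdamped Langevin trajectories with the full LN and ULN window
# schedules, written as COLVAR files plus window manifests.
#
# The landscapes are desk-scale stand-ins with the shape of the two
# systems' free-energy profiles: a shallow harmonic well
# (k = 0.01 kcal/mol/A^2, minimum 225 A) for linked nucleosomes and a
# steep exponential repulsion wall for unlinked stacked nucleosomes.
#
# Output: results/campaign_ln/, results/campaign_uln/

suppressMessages(library(nuccg))
dir.create("results", showWarnings = FALSE)

seed <- 20260921L

params <- langevin_params(temperature = 303.15, D = 1, dt = 0.01,
                          n_steps = 2e5, save_stride = 20, seed = seed)

t0 <- proc.time()[3]
ln <- generate_campaign(ref_pmf_ln_like(), schedule_ln(), params,
                        dir = "results/campaign_ln")
cat(sprintf("LN campaign: %d windows x %d samples (%.1f s)\n",
            length(ln), length(ln[[1]]$samples), proc.time()[3] - t0))

t0 <- proc.time()[3]
p2 <- params; p2$seed <- seed + 1000L
uln <- generate_campaign(ref_pmf_uln_like(), schedule_uln(), p2,
                         dir = "results/campaign_uln")
cat(sprintf("ULN campaign: %d windows x %d samples (%.1f s)\n",
            length(uln), length(uln[[1]]$samples), proc.time()[3] - t0))

g_ln <- vapply(ln, function(tr) statistical_inefficiency(tr$samples),
               numeric(1))
cat(sprintf("LN statistical inefficiency g: median %.1f (decorrelated samples/window ~ %d)\n",
            median(g_ln), round(length(ln[[1]]$samples) / median(g_ln))))
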