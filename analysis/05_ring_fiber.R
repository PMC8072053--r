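#!/usr/bin/env Rscript
# Langevin dynamics of a covalently closed 100-bead nucleosome fiber
# under the fitted coarse-grained potentials.
#
# Three runs from the same stacked two-start start and seed:
#  (a) exponential repulsion only         - the stacks disperse,
#  (b) + weak Gaussian stacking attraction - stacked contacts persist
#      longer (the histone-tail surrogate),
#  (c) shifted-Coulomb repulsion started inside its near-singular core -
#      the linear-continuation guard logs every entry into the core and
#      the stacks are expelled violently; the bare 1/(d-B) form would
#      overflow here.
#
# Output: results/fiber_*.tsv / .xyz, results/fiber_summary.txt

suppressMessages(library(nuccg))
dir.create("results", showWarnings = FALSE)
lines <- character(0)
say <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n")
  lines <<- c(lines, msg)
}

run_ring <- function(tag, attraction = NULL) {
  sys <- build_ring_fiber(100, 225, geometry = "stacked-zigzag",
                          stack_distance = 60, seed = 70)
  ff <- force_field(harmonic_model(0.01, 225),
                    nonbonded = exponential_model(0.1213, 9.2086),
                    attraction = attraction, cutoff = 400)
  # observation window ~ the 1e4 ps contact-crossing time
  cfg <- sim_config(temperature = 303.15, friction = 1, dt = 10,
                    n_steps = 1000, save_stride = 50, seed = 71)
  tr <- run_langevin(sys$state, sys$topology, ff, cfg)
  rep <- stability_report(tr, sys$topology, ff)
  write_xyz(tr, sprintf("results/fiber_%s.xyz", tag))
  write_observables_tsv(tr, rep, sprintf("results/fiber_%s.tsv", tag))
  rep
}

t0 <- proc.time()[3]
bare <- run_ring("bare")
attr <- run_ring("attraction", attraction = list(eps = 1, r0 = 60, w = 5))
say("paired 100-bead runs, 1000 steps x 10 ps (%.1f s):",
    proc.time()[3] - t0)
say("  bare repulsion:      crashed = %s, stacked contacts %d -> fraction %.2f retained",
    bare$crashed, bare$n_initial_contacts, bare$contact_fraction)
say("  + stacking well:     crashed = %s, stacked contacts %d -> fraction %.2f retained",
    attr$crashed, attr$n_initial_contacts, attr$contact_fraction)
say("  final Rg: %.0f A (bare) vs %.0f A (attraction); start %.0f A",
    tail(bare$rg, 1), tail(attr$rg, 1), bare$rg[1])

## shifted-Coulomb failure mode: a stack spacing of 53 A sits inside the
## continuation region (B + 0.5 = 53.32 A), where the bare 1/(d - B)
## force diverges; every entry into the core is logged
sys <- build_ring_fiber(100, 225, geometry = "stacked-zigzag",
                        stack_distance = 53, seed = 72)
ff_c <- force_field(harmonic_model(0.01, 225),
                    nonbonded = shifted_coulomb_model(39.53, 52.82),
                    cutoff = 400)
cfg <- sim_config(temperature = 303.15, friction = 1, dt = 10,
                  n_steps = 500, save_stride = 50, seed = 73)
tr_c <- run_langevin(sys$state, sys$topology, ff_c, cfg)
rep_c <- stability_report(tr_c, sys$topology, ff_c)
say("shifted-Coulomb ring started at 53 A stacking: %d near-singular continuation events; crashed = %s; stacked contacts -> fraction %.2f retained",
    rep_c$n_clamped, rep_c$crashed, rep_c$contact_fraction)

writeLines(lines, "results/fiber_summary.txt")
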