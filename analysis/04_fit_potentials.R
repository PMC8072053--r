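#!/usr/bin/env Rscript
# Fits the coarse-grained potential forms to the WHAM profiles: a
# harmonic bond term on the linked-nucleosome PMF, and the two repulsive
# forms (exponential, shifted Coulomb) on the unlinked-nucleosome PMF.
#
# Input:  results/pmf_ln.tsv, results/pmf_uln.tsv (from 03)
# Output: results/fits.txt

suppressMessages(library(nuccg))

pmf_ln <- read_pmf_tsv("results/pmf_ln.tsv")
pmf_uln <- read_pmf_tsv("results/pmf_uln.tsv")
lines <- character(0)
say <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n")
  lines <<- c(lines, msg)
}

## bonded term from the LN profile
fh <- fit_harmonic(pmf_ln)
say("harmonic bond: k = %.5f kcal/mol/A^2, d0 = %.2f A (window %.1f-%.1f A, rms %.3f)",
    fh$model$k, fh$model$d0, fh$report$fit_window[1],
    fh$report$fit_window[2], fh$report$rms)

## the reduced mass implied by pairing this curvature with a 2.41e9 1/s
## bond vibration; an order of magnitude below a nucleosome-pair reduced
## mass, so the frequency is reported as descriptive only
mu_imp <- implied_reduced_mass(fh$model$k, 2.41e9)
say("implied reduced mass for nu = 2.41e9 1/s at fitted k: %.3g Da (nucleosome pair ~ 1e5 Da)",
    mu_imp)
say("bond vibration at mu = 1e5 Da: nu = %.3g 1/s",
    vibrational_frequency(fh$model, 1e5))

## repulsive terms from the ULN profile; the flat tail defines the zero,
## so re-reference to the mean of the last 10 well-sampled bins
occ <- which(pmf_uln$occupied & pmf_uln$n_eff >= 50)
tail_bins <- utils::tail(occ, 10)
shift <- mean(pmf_uln$F[tail_bins])
uln <- pmf_profile(pmf_uln$d, pmf_uln$F - shift, pmf_uln$temperature,
                   F_err = pmf_uln$F_err, n_eff = pmf_uln$n_eff,
                   anchor = FALSE)
win <- c(55, 85)
fe <- fit_exponential(uln, fit_window = win)
say("exponential repulsion: alpha = %.4f 1/A, beta = %.4f (window %g-%g A, rms %.3f)",
    fe$model$alpha, fe$model$beta, win[1], win[2], fe$report$rms)
fc <- fit_shifted_coulomb(uln, fit_window = win)
say("shifted Coulomb repulsion: A = %.2f kcal/mol*A, B = %.2f A (window %g-%g A, rms %.3f)",
    fc$model$A, fc$model$B, win[1], win[2], fc$report$rms)

say("exponential vs shifted-Coulomb discrepancy over 60-90 A: RMS %.3f kcal/mol",
    model_consistency(fe$model, fc$model, c(60, 90)))

writeLines(lines, "results/fits.txt")
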