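# Independent multistate-reweighting (MBAR-style) free-energy estimator,
# used as a cross-check oracle for the WHAM path. Works on the unbinned
# pooled samples via the self-consistent equations
#   f_k = -log sum_n exp(-u_k(x_n)) / sum_j N_j exp(f_j - u_j(x_n)),
# then bins the unbiased sample weights on the WHAM grid. Deliberately
# shares no code with wham_solve().
mbar_pmf <- function(trajs, temperature, edges, tol = 1e-11,
                     max_iter = 5e4) {
  kt <- kbt(temperature)
  x <- unlist(lapply(trajs, `[[`, "samples"))
  N <- vapply(trajs, function(tr) length(tr$samples), numeric(1))
  K <- length(trajs)
  U <- t(vapply(trajs, function(tr) bias_energy(x, tr$bias) / kt,
                numeric(length(x))))           # K x Ntot, reduced units
  f <- rep(0, K)
  for (it in seq_len(max_iter)) {
    denom <- colSums(N * exp(f - U))           # length Ntot
    f_new <- -log(as.vector(exp(-U) %*% (1 / denom)))
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  w <- 1 / colSums(N * exp(f - U))
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= length(edges) - 1
  wsum <- vapply(seq_len(length(edges) - 1),
                 function(b) sum(w[inside & bin == b]), numeric(1))
  F <- ifelse(wsum > 0, -kt * log(wsum), NA_real_)
  F - min(F, na.rm = TRUE)
}
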