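# Histogramming, WHAM self-consistency, bootstrap, diagnostics.

test_that("histograms conserve samples and report out-of-range counts", {
  b <- bias_spec(10, 1)
  tr1 <- biased_trajectory(rep(10, 100), b)
  h1 <- build_histograms(list(tr1), bin_width = 0.5)
  expect_equal(sum(h1$counts == 100), 1)
  expect_equal(sum(h1$counts), 100)

  set.seed(4)
  tr2 <- biased_trajectory(runif(500, 5, 15), b)
  h2 <- build_histograms(list(tr1, tr2), bin_width = 0.5, range = c(8, 12))
  expect_equal(rowSums(h2$counts) + h2$out_of_range,
               c(100, 500), ignore_attr = TRUE)
  h3 <- build_histograms(list(tr1, tr2), bin_width = 0.25, range = c(8, 12))
  expect_equal(rowSums(h3$counts), rowSums(h2$counts))
  expect_error(build_histograms(list(tr1), range = c(50, 60)), "outside")
})

test_that("single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(8)
  x <- rnorm(20000, mean = 30, sd = 2)
  tr <- biased_trajectory(x, bias_spec(30, 0))
  h <- build_histograms(list(tr), bin_width = 0.5, range = c(22, 38))
  pmf <- wham_solve(h, temperature = 303.15)
  counts <- h$counts[1, ]
  direct <- -kbt(303.15) * log(counts / sum(counts))
  direct <- direct - min(direct[counts > 0])
  expect_equal(pmf$F[pmf$occupied], direct[counts > 0], tolerance = 1e-9)
})

test_that("overlapping windows on a flat landscape recover a flat profile", {
  ref <- ref_pmf_flat(c(0, 60))
  trajs <- toy_campaign(ref, centers = c(28, 32), k_kj = 2,
                        n_steps = 4e5, seed = 21)
  pmf <- bootstrap_pmf(trajs, n_boot = 20, seed = 22, bin_width = 0.5)
  sel <- pmf$occupied & pmf$n_eff > 50
  spread <- pmf$F[sel] - mean(pmf$F[sel])
  expect_true(all(abs(spread) <= 2 * pmax(pmf$F_err[sel], 0.02)))
})

test_that("WHAM is gauge-invariant to per-window bias offsets", {
  ref <- ref_pmf_ln_like()
  trajs <- toy_campaign(ref, centers = seq(215, 235, by = 5), k_kj = 1,
                        n_steps = 4e4, seed = 31)
  h <- build_histograms(trajs, bin_width = 0.5)
  W <- t(vapply(h$biases, function(b) bias_energy(h$centers, b),
                numeric(length(h$centers))))
  p1 <- wham_solve(h, temperature = 303.15, bias_matrix = W)
  W2 <- W
  W2[2, ] <- W2[2, ] + 3.7   # constant added to one window's bias
  p2 <- wham_solve(h, temperature = 303.15, bias_matrix = W2)
  expect_equal(p1$F, p2$F, tolerance = 1e-6)
})

test_that("the WHAM residual is non-increasing over the final iterations", {
  ref <- ref_pmf_ln_like()
  trajs <- toy_campaign(ref, centers = seq(218, 232, by = 7), k_kj = 1,
                        n_steps = 4e4, seed = 61)
  pmf <- wham_solve(build_histograms(trajs), temperature = 303.15)
  trace <- pmf$meta$residual_trace
  expect_true(all(diff(trace) <= 1e-15))
  expect_true(pmf$meta$converged)
})

test_that("bootstrap uncertainties: deterministic, near zero for degenerate data, shrinking with sampling", {
  # degenerate: every window a point mass
  degen <- lapply(1:3, function(i)
    biased_trajectory(rep(20 + i, 200), bias_spec(20 + i, 1),
                      window_id = i))
  pd <- bootstrap_pmf(degen, n_boot = 10, seed = 1, bin_width = 1)
  expect_true(all(pd$F_err[is.finite(pd$F_err)] < 1e-12))

  # exact (uncorrelated) Boltzmann window samples isolate the estimator:
  # quadrupling every window's sample count must shrink the uncertainty
  make_iid <- function(n, seed) {
    set.seed(seed)
    centers <- seq(20, 32, by = 3)
    lapply(seq_along(centers), function(i) {
      b <- bias_spec(centers[i], 1)
      biased_trajectory(rnorm(n, centers[i], sqrt(kbt(303.15) / b$k)),
                        b, window_id = i)
    })
  }
  ps1 <- bootstrap_pmf(make_iid(500, 1), n_boot = 25, seed = 5)
  ps1b <- bootstrap_pmf(make_iid(500, 1), n_boot = 25, seed = 5)
  expect_identical(ps1$F_err, ps1b$F_err)
  pb <- bootstrap_pmf(make_iid(2000, 1), n_boot = 25, seed = 5)
  sel_s <- ps1$occupied & ps1$n_eff >= 20
  sel_b <- pb$occupied & pb$n_eff >= 80
  expect_lt(mean(pb$F_err[sel_b], na.rm = TRUE),
            mean(ps1$F_err[sel_s], na.rm = TRUE))
})

test_that("overlap matrix is a symmetric [0,1] overlap fraction", {
  b <- bias_spec(10, 1)
  t1 <- biased_trajectory(c(1, 1, 2, 2), b)
  t2 <- biased_trajectory(c(1, 1, 2, 2), b, window_id = 2)
  t3 <- biased_trajectory(c(8, 8, 9, 9), bias_spec(8, 1), window_id = 3)
  h <- build_histograms(list(t1, t2, t3), bin_width = 1, range = c(0, 10))
  ov <- overlap_matrix(h)$overlap
  expect_equal(ov[1, 2], 1)
  expect_equal(ov[1, 3], 0)
  expect_equal(ov, t(ov))
  expect_true(all(ov >= 0 & ov <= 1))
  expect_true(all(diag(ov) == 1))

  # adjacent-overlap diagnostic flags the gap
  lowov <- overlap_matrix(h)
  expect_true(length(lowov$adjacent_low) >= 1)
})

test_that("radial Jacobian correction follows its closed form and round-trips", {
  d <- seq(50, 90, by = 1)
  flat <- pmf_profile(d, rep(1, length(d)), temperature = 303.15)
  expect_identical(jacobian_correction(flat, "none")$F, flat$F)
  corr <- jacobian_correction(flat, "radial")
  kt <- kbt(303.15)
  expected <- 2 * kt * log(d)
  expect_equal(corr$F, expected - min(expected), tolerance = 1e-12)
  # subtracting the analytic term recovers the original up to anchoring
  back <- corr$F - 2 * kt * log(d)
  expect_equal(back - min(back), flat$F - min(flat$F), tolerance = 1e-12)
})

test_that("statistical inefficiency reflects series correlation", {
  set.seed(12)
  white <- rnorm(5000)
  expect_equal(statistical_inefficiency(white), 1, tolerance = 0.25)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  # AR(1) with phi = 0.9 has g = (1+phi)/(1-phi) = 19
  expect_gt(statistical_inefficiency(ar), 8)
  expect_equal(statistical_inefficiency(rep(3, 100)), 1)
})

test_that("PMF TSV files round-trip", {
  ref <- ref_pmf_ln_like()
  trajs <- toy_campaign(ref, centers = c(222, 226), n_steps = 2e4,
                        seed = 91)
  pmf <- bootstrap_pmf(trajs, n_boot = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf_tsv(pmf, path)
  back <- read_pmf_tsv(path)
  expect_equal(back$d, pmf$d)
  expect_equal(back$F, pmf$F)
  expect_equal(back$F_err, pmf$F_err)
})
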