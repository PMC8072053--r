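# Fitting the three coarse-grained potential forms and derived quantities.

lit_pars <- list(harm = c(k = 0.01, d0 = 225.0),
                   expo = c(alpha = 0.1213, beta = 9.2086),
                   coul = c(A = 39.53, B = 52.82))

test_that("harmonic fit round-trips exactly and ignores anchoring", {
  d <- seq(200, 250, by = 1)
  truth <- harmonic_model(lit_pars$harm["k"], lit_pars$harm["d0"])
  F <- eval_potential(truth, d)
  pmf <- pmf_profile(d, F, temperature = 303.15)
  fit <- fit_harmonic(pmf, fit_window = c(200, 250))
  expect_equal(fit$model$k, 0.01, tolerance = 1e-9)
  expect_equal(fit$model$d0, 225.0, tolerance = 1e-9)
  expect_lt(fit$report$rms, 1e-10)
  # adding a constant changes nothing (pmf_profile re-anchors, and the
  # fit itself absorbs any remaining constant)
  fit2 <- fit_harmonic(pmf_profile(d, F + 12.3, temperature = 303.15),
                       fit_window = c(200, 250))
  expect_equal(fit2$model$k, fit$model$k, tolerance = 1e-9)
  expect_equal(fit2$model$d0, fit$model$d0, tolerance = 1e-9)
  # curvature equals the second central difference at the minimum
  i0 <- which(d == 225)
  k_fd <- (F[i0 + 1] - 2 * F[i0] + F[i0 - 1]) / 1^2
  expect_equal(fit$model$k, k_fd, tolerance = 1e-9)
})

test_that("harmonic fit under Gaussian noise recovers k within 10% and d0 within 1 A", {
  d <- seq(205, 245, by = 1)
  truth <- harmonic_model(0.01, 225)
  F <- eval_potential(truth, d)
  set.seed(314)
  ok <- vapply(1:60, function(rep) {
    noisy <- pmf_profile(d, F + rnorm(length(d), sd = 0.05),
                         temperature = 303.15)
    fit <- tryCatch(fit_harmonic(noisy, fit_window = c(205, 245)),
                    error = function(e) NULL)
    !is.null(fit) && abs(fit$model$k - 0.01) / 0.01 < 0.1 &&
      abs(fit$model$d0 - 225) < 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("exponential fit recovers its generating parameters to 4 significant figures", {
  d <- seq(55, 90, by = 0.5)
  truth <- exponential_model(lit_pars$expo["alpha"],
                             lit_pars$expo["beta"])
  # tail-referenced profile: the generating curve decays to zero at
  # large d, so it is kept unanchored rather than min-shifted
  pmf <- pmf_profile(d, eval_potential(truth, d), temperature = 303.15,
                     anchor = FALSE)
  fit <- fit_exponential(pmf, fit_window = c(55, 90))
  expect_equal(fit$model$alpha, 0.1213, tolerance = 5e-5)
  expect_equal(fit$model$beta, 9.2086, tolerance = 5e-5)
  # algebraic identity: V(beta/alpha) = exp(0) = 1 kcal/mol
  expect_equal(eval_potential(fit$model, fit$model$beta / fit$model$alpha),
               1, tolerance = 1e-6)
  expect_equal(9.2086 / 0.1213, 75.92, tolerance = 1e-4)
  # doubling alpha halves the e-fold decay distance
  m2 <- exponential_model(2 * 0.1213, 9.2086)
  efold <- function(m) 1 / unname(m$alpha)
  expect_equal(efold(m2), efold(truth) / 2)
})

test_that("shifted-Coulomb fit recovers its generating parameters to 4 significant figures", {
  d <- seq(55, 90, by = 0.5)
  truth <- shifted_coulomb_model(lit_pars$coul["A"],
                                 lit_pars$coul["B"])
  pmf <- pmf_profile(d, eval_potential(truth, d), temperature = 303.15,
                     anchor = FALSE)
  fit <- fit_shifted_coulomb(pmf, fit_window = c(55, 90))
  expect_equal(fit$model$A, 39.53, tolerance = 1e-4)
  expect_equal(fit$model$B, 52.82, tolerance = 1e-4)
  # V(B + A * 1A/(1 kcal/mol)) = 1 kcal/mol
  expect_equal(eval_potential(fit$model, fit$model$B + fit$model$A), 1)
  # strictly decreasing and convex beyond the singularity
  v <- eval_potential(truth, seq(53.5, 100, by = 0.5))
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(diff(v)) > 0))
  expect_error(eval_potential(truth, 52), "singular")
})

test_that("fitters reject ill-posed inputs", {
  d <- seq(60, 90, by = 1)
  down <- pmf_profile(d, (90 - d) * 0.1, temperature = 303.15)
  expect_error(fit_harmonic(down, fit_window = c(60, 90)),
               "minimum|curvature")
  withneg <- pmf_profile(d, (75 - d) * 0.1, temperature = 303.15,
                         anchor = FALSE)   # contains negatives
  expect_error(fit_exponential(withneg, fit_window = c(60, 90)),
               "positive")
})

test_that("vibrational frequency scales as sqrt(k/mu) and inverts consistently", {
  m <- harmonic_model(0.01, 225)
  mu <- 1e5
  nu <- vibrational_frequency(m, mu)
  expect_equal(vibrational_frequency(harmonic_model(0.04, 225), mu),
               2 * nu)
  expect_equal(vibrational_frequency(m, 4 * mu), nu / 2)
  # closed-form inversion round-trips
  mu_imp <- implied_reduced_mass(0.01, 2.41e9)
  expect_equal(vibrational_frequency(m, mu_imp), 2.41e9, tolerance = 1e-9)
  # the implied mass is ~1.8e4 Da, far below a nucleosome-pair reduced
  # mass, which is why the frequency is descriptive only
  expect_equal(mu_imp, 1.8e4, tolerance = 0.05)
})

test_that("model consistency is a symmetric RMS discrepancy", {
  e <- exponential_model(0.1213, 9.2086)
  c <- shifted_coulomb_model(39.53, 52.82)
  expect_equal(model_consistency(e, e, c(60, 90)), 0)
  expect_equal(model_consistency(e, c, c(60, 90)),
               model_consistency(c, e, c(60, 90)))
  rms <- model_consistency(e, c, c(60, 90))
  expect_true(is.finite(rms) && rms > 0)
  expect_error(model_consistency(e, c, c(50, 90)), "singular")
})
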