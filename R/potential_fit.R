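## Coarse-grained potential forms fitted to a PMF profile: a harmonic bond
## term for linked nucleosomes and two repulsive forms (exponential and
## shifted Coulomb) for the nonbonded stacked-pair interaction.

#' Coarse-grained potential models
#'
#' Three functional forms:
#' * harmonic: V(d) = 1/2 k (d - d0)^2, the bonded term between
#'   linker-connected beads;
#' * exponential: V(d) = exp(beta - alpha d), a soft repulsive wall
#'   (the adopted algebraic reading is recorded on the model as
#'   `sign_convention`);
#' * shifted Coulomb: V(d) = A / (d - B), a screened-repulsion form
#'   singular at d = B.
#'
#' @param k curvature, kcal/mol/A^2 (> 0)
#' @param d0 equilibrium distance, Angstrom
#' @return an object of classes `c("<form>_model", "potential_model")`
#' @export
harmonic_model <- function(k, d0) {
  stopifnot(k > 0)
  structure(list(k = k, d0 = d0, form = "harmonic"),
            class = c("harmonic_model", "potential_model"))
}

#' @rdname harmonic_model
#' @param alpha decay constant, 1/A (> 0)
#' @param beta dimensionless offset
#' @param sign_convention algebraic reading of the exponential form;
#'   `"exp(beta-alpha*d)"` (default) or `"exp(-alpha*d-beta)"`
#' @export
exponential_model <- function(alpha, beta,
                              sign_convention = c("exp(beta-alpha*d)",
                                                  "exp(-alpha*d-beta)")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, beta = beta,
                 sign_convention = sign_convention, form = "exponential"),
            class = c("exponential_model", "potential_model"))
}

#' @rdname harmonic_model
#' @param A strength, kcal/mol*A (> 0)
#' @param B distance shift, Angstrom; evaluation requires d > B
#' @export
shifted_coulomb_model <- function(A, B) {
  stopifnot(A > 0)
  structure(list(A = A, B = B, form = "shifted_coulomb"),
            class = c("shifted_coulomb_model", "potential_model"))
}

#' Evaluate a coarse-grained potential model
#'
#' @param model a `potential_model`
#' @param d distances (Angstrom)
#' @return V(d) in kcal/mol
#' @export
eval_potential <- function(model, d) UseMethod("eval_potential")

#' @export
eval_potential.harmonic_model <- function(model, d) {
  0.5 * model$k * (d - model$d0)^2
}

#' @export
eval_potential.exponential_model <- function(model, d) {
  if (model$sign_convention == "exp(beta-alpha*d)") {
    exp(model$beta - model$alpha * d)
  } else {
    exp(-model$alpha * d - model$beta)
  }
}

#' @export
eval_potential.shifted_coulomb_model <- function(model, d) {
  if (any(d <= model$B)) {
    stop("shifted-Coulomb potential is singular at d <= B = ", model$B)
  }
  model$A / (d - model$B)
}

#' @export
print.potential_model <- function(x, ...) {
  pars <- x[setdiff(names(x), c("form", "sign_convention"))]
  cat(sprintf("%s potential: %s\n", x$form,
              paste(names(pars), signif(unlist(pars), 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

fit_report <- function(model, fit_window, resid, se) {
  structure(list(model = model, fit_window = fit_window,
                 rms = sqrt(mean(resid^2)), stderr = se),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  print(x$model)
  cat(sprintf("  fit window: [%g, %g] A; residual RMS %.4g kcal/mol\n",
              x$fit_window[1], x$fit_window[2], x$rms))
  invisible(x)
}

## occupied (d, F, w) triples of a PMF restricted to a window; weights
## 1/sigma^2 when bootstrap uncertainties exist, unweighted otherwise.
pmf_fit_data <- function(pmf, fit_window) {
  stopifnot(inherits(pmf, "pmf_profile"))
  sel <- pmf$occupied & pmf$d >= fit_window[1] & pmf$d <= fit_window[2]
  d <- pmf$d[sel]; F <- pmf$F[sel]
  w <- rep(1, length(d))
  if (!is.null(pmf$F_err)) {
    e <- pmf$F_err[sel]
    ok <- is.finite(e) & e > 0
    if (all(ok)) w <- 1 / e^2
  }
  list(d = d, F = F, w = w)
}

#' Fit a harmonic potential around a PMF minimum
#'
#' Weighted least squares of 1/2 k (d - d0)^2 + c against F(d); the
#' constant c absorbs the anchoring convention, so the fit is invariant to
#' adding any constant to the PMF. The default fit window is all occupied
#' bins within 2 kcal/mol of the minimum; bins holding fewer than 5
#' samples are ignored when locating that window, so a stray outlier bin
#' at the profile edge cannot masquerade as the minimum.
#'
#' @param pmf a [pmf_profile()]
#' @param fit_window `c(lo, hi)` in Angstrom, or NULL for the default
#' @return list with `model` ([harmonic_model()]) and `report`
#' @export
fit_harmonic <- function(pmf, fit_window = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(fit_window)) {
    occ <- which(pmf$occupied)
    if (!is.null(pmf$n_eff)) occ <- occ[pmf$n_eff[occ] >= 5]
    near <- occ[pmf$F[occ] <= min(pmf$F[occ]) + 2]
    fit_window <- range(pmf$d[near])
  }
  dat <- pmf_fit_data(pmf, fit_window)
  if (length(dat$d) < 5) stop("fit window holds fewer than 5 occupied bins")
  imin <- which.min(dat$F)
  if (imin == 1 || imin == length(dat$F)) {
    stop("no interior minimum inside the harmonic fit window")
  }
  fit <- stats::lm(F ~ d + I(d^2), data = dat, weights = dat$w)
  cf <- stats::coef(fit)
  if (!is.finite(cf[3]) || cf[3] <= 0) {
    stop("fit window has no positive curvature")
  }
  k <- 2 * cf[[3]]
  d0 <- -cf[[2]] / (2 * cf[[3]])
  ## delta-method standard errors on (k, d0)
  vc <- stats::vcov(fit)
  se_k <- 2 * sqrt(vc[3, 3])
  gr <- c(-1 / (2 * cf[[3]]), cf[[2]] / (2 * cf[[3]]^2))
  se_d0 <- sqrt(drop(t(gr) %*% vc[2:3, 2:3] %*% gr))
  model <- harmonic_model(k, d0)
  resid <- stats::residuals(fit)
  list(model = model,
       report = fit_report(model, fit_window, resid,
                           c(k = se_k, d0 = se_d0)))
}

#' Fit an exponential repulsion to a PMF
#'
#' Nonlinear least squares of V(d) = exp(beta - alpha d) against F over
#' the fit window; F must be strictly positive there (anchor the flat tail
#' at zero first). Starting values come from the log-linear regression
#' log F = beta - alpha d.
#'
#' @param pmf a [pmf_profile()]
#' @param fit_window `c(lo, hi)` in Angstrom (default: occupied range)
#' @return list with `model` ([exponential_model()]) and `report`
#' @export
fit_exponential <- function(pmf, fit_window = NULL) {
  if (is.null(fit_window)) fit_window <- range(pmf$d[pmf$occupied])
  dat <- pmf_fit_data(pmf, fit_window)
  if (length(dat$d) < 3) stop("fit window holds fewer than 3 occupied bins")
  if (any(dat$F <= 0)) {
    stop("exponential fit requires strictly positive F over the window; ",
         "re-anchor the tail to zero first")
  }
  lin <- stats::lm(log(F) ~ d, data = dat, weights = dat$w * dat$F^2)
  start <- list(alpha = -stats::coef(lin)[[2]], beta = stats::coef(lin)[[1]])
  if (start$alpha <= 0) start$alpha <- 0.1
  fit <- minpack.lm::nlsLM(F ~ exp(beta - alpha * d), data = dat,
                           start = start, weights = dat$w,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(alpha = NA, beta = NA))
  model <- exponential_model(cf[["alpha"]], cf[["beta"]])
  list(model = model,
       report = fit_report(model, fit_window, stats::residuals(fit), se))
}

#' Fit a shifted-Coulomb repulsion to a PMF
#'
#' Nonlinear least squares of V(d) = A / (d - B) against F over the fit
#' window; every distance in the window must exceed the singularity B.
#' Starting values come from the linearization 1/F = (d - B)/A.
#'
#' @param pmf a [pmf_profile()]
#' @param fit_window `c(lo, hi)` in Angstrom (default: occupied range)
#' @return list with `model` ([shifted_coulomb_model()]) and `report`
#' @export
fit_shifted_coulomb <- function(pmf, fit_window = NULL) {
  if (is.null(fit_window)) fit_window <- range(pmf$d[pmf$occupied])
  dat <- pmf_fit_data(pmf, fit_window)
  if (length(dat$d) < 3) stop("fit window holds fewer than 3 occupied bins")
  if (any(dat$F <= 0)) {
    stop("shifted-Coulomb fit requires strictly positive F over the window")
  }
  lin <- stats::lm(I(1 / F) ~ d, data = dat)
  A0 <- 1 / stats::coef(lin)[[2]]
  B0 <- -stats::coef(lin)[[1]] * A0
  if (!is.finite(A0) || A0 <= 0) { A0 <- 40; B0 <- min(dat$d) - 10 }
  B0 <- min(B0, min(dat$d) - 0.5)
  fit <- minpack.lm::nlsLM(F ~ A / (d - B), data = dat,
                           start = list(A = A0, B = B0), weights = dat$w,
                           upper = c(A = Inf, B = min(dat$d) - 1e-6),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  cf <- stats::coef(fit)
  if (any(dat$d <= cf[["B"]])) {
    stop("fitted singularity lies inside the fit window")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A = NA, B = NA))
  model <- shifted_coulomb_model(cf[["A"]], cf[["B"]])
  list(model = model,
       report = fit_report(model, fit_window, stats::residuals(fit), se))
}

#' Harmonic vibrational frequency of a bonded bead pair
#'
#' nu = (1/2 pi) sqrt(k / mu) with k converted from kcal/mol/A^2 to J/m^2
#' per molecule and the reduced mass from Dalton to kg.
#'
#' @param model a [harmonic_model()]
#' @param reduced_mass reduced mass in Da (> 0)
#' @return frequency in 1/s
#' @export
vibrational_frequency <- function(model, reduced_mass) {
  stopifnot(inherits(model, "harmonic_model"), reduced_mass > 0)
  k_si <- model$k * 4184 / N_AVOGADRO * 1e20   # J/m^2 per molecule
  mu_si <- reduced_mass * DA_KG
  sqrt(k_si / mu_si) / (2 * pi)
}

#' Reduced mass implied by a (curvature, frequency) pair
#'
#' Inverts nu = (1/2 pi) sqrt(k/mu): mu = k / (2 pi nu)^2. For the
#' reported pair k = 0.01 kcal/mol/A^2 and nu = 2.41e9 1/s this gives
#' ~1.8e4 Da, an order of magnitude below the reduced mass of a
#' two-nucleosome pair (~1e5 Da), so the frequency is treated as
#' descriptive rather than as a constraint on the bead mass.
#'
#' @param k curvature in kcal/mol/A^2
#' @param nu frequency in 1/s
#' @return reduced mass in Da
#' @export
implied_reduced_mass <- function(k, nu) {
  stopifnot(k > 0, nu > 0)
  k_si <- k * 4184 / N_AVOGADRO * 1e20
  k_si / (2 * pi * nu)^2 / DA_KG
}

#' RMS discrepancy between two potential models over a range
#'
#' Both models are evaluated on a uniform grid and the root-mean-square
#' of their difference is returned; errors if either model is singular
#' inside the range.
#'
#' @param m1,m2 `potential_model` objects
#' @param range `c(lo, hi)` in Angstrom
#' @param n grid size (default 201)
#' @return RMS discrepancy in kcal/mol
#' @export
model_consistency <- function(m1, m2, range, n = 201) {
  stopifnot(length(range) == 2, range[1] < range[2], n >= 2)
  d <- seq(range[1], range[2], length.out = n)
  v1 <- eval_potential(m1, d)
  v2 <- eval_potential(m2, d)
  if (!all(is.finite(v1)) || !all(is.finite(v2))) {
    stop("model evaluation is singular inside the comparison range")
  }
  sqrt(mean((v1 - v2)^2))
}
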