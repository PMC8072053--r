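## Reference free-energy landscapes used by the synthetic-trajectory
## generator. These stand in for the converged atomistic landscapes: a
## harmonic well for a linked-nucleosome-like coordinate and a steep
## repulsive wall with a flat tail for an unlinked (stacked) pair.

#' Construct a reference potential of mean force
#'
#' A reference PMF is a smooth free-energy curve F(d) over a finite
#' distance domain, used as the known ground truth when generating
#' synthetic biased trajectories and when validating WHAM recovery.
#'
#' @param fun function of d (Angstrom) returning free energy (kcal/mol);
#'   must be vectorized and finite on the domain
#' @param domain numeric length-2, valid distance range in Angstrom
#' @param label short name for reports
#' @param grad optional analytic gradient dF/dd; when absent, gradients are
#'   taken by central finite differences with step 0.01 Angstrom
#' @return an object of class `reference_pmf`
#' @export
reference_pmf <- function(fun, domain, label = "custom", grad = NULL) {
  stopifnot(is.function(fun), length(domain) == 2, domain[1] < domain[2])
  probe <- suppressWarnings(fun(seq(domain[1], domain[2],
                                    length.out = 257)))
  if (!all(is.finite(probe))) {
    stop("reference PMF is not finite everywhere on its domain")
  }
  structure(list(fun = fun, domain = as.numeric(domain), label = label,
                 grad = grad),
            class = "reference_pmf")
}

#' Harmonic-well reference landscape (linked-nucleosome-like)
#'
#' F(d) = 1/2 k (d - d0)^2: a single interior minimum, the shape of the
#' free-energy profile of two nucleosomes tethered by linker DNA near its
#' equilibrium separation.
#'
#' @param k curvature in kcal/mol/A^2 (default 0.01)
#' @param d0 minimum position in Angstrom (default 225)
#' @param domain distance range in Angstrom
#' @return a `reference_pmf`
#' @export
ref_pmf_ln_like <- function(k = 0.01, d0 = 225, domain = c(165, 260)) {
  stopifnot(k > 0, d0 > domain[1], d0 < domain[2])
  reference_pmf(function(d) 0.5 * k * (d - d0)^2, domain,
                label = "LN-like",
                grad = function(d) k * (d - d0))
}

#' Repulsive-wall reference landscape (unlinked-nucleosome-like)
#'
#' F(d) = exp(beta - alpha*d): strictly decreasing, a steep kcal-scale wall
#' below ~70 A decaying to a flat tail, the shape of the profile of two
#' free stacked nucleosomes whose interaction is dominated by
#' electrostatic repulsion (no histone tails).
#'
#' @param alpha decay constant in 1/A (default 0.1213)
#' @param beta dimensionless offset (default 9.2086)
#' @param domain distance range in Angstrom
#' @return a `reference_pmf`
#' @export
ref_pmf_uln_like <- function(alpha = 0.1213, beta = 9.2086,
                             domain = c(50, 100)) {
  stopifnot(alpha > 0)
  reference_pmf(function(d) exp(beta - alpha * d), domain,
                label = "ULN-like",
                grad = function(d) -alpha * exp(beta - alpha * d))
}

#' Flat reference landscape
#'
#' F(d) = 0 everywhere; used for free-diffusion and pure-bias checks.
#'
#' @param domain distance range in Angstrom
#' @return a `reference_pmf`
#' @export
ref_pmf_flat <- function(domain = c(0, 100)) {
  reference_pmf(function(d) rep(0, length(d)), domain, label = "flat",
                grad = function(d) rep(0, length(d)))
}

#' Evaluate a reference PMF
#' @param ref a `reference_pmf`
#' @param d distances (Angstrom)
#' @return free energies (kcal/mol)
#' @export
ref_value <- function(ref, d) {
  stopifnot(inherits(ref, "reference_pmf"))
  ref$fun(d)
}

#' Gradient of a reference PMF
#'
#' Analytic when the preset provides one, otherwise a central finite
#' difference with h = 0.01 Angstrom (one-sided at the domain edges).
#'
#' @param ref a `reference_pmf`
#' @param d distances (Angstrom)
#' @return dF/dd (kcal/mol/A)
#' @export
ref_grad <- function(ref, d) {
  stopifnot(inherits(ref, "reference_pmf"))
  if (!is.null(ref$grad)) return(ref$grad(d))
  h <- 0.01
  lo <- pmax(d - h, ref$domain[1])
  hi <- pmin(d + h, ref$domain[2])
  (ref$fun(hi) - ref$fun(lo)) / (hi - lo)
}

#' @export
print.reference_pmf <- function(x, ...) {
  cat(sprintf("Reference PMF '%s' on [%g, %g] A\n",
              x$label, x$domain[1], x$domain[2]))
  invisible(x)
}
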