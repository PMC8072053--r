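## Weighted histogram analysis method: combining biased window histograms
## into one unbiased potential of mean force, with Monte Carlo bootstrap
## uncertainties and window-overlap diagnostics.

#' Bin biased trajectories on a common grid
#'
#' All windows are histogrammed on one shared set of bin edges. Samples
#' falling outside the requested range are counted per window and reported
#' in the result, never silently dropped.
#'
#' @param trajs list of [biased_trajectory()]
#' @param bin_width bin width in Angstrom (default 0.5)
#' @param range `c(lo, hi)` in Angstrom, or NULL to span the pooled data
#' @return an object of class `histogram_set`: list with `edges`,
#'   `centers`, `counts` (windows x bins), `N` (per-window totals in
#'   range), `out_of_range`, `biases`, `dt_sample`
#' @export
build_histograms <- function(trajs, bin_width = 0.5, range = NULL) {
  stopifnot(length(trajs) >= 1, bin_width > 0)
  for (tr in trajs) stopifnot(inherits(tr, "biased_trajectory"))
  pooled <- unlist(lapply(trajs, `[[`, "samples"))
  if (is.null(range)) {
    range <- c(min(pooled), max(pooled))
  }
  lo <- floor(range[1] / bin_width) * bin_width
  n_bins <- max(1L, ceiling((range[2] - lo) / bin_width - 1e-9))
  edges <- lo + bin_width * (0:n_bins)
  counts <- t(vapply(trajs, function(tr) {
    x <- tr$samples
    inside <- x >= edges[1] & x <= edges[length(edges)]
    idx <- pmin(pmax(floor((x[inside] - edges[1]) / bin_width) + 1, 1),
                n_bins)
    tabulate(idx, nbins = n_bins)
  }, integer(n_bins)))
  if (n_bins == 1L) counts <- matrix(counts, ncol = 1)
  N <- rowSums(counts)
  oor <- vapply(trajs, function(tr) sum(tr$samples < edges[1] |
                                          tr$samples > edges[length(edges)]),
                integer(1))
  if (all(N == 0)) stop("all samples fall outside the histogram range")
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, N = N, out_of_range = oor,
                 biases = lapply(trajs, `[[`, "bias"),
                 dt_sample = vapply(trajs, `[[`, numeric(1), "dt_sample")),
            class = "histogram_set")
}

#' PMF profile container
#'
#' Binned free-energy curve with the anchoring convention min(F) = 0 over
#' occupied bins. Unoccupied bins carry NA and are masked, never
#' interpolated.
#'
#' @param d bin centers (Angstrom)
#' @param F free energies (kcal/mol), NA on unoccupied bins
#' @param temperature temperature (K)
#' @param F_err per-bin uncertainties (kcal/mol) or NULL
#' @param n_eff per-bin total counts or NULL
#' @param meta list of solver diagnostics
#' @param anchor shift F so min over occupied bins is 0 (default TRUE);
#'   set FALSE to keep an externally anchored curve, e.g. a repulsive
#'   profile whose tail is referenced to zero at large distance
#' @return object of class `pmf_profile`
#' @export
pmf_profile <- function(d, F, temperature, F_err = NULL, n_eff = NULL,
                        meta = list(), anchor = TRUE) {
  stopifnot(length(d) == length(F))
  occ <- is.finite(F)
  if (anchor && any(occ)) F <- F - min(F[occ])
  if (!is.null(F_err)) stopifnot(all(F_err[is.finite(F_err)] >= 0))
  structure(list(d = as.numeric(d), F = as.numeric(F),
                 F_err = F_err, n_eff = n_eff, occupied = occ,
                 temperature = temperature, meta = meta),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins (%d occupied), d in [%g, %g] A, T = %g K\n",
              length(x$d), sum(x$occupied), min(x$d), max(x$d),
              x$temperature))
  if (!is.null(x$meta$iterations)) {
    cat(sprintf("  WHAM: %d iterations, residual %.3g kcal/mol\n",
                x$meta$iterations, x$meta$residual))
  }
  invisible(x)
}

## Bias-energy matrix w_i(x_b): windows x bins, kcal/mol.
bias_matrix_for <- function(hists, biases) {
  t(vapply(biases, function(b) bias_energy(hists$centers, b),
           numeric(length(hists$centers))))
}

#' Solve the WHAM self-consistent equations
#'
#' Iterates the standard coupled equations
#' P(x_b) = sum_i n_ib / sum_i N_i exp((f_i - w_i(x_b))/kBT) and
#' f_i = -kBT log sum_b P(x_b) exp(-w_i(x_b)/kBT)
#' by direct iteration until the largest change in any window free energy
#' f_i falls below `tol`, then returns F(x_b) = -kBT log P(x_b) anchored so
#' that min F = 0 over occupied bins. Iteration count, final residual and
#' the residual trace of the last iterations are reported in `$meta`.
#'
#' @param hists a [build_histograms()] result
#' @param biases per-window [bias_spec()] list (default: those stored in
#'   `hists`)
#' @param temperature temperature in K (default 303.15)
#' @param tol convergence tolerance on f_i shifts, kcal/mol (default 1e-8)
#' @param max_iter maximum iterations (default 1e5)
#' @param bias_matrix optional explicit windows-x-bins bias-energy matrix
#'   (kcal/mol) overriding the harmonic evaluation, e.g. for gauge checks
#' @return a [pmf_profile()]; `$meta` carries `iterations`, `residual`,
#'   `residual_trace` (last 10), `f` (window free energies), `converged`,
#'   and `disconnected` (TRUE when occupied support splits into islands)
#' @export
wham_solve <- function(hists, biases = NULL, temperature = 303.15,
                       tol = 1e-8, max_iter = 1e5, bias_matrix = NULL) {
  stopifnot(inherits(hists, "histogram_set"))
  if (is.null(biases)) biases <- hists$biases
  if (length(biases) != nrow(hists$counts)) {
    stop("biases do not align with histogram windows")
  }
  kt <- kbt(temperature)
  W <- if (is.null(bias_matrix)) bias_matrix_for(hists, biases) else
    as.matrix(bias_matrix)
  stopifnot(all(dim(W) == dim(hists$counts)))
  n_tot <- colSums(hists$counts)
  occ <- n_tot > 0
  if (!any(occ)) stop("no occupied bins")
  ## coverage precondition: every occupied bin reachable by some window
  C <- exp(-W / kt)                      # windows x bins
  if (any(occ & colSums(C * hists$N) == 0)) {
    stop("occupied bin not covered by any window")
  }
  ## disconnected support diagnostic: more than one substantial occupied
  ## island (stray outlier bins holding a negligible share of the samples
  ## are finite-sampling artifacts, not a split support)
  runs <- rle(occ)
  island_id <- rep(seq_along(runs$values), runs$lengths)
  island_counts <- vapply(unique(island_id[occ]), function(i)
    sum(n_tot[island_id == i]), numeric(1))
  substantial <- island_counts >= max(10, 1e-3 * sum(n_tot))
  disconnected <- sum(substantial) > 1
  if (disconnected) {
    warning("histogram support is disconnected; PMF branches are only ",
            "determined up to independent constants")
  }
  f <- rep(0, length(biases))
  resid_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums((hists$N * exp(f / kt)) * C)
    P <- ifelse(occ, n_tot / denom, 0)
    f_new <- -kt * log(as.vector(C %*% P))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    resid_trace <- c(resid_trace, resid)
    f <- f_new
    if (resid < tol || iter >= max_iter) break
  }
  converged <- resid_trace[length(resid_trace)] < tol
  if (!converged) {
    warning(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                    iter, resid_trace[length(resid_trace)]))
  }
  F <- ifelse(occ, -kt * log(P), NA_real_)
  pmf_profile(hists$centers, F, temperature, n_eff = n_tot,
              meta = list(iterations = iter,
                          residual = resid_trace[length(resid_trace)],
                          residual_trace = utils::tail(resid_trace, 10),
                          f = f, converged = converged,
                          disconnected = disconnected,
                          out_of_range = hists$out_of_range))
}

#' Statistical inefficiency of a correlated series
#'
#' g = 1 + 2 tau_int, with the integrated autocorrelation time taken from
#' the empirical autocorrelation function summed until it first drops
#' below zero (initial positive-sequence style truncation). A series too
#' short or with zero variance returns g = 1.
#'
#' @param x numeric series
#' @param max_lag cap on summed lags (default: length/3)
#' @return statistical inefficiency g >= 1
#' @export
statistical_inefficiency <- function(x, max_lag = NULL) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(1)
  if (is.null(max_lag)) max_lag <- floor(n / 3)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  neg <- which(ac <= 0)
  if (length(neg) > 0) ac <- ac[seq_len(neg[1] - 1)]
  max(1, 1 + 2 * sum(ac))
}

#' WHAM with Monte Carlo bootstrap uncertainties
#'
#' For each bootstrap replicate every window's samples are resampled with
#' replacement using N_i / g_i effective draws (g_i the window's
#' statistical inefficiency), WHAM is re-solved, and each replicate is
#' anchored at its own minimum; the per-bin uncertainty is the standard
#' deviation of F across replicates. Replicates that fail to converge are
#' dropped with a warning.
#'
#' @param trajs list of [biased_trajectory()]
#' @param temperature temperature in K
#' @param n_boot number of bootstrap replicates (>= 2; default 20)
#' @param seed RNG seed for resampling
#' @param g per-window statistical inefficiencies, or `"auto"` to estimate
#'   from each window's autocorrelation (window-average fallback for
#'   series shorter than 10 samples)
#' @param bin_width,range,tol,max_iter passed to [build_histograms()] /
#'   [wham_solve()]
#' @return a [pmf_profile()] with `F_err` filled; `$meta$n_boot_used`
#'   reports surviving replicates and `$meta$g` the inefficiencies
#' @export
bootstrap_pmf <- function(trajs, temperature = 303.15, n_boot = 20,
                          seed = NULL, g = "auto", bin_width = 0.5,
                          range = NULL, tol = 1e-8, max_iter = 1e5) {
  stopifnot(n_boot >= 2)
  hists <- build_histograms(trajs, bin_width = bin_width, range = range)
  main <- wham_solve(hists, temperature = temperature, tol = tol,
                     max_iter = max_iter)
  if (identical(g, "auto")) {
    g <- vapply(trajs, function(tr)
      statistical_inefficiency(tr$samples), numeric(1))
    long <- vapply(trajs, function(tr) length(tr$samples) >= 10, logical(1))
    if (any(long) && any(!long)) g[!long] <- mean(g[long])
  }
  g <- rep_len(pmax(1, g), length(trajs))
  if (!is.null(seed)) set.seed(as.integer(seed))
  reps <- vector("list", n_boot)
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    bt <- lapply(seq_along(trajs), function(i) {
      tr <- trajs[[i]]
      n_eff <- max(2L, round(length(tr$samples) / g[i]))
      biased_trajectory(sample(tr$samples, n_eff, replace = TRUE),
                        tr$bias, window_id = tr$window_id,
                        dt_sample = tr$dt_sample)
    })
    res <- tryCatch({
      h <- build_histograms(bt, bin_width = bin_width,
                            range = c(hists$edges[1],
                                      hists$edges[length(hists$edges)]))
      p <- withCallingHandlers(
        wham_solve(h, temperature = temperature, tol = tol,
                   max_iter = max_iter),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!p$meta$converged) NULL else p
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1L else reps[[b]] <- res
  }
  reps <- Filter(Negate(is.null), reps)
  if (n_fail > 0) {
    warning(n_fail, " bootstrap replicate(s) failed to converge and were dropped")
  }
  if (length(reps) == 0) stop("all bootstrap replicates failed")
  Fm <- vapply(reps, function(p) {
    ## replicate F on the main grid; replicates share the bin edges
    p$F
  }, numeric(length(main$d)))
  F_err <- apply(Fm, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  pmf_profile(main$d, main$F, temperature, F_err = F_err,
              n_eff = main$n_eff,
              meta = c(main$meta,
                       list(n_boot_used = length(reps), g = g)))
}

#' Pairwise window-overlap matrix
#'
#' Entry (i, j) is the overlap fraction sum_b min(p_ib, p_jb) of the two
#' windows' normalized histograms: 1 for identical, 0 for disjoint.
#'
#' @param hists a [build_histograms()] result with >= 2 windows
#' @return list with `overlap` (symmetric matrix in \[0,1\]) and
#'   `adjacent_low` (indices i where overlap(i, i+1) < 0.05, windows taken
#'   in order of bias center)
#' @export
overlap_matrix <- function(hists) {
  stopifnot(inherits(hists, "histogram_set"), nrow(hists$counts) >= 2)
  P <- hists$counts / pmax(hists$N, 1)
  n <- nrow(P)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      M[i, j] <- M[j, i] <- sum(pmin(P[i, ], P[j, ]))
    }
  }
  ord <- order(vapply(hists$biases, `[[`, numeric(1), "d0"))
  adj <- vapply(seq_len(n - 1),
                function(k) M[ord[k], ord[k + 1]], numeric(1))
  list(overlap = M, adjacent_low = which(adj < 0.05))
}

#' Entropic (Jacobian) correction of a distance-coordinate PMF
#'
#' In `radial` mode adds the 3D radial-shell term 2 kBT log(d) and
#' re-anchors; `none` is the identity. Standard 1D distance WHAM reports
#' the uncorrected profile, which is the default throughout.
#'
#' @param pmf a [pmf_profile()]
#' @param mode `"none"` or `"radial"`
#' @return a [pmf_profile()]
#' @export
jacobian_correction <- function(pmf, mode = c("none", "radial")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pmf, "pmf_profile"))
  if (mode == "none") return(pmf)
  if (any(pmf$d <= 0)) stop("radial correction requires positive distances")
  kt <- kbt(pmf$temperature)
  F <- pmf$F + 2 * kt * log(pmf$d)
  pmf_profile(pmf$d, F, pmf$temperature, F_err = pmf$F_err,
              n_eff = pmf$n_eff,
              meta = c(pmf$meta, list(jacobian = "radial")))
}

#' Write / read a PMF profile as TSV
#'
#' Columns: `d_center` (Angstrom), `F` (kcal/mol), `F_err` (kcal/mol, NA
#' when no bootstrap was run), `n_eff` (per-bin counts); header line
#' `# d_center F F_err n_eff`.
#'
#' @param pmf a [pmf_profile()]
#' @param path file path
#' @param temperature temperature (K) assumed when reading
#' @return `path` invisibly (write); a [pmf_profile()] (read)
#' @export
write_pmf_tsv <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  err <- if (is.null(pmf$F_err)) rep(NA_real_, length(pmf$d)) else pmf$F_err
  ne <- if (is.null(pmf$n_eff)) rep(NA_real_, length(pmf$d)) else pmf$n_eff
  lines <- c("# d_center F F_err n_eff",
             sprintf("%.17g\t%.17g\t%.17g\t%.17g", pmf$d, pmf$F, err, ne))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pmf_tsv
#' @export
read_pmf_tsv <- function(path, temperature = 303.15) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("d_center", "F", "F_err", "n_eff"),
                           na.strings = c("NA", "nan"))
  pmf_profile(tab$d_center, tab$F, temperature,
              F_err = if (all(is.na(tab$F_err))) NULL else tab$F_err,
              n_eff = if (all(is.na(tab$n_eff))) NULL else tab$n_eff)
}
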