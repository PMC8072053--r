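## Synthetic biased reaction-coordinate trajectories. An overdamped
## Langevin walker on (reference PMF + harmonic bias) produces stationary,
## Boltzmann-distributed, autocorrelated 1D samples with the statistical
## structure the WHAM analysis assumes, standing in for per-window
## atomistic umbrella-sampling runs.

#' Parameters for the 1D overdamped Langevin sampler
#'
#' @param temperature temperature in K (default 303.15)
#' @param D diffusion coefficient in A^2/ps (default 1); sets the
#'   autocorrelation time of the coordinate, not its stationary law
#' @param dt integration time step in ps (default 0.05)
#' @param n_steps number of integration steps
#' @param save_stride save every `save_stride`-th step (default 10)
#' @param seed integer RNG seed; fixed seed + params gives bitwise-identical
#'   output
#' @return an object of class `langevin_params`
#' @export
langevin_params <- function(temperature = 303.15, D = 1, dt = 0.05,
                            n_steps = 20000, save_stride = 10,
                            seed = NULL) {
  stopifnot(temperature > 0, D > 0, dt > 0, n_steps >= 1, save_stride >= 1)
  structure(list(temperature = temperature, D = D, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride), seed = seed),
            class = "langevin_params")
}

#' Biased trajectory container
#'
#' @param samples reaction-coordinate samples (Angstrom)
#' @param bias the window's [bias_spec()]
#' @param window_id integer window label
#' @param dt_sample sampling interval of the saved series (ps)
#' @return object of class `biased_trajectory`
#' @export
biased_trajectory <- function(samples, bias, window_id = 1L,
                              dt_sample = 1) {
  stopifnot(inherits(bias, "bias_spec"), length(samples) >= 1,
            all(is.finite(samples)))
  structure(list(window_id = as.integer(window_id), bias = bias,
                 samples = as.numeric(samples),
                 dt_sample = as.numeric(dt_sample)),
            class = "biased_trajectory")
}

#' Sample one umbrella window by overdamped Langevin dynamics
#'
#' Integrates x' = x - (D/kBT) V'(x) dt + sqrt(2 D dt) xi on
#' V(d) = ref(d) + 1/2 k (d - d0)^2 with reflecting boundaries at the
#' domain edges, so the stationary law is the Boltzmann density
#' exp(-V/kBT) on the finite domain. The force is pre-tabulated on a
#' 0.01 A grid (analytic gradients used where the reference provides one).
#'
#' @param ref a [reference_pmf()]
#' @param bias a [bias_spec()]; `d0` must lie inside the reference domain
#' @param params a [langevin_params()]
#' @param x0 starting point (default: the bias center)
#' @param window_id label for the output trajectory
#' @return a [biased_trajectory()] of `floor(n_steps/save_stride)` samples
#' @export
sample_biased_trajectory <- function(ref, bias, params, x0 = NULL,
                                     window_id = 1L) {
  stopifnot(inherits(ref, "reference_pmf"), inherits(bias, "bias_spec"),
            inherits(params, "langevin_params"))
  dom <- ref$domain
  if (bias$d0 < dom[1] || bias$d0 > dom[2]) {
    stop("bias center d0 = ", bias$d0, " outside reference domain [",
         dom[1], ", ", dom[2], "]")
  }
  h <- 0.01
  grid <- seq(dom[1], dom[2], by = h)
  vref <- ref_value(ref, grid)
  if (!all(is.finite(vref))) stop("reference PMF not finite on its domain")
  ## total force = -dV/dx = -(ref' + k (x - d0))
  fgrid <- -(ref_grad(ref, grid) + bias$k * (grid - bias$d0))
  if (is.null(x0)) x0 <- bias$d0
  stopifnot(x0 >= dom[1], x0 <= dom[2])
  kt <- kbt(params$temperature)
  if (!is.null(params$seed)) set.seed(as.integer(params$seed))
  samples <- sim_overdamped_1d(x0, dom[1], dom[2], fgrid, grid[1], h,
                               params$D / kt, params$dt, params$n_steps,
                               params$save_stride,
                               sqrt(2 * params$D * params$dt))
  biased_trajectory(samples, bias, window_id = window_id,
                    dt_sample = params$dt * params$save_stride)
}

#' Generate a full umbrella campaign on a reference landscape
#'
#' One biased trajectory per window of the schedule. Per-window seeds are
#' derived deterministically as `base seed + window index`, so a campaign
#' is reproducible from its base seed and re-running any single window
#' reproduces the campaign's trajectory for that window.
#'
#' @param ref a [reference_pmf()]
#' @param schedule a `window_schedule`; all centers must be in the domain
#' @param params a [langevin_params()]; its `seed` is the campaign base seed
#' @param dir if non-NULL, write one COLVAR-style file per window plus a
#'   window manifest into this directory
#' @return list of [biased_trajectory()], one per window
#' @export
generate_campaign <- function(ref, schedule, params, dir = NULL) {
  stopifnot(inherits(schedule, "window_schedule"))
  if (length(schedule) == 0) stop("empty window schedule")
  base_seed <- if (is.null(params$seed)) 0L else as.integer(params$seed)
  trajs <- lapply(seq_along(schedule), function(i) {
    p <- params
    p$seed <- base_seed + i
    sample_biased_trajectory(ref, schedule[[i]], p, window_id = i)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_window_manifest(schedule, file.path(dir, "windows.txt"))
    for (tr in trajs) {
      write_colvar(tr, file.path(dir, sprintf("window_%03d.colvar",
                                              tr$window_id)))
    }
  }
  trajs
}

#' Write / read a COLVAR-style time series
#'
#' Format: header line `#! FIELDS time dist`, then two whitespace-separated
#' columns (time in ps, distance in Angstrom), 17 significant digits.
#'
#' @param traj a [biased_trajectory()]
#' @param path file path
#' @return `path` invisibly (write); a data.frame with columns `time`,
#'   `dist` (read)
#' @export
write_colvar <- function(traj, path) {
  stopifnot(inherits(traj, "biased_trajectory"))
  tm <- seq_along(traj$samples) * traj$dt_sample
  lines <- c("#! FIELDS time dist",
             sprintf("%.17g %.17g", tm, traj$samples))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", first)) {
    stop("not a COLVAR file (missing '#! FIELDS' header): ", path)
  }
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", first), "\\s+")[[1]]
  tab <- utils::read.table(path, comment.char = "#")
  names(tab) <- fields[seq_len(ncol(tab))]
  tab
}

#' Read a campaign written by [generate_campaign()]
#'
#' @param dir directory holding `windows.txt` and `window_*.colvar`
#' @return list of [biased_trajectory()]
#' @export
read_campaign <- function(dir) {
  schedule <- read_window_manifest(file.path(dir, "windows.txt"))
  files <- sort(list.files(dir, pattern = "^window_.*\\.colvar$",
                           full.names = TRUE))
  if (length(files) != length(schedule)) {
    stop("manifest lists ", length(schedule), " windows but found ",
         length(files), " COLVAR files")
  }
  lapply(seq_along(files), function(i) {
    tab <- read_colvar(files[i])
    dt <- if (nrow(tab) > 1) tab$time[2] - tab$time[1] else 1
    biased_trajectory(tab$dist, schedule[[i]], window_id = i,
                      dt_sample = dt)
  })
}
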