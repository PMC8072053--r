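## Coarse-grained nucleosome fiber: a covalently closed ring of beads
## (one bead per nucleosome) driven by the fitted bond and nonbonded
## potentials under Langevin dynamics, with stability diagnostics.

#' Ring fiber topology
#'
#' N beads bonded in a single cycle (i, i+1 mod N); bonded pairs are
#' excluded from the nonbonded interaction.
#'
#' @param N bead count; >= 3 for a true ring, N = 2 is accepted as the
#'   degenerate bonded-dumbbell case (a single bond)
#' @return object of class `fiber_topology` with `N` and a `bonds` matrix
#' @export
fiber_topology <- function(N) {
  N <- as.integer(N)
  stopifnot(N >= 2)
  bonds <- if (N == 2L) matrix(c(1L, 2L), 1) else
    cbind(seq_len(N), c(seq_len(N)[-1], 1L))
  structure(list(N = N, bonds = bonds), class = "fiber_topology")
}

#' Coarse-grained force field for the bead fiber
#'
#' Implements the bonded term (harmonic, between linker-connected beads)
#' and the nonbonded repulsion (exponential or shifted-Coulomb) of the
#' coarse-grained Hamiltonian, plus an optional short-ranged Gaussian
#' attraction well mimicking the stabilizing effect of histone tails on
#' stacked nucleosomes. The repulsion is energy-shifted to zero at the
#' cutoff. The shifted-Coulomb form is linearly continued (constant
#' force) below B + 0.5 A and continuation events are counted in the
#' diagnostics, so its near-singular behavior remains observable without
#' numeric overflow.
#'
#' @param bond a [harmonic_model()]
#' @param nonbonded an [exponential_model()], [shifted_coulomb_model()],
#'   or NULL for none
#' @param attraction NULL, or `list(eps, r0, w)`: well depth (kcal/mol),
#'   center (A) and width (A); defaults eps = 1, r0 = 60, w = 5 are filled
#'   for missing fields
#' @param cutoff nonbonded cutoff in Angstrom (default 400); when the
#'   attraction is enabled the cutoff must exceed `r0 + 3 w`
#' @return object of class `force_field`
#' @export
force_field <- function(bond, nonbonded = NULL, attraction = NULL,
                        cutoff = 400) {
  stopifnot(inherits(bond, "harmonic_model"), cutoff > 0)
  nb_type <- 0L
  pars <- list(alpha = 0, beta = 0, A = 1, B = 0)
  if (!is.null(nonbonded)) {
    if (inherits(nonbonded, "exponential_model")) {
      nb_type <- 1L
      if (nonbonded$sign_convention != "exp(beta-alpha*d)") {
        stop("fiber force field supports the exp(beta - alpha*d) convention")
      }
      pars$alpha <- nonbonded$alpha; pars$beta <- nonbonded$beta
    } else if (inherits(nonbonded, "shifted_coulomb_model")) {
      nb_type <- 2L
      pars$A <- nonbonded$A; pars$B <- nonbonded$B
    } else {
      stop("nonbonded must be an exponential or shifted-Coulomb model")
    }
  }
  att <- list(eps = 0, r0 = 60, w = 5)
  if (!is.null(attraction)) {
    att[names(attraction)] <- attraction
    stopifnot(att$eps >= 0, att$w > 0)
    if (att$eps > 0 && cutoff <= att$r0 + 3 * att$w) {
      stop("cutoff must exceed attraction r0 + 3*w")
    }
  }
  structure(list(bond = bond, nonbonded = nonbonded, attraction = att,
                 cutoff = cutoff), class = "force_field")
}

## flat parameter list handed to the C++ kernels
ff_as_list <- function(ff) {
  nb_type <- if (is.null(ff$nonbonded)) 0L else
    if (inherits(ff$nonbonded, "exponential_model")) 1L else 2L
  list(bond_k = ff$bond$k, bond_d0 = ff$bond$d0, nb_type = nb_type,
       alpha = if (nb_type == 1L) ff$nonbonded$alpha else 0,
       beta = if (nb_type == 1L) ff$nonbonded$beta else 0,
       A = if (nb_type == 2L) ff$nonbonded$A else 1,
       B = if (nb_type == 2L) ff$nonbonded$B else 0,
       eps = ff$attraction$eps, r0 = ff$attraction$r0,
       w = ff$attraction$w, cutoff = ff$cutoff)
}

#' Langevin simulation settings for the fiber
#'
#' A stability pre-check refuses time steps larger than 0.05 of the
#' fastest bond vibration period implied by the bond curvature and the
#' lightest bead.
#'
#' @param temperature K (default 303.15)
#' @param friction Langevin friction in 1/ps (default 1); 0 gives
#'   velocity-Verlet (NVE) dynamics
#' @param dt time step in ps (default 10)
#' @param n_steps number of steps
#' @param save_stride save every n-th frame (default 100)
#' @param seed RNG seed
#' @param crash_bond_factor crash when any bond exceeds this multiple of
#'   the bond equilibrium length (default 5)
#' @param contact_distance stacked-contact distance in Angstrom
#'   (default 70)
#' @return object of class `sim_config`
#' @export
sim_config <- function(temperature = 303.15, friction = 1, dt = 10,
                       n_steps = 10000, save_stride = 100, seed = NULL,
                       crash_bond_factor = 5, contact_distance = 70) {
  stopifnot(temperature >= 0, friction >= 0, dt > 0, n_steps >= 1,
            save_stride >= 1, crash_bond_factor > 1, contact_distance > 0)
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride), seed = seed,
                 crash_bond_factor = crash_bond_factor,
                 contact_distance = contact_distance),
            class = "sim_config")
}

#' Build a covalently closed bead fiber
#'
#' `circle` places the beads uniformly on a circle of circumference
#' N * bond_length. `stacked-zigzag` arranges the beads as a two-start
#' helical ring: even- and odd-indexed beads form two circular stacks so
#' that beads i and i+2 sit at the stacking distance while consecutive
#' (bonded) beads span the fiber, mirroring the nucleosome packing of the
#' condensed-fiber template. Velocities are drawn from the
#' Maxwell-Boltzmann distribution at `temperature` with the total
#' momentum removed.
#'
#' @param N bead count (>= 3; even for `stacked-zigzag`)
#' @param bond_length bonded-neighbor distance in Angstrom
#' @param geometry `"circle"` or `"stacked-zigzag"`
#' @param stack_distance stacked-pair (i, i+2) distance in Angstrom for
#'   the zigzag geometry (default 60, near the crystal stacking distance)
#' @param mass bead mass in Da (default 2e5, the order of a nucleosome's
#'   protein + DNA mass; affects kinetics only)
#' @param temperature K for velocity initialization
#' @param seed RNG seed for the velocities
#' @return list with `topology` ([fiber_topology()]) and `state`
#'   (class `fiber_state`: `positions`, `velocities`, `masses`, `time`)
#' @export
build_ring_fiber <- function(N, bond_length,
                             geometry = c("circle", "stacked-zigzag"),
                             stack_distance = 60, mass = 2e5,
                             temperature = 303.15, seed = NULL) {
  geometry <- match.arg(geometry)
  topo <- fiber_topology(N)
  N <- topo$N
  if (geometry == "circle") {
    ## chord-correct radius so bonded neighbors sit exactly at bond_length
    R <- bond_length / (2 * sin(pi / N))
    th <- 2 * pi * (seq_len(N) - 1) / N
    x <- cbind(R * cos(th), R * sin(th), 0)
  } else {
    if (N %% 2 != 0) stop("stacked-zigzag geometry requires even N")
    M <- N / 2
    R <- stack_distance / (2 * sin(pi / M))
    half_chord <- 2 * R * sin(pi / (2 * M))
    if (bond_length <= half_chord) {
      stop("bond_length too short for the requested stack_distance")
    }
    h <- sqrt(bond_length^2 - half_chord^2)
    x <- matrix(0, N, 3)
    for (i in seq_len(N)) {
      j <- floor((i - 1) / 2)           # rung index
      odd <- (i - 1) %% 2               # 0 = stack A, 1 = stack B
      ang <- 2 * pi * j / M + odd * pi / M
      x[i, ] <- c(R * cos(ang), R * sin(ang), odd * h)
    }
  }
  ## overlap guard
  dmin <- min(stats::dist(x))
  if (dmin < 1) stop("geometry places beads closer than 1 A")
  if (!is.null(seed)) set.seed(as.integer(seed))
  vsd <- if (temperature > 0) sqrt(kbt(temperature) * ACC_KCAL_DA / mass)
         else 0
  v <- matrix(stats::rnorm(3 * N, sd = vsd), N, 3)
  v <- sweep(v, 2, colMeans(v))          # zero total momentum
  state <- structure(list(positions = x, velocities = v,
                          masses = rep(mass, N), time = 0),
                     class = "fiber_state")
  list(topology = topo, state = state)
}

check_state <- function(state, topology) {
  stopifnot(inherits(state, "fiber_state"),
            inherits(topology, "fiber_topology"),
            nrow(state$positions) == topology$N)
}

#' Potential-energy components of a fiber state
#'
#' @param state a `fiber_state`
#' @param topology a [fiber_topology()]
#' @param ff a [force_field()]
#' @return named numeric: `bond`, `nonbonded`, `attraction` (kcal/mol);
#'   attribute `n_clamped` counts shifted-Coulomb linear-continuation
#'   events
#' @export
total_energy <- function(state, topology, ff) {
  check_state(state, topology)
  stopifnot(inherits(ff, "force_field"))
  r <- fiber_energy_forces(state$positions, ff_as_list(ff), forces = FALSE)
  structure(c(bond = r$e_bond, nonbonded = r$e_nonbonded,
              attraction = r$e_attraction),
            n_clamped = r$n_clamped)
}

#' Analytic forces on every bead
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces (kcal/mol/A)
#' @export
fiber_forces <- function(state, topology, ff) {
  check_state(state, topology)
  r <- fiber_energy_forces(state$positions, ff_as_list(ff), forces = TRUE)
  r$forces
}

#' Langevin dynamics of the bead fiber
#'
#' BAOAB-discretized Langevin integration; with `friction = 0` and
#' `temperature = 0` the scheme reduces to velocity Verlet. The run is
#' deterministic for a fixed seed. Crash diagnostics (non-finite state or
#' a bond beyond `crash_bond_factor * d0`) terminate the run early and
#' return the trajectory up to the failure together with a crash record
#' rather than raising an error.
#'
#' @param state initial `fiber_state`
#' @param topology a [fiber_topology()]
#' @param ff a [force_field()]
#' @param config a [sim_config()]
#' @return object of class `fiber_trajectory`: `frames` (N x 3 x n array),
#'   `times` (ps), `energies` (data.frame: time, e_bond, e_nonbonded,
#'   e_attraction, e_kinetic), `final` state, `crash` (NULL or
#'   `list(step, reason)`), `n_clamped`
#' @export
run_langevin <- function(state, topology, ff, config) {
  check_state(state, topology)
  stopifnot(inherits(ff, "force_field"), inherits(config, "sim_config"))
  ## time-step stability pre-check against the fastest bond vibration
  nu_max <- sqrt(ff$bond$k * ACC_KCAL_DA / min(state$masses)) / (2 * pi)
  if (nu_max > 0 && config$dt > 0.05 / nu_max) {
    stop(sprintf("dt = %g ps exceeds 0.05 of the bond vibration period (%g ps)",
                 config$dt, 1 / nu_max))
  }
  f0 <- fiber_forces(state, topology, ff)
  if (!all(is.finite(f0))) stop("non-finite forces at the initial state")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  out <- run_baoab(state$positions, state$velocities, state$masses,
                   ff_as_list(ff), config$dt, config$n_steps,
                   config$save_stride, config$friction,
                   kbt_or_zero(config$temperature),
                   config$crash_bond_factor * ff$bond$d0, ACC_KCAL_DA)
  en <- as.data.frame(out$energies)
  names(en) <- c("e_bond", "e_nonbonded", "e_attraction", "e_kinetic")
  en <- cbind(time = out$times, en)
  crash <- if (out$crash_step >= 0)
    list(step = out$crash_step, reason = out$crash_reason) else NULL
  final <- structure(list(positions = out$frames[, , dim(out$frames)[3]],
                          velocities = out$velocities,
                          masses = state$masses,
                          time = out$times[length(out$times)]),
                     class = "fiber_state")
  structure(list(frames = out$frames, times = out$times, energies = en,
                 final = final, crash = crash, n_clamped = out$n_clamped,
                 config = config),
            class = "fiber_trajectory")
}

kbt_or_zero <- function(temperature) {
  if (temperature <= 0) 0 else kbt(temperature)
}

#' Kinetic temperature of a trajectory
#'
#' 2 <KE> / (3 N kB) averaged over saved frames after discarding a
#' burn-in fraction.
#'
#' @param traj a `fiber_trajectory`
#' @param N bead count
#' @param burn_in fraction of frames discarded (default 0.1)
#' @return temperature in K
#' @export
kinetic_temperature <- function(traj, N, burn_in = 0.1) {
  ke <- traj$energies$e_kinetic
  ke <- ke[-seq_len(max(1, floor(length(ke) * burn_in)))]
  2 * mean(ke) / (3 * N * KB_KCAL)
}

pair_dist_frame <- function(xyz, pairs) {
  sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                  xyz[pairs[, 2], , drop = FALSE])^2))
}

#' Stability diagnostics of a fiber trajectory
#'
#' Reports whether the run crashed (and at which step), the largest bond
#' deviation from the equilibrium length, the radius-of-gyration series,
#' the stacked-contact count series (non-bonded pairs within
#' `contact_distance`, with the initial frame defining the reference
#' contact set), the fraction of initial contacts retained in the final
#' frame, and the total-energy drift between the first and last frames.
#'
#' @param traj a `fiber_trajectory`
#' @param topology a [fiber_topology()]
#' @param ff the [force_field()] used (for the bond reference length)
#' @param contact_distance contact cutoff in Angstrom (default: the
#'   trajectory config value)
#' @return list of diagnostics
#' @export
stability_report <- function(traj, topology, ff,
                             contact_distance = NULL) {
  stopifnot(inherits(traj, "fiber_trajectory"),
            dim(traj$frames)[3] >= 2)
  if (is.null(contact_distance)) {
    contact_distance <- traj$config$contact_distance
  }
  N <- topology$N
  n_frames <- dim(traj$frames)[3]
  bonds <- topology$bonds
  ## non-bonded pairs (reference set from frame 1)
  all_pairs <- t(utils::combn(N, 2))
  bonded_key <- paste(pmin(bonds[, 1], bonds[, 2]),
                      pmax(bonds[, 1], bonds[, 2]))
  nb <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% bonded_key),
                  , drop = FALSE]
  d0_frame <- pair_dist_frame(traj$frames[, , 1], nb)
  initial_contacts <- nb[d0_frame <= contact_distance, , drop = FALSE]

  rg <- numeric(n_frames)
  n_contacts <- integer(n_frames)
  max_bond_dev <- 0
  for (fidx in seq_len(n_frames)) {
    xyz <- traj$frames[, , fidx]
    ctr <- colMeans(xyz)
    rg[fidx] <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
    db <- pair_dist_frame(xyz, bonds)
    max_bond_dev <- max(max_bond_dev, max(abs(db - ff$bond$d0),
                                          na.rm = TRUE), na.rm = TRUE)
    n_contacts[fidx] <- if (nrow(nb) > 0)
      sum(pair_dist_frame(xyz, nb) <= contact_distance) else 0L
  }
  contact_fraction <- if (nrow(initial_contacts) > 0) {
    dfin <- pair_dist_frame(traj$frames[, , n_frames], initial_contacts)
    mean(dfin <= contact_distance)
  } else NA_real_

  etot <- rowSums(traj$energies[, c("e_bond", "e_nonbonded",
                                    "e_attraction", "e_kinetic")])
  list(crashed = !is.null(traj$crash),
       first_failure_step = if (is.null(traj$crash)) NA_integer_ else
         traj$crash$step,
       crash_reason = if (is.null(traj$crash)) NA_character_ else
         traj$crash$reason,
       max_bond_deviation = max_bond_dev,
       rg = rg,
       n_contacts = n_contacts,
       n_initial_contacts = nrow(initial_contacts),
       contact_fraction = contact_fraction,
       energy_drift = etot[length(etot)] - etot[1],
       n_clamped = traj$n_clamped)
}

#' Write a fiber trajectory in XYZ format
#'
#' One pseudo-atom (`NUC`) per bead; the comment line carries the frame
#' time in ps.
#'
#' @param traj a `fiber_trajectory`
#' @param path output file
#' @return `path` invisibly
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  N <- dim(traj$frames)[1]
  for (fidx in seq_len(dim(traj$frames)[3])) {
    xyz <- traj$frames[, , fidx]
    writeLines(c(as.character(N),
                 sprintf("t = %.17g ps", traj$times[fidx]),
                 sprintf("NUC %.17g %.17g %.17g",
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Write the per-frame observable log as TSV
#'
#' Columns: time (ps), energy components (kcal/mol), radius of gyration
#' (A), stacked-contact count.
#'
#' @param traj a `fiber_trajectory`
#' @param report a [stability_report()] for the same trajectory
#' @param path output file
#' @return `path` invisibly
#' @export
write_observables_tsv <- function(traj, report, path) {
  tab <- cbind(traj$energies,
               rg = report$rg, n_contacts = report$n_contacts)
  lines <- c(paste0("# ", paste(names(tab), collapse = "\t")),
             do.call(sprintf,
                     c(list(fmt = paste(rep("%.17g", ncol(tab)),
                                        collapse = "\t")),
                       unname(as.list(tab)))))
  writeLines(lines, path)
  invisible(path)
}
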