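# Ring-fiber construction, energies/forces, Langevin dynamics, stability.

demo_ff <- function(attraction = NULL, nonbonded = "exp", cutoff = 400) {
  nb <- if (identical(nonbonded, "exp")) exponential_model(0.1213, 9.2086)
        else if (identical(nonbonded, "coul")) shifted_coulomb_model(39.53, 52.82)
        else NULL
  force_field(harmonic_model(0.01, 225), nonbonded = nb,
              attraction = attraction, cutoff = cutoff)
}

test_that("circle geometry places all bonds at the bond length with ring closure", {
  sys <- build_ring_fiber(100, 225, geometry = "circle", seed = 1)
  x <- sys$state$positions
  d <- sqrt(rowSums((x - x[c(2:100, 1), ])^2))
  expect_true(all(abs(d - 225) < 1e-6))
  expect_equal(sys$topology$bonds[100, ], c(100L, 1L), ignore_attr = TRUE)
  # Maxwell-Boltzmann velocities with zero total momentum
  mom <- colSums(sys$state$velocities * sys$state$masses)
  expect_true(all(abs(mom) < 1e-6))
})

test_that("stacked-zigzag geometry stacks next-nearest beads at the stacking distance", {
  sys <- build_ring_fiber(100, 225, geometry = "stacked-zigzag",
                          stack_distance = 60, seed = 2)
  x <- sys$state$positions
  bond <- sqrt(rowSums((x - x[c(2:100, 1), ])^2))
  expect_true(all(abs(bond - 225) < 1e-6))
  stack <- sqrt(rowSums((x - x[c(3:100, 1, 2), ])^2))
  expect_true(all(abs(stack - 60) < 1e-6))
  expect_error(build_ring_fiber(100, 20, geometry = "stacked-zigzag",
                                stack_distance = 60), "bond_length")
})

test_that("energy components match hand-evaluated values", {
  # square of side d0: 4 bonds exactly at d0, two diagonal nonbonded pairs
  d0 <- 225
  ff <- demo_ff()
  x <- rbind(c(0, 0, 0), c(d0, 0, 0), c(d0, d0, 0), c(0, d0, 0))
  st <- structure(list(positions = x, velocities = matrix(0, 4, 3),
                       masses = rep(2e5, 4), time = 0),
                  class = "fiber_state")
  topo <- fiber_topology(4)
  e <- total_energy(st, topo, ff)
  expect_equal(e[["bond"]], 0, tolerance = 1e-10)
  diag_d <- d0 * sqrt(2)
  vrep <- function(r) exp(9.2086 - 0.1213 * r) - exp(9.2086 - 0.1213 * 400)
  expect_equal(e[["nonbonded"]], 2 * vrep(diag_d), tolerance = 1e-10)
  expect_equal(e[["attraction"]], 0)

  # squeezing the square onto a 60 A rhombus-like diagonal brings the
  # attraction well into play
  ff2 <- demo_ff(attraction = list(eps = 1, r0 = 60, w = 5))
  x2 <- rbind(c(0, 0, 0), c(30, 100, 0), c(60, 0, 0), c(30, -100, 0))
  st2 <- structure(list(positions = x2, velocities = matrix(0, 4, 3),
                        masses = rep(2e5, 4), time = 0),
                   class = "fiber_state")
  e2 <- total_energy(st2, topo, ff2)
  d13 <- 60; d24 <- 200
  expect_equal(e2[["attraction"]],
               -exp(-(d13 - 60)^2 / 50) - exp(-(d24 - 60)^2 / 50),
               tolerance = 1e-10)
  expect_equal(e2[["nonbonded"]], vrep(60) + vrep(200), tolerance = 1e-10)
})

test_that("energies are invariant under rigid rotation and translation", {
  set.seed(9)
  sys <- build_ring_fiber(12, 225, seed = 9)
  sys$state$positions <- sys$state$positions +
    matrix(rnorm(36, sd = 10), 12, 3)
  ff <- demo_ff(attraction = list(eps = 1, r0 = 225, w = 20),
                 cutoff = 500)
  e1 <- total_energy(sys$state, sys$topology, ff)
  R <- rotation_matrix(c(1, 2, 3), 1.1)
  st2 <- sys$state
  st2$positions <- sweep(sys$state$positions %*% t(R), 2, c(50, -20, 7), `+`)
  e2 <- total_energy(st2, sys$topology, ff)
  expect_equal(e1, e2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("analytic forces match central differences of the energy", {
  set.seed(10)
  for (nb in c("exp", "coul")) {
    sys <- build_ring_fiber(8, 225, seed = 10)
    # perturb away from symmetry; for the shifted-Coulomb keep distances
    # above the continuation region
    sys$state$positions <- sys$state$positions +
      matrix(rnorm(24, sd = 8), 8, 3)
    ff <- demo_ff(nonbonded = nb,
                   attraction = list(eps = 0.7, r0 = 225, w = 15),
                   cutoff = 500)
    f <- fiber_forces(sys$state, sys$topology, ff)
    h <- 1e-5
    scale <- max(abs(f))
    for (i in c(1, 4, 8)) {
      for (c in 1:3) {
        stp <- sys$state
        stp$positions[i, c] <- stp$positions[i, c] + h
        stm <- sys$state
        stm$positions[i, c] <- stm$positions[i, c] - h
        fd <- -(sum(total_energy(stp, sys$topology, ff)) -
                  sum(total_energy(stm, sys$topology, ff))) / (2 * h)
        expect_lt(abs(f[i, c] - fd), 1e-6 * max(1, scale))
      }
    }
  }
})

test_that("dynamics are deterministic and stationary at a zero-temperature minimum", {
  sys <- build_ring_fiber(10, 225, temperature = 0, seed = 3)
  ff <- force_field(harmonic_model(0.01, 225))  # bonds only: circle is a minimum
  cfg <- sim_config(temperature = 0, friction = 0, dt = 5, n_steps = 200,
                    save_stride = 20, seed = 4)
  tr <- run_langevin(sys$state, sys$topology, ff, cfg)
  expect_null(tr$crash)
  expect_lt(max(abs(tr$final$positions - sys$state$positions)), 1e-8)

  sys2 <- build_ring_fiber(10, 225, seed = 5)
  cfg2 <- sim_config(dt = 5, n_steps = 200, save_stride = 20, seed = 6)
  t1 <- run_langevin(sys2$state, sys2$topology, ff, cfg2)
  t2 <- run_langevin(sys2$state, sys2$topology, ff, cfg2)
  expect_identical(t1$frames, t2$frames)
  expect_error(run_langevin(sys2$state, sys2$topology, ff,
                            sim_config(dt = 1e4, n_steps = 10)),
               "dt")
})

test_that("frictionless zero-temperature dynamics conserve energy", {
  sys <- build_ring_fiber(8, 225, temperature = 0, seed = 7)
  set.seed(7)
  sys$state$positions <- sys$state$positions + matrix(rnorm(24, sd = 5), 8, 3)
  ff <- demo_ff()
  cfg <- sim_config(temperature = 0, friction = 0, dt = 2, n_steps = 1e4,
                    save_stride = 100, seed = 8)
  tr <- run_langevin(sys$state, sys$topology, ff, cfg)
  etot <- rowSums(tr$energies[, c("e_bond", "e_nonbonded",
                                  "e_attraction", "e_kinetic")])
  pe0 <- sum(tr$energies[1, c("e_bond", "e_nonbonded", "e_attraction")])
  expect_lt(max(abs(etot - etot[1])), 1e-3 * abs(pe0))
})

test_that("thermostated dynamics equilibrate to the target temperature", {
  # light beads and soft bonds give fast decorrelation at small dt
  sys <- build_ring_fiber(8, 225, mass = 1e3, seed = 11)
  ff <- force_field(harmonic_model(0.01, 225))
  cfg <- sim_config(temperature = 303.15, friction = 1, dt = 1,
                    n_steps = 2e5, save_stride = 10, seed = 12)
  tr <- run_langevin(sys$state, sys$topology, ff, cfg)
  expect_equal(kinetic_temperature(tr, 8), 303.15, tolerance = 0.02)
})

test_that("bonded dumbbell reproduces the Boltzmann bond-length distribution", {
  sys <- build_ring_fiber(2, 60, mass = 1e3, seed = 13)
  k <- 1
  ff <- force_field(harmonic_model(k, 60))
  cfg <- sim_config(temperature = 303.15, friction = 1, dt = 0.2,
                    n_steps = 5e5, save_stride = 5, seed = 14)
  tr <- run_langevin(sys$state, sys$topology, ff, cfg)
  r <- sqrt(colSums((tr$frames[1, , ] - tr$frames[2, , ])^2))
  r <- r[-seq_len(1000)]
  # exact radial law p(r) ~ r^2 exp(-V(r)/kBT): Jacobian-aware oracle by
  # numerical quadrature
  kt <- kbt(303.15)
  grid <- seq(50, 70, by = 0.001)
  dens <- grid^2 * exp(-0.5 * k * (grid - 60)^2 / kt)
  dens <- dens / sum(dens)
  mu <- sum(grid * dens)
  v_exact <- sum((grid - mu)^2 * dens)
  expect_equal(var(r), v_exact, tolerance = 0.05)
})

test_that("crash diagnostics record the failing step and the report reflects it", {
  # weak short bonds against a strong repulsion: bonds stretch past the
  # crash threshold
  topo_sys <- build_ring_fiber(4, 10, mass = 1e2, seed = 15)
  ff <- force_field(harmonic_model(1e-4, 10),
                    nonbonded = shifted_coulomb_model(500, 5),
                    cutoff = 400)
  cfg <- sim_config(temperature = 303.15, friction = 1, dt = 1,
                    n_steps = 5000, save_stride = 10, seed = 16)
  tr <- run_langevin(topo_sys$state, topo_sys$topology, ff, cfg)
  expect_false(is.null(tr$crash))
  rep <- stability_report(tr, topo_sys$topology, ff)
  expect_true(rep$crashed)
  expect_equal(rep$first_failure_step, tr$crash$step)
  expect_gt(rep$max_bond_deviation, 4 * 10)

  # a stationary run is not crashed and has zero drift
  sys0 <- build_ring_fiber(6, 225, temperature = 0, seed = 17)
  ff0 <- force_field(harmonic_model(0.01, 225))
  tr0 <- run_langevin(sys0$state, sys0$topology, ff0,
                      sim_config(temperature = 0, friction = 0, dt = 5,
                                 n_steps = 100, save_stride = 10))
  rep0 <- stability_report(tr0, sys0$topology, ff0)
  expect_false(rep0$crashed)
  expect_lt(abs(rep0$energy_drift), 1e-10)
})

test_that("trajectory files are written in XYZ and TSV form", {
  sys <- build_ring_fiber(6, 225, seed = 18)
  ff <- force_field(harmonic_model(0.01, 225))
  tr <- run_langevin(sys$state, sys$topology, ff,
                     sim_config(dt = 5, n_steps = 100, save_stride = 20,
                                seed = 19))
  rep <- stability_report(tr, sys$topology, ff)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_xyz(tr, xyz)
  write_observables_tsv(tr, rep, tsv)
  lines <- readLines(xyz)
  expect_equal(lines[1], "6")
  expect_match(lines[2], "^t = ")
  expect_equal(length(lines), (6 + 2) * dim(tr$frames)[3])
  tab <- read.table(tsv)
  expect_equal(nrow(tab), dim(tr$frames)[3])
  expect_equal(ncol(tab), 7)
})
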