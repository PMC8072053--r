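# Geometric and file fixtures built in code at test time.

# n points on a circle of given radius in the plane spanned by (e1, e2),
# centered at `center`: a disc-like cloud whose least-variance axis is
# the plane normal.
ring_points <- function(n = 24, radius = 40, center = c(0, 0, 0),
                        e1 = c(1, 0, 0), e2 = c(0, 1, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  xyz <- t(sapply(th, function(a) center + radius * (cos(a) * e1 +
                                                       sin(a) * e2)))
  point_set(xyz)
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotate_point_set <- function(ps, R) {
  point_set(ps$xyz %*% t(R), weights = ps$weights)
}

translate_point_set <- function(ps, v) {
  point_set(sweep(ps$xyz, 2, v, `+`), weights = ps$weights)
}

# Minimal synthetic two-chain PDB: 3 DNA phosphorus atoms on chain A and
# 4 protein C-alpha atoms split across chains B and C.
write_fixture_pdb <- function(path) {
  fmt <- function(serial, name, resn, chain, resi, x, y, z, elem) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resn, chain, resi, x, y, z, elem)
  }
  lines <- c(
    fmt(1, " P  ", " DA", "A", 1, 0, 0, 0, "P"),
    fmt(2, " P  ", " DT", "A", 2, 3, 4, 0, "P"),
    fmt(3, " P  ", " DG", "A", 3, 6, 0, 8, "P"),
    fmt(4, " CA ", "ALA", "B", 1, 10, 0, 0, "C"),
    fmt(5, " CA ", "GLY", "B", 2, 13, 4, 0, "C"),
    fmt(6, " CA ", "SER", "C", 1, 16, 0, 8, "C"),
    fmt(7, " CA ", "LEU", "C", 2, 19, 4, 8, "C"),
    "END")
  writeLines(lines, path)
  path
}

# Small synthetic umbrella campaign on a reference landscape.
toy_campaign <- function(ref, centers, k_kj = 5, n_steps = 2e5,
                         dt = 0.01, save_stride = 20, seed = 42) {
  sch <- make_window_schedule(c(centers[1], centers[1], 1),
                              extra_ranges = lapply(centers[-1],
                                                    function(d) c(d, d, 1)),
                              k = k_kj, k_unit = "kJ", label = "toy")
  generate_campaign(ref, sch,
                    langevin_params(dt = dt, n_steps = n_steps,
                                    save_stride = save_stride, seed = seed))
}
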