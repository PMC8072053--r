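## Umbrella-sampling window construction, harmonic bias energies, and the
## two structural observables: the center-of-mass distance between
## nucleosomes and the angle between their superhelical axes.

#' Harmonic bias restraint for one umbrella window
#'
#' The sampled Hamiltonian of a window is H0 + 1/2 k (d - d0)^2; a
#' `bias_spec` stores the restraint center d0 and force constant k.
#' Force constants are stored internally in kcal/mol/A^2; the conventional
#' kJ/mol/A^2 values are converted on input.
#'
#' @param d0 restraint center (Angstrom), > 0
#' @param k force constant, >= 0
#' @param k_unit `"kcal"` (kcal/mol/A^2) or `"kJ"` (kJ/mol/A^2, converted)
#' @return an object of class `bias_spec` with fields `d0`, `k` (kcal/mol/A^2)
#' @export
#' @examples
#' bias_spec(225, 5, k_unit = "kJ")$k # 1.1951...
bias_spec <- function(d0, k, k_unit = c("kcal", "kJ")) {
  k_unit <- match.arg(k_unit)
  stopifnot(is.numeric(d0), length(d0) == 1, d0 > 0,
            is.numeric(k), length(k) == 1, k >= 0)
  if (k_unit == "kJ") k <- kj_to_kcal(k)
  structure(list(d0 = as.numeric(d0), k = as.numeric(k)),
            class = "bias_spec")
}

#' Bias energy of a window restraint
#'
#' @param d distance(s) in Angstrom
#' @param bias a [bias_spec()]
#' @return 1/2 k (d - d0)^2 in kcal/mol
#' @export
bias_energy <- function(d, bias) {
  stopifnot(inherits(bias, "bias_spec"))
  0.5 * bias$k * (d - bias$d0)^2
}

#' Build an umbrella window schedule
#'
#' Takes the union of inclusive arithmetic sequences of restraint centers
#' (a primary range plus any number of extra ranges), sorts them, merges
#' duplicates closer than 1e-6 Angstrom, and assigns force constants.
#'
#' @param primary_range numeric `c(lo, hi, step)` in Angstrom
#' @param extra_ranges list of further `c(lo, hi, step)` triples
#' @param k force constant(s): a scalar applied uniformly, a length-2 vector
#'   `c(k_even, k_odd)` applied alternately by 1-based sorted window index
#'   (even indices get `k[1]`), or a vector of one value per merged window
#' @param k_unit `"kJ"` (default, the conventional input unit) or `"kcal"`
#' @param label schedule name
#' @return an object of class `window_schedule`: a list of [bias_spec()]
#'   with attributes `label` and `centers`
#' @export
#' @examples
#' length(make_window_schedule(c(0, 10, 1))) # 11 windows, inclusive ends
make_window_schedule <- function(primary_range, extra_ranges = list(),
                                 k = 5, k_unit = c("kJ", "kcal"),
                                 label = "custom") {
  k_unit <- match.arg(k_unit)
  ranges <- c(list(primary_range), extra_ranges)
  centers <- unlist(lapply(ranges, function(r) {
    stopifnot(length(r) == 3)
    lo <- r[1]; hi <- r[2]; step <- r[3]
    if (step <= 0) stop("window range step must be > 0")
    if (lo > hi) stop("window range must have lo <= hi")
    ## inclusive endpoints; guard float drift at the upper end
    seq(lo, hi + step * 1e-9, by = step)
  }))
  centers <- sort(centers)
  keep <- c(TRUE, diff(centers) > 1e-6)
  centers <- centers[keep]
  n <- length(centers)
  if (length(k) == 1) {
    kv <- rep(k, n)
  } else if (length(k) == 2 && n > 2) {
    kv <- ifelse(seq_len(n) %% 2 == 0, k[1], k[2])
  } else if (length(k) == n) {
    kv <- k
  } else {
    stop("k must be scalar, length 2 (alternating), or one value per window")
  }
  windows <- Map(function(d0, ki) bias_spec(d0, ki, k_unit = k_unit),
                 centers, kv)
  structure(windows, label = label, centers = centers,
            class = "window_schedule")
}

#' Linked-nucleosome (LN) window schedule preset
#'
#' Centers from 175 to 250 A in 1 A steps plus additional windows from
#' 187.5 to 237.5 A in 1 A steps, uniform k = 5 kJ/mol/A^2: 127 windows.
#'
#' @return a `window_schedule` of 127 windows
#' @export
schedule_ln <- function() {
  make_window_schedule(c(175, 250, 1),
                       extra_ranges = list(c(187.5, 237.5, 1)),
                       k = 5, k_unit = "kJ", label = "LN")
}

#' Unlinked-nucleosome (ULN) window schedule preset
#'
#' Centers from 60 to 91 A in 0.5 A steps plus five additional windows
#' from 55 to 59 A in 1 A steps: 68 windows. Force constants alternate by
#' sorted window index (10 kJ/mol/A^2 on even 1-based indices, 5 on odd);
#' pass `k` to override, e.g. a per-window vector.
#'
#' @param k force-constant assignment as in [make_window_schedule()]
#' @return a `window_schedule` of 68 windows
#' @export
schedule_uln <- function(k = c(10, 5)) {
  make_window_schedule(c(60, 91, 0.5),
                       extra_ranges = list(c(55, 59, 1)),
                       k = k, k_unit = "kJ", label = "ULN")
}

#' Restraint centers of a schedule
#' @param schedule a `window_schedule`
#' @return numeric vector of d0 values (Angstrom)
#' @export
schedule_centers <- function(schedule) {
  stopifnot(inherits(schedule, "window_schedule"))
  attr(schedule, "centers")
}

#' @export
print.window_schedule <- function(x, ...) {
  ctr <- attr(x, "centers")
  cat(sprintf("Window schedule '%s': %d windows, centers %g..%g A\n",
              attr(x, "label"), length(x), min(ctr), max(ctr)))
  invisible(x)
}

#' Write / read a window manifest
#'
#' Plain-text sidecar describing a schedule, one line per window:
#' `window_id d0 k_kcal` (d0 in Angstrom, k in kcal/mol/A^2).
#'
#' @param schedule a `window_schedule`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_window_manifest <- function(schedule, path) {
  stopifnot(inherits(schedule, "window_schedule"))
  lines <- c("# window_id d0 k_kcal",
             vapply(seq_along(schedule), function(i) {
               sprintf("%d %.17g %.17g", i, schedule[[i]]$d0, schedule[[i]]$k)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_window_manifest
#' @export
read_window_manifest <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("window_id", "d0", "k_kcal"))
  windows <- Map(function(d0, k) bias_spec(d0, k, k_unit = "kcal"),
                 tab$d0, tab$k_kcal)
  structure(windows, label = basename(path), centers = tab$d0,
            class = "window_schedule")
}

## ---- structural observables ------------------------------------------

#' Weighted 3D point set
#'
#' Coordinates with per-point weights (atomic masses or unit weights),
#' representing an atom selection such as the DNA phosphorus atoms or the
#' histone-core C-alpha atoms of one nucleosome.
#'
#' @param xyz numeric matrix n x 3 (Angstrom)
#' @param weights per-point weights, >= 0 and not all zero (default unit)
#' @return an object of class `point_set`
#' @export
point_set <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("point_set coordinates must be n x 3")
  if (nrow(xyz) < 1) stop("point_set must contain at least one point")
  if (is.null(weights)) weights <- rep(1, nrow(xyz))
  stopifnot(length(weights) == nrow(xyz))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("point weights must be non-negative with positive total")
  }
  structure(list(xyz = xyz, weights = as.numeric(weights)),
            class = "point_set")
}

ps_centroid <- function(ps) {
  colSums(ps$xyz * ps$weights) / sum(ps$weights)
}

#' Distance between weighted centroids of two point sets
#'
#' The reaction coordinate d: the Euclidean distance between the weighted
#' centers of mass of two atom selections.
#'
#' @param a,b [point_set()] objects
#' @return distance in Angstrom
#' @export
com_distance <- function(a, b) {
  stopifnot(inherits(a, "point_set"), inherits(b, "point_set"))
  sqrt(sum((ps_centroid(a) - ps_centroid(b))^2))
}

## Smallest-variance principal axis of a weighted point cloud: the normal
## of the best-fit disc plane. Errors on (near-)collinear clouds where the
## plane normal is not defined.
ps_axis <- function(ps) {
  if (nrow(ps$xyz) < 3) stop("axis estimation needs >= 3 points")
  mu <- ps_centroid(ps)
  x <- sweep(ps$xyz, 2, mu)
  w <- ps$weights / sum(ps$weights)
  cv <- crossprod(x * sqrt(w))
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-10) {
    stop("degenerate (collinear) point cloud: superhelical axis undefined")
  }
  eg$vectors[, 3]
}

#' Angle between the superhelical axes of two point clouds
#'
#' Each axis is the direction of least variance of the centered, weighted
#' cloud (the disc-plane normal of the nucleosomal DNA superhelix). The
#' returned angle is between the two axes treated as unsigned directions,
#' folded into \[0, 90\] degrees; set `fold = FALSE` to keep the full
#' \[0, 180\] range (the sign of a plane normal is then arbitrary).
#'
#' @param a,b [point_set()] objects with >= 3 non-collinear points each
#' @param fold fold the angle to \[0, 90\] degrees (default TRUE)
#' @return angle in degrees
#' @export
superhelical_angle <- function(a, b, fold = TRUE) {
  stopifnot(inherits(a, "point_set"), inherits(b, "point_set"))
  na <- ps_axis(a); nb <- ps_axis(b)
  ct <- sum(na * nb) / sqrt(sum(na^2) * sum(nb^2))
  ct <- max(-1, min(1, ct))
  ang <- acos(if (fold) abs(ct) else ct) * 180 / pi
  ang
}

## Atomic masses from PDB atom names via the element assignment and mass
## table shipped with bio3d; unit weights for anything unrecognized.
atom_masses <- function(elety) {
  ev <- new.env()
  utils::data("elements", package = "bio3d", envir = ev)
  el <- tryCatch(suppressWarnings(bio3d::atom2ele(elety)),
                 error = function(e) rep(NA_character_, length(elety)))
  m <- ev$elements$mass[match(el, ev$elements$symb)]
  m[!is.finite(m)] <- 1
  m
}

#' Read an atom selection from a PDB file as a weighted point set
#'
#' Parses the first MODEL of a standard PDB file and returns the
#' coordinates and atomic masses of the matching atoms, in file order.
#' Typical selections: `elety = "P"` for DNA phosphorus atoms,
#' `elety = "CA", string = "protein"` for histone-core C-alpha atoms.
#'
#' @param path PDB file
#' @param elety atom-name filter (PDB atom type), or NULL for all
#' @param chain chain identifier(s), or NULL for all
#' @param string bio3d selection keyword (e.g. "protein", "nucleic"),
#'   or NULL
#' @return a [point_set()] with atomic-mass weights
#' @export
read_structure_points <- function(path, elety = NULL, chain = NULL,
                                  string = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file: ",
                                           conditionMessage(e)))
  args <- list(pdb = pdb)
  if (!is.null(string)) args$string <- string
  if (!is.null(elety)) args$elety <- elety
  if (!is.null(chain)) args$chain <- chain
  sel <- suppressWarnings(do.call(bio3d::atom.select, c(args,
                                                        verbose = FALSE)))
  if (length(sel$atom) == 0) {
    stop("selection matched no atoms in ", basename(path))
  }
  at <- pdb$atom[sel$atom, ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  point_set(xyz, weights = atom_masses(at$elety))
}
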