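#' Specification for a synthetic orientation-mixture trajectory
#'
#' Emulates a rigid ectodomain tethered to a planar membrane whose
#' orientation samples a mixture of preferred poses. Each frame draws a
#' mixture component, then a tilt pair (theta about y, psi about x) from
#' independent Gaussians clipped to the valid ranges, and an unconstrained
#' azimuth phi (rotation about the membrane normal) uniform on
#' (-180, 180]. The frame coordinates are
#' `Rz(phi) Ry(theta) Rx(psi) %*% reference`.
#'
#' @param components data.frame with columns `mean_theta`, `mean_psi`
#'   (degrees), `stdev` (degrees, > 0) and `weight` (summing to 1)
#' @param n_frames number of frames
#' @param seed RNG seed; the generator is a pure function of the spec
#' @param reference_coords `n x 3` matrix (nm) of at least 4 non-coplanar
#'   pseudo-atoms; default is a 5-point rigid body
#' @return object of class `orientation_mixture_spec`
#' @export
orientation_mixture_spec <- function(components, n_frames, seed,
                                     reference_coords = default_rigid_body()) {
  components <- as.data.frame(components)
  need <- c("mean_theta", "mean_psi", "stdev", "weight")
  if (!all(need %in% names(components)))
    stop("components needs columns: ", paste(need, collapse = ", "))
  if (abs(sum(components$weight) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(components$stdev <= 0)) stop("stdev must be > 0")
  if (any(components$mean_theta < -90 | components$mean_theta > 90))
    stop("mean_theta must lie in [-90, 90]")
  if (any(components$mean_psi <= -180 | components$mean_psi > 180))
    stop("mean_psi must lie in (-180, 180]")
  reference_coords <- as.matrix(reference_coords)
  if (nrow(reference_coords) < 4 ||
      qr(sweep(reference_coords, 2, colMeans(reference_coords)))$rank < 3)
    stop("degenerate body: need >= 4 non-coplanar reference atoms ",
         "(superposition would be underdetermined)")
  structure(list(components = components, n_frames = as.integer(n_frames),
                 seed = as.integer(seed),
                 reference_coords = reference_coords),
            class = "orientation_mixture_spec")
}

#' A small non-coplanar rigid body (nm) used as default reference
#' @param scale overall size in nm
#' @return 5 x 3 coordinate matrix
#' @export
default_rigid_body <- function(scale = 1) {
  scale * matrix(c(0, 0, 0,
                   1, 0, 0,
                   0, 1, 0,
                   0, 0, 2,
                   -0.5, -0.5, 0.5), ncol = 3, byrow = TRUE)
}

#' Generate an orientation-mixture trajectory with ground truth
#'
#' @param spec an [orientation_mixture_spec()]
#' @return list with `topology`, `trajectory` and `truth` (data.frame with
#'   0-based `frame`, `theta`, `psi`, `phi` in degrees and 1-based
#'   `component`)
#' @export
make_orientation_trajectory <- function(spec) {
  stopifnot(inherits(spec, "orientation_mixture_spec"))
  comp <- spec$components
  ref <- spec$reference_coords
  nf <- spec$n_frames
  withr_seed <- .with_seed(spec$seed)
  on.exit(withr_seed())
  k <- sample.int(nrow(comp), nf, replace = TRUE, prob = comp$weight)
  theta <- pmin(90, pmax(-90, stats::rnorm(nf, comp$mean_theta[k], comp$stdev[k])))
  psi <- stats::rnorm(nf, comp$mean_psi[k], comp$stdev[k])
  psi <- pmin(180, pmax(-180 + 1e-9, psi))
  phi <- stats::runif(nf, -180, 180)
  coords <- array(0, dim = c(nf, nrow(ref), 3))
  for (f in seq_len(nf)) {
    M <- rot_z(phi[f]) %*% rot_y(theta[f]) %*% rot_x(psi[f])
    coords[f, , ] <- ref %*% t(M)
  }
  atoms <- data.frame(
    name = "CA", element = "C",
    residue_seq = seq_len(nrow(ref)), residue_name = "PSD", chain = "A",
    protein = TRUE, stringsAsFactors = FALSE)
  truth <- data.frame(frame = seq_len(nf) - 1L, theta = theta, psi = psi,
                      phi = phi, component = k)
  list(topology = Topology(atoms), trajectory = Trajectory(coords),
       truth = truth)
}

# Save/restore global RNG state so generators are pure functions of the spec
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specification for two-state Markov contact kinetics
#'
#' Each residue-lipid pair evolves as a two-state (bound/unbound) Markov
#' chain: unbound -> bound with probability `p_on` per frame, bound ->
#' unbound with probability `p_off`. Bound frames draw a distance uniform in
#' `bound_distance_range`, unbound frames in `unbound_distance_range`. The
#' stationary bound fraction is `p_on / (p_on + p_off)` and the mean bound
#' dwell is `1 / p_off` frames, giving analytic ground truth for occupancy
#' and residence-time estimators.
#'
#' @param p_on,p_off per-frame transition probabilities in (0, 1)
#' @param n_frames,n_pairs series length and number of independent pairs
#' @param bound_distance_range length-2 numeric (nm), must lie entirely
#'   below the lower contact cutoff in force
#' @param unbound_distance_range length-2 numeric (nm), entirely above the
#'   upper cutoff
#' @param seed RNG seed
#' @param criteria the [contact_criteria()] the ranges are validated against
#' @return object of class `contact_kinetics_spec`
#' @export
contact_kinetics_spec <- function(p_on, p_off, n_frames, n_pairs = 1,
                                  bound_distance_range = c(0.30, 0.50),
                                  unbound_distance_range = c(1.20, 2.50),
                                  seed = 1,
                                  criteria = contact_criteria()) {
  if (p_on < 0 || p_on >= 1 || p_off <= 0 || p_off >= 1)
    stop("p_on must lie in [0, 1) and p_off in (0, 1)")
  if (max(bound_distance_range) >= criteria$lower_cutoff)
    stop("spec error: bound range overlaps the cutoff band ",
         "(booking would be ambiguous)")
  if (min(unbound_distance_range) <= criteria$upper_cutoff)
    stop("spec error: unbound range overlaps the cutoff band ",
         "(booking would be ambiguous)")
  structure(list(p_on = p_on, p_off = p_off,
                 n_frames = as.integer(n_frames),
                 n_pairs = as.integer(n_pairs),
                 bound_distance_range = bound_distance_range,
                 unbound_distance_range = unbound_distance_range,
                 seed = as.integer(seed)),
            class = "contact_kinetics_spec")
}

#' Generate Markov-switching distance series with ground-truth states
#'
#' @param spec a [contact_kinetics_spec()]
#' @return list with `distances` (`n_frames x n_pairs` matrix, nm) and
#'   `states` (logical matrix, TRUE = bound)
#' @export
make_contact_series <- function(spec) {
  stopifnot(inherits(spec, "contact_kinetics_spec"))
  restore <- .with_seed(spec$seed)
  on.exit(restore())
  nf <- spec$n_frames; np <- spec$n_pairs
  states <- matrix(FALSE, nf, np)
  p_bound0 <- if (spec$p_on + spec$p_off > 0)
    spec$p_on / (spec$p_on + spec$p_off) else 0
  for (p in seq_len(np)) {
    s <- logical(nf)
    s[1] <- stats::runif(1) < p_bound0   # start at stationarity
    u <- stats::runif(nf)
    for (f in seq_len(nf - 1)) {
      s[f + 1] <- if (s[f]) u[f] >= spec$p_off else u[f] < spec$p_on
    }
    states[, p] <- s
  }
  d <- matrix(stats::runif(nf * np), nf, np)
  br <- spec$bound_distance_range; ur <- spec$unbound_distance_range
  distances <- ifelse(states, br[1] + d * diff(range(br)),
                      ur[1] + d * diff(range(ur)))
  list(distances = distances, states = states)
}

#' Specification for constructed hydrogen-bond geometries
#'
#' @param triplets data.frame with columns `da_dist` (donor-acceptor
#'   distance, Angstrom), `dha_angle` (donor-hydrogen-acceptor angle,
#'   degrees) and logical `expected_bond`
#' @param dh_dist donor-hydrogen covalent distance used in the
#'   construction (Angstrom, default 1.0)
#' @return object of class `hbond_fixture_spec`
#' @export
hbond_fixture_spec <- function(triplets, dh_dist = 1.0) {
  triplets <- as.data.frame(triplets)
  need <- c("da_dist", "dha_angle", "expected_bond")
  if (!all(need %in% names(triplets)))
    stop("triplets needs columns: ", paste(need, collapse = ", "))
  if (any(triplets$da_dist <= 0)) stop("distances must be > 0")
  if (any(triplets$dha_angle < 0 | triplets$dha_angle > 180))
    stop("angles must lie in [0, 180]")
  structure(list(triplets = triplets, dh_dist = dh_dist),
            class = "hbond_fixture_spec")
}

# Place H so that the D-H-A angle at vertex H equals `angle_deg`, with D at
# the origin and A at (da, 0, 0), |DH| = dh. The achievable angle is a
# monotone function of the D-side opening angle beta; solved with uniroot.
.place_hydrogen <- function(da, dh, angle_deg) {
  alpha_of_beta <- function(beta) {
    H <- dh * c(cos(beta), sin(beta), 0)
    HD <- -H; HA <- c(da, 0, 0) - H
    acos(min(1, max(-1, sum(HD * HA) / sqrt(sum(HD^2) * sum(HA^2))))) * 180 / pi
  }
  lo <- 1e-9; hi <- pi - 1e-9
  a_lo <- alpha_of_beta(lo); a_hi <- alpha_of_beta(hi)
  if (angle_deg > max(a_lo, a_hi) + 1e-6 || angle_deg < min(a_lo, a_hi) - 1e-6)
    stop("construction error: D-H-A angle ", angle_deg,
         " deg unrealisable with D-A ", da, " A and D-H ", dh, " A")
  beta <- stats::uniroot(function(b) alpha_of_beta(b) - angle_deg,
                         c(lo, hi), tol = 1e-14)$root
  dh * c(cos(beta), sin(beta), 0)
}

#' Realise hydrogen-bond triplets as explicit atoms
#'
#' Each triplet becomes three atoms — a donor nitrogen with its hydrogen on
#' a protein-flagged residue (chain A) and an acceptor oxygen on a
#' lipid-flagged residue (chain B) — with exactly the requested
#' donor-acceptor distance and donor-hydrogen-acceptor angle. Triplets are
#' spaced 5 nm apart so they cannot interact.
#'
#' @param spec an [hbond_fixture_spec()]
#' @return list with `topology`, `trajectory` (one frame) and `truth`
#'   (the spec's triplet table with atom indices attached)
#' @export
make_hbond_frames <- function(spec) {
  stopifnot(inherits(spec, "hbond_fixture_spec"))
  tr <- spec$triplets
  n <- nrow(tr)
  coords <- matrix(0, 3 * n, 3)
  atoms <- data.frame(
    name = rep(c("N", "HN", "O"), n),
    element = rep(c("N", "H", "O"), n),
    residue_seq = rep(seq_len(n), each = 3),
    residue_name = rep(c("GLY", "GLY", "LIP"), n),
    chain = rep(c("A", "A", "B"), n),
    protein = rep(c(TRUE, TRUE, FALSE), n),
    lipid = rep(c(FALSE, FALSE, TRUE), n),
    hbond_donor = rep(c(TRUE, FALSE, FALSE), n),
    hbond_acceptor = rep(c(FALSE, FALSE, TRUE), n),
    hydrogen = rep(c(FALSE, TRUE, FALSE), n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    offset <- c(0, 5 * (i - 1), 0)            # nm
    H <- .place_hydrogen(tr$da_dist[i], spec$dh_dist, tr$dha_angle[i])
    base <- (i - 1) * 3
    coords[base + 1, ] <- offset                                 # donor
    coords[base + 2, ] <- offset + H / 10                        # hydrogen
    coords[base + 3, ] <- offset + c(tr$da_dist[i], 0, 0) / 10   # acceptor
  }
  truth <- tr
  truth$donor_index <- (seq_len(n) - 1L) * 3L
  truth$hydrogen_index <- truth$donor_index + 1L
  truth$acceptor_index <- truth$donor_index + 2L
  list(topology = Topology(atoms), trajectory = Trajectory(coords),
       truth = truth)
}

#' Add per-residue isotropic positional jitter to a base structure
#'
#' Every frame adds independent Gaussian noise (standard deviation
#' `sigma_nm` per axis, per atom) to each residue's atoms around the base
#' coordinates; no rigid-body drift is added, so the per-residue RMSF of the
#' result converges to `sqrt(3) * sigma`.
#'
#' @param topology a [Topology()]
#' @param base_coords `n_atoms x 3` matrix (nm)
#' @param sigma_nm per-residue noise amplitude, recycled over residues in
#'   topology order
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return a [Trajectory()]
#' @export
make_jitter_trajectory <- function(topology, base_coords, sigma_nm,
                                   n_frames, seed) {
  base_coords <- as.matrix(base_coords)
  check_topology_trajectory(topology, Trajectory(base_coords))
  nres <- length(topology$residue_index)
  sigma_nm <- rep_len(sigma_nm, nres)
  if (any(sigma_nm < 0)) stop("sigma must be >= 0")
  sigma_atom <- numeric(n_atoms(topology))
  for (r in seq_len(nres))
    sigma_atom[topology$residue_index[[r]] + 1L] <- sigma_nm[r]
  restore <- .with_seed(seed)
  on.exit(restore())
  nf <- as.integer(n_frames)
  na <- nrow(base_coords)
  coords <- array(stats::rnorm(nf * na * 3), dim = c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- base_coords + coords[f, , ] * sigma_atom
  Trajectory(coords)
}
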