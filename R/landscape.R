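#' Per-frame Euler poses relative to a reference structure
#'
#' Superposes the alignment selection of every frame onto the reference
#' with [kabsch_superpose()], takes the body's orientation matrix (the
#' inverse of the superposition rotation: the rotation carrying the
#' reference into the frame) and decomposes it with
#' [euler_from_rotation()].
#'
#' @param trajectory a [Trajectory()]
#' @param topology a [Topology()]
#' @param reference reference coordinates: an `n x 3` matrix over the
#'   alignment selection, a full-system `n_atoms x 3` matrix, or a 0-based
#'   frame index into the trajectory (default frame 0)
#' @param align_sel selection string for the alignment atoms
#' @param replicate replicate label stored with the poses
#' @return data.frame with `replicate`, 0-based `frame`, `theta_deg`,
#'   `psi_deg`, `rmsd_nm`, `gimbal_flag`
#' @export
euler_poses <- function(trajectory, topology, reference = 0L,
                        align_sel = "role protein and name CA",
                        replicate = 1L) {
  check_topology_trajectory(topology, trajectory)
  idx <- .resolve_selection(topology, align_sel)
  if (length(idx) < 3) stop("selection error: need >= 3 alignment atoms")
  if (is.numeric(reference) && length(reference) == 1L) {
    ref <- matrix(trajectory$coords[as.integer(reference) + 1L, idx + 1L, ],
                  ncol = 3)
  } else {
    reference <- as.matrix(reference)
    ref <- if (nrow(reference) == trajectory$n_atoms)
      reference[idx + 1L, , drop = FALSE] else reference
    if (nrow(ref) != length(idx))
      stop("pairing error: reference does not cover the alignment selection")
  }
  nf <- trajectory$n_frames
  out <- data.frame(replicate = rep(replicate, nf),
                    frame = seq_len(nf) - 1L,
                    theta_deg = numeric(nf), psi_deg = numeric(nf),
                    rmsd_nm = numeric(nf), gimbal_flag = logical(nf))
  for (f in seq_len(nf)) {
    mob <- matrix(trajectory$coords[f, idx + 1L, ], ncol = 3)
    fit <- kabsch_superpose(mob, ref)
    pose <- euler_from_rotation(t(fit$R))
    out$theta_deg[f] <- pose$theta
    out$psi_deg[f] <- pose$psi
    out$rmsd_nm[f] <- fit$rmsd
    out$gimbal_flag[f] <- pose$gimbal
  }
  out
}

# Scott's rule per axis for a 2-d KDE
.scott_bw <- function(x, n) stats::sd(x) * n^(-1 / 6)

#' Build an orientation landscape from a trajectory
#'
#' Computes per-frame Euler poses ([euler_poses()]), pools them (several
#' replicates may be supplied as a list of trajectories), evaluates a
#' Gaussian kernel density estimate on a regular 1-degree grid over
#' theta in `[-90, 90]` and psi in `[-180, 180]`, and detects density modes
#' (8-neighbour local maxima above `mode_threshold` of the global maximum;
#' the psi axis wraps). Each mode carries the member frames closer to it
#' than to any other mode. Gimbal-locked frames are kept in the pose table
#' but excluded from the density, with a reported count.
#'
#' @param trajectory a [Trajectory()] or a list of them (replicates)
#' @param topology a [Topology()]
#' @param reference as in [euler_poses()]; a frame index refers to the
#'   first replicate
#' @param align_sel selection string for the alignment atoms
#' @param bandwidth length-2 numeric KDE bandwidth (degrees) for
#'   (theta, psi); default Scott's rule per axis
#' @param mode_threshold fraction of the global density maximum a local
#'   maximum must reach (default 0.1)
#' @param grid_step grid spacing in degrees (default 1)
#' @return object of class `OrientationLandscape`: list with `poses`,
#'   `theta_grid`, `psi_grid`, `density` (matrix, integrates to ~1),
#'   `bandwidth`, `modes` (data.frame with `theta_deg`, `psi_deg`,
#'   `density`, `n_members`) and `members` (list of 0-based pose row
#'   indices per mode)
#' @export
build_landscape <- function(trajectory, topology, reference = 0L,
                            align_sel = "role protein and name CA",
                            bandwidth = NULL, mode_threshold = 0.1,
                            grid_step = 1) {
  trajs <- if (inherits(trajectory, "Trajectory")) list(trajectory)
  else trajectory
  if (is.numeric(reference) && length(reference) == 1L) {
    idx <- .resolve_selection(topology, align_sel)
    reference <- matrix(trajs[[1]]$coords[as.integer(reference) + 1L,
                                          idx + 1L, ], ncol = 3)
  }
  poses <- do.call(rbind, lapply(seq_along(trajs), function(r)
    euler_poses(trajs[[r]], topology, reference, align_sel, replicate = r)))
  use <- !poses$gimbal_flag
  n_gimbal <- sum(!use)
  if (n_gimbal)
    message(n_gimbal, " gimbal-locked frame(s) excluded from the density")
  th <- poses$theta_deg[use]; ps <- poses$psi_deg[use]
  n <- length(th)
  if (!n) stop("no usable poses")
  if (is.null(bandwidth)) {
    bandwidth <- c(max(.scott_bw(th, n), grid_step),
                   max(.scott_bw(ps, n), grid_step))
  }
  theta_grid <- seq(-90, 90, by = grid_step)
  psi_grid <- seq(-180, 180, by = grid_step)
  # separable Gaussian kernel; psi wrapped on its 360-degree circle
  Dth <- outer(theta_grid, th, function(g, x) stats::dnorm(g - x, sd = bandwidth[1]))
  dpsi <- outer(psi_grid, ps, "-")
  dpsi <- (dpsi + 180) %% 360 - 180
  Dps <- stats::dnorm(dpsi, sd = bandwidth[2])
  density <- (Dth %*% t(Dps)) / n
  modes <- .find_modes(density, theta_grid, psi_grid, mode_threshold)
  members <- .assign_members(poses, use, modes)
  modes$n_members <- vapply(members, length, integer(1))
  structure(list(poses = poses, theta_grid = theta_grid, psi_grid = psi_grid,
                 density = density, bandwidth = bandwidth, modes = modes,
                 members = members, n_gimbal = n_gimbal),
            class = "OrientationLandscape")
}

# 8-neighbour local maxima on the (theta, psi) grid; psi wraps, theta does
# not. Ties broken towards lower (theta, psi).
.find_modes <- function(density, theta_grid, psi_grid, mode_threshold) {
  nt <- nrow(density); np <- ncol(density)
  thr <- mode_threshold * max(density)
  hits <- data.frame(theta_deg = numeric(), psi_deg = numeric(),
                     density = numeric())
  wrap_p <- function(j) ((j - 1) %% (np - 1)) + 1  # first/last psi column coincide
  for (i in seq_len(nt)) {
    for (j in seq_len(np - 1)) {       # skip duplicated +180 column
      v <- density[i, j]
      if (v < thr) next
      is_max <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di
        if (ii < 1 || ii > nt) next
        vv <- density[ii, wrap_p(j + dj)]
        if (vv > v || (vv == v && (ii < i || (ii == i && wrap_p(j + dj) < j))))
          is_max <- FALSE
      }
      if (is_max)
        hits <- rbind(hits, data.frame(theta_deg = theta_grid[i],
                                       psi_deg = psi_grid[j], density = v))
    }
  }
  hits[order(-hits$density), , drop = FALSE]
}

.assign_members <- function(poses, use, modes) {
  if (!nrow(modes)) return(list())
  rows <- which(use)
  members <- vector("list", nrow(modes))
  if (length(rows)) {
    d <- sapply(seq_len(nrow(modes)), function(m)
      angular_pose_distance(poses$theta_deg[rows], poses$psi_deg[rows],
                            modes$theta_deg[m], modes$psi_deg[m]))
    d <- matrix(d, nrow = length(rows))
    nearest <- max.col(-d, ties.method = "first")
    for (m in seq_len(nrow(modes)))
      members[[m]] <- rows[nearest == m] - 1L   # 0-based pose row ids
  }
  members
}

#' Distance between poses in the (theta, psi) plane
#'
#' `sqrt(dtheta^2 + dpsi_wrapped^2)` with psi differences wrapped onto
#' (-180, 180].
#'
#' @param theta,psi pose coordinates (degrees; vectorised)
#' @param theta0,psi0 target coordinates (degrees)
#' @return numeric distances in degrees
#' @export
angular_pose_distance <- function(theta, psi, theta0, psi0) {
  dpsi <- (psi - psi0 + 180) %% 360 - 180
  sqrt((theta - theta0)^2 + dpsi^2)
}

#' Frames nearest a queried orientation
#'
#' @param landscape an [build_landscape()] result
#' @param theta,psi target orientation (degrees)
#' @param k number of frames to return
#' @return the `k` pose rows nearest the target, ordered by distance, with
#'   a `distance_deg` column
#' @export
frames_near <- function(landscape, theta, psi, k = 1L) {
  poses <- landscape$poses
  if (!nrow(poses)) stop("empty landscape")
  if (k > nrow(poses)) {
    warning("k exceeds the number of frames; returning all")
    k <- nrow(poses)
  }
  d <- angular_pose_distance(poses$theta_deg, poses$psi_deg, theta, psi)
  ord <- order(d)[seq_len(k)]
  out <- poses[ord, , drop = FALSE]
  out$distance_deg <- d[ord]
  rownames(out) <- NULL
  out
}

#' @export
print.OrientationLandscape <- function(x, ...) {
  cat("Orientation landscape:", nrow(x$poses), "poses",
      sprintf("(%d gimbal-locked excluded from KDE)", x$n_gimbal), "\n")
  cat("KDE bandwidth (theta, psi):",
      paste(format(x$bandwidth, digits = 3), collapse = ", "), "deg\n")
  cat("Modes:\n")
  print.data.frame(x$modes)
  invisible(x)
}

#' Serialise an orientation landscape to JSON
#'
#' @param landscape an [build_landscape()] result
#' @param path output path
#' @param include_density write the full density grid (default TRUE)
#' @return `path`, invisibly
#' @export
write_landscape_json <- function(landscape, path, include_density = TRUE) {
  modes <- landscape$modes
  modes$member_frames <- lapply(landscape$members, function(m)
    landscape$poses$frame[m + 1L])
  obj <- list(poses = landscape$poses,
              bandwidth = landscape$bandwidth,
              theta_grid = landscape$theta_grid,
              psi_grid = landscape$psi_grid,
              modes = modes,
              n_gimbal = landscape$n_gimbal)
  if (include_density) obj$density <- landscape$density
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
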