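#' Tilt angle of a vector against the membrane normal
#'
#' The membrane normal is taken as the +z axis of the simulation box, the
#' usual approximation for a planar bilayer built in an orthorhombic box.
#' The angle is `acos(v . z / |v|)`, unsigned, in `[0, 180]` degrees.
#'
#' @param v length-3 vector, or an `n x 3` matrix of vectors (rows)
#' @return tilt angle(s) in degrees
#' @export
tilt_angle <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("degenerate vector: zero length")
  acos(pmin(1, pmax(-1, v[, 3] / nrm))) * 180 / pi
}

#' Per-frame tilt of an axis defined by two atoms
#'
#' The axis runs from a tail atom to a head atom (each resolved from a
#' selection that must match exactly one atom), e.g. the two terminal
#' backbone nitrogens of an ectodomain, or the inositol-C6 to mannose-C4
#' vector of a GPI anchor linker.
#'
#' @param trajectory a [Trajectory()]
#' @param topology a [Topology()]
#' @param tail_sel,head_sel selection strings (or single 0-based indices)
#'   each resolving to exactly one atom
#' @return numeric vector of per-frame tilt angles (degrees in `[0, 180]`)
#' @export
axis_angle_series <- function(trajectory, topology, tail_sel, head_sel) {
  check_topology_trajectory(topology, trajectory)
  it <- .resolve_selection(topology, tail_sel)
  ih <- .resolve_selection(topology, head_sel)
  if (length(it) != 1L || length(ih) != 1L)
    stop("selection error: axis tail/head must each resolve to one atom ",
         "(got ", length(it), " and ", length(ih), ")")
  v <- trajectory$coords[, ih + 1L, , drop = FALSE] -
    trajectory$coords[, it + 1L, , drop = FALSE]
  tilt_angle(matrix(v, ncol = 3))
}

#' Per-residue root mean square fluctuation
#'
#' RMSF of each selected atom about its trajectory-mean position,
#' `sqrt(mean |r_i - <r_i>|^2)`, reported per residue (mean over the
#' residue's selected atoms; with the default C-alpha selection, one atom
#' per residue). With `superpose = TRUE` rigid-body motion is removed
#' first: every frame is least-squares superposed onto the mean structure
#' of the selected atoms, the mean is recomputed, and the procedure
#' iterates until the mean structure moves by less than `tol` (at most
#' `max_iter` rounds).
#'
#' @param trajectory a [Trajectory()]
#' @param topology a [Topology()]
#' @param atom_sel selection string for the atoms entering the analysis
#'   (default C-alpha atoms of protein residues)
#' @param superpose remove rigid-body motion before averaging (default TRUE)
#' @param max_iter,tol iteration controls for the mean-structure fit
#' @return data.frame of class `rmsf_profile` with `chain`, `residue_seq`,
#'   `residue_name`, `rmsf_nm`
#' @export
rmsf <- function(trajectory, topology, atom_sel = "role protein and name CA",
                 superpose = TRUE, max_iter = 10, tol = 1e-6) {
  check_topology_trajectory(topology, trajectory)
  if (trajectory$n_frames < 2)
    stop("undefined fluctuation: need at least 2 frames")
  idx <- .resolve_selection(topology, atom_sel)
  if (!length(idx)) stop("selection error: no atoms selected")
  nf <- trajectory$n_frames
  frames <- lapply(seq_len(nf) - 1L, function(f)
    matrix(trajectory$coords[f + 1L, idx + 1L, ], ncol = 3))
  if (superpose) {
    mean_str <- Reduce(`+`, frames) / nf
    for (it in seq_len(max_iter)) {
      frames <- lapply(frames, function(x) {
        fit <- kabsch_superpose(x, mean_str)
        sweep(x %*% t(fit$R), 2, fit$t, `+`)
      })
      new_mean <- Reduce(`+`, frames) / nf
      shift <- sqrt(max(rowSums((new_mean - mean_str)^2)))
      mean_str <- new_mean
      if (shift < tol) break
    }
  } else {
    mean_str <- Reduce(`+`, frames) / nf
  }
  dev2 <- Reduce(`+`, lapply(frames, function(x) rowSums((x - mean_str)^2))) / nf
  atom_rmsf <- sqrt(dev2)
  a <- topology$atoms[idx + 1L, , drop = FALSE]
  key <- paste(a$chain, a$residue_seq, sep = ":")
  agg <- tapply(atom_rmsf, factor(key, levels = unique(key)), mean)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], residue_seq = a$residue_seq[first],
                    residue_name = a$residue_name[first],
                    rmsf_nm = as.numeric(agg), stringsAsFactors = FALSE)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Per-residue spread of a structural ensemble
#'
#' Per-residue RMSD of a multi-model ensemble (e.g. an NMR deposition)
#' about its superposed mean structure — the same estimator as [rmsf()]
#' with models playing the role of frames, enabling a direct overlay with a
#' simulation RMSF profile.
#'
#' @param ensemble a list with `topology` and `trajectory` as returned by
#'   [read_structure()] on a multi-model file
#' @param atom_sel selection string (default C-alpha atoms)
#' @return an `rmsf_profile` data.frame
#' @export
ensemble_spread <- function(ensemble, atom_sel = "role protein and name CA") {
  if (ensemble$trajectory$n_frames < 2)
    stop("structural error: ensemble needs >= 2 models")
  rmsf(ensemble$trajectory, ensemble$topology, atom_sel = atom_sel,
       superpose = TRUE)
}

#' Gaussian kernel density estimate of an angle distribution
#'
#' Convenience wrapper used when exporting tilt-angle distributions as
#' smooth curves per replicate alongside the raw series.
#'
#' @param angles numeric vector of angles (degrees)
#' @param from,to,n evaluation grid (defaults cover `[0, 180]`)
#' @param bw bandwidth; default is `stats::bw.nrd0`
#' @return data.frame with `angle_deg` and `density`
#' @export
angle_density <- function(angles, from = 0, to = 180, n = 361, bw = NULL) {
  d <- if (is.null(bw)) stats::density(angles, from = from, to = to, n = n)
  else stats::density(angles, bw = bw, from = from, to = to, n = n)
  data.frame(angle_deg = d$x, density = d$y)
}
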