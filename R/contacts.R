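#' Dual-cutoff contact criteria
#'
#' The hysteresis (dual-cutoff) contact definition: a residue-lipid contact
#' begins when their minimum atom-atom distance first drops below
#' `lower_cutoff` and persists until it first reaches `upper_cutoff`,
#' suppressing boundary flicker at a single threshold.
#'
#' @param lower_cutoff lower distance cutoff in nm (default 0.55)
#' @param upper_cutoff upper distance cutoff in nm (default 1.0)
#' @return object of class `contact_criteria`
#' @export
contact_criteria <- function(lower_cutoff = 0.55, upper_cutoff = 1.0) {
  if (!(lower_cutoff > 0 && lower_cutoff < upper_cutoff))
    stop("need 0 < lower_cutoff < upper_cutoff")
  structure(list(lower_cutoff = lower_cutoff, upper_cutoff = upper_cutoff),
            class = "contact_criteria")
}

#' Minimum-image displacement components along one axis
#' @noRd
.min_image <- function(delta, box_len) {
  if (is.null(box_len)) return(delta)
  delta - box_len * round(delta / box_len)
}

#' Per-frame minimum distance between two atom groups
#'
#' For every frame, the minimum over all atom pairs of the Euclidean
#' distance, using the minimum-image convention per axis when the trajectory
#' carries an orthorhombic box, and plain distance otherwise.
#'
#' @param trajectory a [Trajectory()]
#' @param topology a [Topology()]
#' @param group_a,group_b selection strings (see [select_atoms()]) or
#'   integer vectors of 0-based atom indices
#' @return numeric vector of per-frame minimum distances (nm)
#' @export
min_distance_series <- function(trajectory, topology, group_a, group_b) {
  check_topology_trajectory(topology, trajectory)
  ia <- .resolve_selection(topology, group_a)
  ib <- .resolve_selection(topology, group_b)
  if (!length(ia) || !length(ib))
    stop("selection error: empty atom group")
  nf <- trajectory$n_frames
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    A <- matrix(trajectory$coords[f, ia + 1L, ], ncol = 3)
    B <- matrix(trajectory$coords[f, ib + 1L, ], ncol = 3)
    box <- if (!is.null(trajectory$box)) trajectory$box[f, ] else NULL
    d2 <- 0
    for (ax in 1:3) {
      delta <- outer(A[, ax], B[, ax], "-")
      delta <- .min_image(delta, box[ax])
      d2 <- d2 + delta^2
    }
    out[f] <- sqrt(min(d2))
  }
  out
}

.resolve_selection <- function(topology, sel) {
  if (is.character(sel)) return(select_atoms(topology, sel))
  sel <- as.integer(sel)
  if (any(sel < 0 | sel >= n_atoms(topology)))
    stop("selection error: atom index out of range")
  sort(sel)
}

#' Book contact events from a distance series under dual-cutoff hysteresis
#'
#' A contact starts at the first frame with distance below the lower
#' cutoff while unbound, persists while the distance stays below the upper
#' cutoff, and ends at the first frame at or above the upper cutoff. An
#' event still open at the end of the series is closed at `n_frames`
#' (truncated duration, no censoring correction).
#'
#' @param distances per-frame minimum distances (nm)
#' @param criteria a [contact_criteria()]
#' @return data.frame with 0-based `start_frame` and half-open `end_frame`;
#'   zero rows when no contact forms
#' @export
book_events <- function(distances, criteria = contact_criteria()) {
  if (!length(distances))
    return(data.frame(start_frame = integer(), end_frame = integer()))
  if (any(!is.finite(distances))) stop("distances must be finite")
  lower <- criteria$lower_cutoff; upper <- criteria$upper_cutoff
  n <- length(distances)
  starts <- integer(); ends <- integer()
  bound <- FALSE; start <- NA_integer_
  for (f in seq_len(n)) {
    d <- distances[f]
    if (!bound) {
      if (d < lower) { bound <- TRUE; start <- f - 1L }
    } else if (d >= upper) {
      starts <- c(starts, start); ends <- c(ends, f - 1L)
      bound <- FALSE
    }
  }
  if (bound) { starts <- c(starts, start); ends <- c(ends, n) }
  data.frame(start_frame = as.integer(starts), end_frame = as.integer(ends))
}

#' Per-residue, per-species occupancy and residence time
#'
#' Aggregates booked events into the per-residue statistics: occupancy is
#' the percentage of frames in which the residue touches at least one lipid
#' molecule of the species (union of event windows over molecules);
#' residence time is the mean event duration pooled over the species'
#' molecules, or the characteristic time of an exponential fit to the event
#' survival curve when `estimator = "survival-exp"`. Replicates are pooled
#' with equal frame weight by concatenating their event tables and summing
#' `n_frames`.
#'
#' @param events data.frame with columns `residue` (identifier), `species`,
#'   `molecule` (lipid molecule id), `start_frame`, `end_frame`
#' @param n_frames total frames the events were booked over
#' @param estimator `"mean"` (default) or `"survival-exp"`
#' @param biexponential for the survival estimator, fit a two-component
#'   exponential (default TRUE, falling back to one component on failure)
#' @return data.frame of class `contact_stats` with columns `residue`,
#'   `species`, `occupancy_pct`, `residence_frames`, `n_events`
#' @export
contact_stats <- function(events, n_frames,
                          estimator = c("mean", "survival-exp"),
                          biexponential = TRUE) {
  estimator <- match.arg(estimator)
  if (n_frames <= 0) stop("empty trajectory: n_frames must be > 0")
  need <- c("residue", "species", "molecule", "start_frame", "end_frame")
  if (!all(need %in% names(events)))
    stop("events needs columns: ", paste(need, collapse = ", "))
  if (nrow(events) && any(events$end_frame <= events$start_frame))
    stop("invalid events: end_frame must exceed start_frame")
  key <- interaction(events$residue, events$species, drop = TRUE, sep = "\r")
  groups <- split(events, key)
  out <- lapply(groups, function(g) {
    frames <- logical(n_frames)
    for (i in seq_len(nrow(g)))
      frames[(g$start_frame[i] + 1L):g$end_frame[i]] <- TRUE
    dur <- g$end_frame - g$start_frame
    res <- switch(estimator,
                  "mean" = mean(dur),
                  "survival-exp" = .survival_residence(dur, biexponential))
    data.frame(residue = g$residue[1], species = g$species[1],
               occupancy_pct = 100 * sum(frames) / n_frames,
               residence_frames = res,
               n_events = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(residue = character(), species = character(),
                      occupancy_pct = numeric(), residence_frames = numeric(),
                      n_events = integer())
  class(out) <- c("contact_stats", "data.frame")
  out
}

# Residence time from an exponential fit to the event survival curve
# S(t) = P(duration >= t). Single exponential gives 1/k; the biexponential
# A exp(-k1 t) + (1-A) exp(-k2 t) gives the mixture mean A/k1 + (1-A)/k2.
.survival_residence <- function(durations, biexponential = TRUE) {
  if (length(durations) < 3) return(mean(durations))
  t <- sort(unique(c(0, durations)))
  S <- vapply(t, function(x) mean(durations >= x), numeric(1))
  k0 <- 1 / max(mean(durations), 1e-9)
  # warnOnly + suppressWarnings: a biexponential fit to memoryless dwell
  # data is legitimately singular in its second component
  fit1 <- try(suppressWarnings(
    stats::nls(S ~ exp(-k * t), start = list(k = k0),
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (biexponential) {
    fit2 <- try(suppressWarnings(
      stats::nls(S ~ A * exp(-k1 * t) + (1 - A) * exp(-k2 * t),
                 start = list(A = 0.7, k1 = k0 * 2, k2 = k0 / 2),
                 lower = c(0, 1e-9, 1e-9), upper = c(1, Inf, Inf),
                 algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    if (!inherits(fit2, "try-error")) {
      p <- stats::coef(fit2)
      return(unname(p["A"] / p["k1"] + (1 - p["A"]) / p["k2"]))
    }
  }
  if (!inherits(fit1, "try-error"))
    return(unname(1 / stats::coef(fit1)["k"]))
  mean(durations)
}

#' @export
print.contact_stats <- function(x, ...) {
  cat("Contact statistics:", nrow(x), "residue-species pairs\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Flag contact hotspots
#'
#' Residues whose occupancy and residence time both reach their thresholds,
#' evaluated per species. The thresholds are analysis parameters: weaker
#' lipid partners (e.g. cholesterol versus a phosphatidylcholine) typically
#' warrant lower thresholds.
#'
#' @param stats a [contact_stats()] table
#' @param occ_threshold minimum occupancy in percent
#' @param res_threshold minimum residence time in frames
#' @return subset of `stats` rows meeting both thresholds
#' @export
hotspot_flags <- function(stats, occ_threshold, res_threshold) {
  if (occ_threshold < 0 || res_threshold < 0) stop("thresholds must be >= 0")
  stats[stats$occupancy_pct >= occ_threshold &
          stats$residence_frames >= res_threshold, , drop = FALSE]
}

#' Full residue-by-lipid contact analysis of a trajectory
#'
#' Drives [min_distance_series()], [book_events()] and [contact_stats()]
#' over every protein residue against every lipid molecule of the requested
#' species.
#'
#' @param trajectory a [Trajectory()]
#' @param topology a [Topology()]
#' @param species character vector of lipid species labels to analyse
#'   (default: all in the species map)
#' @param criteria a [contact_criteria()]
#' @param residue_sel selection string restricting the protein residues
#'   (default `"role protein"`)
#' @param ... passed to [contact_stats()]
#' @return a [contact_stats()] table; `residue` is `chain:residue_seq`
#' @export
lipid_contact_analysis <- function(trajectory, topology,
                                   species = NULL,
                                   criteria = contact_criteria(),
                                   residue_sel = "role protein", ...) {
  check_topology_trajectory(topology, trajectory)
  a <- topology$atoms
  if (is.null(species)) species <- unique(unname(topology$species_map))
  prot_idx <- select_atoms(topology, residue_sel)
  if (!length(prot_idx)) stop("selection error: no protein atoms selected")
  prot_key <- paste(a$chain, a$residue_seq, sep = ":")[prot_idx + 1L]
  residues <- split(prot_idx, factor(prot_key, levels = unique(prot_key)))
  lip <- a$lipid & species_of(topology, a$residue_name) %in% species
  lip_key <- paste(a$chain, a$residue_seq, sep = ":")[lip]
  lipids <- split(a$index[lip], factor(lip_key, levels = unique(lip_key)))
  ev_list <- list()
  for (rn in names(residues)) {
    for (ln in names(lipids)) {
      d <- min_distance_series(trajectory, topology, residues[[rn]],
                               lipids[[ln]])
      ev <- book_events(d, criteria)
      if (nrow(ev)) {
        ev$residue <- rn
        ev$molecule <- ln
        sp <- species_of(topology,
                         a$residue_name[lipids[[ln]][1] + 1L])
        ev$species <- sp
        ev_list[[length(ev_list) + 1L]] <- ev
      }
    }
  }
  if (!length(ev_list)) {
    return(contact_stats(
      data.frame(residue = character(), species = character(),
                 molecule = character(), start_frame = integer(),
                 end_frame = integer()), trajectory$n_frames, ...))
  }
  contact_stats(do.call(rbind, ev_list), trajectory$n_frames, ...)
}
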