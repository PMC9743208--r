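# Encounter-complex scoring: electrostatic protein-DNA interaction energy
# and specific-contact occupancy over target-aligned frames.

#' Per-frame electrostatic protein-DNA interaction energy
#'
#' Debye-Hueckel sum restricted to inter-molecular charged pairs (protein
#' bead x DNA bead), evaluated for each selected trajectory frame.
#'
#' @param trajectory a `cg_trajectory`
#' @param topology the matching `cg_topology` (default: the trajectory's)
#' @param params a [forcefield_params()] (default: the trajectory's)
#' @param frames frame indices to analyse (default all)
#' @return numeric vector of energies, kcal/mol (all zero, with a message,
#'   when no inter-molecular charged pair exists)
#' @export
interaction_electrostatic_energy <- function(trajectory,
                                             topology = trajectory$topology,
                                             params = trajectory$params,
                                             frames = NULL) {
  if (is.null(frames)) frames <- seq_len(trajectory$n_frames)
  nb <- nonbonded_pairs(topology, sigma_rule = params$sigma_rule)
  el <- nb$elec
  mol <- topology$beads$molecule
  el <- el[mol[el$i] != mol[el$j], , drop = FALSE]
  if (!nrow(el)) {
    message("no inter-molecular charged pairs; interaction energy is 0")
    return(rep(0, length(frames)))
  }
  ff <- .ff_terms(topology, params, include = character(0))
  ff$el_i <- as.integer(el$i) - 1L
  ff$el_j <- as.integer(el$j) - 1L
  ff$el_qq <- el$qq
  vapply(frames, function(fr) {
    .cg_energy_forces(trajectory$frames[, , fr], ff,
                      forces = FALSE)$electrostatic
  }, numeric(1))
}

#' Occupancy of target-site contacts
#'
#' For every target-site (12-10) term, the fraction of analysed frames in
#' which the pair distance is at or below `formed_threshold` times the
#' contact minimum `A_ij`.
#'
#' @param trajectory a `cg_trajectory`
#' @param topology the matching `cg_topology` with `target_site` terms
#' @param formed_threshold multiple of `A_ij` below which the contact
#'   counts as formed (default 1.2)
#' @param frames frame indices to analyse (default all)
#' @return list with `per_contact` (data frame `i`, `j`, `a`, `occupancy`)
#'   and `aggregate` (mean occupancy across contacts)
#' @export
contact_occupancy <- function(trajectory, topology = trajectory$topology,
                              formed_threshold = 1.2, frames = NULL) {
  ts <- topology$target_site
  if (!nrow(ts)) stop("topology has no target-site terms")
  if (is.null(frames)) frames <- seq_len(trajectory$n_frames)
  if (!length(frames)) {
    warning("no frames to analyse; occupancy undefined")
    return(list(per_contact = transform(ts, occupancy = NA_real_),
                aggregate = NA_real_, n_frames = 0L))
  }
  formed <- matrix(FALSE, length(frames), nrow(ts))
  for (q in seq_along(frames)) {
    xyz <- trajectory$frames[, , frames[q]]
    d <- sqrt(rowSums((xyz[ts$i, , drop = FALSE] -
                       xyz[ts$j, , drop = FALSE])^2))
    formed[q, ] <- d <= formed_threshold * ts$a
  }
  occ <- colMeans(formed)
  list(per_contact = data.frame(i = ts$i, j = ts$j, a = ts$a,
                                occupancy = occ),
       aggregate = mean(occ), n_frames = length(frames))
}

#' Select trajectory frames aligned with the target site
#'
#' Keeps the 1D frames (region distance from the axis at or below the
#' trace's `R_c`) in which every recognition region's Z lies within
#' `half_width_bp` base pairs of its target position.
#'
#' @param trace a `helix_trace`
#' @param target_z target-site Z position per region, Angstrom (recycled
#'   across regions if scalar)
#' @param half_width_bp alignment half-width, bp (default 2; `Inf` keeps
#'   all 1D frames)
#' @return integer vector of frame indices (empty selections are flagged
#'   with a warning)
#' @export
select_aligned_frames <- function(trace, target_z, half_width_bp = 2) {
  rise <- if (!is.null(trace$groove)) trace$groove$rise else .BP_RISE
  target_z <- rep_len(target_z, trace$n_regions)
  ok <- NULL
  for (r in seq_len(trace$n_regions)) {
    fr <- .trace_region(trace, r)
    this <- fr$d <= trace$R_c &
      (is.infinite(half_width_bp) |
       abs(fr$Z - target_z[r]) <= half_width_bp * rise)
    ok <- if (is.null(ok)) this else ok & this
  }
  sel <- which(ok)
  if (!length(sel)) warning("no frames aligned with the target site")
  sel
}

#' Score an encounter complex
#'
#' Convenience wrapper: selects target-aligned frames and reports the mean
#' (and sd) electrostatic protein-DNA interaction energy together with the
#' specific-contact occupancies (at the requested thresholds).
#'
#' @param trajectory a `cg_trajectory` of a protein-DNA complex whose
#'   topology carries target-site terms
#' @param trace a `helix_trace` for the recognition regions
#' @param target_z target Z per region, Angstrom
#' @param half_width_bp alignment half-width, bp (default 2)
#' @param thresholds occupancy thresholds to report (default
#'   `c(1.1, 1.2, 1.5)`)
#' @return object of class `encounter_stats`
#' @export
encounter_statistics <- function(trajectory, trace, target_z,
                                 half_width_bp = 2,
                                 thresholds = c(1.1, 1.2, 1.5)) {
  frames <- select_aligned_frames(trace, target_z, half_width_bp)
  if (!length(frames))
    return(structure(list(n_frames = 0L, energy_mean = NA_real_,
                          energy_sd = NA_real_, occupancy = NULL,
                          half_width_bp = half_width_bp),
                     class = "encounter_stats"))
  en <- interaction_electrostatic_energy(trajectory, frames = frames)
  occ <- lapply(thresholds, function(th)
    contact_occupancy(trajectory, formed_threshold = th, frames = frames))
  names(occ) <- paste0("t", thresholds)
  structure(list(
    n_frames = length(frames),
    energy_mean = mean(en), energy_sd = sd(en),
    occupancy = occ, thresholds = thresholds,
    half_width_bp = half_width_bp
  ), class = "encounter_stats")
}

#' @export
print.encounter_stats <- function(x, ...) {
  cat("encounter_stats over", x$n_frames, "aligned frames:\n")
  cat(sprintf("  electrostatic interaction energy %.3g +/- %.3g kcal/mol\n",
              x$energy_mean, x$energy_sd))
  for (nm in names(x$occupancy))
    cat(sprintf("  occupancy (threshold %s x A_ij): %.3g\n",
                sub("^t", "", nm), x$occupancy[[nm]]$aggregate))
  invisible(x)
}
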