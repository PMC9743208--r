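# Langevin dynamics in the study box.
#
# Reduced units: bead mass 1, thermal energy kT in kcal/mol, time step dt
# in reduced time units with friction gamma per reduced time. The mapping
# to physical time is by convention only: one MD step represents 50 ps, so
# a frame saved every 1000 steps is 50 ns and 1e8 steps are 5 ms.

#' Simulation configuration
#'
#' @param n_steps number of MD steps
#' @param dt integration time step in reduced units (default 0.005)
#' @param gamma Langevin friction coefficient (default 0.01)
#' @param kT thermal energy, kcal/mol (default 0.593, i.e. 298 K)
#' @param save_interval save a frame every this many steps (default 1000,
#'   i.e. one frame per 50 ns of mapped time)
#' @param seed RNG seed; (topology, config, seed) fully determine the
#'   trajectory
#' @param box list with `lo` and `hi`, the reflecting-wall bounds in
#'   Angstrom (default x, y in [-240, 240], z in [-225, 225])
#' @param rigid_dna hold DNA beads fixed (default `TRUE`; all analyses
#'   treat the DNA axis as the fixed Z axis)
#' @param ps_per_step physical time represented by one step, ps (default 50)
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_steps = 1e6, dt = 0.005, gamma = 0.01, kT = 0.593,
                       save_interval = 1000, seed = 1,
                       box = list(lo = c(-240, -240, -225),
                                  hi = c(240, 240, 225)),
                       rigid_dna = TRUE, ps_per_step = .PS_PER_STEP) {
  stopifnot(n_steps >= 0, dt > 0, gamma >= 0, kT >= 0, save_interval >= 1,
            length(box$lo) == 3, length(box$hi) == 3, all(box$hi > box$lo))
  structure(list(n_steps = as.numeric(n_steps), dt = dt, gamma = gamma,
                 kT = kT, save_interval = as.integer(save_interval),
                 seed = as.integer(seed), box = box, rigid_dna = rigid_dna,
                 ps_per_step = ps_per_step),
            class = "sim_config")
}

# movable-bead mask under the rigid-DNA convention
.movable_mask <- function(topology, rigid_dna) {
  if (rigid_dna) topology$beads$molecule != "dna"
  else rep(TRUE, nrow(topology$beads))
}

#' Advance the system by single Langevin steps
#'
#' One (or a few) BAOAB integration steps, exposed mainly for testing and
#' custom protocols; [run_simulation()] is the production entry point.
#' With zero force, zero temperature and zero velocity the positions are
#' unchanged; the same seed reproduces the same trajectory bitwise.
#'
#' @param topology a `cg_topology`
#' @param state list with `positions` (n x 3) and `velocities` (n x 3);
#'   `NULL` velocities mean zero
#' @param config a [sim_config()]
#' @param params a [forcefield_params()]
#' @param n_steps number of steps to take (default 1)
#' @return updated state list (`positions`, `velocities`, `energies`)
#' @export
langevin_step <- function(topology, state, config = sim_config(),
                          params = forcefield_params(), n_steps = 1) {
  pos <- .as_positions(topology, state$positions)
  vel <- state$velocities
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  ff <- .ff_terms(topology, params, rigid_dna = config$rigid_dna)
  res <- .cg_run_langevin(pos, as.matrix(vel), ff,
                          .movable_mask(topology, config$rigid_dna),
                          config$box$lo, config$box$hi,
                          as.integer(n_steps), config$dt, config$gamma,
                          config$kT, as.integer(n_steps) + 1L)
  list(positions = res$positions, velocities = res$velocities,
       energies = res$energies[nrow(res$energies), ])
}

#' Run a Langevin dynamics simulation
#'
#' Propagates the topology for `config$n_steps` BAOAB steps in the
#' reflecting-wall box, saving a frame every `config$save_interval` steps
#' (the initial state is always frame 1). Initial velocities are drawn
#' from the Maxwell-Boltzmann distribution at `config$kT`. The trajectory
#' is fully determined by (topology, config, seed). When
#' `config$rigid_dna` is `TRUE`, DNA beads are held fixed and DNA-internal
#' energy terms (constant by construction) are excluded from the reported
#' potential energy.
#'
#' @param topology a `cg_topology`
#' @param config a [sim_config()]
#' @param params a [forcefield_params()]
#' @return object of class `cg_trajectory`: list with `frames` (array
#'   n_beads x 3 x n_frames, Angstrom), `energies` (per-frame breakdown,
#'   kcal/mol), `frame_ns` (mapped time between frames), `config`,
#'   `params`, and `topology`
#' @export
run_simulation <- function(topology, config = sim_config(),
                           params = forcefield_params()) {
  stopifnot(inherits(topology, "cg_topology"), inherits(config, "sim_config"))
  n <- nrow(topology$beads)
  pos <- bead_positions(topology)
  movable <- .movable_mask(topology, config$rigid_dna)
  set.seed(config$seed)
  vel <- matrix(0, n, 3)
  if (config$kT > 0)
    vel[movable, ] <- matrix(rnorm(3 * sum(movable), sd = sqrt(config$kT)),
                             ncol = 3)
  ff <- .ff_terms(topology, params, rigid_dna = config$rigid_dna)
  res <- .cg_run_langevin(pos, vel, ff, movable,
                          config$box$lo, config$box$hi,
                          as.integer(config$n_steps), config$dt,
                          config$gamma, config$kT, config$save_interval)
  en <- as.data.frame(res$energies)
  names(en) <- c("bond", "angle", "dihedral", "contact", "excluded_volume",
                 "electrostatic", "potential", "kinetic")
  structure(list(
    frames = res$frames,
    energies = en,
    frame_ns = config$save_interval * config$ps_per_step / 1000,
    n_frames = dim(res$frames)[3],
    config = config, params = params, topology = topology
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", x$n_frames, "frames of", dim(x$frames)[1], "beads,",
      x$frame_ns, "ns/frame (", steps_to_time(x$config$n_steps), "ms total )\n")
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param trajectory a `cg_trajectory`
#' @param frame frame index (1-based)
#' @return n x 3 coordinate matrix
#' @export
trajectory_frame <- function(trajectory, frame) {
  trajectory$frames[, , frame]
}

#' Write a trajectory as plain-text XYZ with a JSON metadata sidecar
#'
#' @param trajectory a `cg_trajectory`
#' @param file output XYZ path; metadata goes to `<file>.meta.json`
#' @return `file`, invisibly
#' @export
write_trajectory_xyz <- function(trajectory, file) {
  n <- dim(trajectory$frames)[1]
  roles <- trajectory$topology$beads$role
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in seq_len(trajectory$n_frames)) {
    writeLines(c(as.character(n), paste("frame", fr)), con)
    xyz <- trajectory$frames[, , fr]
    writeLines(sprintf("%s %.6f %.6f %.6f", roles, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  jsonlite::write_json(
    list(frame_ns = trajectory$frame_ns, n_frames = trajectory$n_frames,
         seed = trajectory$config$seed, box = trajectory$config$box,
         n_steps = trajectory$config$n_steps),
    paste0(file, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
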