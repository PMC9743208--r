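# Orchestration: build -> simulate -> analyse -> report over a grid of
# (binder variant, salt concentration, replica), with deterministic seeds
# and a run manifest. The desk-scale preset exercises the full pipeline
# with the toy binder on a short duplex; the cluster-scale preset states
# the study-scale conditions (100 bp DNA, 1e8 steps, up to eight replicas,
# salts 0.01-0.06 M) for users with the corresponding compute budget.

#' Desk-scale pipeline preset
#'
#' Toy dimeric binder on 30-bp ideal B-DNA, 1e6 steps per replica, four
#' replicas at salts 0.01/0.02/0.04 M -- small enough to run on a laptop
#' while still showing rotation-coupled sliding and its salt dependence.
#'
#' @param n_steps steps per replica (default 1e6)
#' @param replicas replicas per condition (default 4)
#' @param salts ionic strengths, M
#' @param variants named numeric vector of hinge flexibility scales per
#'   binder variant (default: fully flexible "search"-like hinge)
#' @return a preset list for [run_condition_grid()]
#' @export
desk_preset <- function(n_steps = 1e6, replicas = 4,
                        salts = c(0.01, 0.02, 0.04),
                        variants = c(search = 0)) {
  list(name = "desk",
       n_bp = 30L, n_residues = 20L, dimeric = TRUE,
       variants = variants, salts = salts, replicas = as.integer(replicas),
       n_steps = n_steps, save_interval = 1000L,
       box = list(lo = c(-60, -60, -72), hi = c(60, 60, 72)),
       fit_window = c(50, 200))
}

#' Cluster-scale pipeline preset
#'
#' The study-scale conditions: 100-bp straight B-DNA in the
#' (-240, 240) x (-240, 240) x (-225, 225) A box, 1e8 MD steps (5 ms at
#' 50 ps/step) in eight replicas, ionic strengths 0.01-0.06 M, both hinge
#' variants. Provided for completeness; running it requires a cluster.
#'
#' @return a preset list for [run_condition_grid()]
#' @export
cluster_preset <- function() {
  list(name = "cluster",
       n_bp = 100L, n_residues = 24L, dimeric = TRUE,
       variants = c(search = 0, recognition = 1),
       salts = seq(0.01, 0.06, by = 0.01), replicas = 8L,
       n_steps = 1e8, save_interval = 1000L,
       box = list(lo = c(-240, -240, -225), hi = c(240, 240, 225)),
       fit_window = c(50, 200))
}

#' Read / write a pipeline preset as a YAML config file
#'
#' @param preset a preset list
#' @param file path
#' @return `read_run_config`: the preset list; `write_run_config`: `file`
#' @export
write_run_config <- function(preset, file) {
  preset$variants <- as.list(preset$variants) # keep names for length-1 vectors
  yaml::write_yaml(preset, file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg$variants <- unlist(cfg$variants)
  cfg$box <- list(lo = as.numeric(unlist(cfg$box$lo)),
                  hi = as.numeric(unlist(cfg$box$hi)))
  cfg
}

# md5 of a topology's JSON serialization (for the manifest)
.topology_hash <- function(topology) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_topology(topology, tmp)
  unname(tools::md5sum(tmp))
}

# recognition-region bead index sets of a merged (DNA + binder) system
.recognition_sets <- function(system_topology, rec_residues) {
  b <- system_topology$beads
  chains <- unique(b$chain_id[b$molecule == "protein"])
  lapply(chains, function(ch)
    which(b$molecule == "protein" & b$chain_id == ch &
          b$residue_id %in% rec_residues))
}

#' Build one simulation system (toy binder docked on ideal B-DNA)
#'
#' @param preset a preset list
#' @param hinge_f hinge flexibility scale for the binder variant
#' @param binder_seed seed for the binder generator
#' @return list with `topology` (merged system), `dna` (the `dna_model`),
#'   `binder`, and `recognition_sets`
#' @export
build_system <- function(preset = desk_preset(), hinge_f = 0,
                         binder_seed = 1) {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = preset$n_bp))
  binder <- generate_toy_binder(
    n_residues_per_monomer = preset$n_residues, dimeric = preset$dimeric,
    hinge_flexible = TRUE, hinge_f = hinge_f, seed = binder_seed)
  docked <- dock_binder(binder, dna)
  system <- merge_topologies(coarse_grain_dna(dna$atoms), docked)
  list(topology = system, dna = dna, binder = binder,
       recognition_sets = .recognition_sets(system, binder$rec_residues))
}

#' Run a (variant x salt x replica) condition grid
#'
#' For each binder variant and salt concentration, runs `replicas`
#' independent simulations (seeds derived deterministically from `seed`),
#' classifies the trajectories and estimates diffusion properties. A
#' failed replica is recorded in the manifest and the grid continues.
#'
#' @param preset a preset list ([desk_preset()] or [cluster_preset()])
#' @param seed base seed; replica seeds are `seed + 1000 * replica_index`
#' @param out_dir optional directory for per-condition CSV tables and the
#'   manifest JSON
#' @param keep_trajectories retain trajectories in the result (default
#'   `FALSE`: only analysis outputs are kept)
#' @return object of class `condition_grid`: list with `replicates` (one
#'   row per replica run), `summary` (mean/sd over replicas per
#'   condition), and `manifest`
#' @export
run_condition_grid <- function(preset = desk_preset(), seed = 1,
                               out_dir = NULL, keep_trajectories = FALSE) {
  stopifnot(all(preset$salts >= 0.005), all(preset$salts <= 0.1))
  rows <- list(); trajs <- list(); entries <- list()
  counter <- 0L
  for (v in seq_along(preset$variants)) {
    vname <- names(preset$variants)[v]
    sys <- build_system(preset, hinge_f = preset$variants[[v]],
                        binder_seed = seed)
    thash <- .topology_hash(sys$topology)
    for (salt in preset$salts) {
      params <- forcefield_params(ionic_strength = salt)
      for (rep_i in seq_len(preset$replicas)) {
        counter <- counter + 1L
        rep_seed <- as.integer(seed + 1000L * counter)
        entry <- list(variant = vname, salt = salt, replica = rep_i,
                      seed = rep_seed, topology_md5 = thash,
                      n_steps = preset$n_steps, status = "ok")
        res <- tryCatch({
          cfg <- sim_config(n_steps = preset$n_steps,
                            save_interval = preset$save_interval,
                            seed = rep_seed, box = preset$box)
          traj <- run_simulation(sys$topology, cfg, params)
          trace <- compute_helix_trace(traj, sys$recognition_sets,
                                       groove = sys$dna$groove)
          diff1 <- estimate_diffusion(trace, region = 1,
                                      window = preset$fit_window)
          seg <- segment_events(trace, region = 1)
          st <- event_statistics(seg$events,
                                 total_time_us = (traj$n_frames - 1) *
                                   traj$frame_ns * 1e-3)
          flips <- if (trace$n_regions >= 2) detect_flips(trace) else numeric(0)
          list(row = data.frame(
            variant = vname, salt = salt, replica = rep_i, seed = rep_seed,
            D = diff1$D, D_r = diff1$D_r, pitch_bp = diff1$pitch_bp,
            k_hop_per_ms = st$k_hop_per_ms,
            long_hop_per_ms = st$long_hop_per_ms,
            groove_duration_us = st$groove$mean_duration_us,
            groove_span_bp = st$groove$mean_span_bp,
            hop_duration_us = st$hop$mean_duration_us,
            hop_span_bp = st$hop$mean_span_bp,
            n_flips = length(flips),
            frac_3d = mean(classify_1d_3d(trace) == "3D"),
            stringsAsFactors = FALSE), traj = traj)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          entry$status <- conditionMessage(res)
          warning("replica failed (", vname, ", ", salt, " M, rep ", rep_i,
                  "): ", conditionMessage(res))
        } else {
          rows[[length(rows) + 1L]] <- res$row
          if (keep_trajectories) trajs[[length(trajs) + 1L]] <- res$traj
        }
        entries[[counter]] <- entry
      }
    }
  }
  replicates <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- NULL
  if (!is.null(replicates)) {
    agg <- function(col, f) stats::aggregate(
      replicates[[col]], by = list(variant = replicates$variant,
                                   salt = replicates$salt),
      FUN = f, na.rm = TRUE)$x
    base <- unique(replicates[, c("variant", "salt")])
    base <- base[order(base$variant, base$salt), ]
    summary <- data.frame(
      base,
      D_mean = agg("D", mean), D_sd = agg("D", sd),
      D_r_mean = agg("D_r", mean), D_r_sd = agg("D_r", sd),
      pitch_bp_mean = agg("pitch_bp", mean),
      pitch_bp_median = agg("pitch_bp", median),
      pitch_bp_sd = agg("pitch_bp", sd),
      k_hop_mean = agg("k_hop_per_ms", mean),
      row.names = NULL
    )
  }
  manifest <- list(preset = preset[setdiff(names(preset), "box")],
                   box = preset$box, base_seed = seed,
                   package_version = as.character(utils::packageVersion("cgslide")),
                   runs = entries)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(replicates))
      write.csv(replicates, file.path(out_dir, "replicates.csv"),
                row.names = FALSE)
    if (!is.null(summary))
      write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(replicates = replicates, summary = summary,
                 manifest = manifest,
                 trajectories = if (keep_trajectories) trajs else NULL),
            class = "condition_grid")
}

#' Human-readable condition report
#'
#' Formats a grid result as per-condition tables: diffusion properties
#' (D, pitch, D_r against salt), event statistics, and (when present)
#' encounter energetics. Values equal the numbers in the CSV outputs.
#'
#' @param grid a `condition_grid` from [run_condition_grid()]
#' @return list of data frames (`diffusion`, `events`), printed as a
#'   report
#' @export
report_summary <- function(grid) {
  if (is.null(grid$replicates)) {
    cat("empty condition grid: no successful replicas\n")
    return(invisible(list(diffusion = NULL, events = NULL)))
  }
  s <- grid$summary
  diffusion <- s[, c("variant", "salt", "D_mean", "D_sd", "pitch_bp_mean",
                     "pitch_bp_median", "D_r_mean", "D_r_sd")]
  r <- grid$replicates
  events <- stats::aggregate(
    r[, c("k_hop_per_ms", "long_hop_per_ms", "groove_duration_us",
          "groove_span_bp", "hop_duration_us", "hop_span_bp", "n_flips")],
    by = list(variant = r$variant, salt = r$salt),
    FUN = function(x) mean(x, na.rm = TRUE))
  cat("Diffusion properties by condition:\n")
  print(diffusion, digits = 3)
  cat("\nEvent statistics by condition (replica means):\n")
  print(events, digits = 3)
  invisible(list(diffusion = diffusion, events = events))
}
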