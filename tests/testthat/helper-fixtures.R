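# Shared fixtures built in code.

# minimal protein atom table: one CA per residue on a straight line
straight_peptide <- function(resnames, spacing = 3.8, chain = "A") {
  n <- length(resnames)
  data.frame(
    eleno = seq_len(n), elety = "CA", resid = resnames, chain = chain,
    resno = seq_len(n), x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    stringsAsFactors = FALSE
  )
}

# bare topology around explicit bead coordinates (no bonded terms)
bare_topology <- function(xyz, charge = 0, molecule = "protein",
                          radius = 2.0, chain = "A",
                          residue_id = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  beads <- data.frame(
    index = seq_len(n), role = if (molecule == "protein") "CA" else "phosphate",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n),
    residue_id = if (is.null(residue_id)) seq_len(n) else residue_id,
    chain_id = rep_len(chain, n), resname = "GLY",
    repulsion_radius = rep_len(radius, n),
    molecule = rep_len(molecule, n), stringsAsFactors = FALSE
  )
  cgslide:::new_cg_topology(beads)
}

# a small docked binder + DNA system used by several suites
desk_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_system(desk_preset(), hinge_f = 0, binder_seed = 1)
    cache
  }
})

# helix_trace built directly from per-frame values (single region)
manual_trace <- function(Z, d, phi, frame_ns = 50,
                         groove = list(slope = 2 * pi / 33.2, phase0 = 0,
                                       repeat_bp = 10, rise = 3.32),
                         region = 1L) {
  n <- length(Z)
  frames <- data.frame(region = region, frame = seq_len(n),
                       time_us = (seq_len(n) - 1) * frame_ns * 1e-3,
                       Z = Z, d = d, phi = cgslide:::.wrap_angle(phi),
                       phi_unwrapped = phi)
  structure(list(frames = frames, groove = groove, frame_ns = frame_ns,
                 R_c = 32, n_regions = length(unique(frames$region))),
            class = "helix_trace")
}
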