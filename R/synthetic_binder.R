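# Toy DNA binder: a schematic mini-protein used to exercise the full
# model-building / simulation / analysis chain at desk scale. Per monomer it
# has a compact helical core held by a dense native-contact network, a short
# hinge, and an 8-residue "recognition helix" carrying five +1 charges
# (arginines) laid out along the major-groove helix of an ideal B-DNA whose
# groove azimuth is 0 at Z = 0 (see dock_binder() for placement on an
# arbitrary duplex). The fold is schematic -- helix-like spacings chosen for
# charge and shape placement, not a physical protein structure.

.toy_rec_len <- 13L
.toy_hinge_len <- 2L

#' Generate a toy DNA-binding mini-protein
#'
#' Builds a deterministic-for-seed monomeric or dimeric binder in the
#' docking frame of an ideal B-DNA on the Z axis (major groove azimuth 0 at
#' Z = 0). The last `8` residues of each monomer form the recognition group
#' whose five arginine beads face the DNA; the preceding 3 glycines are the
#' hinge; the remaining residues form the core. The dimer is generated by a
#' two-fold rotation about the Y axis, and the two recognition groups are
#' crosslinked by one inter-chain bond in the topology (an engineered
#' disulfide-like link that keeps the dimer associated).
#'
#' @param n_residues_per_monomer residues per monomer (>= 20); residues
#'   beyond 20 extend the core
#' @param dimeric if `TRUE` (default) generate the two-fold symmetric dimer
#' @param hinge_flexible if `TRUE` (default) scale hinge dihedrals and
#'   hinge contacts by `hinge_f`
#' @param hinge_f flexibility scale applied to the hinge when
#'   `hinge_flexible` (default 0: fully flexible hinge, the search-like state)
#' @param seed integer seed for the small coordinate jitter (0.05 A) that
#'   breaks exact symmetry; identical seeds give identical coordinates
#' @param groove_slope azimuth advance of the target groove in rad/A
#'   (default the ideal B-DNA value 2 * pi / (10 * 3.32))
#' @param contact_cutoff native-contact detection cutoff used for the toy
#'   topology, Angstrom (default 6.0; the toy model is C-alpha only, so a
#'   larger-than-heavy-atom cutoff gives it a stabilizing elastic network)
#' @return object of class `toy_binder`: list with `atoms` (C-alpha atom
#'   table), `topology` (a [cg_topology]), `rec_residues` (per-chain list of
#'   recognition-group residue ids), `hinge_residues`, and the call
#'   parameters
#' @export
generate_toy_binder <- function(n_residues_per_monomer = 20, dimeric = TRUE,
                                hinge_flexible = TRUE, hinge_f = 0,
                                seed = 1,
                                groove_slope = 2 * pi / (.HELICAL_REPEAT * .BP_RISE),
                                contact_cutoff = 6.0, rec_radius = 13.4) {
  n <- as.integer(n_residues_per_monomer)
  if (n < 20) stop("n_residues_per_monomer must be >= 20")
  if (hinge_f < 0 || hinge_f > 1) stop("hinge_f must be in [0, 1]")
  n_core <- n - .toy_rec_len - .toy_hinge_len

  # recognition clamp: a 13-bead arc lying across the major groove at a
  # base-pair plane, spanning the +/- 110 degree opening between the two
  # phosphate ridges that flank the groove. Its end beads are arginines
  # sitting ~3.5 A outside the two ridges, in z-registry with the
  # phosphate lattice; together with the mirrored arch of the second
  # monomer the dimer grips the DNA at four in-register points, so the
  # stable azimuth is the groove center and translation along the DNA is
  # coupled to rotation with the helical repeat. The arch spans the whole
  # groove opening, so it cannot fall into it.
  s <- groove_slope
  z_c <- 4.98 # a base-pair plane height for an even-length centered duplex
  half_major <- 110 * pi / 180 # ridge azimuth relative to the groove center
  m <- seq_len(.toy_rec_len)
  theta <- half_major - (m - 1) * 2 * half_major / (.toy_rec_len - 1)
  psi <- s * z_c + theta
  rec <- cbind(rec_radius * sin(psi), rec_radius * cos(psi), z_c)
  rec_names <- rep("ALA", .toy_rec_len)
  rec_names[c(1, 2, .toy_rec_len - 1, .toy_rec_len)] <- "ARG"

  # hinge: straight 3.8 A steps from the first recognition bead up to the
  # core anchor, heading radially outward and slightly up in Z
  rec1 <- rec[1, ]
  away <- c(rec1[1], rec1[2], 0) / sqrt(rec1[1]^2 + rec1[2]^2)
  hdir <- away + c(0, 0, 0.4)
  hdir <- hdir / sqrt(sum(hdir^2))
  core_end <- rec1 + hdir * 3.8 * (.toy_hinge_len + 1)
  tfrac <- seq_len(.toy_hinge_len) / (.toy_hinge_len + 1)
  hinge <- t(sapply(rev(tfrac), function(t) rec1 + t * (core_end - rec1)))

  # core: alpha-like helix advancing radially away from the DNA, last core
  # residue at the anchor
  omega <- 100 * pi / 180
  cdir <- c(core_end[1], core_end[2], 0)
  cdir <- cdir / sqrt(sum(cdir^2))
  core <- if (n_core > 0) t(sapply(seq_len(n_core), function(ii)
    core_end + (n_core - ii) * 1.2 * cdir +
      2.3 * ((cos(omega * ii) - cos(omega * n_core)) * c(0, 0, 1) +
             (sin(omega * ii) - sin(omega * n_core)) *
               c(-cdir[2], cdir[1], 0)))) else matrix(0, 0, 3)

  xyz <- rbind(core, hinge, rec)
  resnames <- c(rep(c("ALA", "SER", "LEU"), length.out = n_core),
                rep("GLY", .toy_hinge_len),
                rec_names)
  if (dimeric) {
    xyz2 <- xyz %*% diag(c(-1, 1, -1)) # two-fold rotation about Y
    xyz <- rbind(xyz, xyz2)
    resnames <- rep(resnames, 2)
    chain <- rep(c("A", "B"), each = n)
  } else {
    chain <- rep("A", n)
  }
  set.seed(as.integer(seed))
  xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.05), ncol = 3)

  atoms <- data.frame(
    eleno = seq_len(nrow(xyz)), elety = "CA", resid = resnames,
    chain = chain, resno = rep(seq_len(n), length.out = nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE
  )

  hinge_res <- (n_core + 1):(n_core + .toy_hinge_len)
  rec_res <- (n_core + .toy_hinge_len + 1):n

  topo <- coarse_grain_protein(atoms)
  topo <- add_topology_contacts(
    topo, compute_native_contacts(atoms, topo, heavy_atom_cutoff = contact_cutoff))
  # brace the recognition arch(es) into a rigid scaffold: stiff harmonic
  # restraint bonds between arch bead pairs more than three residues apart
  # and, for the dimer, between the two arches (the paired clamp then moves
  # as one rigid body, standing in for the folded dimeric DNA-binding
  # domain held together by the engineered inter-chain crosslink)
  bd <- topo$beads
  xyzb <- as.matrix(bd[, c("x", "y", "z")])
  brace <- NULL
  add_brace <- function(i, j2) {
    d0 <- sqrt(sum((xyzb[i, ] - xyzb[j2, ])^2))
    rbind(brace, data.frame(i = i, j = j2, x0 = d0, kf = 10))
  }
  for (ch in unique(bd$chain_id)) {
    ridx <- which(bd$chain_id == ch & bd$residue_id %in% rec_res)
    for (a in seq_along(ridx)) for (b2 in seq_along(ridx))
      if (b2 - a > 3) brace <- add_brace(ridx[a], ridx[b2])
  }
  if (dimeric) {
    ra <- which(bd$chain_id == "A" & bd$residue_id %in% rec_res)
    rb <- which(bd$chain_id == "B" & bd$residue_id %in% rec_res)
    for (i in ra) for (j2 in rb)
      if (sqrt(sum((xyzb[i, ] - xyzb[j2, ])^2)) < 25)
        brace <- add_brace(i, j2)
  }
  if (!is.null(brace)) {
    topo$bonds <- rbind(topo$bonds, brace)
    bkey <- paste(pmin(brace$i, brace$j), pmax(brace$i, brace$j))
    drop <- paste(pmin(topo$contacts$i, topo$contacts$j),
                  pmax(topo$contacts$i, topo$contacts$j)) %in% bkey
    topo$contacts <- topo$contacts[!drop, , drop = FALSE]
  }
  if (hinge_flexible) {
    # soften the hinge region including its flanking residues, so the
    # dihedrals that span the core-hinge and hinge-clamp junctions carry
    # the flexibility scale
    flex_set <- max(1L, min(hinge_res) - 1L):min(n, max(hinge_res) + 1L)
    topo <- apply_flexibility(topo, residue_set = flex_set, f = hinge_f)
  }

  structure(list(
    atoms = atoms, topology = topo,
    rec_residues = rec_res, hinge_residues = hinge_res,
    n_residues_per_monomer = n, dimeric = dimeric,
    hinge_flexible = hinge_flexible, hinge_f = hinge_f, seed = seed,
    groove_slope = groove_slope
  ), class = "toy_binder")
}

#' Place a binder topology onto a DNA model's major groove
#'
#' The toy binder is generated against a groove whose azimuth is 0 at
#' Z = 0. This helper rotates the binder about Z (and optionally shifts it
#' along Z with the matching azimuthal advance) so its recognition face
#' lines up with the major groove of the given straight DNA model.
#'
#' @param topology binder [cg_topology] (or a `toy_binder`, whose topology
#'   is used)
#' @param dna a straight `dna_model` from [generate_ideal_bdna()]
#' @param z_offset axial shift in Angstrom (default 0)
#' @return the topology with transformed bead coordinates
#' @export
dock_binder <- function(topology, dna, z_offset = 0) {
  if (inherits(topology, "toy_binder")) topology <- topology$topology
  stopifnot(inherits(topology, "cg_topology"), inherits(dna, "dna_model"))
  ang <- dna$groove$phase0 + dna$groove$slope * z_offset
  b <- topology$beads
  x <- b$x * cos(ang) + b$y * sin(ang)
  y <- -b$x * sin(ang) + b$y * cos(ang)
  topology$beads$x <- x
  topology$beads$y <- y
  topology$beads$z <- b$z + z_offset
  topology
}
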