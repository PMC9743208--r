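# Synthetic DNA generators: ideal straight B-DNA and a bent two-arm mimic.
#
# Beads/atoms are laid out on regular helices in idealized cylindrical
# coordinates. Radii approximate the geometric group centers of B-DNA
# (phosphate ~9.4 A, sugar ~7.4 A, base ~2.0 A from the helix axis). Each
# coarse-grained group is emitted as a small set of pseudo-atoms whose
# geometric center sits exactly on the ideal bead position, so the DNA
# coarse-graining code path (group detection + centroid) is exercised for
# real when these models are written to PDB and read back.

#' DNA helix geometry description
#'
#' @param n_bp number of base pairs (>= 1)
#' @param rise axial rise per base pair in Angstrom (default 3.32)
#' @param twist helical twist per base pair in degrees (default 36, i.e. a
#'   10-bp helical repeat)
#' @param groove_phase azimuth (radians) of the major-groove center at the
#'   first base pair
#' @param r_phosphate,r_sugar,r_base radial distance of the phosphate, sugar
#'   and base group centers from the helix axis, Angstrom
#' @param minor_groove_width angular width of the minor groove between the
#'   two backbone strands, degrees
#' @return object of class `dna_geometry`
#' @export
dna_geometry <- function(n_bp = 100, rise = 3.32, twist = 36,
                         groove_phase = 0,
                         r_phosphate = 9.4, r_sugar = 7.4, r_base = 2.0,
                         minor_groove_width = 140) {
  if (!is.numeric(n_bp) || length(n_bp) != 1 || n_bp < 1)
    stop("n_bp must be a single number >= 1")
  if (rise <= 0) stop("rise must be positive")
  if (twist <= 0 || twist >= 180) stop("twist (degrees per bp) must be in (0, 180)")
  structure(list(
    n_bp = as.integer(n_bp), rise = rise, twist = twist,
    groove_phase = groove_phase,
    r_phosphate = r_phosphate, r_sugar = r_sugar, r_base = r_base,
    minor_groove_width = minor_groove_width
  ), class = "dna_geometry")
}

#' Helical repeat of a DNA geometry, in base pairs
#' @param geom a [dna_geometry()]
#' @return base pairs per full turn (360 / twist)
#' @export
helical_repeat <- function(geom) 360 / geom$twist

# azimuth convention used throughout the package: phi = atan2(x, y), i.e.
# phi = 0 points along +y and the sign follows the x component.
.azim_to_xy <- function(phi, r) cbind(x = r * sin(phi), y = r * cos(phi))

# per-bp axial coordinates, duplex centered at the origin
.bp_z <- function(geom) {
  (seq_len(geom$n_bp) - 1) * geom$rise - (geom$n_bp - 1) * geom$rise / 2
}

# major-groove center azimuth at each bp
.bp_groove_azimuth <- function(geom) {
  geom$groove_phase + (seq_len(geom$n_bp) - 1) * geom$twist * pi / 180
}

# one nucleotide's pseudo-atoms; group centroids land exactly on the ideal
# bead positions (phosphate, sugar, base)
.nucleotide_atoms <- function(resname, chain, resno, phi, z, geom) {
  pos <- function(r, dphi = 0) c(.azim_to_xy(phi + dphi, r), z)
  p <- pos(geom$r_phosphate)
  s <- pos(geom$r_sugar)
  b <- pos(geom$r_base)
  data.frame(
    elety = c("P", "OP1", "OP2", "C1'", "C4'", "O4'", "N1", "C2", "C4"),
    resid = resname, chain = chain, resno = resno,
    x = c(p[1], p[1], p[1], s[1] + 0.6, s[1] - 0.6, s[1], b[1], b[1], b[1]),
    y = c(p[2], p[2], p[2], s[2], s[2], s[2], b[2], b[2] + 0.6, b[2] - 0.6),
    z = c(p[3], p[3] + 0.8, p[3] - 0.8, s[3], s[3], s[3], z, z + 0.7, z - 0.7),
    stringsAsFactors = FALSE
  )
}

#' Generate an ideal straight B-DNA duplex
#'
#' Constructs a generic straight duplex centered at the origin with its
#' helix axis on Z: three coarse-grained groups (phosphate, sugar, base) per
#' nucleotide on regular helices set by `rise` and `twist`. The default
#' 100-bp, 3.32 A-rise duplex spans (100 - 1) x 3.32 = 328.7 A, about 330 A.
#' Deterministic: no randomness is involved.
#'
#' @param geom a [dna_geometry()]
#' @return an object of class `dna_model`: list with `atoms` (pseudo-atom
#'   table), `geometry`, `kind = "straight"`, `bp_z` (axial coordinate per
#'   bp) and `groove` (exact linear major-groove calibration: `slope` in
#'   rad/A and `phase0`, the groove azimuth at Z = 0)
#' @examples
#' dna <- generate_ideal_bdna(dna_geometry(n_bp = 100))
#' diff(range(dna$bp_z)) # 328.68 A
#' @export
generate_ideal_bdna <- function(geom = dna_geometry()) {
  stopifnot(inherits(geom, "dna_geometry"))
  n <- geom$n_bp
  z <- .bp_z(geom)
  gc <- .bp_groove_azimuth(geom)
  half_major <- (360 - geom$minor_groove_width) / 2 * pi / 180
  seq_a <- rep(c("DA", "DT"), length.out = n)
  seq_b <- ifelse(seq_a == "DA", "DT", "DA")
  atoms <- vector("list", 2L * n)
  for (k in seq_len(n)) {
    atoms[[k]] <- .nucleotide_atoms(seq_a[k], "A", k, gc[k] + half_major, z[k], geom)
    # strand B is antiparallel: its residue numbering runs against +Z
    atoms[[n + k]] <- .nucleotide_atoms(seq_b[k], "B", n - k + 1L,
                                        gc[k] - half_major, z[k], geom)
  }
  atoms <- do.call(rbind, atoms)
  atoms$eleno <- seq_len(nrow(atoms))
  slope <- (geom$twist * pi / 180) / geom$rise
  phase0 <- .wrap_angle(geom$groove_phase + (geom$n_bp - 1) * geom$twist * pi / 180 / 2)
  structure(list(
    atoms = atoms, geometry = geom, kind = "straight", bp_z = z,
    bend = NULL,
    groove = list(slope = slope, phase0 = phase0,
                  repeat_bp = helical_repeat(geom), rise = geom$rise)
  ), class = "dna_model")
}

#' Generate a bent DNA mimic from two straight helical arms
#'
#' Builds an ideal duplex and rigidly rotates the arm beyond `bend_center`
#' about an axis perpendicular to the helix axis at the junction, producing
#' two straight arms whose axes meet at the given angle (the minor groove
#' opens on the convex side of the junction). `bend_angle = 0` returns a
#' model identical to [generate_ideal_bdna()].
#'
#' @param geom a [dna_geometry()]
#' @param bend_angle inter-arm angle in degrees, in `[0, 90]`
#' @param bend_center base-pair index of the junction, in `[1, n_bp]`
#' @return a `dna_model` (see [generate_ideal_bdna()]); `kind = "bent"`,
#'   with `bend = list(angle, center)`
#' @export
generate_bent_dna <- function(geom = dna_geometry(), bend_angle = 40,
                              bend_center = NULL) {
  stopifnot(inherits(geom, "dna_geometry"))
  if (is.null(bend_center)) bend_center <- ceiling(geom$n_bp / 2)
  if (bend_angle < 0 || bend_angle > 90)
    stop("bend_angle must be in [0, 90] degrees")
  if (bend_center < 1 || bend_center > geom$n_bp)
    stop("bend_center must be a bp index in [1, n_bp]")
  model <- generate_ideal_bdna(geom)
  if (bend_angle == 0) {
    model$kind <- "bent"
    model$bend <- list(angle = 0, center = bend_center)
    return(model)
  }
  zc <- model$bp_z[bend_center]
  beta <- bend_angle * pi / 180
  # which atoms belong to the distal arm (bp index > bend_center)
  bp_of_atom <- .atom_bp_index(model)
  sel <- bp_of_atom > bend_center
  a <- model$atoms
  yz <- cbind(a$y[sel], a$z[sel] - zc)
  rot <- yz %*% rbind(c(cos(beta), sin(beta)), c(-sin(beta), cos(beta)))
  a$y[sel] <- rot[, 1]
  a$z[sel] <- rot[, 2] + zc
  model$atoms <- a
  model$kind <- "bent"
  model$bend <- list(angle = bend_angle, center = bend_center)
  model
}

# bp index (1..n_bp) for every atom row of a dna_model
.atom_bp_index <- function(model) {
  n <- model$geometry$n_bp
  ifelse(model$atoms$chain == "A", model$atoms$resno, n - model$atoms$resno + 1L)
}

# wrap an angle (or vector) to (-pi, pi]
.wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
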