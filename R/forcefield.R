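# Force-field parameters and R-level energy/force evaluation.
#
# Units: energies kcal/mol, lengths Angstrom, charges in elementary
# charges. The screened Coulomb interaction is
#   E = K_Coulomb * B(kappa) * q_i q_j * exp(-kappa r) / (eps r)
# with K_Coulomb = 332 kcal/mol (so that two unit charges 1 A apart in
# vacuum-like eps = 1 interact with 332 kcal/mol) and the ion dependency
# B(kappa) approximated as 1 for dilute solutions.

.K_COULOMB <- 332
.KB_KCAL <- 0.0019872      # Boltzmann constant, kcal/mol/K
.E2_4PIEPS0 <- 332.0637    # e^2/(4 pi eps0) in kcal*A/mol, for Bjerrum length

#' Inverse Debye screening length
#'
#' For a 1:1 salt at ionic strength `c_i` (mol/L):
#' `kappa = sqrt(8 pi l_B N_A c_i 1e-27)` per Angstrom, with the Bjerrum
#' length `l_B = e^2 / (4 pi eps0 eps k_B T)` in Angstrom. At
#' `c_i = 0.01` M, `eps = 70`, `T = 298` K this gives a screening length
#' `1/kappa` of about 28.7 A (`l_B` about 8.01 A).
#'
#' @param c_i ionic strength in mol/L (> 0)
#' @param epsilon relative dielectric constant (default 70)
#' @param temperature absolute temperature in K (default 298)
#' @return kappa in 1/Angstrom
#' @export
debye_kappa <- function(c_i, epsilon = 70, temperature = 298) {
  if (any(c_i <= 0)) stop("ionic strength c_i must be positive")
  l_b <- .E2_4PIEPS0 / (epsilon * .KB_KCAL * temperature)
  sqrt(8 * pi * l_b * 6.02214076e23 * c_i * 1e-27)
}

#' Force-field parameter set
#'
#' @param ionic_strength 1:1 salt ionic strength, mol/L
#' @param dielectric relative dielectric constant (default 70)
#' @param temperature temperature in K used for the screening length
#' @param kT thermal energy in kcal/mol (default 0.593, i.e. 298 K)
#' @param k_coulomb Coulomb prefactor, kcal/mol (default 332)
#' @param b_kappa ion-dependency factor B(kappa), approximated as 1
#' @param k_ev excluded-volume prefactor, kcal/mol (default 1)
#' @param elec_cutoff electrostatic cutoff in Angstrom with energy shift;
#'   `NULL` (default) disables the cutoff
#' @param dihedral_form `"cosine"` (default; the standard structure-based
#'   series `K[(1 - cos d) + (1/2)(1 - cos 3d)]`) or `"harmonic"`
#' @param sigma_rule combination rule for per-bead repulsion radii
#'   (see [nonbonded_pairs()])
#' @return object of class `ff_params` (includes the derived `kappa`)
#' @export
forcefield_params <- function(ionic_strength = 0.02, dielectric = 70,
                              temperature = 298, kT = 0.593,
                              k_coulomb = .K_COULOMB, b_kappa = 1,
                              k_ev = .K_EV, elec_cutoff = NULL,
                              dihedral_form = c("cosine", "harmonic"),
                              sigma_rule = "mean") {
  dihedral_form <- match.arg(dihedral_form)
  stopifnot(ionic_strength > 0, dielectric > 0, kT > 0)
  structure(list(
    ionic_strength = ionic_strength, dielectric = dielectric,
    temperature = temperature, kT = kT, k_coulomb = k_coulomb,
    b_kappa = b_kappa, k_ev = k_ev,
    kappa = debye_kappa(ionic_strength, dielectric, temperature),
    elec_cutoff = if (is.null(elec_cutoff)) -1 else elec_cutoff,
    dihedral_form = dihedral_form, sigma_rule = sigma_rule
  ), class = "ff_params")
}

# Build the flat term list consumed by the compiled kernel. `include`
# selects term classes; `rigid_dna` drops all DNA-internal terms (their
# energy is constant when the DNA beads are held fixed).
.ff_terms <- function(topology, params = forcefield_params(),
                      include = c("bonded", "contact", "ev", "elec"),
                      rigid_dna = FALSE) {
  b <- topology$beads
  is_dna <- b$molecule == "dna"
  keep_rows <- function(df, cols) {
    if (!nrow(df) || !rigid_dna) return(df)
    all_dna <- Reduce(`&`, lapply(cols, function(cc) is_dna[df[[cc]]]))
    df[!all_dna, , drop = FALSE]
  }
  empty_i <- integer(0); empty_n <- numeric(0)
  out <- list(bond_i = empty_i, bond_j = empty_i, bond_x0 = empty_n,
              bond_k = empty_n,
              angle_i = empty_i, angle_j = empty_i, angle_k = empty_i,
              angle_x0 = empty_n, angle_kf = empty_n,
              dih_i = empty_i, dih_j = empty_i, dih_k = empty_i,
              dih_l = empty_i, dih_x0 = empty_n, dih_kf = empty_n,
              con_i = empty_i, con_j = empty_i, con_a = empty_n,
              con_kf = empty_n,
              ev_i = empty_i, ev_j = empty_i, ev_sigma = empty_n,
              el_i = empty_i, el_j = empty_i, el_qq = empty_n,
              k_ev = params$k_ev,
              k_coul_eff = params$k_coulomb * params$b_kappa / params$dielectric,
              kappa = params$kappa,
              elec_cutoff = params$elec_cutoff,
              dihedral_form = if (params$dihedral_form == "cosine") 0L else 1L)
  if ("bonded" %in% include) {
    bd <- keep_rows(topology$bonds, c("i", "j"))
    an <- keep_rows(topology$angles, c("i", "j", "k"))
    dh <- keep_rows(topology$dihedrals, c("i", "j", "k", "l"))
    out$bond_i <- as.integer(bd$i) - 1L; out$bond_j <- as.integer(bd$j) - 1L
    out$bond_x0 <- bd$x0; out$bond_k <- bd$kf
    out$angle_i <- as.integer(an$i) - 1L; out$angle_j <- as.integer(an$j) - 1L
    out$angle_k <- as.integer(an$k) - 1L
    out$angle_x0 <- an$x0; out$angle_kf <- an$kf
    out$dih_i <- as.integer(dh$i) - 1L; out$dih_j <- as.integer(dh$j) - 1L
    out$dih_k <- as.integer(dh$k) - 1L; out$dih_l <- as.integer(dh$l) - 1L
    out$dih_x0 <- dh$x0; out$dih_kf <- dh$kf * dh$f
  }
  if ("contact" %in% include) {
    ct <- keep_rows(topology$contacts, c("i", "j"))
    ts <- topology$target_site
    out$con_i <- c(as.integer(ct$i), as.integer(ts$i)) - 1L
    out$con_j <- c(as.integer(ct$j), as.integer(ts$j)) - 1L
    out$con_a <- c(ct$a, ts$a)
    out$con_kf <- c(ct$kf * ct$f, ts$kf)
  }
  if (any(c("ev", "elec") %in% include)) {
    nb <- nonbonded_pairs(topology, include_dna_dna = !rigid_dna,
                          sigma_rule = params$sigma_rule)
    if ("ev" %in% include) {
      out$ev_i <- as.integer(nb$ev$i) - 1L
      out$ev_j <- as.integer(nb$ev$j) - 1L
      out$ev_sigma <- nb$ev$sigma
    }
    if ("elec" %in% include) {
      out$el_i <- as.integer(nb$elec$i) - 1L
      out$el_j <- as.integer(nb$elec$j) - 1L
      out$el_qq <- nb$elec$qq
    }
  }
  out
}

.as_positions <- function(topology, positions) {
  if (is.null(positions)) positions <- bead_positions(topology)
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(topology$beads) || ncol(positions) != 3)
    stop("positions must be an n_beads x 3 matrix")
  positions
}

#' Bonded energy (bonds + angles + dihedrals)
#'
#' @param topology a `cg_topology`
#' @param positions n x 3 coordinate matrix (default: reference positions)
#' @param params a [forcefield_params()]
#' @return list with `total` and the `bond`, `angle`, `dihedral` breakdown
#' @export
bonded_energy <- function(topology, positions = NULL,
                          params = forcefield_params()) {
  pos <- .as_positions(topology, positions)
  e <- .cg_energy_forces(pos, .ff_terms(topology, params, include = "bonded"),
                         forces = FALSE)
  list(total = e$bond + e$angle + e$dihedral,
       bond = e$bond, angle = e$angle, dihedral = e$dihedral)
}

#' Native-contact (12-10) energy, including target-site terms
#' @inheritParams bonded_energy
#' @return energy in kcal/mol
#' @export
contact_energy <- function(topology, positions = NULL,
                           params = forcefield_params()) {
  pos <- .as_positions(topology, positions)
  .cg_energy_forces(pos, .ff_terms(topology, params, include = "contact"),
                    forces = FALSE)$contact
}

#' Excluded-volume energy
#' @inheritParams bonded_energy
#' @return energy in kcal/mol
#' @export
excluded_volume_energy <- function(topology, positions = NULL,
                                   params = forcefield_params()) {
  pos <- .as_positions(topology, positions)
  .cg_energy_forces(pos, .ff_terms(topology, params, include = "ev"),
                    forces = FALSE)$excluded_volume
}

#' Debye-Hueckel electrostatic energy
#' @inheritParams bonded_energy
#' @return energy in kcal/mol
#' @export
electrostatic_energy <- function(topology, positions = NULL,
                                 params = forcefield_params()) {
  pos <- .as_positions(topology, positions)
  .cg_energy_forces(pos, .ff_terms(topology, params, include = "elec"),
                    forces = FALSE)$electrostatic
}

#' Total energy and forces
#'
#' @inheritParams bonded_energy
#' @return list with the energy breakdown (`bond`, `angle`, `dihedral`,
#'   `contact`, `excluded_volume`, `electrostatic`, `total`) and `forces`,
#'   the n x 3 matrix of `-dE/dx` in kcal/mol/A
#' @export
total_energy_and_forces <- function(topology, positions = NULL,
                                    params = forcefield_params()) {
  pos <- .as_positions(topology, positions)
  .cg_energy_forces(pos, .ff_terms(topology, params), forces = TRUE)
}
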