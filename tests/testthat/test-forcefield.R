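# Force-field correctness: closed-form term values, the Debye screening
# length, gradient consistency, and the pair-channel bookkeeping.

test_that("bonded terms reproduce the stated force constants", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  topo <- bare_topology(xyz)
  topo$bonds <- data.frame(i = 1:2, j = 2:3, x0 = 3.8, kf = 100)
  topo$angles <- data.frame(i = 1, j = 2, k = 3, x0 = pi, kf = 20)
  expect_equal(bonded_energy(topo)$total, 0)

  # one bond stretched by 0.1 A: 100 * 0.01 = 1.0 kcal/mol
  p <- xyz; p[3, 1] <- p[3, 1] + 0.1
  expect_equal(bonded_energy(topo, p)$bond, 1.0, tolerance = 1e-12)

  # one angle displaced by 0.1 rad: 20 * 0.01 = 0.2 kcal/mol
  th <- pi - 0.1
  p2 <- rbind(c(0, 0, 0), c(3.8, 0, 0),
              c(3.8 - 3.8 * cos(th), 3.8 * sin(th), 0))
  topo2 <- topo; topo2$bonds <- topo$bonds[0, ]
  e2 <- bonded_energy(topo2, p2)
  expect_equal(e2$angle, 0.2, tolerance = 1e-9)

  # colinear angle is a well-defined limit, not a failure
  expect_silent(total_energy_and_forces(topo, xyz))
})

test_that("the 12-10 contact has depth -k at A_ij and a flat minimum", {
  topo <- bare_topology(rbind(c(0, 0, 0), c(6, 0, 0)))
  topo$contacts <- data.frame(i = 1, j = 2, a = 6, kf = 1, f = 1)
  expect_equal(contact_energy(topo), -1) # 5 - 6 = -1 exactly
  far <- rbind(c(0, 0, 0), c(600, 0, 0))
  expect_lt(abs(contact_energy(topo, far)), 1e-9)
  # numeric slope at the minimum
  h <- 1e-4
  up <- contact_energy(topo, rbind(c(0, 0, 0), c(6 + h, 0, 0)))
  dn <- contact_energy(topo, rbind(c(0, 0, 0), c(6 - h, 0, 0)))
  expect_lt(abs(up - dn) / (2 * h), 1e-6)
})

test_that("excluded volume follows (sigma/r)^12 with k_ev = 1", {
  topo <- bare_topology(rbind(c(0, 0, 0), c(2.0, 0, 0)), residue_id = c(1, 10))
  expect_equal(excluded_volume_energy(topo), 1) # r = sigma (2+2)/2 = 2
  p2 <- rbind(c(0, 0, 0), c(4.0, 0, 0))
  expect_equal(excluded_volume_energy(topo, p2), 2^-12, tolerance = 1e-9)
})

test_that("excluded-volume total equals a brute-force all-pairs sum", {
  set.seed(9)
  xyz <- matrix(runif(60, 0, 14), 20, 3)
  topo <- bare_topology(xyz) # residues 1..20 on one chain
  got <- excluded_volume_energy(topo)
  want <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    if (j - i <= 3) next
    r <- sqrt(sum((xyz[j, ] - xyz[i, ])^2))
    if (r <= 3 * 2.0) want <- want + (2.0 / r)^12 # kernel truncates at 3 sigma
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the Debye screening length matches the closed form and scaling laws", {
  k1 <- debye_kappa(0.01, 70, 298)
  expect_equal(1 / k1, 28.7, tolerance = 0.01) # l_B about 8.01 A
  expect_equal(debye_kappa(0.04) / debye_kappa(0.01), 2, tolerance = 1e-12)
  expect_error(debye_kappa(0), "positive")
  expect_lt(debye_kappa(1e-12), 1e-5) # Coulomb limit
})

test_that("Debye-Hueckel energies match closed forms", {
  topo <- bare_topology(rbind(c(0, 0, 0), c(10, 0, 0)),
                        charge = c(1, -1), residue_id = c(1, 10))
  params <- forcefield_params(ionic_strength = 0.01)
  params$kappa <- 0 # unscreened Coulomb limit
  expect_equal(electrostatic_energy(topo, params = params),
               332 * (-1) / (70 * 10), tolerance = 1e-12) # -0.47428...
  params$kappa <- 1 / 28.7
  expect_equal(electrostatic_energy(topo, params = params),
               -0.4742857 * exp(-10 / 28.7), tolerance = 1e-6) # about -0.335
  topo0 <- bare_topology(rbind(c(0, 0, 0), c(10, 0, 0)), charge = 0,
                         residue_id = c(1, 10))
  expect_equal(electrostatic_energy(topo0, params = params), 0)
})

test_that("electrostatic attraction weakens monotonically with ionic strength", {
  sys <- desk_system()
  salts <- c(0.01, 0.02, 0.03, 0.04, 0.06)
  topo <- sys$topology
  fake_traj <- structure(
    list(frames = array(bead_positions(topo),
                        dim = c(nrow(topo$beads), 3, 1)),
         n_frames = 1, topology = topo),
    class = "cg_trajectory")
  e <- vapply(salts, function(s)
    interaction_electrostatic_energy(
      fake_traj, params = forcefield_params(ionic_strength = s)),
    numeric(1))
  expect_true(all(e < 0))
  expect_true(all(diff(abs(e)) < 0))
})

test_that("forces match central finite differences on a random configuration", {
  sys <- desk_system()
  topo <- sys$topology
  params <- forcefield_params(ionic_strength = 0.02)
  set.seed(31)
  pos <- bead_positions(topo) + matrix(rnorm(nrow(topo$beads) * 3, sd = 0.1),
                                       ncol = 3)
  ef <- total_energy_and_forces(topo, pos, params)
  h <- 1e-5
  worst <- 0
  for (trial in 1:30) {
    i <- sample(nrow(pos), 1); q <- sample(3, 1)
    pp <- pos; pp[i, q] <- pp[i, q] + h
    pm <- pos; pm[i, q] <- pm[i, q] - h
    fd <- -(total_energy_and_forces(topo, pp, params)$total -
            total_energy_and_forces(topo, pm, params)$total) / (2 * h)
    scale <- max(abs(fd), 1e-3)
    worst <- max(worst, abs(fd - ef$forces[i, q]) / scale)
  }
  expect_lt(worst, 1e-5)

  # Newton's third law: forces sum to zero
  expect_lt(max(abs(colSums(ef$forces))), 1e-9)

  # energy decomposition sums to the total
  parts <- ef$bond + ef$angle + ef$dihedral + ef$contact +
    ef$excluded_volume + ef$electrostatic
  expect_equal(parts, ef$total, tolerance = 1e-12)
})

test_that("the energy is invariant under rigid rotation of the whole system", {
  sys <- desk_system()
  params <- forcefield_params(ionic_strength = 0.02)
  pos <- bead_positions(sys$topology)
  e0 <- total_energy_and_forces(sys$topology, pos, params)$total
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e1 <- total_energy_and_forces(sys$topology, pos %*% R, params)$total
  expect_lt(abs(e1 - e0), 1e-8 * max(1, abs(e0)))
})

test_that("each nonbonded pair uses exactly one channel (contact XOR EV)", {
  sys <- desk_system()
  nb <- nonbonded_pairs(sys$topology)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ev_keys <- key(nb$ev$i, nb$ev$j)
  ct_keys <- c(key(sys$topology$contacts$i, sys$topology$contacts$j),
               key(sys$topology$target_site$i, sys$topology$target_site$j))
  expect_length(intersect(ev_keys, ct_keys), 0)
  # bonded pairs appear in neither channel
  bd_keys <- key(sys$topology$bonds$i, sys$topology$bonds$j)
  expect_length(intersect(ev_keys, bd_keys), 0)
  expect_length(intersect(key(nb$elec$i, nb$elec$j), bd_keys), 0)
  # electrostatic pairs all carry nonzero charge products
  expect_true(all(nb$elec$qq != 0))
})
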