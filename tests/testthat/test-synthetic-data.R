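# Synthetic generators: ideal/bent DNA geometry, toy binder, oracle traces.

test_that("ideal B-DNA has the expected axial extent and helical repeat", {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = 100, rise = 3.32))
  expect_equal(diff(range(dna$bp_z)), 99 * 3.32) # 328.68 A, about 330 A
  expect_lt(abs(diff(range(dna$bp_z)) - 330), 2)

  one <- generate_ideal_bdna(dna_geometry(n_bp = 1))
  expect_equal(diff(range(one$bp_z)), 0)
  expect_error(dna_geometry(n_bp = 0), "n_bp")

  # 36 deg/bp twist: azimuth at bp k+10 equals bp k (mod 2pi)
  topo <- coarse_grain_dna(dna$atoms)
  pa <- topo$beads[topo$beads$role == "phosphate" &
                   topo$beads$chain_id == "A", ]
  pa <- pa[order(pa$residue_id), ]
  az <- atan2(pa$x, pa$y)
  dev <- cgslide:::.wrap_angle(az[11:100] - az[1:90])
  expect_lt(max(abs(dev)), 1e-9)
})

test_that("DNA generators are deterministic and beads sit on the stated radii", {
  g <- dna_geometry(n_bp = 12)
  expect_identical(generate_ideal_bdna(g), generate_ideal_bdna(g))
  topo <- coarse_grain_dna(generate_ideal_bdna(g)$atoms)
  r <- sqrt(topo$beads$x^2 + topo$beads$y^2)
  r_mean <- tapply(r, topo$beads$role, mean)
  expect_equal(as.vector(r_mean[c("phosphate", "sugar", "base")]),
               c(9.4, 7.4, 2.0), tolerance = 1e-6)
  expect_equal(sum(topo$beads$charge), -2 * 12)
})

test_that("bent DNA reduces to straight at zero angle and hits the target arm angle", {
  g <- dna_geometry(n_bp = 30)
  straight <- generate_ideal_bdna(g)
  bent0 <- generate_bent_dna(g, bend_angle = 0, bend_center = 15)
  expect_equal(bent0$atoms, straight$atoms)

  bent <- generate_bent_dna(g, bend_angle = 40, bend_center = 15)
  # arm axis as the direction between centroids of two full-turn windows
  # (averaging over a whole helical repeat puts each centroid on the axis)
  arm_axis <- function(model, bps) {
    bp <- cgslide:::.atom_bp_index(model)
    ctr <- function(ks) colMeans(model$atoms[bp %in% ks, c("x", "y", "z")])
    v <- ctr(bps[6:15]) - ctr(bps[1:10])
    v / sqrt(sum(v^2))
  }
  a1 <- arm_axis(bent, 1:15)
  a2 <- arm_axis(bent, 16:30)
  ang <- acos(abs(sum(a1 * a2))) * 180 / pi
  expect_lt(abs(ang - 40), 1)

  # end-to-end distance strictly decreases with bend angle
  e2e <- vapply(c(0, 20, 40, 60, 80), function(b) {
    m <- generate_bent_dna(g, bend_angle = b, bend_center = 15)
    t1 <- coarse_grain_dna(m$atoms)$beads
    s <- t1[t1$role == "sugar" & t1$chain_id == "A", ]
    s <- s[order(s$residue_id), ]
    sqrt(sum((unlist(s[nrow(s), c("x", "y", "z")]) -
              unlist(s[1, c("x", "y", "z")]))^2))
  }, numeric(1))
  expect_true(all(diff(e2e) < 0))
  expect_error(generate_bent_dna(g, bend_angle = 120), "bend_angle")
  expect_error(generate_bent_dna(g, bend_center = 99), "bend_center")
})

test_that("toy binder is deterministic for a seed, dimerizes, and carries a charged face", {
  b1 <- generate_toy_binder(seed = 5)
  b2 <- generate_toy_binder(seed = 5)
  expect_identical(b1$atoms, b2$atoms)
  b3 <- generate_toy_binder(seed = 6)
  expect_false(identical(b1$atoms, b3$atoms))

  mono <- generate_toy_binder(seed = 5, dimeric = FALSE)
  expect_equal(nrow(b1$topology$beads), 2 * nrow(mono$topology$beads))

  # per monomer, at least four +1 beads in the recognition group, facing
  # the DNA (much closer to the axis than the core)
  bd <- b1$topology$beads
  for (ch in c("A", "B")) {
    rec <- bd[bd$chain_id == ch & bd$residue_id %in% b1$rec_residues, ]
    pos_beads <- rec[rec$charge > 0, ]
    expect_gte(sum(pos_beads$charge), 4)
    core <- bd[bd$chain_id == ch &
               !(bd$residue_id %in% c(b1$rec_residues, b1$hinge_residues)), ]
    expect_lt(mean(sqrt(pos_beads$x^2 + pos_beads$y^2)),
              mean(sqrt(core$x^2 + core$y^2)))
  }
  expect_error(generate_toy_binder(n_residues_per_monomer = 10), ">= 20")
})

test_that("binder topologies respect the two-fold symmetry of the dimer", {
  b <- generate_toy_binder(seed = 2)
  bd <- b$topology$beads
  a <- bd[bd$chain_id == "A", c("x", "y", "z")]
  bb <- bd[bd$chain_id == "B", c("x", "y", "z")]
  # two-fold rotation about Y maps chain A onto chain B (up to jitter)
  expect_equal(unname(as.matrix(a) %*% diag(c(-1, 1, -1))),
               unname(as.matrix(bb)), tolerance = 0.5)
})

test_that("oracle traces encode the planned labels, spans and rates", {
  # all-groove plan
  tr <- generate_oracle_trace(list(oracle_segment("groove", 1000, span_bp = 2)))
  expect_true(all(tr$true_labels == "groove"))
  expect_equal(nrow(tr$frames), 1000 / 0.05)

  # 2 hops in 0.5 ms -> 4 hops per ms by construction
  plan <- list(oracle_segment("groove", 100, 1),
               oracle_segment("hop", 50, 10),
               oracle_segment("groove", 200, 1),
               oracle_segment("hop", 50, 8),
               oracle_segment("groove", 100, 0.5))
  tr2 <- generate_oracle_trace(plan)
  expect_equal(sum(tr2$true_events$type == "hop") /
                 (sum(tr2$true_events$duration_us) * 1e-3), 4,
               tolerance = 1e-6)

  # a 10-bp hop advances Z by 33.2 A
  pre <- max(tr2$frames$Z[tr2$true_segments == 1])
  post <- max(tr2$frames$Z[tr2$true_segments == 2])
  expect_equal(post - pre, 10 * 3.32, tolerance = 1e-9)

  # span validation against the DNA length
  expect_error(generate_oracle_trace(plan, dna_length_bp = 15), "exceeding")

  # groove frames obey the groove relation; hop frames do not
  dev <- cgslide:::.wrap_angle(
    tr2$frames$phi - (tr2$groove$slope * tr2$frames$Z + tr2$groove$phase0))
  dev_bp <- dev / (2 * pi / tr2$groove$repeat_bp)
  expect_true(all(abs(dev_bp[tr2$true_labels == "groove"]) < 1e-9))
  expect_true(all(abs(dev_bp[tr2$true_labels == "hop"]) > 1.5))
})

test_that("generated structures survive a PDB round trip through the real reader", {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = 6))
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(dna, f)
  back <- read_structure(f)
  t1 <- coarse_grain_dna(dna$atoms)
  t2 <- coarse_grain_dna(back)
  expect_equal(bead_positions(t2), bead_positions(t1), tolerance = 1e-3)
  expect_equal(t2$beads$charge, t1$beads$charge)

  b <- generate_toy_binder(seed = 1, dimeric = FALSE)
  f2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(b, f2)
  tp <- coarse_grain_protein(read_structure(f2))
  expect_equal(bead_positions(tp), bead_positions(b$topology),
               tolerance = 1e-3)
  unlink(c(f, f2))
})
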