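# Coarse-graining: protein and DNA reduction, native contacts,
# flexibility scaling, target-site potentials, serialization.

test_that("protein coarse-graining assigns charges and sequential bonded terms", {
  tri <- straight_peptide(c("LYS", "GLY", "GLU"))
  topo <- coarse_grain_protein(tri)
  expect_equal(topo$beads$charge, c(1, 0, -1))
  expect_equal(nrow(topo$bonds), 2)
  expect_equal(nrow(topo$angles), 1)
  expect_equal(nrow(topo$dihedrals), 0)

  one <- coarse_grain_protein(straight_peptide("ALA"))
  expect_equal(nrow(one$beads), 1)
  expect_equal(nrow(one$bonds) + nrow(one$angles) + nrow(one$dihedrals), 0)

  ala3 <- coarse_grain_protein(straight_peptide(c("ALA", "ALA", "ALA")))
  expect_equal(ala3$bonds$x0, c(3.8, 3.8))
  expect_equal(ala3$angles$x0, pi)

  # histidine: neutral by default, +1 when protonated
  his <- straight_peptide(c("HIS", "GLY"))
  expect_equal(coarse_grain_protein(his)$beads$charge[1], 0)
  expect_equal(coarse_grain_protein(his, his_protonated = TRUE)$beads$charge[1], 1)
})

test_that("missing C-alpha is an error naming the residue; breaks drop bonds", {
  tab <- straight_peptide(c("ALA", "GLY", "SER"))
  tab$elety[2] <- "CB"
  expect_error(coarse_grain_protein(tab), "A 2")

  gap <- straight_peptide(c("ALA", "GLY", "SER", "ALA"))
  gap$x[3:4] <- gap$x[3:4] + 10 # break between residues 2 and 3
  expect_warning(topo <- coarse_grain_protein(gap), "chain break")
  expect_equal(nrow(topo$bonds), 2)
  expect_false(any(topo$bonds$i == 2 & topo$bonds$j == 3))
})

test_that("net protein charge equals the charged-residue count difference", {
  aa <- c("ALA", "ARG", "ASN", "ASP", "GLU", "GLY", "HIS", "LYS", "SER", "TRP")
  set.seed(42)
  for (trial in 1:5) {
    seqs <- sample(aa, 30, replace = TRUE)
    topo <- coarse_grain_protein(straight_peptide(seqs))
    expected <- sum(seqs %in% c("LYS", "ARG")) - sum(seqs %in% c("GLU", "ASP"))
    expect_equal(topology_net_charge(topo), expected)
  }
})

test_that("DNA coarse-graining yields 3 beads/nt at group geometric centers", {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = 1))
  topo <- coarse_grain_dna(dna$atoms)
  expect_equal(nrow(topo$beads), 6) # 1-bp duplex
  expect_equal(sum(topo$beads$charge == -1), 2)
  expect_true(all(topo$beads$repulsion_radius == 3.7))

  big <- coarse_grain_dna(generate_ideal_bdna(dna_geometry(n_bp = 100))$atoms)
  expect_equal(nrow(big$beads), 600) # 3 beads x 200 nt
  expect_equal(sum(big$beads$charge), -200)

  # sugar bead at the geometric center of the sugar atoms
  nt <- data.frame(
    eleno = 1:4, elety = c("C1'", "C4'", "N1", "P"), resid = "DA",
    chain = "A", resno = 1,
    x = c(0, 2, 5, 8), y = 0, z = 0, stringsAsFactors = FALSE)
  t1 <- coarse_grain_dna(nt)
  sugar <- t1$beads[t1$beads$role == "sugar", ]
  expect_equal(c(sugar$x, sugar$y, sugar$z), c(1, 0, 0))

  expect_error(coarse_grain_dna(transform(nt, resid = "XNA")), "XNA")
})

test_that("a 5' nucleotide without phosphate loses that bead with a warning", {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = 3))
  atoms <- dna$atoms
  drop <- atoms$chain == "A" & atoms$resno == 1 &
    atoms$elety %in% c("P", "OP1", "OP2")
  expect_warning(topo <- coarse_grain_dna(atoms[!drop, ]), "5'")
  expect_equal(nrow(topo$beads), 3 * 6 - 1)
  expect_equal(sum(topo$beads$charge), -5)
})

test_that("native contacts equal a brute-force heavy-atom pair scan", {
  b <- generate_toy_binder(seed = 3, dimeric = TRUE)
  cutoff <- 6
  got <- compute_native_contacts(b$atoms, coarse_grain_protein(b$atoms),
                                 heavy_atom_cutoff = cutoff)
  # independent oracle: exhaustive double loop over residues (the toy model
  # is CA-only, so residue distance = bead distance)
  tab <- b$atoms
  n <- nrow(tab)
  want <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- tab$chain[i] != tab$chain[j]
      if (!inter && abs(tab$resno[i] - tab$resno[j]) <= 3) next
      d <- sqrt((tab$x[i] - tab$x[j])^2 + (tab$y[i] - tab$y[j])^2 +
                (tab$z[i] - tab$z[j])^2)
      if (d <= cutoff) want <- rbind(want, c(i, j, d))
    }
  }
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$a, want[, 3], tolerance = 1e-12)
  expect_true(all(got$i < got$j))
  # sequence separation of exactly 3 never yields a contact
  same_chain <- tab$chain[got$i] == tab$chain[got$j]
  expect_true(all(abs(tab$resno[got$i] - tab$resno[got$j])[same_chain] > 3))
  expect_error(compute_native_contacts(b$atoms, b$topology, -1), "positive")
})

test_that("a constructed residue pair in contact gets A_ij from the bead distance", {
  # residues 1 and 8: heavy atoms 4.0 A apart, CA beads 6.2 A apart; the
  # intervening chain sits far away so no other pair qualifies
  tab <- straight_peptide(rep("ALA", 8), spacing = 10)
  tab$x[c(1, 8)] <- c(0, 6.2)
  tab$y[c(1, 8)] <- 30
  tab <- rbind(tab,
               data.frame(eleno = 9:10, elety = c("CB", "CB"),
                          resid = "ALA", chain = "A", resno = c(1, 8),
                          x = c(0, 4), y = 35, z = 0))
  suppressWarnings(cg <- coarse_grain_protein(tab)) # spacing 10 breaks chain
  ct <- compute_native_contacts(tab, cg, heavy_atom_cutoff = 4.5)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$i, 1); expect_equal(ct$j, 8)
  expect_equal(ct$a, 6.2)
})

test_that("flexibility scaling is bounded, targeted, and idempotent", {
  b <- generate_toy_binder(seed = 1, hinge_flexible = FALSE)
  topo <- b$topology
  expect_error(apply_flexibility(topo, b$hinge_residues, 1.5), "\\[0, 1\\]")
  expect_error(apply_flexibility(topo, 999, 0.5), "not present")

  # f = 1 is the identity, twice equals once
  t1 <- apply_flexibility(topo, b$hinge_residues, 1)
  expect_identical(t1, topo)
  expect_identical(apply_flexibility(t1, b$hinge_residues, 1), t1)

  # f = 0 zeroes hinge dihedral and contact energies for any conformation
  t0 <- apply_flexibility(topo, b$hinge_residues, 0)
  res_of <- topo$beads$residue_id
  hinge_d <- with(topo$dihedrals,
                  res_of[i] %in% b$hinge_residues &
                  res_of[j] %in% b$hinge_residues &
                  res_of[k] %in% b$hinge_residues &
                  res_of[l] %in% b$hinge_residues)
  expect_true(all(t0$dihedrals$f[hinge_d] == 0))
  hinge_c <- with(topo$contacts,
                  res_of[i] %in% b$hinge_residues |
                  res_of[j] %in% b$hinge_residues)
  expect_true(all(t0$contacts$f[hinge_c] == 0))
  # bonds and angles untouched
  expect_identical(t0$bonds, topo$bonds)
  expect_identical(t0$angles, topo$angles)

  # f = 0.5 halves the contact well depth (k_ij = 1 -> minimum -0.5)
  th <- apply_flexibility(topo, b$hinge_residues, 0.5)
  if (any(hinge_c)) {
    m <- which(hinge_c)[1]
    pos <- bead_positions(th)
    # move the pair to its contact minimum distance along x
    i <- th$contacts$i[m]; j <- th$contacts$j[m]
    small <- cgslide:::new_cg_topology(th$beads[c(i, j), ],
                                       contacts = transform(th$contacts[m, ],
                                                            i = 1, j = 2))
    p2 <- rbind(c(0, 0, 0), c(th$contacts$a[m], 0, 0))
    expect_equal(contact_energy(small, p2), -0.5)
  }
})

test_that("contact bookkeeping keeps pairs unique, ordered and bond-free", {
  topo <- bare_topology(diag(3) * 5)
  ct <- data.frame(i = c(3, 1), j = c(1, 3), a = c(7, 7), kf = 1, f = 1)
  t2 <- add_topology_contacts(topo, ct)
  expect_equal(nrow(t2$contacts), 1)
  expect_true(all(t2$contacts$i < t2$contacts$j))
  t2$bonds <- data.frame(i = 1, j = 2, x0 = 5, kf = 100)
  expect_error(
    add_topology_contacts(t2, data.frame(i = 2, j = 1, a = 5, kf = 1, f = 1)),
    "bonded")
})

test_that("target-site terms match a brute-force scan and soften DNA repulsion", {
  dna <- generate_ideal_bdna(dna_geometry(n_bp = 10))
  binder <- generate_toy_binder(seed = 1)
  docked <- dock_binder(binder, dna, z_offset = 0)
  sys <- merge_topologies(coarse_grain_dna(dna$atoms), docked)
  # complex structure: DNA atoms + binder CA atoms moved to the docked pose
  prot_atoms <- binder$atoms
  pose <- docked$beads[docked$beads$molecule == "protein", ]
  prot_atoms$x <- pose$x; prot_atoms$y <- pose$y; prot_atoms$z <- pose$z
  complex <- rbind(dna$atoms[, names(prot_atoms)], prot_atoms)

  cutoff <- 6
  out <- build_target_site_potential(complex, sys, dna_span = 1:10,
                                     cutoff = cutoff)
  expect_gt(nrow(out$target_site), 0)
  # every term's protein CA has a DNA group atom within the cutoff; A_ij is
  # the current bead-bead distance
  pos <- bead_positions(sys)
  d <- sqrt(rowSums((pos[out$target_site$i, , drop = FALSE] -
                     pos[out$target_site$j, , drop = FALSE])^2))
  expect_equal(out$target_site$a, unname(d), tolerance = 1e-9)
  expect_true(all(out$beads$repulsion_radius[unique(out$target_site$j)] == 3.0))

  # independent oracle: count protein-bead x DNA-bead pairs within reach
  db <- sys$beads[sys$beads$molecule == "dna", ]
  pb <- sys$beads[sys$beads$molecule == "protein", ]
  n_expected <- 0
  for (bi in seq_len(nrow(db))) {
    # group atoms of this DNA bead
    ga <- dna$atoms[dna$atoms$chain == db$chain_id[bi] &
                    dna$atoms$resno == db$residue_id[bi], ]
    grp <- ifelse(ga$elety %in% c("P", "OP1", "OP2"), "phosphate",
                  ifelse(grepl("'", ga$elety), "sugar", "base"))
    ga <- ga[grp == db$role[bi], ]
    for (pi in seq_len(nrow(pb))) {
      dmin <- min(sqrt((ga$x - pb$x[pi])^2 + (ga$y - pb$y[pi])^2 +
                       (ga$z - pb$z[pi])^2))
      if (dmin <= cutoff) n_expected <- n_expected + 1
    }
  }
  expect_equal(nrow(out$target_site), n_expected)

  # empty span: unchanged topology
  expect_identical(build_target_site_potential(complex, sys, integer(0)),
                   sys)
  # far-away protein: empty potential with a warning
  far <- complex
  far$y[far$elety == "CA"] <- far$y[far$elety == "CA"] + 500
  expect_warning(out2 <- build_target_site_potential(far, sys, 1:10),
                 "target-site")
  expect_equal(nrow(out2$target_site), 0)
})

test_that("a single target-site term reaches -k at its reference separation", {
  beads_p <- bare_topology(matrix(c(0, 0, 0), 1), charge = 1)
  beads_d <- bare_topology(matrix(c(5.5, 0, 0), 1), molecule = "dna",
                           radius = 3.0, chain = "D")
  sys <- merge_topologies(beads_p, beads_d)
  sys$target_site <- data.frame(i = 1, j = 2, a = 5.5, kf = 1)
  expect_equal(contact_energy(sys), -1)
})

test_that("topology JSON serialization round-trips losslessly", {
  sys <- desk_system()$topology
  f <- tempfile(fileext = ".json")
  write_topology(sys, f)
  back <- read_topology(f)
  for (part in c("bonds", "angles", "dihedrals", "contacts", "target_site",
                 "exclusions"))
    expect_equal(back[[part]], sys[[part]], ignore_attr = TRUE)
  expect_equal(back$beads$x, sys$beads$x, tolerance = 0)
  expect_equal(back$beads$charge, sys$beads$charge)
  expect_equal(back$beads$role, sys$beads$role)
  unlink(f)
})
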