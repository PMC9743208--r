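# Coarse-grained topology construction.
#
# Proteins are reduced to one bead per residue at the C-alpha position;
# DNA to three beads per nucleotide at the geometric centers of the
# phosphate, sugar and base groups. Bonded terms (bonds, angles, dihedrals)
# take their equilibrium values from the reference structure; native
# contacts use a 12-10 potential with A_ij equal to the reference bead-bead
# distance. Force constants: 100 kcal/mol/A^2 (bonds), 20 kcal/mol (angles),
# 1 kcal/mol (dihedrals, contacts, excluded volume). Lys/Arg (and His when
# protonated) carry +1; Glu/Asp and DNA phosphates carry -1. Repulsion
# radii: 2.0 A for protein beads, 3.7 A for DNA beads (3.0 A for DNA beads
# engaged by a target-site potential).

.K_BOND <- 100
.K_ANGLE <- 20
.K_DIHEDRAL <- 1
.K_CONTACT <- 1
.K_EV <- 1
.R_CA <- 2.0
.R_DNA <- 3.7
.R_DNA_TARGET <- 3.0
.CHAIN_BREAK <- 4.5 # A; consecutive C-alpha farther apart than this

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.NT_NAMES <- c("DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U")
.PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P")

# residue charge for protein beads
.aa_charge <- function(resname, his_protonated = FALSE) {
  ch <- numeric(length(resname))
  ch[resname %in% c("LYS", "ARG")] <- 1
  if (his_protonated) ch[resname == "HIS"] <- 1
  ch[resname %in% c("GLU", "ASP")] <- -1
  ch
}

.empty_bonds <- function() data.frame(i = integer(), j = integer(),
                                      x0 = numeric(), kf = numeric())
.empty_angles <- function() data.frame(i = integer(), j = integer(),
                                       k = integer(), x0 = numeric(),
                                       kf = numeric())
.empty_dihedrals <- function() data.frame(i = integer(), j = integer(),
                                          k = integer(), l = integer(),
                                          x0 = numeric(), kf = numeric(),
                                          f = numeric())
.empty_contacts <- function() data.frame(i = integer(), j = integer(),
                                         a = numeric(), kf = numeric(),
                                         f = numeric())
.empty_pairs <- function() data.frame(i = integer(), j = integer())

new_cg_topology <- function(beads,
                            bonds = .empty_bonds(),
                            angles = .empty_angles(),
                            dihedrals = .empty_dihedrals(),
                            contacts = .empty_contacts(),
                            target_site = .empty_contacts()[c("i", "j", "a", "kf")],
                            exclusions = .empty_pairs()) {
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, contacts = contacts,
                 target_site = target_site, exclusions = exclusions),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology:", nrow(x$beads), "beads (",
      sum(x$beads$molecule == "protein"), "protein,",
      sum(x$beads$molecule == "dna"), "DNA ),",
      nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedrals,", nrow(x$contacts), "contacts,",
      nrow(x$target_site), "target-site terms\n")
  cat("net charge:", sum(x$beads$charge), "e\n")
  invisible(x)
}

#' Bead coordinate matrix of a topology
#' @param topology a `cg_topology`
#' @return numeric matrix (n beads x 3)
#' @export
bead_positions <- function(topology) {
  unname(as.matrix(topology$beads[, c("x", "y", "z")]))
}

#' Net charge of a topology, in elementary charges
#' @param topology a `cg_topology`
#' @return sum of bead charges
#' @export
topology_net_charge <- function(topology) sum(topology$beads$charge)

# interior angle at p2 (radians); vectorized over rows
.angles_at <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosa <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
  acos(pmin(1, pmax(-1, cosa)))
}

# signed dihedral angle (radians); vectorized over rows
.dihedrals_at <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  atan2(rowSums(m1 * n2) / b2n, rowSums(n1 * n2))
}

# sequential bonds/angles/dihedrals along an ordered bead chain, honoring
# break positions (logical vector: break after bead s)
.chain_bonded_terms <- function(xyz, offset, breaks) {
  n <- nrow(xyz)
  bonds <- .empty_bonds(); angles <- .empty_angles(); dihedrals <- .empty_dihedrals()
  if (n >= 2) {
    s <- which(!breaks[seq_len(n - 1)])
    if (length(s))
      bonds <- data.frame(i = offset + s, j = offset + s + 1,
                          x0 = sqrt(rowSums((xyz[s + 1, , drop = FALSE] -
                                             xyz[s, , drop = FALSE])^2)),
                          kf = .K_BOND)
  }
  if (n >= 3) {
    s <- which(!breaks[seq_len(n - 2)] & !breaks[seq_len(n - 2) + 1])
    if (length(s))
      angles <- data.frame(i = offset + s, j = offset + s + 1, k = offset + s + 2,
                           x0 = .angles_at(xyz[s, , drop = FALSE],
                                           xyz[s + 1, , drop = FALSE],
                                           xyz[s + 2, , drop = FALSE]),
                           kf = .K_ANGLE)
  }
  if (n >= 4) {
    s <- which(!breaks[seq_len(n - 3)] & !breaks[seq_len(n - 3) + 1] &
               !breaks[seq_len(n - 3) + 2])
    if (length(s))
      dihedrals <- data.frame(i = offset + s, j = offset + s + 1,
                              k = offset + s + 2, l = offset + s + 3,
                              x0 = .dihedrals_at(xyz[s, , drop = FALSE],
                                                 xyz[s + 1, , drop = FALSE],
                                                 xyz[s + 2, , drop = FALSE],
                                                 xyz[s + 3, , drop = FALSE]),
                              kf = .K_DIHEDRAL, f = 1)
  }
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Coarse-grain a protein structure to one bead per residue
#'
#' Places one bead at each C-alpha position, assigns charges (+1 Lys/Arg,
#' +1 His when `his_protonated`, -1 Glu/Asp, 0 otherwise) and builds
#' sequential bonds, angles and dihedrals per chain with equilibrium values
#' taken from the reference geometry. Consecutive C-alpha beads more than
#' 4.5 A apart are treated as a chain break (warning, no bonded terms
#' across the break). A protein residue without a C-alpha atom is an error.
#'
#' @param structure anything [as_atom_table()] accepts
#' @param his_protonated logical: treat histidine as +1 (default `FALSE`)
#' @return a `cg_topology` fragment (no contacts yet; see
#'   [compute_native_contacts()])
#' @export
coarse_grain_protein <- function(structure, his_protonated = FALSE) {
  tab <- as_atom_table(structure)
  tab <- tab[tab$resid %in% .AA3, , drop = FALSE]
  if (!nrow(tab)) stop("no protein residues found in structure")
  res <- unique(tab[, c("chain", "resno")])
  res <- res[order(res$chain, res$resno), ]
  ca <- tab[tab$elety == "CA", , drop = FALSE]
  key <- function(d) paste(d$chain, d$resno)
  miss <- !(key(res) %in% key(ca))
  if (any(miss))
    stop("residue(s) without a C-alpha atom: ",
         paste(key(res)[miss], collapse = ", "))
  ca <- ca[match(key(res), key(ca)), ]

  beads <- data.frame(
    index = seq_len(nrow(ca)), role = "CA",
    x = ca$x, y = ca$y, z = ca$z,
    charge = .aa_charge(ca$resid, his_protonated),
    residue_id = ca$resno, chain_id = ca$chain, resname = ca$resid,
    repulsion_radius = .R_CA, molecule = "protein",
    stringsAsFactors = FALSE
  )

  bonds <- .empty_bonds(); angles <- .empty_angles(); dihedrals <- .empty_dihedrals()
  for (ch in unique(beads$chain_id)) {
    idx <- which(beads$chain_id == ch)
    xyz <- as.matrix(beads[idx, c("x", "y", "z")])
    n <- length(idx)
    breaks <- logical(max(n - 1, 0))
    if (n >= 2) {
      d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
      breaks <- d > .CHAIN_BREAK
      if (any(breaks))
        warning("chain break(s) in chain ", ch, " after residue(s) ",
                paste(beads$residue_id[idx[which(breaks)]], collapse = ", "),
                " (C-alpha gap > ", .CHAIN_BREAK, " A); no bond across the break")
    }
    terms <- .chain_bonded_terms(xyz, offset = idx[1] - 1, breaks = breaks)
    bonds <- rbind(bonds, terms$bonds)
    angles <- rbind(angles, terms$angles)
    dihedrals <- rbind(dihedrals, terms$dihedrals)
  }
  new_cg_topology(beads, bonds, angles, dihedrals)
}

#' Coarse-grain duplex DNA to three beads per nucleotide
#'
#' Beads are placed at the geometric centers of the phosphate group
#' (P/OP1/OP2/...), the sugar (primed atoms) and the base (remaining heavy
#' atoms) of each nucleotide. Phosphate beads carry charge -1; sugar and
#' base beads are neutral. Intra-strand connectivity is built as
#' P(k)-S(k), S(k)-B(k) and S(k)-P(k+1) bonds with backbone angles and
#' dihedrals, equilibrium values from the reference geometry. A 5'
#' nucleotide without phosphate atoms loses that bead with a warning; an
#' unknown residue name is an error.
#'
#' @param structure anything [as_atom_table()] accepts
#' @return a `cg_topology` fragment
#' @export
coarse_grain_dna <- function(structure) {
  tab <- as_atom_table(structure)
  tab <- tab[!grepl("^H", trimws(tab$elety)), , drop = FALSE] # heavy atoms only
  tab$resid <- trimws(tab$resid)
  is_nt <- tab$resid %in% .NT_NAMES
  bad <- unique(tab$resid[!is_nt])
  if (length(bad))
    stop("unknown DNA residue name(s): ", paste(bad, collapse = ", "))
  if (!nrow(tab)) stop("no nucleotides found in structure")

  beads <- NULL
  bonds <- .empty_bonds(); angles <- .empty_angles(); dihedrals <- .empty_dihedrals()
  for (ch in sort(unique(tab$chain))) {
    sub <- tab[tab$chain == ch, , drop = FALSE]
    resnos <- sort(unique(sub$resno))
    # per-nucleotide bead list in strand order: P, S, B (P may be absent)
    pidx <- sidx <- bidx <- rep(NA_integer_, length(resnos))
    ch_beads <- NULL
    for (m in seq_along(resnos)) {
      nt <- sub[sub$resno == resnos[m], , drop = FALSE]
      grp <- ifelse(trimws(nt$elety) %in% .PHOSPHATE_ATOMS, "phosphate",
                    ifelse(grepl("'", nt$elety), "sugar", "base"))
      add_bead <- function(role, charge) {
        sel <- grp == role
        if (!any(sel)) return(NA_integer_)
        ctr <- colMeans(nt[sel, c("x", "y", "z")])
        ch_beads <<- rbind(ch_beads, data.frame(
          index = NA_integer_, role = role,
          x = ctr[1], y = ctr[2], z = ctr[3], charge = charge,
          residue_id = resnos[m], chain_id = ch, resname = nt$resid[1],
          repulsion_radius = .R_DNA, molecule = "dna",
          stringsAsFactors = FALSE))
        nrow(ch_beads)
      }
      pidx[m] <- add_bead("phosphate", -1)
      if (m == 1 && is.na(pidx[m]))
        warning("5' nucleotide ", ch, " ", resnos[m],
                " has no phosphate atoms; bead omitted")
      else if (is.na(pidx[m]))
        warning("nucleotide ", ch, " ", resnos[m],
                " has no phosphate atoms; bead omitted")
      sidx[m] <- add_bead("sugar", 0)
      bidx[m] <- add_bead("base", 0)
      if (is.na(sidx[m]) || is.na(bidx[m]))
        stop("nucleotide ", ch, " ", resnos[m], " lacks sugar or base atoms")
    }
    off <- if (is.null(beads)) 0L else nrow(beads)
    gi <- function(v) ifelse(is.na(v), NA_integer_, v + off)
    p <- gi(pidx); s <- gi(sidx); b <- gi(bidx)
    xyzc <- as.matrix(ch_beads[, c("x", "y", "z")])
    pos <- function(v) xyzc[v - off, , drop = FALSE]
    bnd <- function(i, j) {
      ok <- !is.na(i) & !is.na(j)
      if (!any(ok)) return(.empty_bonds())
      data.frame(i = i[ok], j = j[ok],
                 x0 = sqrt(rowSums((pos(j[ok]) - pos(i[ok]))^2)), kf = .K_BOND)
    }
    nm <- length(resnos)
    p_next <- c(p[-1], NA)
    s_next <- c(s[-1], NA)
    p_next2 <- c(p[-(1:2)], NA, NA)
    bonds <- rbind(bonds, bnd(p, s), bnd(s, b), bnd(s, p_next))
    ang <- function(i, j, k) {
      ok <- !is.na(i) & !is.na(j) & !is.na(k)
      if (!any(ok)) return(.empty_angles())
      data.frame(i = i[ok], j = j[ok], k = k[ok],
                 x0 = .angles_at(pos(i[ok]), pos(j[ok]), pos(k[ok])),
                 kf = .K_ANGLE)
    }
    angles <- rbind(angles,
                    ang(p, s, b),
                    ang(p, s, p_next),
                    ang(b, s, p_next),
                    ang(s, p_next, s_next))
    dih <- function(i, j, k, l) {
      ok <- !is.na(i) & !is.na(j) & !is.na(k) & !is.na(l)
      if (!any(ok)) return(.empty_dihedrals())
      data.frame(i = i[ok], j = j[ok], k = k[ok], l = l[ok],
                 x0 = .dihedrals_at(pos(i[ok]), pos(j[ok]), pos(k[ok]), pos(l[ok])),
                 kf = .K_DIHEDRAL, f = 1)
    }
    dihedrals <- rbind(dihedrals,
                       dih(p, s, p_next, s_next),
                       dih(s, p_next, s_next, p_next2))
    beads <- rbind(beads, ch_beads)
  }
  beads$index <- seq_len(nrow(beads))
  new_cg_topology(beads, bonds, angles, dihedrals)
}

#' Detect native contacts from a reference structure
#'
#' A residue pair becomes a native contact when any inter-residue
#' heavy-atom distance in the reference is at or below `heavy_atom_cutoff`
#' and the pair is either on different chains or more than three residues
#' apart in sequence. The contact minimum `A_ij` is the bead-bead
#' (C-alpha) distance in the reference; the well depth is 1 kcal/mol.
#'
#' @param structure reference structure aligned with `cg`
#' @param cg `cg_topology` whose protein beads the contacts attach to
#' @param heavy_atom_cutoff detection cutoff in Angstrom (default 4.5)
#' @return contact data frame (`i`, `j`, `a`, `kf`, `f`) with `i < j`
#' @export
compute_native_contacts <- function(structure, cg, heavy_atom_cutoff = 4.5) {
  if (heavy_atom_cutoff <= 0) stop("heavy_atom_cutoff must be positive")
  tab <- as_atom_table(structure)
  tab <- tab[!grepl("^H", trimws(tab$elety)) & tab$resid %in% .AA3, ,
             drop = FALSE]
  pb <- cg$beads[cg$beads$molecule == "protein", , drop = FALSE]
  n <- nrow(pb)
  if (n < 2) return(.empty_contacts())
  xyz <- as.matrix(pb[, c("x", "y", "z")])
  akey <- paste(tab$chain, tab$resno)
  atom_xyz <- as.matrix(tab[, c("x", "y", "z")])
  res_atoms <- split(seq_len(nrow(tab)), akey)
  out <- vector("list", 0)
  prefilter <- heavy_atom_cutoff + 15 # bead distance bound given atom cutoff
  for (ii in seq_len(n - 1)) {
    for (jj in (ii + 1):n) {
      inter <- pb$chain_id[ii] != pb$chain_id[jj]
      if (!inter && abs(pb$residue_id[ii] - pb$residue_id[jj]) <= 3) next
      dbead <- sqrt(sum((xyz[jj, ] - xyz[ii, ])^2))
      if (dbead > prefilter) next
      ai <- res_atoms[[paste(pb$chain_id[ii], pb$residue_id[ii])]]
      aj <- res_atoms[[paste(pb$chain_id[jj], pb$residue_id[jj])]]
      if (is.null(ai) || is.null(aj)) next
      dmin <- min(.cross_dist(atom_xyz[ai, , drop = FALSE],
                              atom_xyz[aj, , drop = FALSE]))
      if (dmin <= heavy_atom_cutoff)
        out[[length(out) + 1]] <- data.frame(
          i = pb$index[ii], j = pb$index[jj], a = dbead,
          kf = .K_CONTACT, f = 1)
    }
  }
  if (!length(out)) return(.empty_contacts())
  do.call(rbind, out)
}

# all pairwise distances between two coordinate sets
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Add contact terms to a topology
#'
#' Normalizes pair order (`i < j`), drops duplicates, and refuses contacts
#' that coincide with a bonded pair.
#'
#' @param topology a `cg_topology`
#' @param contacts contact data frame from [compute_native_contacts()]
#' @return the updated topology
#' @export
add_topology_contacts <- function(topology, contacts) {
  if (!nrow(contacts)) return(topology)
  swap <- contacts$i > contacts$j
  tmp <- contacts$i[swap]; contacts$i[swap] <- contacts$j[swap]; contacts$j[swap] <- tmp
  all <- rbind(topology$contacts, contacts)
  all <- all[!duplicated(all[, c("i", "j")]), , drop = FALSE]
  bk <- paste(pmin(topology$bonds$i, topology$bonds$j),
              pmax(topology$bonds$i, topology$bonds$j))
  clash <- paste(all$i, all$j) %in% bk
  if (any(clash)) stop("contact pair(s) duplicate bonded pair(s)")
  topology$contacts <- all
  rownames(topology$contacts) <- NULL
  topology
}

#' Scale the flexibility of a residue set
#'
#' Sets the flexibility scale `f` on every dihedral whose four residues all
#' lie in `residue_set` and on every contact with either residue in the
#' set. Bonds and angles are untouched. Applying the same `f` twice equals
#' applying it once.
#'
#' @param topology a `cg_topology`
#' @param residue_set residue ids (matched against `residue_id`, all chains)
#' @param f flexibility scale in `[0, 1]`
#' @return the updated topology
#' @export
apply_flexibility <- function(topology, residue_set, f) {
  if (!is.numeric(f) || length(f) != 1 || f < 0 || f > 1)
    stop("flexibility scale f must be a single value in [0, 1]")
  if (!all(residue_set %in% topology$beads$residue_id))
    stop("residue_set contains residues not present in the topology")
  res_of <- topology$beads$residue_id
  if (nrow(topology$dihedrals)) {
    d <- topology$dihedrals
    sel <- res_of[d$i] %in% residue_set & res_of[d$j] %in% residue_set &
           res_of[d$k] %in% residue_set & res_of[d$l] %in% residue_set
    topology$dihedrals$f[sel] <- f
  }
  if (nrow(topology$contacts)) {
    ct <- topology$contacts
    sel <- res_of[ct$i] %in% residue_set | res_of[ct$j] %in% residue_set
    topology$contacts$f[sel] <- f
  }
  topology
}

#' Merge two coarse-grained topologies
#'
#' Re-indexes the second topology's beads and terms and concatenates. Used
#' to combine a protein fragment with a DNA fragment into one system.
#'
#' @param a,b `cg_topology` objects
#' @return merged `cg_topology`
#' @export
merge_topologies <- function(a, b) {
  off <- nrow(a$beads)
  shift <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- df[[cc]] + off
    df
  }
  beads <- rbind(a$beads, b$beads)
  beads$index <- seq_len(nrow(beads))
  new_cg_topology(
    beads,
    bonds = rbind(a$bonds, shift(b$bonds, c("i", "j"))),
    angles = rbind(a$angles, shift(b$angles, c("i", "j", "k"))),
    dihedrals = rbind(a$dihedrals, shift(b$dihedrals, c("i", "j", "k", "l"))),
    contacts = rbind(a$contacts, shift(b$contacts, c("i", "j"))),
    target_site = rbind(a$target_site, shift(b$target_site, c("i", "j"))),
    exclusions = rbind(a$exclusions, shift(b$exclusions, c("i", "j")))
  )
}

#' Build a target-site potential from a bound complex
#'
#' Scans a protein-DNA complex for protein residues whose heavy atoms come
#' within `cutoff` of the atoms of a DNA bead group in the selected
#' base-pair span, and creates a 12-10 term between the protein bead and
#' that DNA bead with `A_ij` taken from the complex geometry. DNA beads
#' engaged by at least one term get their repulsion radius reduced to
#' 3.0 A so the contact minimum is reachable.
#'
#' @param complex_structure atom table of the bound complex (protein + DNA)
#' @param cg merged `cg_topology` of the same complex
#' @param dna_span base-pair indices of the target site (bp 1 = first
#'   residue of the leading strand; the complementary strand is assumed to
#'   be numbered antiparallel over the full duplex length)
#' @param cutoff heavy-atom detection cutoff, Angstrom (default 4.5)
#' @return the topology with `target_site` terms attached
#' @export
build_target_site_potential <- function(complex_structure, cg, dna_span,
                                        cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be positive")
  tab <- as_atom_table(complex_structure)
  tab <- tab[!grepl("^H", trimws(tab$elety)), , drop = FALSE]
  db <- cg$beads[cg$beads$molecule == "dna", , drop = FALSE]
  pb <- cg$beads[cg$beads$molecule == "protein", , drop = FALSE]
  if (!length(dna_span) || !nrow(db) || !nrow(pb)) {
    if (!length(dna_span)) return(cg)
    warning("no protein-DNA pairs available for a target-site potential")
    return(cg)
  }
  n_bp <- max(db$residue_id)
  chains <- sort(unique(db$chain_id))
  bp_of <- ifelse(db$chain_id == chains[1], db$residue_id,
                  n_bp - db$residue_id + 1L)
  db <- db[bp_of %in% dna_span, , drop = FALSE]
  if (!nrow(db)) {
    warning("dna_span selects no DNA beads; empty target-site potential")
    return(cg)
  }
  # protein and DNA atoms are keyed separately: chain/residue labels may
  # collide between the two molecules in a merged complex
  is_prot_atom <- tab$resid %in% .AA3
  is_dna_atom <- tab$resid %in% .NT_NAMES
  atom_xyz <- as.matrix(tab[, c("x", "y", "z")])
  akey <- paste(tab$chain, tab$resno)
  grp_of <- ifelse(trimws(tab$elety) %in% .PHOSPHATE_ATOMS, "phosphate",
                   ifelse(grepl("'", tab$elety), "sugar", "base"))
  terms <- vector("list", 0)
  for (bi in seq_len(nrow(db))) {
    sel <- is_dna_atom & akey == paste(db$chain_id[bi], db$residue_id[bi]) &
           grp_of == db$role[bi]
    if (!any(sel)) next
    gxyz <- atom_xyz[sel, , drop = FALSE]
    for (pi in seq_len(nrow(pb))) {
      psel <- is_prot_atom &
              akey == paste(pb$chain_id[pi], pb$residue_id[pi])
      if (!any(psel)) next
      dmin <- min(.cross_dist(atom_xyz[psel, , drop = FALSE], gxyz))
      if (dmin <= cutoff) {
        a <- sqrt(sum((c(pb$x[pi], pb$y[pi], pb$z[pi]) -
                       c(db$x[bi], db$y[bi], db$z[bi]))^2))
        terms[[length(terms) + 1]] <- data.frame(
          i = pb$index[pi], j = db$index[bi], a = a, kf = .K_CONTACT)
      }
    }
  }
  if (!length(terms)) {
    warning("no protein-DNA atom pairs within ", cutoff,
            " A; empty target-site potential")
    return(cg)
  }
  ts <- do.call(rbind, terms)
  cg$target_site <- rbind(cg$target_site, ts)
  cg$beads$repulsion_radius[unique(ts$j)] <- .R_DNA_TARGET
  cg
}

# ---------------------------------------------------------------------------
# Nonbonded pair enumeration.
#
# Candidate nonbonded pairs are those more than three residues apart in
# sequence (or on different chains/molecules), excluding bonded pairs and
# explicit exclusions. Candidates that are native contacts or target-site
# terms interact through the 12-10 channel; all others through excluded
# volume. Electrostatics acts on every candidate pair with q_i q_j != 0,
# regardless of channel.

#' Enumerate nonbonded interaction pairs of a topology
#'
#' @param topology a `cg_topology`
#' @param include_dna_dna keep DNA-DNA pairs (default `TRUE`; set `FALSE`
#'   when the DNA is rigid and intra-DNA terms are constant)
#' @param sigma_rule how per-bead repulsion radii combine into the pair
#'   sigma: `"mean"` (default), `"max"` or `"sum"`
#' @return list with data frames `ev` (`i`, `j`, `sigma`) and `elec`
#'   (`i`, `j`, `qq`)
#' @export
nonbonded_pairs <- function(topology, include_dna_dna = TRUE,
                            sigma_rule = c("mean", "max", "sum")) {
  sigma_rule <- match.arg(sigma_rule)
  b <- topology$beads
  n <- nrow(b)
  if (n < 2)
    return(list(ev = data.frame(i = integer(), j = integer(),
                                sigma = numeric()),
                elec = data.frame(i = integer(), j = integer(),
                                  qq = numeric())))
  pr <- t(combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  near <- b$molecule[i] == b$molecule[j] & b$chain_id[i] == b$chain_id[j] &
          abs(b$residue_id[i] - b$residue_id[j]) <= 3
  keep <- !near
  if (!include_dna_dna)
    keep <- keep & !(b$molecule[i] == "dna" & b$molecule[j] == "dna")
  pkey <- paste(i, j)
  drop_keys <- character(0)
  if (nrow(topology$bonds))
    drop_keys <- c(drop_keys, paste(pmin(topology$bonds$i, topology$bonds$j),
                                    pmax(topology$bonds$i, topology$bonds$j)))
  if (nrow(topology$exclusions))
    drop_keys <- c(drop_keys,
                   paste(pmin(topology$exclusions$i, topology$exclusions$j),
                         pmax(topology$exclusions$i, topology$exclusions$j)))
  keep <- keep & !(pkey %in% drop_keys)
  i <- i[keep]; j <- j[keep]; pkey <- pkey[keep]

  ckey <- character(0)
  if (nrow(topology$contacts))
    ckey <- paste(pmin(topology$contacts$i, topology$contacts$j),
                  pmax(topology$contacts$i, topology$contacts$j))
  if (nrow(topology$target_site))
    ckey <- c(ckey, paste(pmin(topology$target_site$i, topology$target_site$j),
                          pmax(topology$target_site$i, topology$target_site$j)))
  is_contact <- pkey %in% ckey

  ri <- b$repulsion_radius[i]; rj <- b$repulsion_radius[j]
  sigma <- switch(sigma_rule,
                  mean = (ri + rj) / 2,
                  max = pmax(ri, rj),
                  sum = ri + rj)
  ev <- data.frame(i = i[!is_contact], j = j[!is_contact],
                   sigma = sigma[!is_contact])
  qq <- b$charge[i] * b$charge[j]
  sel <- qq != 0
  elec <- data.frame(i = i[sel], j = j[sel], qq = qq[sel])
  list(ev = ev, elec = elec)
}

# ---------------------------------------------------------------------------
# Topology serialization (structured JSON text; lossless round trip)

#' Write a topology to a JSON file
#'
#' All numeric fields are written at full precision so that
#' `read_topology(write_topology(x, f))` reproduces `x` exactly.
#'
#' @param topology a `cg_topology`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_topology <- function(topology, file) {
  strip <- function(df) { rownames(df) <- NULL; df }
  payload <- list(format = "cgslide-topology", version = 1L,
                  beads = strip(topology$beads), bonds = strip(topology$bonds),
                  angles = strip(topology$angles),
                  dihedrals = strip(topology$dihedrals),
                  contacts = strip(topology$contacts),
                  target_site = strip(topology$target_site),
                  exclusions = strip(topology$exclusions))
  jsonlite::write_json(payload, file, dataframe = "columns",
                       digits = I(17), auto_unbox = TRUE, null = "null")
  invisible(file)
}

#' Read a topology written by [write_topology()]
#'
#' @param file path to a topology JSON file
#' @return a `cg_topology`
#' @export
read_topology <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(payload$format, "cgslide-topology"))
    stop("not a cgslide topology file: ", file)
  as_df <- function(x, template) {
    if (is.null(x) || !length(x) ||
        all(vapply(x, length, integer(1)) == 0))
      return(template)
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    for (cc in names(template))
      if (is.integer(template[[cc]])) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  new_cg_topology(
    beads = as.data.frame(payload$beads, stringsAsFactors = FALSE),
    bonds = as_df(payload$bonds, .empty_bonds()),
    angles = as_df(payload$angles, .empty_angles()),
    dihedrals = as_df(payload$dihedrals, .empty_dihedrals()),
    contacts = as_df(payload$contacts, .empty_contacts()),
    target_site = as_df(payload$target_site,
                        .empty_contacts()[c("i", "j", "a", "kf")]),
    exclusions = as_df(payload$exclusions, .empty_pairs())
  )
}
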