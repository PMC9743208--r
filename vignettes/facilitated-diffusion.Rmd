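---
title: "Coarse-grained models of protein sliding on DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained models of protein sliding on DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgslide)
```

# The scientific problem

DNA-binding proteins find their target sites by facilitated diffusion:
three-dimensional excursions through solution alternate with
one-dimensional translocation along nonspecific DNA. The 1D mode itself
splits into *groove tracking* (rotation-coupled sliding in which the
recognition region follows the helical major groove, advancing about one
base pair per 36 degrees of rotation) and *hopping*
(rotation-decoupled micro-dissociation and reattachment, typically around
ten base pairs away). Which mode dominates, and how the balance shifts
with ionic strength, controls the search speed; for the *lac* repressor,
hopping has been estimated to accelerate 1D diffusion roughly an order of
magnitude over pure groove tracking.

`cgslide` implements the complete simulation-and-analysis chain for this
problem at coarse-grained resolution: structure-based model construction,
Langevin dynamics with Debye-Hueckel electrostatics, the
(Z, d, phi) trace analysis that classifies groove tracking, hopping,
3D diffusion and flips, MSD-based diffusion and pitch estimators, the
hopping-augmented 1D diffusion coefficient, and encounter-complex scoring.

# The coarse-grained model

## Representation

* **Protein**: one bead per residue at the C-alpha position. Lysine and
  arginine carry +1 (histidine +1 only when flagged protonated);
  glutamate and aspartate carry -1. Repulsion radius 2.0 A.
* **DNA**: three beads per nucleotide at the geometric centers of the
  phosphate group, the sugar, and the base. Phosphates carry -1.
  Repulsion radius 3.7 A, reduced to 3.0 A for beads engaged by a
  target-site potential so those contacts can close.

## Energy function

With lengths in Angstrom and energies in kcal/mol:

* bonds: $k_b (r - r^0)^2$ with $k_b = 100$;
* angles: $k_a (\theta - \theta^0)^2$ with $k_a = 20$;
* dihedrals: the standard structure-based cosine series
  $k_d [(1 - \cos\Delta) + \tfrac12 (1 - \cos 3\Delta)]$,
  $\Delta = \varphi - \varphi^0$, $k_d = 1$ (a plain harmonic form is
  available); equilibrium values come from the reference structure;
* native contacts: the 12-10 potential
  $k_{ij} [5 (A_{ij}/r)^{12} - 6 (A_{ij}/r)^{10}]$ with
  $k_{ij} = 1$ and $A_{ij}$ the reference bead separation, detected for
  residue pairs with any heavy-atom distance at or below 4.5 A and
  sequence separation above 3 (the detection rule is configurable; the
  4.5 A heavy-atom criterion is standard structure-based-model practice);
* excluded volume: $k_{ev} (\sigma_{ij}/r)^{12}$, $k_{ev} = 1$, acting on
  all nonbonded non-contact pairs more than three residues apart. The
  per-class repulsion distances are combined per pair as
  $\sigma_{ij} = (r_i + r_j)/2$ (the arithmetic mean; `max` and `sum`
  rules are available). The kernel truncates this term beyond
  $3\sigma$, where it is below $2\times10^{-6}$ kcal/mol;
* electrostatics: the Debye-Hueckel form
  $K_C\, B(\kappa)\, q_i q_j\, e^{-\kappa r} / (\varepsilon r)$ with
  $K_C = 332$ kcal/mol, $B(\kappa) = 1$ (dilute-solution approximation),
  $\varepsilon = 70$, and
  $\kappa = \sqrt{8 \pi \ell_B N_A c_i \times 10^{-27}}$ for a 1:1 salt
  of ionic strength $c_i$ (mol/L), with the Bjerrum length
  $\ell_B = e^2 / (4\pi\varepsilon_0 \varepsilon k_B T)$ -- about
  8.01 A at $\varepsilon = 70$, 298 K, giving a screening length of
  28.7 A at 0.01 M. No cutoff is applied at desk scale; an optional
  shifted cutoff is available for large systems.

Every nonbonded pair interacts through exactly one of the contact or
excluded-volume channels, plus electrostatics when both beads are
charged.

## Dynamics

Underdamped Langevin dynamics with friction $\gamma = 0.01$ per reduced
time unit, bead mass 1, and $k_BT = 0.593$ kcal/mol (298 K), integrated
with the BAOAB splitting at $dt = 0.005$. BAOAB was chosen over
kick-based discretizations because it needs one force evaluation per
step, treats the Ornstein-Uhlenbeck substep exactly (so the sampled
kinetic temperature is correct for any $\gamma$), reduces to velocity
Verlet at $\gamma = 0$ (which is how the symplectic-limit energy-drift
property is tested), and has well-documented superior configurational
sampling at large $dt$. The box (default $x, y \in [-240, 240]$,
$z \in [-225, 225]$ A) has reflecting walls; boundary handling is not
prescribed by the physics of the open system being mimicked, and
reflection is the least intrusive choice for a single molecule. DNA
beads are held rigid by default -- every analysis treats the DNA axis as
the fixed Z axis -- and a switch exposes mobile DNA.

Physical time is attached by convention only: one MD step represents
50 ps, so $10^8$ steps correspond to 5 ms and a frame saved every 1000
steps advances the clock by 50 ns. No friction-based calibration is
attempted; all reported times inherit this convention.

# Trajectory classification

For each recognition region, every frame is reduced to the projection
$Z$ of the region's center of mass on the DNA axis, its distance $d$
from the axis, and the rotation angle $\varphi = \mathrm{atan2}(x, y)$
measured against the reference direction (0, 1) and signed by the x
component. Frames with $d > R_c = 32$ A are 3D diffusion (the threshold
is closed: $d = R_c$ counts as 1D). Within 1D intervals of at least 5 ns
(100 MD steps at the 50 ps/step convention; the rule is applied on the
finest available frame clock and exposed as a parameter), a frame is
groove tracking when its angle lies within 1.5 bp of the major-groove
center, where the groove center is the fitted linear relation
$\varphi_g(Z) = (2\pi / (\text{repeat} \times \text{rise})) Z +
\varphi_0$ calibrated from the phosphate geometry (for each base pair,
the groove azimuth is the bisector of the two backbone azimuths on the
major-groove side, and a least-squares line through the unwrapped
bisectors gives slope and phase). Remaining 1D frames are hopping.

Two smoothing rules remove noise events and are iterated to a fixed
point: hops spanning less than 1 bp are counted as parts of groove
tracking, and groove tracking lasting under 0.5 ns is counted as
hopping. A hop's span is Z at reattachment minus Z at detachment (signed
internally, magnitudes reported). Flips of a dimeric binder are recorded
when the Z-order of the two recognition regions inverts and persists for
a debounce window (default 10 frames). Event statistics report mean and
standard deviation of durations and spans per type, and the hopping
frequency per millisecond of 1D time; because it is not obvious whether
such a frequency should be normalized by 1D time or by total trace time,
both are reported (the 1D-time normalization is primary).

# Diffusion metrics

Translational and rotational MSDs are time averages over all start
frames of the squared displacement of $Z$ and of the unwrapped
$\varphi$. Diffusion coefficients are least-squares slopes over the lag
window 50-200 frames (2.5-10 us at the 50 ns frame clock) divided by 2,
with unit conversion to um^2/s and rad^2/s; a negative slope clamps
D to zero with a warning, and a log-log exponent well above 1 flags
super-diffusive curvature. The pitch of rotation-coupled sliding is
$p = 2\pi\sqrt{D/D_r}$ (10 bp at 3.32 A/bp signals faithful groove
tracking), and the hopping-augmented coefficient is
$D_{1D} = D_{helix} + x_{hop}^2 k_{hop} / 2$ with the hop length in
Angstrom and the frequency per ms. Both closed forms were validated
against the two published worked examples they must reproduce
(0.0026 um^2/s with 9.4 bp at 3.24/ms giving about 0.019 um^2/s, and
with 10.0 bp at 6.78/ms giving 0.04 um^2/s); with the printed
(rounded) inputs the first case evaluates to 0.0184 um^2/s, consistent
with 0.019 to one unit in the final printed digit.

# Synthetic inputs and what they do (and do not) show

All tests and the desk-scale pipeline run on generated inputs; no
downloads are required.

**Ideal B-DNA** places the three bead types on regular helices (radii
9.4, 7.4 and 2.0 A for phosphate, sugar, base; 3.32 A rise). The twist
default is 36 degrees/bp -- an exact 10-bp repeat -- rather than the
crystallographic 34.3 degrees, so that the groove-tracking signature sits
at exactly 10 bp/turn; both are configurable. The minor groove spans 140
degrees between the backbones. Each bead group is emitted as a small set
of pseudo-atoms whose centroid is exactly the ideal bead position, so
the real PDB reader and group-centroid coarse-graining path is exercised
end to end. The bent-DNA mimic joins two ideal arms at a chosen base
pair with a chosen inter-axis angle.

**The toy binder** is a schematic mini-protein, not a fold: a compact
helical core, a short glycine hinge whose dihedrals and contacts carry
the flexibility scale $f$ (default 0, the search-like fully flexible
state; $f = 1$ is the rigid recognition-like state), and a recognition
clamp -- a 13-bead arc spanning the 220-degree major-groove opening at
radius ~13.4 A, whose four arginine end beads sit ~3.5 A outside the two
phosphate ridges, in z-registry with the phosphate lattice. The dimer is
generated by a two-fold rotation about an axis perpendicular to the DNA,
its two arches are braced into one rigid body by stiff restraint bonds,
and an engineered inter-chain crosslink bond mimics the disulfide used
to stabilize dimeric DNA-binding-domain constructs. The geometry was
designed for one purpose: the symmetric two-ridge grip of the
in-register arginines makes the groove center the stable azimuth and
locks the clamp to the helical charge lattice, so the toy binder slides
with a near-10-bp pitch at low salt, while the arch -- wider than the
groove opening -- cannot wedge into the hollow of the three-bead DNA.
As screening increases, the grip loosens and registry slips
(rotation-decoupled moves) become more frequent.

What passing desk-scale tests show is that the machinery -- model
building, force field, integrator, classifier, estimators -- behaves
correctly and reproduces the qualitative physics (rotation-coupled
sliding near the helical repeat, salt-loosened grip, hopping-dominated
transport). They do not show that a real transcription factor's absolute
diffusion coefficients, event durations or hopping frequencies are
reproduced: those require the published reference structures
(crystal/NMR-derived models), 100-bp DNA and multi-millisecond
multi-replica sampling, for which `cluster_preset()` states the
conditions ($10^8$ steps, eight replicas, salts 0.01-0.06 M).

**Oracle traces** tile a time axis from planned segments: groove frames
obey the linear groove relation to within the chosen noise, hop frames
carry a half-turn rotational offset while Z advances by the planned
span, 3D frames sit beyond $R_c$, and flips swap the Z-order of two
regions at planned times. They provide exact ground truth for the
classifier, including the two smoothing rules.

# Numerical choices and degenerate inputs

* Angle terms at colinear geometry take the well-defined limit (zero
  gradient direction is dropped); dihedrals on colinear backbones are
  skipped for the degenerate frame rather than failing.
* A frame whose recognition-region COM lies on the DNA axis has
  undefined $\varphi$; it is excluded from the groove test.
* Contact detection normalizes pair order, removes duplicates, and
  refuses pairs that are already bonded; excluded-volume enumeration
  likewise excludes bonded neighbors (sequence separation up to 3).
* The topology JSON serialization writes full-precision numbers and
  round-trips losslessly.
* Event smoothing iterates the two rules to a fixed point (bounded at
  100 sweeps) so that re-applying the smoothing is a no-op.
* The equipartition check on a tethered bead is run at $\gamma = 1$:
  the thermostat's stationary distribution is independent of
  $\gamma$, but at the production value 0.01 the energy autocorrelation
  time (about $1/\gamma$) would leave too few independent samples in a
  $10^6$-step run to resolve a 5% variance check.

# Desk-scale study conditions

The desk preset simulates the dimeric toy binder on 30-bp ideal B-DNA
in a $120 \times 120 \times 144$ A reflecting box, four replicas of
$10^6$ steps (50 us mapped time, 1000 saved frames) at ionic strengths
0.01, 0.02 and 0.04 M, with diffusion fits over the 50-200-frame lag
window. These sizes keep a full grid within minutes on one core while
leaving enough sliding statistics for pitch and trend estimates; they
are stated here as the package's study conditions and used verbatim by
the test suite. Replicate aggregation is mean plus-or-minus standard
deviation (medians are reported alongside for the pitch, whose
per-replica estimates are heavy-tailed).

# Known limitations

* The three-beads-per-nucleotide DNA is geometrically hollow: small
  probes can in principle enter the groove vacuum between the bead
  helices. The toy binder's clamp is deliberately wider than the groove
  opening to avoid this; arbitrary user-built binders may not be.
* $B(\kappa) = 1$ ignores ion-condensation corrections, and the
  screening behaviour of the coarse-grained charge distribution shifts
  salt effects to lower concentrations than atomistic models.
* The reduced-time-to-physical-time mapping is conventional; absolute
  rates inherit it.
* The classifier implements the published rule set (cutoffs, tolerance,
  two smoothing rules) verbatim; no HMM or change-point alternative is
  provided.
* No solvent beyond Debye-Hueckel screening, no hydrodynamics, no
  replica exchange, and no free-energy or DNA-bending-penalty
  estimates.
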