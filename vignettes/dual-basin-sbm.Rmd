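---
title: "Dual-basin structure-based models of two-state conformational transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-basin structure-based models of two-state conformational transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Periplasmic binding proteins and their relatives interconvert between an
*open* and a *closed* conformation by a hinge motion of two lobes. Both end
states are usually known crystallographically, and the question is how the
protein moves between them and what structural elements bias that motion —
for the arginine-binding protein from *Thermotoga maritima* the element of
interest is a C-terminal helix (CTH) that docks between the lobes only in
the open state.

`twostateSBM` builds a coarse-grained structure-based ("Gō-like") model in
which each residue is one bead at its C-alpha position and **both** end
states shape the energy surface:

$$
E = \sum_{\mathrm{bonds}} K_r (r - r_0)^2
  + \sum_{\mathrm{angles}} K_\theta (\theta - \theta_0)^2
  + \sum_{\mathrm{dihedrals}} \sum_{n=1,3} K_{\phi,n}\!\left(1 - \cos n(\phi - \phi_0)\right)
  + U^{\mathrm{common}}_{\mathrm{DG}}
  + U^{\mathrm{OS}}_{10\text{-}12} + U^{\mathrm{CS}}_{10\text{-}12}
  + \sum_{\mathrm{non\text{-}contacts}} \varepsilon_4 \left(\frac{\sigma^{NC}}{r}\right)^{12}
$$

* **Bonded terms** take their native values $r_0, \theta_0, \phi_0$ from the
  open-state reference structure, with $K_r = 100$, $K_\theta = 20$,
  $K_{\phi,1} = 1$, $K_{\phi,3} = 0.5$ (energies in the reduced unit
  $\varepsilon$ = 1 kJ/mol, lengths in nm).
* **Common contacts** — residue pairs in contact in both states — carry a
  dual-Gaussian well
  $U_{\mathrm{DG}} = \varepsilon_{DG}\left[(1 + (\sigma^{NC}/r)^{12})(1 + G(r, r_1))(1 + G(r, r_2)) - 1\right]$
  with $G(r, r_n) = -\exp(-(r - r_n)^2 / 2\sigma_n^2)$, one minimum at the
  open-state pair distance $r_1$ and one at the closed-state distance $r_2$,
  each of depth exactly $-\varepsilon_{DG}$. A conventional Lennard-Jones well at
  $r_1$ would wall off any $r_2 < r_1$ behind its repulsive core; the
  Gaussian form removes that artificial barrier.
* **State-specific contacts** — pairs in contact in exactly one state — carry
  a 10–12 well $\varepsilon\,[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ at their own
  state's distance: strength $\varepsilon_{OS}$ (open) or $\varepsilon_{CS}$
  (closed), with open-specific contacts that involve the C-terminal tail
  scaled by a separate factor (`cth_scale`), the dial used to ask how tail
  docking strength restrains the transition.
* **Everything else** is excluded volume, $\varepsilon_4 (\sigma^{NC}/r)^{12}$
  with $\sigma^{NC} = 0.4$ nm.

Contacts are detected per state either from all heavy-atom proximity
(default cutoff 0.45 nm, the standard stand-in for surface-complementarity
contact callers, configurable in 0.40–0.50 nm) or from C-alpha distances
(for C-alpha-only inputs such as the synthetic toy). A pair present in only
one state is ratified as state-specific only when its distance in the other
state is *strictly* more than 1.5 times its own-state distance; single-state
detections failing that ratio are reported as `discarded` and contribute no
attractive term (they fall back to plain excluded volume). Pairs detected in
both states are common unconditionally. Contact distances entering the
potential are always C-alpha distances, because the model lives at C-alpha
resolution.

## Simulation protocol

Dynamics are Langevin in reduced units: time step 0.0005, temperature
entered on a Kelvin-like scale with $k_B = 0.008314$ (so the standard
T = 100 means $k_BT = 0.8314\,\varepsilon$), bead mass 1, friction 1 (neither is
stated by the usual protocols; they rescale time only, not equilibrium
averages). Frames and energy components are saved every 2000 steps. The
integrator is the BAOAB splitting of Langevin leapfrog; at zero friction it
reduces exactly to velocity Verlet, which is why the no-thermostat energy
drift is a meaningful correctness check. Velocities are initialised from the
Maxwell–Boltzmann distribution with the centre-of-mass motion removed, and
the R RNG seed fixes the noise stream, so trajectories are bit-reproducible.

The working protocol fixes $\varepsilon_{OS} = 1$ and raises $\varepsilon_{CS}$
along a grid until the trajectory shows multiple committed transitions with
both basins populated (`tuneEpsilonCS()`). State assignment along the
reaction coordinate (a cross-lobe C-alpha distance) is hysteretic: commit to
open above one threshold, to closed below a lower one, keep the previous
commitment in between. Hysteresis is deliberate — a single dividing surface
would count every noisy recrossing as two transitions. Defaults place the
thresholds at the midpoint of the two native distances ±25%. "Balanced" is
operationalised as each committed basin holding at least 20% of committed
frames at test scale (the full-scale criterion of equal populations with ≥50
transitions applies to production-length runs of ~10⁹ steps, which are
supported but not run in tests). Free-energy profiles are Boltzmann
inversion, $F = -k_BT \ln P$, over 50 bins by default, zero-count bins
omitted rather than smoothed, minimum shifted to zero.

## The synthetic two-state toy

Tests and the acceptance analysis run on a generated two-state protein, so
no downloads are involved. The toy reproduces the *architecture* that the
method needs, not protein geometry:

* two lobes built as three-strand-spaced hairpin bead arrangements
  (cross-strand spacing 0.55 nm, virtual bond 0.38 nm), giving a reliable
  population of common contacts;
* a curved hinge of 8 beads whose per-bond turn differs between the states,
  so the 45° lobe rotation is distributed and no single backbone angle is
  strained far from its reference value;
* a closed state in which the lobes converge tip-to-tip across a binding
  mouth (closed-specific contacts), all-bead open/closed RMSD well above
  0.3 nm;
* a 6-bead C-terminal tail that docks into the inter-lobe cleft in the open
  state — the same cleft the fixed lobe occupies when the protein closes, so
  tail docking and closing are mutually exclusive, which is exactly the
  coupling that makes the tail-strength dial (`cth_scale`) suppress the
  closed basin;
* in the closed state the tail is peeled out of the cleft by a rigid,
  joint-distributed rotation, preserving its internal geometry (a tail that
  changed internal conformation between states would fight the open-state
  bonded natives with tens of $\varepsilon$ of strain).

The generator also emits ground truth: a planted contact map computed by an
independent brute-force pair scan, used to check the detection and
classification code exactly; per-state clash checks (no non-bonded pair
below 0.35 nm); and a suggested reaction-coordinate pair (the two lobe
tips, ~3.2 nm open / ~1.0 nm closed at the defaults).

What the toy does *not* emulate: side chains (so all-atom detection is
exercised on a separate all-atom salt-bridge fixture instead), realistic
secondary structure, solvent, and the size of a real binding protein
(~44 beads vs ~230 residues). Passing tests on the toy therefore validate
the machinery — potentials, forces, sampling, classification, tuning — not
any biological statement about a particular protein.

## Numerical choices

* Forces are analytic for every term (including the product rule through the
  dual-Gaussian bracket) and are validated against central finite
  differences to 10⁻⁵ ε/nm on random configurations.
* Excluded volume is truncated at 2.5 nm, where the term is below 10⁻⁹ ε;
  the pair list is the precomputed complement of bonded (|i−j| ≤ 3) and
  contact pairs, swept with a plain distance check each step — at the system
  sizes used here (≤ ~250 beads) this is cheaper than maintaining a Verlet
  list.
* Angle forces guard the $1/\sin\theta$ factor at $10^{-8}$; the toy's
  zig-zag geometry keeps angles far from collinearity, where the spherical
  angle coordinate itself is singular.
* Dihedrals use the signed IUPAC convention in $(-\pi, \pi]$; periodicity is
  handled entirely through cosines, so no wrapping is needed.
* The energy-divergence guard aborts a run when |E| exceeds 10⁶ ε or goes
  non-finite, reporting the step.
* Test- and acceptance-scale run lengths (10⁵ steps for energy
  conservation, 10⁶ for thermostat calibration, 3–5 × 10⁶ for transition
  sampling, 20–80-bin profile stability at 10⁵ samples) were chosen as the
  smallest sizes at which the corresponding statistics are stable; the
  production protocol of ~10⁹ steps is supported by the same code path.

## Design decisions taken where the method leaves room

* **Dual-Gaussian depth placement.** $\varepsilon_{DG}$ multiplies the whole
  bracketed expression, making the well depth exactly $-\varepsilon_{DG}$ at both
  native distances; this matches its role as "the depth of the Gaussian
  well".
* **Dihedral functional form** is the standard two-term C-alpha-SBM cosine
  series $\sum_{n=1,3} K_n (1 - \cos n(\phi - \phi_0))$, consistent with the
  stated force constants.
* **Single-state detections failing the 1.5× ratio are dropped** from the
  attractive potential but kept in the map as `discarded`, so the common
  class equals the both-state set and the specific classes are exactly the
  rule-filtered ones; the choice is conservative and auditable.
* **Superposition** is Kabsch on matched C-alpha atoms of shared author
  residue numbers (sequence-independent structural alignment is out of
  scope); residue correspondence across constructs that differ by small
  insertions is recovered by global sequence alignment
  (`mapResidueNumbering()`).
* **Accession-based regression numbers** (contact-class counts of the real
  open/closed crystal pair and the grafted helix-bearing monomer) require
  the deposited PDB files; the test suite looks for them in
  `tests/testthat/pdb-cache/` and reports the regression as failed when they
  are absent rather than silently skipping it. The detection cutoff used for
  those counts is recorded in the contact map's parameter block.
* **Tail undocking in the toy** is modelled as a rigid distributed curl
  (80° total) rather than a conformational change, for the strain reason
  above.
* A generator request with `hinge_angle = 0` is rejected rather than
  returning two identical structures: the supported range (20°, 120°) is
  part of the toy's contract that the two states be genuinely distinct.

## Known limitations

* The physical time scale of reduced-unit Langevin dynamics is not mapped to
  seconds; transition *counts* are comparable between runs, rates are not.
* The 10–12 and dual-Gaussian forms encode native-centric energetics only:
  no electrostatics, no desolvation barriers, no non-native attraction.
* All-atom analyses (salt-bridge monitoring) apply to externally produced
  all-atom trajectories; the package does not run all-atom MD.
* Exact reproduction of contact counts from deposited structures depends on
  the contact caller; the all-heavy-atom proximity criterion is a documented
  stand-in for surface-complementarity callers, and its cutoff is the one
  calibration knob (0.40–0.50 nm).

## A worked example

```{r, eval = FALSE}
library(twostateSBM)

toy <- makeTwoStateToy(toySpec(seed = 1))
classCounts(toy$contacts)

params <- sbmParams(eps_os = 1, eps_cs = 1.25,
                    cth_range = attr(toy$contacts, "params")$cth_range)
top <- buildTopology(toy$open, toy$contacts, params)
traj <- runDynamics(top, params = integratorParams(
  n_steps = 5e6, save_every = 2000, temperature = 100, seed = 11))

rc <- rcSeries(traj, toy$rc_pair[1], toy$rc_pair[2])
labels <- assignStates(rc, open_threshold = 2.6, closed_threshold = 1.6)
countTransitions(labels)
basinPopulations(labels)
plot(pmf(rc, temperature = 100)$bin_center,
     pmf(rc, temperature = 100)$F, type = "b",
     xlab = "lobe-tip distance (nm)", ylab = "F (eps)")
```
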