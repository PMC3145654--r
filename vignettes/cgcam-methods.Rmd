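---
title: "Models and methods in cgcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cgcam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcam)
```

# The physical model

## Coarse graining

Calmodulin is represented with two beads per residue: a backbone bead at
the C$_\alpha$ position and a side-chain bead at the centroid of the
side-chain heavy atoms; glycine contributes no side-chain bead, so the
148-residue protein maps to $2 \times 148 - 11 = 285$ beads. The bonded
Hamiltonian is

$$E_{bond} = \sum k_b (r - r^0)^2, \qquad
  E_{angle} = \sum k_\theta (\theta - \theta^0)^2,$$

with $k_b = 100\,\varepsilon$, $k_\theta = 20\,\varepsilon$ and
$\varepsilon = 0.6$ kcal/mol the solvent-mediated energy unit. We use the
convention without the $\tfrac12$ prefactor, which is the convention of the
side-chain C$_\alpha$ model family this package follows. All reference
values ($r^0$, $\theta^0$, and the dihedral phases $\phi^0$) are measured
from the input structure, so the bonded energy of the input conformation is
exactly zero — a property the test suite asserts to $10^{-6}$ Å.

Backbone dihedrals use a 1-fold + 3-fold cosine series
$k_1[1-\cos(\phi-\phi^0)] + k_3[1-\cos 3(\phi-\phi^0)]$ with defaults
$k_1 = 1.0\,\varepsilon$, $k_3 = 0.5\,\varepsilon$. Dihedrals that involve
rebuilt terminal residues can be disabled per residue
(`dihedral_disable`), preserving the polymeric flexibility of termini
that were not resolved in the crystal structure.

## Native contacts and excluded volume

A residue pair at sequence separation $\ge 3$ forms a native contact when
its heavy-atom minimum distance in the reference structure is below 4.5 Å
(side-chain atoms define side-chain bead contacts, backbone atoms define
C$_\alpha$ contacts). Each contact carries a 12-10 well
$d\,[5(r^0/r)^{12} - 6(r^0/r)^{10}]$ with minimum $-d$ at the native
distance. The default depth model is uniform ($d = \varepsilon$); a
residue-pair statistical potential can be plugged in as a function
`(resid_i, resid_j) -> depth` because the published depth tables belong to
the cited statistical-potential literature and users may prefer different
scalings.

All other non-bonded, non-contact pairs — and every pair involving a
calcium bead or a crowder — are strictly repulsive:
$\varepsilon(\bar\sigma_{ij}/r)^{12}$ with
$\bar\sigma_{ij} = f(\sigma_i + \sigma_j)$, $f = 0.9$, where $\sigma_i$
are the stored bead radii. With this combination the repulsion reaches
exactly $\varepsilon$ when two beads touch at $f$ times their contact
distance; in particular two 55 Å crowders at centre separation 110 Å
interact with $0.9^{12}\,\varepsilon$. (Combining *radii* with a factor
$f/2$ instead would let "hard" spheres overlap at negligible energetic
cost, which contradicts the excluded-volume role of the term.)

## Electrostatics

Charged beads interact through the Debye–Hückel potential

$$V_{ij} = \frac{Z_i Z_j e^2}{4\pi\epsilon_0\epsilon_r r}\,e^{-\kappa r},
\qquad
\kappa^2 = \frac{2 N_A e^2 I \cdot 10^3}{\epsilon_0 \epsilon_r k_B T},$$

with $\epsilon_r = 80$. This is the only place physical units enter the
package; the result is converted once to reduced units by dividing by
$\varepsilon = 0.6$ kcal/mol. CODATA 2022 constants give a screening
length of 9.71 Å at $I = 0.1$ M and 4.34 Å at 0.5 M (298 K), and a Bjerrum
length of 7.01 Å. Bonded (1-2) and angle (1-3) pairs are excluded.
Calcium beads carry no Debye–Hückel charge: their non-bonded role is
strictly steric, and their electrostatic association with the EF-hand
ligands is represented by the explicit springs. Charge assignment uses an
explicit per-residue table when available (backbone and side-chain bead
charges per residue, as produced by ensemble-averaged quantum-chemical
calculations); the fallback mode assigns formal charges (Asp/Glu $-1$,
Lys/Arg $+1$, all backbone beads and termini neutral, matching chemically
capped termini), which reproduces the protein's net charge of $-24\,e$.
Both the screened-Coulomb and dispersion terms contain dipolar physics, so
some double counting of electrostatics is inherent to the model; no
correction is applied.

# Dynamics

## Langevin integration

Propagation uses the BBK discretisation of the Langevin equation
(velocity Verlet with friction and noise): the random force has variance
$2\zeta k_B T/h$ per degree of freedom and enters both half-kicks, and the
scheme reduces exactly to velocity Verlet at $\zeta = 0$ — the test suite
verifies $10^{-4}\,\varepsilon$ energy conservation over $10^4$ steps for
a bonded dimer, and equipartition of the sampled velocities. Defaults are
the low-friction regime used for coarse-grained folding studies:
$h = 0.005\,\tau_L$, $\zeta = 0.05\,m/\tau_L$, with
$\tau_L = \sigma\sqrt{m/\varepsilon}$ the reduced time unit. A step that
moves any bead by more than half the smallest bead radius aborts with
advice to reduce $h$. In a periodic box only crowder beads are wrapped
into the primary cell; bonded beads keep continuous coordinates, because
bonded distances are deliberately non-periodic while all non-bonded terms
use the minimum image.

## Replica exchange

One replica runs per ladder temperature (production default: 18 replicas,
geometric spacing from 1.0 to 1.63 $k_BT/\varepsilon$; the spacing rule is
our choice, as only the endpoints and count are prescribed by the study
design). Every `exchange_interval` (default $400\,\tau_L$) neighbouring
pairs — alternating even/odd pairs on successive attempts — exchange with
the Metropolis probability
$\min\!\big(1, e^{(\beta_i-\beta_j)(E_i-E_j)}\big)$; on acceptance the
replicas swap temperatures and velocities are rescaled by
$\sqrt{T_{new}/T_{old}}$. Frames are recorded every 1000 steps by default;
`energy_autocorrelation_time()` reports how correlated the recorded
energies still are. All randomness in a run flows from a single seed, and
identical seeds give bitwise-identical trajectories.

## Crowders

Ficoll 70 is modelled as a 55 Å hard sphere. The number of crowders at
volume fraction $\phi_c$ in a cubic box of edge $L$ is
$\lfloor \phi_c L^3 / (\tfrac43\pi R^3) \rfloor$ — 850 at $\phi_c = 0.40$
and 531 at 0.25 for the 1140 Å production box. Dilute systems
($\phi_c \le 0.2$) are placed by random sequential insertion; denser
systems use a jittered simple-cubic lattice, because sequential insertion
of equal spheres becomes impractically slow well before its jamming
density ($\phi \approx 0.38$) and the 0.40 condition lies beyond it. The
lattice construction is deterministic per seed and provably overlap-free
(jitter amplitude $(L/n - 2R)/2$ per axis). Crowders default to mobile
particles of reduced mass 10 — scaling mass with crowder volume would
freeze their dynamics relative to the protein — with a
`frozen_crowders` option.

# Ensemble analysis

- **Overlap function** $\chi$: the fraction of bead-pair distances
  (residue separation $\ge 2$) deviating from the reference by more than
  2 Å. Both the tolerance and the separation rule are package defaults,
  configurable, since the underlying similarity measure is conventionally
  reported without parameters.
- **Asphericity** $\Delta = \tfrac32 \sum_i (\lambda_i - \bar\lambda)^2 /
  (\sum_i \lambda_i)^2$ from the gyration-tensor eigenvalues: 0 for a
  sphere, 1 for a rod.
- **Helicity**: residue $i$ is helical when the C$_\alpha$ virtual
  dihedral $(i{-}1,i,i{+}1,i{+}2)$ lies in $[30^\circ, 80^\circ]$ and
  $d(\mathrm{C}_\alpha^i, \mathrm{C}_\alpha^{i+4}) < 6.5$ Å; chain ends
  where the criteria are undefined are excluded from the denominator.
  This estimator is a design choice (the window brackets the canonical
  $\approx 50^\circ$ helical value realised by the ideal-helix fixture);
  no standard definition exists at C$_\alpha$ resolution.
- **EF-hand angle** $\Theta_{ij}$: each helix is reduced to the vector
  from the mean of its first four residues to the mean of its last four;
  $\Theta$ is the arccosine of the unit-vector inner product. Helix
  ranges default to the HELIX records of the input structure, with a
  packaged fallback table for calmodulin's helices A–H.
- **Contacts**: a native contact is formed at $r < 1.2\,r^0$, a nonnative
  candidate at side-chain distance $< 8$ Å (both configurable). Formation
  probabilities are arranged residue-by-residue with native contacts in
  the upper triangle and nonnative in the lower; the covariance matrix is
  the Pearson correlation of the per-frame indicators, with
  zero-variance contacts flagged NA rather than filled.
- **WHAM**: the standard two self-consistent equations on binned energies
  (200 bins, tolerance $10^{-7}$ on the free-energy increments, $10^5$
  iteration cap, log-sum-exp throughout), with a histogram-overlap
  diagnostic that rejects disconnected ladders. Reweighted averages use
  per-sample (not binned) energies. Standard errors default to block
  averaging over 20 contiguous blocks, which absorbs the autocorrelation
  of dynamical samples; the naive effective-sample-size error is
  available for genuinely independent samples.
- **Free-energy surfaces** $F(\chi, \Delta) = -k_BT \ln P$ on a
  $50 \times 50$ grid over $[0,1]^2$, minimum shifted to zero, unvisited
  bins left NA. Basin populations (M1: $0.1<\chi<0.3$, $0.28<\Delta<0.3$;
  M2: $0.3<\chi<0.4$, $0.03<\Delta<0.15$; M3: $0.38<\chi<0.45$,
  $0.01<\Delta<0.1$) use closed lower and open upper bounds.
- **CD synthesis**: $\theta(\lambda) = f_H B_H + f_\beta B_\beta +
  (1-f_H-f_\beta) B_C$ over a packaged basis grid. The shipped basis is a
  smooth *synthetic* stand-in shaped after the classic poly-amino-acid
  reference spectra (positive ~193 nm band and 208/222 nm double minimum
  for helix, etc.); digitised experimental reference spectra can be
  substituted via the `basis` argument. Only secondary-structure content
  enters this approximation — contributions from tertiary rearrangements
  such as helix reorientation are not representable.

# CD thermal-unfolding analysis

Raw millidegrees are converted to mean residue ellipticity with
$[\theta] = \mathrm{mdeg} \cdot MW / (\ell_{mm} \cdot c_{mg/ml} \cdot
N_{res})$. Unfolding free energies come from the modified Gibbs–Helmholtz
equation with $\Delta G(T_m) = 0$ and $K = e^{-\Delta G/RT}$, so the
unfolded species is favoured above the midpoint. The three-state model is
the sequential scheme N↔I↔U with populations
$f_N = 1/(1+K_1+K_1K_2)$, $f_I = K_1 f_N$, $f_U = K_1K_2 f_N$; the
two-state model is its exact $K_2 \to 0$ limit (asserted numerically to
$10^{-10}$). All six baseline parameters of the three-state model are
free by default; `pin_intermediate_slope` fixes $S_I = 0$ for difficult
curves.

Fitting is Levenberg–Marquardt with box constraints (midpoints within the
data range ± 30 K, enthalpies in $[0.5, 300]$ kcal/mol) and multi-start
initialisation: midpoints are seeded from extrema of the smoothed
numerical derivative, baselines from lines through the curve ends, and
restarts perturb both. When heat-capacity terms are free the fit is
staged — a first pass with $\Delta C_p$ pinned at 0 locates the
transitions before the full fit releases it — which keeps
edge-of-range transitions from collapsing into baseline drift.
Conditioning is judged on the parameter-scaled Hessian
($H_{ij}/\sqrt{H_{ii}H_{jj}}$, reciprocal condition number below
$10^{-10}$, or any relative standard error above 10), so the disparate
natural scales of ellipticity intercepts and midpoint temperatures do not
trip the flag; a featureless straight line is reliably flagged.

## The synthetic melting-curve generator

`generate_melting_curve()` produces model curves plus i.i.d. Gaussian
noise on a 5–95 °C grid (1 °C pitch, 91 points). The default study
conditions for recovery tests use the apo three-state magnitudes —
midpoints 46.6/61.3 °C, enthalpies 27.2/43.0 kcal/mol, $\Delta C_p = 0$ —
with baselines shaped like an apo-CaM 222 nm melt (native near
$-17{,}700$ deg cm²/dmol at 5 °C, a distinguishable intermediate
shoulder, unfolded near $-2{,}400$ at 95 °C) and noise of 25 deg cm²/dmol.
That noise level was chosen as representative of averaged duplicate CD
melts; at it, the spread of recovered parameters across replicates matches
the standard errors the fits themselves report. The generator emulates
independent homoscedastic noise only: it does not reproduce instrument
drift, temperature-lag autocorrelation, or baseline curvature, so
parameter recovery here demonstrates estimator correctness, not robustness
to those systematics.

# Problem sizes and numerical tolerances

The test and acceptance workloads are desk-scale by design: energy/force
oracles run on random systems of $\le 30$ beads (brute-force double loop,
$10^{-10}$ relative; forces vs central differences, $10^{-5}$ relative);
sampling correctness uses 3 particles in harmonic wells under a 4-replica
ladder (1.0–1.6) for $5 \times 10^4$ steps at $h = 0.02$, $\zeta = 1.5$,
with the first 10% discarded as burn-in — the friction is higher than the
protein-production default purely to decorrelate the benchmark quickly —
and WHAM-reweighted $\langle E_{pot}\rangle$ is required to sit within 3
block-averaged standard errors of $\tfrac32 N k_BT$ at every ladder
temperature and an interpolated one; unfolding recovery uses 100 replicate
fits. Full production landscapes of calmodulin (18 replicas, $\ge 4\times
10^7$ steps, several ionic strengths and crowding levels, real crystal
structures) are cluster-scale and out of scope for the packaged checks;
the synthetic 148-residue helical stand-in used in tests exercises the
bookkeeping (bead counts, charges, calcium connectivity) but is *not* a
conformational model of calmodulin.

# Known limitations

- Nonnative side-chain attractions are off by default (repulsive-only);
  an attractive statistical-potential mode can be supplied through the
  contact-depth hook, and the choice is recorded in the topology.
- The Debye–Hückel term double-counts some dispersion electrostatics, as
  noted above.
- The CD basis is synthetic; quantitative spectrum comparisons require a
  measured reference basis.
- Pure R pair loops limit practical system sizes to a few hundred protein
  beads plus $O(10^3)$ crowders for single-point evaluation; long
  production replica-exchange runs at that size need compiled kernels,
  which this package intentionally does not include.
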