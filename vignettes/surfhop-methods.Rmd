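---
title: "Surface hopping with competing internal conversion and intersystem crossing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface hopping with competing internal conversion and intersystem crossing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfhop)
```

## The problem

UV-excited pyrimidine nucleobases relax through a network of radiationless
transitions: internal conversion (IC) between states of equal spin
multiplicity through conical intersections, and intersystem crossing (ISC)
into the triplet manifold mediated by spin–orbit coupling (SOC). For uracil,
surface-hopping simulations that treat non-adiabatic couplings and SOC on the
same footing show that ISC out of the dark ¹nπ* state competes directly with
internal conversion to the ground state, leaving a sizeable triplet
population after a picosecond and quenching ground-state recovery.

`surfhop` implements that simulation protocol end to end — initial
conditions, propagation, population analysis, kinetics — against a synthetic
electronic-structure provider, so every stage runs and is verifiable at desk
scale. The provider contract (a complex Hermitian spin-component Hamiltonian,
per-state gradients, Hamiltonian derivatives and transition dipoles at any
nuclear configuration) is the same one an on-the-fly quantum-chemistry
adapter would satisfy, so the propagator never needs to know whether energies
come from a model or from an *ab initio* engine.

## The electronic model

The synthetic provider is a linear vibronic coupling (LVC) model. In a
quasi-diabatic basis of spin components (all singlets first, then triplets
grouped by state with $M_s$ ascending),

$$H_{ii}(q) = \epsilon_i + \sum_m \kappa_{i,m}\,q_m + \sum_m \tfrac12\,\omega_m q_m^2,$$

with the harmonic part shared by all states, linear spin-free couplings
$H_{ij} = \sum_m \lambda_{ij,m} q_m$ between equal multiplicities, and
constant complex SOC elements $\eta$ between singlet and triplet spin
components. Coordinates are dimensionless mass–frequency scaled normal
coordinates (effective mass $1/\omega$), the natural units of vibronic
coupling models. Because the interstate couplings are linear in the
coupling-mode displacement, they vanish at the reference geometry, and the
configured vertical energies are *exact* eigenvalues there when SOC is
disabled.

The default, uracil-like parameterization spans 4 singlets and 3 triplets
(13 spin components) over three effective modes:

* a **tuning mode** (1520 cm⁻¹) along which the bright ¹ππ* diabat relaxes
  and crosses the dark ¹nπ* state,
* a **coupling mode** (880 cm⁻¹) carrying all spin-free interstate couplings,
* a **recovery/ISC mode** (1210 cm⁻¹) along which the ¹nπ* state is strongly
  displaced, sweeping both the singlet–triplet crossing region and,
  at larger elongation, the ground-state recovery funnel.

Vertical energies at the reference geometry are the multi-configurational
benchmark values for the diketo tautomer (S₁ nπ\* 5.13, S₂ ππ\* 7.04,
S₃ 7.07, T₁ ππ\* 4.00, T₂ nπ\* 4.95, T₃ ππ\* 5.86 eV). SOC magnitudes follow
El-Sayed's rule: pairs that change orbital character (¹nπ\* ↔ ³ππ\*,
¹ππ\* ↔ ³nπ\*) carry 40 cm⁻¹; same-character pairs an order of magnitude
less (4 cm⁻¹). Each SOC magnitude is split evenly over the three $M_s$
components with real coefficients $1/\sqrt{3}$ — a fixed, documented phase
convention under which only the symmetric $M_s$ combination couples, which is
the physically relevant single ISC channel of the pair.

The intrastate slopes $\kappa$ were chosen by placing the crossings the
mechanism requires (the model is synthetic; no published surfaces exist to
fit):

* the ¹ππ*/¹nπ* crossing sits ~0.1 eV above the relaxed bright-state
  minimum, so early hot trajectories convert quickly while later ones are
  partly trapped;
* the ¹nπ* state is steeply displaced along the third mode, so that its
  vibrational excursions sweep a singlet–triplet crossing with the ³ππ*
  diabat near the outer turning point (slow passage, efficient ISC despite
  small SOC) and reach the ground-state crossing seam at larger elongation;
* triplet–triplet couplings are strong (0.008 hartree per unit displacement),
  so internal conversion into the lowest triplet is fast once ISC happened,
  making the triplet manifold an effective population ratchet.

One deliberate departure from the reference-geometry state characters: the
S₃ diabat carries a bright transition dipole (1.1 a.u.) although the
benchmark labels S₃ dark nπ* at the Franck–Condon point. The character of
that state swaps with tiny displacements in the real molecule, and it hosts a
substantial share of the photoexcited population; a Condon-diabatic model can
only reproduce that by making the diabat itself bright. With dipoles of 1.2
(S₂) and 1.1 (S₃) a.u. the δ-pulse selection splits roughly 55:45 between the
two bright states, close to the reported trajectory splits.

```{r}
model <- build_uracil_lvc_model()
model
```

## Initial conditions

Geometries and velocities are sampled from the Wigner function of the ground
vibrational state (0 K): per mode, independent Gaussians with position
variance $\hbar/(2m\omega)$ and momentum variance $m\omega\hbar/2$. No
thermal excitation is applied. Excitation energies and oscillator strengths
($f = \tfrac23\,\Delta E\,|\mu|^2$, length gauge) are tabulated for every
sample, a broadened absorption spectrum is a sum of Gaussians with area
proportional to $f$ (default FWHM 0.1 eV — the width is a display choice, not
a physical parameter), and initial excited states are drawn with probability
proportional to $f$, optionally restricted to an inclusive excitation-energy
window (the analogue of a finite-bandwidth experiment, e.g. 6.52–6.66 eV).
Selection is with replacement: under a δ-pulse each trajectory's initial
state is an independent draw from the same distribution.

## Propagation

One nuclear step (default $\Delta t$ = 0.5 fs, 1 ps total) proceeds as:

1. **Diagonalization with continuity tracking.** The full Hamiltonian
   including SOC is diagonalized; eigenvector columns are matched to the
   previous step greedily by largest squared overlap and phases are fixed so
   $\mathrm{diag}(U_{prev}^\dagger U)$ is real positive. Nuclei move on these
   *diagonal* (spin-mixed) surfaces. When the model carries no SOC at all,
   the multiplicity blocks are diagonalized separately, so spin purity is
   structural rather than numerical.
2. **Velocity Verlet** on the active diagonal surface with exact
   Hellmann–Feynman gradients $\langle u|\partial H/\partial q_m|u\rangle$.
3. **Amplitude propagation** in the quasi-diabatic basis with $H(t)$
   linearly interpolated across the step and advanced by exact midpoint
   exponentials over substeps (default $\delta t$ = 0.02 fs), then rotated
   into the diagonal basis. This local-diabatization scheme avoids
   differentiating eigenvectors numerically and conserves the amplitude norm
   to ~10⁻¹² per step.
4. **Energy-based decoherence**: every non-active amplitude is damped with
   $\tau_\beta = \frac{\hbar}{|E_\beta - E_{active}|}\bigl(1 +
   \frac{\alpha}{E_{kin}}\bigr)$, $\alpha$ = 0.1 hartree, and the active
   amplitude is rescaled to restore the norm. Degenerate states are left
   untouched.
5. **Fewest-switches hop** with population-flux probabilities: the loss of
   active-state population over the step is apportioned among the states
   whose populations grew. This variant is well defined in the diagonal
   basis without explicit time-derivative couplings; the hopping expression
   is a configuration point, not a law of the package.
6. **Energy bookkeeping.** Accepted hops rescale the full velocity vector
   uniformly so total energy is conserved exactly; energetically forbidden
   upward hops are recorded as frustrated and leave the velocities unchanged
   (no reflection). Uniform rescaling is used because a coupling-vector
   direction is ill-defined for SOC-mediated hops.

Initial amplitudes are a pure state on the diagonal surface that best
overlaps the assigned spin-free state (δ-pulse). Every trajectory owns a
deterministic RNG stream derived from its child seed, so ensembles are
bit-reproducible and individual trajectories can be re-run in isolation.

### Numerical behaviour worth knowing

* On smooth surfaces (no interstate couplings) the integrator's secular
  energy drift is below 10⁻⁶ hartree/ps at the default step; the bounded
  sub-10⁻⁴ hartree oscillation of a velocity-Verlet integrator remains.
  "Drift" is therefore measured as the linear-regression slope of total
  energy against time, not as the peak-to-peak fluctuation.
* Through *narrowly* avoided crossings (weak SOC), the tracked adiabatic
  surfaces carry kinks that a 0.5 fs step cannot fully resolve; single steps
  landing inside such a region pick up a mixed gradient, and total energy
  acquires a random-walk error on the meV scale per crossing passage. This
  is a known property of surface hopping at fixed step size, shared by
  production codes; the drift acceptance threshold is therefore stated for
  smooth surfaces.
* Exactly degenerate triplet $M_s$ components make the eigenbasis within the
  degenerate subspace arbitrary; overlap tracking resolves the assignment,
  and any residual $M_s$ mixing is physically irrelevant (all observables
  aggregate over $M_s$).

## Analysis

Populations are counted by the **active state** of each trajectory (classical
occupations), mapped into one of three representations: the diagonal basis,
the spin-free **MCH** basis (assignment by largest squared overlap of the
active diagonal state), or the **spectroscopic** classes obtained from the
transition dipole of the active MCH state: > 0.05 a.u. bright ¹ππ*,
1 × 10⁻⁶–0.05 a.u. dark ¹nπ* (the boundary value 0.05 a.u. itself classifies
as dark), < 10⁻⁶ a.u. triplet; the lowest singlet is always the closed-shell
ground-state class. Trajectory validity follows the protocol rule: keep
completed trajectories, and early-terminated ones whose final contiguous
residence in S₀ or T₁ is at least 15 fs; kept early-terminated trajectories
are frozen in their terminal class for the remainder of the grid (at low
energy those states do not re-cross in the model). Hop statistics tally IC
and ISC events separately and summarize |SOC| (total over $M_s$, cm⁻¹) and
|ΔE| (eV) at accepted ISC hops. Geometry descriptors (bond lengths,
out-of-plane angles against a least-squares plane) operate on multi-frame XYZ
input for full-coordinate workflows.

## Kinetics

Population traces are fitted by unweighted nonlinear least squares to
mono-/biexponential saturating forms, e.g.
$P(t) = 1 - a e^{-t/\tau_1} - (1-a) e^{-t/\tau_2}$ for the combined
S₀ + T₁ rise and the mirrored complements for decays, with time zero fixed at
0 (δ-pulse; no instrument-response convolution). Standard errors are the
asymptotic ones from the scaled inverse Gauss–Newton normal matrix — they
quantify fit precision only, not the simulation's systematic errors. Fits are
started from a log-spaced 3×3 grid of time-constant guesses; biexponential
results are relabelled so $\tau_1 \le \tau_2$. Constant traces are rejected
loudly rather than returning a meaningless time constant. Model comparison
uses AICc. Unweighted least squares is a stated choice: the counting noise of
an ensemble trace is approximately binomial and nearly homoscedastic in the
population range encountered here.

```{r}
t <- seq(0, 1000, by = 2)
y <- 1 - 0.3 * exp(-t / 60) - 0.7 * exp(-t / 900)
fit_exponential(t, y, "bi_rise")
```

## What the synthetic ensemble does and does not show

With the default model, a ~100-trajectory ensemble reproduces the
*qualitative* mechanism: fast bright-to-dark conversion, a monotonically
growing triplet population fed through the ¹nπ* doorway, suppression of both
the dark-state buildup and the ground-state recovery when the ISC channel is
open, ISC hops at small energy gaps with SOC of a few tens of cm⁻¹. These are
ordinal statements, and the test suite asserts exactly those.

It does **not** reproduce the published time constants or yields, and no test
pretends otherwise: those depend on the full-dimensional CASSCF surfaces. Two
structural limitations matter. First, with three effective modes there is no
intramolecular vibrational-energy bath; trajectories stay microcanonically
hot, so trapped populations re-cross more than in full dimensionality.
Second, the diabats carry fixed (Condon) characters, so character swaps along
a path appear only through state mixing, and the σ(n–π)π* ring-opening
character is not a separate class — the dipole-threshold classification is
applied verbatim.

## Problem sizes used by the shipped checks

The test suite runs 2000-trajectory ensembles on the 1D two-state crossing
fixture (Landau–Zener validation at three coupling strengths), 100-trajectory
ensembles of the uracil-like model over 500 fs for the mechanism comparison
and 150 fs for the spin-purity check, 50 000 Wigner samples for the moment
checks, and 200 replicate fits for the coverage simulation. These sizes were
chosen so each check resolves its effect well beyond 3 Monte-Carlo standard
errors while the whole suite stays convenient to run on a laptop.
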