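---
title: "Modelling CIDNP field dependences of flexible biradicals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CIDNP field dependences of flexible biradicals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cidnpr)
```

This vignette documents the science and the numerical choices behind
`cidnpr`: the spin model that generates the simulated CIDNP field
dependences, the relaxation-dispersion and deconvolution stages around it,
what the synthetic-data generator does and does not emulate, and the known
limitations of the default configuration.

## The physical picture

A photo-excited flavin abstracts an electron from the adenine moiety of the
same FAD molecule, producing a short-lived spin-correlated biradical with a
triplet precursor.  The two radical centres are joined by a flexible
ribityl-phosphate linker, so the inter-radical distance $r$ is not fixed: it
diffuses over an end-to-end distance distribution $p(r)$.  The exchange
interaction $J(r)$ splits the electronic singlet from the triplet, and for
$J<0$ the $S$ and $T_-$ levels cross at an external field $B \approx 2|J|$.
Nonsecular hyperfine terms turn the crossing into an avoided crossing and
drive nuclear-spin-selective triplet-to-singlet conversion there; singlet
pairs recombine, so the geminate product acquires net nuclear polarization
with emissive sign regardless of the sign of the hyperfine coupling — the
signature of the $T_-$–$S$ mechanism.  Because $J$ depends on $r$, the
field position of the resulting CIDNP extremum encodes the distances the
biradical actually samples, which is what makes the field dependence a
structural probe.

## The stochastic Liouville model

`geminate_polarization()` solves, per magnetic field, a linear system for
the time-integrated density matrix of the coupled spin–distance problem:

* **Spin space.** Electron a (adenine, $g_a$) carrying the observed spin-½
  nucleus with isotropic coupling $A$ (full $\mathbf{S}_a\cdot\mathbf{I}$,
  flip-flop terms included); electron b (flavin, $g_b$) carrying $n_{add}$
  additional equivalent spin-½ nuclei of coupling $A_{add}$; exchange
  $H_{ex} = -J(r)\,(\tfrac12 + 2\,\mathbf{S}_a\cdot\mathbf{S}_b)$, so
  negative $J$ puts $T_-$ below $S$ at low field and produces an $S$/$T_-$
  crossing at a positive field.  Nuclear Zeeman terms are neglected (five
  orders of magnitude below the electronic terms at every relevant field).
* **Distance space.** A uniform radial grid (default 81 nodes,
  0.49–1.6 nm) with a nearest-neighbour Smoluchowski generator whose
  hopping rates $(D/h^2)\sqrt{p_{i\pm1}/p_i}$ satisfy detailed balance, so
  the discretised distribution is stationary exactly and columns sum to
  zero.  Boundaries are reflecting.
* **Kinetics.** Singlet-projected recombination $k_p$ acts at the innermost
  node only ("contact"); scavenging $k_s$ acts uniformly on every node and
  spin state.  The observable is the nuclear polarization carried into the
  recombination product, $k_p\,\mathrm{tr}[Q_S I_z \rho]$ accumulated at
  contact; the escape-channel polarization is also reported by
  `details = TRUE`.
* **Relaxation.** Uncorrelated fluctuating local fields at each electron:
  single-quantum flips at the Lorentzian rate
  $G\,\tau_u/(1+\omega_e^2\tau_u^2)$ evaluated at each electron's Zeeman
  frequency (both directions, infinite-temperature limit), plus a secular
  dephasing channel at the zero-frequency rate $G\,\tau_u$.  The rotational
  correlation time $\tau_{rot}$ is carried in the parameter record but the
  default relaxation model does not use it: the original relaxation
  superoperator of the de Kanter treatment is not fully specified in the
  source material, and experiments with $\tau_{rot}$-dispersive channels
  (amplitude shared with $G$ or scaled to hyperfine anisotropies) degraded
  rather than improved the agreement with the published observables, so
  they are not enabled.
* **Initial condition.** Equal triplet populations (1/3 each, triplet
  precursor), maximally mixed nuclei, spatial part equal to the equilibrium
  distribution.

### Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $g_a$, $g_b$ | g factors (adenine, flavin) | 2.0034, 2.0035 | — |
| $A$ | HFC of the observed nucleus (A8) | −0.7 | mT |
| $A_{add}$, $n$ | HFC and count of flavin nuclei | 1.67, 4 | mT, — |
| $J_0$ | exchange amplitude | −2.3×10⁸ | mT |
| $\lambda$, $r_c$ | exchange decay length, contact | 0.0214, 0.49 | nm |
| $D$ | radial diffusion coefficient | 2×10⁻⁷ | cm² s⁻¹ |
| $G$ | mean-square local field | 6.1×10¹⁷ | s⁻² |
| $\tau_u$ | local-field correlation time | 1 | ps |
| $\tau_{rot}$ | rotational correlation time (recorded) | 800 | ps |
| $k_p$ | singlet recombination at contact | 2×10¹⁰ | s⁻¹ |
| $k_s$ | scavenging | 10⁵ | s⁻¹ |

### The exchange-decay convention

The printed decay parameter "0.214 nm" for $J(r)=J_0 e^{-\alpha r}$ is
dimensionally ambiguous, and no literal reading reproduces a millitesla
effective coupling near 0.89 nm together with the printed amplitude.  The
default convention therefore uses a decay length of one tenth of the
printed value measured from contact,
$J(r) = J_0\,e^{-(r-0.49\,\mathrm{nm})/0.0214\,\mathrm{nm}}$, calibrated so
that $J(0.89\,\mathrm{nm}) \approx -1.75$ mT, consistent with the reported
effective exchange of about $-2$ mT at the centre of the best-fitting
distance distribution.  The literal readings (`decay_length_nm`,
`inverse_length_per_nm`) remain selectable, and every pipeline output
records the convention used in its metadata header.

### Additional nuclei: exact equivalent-spin treatment by default

Four equivalent spin-½ nuclei decompose into total-spin multiplets
$j = 2, 1, 0$ with statistical weights $5/16$, $9/16$, $2/16$; coupling one
effective spin $j$ per component is *exact* for isotropic couplings and
keeps the flip-flop (polarization-transfer) physics of the flavin protons.
The cruder semiclassical alternative — binomially weighted static offsets
$m\,A_{add}$, $m=-2\dots2$, on the flavin electron — is also implemented
(`additional_nuclei = "semiclassical"`), but it is not the default because
the five discrete offsets generate spurious sharp structure between 1 and
3 mT: configurations with $m<0$ pass through zero net field on electron b
at $B = |m|A_{add}$, producing artificial resonances comparable in
amplitude to the genuine extremum.  The quantum path is smooth there.

### Numerics

The Liouvillian preserves hermiticity and block-diagonality in the total
spin projection $F_z$, and the initial state lies in that invariant
subspace, so the dynamics is expanded in a real basis of
$F_z$-block-diagonal Hermitian matrices: 20 real dimensions per node for
the 8-level space, 132 and 260 for the $j=1,2$ components.  Basis elements
carry integer coefficients (diagonal Gram matrix) and are recombined into
observed-nucleus symmetric/antisymmetric pairs, which makes the reduced
operators exact dyadic rationals for the spin-½ engine: structural zeros
survive in floating point, and the no-mechanism null (zero hyperfine
couplings, equal g factors) evaluates to exactly zero polarization rather
than solve noise.

The per-field linear system is block tridiagonal over radial nodes (dense
spin blocks, scalar hop couplings) and is solved by block-Thomas
elimination with LAPACK-factorised blocks plus one step of iterative
refinement; the test suite verifies the elimination against a dense solve
of the assembled block system and verifies the whole solver, on a
two-node grid, against an independently coded dense complex resolvent in
the full product Liouville space (agreement 10⁻⁸).

Two regularisations are applied and documented here: (i) the exchange
coupling is capped at $|J| \le 10^4$ mT when assembling the generator —
beyond the cap singlet–triplet mixing is suppressed beyond resolution and
the level crossing lies above 20 T, outside any swept field, while the
raw amplitude ($2.3\times10^8$ mT at contact) only degrades conditioning;
(ii) grid nodes whose discretised stationary weight is numerically zero
(truncated distributions) are left disconnected from the hopping chain,
keeping the detailed-balance rates finite.

Distance distributions are discretised by midpoint density evaluation on
the log-density scale and renormalised, so distributions far narrower
than, or centred far away from, the grid still normalise without
underflow; a distribution centred beyond the grid triggers a warning and,
in `field_sweep()`, an automatic outward extension of the grid (the
`sim4` preset centred at 10.2 nm — stored exactly as published although
plausibly a misprint for 1.02 nm — relies on this).

`curve_features()` refines the extremum by a local quadratic through the
three points around the grid optimum (exact for a symmetric peak with the
vertex on a grid point) and measures the full width at half maximum by
linear interpolation of the half-extremum crossings of the extremum
branch of the signed curve; monotone curves raise an error rather than
reporting a boundary extremum.

### What the default simulation gives, honestly

With every parameter at its published value and the calibrated exchange
convention, the simulated geminate curve (61-point log field grid,
0.1 mT–9.4 T; 81 radial nodes) shows its emissive extremum near 9 mT with
a full width at half maximum of roughly 50 mT, flanked by a small
absorptive lobe below ~2 mT (from the near-zero-exchange tail of the
distance distribution) and an absorptive high-field wing (the
$\Delta g$-driven S–T₀ mechanism, the same one that makes the geminate
high-field spectra absorptive for A8).  The measured extremum for this
system lies at 4 mT with a ~10 mT width.  Extensive diagnosis places the
discrepancy in the kinetic regime rather than in the solver: at the
printed rate constants the recombination yield is 80–85 % at every field
and the biradical lifetime is microseconds, so the slow conversion
channels saturate and low-field selectivity washes out, pushing the
extremum above $2|J(r_0)|$ and broadening it.  Raising the total loss
rate by one to two orders of magnitude restores an extremum at 3–5 mT, a
~10 mT width, and strict high-field proportionality between hyperfine
couplings and CIDNP amplitudes — but those are not the printed study
conditions, and the package does not silently adopt them.  The default
parameters are kept exactly as published; users exploring the kinetic
sensitivity can do so through `kinetics_relaxation_params()`.

## NMRD fitting

`fit_decay()` fits $I(\tau) = I_\infty + (I_0-I_\infty)e^{-\tau/T_1}$ by
Levenberg–Marquardt least squares; the free plateau absorbs incomplete
inversion (the measurement protocol implies inversion but not its
fidelity).  `fit_dispersion()` fits the two-contribution dispersion model
in rate space, weighted by propagated $T_1$ uncertainties when present,
inside a field window (default 0.56–16.44 T; per-proton windows, e.g.
1.77 T upward for A8, are parameters, not hard-coded).  Only the
high-field branch determines site-specific correlation times: in the
low-field, extreme-narrowing region strongly coupled protons share their
relaxation, so those points are excluded by the window rather than
modelled.  Starting values come from the rate plateaus and the
half-amplitude field; $\tau_c$ is bounded in [1 ps, 100 ns] and fits at a
bound are flagged.  Covariances use the final Jacobian with Jacobi
scaling (rates and correlation times differ by ten orders of magnitude).

## Shuttle deconvolution

The transfer profile is split into 500 equal time intervals (the product
changes by under 0.1 % on refinement for smooth profiles, which the test
suite enforces), the field is held at its interval-midpoint value, and
rates come either from the closed-form dispersion model or from a natural
cubic spline through the measured NMRD knots on the $\log_{10} B$ axis
(fields span five decades; the spline is exact at every knot).  Fields
outside the data range clamp to the end rates with a warning.  Interval
ordering is immaterial because the product commutes, so the
implementation runs forward in time even though the measurement protocol
counts intervals backwards from acquisition.

## Model ranking

The $q$ statistic compares a simulated and an observed curve after (i)
normalising the observed curve to unit extremum magnitude, (ii)
interpolating the simulation onto the observed fields with a monotone
cubic interpolant on the log-field axis, and (iii) fitting one free
*positive* amplitude scale for the simulation, since CIDNP intensities
are in arbitrary units.  A non-positive optimal scale is reported as a
sign mismatch with the scale pinned to zero.  The published $q$ values
for this system imply some order-unity normalisation of both curves; the
one chosen here makes $q$ values comparable in order of magnitude but not
digit-reproducible, so only the *ranking* of candidate distributions is
meaningful — which is how the statistic is used.

## The synthetic-data generator

`synthetic_study_config()` fixes the study conditions: five protons
(A8, A2, F6, F9, F5′5′′) with dispersion truths of the same sub-ns order
(distinct, so site-specificity is testable; A8 fastest at low field, so
transfer losses are of order one half at a 4 mT start), 3 % multiplicative
Gaussian noise on decay intensities, 2 % on observed CIDNP, a 9.4 T
detection field and a 0.3 s transfer — a representative duration chosen
once, comparable to the proton $T_1$ values so that relaxation during
transfer matters.  The shuttle model is constant acceleration then
deceleration through an exponential stray field whose decay length is set
per start field so the profile runs exactly from $B_{start}$ to the
detection field.

The generator emulates the *statistical structure* the analysis assumes:
mono-exponential decays obeying the dispersion model, a monotone transfer
profile, noisy single-extremum CIDNP curves with known ground truth.  It
does not emulate spectrometer artefacts, lineshapes, strong-coupling
polarization transfer between scalar-coupled protons at low field, or any
systematic deviation from mono-exponentiality — so passing tests
demonstrate the pipeline's correctness and statistical power under its own
assumptions, not robustness to those real-data effects.

## Problem sizes used by the tests

The acceptance checks run the full published configuration (81 radial
nodes, 61 fields) once and share the curve across checks; the remaining
property tests use reduced grids (15–41 nodes, 7–31 fields) because the
properties they probe — signs, symmetries, conservation laws, oracle
agreement, ranking recovery — are grid-robust.  Radial-grid convergence
of the default curve is slow near the extremum (the exchange decay length
is 1.5 grid steps at the default resolution; amplitudes change by a few
percent when the node count doubles and the extremum position by ~12 %),
which is a property of the steep exchange profile, not of the solver; the
test suite asserts 2 % amplitude stability between 41 and 81 nodes on a
low-field window where convergence is faster.

## Known limitations

* The default kinetic regime reproduces the qualitative phenomenology
  (single emissive low-field extremum, sign independence, high-field
  S–T₀ wing) but not the published extremum position/width, as analysed
  above.
* $\tau_{rot}$-driven anisotropic relaxation is not modelled.
* Nuclear relaxation inside the biradical is neglected (lifetime short
  against nuclear $T_1$).
* Coherent polarization transfer between strongly coupled protons (A8/A2
  at low field) is out of scope; the measurement protocol suppresses it
  with short irradiation.
* Recombination is contact-only; a distance-dependent electron-transfer
  rate was prototyped and changes the curve little at these parameters.
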