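# cidnpr

Spin-chemistry tools for analysing **chemically induced dynamic nuclear
polarization (CIDNP)** formed in short-lived flexible biradicals, with the
light-induced flavin–adenine biradical of FAD as the motivating system.
The package is aimed at magnetic-resonance spectroscopists who measure
CIDNP field dependences and proton relaxation dispersion (NMRD) with
field-cycling / sample-shuttling NMR, and who want to interpret those data
through a quantitative radical-pair model.

## What it computes

**1. CIDNP field dependence of a flexible biradical.**
The core is a distance-resolved stochastic Liouville equation (SLE) of the
de Kanter type.  The biradical carries two electron spins (g factors
*g*<sub>a</sub>, *g*<sub>b</sub>), the observed spin-½ nucleus with isotropic
hyperfine coupling *A* on radical a, and *n* additional equivalent spin-½
nuclei with coupling *A*<sub>add</sub> on radical b.  At inter-radical
distance *r* the exchange interaction

&nbsp;&nbsp;&nbsp;&nbsp;*J*(*r*) = *J*₀ · e<sup>−(*r* − *r*<sub>c</sub>)/λ</sup>

splits singlet and triplet states through
*H*<sub>ex</sub> = −*J*(½ + 2 **S**<sub>a</sub>·**S**<sub>b</sub>), so for
*J* < 0 the S/T₋ levels cross at a field *B* ≈ 2|*J*| and nonsecular
hyperfine terms convert the crossing into a level anti-crossing (LAC) —
the origin of the low-field emissive CIDNP extremum.  The distance
coordinate diffuses over a prescribed end-to-end distance distribution
(discrete Smoluchowski generator with detailed balance), electron spin
relaxation enters through fluctuating local fields with Lorentzian spectral
density *G*·τ<sub>u</sub>/(1 + ω²τ<sub>u</sub>²), singlet pairs recombine at
contact with rate *k*<sub>p</sub>, and all pairs are scavenged at rate
*k*<sub>s</sub>.  The time-integrated nuclear polarization of the geminate
product is obtained from a single resolvent solve per field.  The four
equivalent flavin nuclei are treated exactly via the equivalent-spin
decomposition (total spin *j* = 2, 1, 0 with weights 5/16, 9/16, 2/16); a
semiclassical static-offset treatment is available as an option.

**2. Site-specific NMRD fitting.**
Longitudinal relaxation rates follow the two-contribution dispersion model

&nbsp;&nbsp;&nbsp;&nbsp;1/*T*₁(*B*) = *R*₁ / (1 + (γ<sub>H</sub>*B*τ<sub>c</sub>)²) + *R*₁<sup>∞</sup>,

fitted per proton in rate space from inversion-recovery decay series
(mono-exponential fits with free plateau) inside a configurable high-field
window.

**3. Shuttle-transfer deconvolution.**
Polarization generated at a low field decays while the sample is shuttled
to the detection field.  Given the transfer field–time profile and the
proton's NMRD curve (cubic spline on the log-field axis), the true
intensity is reconstructed as
*P*<sub>true</sub> = *P*<sub>obs</sub> · ∏<sub>n</sub> exp(*R*<sub>n</sub>Δ*t*<sub>n</sub>)
over 500 constant-field intervals.

**4. Model comparison.**
Candidate end-to-end distance distributions (normal, left-half normal,
truncated normal presets `sim1`–`sim4`) are simulated and ranked against an
observed curve with the *q* statistic — the sum of squared deviations after
amplitude normalisation.

**5. Synthetic data.**
Generators for decay series, transfer profiles (constant-acceleration
motion through an exponential stray field) and noisy observed CIDNP curves
emulate the experiment so the entire pipeline is testable end to end.

## Worked example

```r
library(cidnpr)

# simulate the CIDNP field dependence for the default (published) model:
# Table of parameters = FAD biradical; sim1 = normal(0.89 nm, 0.15 nm)
model <- biradical_model()
curve <- field_sweep(log_field_grid(1e-3, 0.1, 21), model = model)
curve_features(curve, branch = "emissive")
#> <curve_features> emissive extremum at 8.962 mT, amplitude -0.008986,
#>   FWHM 52.91 mT (1 interior extrema)
```

The emissive extremum sits near 2|J(r)| for distances in the core of the
distance distribution; its position and width summarise the effective
exchange interaction (see the methods vignette for why this model places
it near 9 mT and what controls that).

```r
# synthetic NMRD stage: generate decays, fit T1 per field, fit the dispersion
cfg <- synthetic_study_config()        # 3 % decay noise, A8/A2/F6/F9/F5p truths
decays <- gen_nmrd_decays(cfg, fields = 10^seq(log10(0.56), log10(16.44),
                                               length.out = 10))
nmrd <- fit_decay_table(decays)
fit <- fit_dispersion(dplyr::filter(nmrd, proton == "A8"))
fit
#> <nmrd_fit> A8: R1 = 4.005 /s, R1inf = 0.5003 /s, tau_c = 0.9165 ns
#>   (n = 10, window 0.56-16.4 T)
tidy(fit)
#> # A tibble: 3 x 3
#>   term  estimate std.error
#> 1 R1    4.01e+ 0  8.84e- 2
#> 2 R1inf 5.00e- 1  3.06e- 2
#> 3 tau_c 9.17e-10  3.69e-11
```

The recovered correlation time (0.92 ns vs the 0.9 ns ground truth)
identifies the motional regime of that proton; coincident τ<sub>c</sub>
values across protons indicate a rigid molecule.

`run_pipeline()` chains all stages — synthesise, fit, deconvolve,
simulate, rank — into one seeded, manifest-writing run, and
`inst/cli/cidnp` exposes the same stages as shell subcommands
(`simulate-cidnp`, `fit-nmrd`, `deconvolve`, `compare`, `synth`,
`run-all`).

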