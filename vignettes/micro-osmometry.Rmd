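---
title: "Micro-osmometry of tissue swelling pressure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-osmometry of tissue swelling pressure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmoflux)
```

## The measurement problem

The nucleus pulposus (NP) of the intervertebral disc is a proteoglycan-rich
gel whose fixed negative charges draw in counter-ions and water, generating a
swelling pressure that carries a large share of spinal load. Measuring that
pressure *inside* a piece of tissue, rather than inferring it from bulk
compression tests, is the problem this package addresses. The instrument is a
needle micro-osmometer: a microdialysis probe filled with 0.15 mol/L NaCl is
inserted into the tissue, and the tissue's excess osmotic potential draws
water out of the probe. The water/air meniscus in the attached tubing is
photographed at one-minute intervals; the displacement rate, multiplied by
the tubing cross-section, is the volumetric flux `q`. Everything downstream
of that displacement series is computation, and that computation is what
this package implements and tests.

## The radial Darcy model

Flow from the probe into the tissue is modelled as steady radial Darcy flow
through two concentric annuli: the probe membrane (inner radius $r_1$, outer
radius $r_2$, length $L$) and the perfused tissue shell ($r_2$ to $r_3$).
For a pressure difference $\Delta\pi = \pi_{tissue} - \pi_{probe}$,

$$ q = \frac{2\pi L\, K_{total}}{\ln(r_3/r_1)}\,\Delta\pi, $$

where $K_{total}$ is the log-weighted harmonic (series-resistance)
combination of the membrane and tissue hydraulic permeabilities:

$$ K_{total} = \frac{\ln(r_3/r_1)}
   {\ln(r_2/r_1)/K_{mem} + \ln(r_3/r_2)/K_{tissue}}. $$

Three modelling commitments are made here, each with a tested consequence:

* **Hydrostatic gradients are dropped.** Transducer measurements put the
  hydrostatic term three orders of magnitude below the osmotic one; the
  inference sets it to zero. A `hydrostatic_offset` argument exists for
  transducer-paired use but defaults to 0.
* **A single hydraulic permeability convention.** All permeabilities are
  $K \equiv k/\mu$ in m$^4$ N$^{-1}$ s$^{-1}$, with the viscosity of
  0.15 mol/L NaCl absorbed. This makes the membrane calibration, the tissue
  permeability law and the harmonic average dimensionally commensurate;
  viscosity never reappears downstream. (The `viscosity` constant exists
  only to convert a user-supplied intrinsic permeability in m$^2$.)
* **The perfusion radius comes from a volume balance.** Over the 5-minute
  measurement the perfused fluid is assumed to occupy a cylindrical shell
  equal to its own volume: $\pi L (r_3^2 - r_2^2) = q\,t$. The closed-form
  pressure drop through both annuli is verified in the test suite against
  numerical integration of $dP/dr = q/(2\pi r L K(r))$ to $10^{-9}$
  relative tolerance over randomized geometries.

Tissue permeability depends on compaction. The package uses an empirical
confined-compression law for bovine NP,

$$ K_{tissue}(\lambda) = 1.59\times10^{-15}
   \left(\frac{\lambda - 0.2}{0.8}\right)^{1.13}
   e^{-0.02(\lambda^2 - 1)^2}, $$

evaluated at the *radial* stretch ratio $\lambda = (m_f/m_0)^{1/3}$ — the
ratio of equivalent spherical radii at post-equilibration versus
post-excision wet mass, at tissue density 1000 kg/m$^3$. Because dialysis
loads the tissue isotropically rather than uniaxially, substituting the
radial stretch into a 1D law is an approximation, adopted deliberately and
without a 3D correction. Below $\lambda = 0.2$ the law predicts pore
closure; the package raises an error there rather than clamping, since any
inferred pressure would be meaningless.

Membrane permeability is measured, not assumed: each probe is calibrated in
polyethylene glycol (PEG) baths of known osmotic pressure, where the whole
pressure drop acts across the membrane alone and the Darcy law inverts
directly. Because membrane permeability itself falls with osmotic load,
calibrations are keyed by (probe, pressure), with a nearest-pressure
fallback that warns. A robust (MAD-based) outlier flag marks torn or
defective membranes without excluding them automatically.

## The Gibbs-Donnan side

Independently of flux, the ionic component of swelling is computed from
intra-tissue sodium measured by ICP-OES. Sodium mass per digested sample is
normalized to total tissue water (TTW) volume — wet minus dry mass at water
density — giving $c_{Na}$ in mol/L. Donnan equilibrium with a 0.15 mol/L
bath then fixes everything else:

* ion product: $c_{Na}\,c_{Cl} = c_{ext}^2$, so $c_{Cl} = c_{ext}^2/c_{Na}$;
* electroneutrality: fixed charge density $c_f = c_{Na} - c_{Cl}$;
* ionic swelling pressure:
  $\Delta\pi_{ion} = \phi R T\left(\sqrt{c_f^2 + 4c_{ext}^2} - 2c_{ext}\right)$;
* osmolality: $\phi\,(c_{Na} + c_{Cl}) \times 1000$ mOsm/kg H$_2$O.

The osmotic coefficient $\phi = 0.93$ is applied to both tissue and bath
ions. Two unit identifications are used throughout and stated here rather
than buried: mEq/g TTW is treated as numerically equal to mol/L of TTW for
a monovalent ion at water density, and mol/m$^3$ is identified with
mOsm/kg H$_2$O for dilute aqueous solutions. A sodium reading below the
bath concentration would imply negative fixed charge; the package warns and
flags such samples instead of erroring, so noisy cohorts survive.

The *Donnan fraction* — the share of the flux-based swelling explained by
ions alone, `(osm_ion - 279)/(osm_flux - 279)` above the 279 mOsm/kg bath
baseline — is the package's summary of how much swelling is non-ionic. An
experimental `water_fraction` argument renormalizes concentrations to an
extrafibrillar-water basis; it is off by default because no validated
fraction is shipped.

## The synthetic cohort generator

No deposited data accompany the method, so the package ships a forward
simulator that is first-class, tested code. Its defaults emulate the
validation experiment: five applied pressures (0.03, 0.10, 0.21, 0.37,
0.57 MPa, the 5–25% g/mL PEG series), five samples per pressure, 5-minute
flux measurements with six meniscus frames.

The generating truth ties swelling pressure to applied pressure exactly
($\Delta\pi = P$, the equilibrium the method validates), so the true
concordance is 1 and any shortfall in recovered concordance measures
pipeline noise. Osmolality follows as $279 + P/RT$; sodium is backed out
through the Donnan product; hydration falls linearly in pressure through
the endpoints 4.96 g/g at 0.03 MPa and 1.64 g/g at 0.57 MPa. The forward
flux problem is implicit — the perfusion radius depends on the flux and
vice versa — and is solved by bracketed root finding between zero and the
membrane-only flux, to $10^{-12}$ relative tolerance. The noise-free
simulate-then-infer round trip is the generator's central contract and is
tested to $10^{-9}$ relative.

Defaults that the experiment's description does not pin down were chosen
once, on physical grounds:

* **Noise**: multiplicative lognormal with relative SD 5% on each flux
  reading, 8% on sodium, 1% on masses, and 10% probe-to-probe scatter in
  membrane permeability. The published data report only group SDs, so this
  is a stand-in noise model, not an estimate of the true variance
  decomposition; the three knobs are exposed rather than fixed to a split.
* **Membrane permeability scale**: $10^{-17}$ m$^4$ N$^{-1}$ s$^{-1}$ at
  the lowest pressure, declining as $P^{-1/4}$. This reproduces the two
  observable scales the experiment reports: millimetre-scale meniscus
  travel over 5 minutes and a perfused volume a fraction of a percent of
  TTW (about 0.25% on average in the default cohort, always below 1%).
* **Excision hydration 5.4 g/g**: places the radial stretch above 0.9 for
  pressures below 0.2 MPa, matching the observed compaction pattern, with
  excision wet masses near 0.2 g at a 35 mg dry mass.
* **PEG virial coefficients**: not published. The shipped default is a
  cubic fitted once to the nominal concentration–pressure design pairs; it
  is documented as non-authoritative, and calibration records can carry
  applied pressures directly to bypass it.

What the simulator does *not* emulate: transient osmotic kinetics (tissue
and probe are assumed at equilibrium), spatial heterogeneity within a
tissue piece, degeneration-dependent composition, or any correlation
between flux, sodium and mass errors. Passing recovery tests therefore
demonstrates that the inference chain is self-consistent and
noise-tolerant under this noise model — not that the instrument model is
correct for real tissue.

## The statistical layer

`summarize_groups()` produces the per-pressure mean ± SD table, including
the osmolality change from the 0.21 MPa reference group (computed
per-sample against the reference group mean, then averaged). `ols_fit()`
wraps `stats::lm` for the linear and quadratic fits; `spearman_rho()`
wraps `stats::cor(method = "spearman")`. Lin's concordance correlation
coefficient is implemented directly from its definition with population
(1/n) moments,

$$ \rho_c = \frac{2\,\mathrm{cov}(x,y)}
   {\mathrm{var}(x) + \mathrm{var}(y) + (\bar{x} - \bar{y})^2}, $$

a choice that matters at the small n typical here and is cross-checked in
the tests against the independent $\rho_c = r \cdot C_b$ factorization.
The diurnal extrapolation evaluates the osmolality-versus-pressure line at
0.2 and 0.6 MPa, the pressures conventionally used to simulate the diurnal
loading cycle. The regression defaults to per-sample data with a
`group_means` option; published comparisons use group means because only
those are printed. ANOVA lettering is out of scope: it needs the
unpublished per-sample data to verify, and base R's `aov` covers the need.

Degenerate inputs are handled by convention, not silently: a constant
response gives $R^2 = 0$; a constant vector makes Spearman and Lin's
coefficients an error; singleton groups report SD 0 with a flag.

## Worked example

```{r example}
coh <- simulate_cohort(sim_config(seed = 42))
fit <- osmoflux(coh$flux, coh$calibration, coh$icp)
summary(fit)
```

The per-sample table is in `fit$samples`; `predict(fit)` evaluates the
osmolality line at 0.2 and 0.6 MPa; `residuals(fit, "concordance")` gives
the per-sample gap between inferred and applied pressure; `simulate(fit)`
re-simulates cohorts at the fitted design for power exploration.

## Numerical choices and limitations

Problem sizes are small everywhere — 25 samples, 6-frame series, five-point
fits — so the default test suite and examples run in seconds. Root finding
and integration tolerances ($10^{-12}$ forward solve, $10^{-9}$ round-trip
assertions) sit well inside measurement noise. Table comparisons round half
away from zero (`round_half_up()`), matching how the published tables were
typeset; note that a value derived from a group-mean sodium is a function
of a mean, not a mean of per-sample functions, so such comparisons carry a
few percent of irreducible slack for the nonlinear quantities (FCD
especially).

Known limitations, inherited from the model rather than the code: the 1D
permeability law under radial stretch; the cylindrical, volume-equal
perfusion region; equilibrium-only interpretation (real diurnal loading
does not reach equilibrium, so equilibrium bounds overestimate the daily
osmotic cycle); and TTW normalization, which understates Donnan swelling
wherever intrafibrillar water is osmotically unavailable.
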