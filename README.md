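# osmoflux

Needle micro-osmometry for cartilaginous tissue: infer intra-tissue
swelling pressure and osmolality from microdialysis-probe fluid flux, and
independently compute the ionic (Gibbs-Donnan) component from measured
intra-tissue sodium.

## The problem and who this is for

The nucleus pulposus of the intervertebral disc — and charged hydrated
tissues generally — swells against applied load because its fixed negative
charges (proteoglycans) hold an excess of mobile ions and water. The
swelling pressure and osmolality inside a piece of tissue set the osmotic
environment its cells experience, yet they are hard to measure *in situ*.
This package implements the computational side of a minimally invasive
measurement: a microdialysis probe filled with 0.15 mol/L NaCl is inserted
into tissue, the tissue's osmotic potential draws water across the probe
membrane, and the meniscus displacement in the attached tubing is tracked
over 5 minutes. It is aimed at tissue biomechanics labs running such
measurements (or planning them via simulation).

## The model

Flux and swelling pressure are related by radial Darcy flow through the
membrane annulus (r1, r2) and the perfused tissue shell (r2, r3):

    q = 2 pi L K_total / ln(r3/r1) * (pi_tissue - pi_probe)

with the series (log-weighted harmonic) permeability

    K_total = ln(r3/r1) / [ ln(r2/r1)/K_mem + ln(r3/r2)/K_tissue ]

K_mem comes from per-probe calibration in PEG baths of known osmotic
pressure; K_tissue from a strain-dependent law
`1.59e-15 ((lambda-0.2)/0.8)^1.13 exp(-0.02 (lambda^2-1)^2)` evaluated at
the radial stretch `lambda = (mf/m0)^(1/3)`; and r3 from the volume
balance `pi L (r3^2 - r2^2) = q t`. Osmolality follows as
`(delta_pi + pi_bath)/RT`, with the 0.15 mol/L NaCl bath at 279 mOsm/kg
H2O (phi = 0.93).

Independently, ICP-OES sodium normalized to total tissue water gives the
ionic state via Gibbs-Donnan equilibrium: chloride `c_ext^2/c_Na`, fixed
charge density `c_Na - c_ext^2/c_Na`, ionic swelling pressure
`phi RT (sqrt(cf^2 + 4 c_ext^2) - 2 c_ext)`. Comparing the two routes
quantifies the non-ionic share of swelling.

## Worked example

No deposited dataset accompanies the method, so the package ships a
forward simulator emulating the validation design (five pressures
0.03–0.57 MPa, five samples each, measurement noise on flux, sodium and
masses):

```r
library(osmoflux)
coh <- simulate_cohort(sim_config(seed = 42))
fit <- osmoflux(coh$flux, coh$calibration, coh$icp)
summary(fit)
```

```
Group summary (mean across samples):
 P (MPa) n hydration Na+ (mol/L) ions (mol/L) FCD (mEq/g) osm ICP osm flux
    0.03 5      4.96        0.20         0.32        0.09     294      291
    0.10 5      4.53        0.26         0.35        0.17     321      319
    0.21 5      3.85        0.33         0.40        0.27     373      365
    0.37 5      2.87        0.40         0.46        0.35     427      430
    0.57 5      1.64        0.50         0.54        0.45     504      507

Osmolality vs pressure: intercept 279.7, slope 400.9 mOsm/(kg MPa), R^2 = 0.999
Concordance applied vs inferred pressure: rho_c = 1.000
Diurnal bounds (0.2-0.6 MPa): 360 to 520 mOsm/kg (magnitude 160)
Donnan fraction trend vs pressure: Spearman rho = -0.05
```

Reading the output: each row is a pressure group; `osm flux` is the
osmolality inferred from probe flux and `osm ICP` the independent
Gibbs-Donnan value from sodium (in this simulation the generating truth
ties swelling pressure exactly to applied pressure, so the two routes
agree and the concordance rho_c is 1 up to noise). The diurnal bounds
evaluate the fitted osmolality line at 0.2 and 0.6 MPa, the pressures
conventionally used to simulate daily spinal loading —
`predict(fit)` returns the same two numbers (360 and 520 mOsm/kg here).
`fit$samples` holds the per-sample table (flux, stretch, permeabilities,
swelling pressure, Donnan state); `plot(fit)` draws the concordance and
osmolality panels.

A thin CLI over the same functions lives at `inst/cli/osmoflux.R`
(subcommands `simulate`, `calibrate`, `infer`, `donnan`, `report`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/osmoflux.R", package="osmoflux"))')" \
  simulate --out-dir fixtures --seed 5
```

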