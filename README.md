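# echbend

Strong bending of semiflexible polymers — double-stranded DNA in
particular — with the **energy convex hull (ECH)** model: convex-hull
analysis of per-site bending-energy profiles, loop energies and DNA
cyclization j-factors beyond the worm-like chain, and coarse-grained
Monte-Carlo simulators that test the theory's structural predictions.
It is written for biophysicists and structural bioinformaticians who work
with DNA looping, cyclization experiments, or protein–DNA complexes.

## The science

Slightly bent DNA behaves as an elastic rod: the worm-like chain (WLC)
assigns each bending site the harmonic energy
`E(θ) = ½ Lp θ²` (kT, θ in radians, persistence length `Lp ≈ 150` bp).
But the *effective* per-base-pair bending energy inferred from thousands
of experimental protein–DNA complex structures,

```
E(θ) = 203.1 θ² − 552.7 θ³ + 416.8 θ⁴   (kT),
```

is **non-convex**. Minimising total bending energy under a constraint on
the average bend θ̄ then phase-separates the chain, exactly as a
double-tangent construction in thermodynamics: below the hull onset angle
θ_a bending is uniform and harmonic; between the two tangency angles
θ_a < θ_b the chain mixes weakly bent sites (θ_a) with localized kinks
(θ_b), the strong fraction growing linearly via the lever rule
`p = (θ̄ − θ_a)/(θ_b − θ_a)`, and the per-site energy follows the straight
hull line `Lp θ_a (θ̄ − θ_a/2)`. For the DNA profile above the tangency
solve gives θ_a = 2.2°, θ_b = 35.8°.

For a closed L-bp loop (θ̄ = 2π/L) the ECH loop energy
`Lp θ_a (2π − L θ_a/2)` approaches a constant for small loops instead of
the WLC's `2π² Lp / L` divergence. Fed into the Shimada–Yamakawa
j-factor,

```
j(L) = k Lp⁻³ (Lp/L)⁵ exp(−E_loop/kT + L/(4Lp)),
```

this predicts strong-bending cyclization probabilities orders of
magnitude above the WLC, and — counter-intuitively — a *minimum* of the
j-factor envelope at `L* = 5 / (1/(4Lp) + Lp θ_a²/2) ≈ 45` bp, below
which cyclization becomes easier again.

The package also ships two bead-per-base-pair Metropolis simulators that
verify the structural claims: closed loops (bimodal bend-angle
distributions with peaks at θ_a and θ_b; annealed minimum-energy rings
tracking the hull line) and an electrostatically confined open chain (a
toy protein–DNA complex showing the crossover from hull-following at
weak confinement to profile-following at strong confinement).

## Worked example

```r
library(echbend)

profile <- dna_quartic_profile()
(hull <- find_double_tangent(profile))
#> <hull_result>
#>   theta_a = 0.038150 rad (2.19 deg), E_a = 0.2658 kT
#>   theta_b = 0.624878 rad (35.80 deg), E_b = 7.9964 kT
#>   common slope lambda = 13.1759 kT/rad

theta_a <- 2.2 * pi / 180          # hull onset at reported precision
loop_energy(50, "ech", Lp = 150, theta_a = theta_a)
#> [1] 30.65974
loop_energy(50, "wlc", Lp = 150)
#> [1] 59.2176

envelope_minimum(150, theta_a)
#> [1] 44.54629

jfactor_ratio(40, 50, "ech", Lp = 150, theta_a = theta_a)
#> [1] 0.9933123
jfactor_ratio(40, 50, "wlc", Lp = 150)
#> [1] 1.116451e-06
```

Read: closing a 50-bp DNA circle costs ~31 kT in the ECH model versus
~59 kT for the WLC; the ECH j-factor envelope bottoms out near 45 bp; and
shortening a loop from 50 to 40 bp barely changes the ECH cyclization
probability (ratio 0.993) while the WLC predicts a million-fold drop —
the discriminating experimental signature of the two models.

Simulation example (closed 60-bp loop, two-state kinking):

```r
ens <- mc_sample(build_regular_loop(60), profile, sweeps = 2e4, seed = 1)
histogram_modes(ens)$modes_deg     # two peaks, near 2.2 and 35.8 degrees
anneal_loop(build_regular_loop(60), profile, seed = 1)$energy_per_site
# ~1.16 kT/bp, on the hull line; uniform bending would cost 1.64 kT/bp
```

A command-line interface is installed as `exec/echbend` with subcommands
`hull`, `loop-energy`, `jfactor`, `ratio`, `fit-k`, `simulate-loop`,
`minimize-loop`, `simulate-confined`, and `fixtures`; angles are degrees
at the CLI, tables are TSV, trajectories standard multi-frame XYZ.

## Package layout

- `R/profiles.R` — bending-energy profiles (quartic / harmonic WLC /
  tabulated) with exact derivatives
- `R/hull.R` — double-tangent detection, hull-line energy, lever rule,
  ECH piecewise energy, constrained minimisation
- `R/cyclization.R` — loop energies, j-factors, ratios, envelope
  minimum, prefactor calibration
- `R/loop_sim.R`, `R/confinement.R`, `src/kernels.cpp` — Monte-Carlo
  samplers and FIRE minimiser (Rcpp)
- `R/io.R` — profile tables, XYZ trajectories, run configs, synthetic
  fixture generator
- `vignettes/ech-model.Rmd` — the model, its assumptions, numerical
  choices and limitations
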