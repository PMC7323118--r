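---
title: "The energy convex hull model of strong polymer bending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The energy convex hull model of strong polymer bending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echbend)
```

## The model

A semiflexible polymer is described as a chain of $N$ identical inextensible
segments with an effective bending energy $E(\theta_i)$ per bending site,
where $\theta_i$ is the angle between successive segment directions
($\theta = 0$ straight, radians; energies in $k_BT$ at 300 K).  The classical
worm-like chain (WLC) takes $E(\theta) = \tfrac12 L_p \theta^2$ with the
persistence length $L_p$ expressed dimensionlessly in bending sites
($L_p = 150$ bp for double-stranded DNA).

For DNA, the effective per-base-pair bending energy inferred from the
distribution of bend angles in a large set of protein–DNA complex
structures is well approximated by the quartic
$$E(\theta) = 203.1\,\theta^2 - 552.7\,\theta^3 + 416.8\,\theta^4
\quad (k_BT),$$
available as `dna_quartic_profile()`.  Unlike the harmonic WLC energy, this
profile has a *non-convex* region.  Minimising the total bending energy
$\sum_i E(\theta_i)$ under a constraint on the total bend
$\sum_i \theta_i = N\bar\theta$ then behaves exactly like a phase
coexistence problem: wherever $E$ is non-convex there is a common-tangent
(double-tangent) line touching the profile at two angles
$\theta_a < \theta_b$ and lying below it in between — the lower convex hull
of $E$.  For average bends inside $(\theta_a, \theta_b)$ the minimum-energy
chain splits into two coexisting populations, weakly bent sites at
$\theta_a$ and strongly bent ("kinked") sites at $\theta_b$, with the
strong fraction given by the lever rule
$p = (\bar\theta - \theta_a)/(\theta_b - \theta_a)$, and the per-site
energy follows the straight hull line.  The energy convex hull (ECH) model
is the resulting piecewise law: harmonic
$\tfrac12 L_p \bar\theta^2$ for $\bar\theta \le \theta_a$, linear
$L_p \theta_a (\bar\theta - \theta_a/2)$ for
$\theta_a < \bar\theta < \theta_b$, continuous with continuous slope at
$\theta_a$.  The regime $\bar\theta \ge \theta_b$ (loops shorter than
about 10 bp for DNA) is excluded from the model's validity and rejected by
the code.

For a closed loop of $L$ sites the closure constraint gives
$\bar\theta = 2\pi/L$, so
$$E_{loop}(L) = \begin{cases}
2\pi^2 L_p / L, & L \ge 2\pi/\theta_a \quad\text{(WLC)}\\
L_p \theta_a\,(2\pi - L\theta_a/2), & 2\pi/\theta_b < L < 2\pi/\theta_a
\quad\text{(ECH)}
\end{cases}$$
The ECH branch approaches a constant as $L \to 0$ instead of diverging —
the origin of every qualitative difference from the WLC below.

Cyclization is quantified by the Jacobson–Stockmayer $j$-factor through
the Shimada–Yamakawa closed form
$$j(L) = k\, L_p^{-3} (L_p/L)^5
\exp\!\left(-E_{loop}/k_BT + L/(4 L_p)\right),$$
with a prefactor $k$ subsuming the closure geometry (calibrated from data
by `fit_k()`, otherwise relative units).  With the ECH loop energy the
envelope of $j(L)$ has a minimum at
$$L^* = \frac{5}{1/(4L_p) + L_p\theta_a^2/2},$$
the balance point between the entropic and bending costs; with
$L_p = 150$ and $\theta_a = 2.2^\circ$ this is 44.5 bp, i.e. $\approx 45$
bp.  No such minimum exists for the WLC.

## Parameters and defaults

| parameter | default | unit | meaning |
|---|---|---|---|
| $L_p$ | 150 | bending sites (bp) | DNA persistence length |
| $\theta_a$, $\theta_b$ | from hull solve ($2.2^\circ$, $35.8^\circ$ for DNA) | rad | tangency angles |
| $h$ | 10 | bp/turn | helical repeat (torsional modulation period) |
| $b$ | 3.3 | Å | bead spacing (B-DNA base-pair rise) |
| bond stiffness | 100 | $k_BT$/Å$^2$ | "virtually inextensible" bonds |
| $l_B$ | 7.1 | Å | Bjerrum length (water, 300 K) |
| profile domain | $[0, 1.2]$ | rad | covers the DNA hull ($\theta_b \approx 0.62$) with margin, excludes the unphysical large-angle tail |

Angles are radians everywhere inside the package; the command-line
interface accepts and reports degrees, matching how the field quotes bend
angles.

## Numerical choices

**Hull detection.** `find_double_tangent()` samples the profile on a
uniform grid (4001 points), builds the discrete lower convex hull by
monotone chain, and brackets the tangency pair with the hull edge that
skips interior samples.  The bracket is refined by a damped Newton
iteration on the tangency system $E'(a) = E'(b) = (E(b)-E(a))/(b-a)$ to a
residual below $10^{-10}$ $k_BT$/rad.  Bracketing guarantees the correct
pair; Newton delivers machine-precision endpoints.  Candidate non-convex
regions are discarded as numerical ripple when they span $\le 5$ grid
samples or dip less than $10^{-5}$ of the profile's energy range below
their chord — monotone-cubic interpolants of tabulated profiles carry
exactly this kind of sub-resolution ripple.  A genuine hull touching the
search boundary raises an error (widen the domain); profiles with several
substantial non-convex regions are rejected rather than silently
mishandled.

**Tabulated profiles** interpolate with the monotone Fritsch–Carlson
piecewise cubic (`splinefun(method = "monoH.FC")`): a continuous
derivative for the tangency equations without the spurious oscillation of
unconstrained cubic splines.

**Integer kinks.** `constrained_minimum()` honours the exact sum
constraint with an integer number of strong sites: both
$\lfloor pN \rfloor$ and $\lceil pN \rceil$ kinks are completed (the weak
angle adjusting) and the lower total kept, with the uniform assignment as
a further competitor.  Near $\theta_a$ this integer effect matters: for a
150-bp loop the continuum hull value undercuts uniform bending by only
0.6%, and once the closed polygon's *vector* closure constraint (which
the lever-rule derivation ignores) is added, the uniform ring is the true
geometric optimum.  Simulated minima can therefore sit exactly on the
uniform value at the weak edge of the hull interval rather than strictly
below it.

**Torsional modulation.** The phase factor applied to the envelope is
$(1+\cos(2\pi L/h))/2$, clamped below at $10^{-3}$ so $j$ stays positive.
The published ratio comparisons use phase-matched length pairs (equal
$L/h$ fractional part), for which any multiplicative modulation cancels;
those ratios are computed unmodulated.  Two published ratio rows (80/101
and 90/101, and the WLC 71/101 entry) are not reproducible from the
unmodulated closed form with $L_p = 150$ — the modulation treatment that
produced them is not specified — and are deliberately not asserted
anywhere in this package.

**Prefactor calibration.** `fit_k()` is the least-squares solution in
$\log j$ with $k$ the only free parameter: the geometric mean of observed
over predicted ($k = 1$) values; exact for a single point.

## The samplers

`mc_sample()` is a single-bead Metropolis sampler for closed rings: stiff
harmonic bonds, the bending potential at every site, Gaussian
displacement moves auto-tuned during burn-in (first 10% of sweeps,
discarded) to $\approx 40\%$ acceptance.  No excluded volume, twist, or
planarity constraint is imposed on plain loops.  Incremental energies are
checked against a full recomputation every $10^3$ sweeps (the maximum
drift is reported and tested below $10^{-6}$ $k_BT$).  All randomness
comes from R's RNG, so a seed fixes the trajectory bit-for-bit.

`minimize_loop()` relaxes a conformation with the FIRE inertial scheme to
a max-norm gradient below $10^{-6}$ $k_BT$/Å.  FIRE was chosen over plain
steepest descent with backtracking because the energy mixes very stiff
bonds with soft angles; the contract (a local minimum at the stated
gradient tolerance) is the same.  Because descent freezes in the kink
count of its starting snapshot — and a 300 K snapshot carries an
entropically excess number of kinks — the hull-tracking minimum-energy
points are produced by `anneal_loop()`: a staged MC cooling
(300 → 5 K by default) followed by FIRE, which lets the kink population
equilibrate before quenching.

**Mode counting.** Bend-angle histograms use fixed 0.5° bins on 0–60°.
`histogram_modes()` smooths with a 9-bin moving average and counts peaks
by topographic prominence (default 2% of the global maximum): a height
floor alone miscounts ripple in the depleted valley between the two
genuine modes.  Weak/strong occupancy is classified at the hull midpoint
$(\theta_a+\theta_b)/2$, which lies in that valley; the boundary is a
documented, configurable choice since no canonical criterion exists.

`simulate_confined()` realises the "protein–DNA complex" toy model: an
open charged chain (bead charge $q_s = -1$) attracted by unscreened
Coulomb ($E = q_i q_j l_B / r$ in $k_BT$, $l_B = 7.1$ Å) to a core charge
$Q$ on an impenetrable sphere or cylinder of radius $R$, between hard
walls $z = \pm\,\mathrm{gap}/2$.  Exclusion combines a steep
inverse-power repulsion in the gap distance (smooth gradients, divergent
at contact) with outright rejection of penetrating moves, so accepted
configurations never violate the hard constraints.  The reported average
angle $\bar\theta$ is taken over bending sites whose bead lies within
$1.5\,b$ of the core surface (the wrapped part of the chain) — the
averaging convention is ours, as the source analysis does not define one.
The dimension $R$ is exposed explicitly as a radius (the source text
calls $\approx 100$ Å a "diameter" for a symbol introduced as a radius).
Because no dielectric constant or screening length is specified for the
reference setup, absolute confinement energies are not reproducible in
principle; only the ordering with $|Q/q_s|$ and the bracketing of the
per-bead energy between the hull line and $E(\bar\theta)$ are asserted.
`unwrap_energy()` estimates the cost of detaching a tail segment as a
difference of mean physical energies between restrained simulations — a
qualitative binding estimate, not a free-energy method.  For the 147-bead
nucleosome-geometry variant, bead–bead Coulomb and soft-core repulsion
are switched on; for the 20-bead minimal model bead charges interact only
with the core.

## The synthetic-data generator

`make_fixtures()` produces every input class the package consumes, with
recorded ground truth: tabulated convex (harmonic) and non-convex
(random quartic with a brute-force-verified hull inside the window)
profiles; $(L, j)$ datasets drawn from the closed-form $j$-factor with a
known prefactor and multiplicative lognormal noise
($\sigma_{\log} = 0.1$, 50 points over 60–200 bp — the realistic scatter
and range of cyclization experiments); and regular ring geometries.  What
the generator deliberately does *not* emulate: sequence-dependent
bending, torsional stress beyond the phase factor, excluded volume,
experimental length-dependent systematics.  Tests passing on these
fixtures therefore validate the machinery (hull detection, calibration,
geometry I/O), not the biological realism of any particular profile.

## Test problem sizes

The simulation checks run at reduced scale, chosen as the smallest
ensembles in which the predicted phenomenology is unambiguous: 60-bp
loops at $2\times10^4$ sweeps for bimodality (peaks within $\pm 3^\circ$
of $\theta_a$, $\theta_b$), 300-bp loops for unimodality, annealed minima
for $N \in \{20, 40, 60, 80, 100, 150\}$ against the hull line (10%),
strong-state occupancy across $N \in \{20 \ldots 80\}$ against the lever
rule (correlation $> 0.9$), and 20-bead confined chains at
$|Q/q_s| \in \{10, 10^3\}$ over three seeds.  Oracles are independent
implementations: a brute-force discrete lower hull on $10^5$ samples, a
dynamic program over a discretised angle grid with exact sum constraint,
and inverse-CDF sampling from the exact single-site density
$\sin\theta\, e^{-E(\theta)}$ for unconstrained open chains.

## Known limitations

* The extreme regime $\bar\theta > \theta_b$ (sub-10-bp loops) is out of
  scope and rejected, as is any entropy correction to the constrained
  minimum.
* $j$-factors are relative unless $k$ is calibrated; no absolute molar
  units are produced.
* The thermal bend-angle histogram of large loops peaks near the
  free-chain thermal angle ($\approx 3.7^\circ$, from the
  $\sin\theta\,e^{-E}$ density), not at $\bar\theta = 2\pi/N$; structural
  comparisons are made at the level of mode count and peak location, not
  pointwise distribution shape.
* At the weak edge of the hull interval (loops just above
  $2\pi/\theta_a$), integer-kink and closure-geometry effects round the
  harmonic-to-linear transition: minimized rings can sit on the uniform
  value instead of marginally below it (see "Integer kinks").
* The quartic DNA profile is itself an empirical inference and is treated
  as the canonical reference input; no alternative profile ships with the
  package, but any tabulated profile can be supplied.

## A worked calculation

```{r example}
profile <- dna_quartic_profile()
hull <- find_double_tangent(profile)
hull

# ECH loop energy of a 50-bp circle and the j-factor envelope minimum
theta_a <- round(hull$theta_a * 180 / pi, 1) * pi / 180
loop_energy(50, "ech", Lp = 150, theta_a = theta_a)
envelope_minimum(150, theta_a)

# prefactor-free ratios at phase-matched lengths
c(ech_40_50 = jfactor_ratio(40, 50, "ech", Lp = 150, theta_a = theta_a),
  wlc_40_50 = jfactor_ratio(40, 50, "wlc", Lp = 150),
  ech_71_101 = jfactor_ratio(71, 101, "ech", Lp = 150, theta_a = theta_a))
```
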