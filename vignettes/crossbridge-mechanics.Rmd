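---
title: "Multi-spring cross-bridge mechanics: models, kinetics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-spring cross-bridge mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbmech)
```

## The problem

Contracting muscle generates force not only along the filament axis but also
radially, perpendicular to it, with radial components of the same order of
magnitude as axial ones. Both components, and the kinetics of the myosin
cross-bridges that generate them, depend on the spacing of the myofilament
lattice. The classic cross-bridge model — a single Hookean spring parallel to
the thick filament — cannot produce radial force and is blind to lattice
spacing by construction. `xbmech` implements two cross-bridge geometries that
can, plus the single-spring reference for comparison:

* **4sXB** — four springs following the mechanically relevant parts of
  myosin II: a torsional spring where S2 joins the thick-filament rod, an
  extensional S2 segment, a torsional "converter" spring linking S2 to the
  light-chain domain (LCD), and the extensional LCD lever arm.
* **2sXB** — a two-spring reduction (one torsional spring at the filament,
  one extensional lever arm) that reproduces most 4sXB behaviour at a small
  fraction of the cost, because its geometry is closed-form.
* **1sXB** — the one-dimensional reference spring (rest offset 5 nm before
  the power stroke, 0 nm after, 5 pN/nm).

All springs are linearly elastic; the energy of a spring with value $v$,
stiffness $k$ and state-dependent rest value $v_0$ is $\frac12 k (v-v_0)^2$.
Torsional stiffnesses are interpreted as pN nm/rad so that this expression
is an energy in pN nm.

## Geometry and the power stroke

The model plane has the thick-filament axis as $x$ (axial, positive toward
the binding sites) and the thick-to-thin surface separation as $y$ (radial).
The 4sXB base sits at the origin; the S2 segment leaves it at the base angle
(rest 40°, unchanged by the stroke), ends at the *converter point*, and the
LCD runs from there to the tip. The converter angle is measured between the
LCD and the filament axis, with LCD direction $(-\cos\theta, \sin\theta)$;
its rest value rotates from 125° to 70° with the power stroke. That switch
of rest values *is* the power stroke: no spring is added, removed or
re-stiffened between states.

```{r}
xb4 <- crossbridge("4sXB")
tip_rest(xb4, state = 2)  # pre-stroke rest tip
tip_rest(xb4, state = 3)  # post-stroke rest tip
```

The 2sXB rest angle/length pairs are not free parameters: they are derived
so that its tip coincides with the 4sXB tip in both rest conformations
(47.16°/19.93 nm before the stroke, 73.20°/16.47 nm after, matching the
rounded values of the shipped parameter table).

For an arbitrary tip position the 2sXB spring values are the polar
decomposition of the base-to-tip vector (closed form). The 4sXB has one
interior degree of freedom — the converter point — which is placed by
minimising the total elastic energy at fixed base and tip. The printed
description of this model family uses a derivative-free dog-leg search for
that minimisation; here the energy is smooth and its gradient with respect
to the converter point is available analytically, so we use quasi-Newton
(BFGS) from the state's rest converter placement, energy tolerance
$10^{-8}$ pN nm, 500-iteration budget, with five deterministically jittered
restarts if a line search fails. The test suite verifies the solver against
exhaustive 0.05-nm converter grids on random tips, and verifies the envelope
property that differentiating the converter-relaxed energy equals
differentiating with the converter frozen at its optimum.

The tip is the distal end of the spring chain. The rigid globular domain
attaches there through a universal joint and keeps a fixed angle to actin,
so it contributes a constant offset that is absorbed into the rest geometry.
Tips with radial separation below 0.5 nm are rejected as outside the
physical lattice rather than extrapolated.

## Lattice spacing

Internally everything is a function of the surface-to-surface spacing
(ssLS) the tip must span. Experiments report the $d_{10}$ Bragg spacing of
the hexagonal filament lattice, in which the thick-to-thin centre distance
is $\tfrac23 d_{10}$; hence

$$\mathrm{ssLS} = \tfrac23\, d_{10} - c.$$

The correction $c$ absorbs the filament radii, but it is not taken from
crystallography: it is calibrated so that at the rest spacing
($d_{10} = 34$ nm) the post-power-stroke cross-bridge at its unstrained
axial offset exerts zero radial force. With the shipped parameters this
yields $c = 6.896$ nm:

```{r}
cal <- lattice_calibration(xb4, rest_d10 = 34)
cal
```

The calibration makes the radial-force sign structure automatic: compressed
lattices ($d_{10} < 34$) put the binding line below the post-stroke rest tip
and the bound head pushes the filaments apart (expansive, positive radial
force); swollen lattices pull it compressive. Spacings outside the studied
30–38 nm window warn but compute.

## Free energies and forces

State 1 (detached, Myosin·ADP·Pi) carries no strain and is the zero of free
energy at every tip and spacing. For the bound states,

$$G_i = -\epsilon_i \,\Delta G_{\mathrm{ATP}} + U_i/kT, \qquad i = 2, 3,$$

in kT units, where $U_i$ is the total (converter-relaxed) elastic energy at
the state's rest values and $\epsilon_2 = 0.28$, $\epsilon_3 = 0.68$ are the
fractions of the ATP budget available to the weakly and strongly bound
states. The per-cycle budget
$\Delta G_{\mathrm{ATP}} = 13 + \ln([\mathrm{ATP}]/([\mathrm{ADP}][\mathrm{P_i}]))
\approx 23.9\,kT$ uses 5 mM ATP, 30 µM ADP and 3 mM phosphate, the standard
values of the three-state literature this model family descends from. The
temperature enters only through $kT$; the model statement leaves it open, so
`thermo_params()` defaults to $kT = 4.11$ pN nm (about 298 K) and exposes it.

Reaction forces are the negative tip-gradient of the elastic energy,
decomposed into axial and radial components (positive radial = expansive).
For the 4sXB the envelope property lets us evaluate the gradient with the
converter held at its optimum, which the analytic expressions do. The
package verifies force = −∇energy by central differences at $10^{-4}$ pN
resolution.

The **step size** at a spacing is the axial distance between the
free-energy-minimising offsets of the pre- and post-stroke states on the
binding line, located by a 0.5-nm pre-bracketing grid plus golden-section
refinement to $10^{-4}$ nm over a ±25 nm window. Under the shipped
parameters the 2sXB step-size curve has a single interior maximum near
$d_{10} = 35.5$ nm, while the 4sXB curve decreases monotonically across the
window. The monotone 4sXB curve is forced by the geometry: its post-stroke
minimum offset is nearly invariant with spacing (the post-stroke LCD is
almost radial) while its pre-stroke minimum falls steadily as the lattice
swells, so their difference cannot peak in the interior. `step_size_curve()`
reproduces both curves in seconds.

## Kinetics

The three-state cycle is: (1) detached ↔ (2) loosely bound pre-stroke ↔
(3) post-stroke ↔ (1), with strain-dependent rates that are transforms of
the free-energy landscapes.

**Attachment (1 → 2)** is a two-step Monte Carlo: the detached head
diffuses thermally, then tests binding against the distance to the site.
Each spring's offset from rest is drawn from the Boltzmann distribution of
a harmonic degree of freedom — a Gaussian with variance $kT/k$ — and the
tip follows by forward kinematics. (This is the density stated in terms of
the offset and the spring constant; equipartition, variance exactly
$kT/k$, is checked at $10^5$ draws in the tests.) The binding probability
per 1 ms step at post-diffusion distance $d$ is

$$P_{12} = \exp(-d^2/\tau),$$

with scale factor $\tau = 12$ nm² (4sXB) and 72 nm² (2sXB); the larger
2sXB value compensates its broader diffusion footprint so the two models'
attachment rates are comparable. An ensemble of $N$ independent
diffuse-and-bind trials gives the rate constant
$r_{12} = -\ln(1-\bar P)/\Delta t$ (switchable to $\bar P/\Delta t$), with
a standard error propagated from the Monte-Carlo error of $\bar P$. The
default ensemble is $N = 10^4$ per grid point.

**Power stroke (2 → 3)** depends only on the free-energy difference:

$$r_{23} = \tfrac12\, r_{23}^{\max}\bigl(1 + \tanh(\gamma\,(G_2 - G_3))\bigr),$$

with $r_{23}^{\max} = 1000$ s⁻¹ and $\gamma = 0.5$ per kT: fast when the
stroke is downhill, shutting off smoothly when strain makes it uphill.

**Detachment (3 → 1)** accelerates exponentially with post-stroke strain:

$$r_{31} = r_{31}^{0} \exp(\alpha U_3),$$

with $U_3$ the converter-relaxed elastic energy in pN nm. The position
dependence of the classic single-spring detachment law is deliberately
absent; only the asymmetry of the spring geometry remains. The two
constants are calibrated, not fitted per run: $r_{31}^0 = 20$ s⁻¹ anchors
the unstrained detachment rate at rest spacing (where the minimum over
offsets sits exactly at zero strain), and $\alpha = 0.68344$ (pN nm)⁻¹ is
set so the detachment minimum rises to 260 s⁻¹ at $d_{10} = 38$ nm, the
model family's stated span across the lattice window.

**Reverse rates** follow detailed balance,
$r_{ji} = r_{ij}\exp(G_j - G_i)$ in kT units. The 2 → 1 reverse uses the
ensemble-estimated $r_{12}$ as its forward partner. The 3 → 1 step crosses
the ATP-turnover boundary — completing it consumes the cycle — so its
reverse balances against $G_1 - \Delta G_{\mathrm{ATP}} - G_3$, which makes
the direct 1 → 3 entry negligible (order $e^{-8}$ of $r_{31}$). Exponents
are clamped at ±50 to guard overflow; every clamp event is counted in
`clamp_log()`.

## The trajectory simulator

`simulate_xb()` advances a single cross-bridge in fixed 1 ms steps. A
detached head diffuses and attempts binding; a bound head tests its forward
transition first and, only if that did not fire, its reverse transition; at
most one event resolves per step. At 1 ms the per-step probabilities are
small enough that this ordering is a second-order detail. All randomness is
pre-drawn in a fixed order from the configuration seed, so trajectories are
byte-identical across runs with equal seeds. Long-run occupancies are
validated against the stationary distribution of the matching three-state
Markov chain (`steady_state_occupancy()`), and post-stroke dwell times
against the competing-exponential rate sum.

```{r}
tr <- simulate_xb(sim_config("2sXB", d10 = 34, duration = 2, seed = 7))
summary(tr)
```

## Landscape scans, summaries and masking

`scan_landscape()` evaluates energies, rates and forces on a rectangular
axial × $d_{10}$ grid (defaults: −5…25 nm at 0.25 nm; 30…38 nm at 0.5 nm).
Deterministic layers are exact and bit-identical across runs; stochastic
layers carry standard errors and per-cell seeds derived from the base seed.
Cells where the solver fails are recorded as `NaN` and counted, not fatal.
`summarize_offsets()` locates per-spacing extrema, refining deterministic
extrema continuously (golden section) and stochastic peaks with a local
5-point quadratic fit — the attachment-rate peak is flat, and a wider fit
suppresses seed-to-seed jitter of the vertex without biasing it.
`mask_unlikely()` flags cells a bound cross-bridge is unlikely to occupy by
thresholding $r_{12} + 1/r_{31}$; the default threshold is chosen so kept
cells carry at least 95% of the total attachment flux, and the rule and
threshold are recorded on the result.

```{r}
g <- scan_landscape(crossbridge("2sXB"), layers = c("energy", "r31"),
                    axial = seq(0, 20, 1), d10 = c(32, 34, 36), cal = cal)
summarize_offsets(g)
```

## What the simulations do and do not represent

The models are deliberately single-cross-bridge and two-dimensional. They
omit, by design: azimuthal (out-of-plane) geometry; filament compliance and
the realignment of binding sites it causes; coupling between neighbouring
cross-bridges through shared filament strain; thin-filament regulation (no
calcium states); worm-like-chain or other entropic elasticity; and
ATP-concentration dependence beyond the fixed per-cycle budget. Agreement
of the test suite with the oracles above therefore demonstrates the
internal consistency of the spring mechanics, energetics and kinetics — not
fidelity to any particular fibre preparation. Where real muscle data enter
at all, they enter through the parameter table (rest geometries and
stiffnesses) and the two calibration anchors (zero radial force at rest
spacing; the detachment span across the window).

## Numerical choices and degenerate inputs

* Energies in pN nm, free energies in kT, angles in radians internally
  (degrees in the parameter file); 1 kT = 4.11 pN nm by default.
* Converter optimisation: BFGS + analytic gradient, rest-placement start,
  tolerance $10^{-8}$ pN nm, ≤500 iterations, 5 jittered restarts; failure
  raises an error carrying the last iterate.
* Axial extremum searches: 0.5 nm bracketing grid + `optimize()` to
  $10^{-4}$ nm.
* Tips at the base (undefined angle) and radial separations ≤ 0.5 nm are
  rejected; conversions yielding non-positive ssLS are errors; spacings
  outside 30–38 nm warn.
* Exponential clamping at |argument| = 50, logged via `clamp_log()`.
* Problem sizes in the shipped tests: $10^4$ diffuse-and-bind trials per
  reported rate point ($10^5$ for equipartition), 100 × 10 s trajectories
  for occupancy contrasts, 50-tip brute-force solver audits at 0.05 nm
  converter resolution. These sizes give Monte-Carlo errors comfortably
  inside the asserted tolerances.

## Known limitations

* The 4sXB step-size curve is monotone over the lattice window under the
  shipped parameters (see above); treat reported "maximum step size over
  the window" values for the 4sXB as edge values, not interior optima.
* The attachment-rate peak is broad; its located offset carries ~±0.2 nm
  seed-to-seed variability at $N = 10^4$ even after quadratic refinement.
* The 2 → 1 reverse rate inherits the Monte-Carlo error of the ensemble
  attachment estimate it balances against.
* Trajectories resolve at most one event per 1 ms step; rate constants far
  above 1000 s⁻¹ saturate the per-step probability and are represented
  faithfully only through the −log(1−P) conversion.
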