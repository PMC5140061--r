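---
title: "Growth-driven kinematics of plant nutation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-driven kinematics of plant nutation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 6)
library(nutkin)
```

## The model

Circumnutation — the slow swinging of a growing shoot or hypocotyl that
traces circles, ellipses or looping curves in the horizontal plane — is
modelled here as a purely growth-driven process. The organ is a cylinder of
constant radius $R$, described by arc length $s$ from the clamped base
($s=0$) to the apex ($s=L$). At each cross-section, two angles matter:

* $\psi_c(s,t)$ — the direction (in the cross-section, measured from a
  reference director) in which the organ is maximally curved, with
  curvature magnitude $C(s,t)$;
* $\psi_g(s,t)$ — the principal direction of differential growth, i.e. the
  direction the growth asymmetry pushes the organ to bend toward.

A surface fiber at cross-section angle $\phi$ of a segment with median
length $L_0$ has length
$$L_s(\phi) = L_0\,\bigl(1 - C R\cos(\phi - \psi_c)\bigr),$$
shortest on the concave side, longest opposite it. Differentiating the
finite fiber strain of this relation in time gives the strain-rate field
over the cross-section,
$$\dot\epsilon(\phi) = \dot E \;-\;
  \frac{\tfrac{d(CR)}{dt}\cos(\phi-\psi_c) + CR\,\dot\psi_c\sin(\phi-\psi_c)}
       {1 - CR\cos(\phi-\psi_c)},$$
where $\dot E$ is the median (average) relative elongation rate. The two
non-uniform contributions dominate in orthogonal planes: changes of
curvature magnitude act at $\phi = \psi_c,\ \psi_c+\pi$, changes of
curvature *direction* at $\phi = \psi_c \pm \pi/2$. A fiber on the concave
side grows slower than the median while curvature increases — the organ
bends toward the slower-growing side.

Projecting the asymmetry of this field (far-side minus near-side rate over
$2\dot E$) onto the curvature frame defines the in-plane and orthogonal
differential growth $\Delta_\parallel$, $\Delta_\perp$, and yields the
evolution laws
$$\frac{D(CR)}{Dt} = \Delta_\parallel\,\dot E\,(1 - C^2R^2),
  \qquad
  \frac{D\psi_c}{Dt} = \frac{\Delta_\perp\,\dot E}{CR},$$
with $\Delta_\parallel = \Delta\cos(\psi_g-\psi_c)$,
$\Delta_\perp = \Delta\sin(\psi_g-\psi_c)$ for a driver of magnitude
$\Delta$ directed along $\psi_g$. These two equations are the whole story:
the curvature direction is *slaved* to the growth direction (with constant
$\psi_g$ the organ aligns, $\psi_c \to \psi_g$), and a rotating $\psi_g$
drags the curvature around, producing nutation.

Two conventions deserve a note, because the analogous printed equations in
parts of the literature are not internally consistent at order $CR$:

* the strain-rate field above is the exact first-order expansion of the
  finite fiber strain — the package's test suite enforces the equivalence
  numerically (single-step finite strain converges to the rate field at
  first order in $dt$ across random states);
* the differential-growth pair is normalized by $2\dot E$ and oriented
  far-minus-near, which is the unique choice making (i) $|\Delta| = 1$
  mean "all growth on one side", (ii) the evolution laws above *exact*
  (quadratic prefactor included), and (iii) bending proceed toward the
  slower side.

### The curvature vector

The direction equation is singular at $C = 0$ ($1/CR$ prefactor), so the
integrator works with the dimensionless curvature vector
$$\boldsymbol\kappa = CR\,(\cos\psi_c,\ \sin\psi_c),$$
for which the same dynamics are the regular linear system
$$\dot{\boldsymbol\kappa} = \Delta\!\cdot\!\dot E\,(\cos\psi_g, \sin\psi_g)
  \;-\; \frac{\gamma\dot E}{R}\,\boldsymbol\kappa.$$
$(C,\psi_c)$ are derived views; at $C=0$ the package reports the direction
of the last nonzero $\boldsymbol\kappa$ (0 for a never-curved segment) and
never uses that value in the dynamics. Equivalence with the
magnitude/direction form for $C>0$ is a tested property.

The second term is **proprioception**: a self-straightening reaction
proportional to the local curvature, with gain $\gamma$ (mm, so that
$\gamma C$ is dimensionless). It acts along $-\boldsymbol\kappa$, i.e.
purely in the plane of curvature, which is exactly the
$-\gamma C$ term added to $\Delta_\parallel$. We adopt the cosine
projection for the driven part of $\Delta_\parallel$ throughout —
consistent with the projection identities above; a sine there would make
the driver orthogonal to its own alignment fixed point.

### Growth, material segments, and the growth zone

The organ is discretized into $n$ *material* segments (default 100), each
carrying rest length, $\boldsymbol\kappa$, and nothing else. Because
segments are co-moving, the advective term of the material derivative
$D/Dt = \partial_t + v\,\partial_s$ never needs to be formed: elongation
updates rest lengths ($\ell \leftarrow \ell\,(1+\dot E\,dt)$), and
abscissas are recomputed as cumulative sums, which *is* the velocity field
$v(s,t) = \int_0^s \dot E\,ds'$ in discrete form (a tested property).

Growth can be confined to a subapical zone of length $L_{gz}$: segments
with $s < L - L_{gz}$ receive $\dot E = 0$ *and* zero differential growth,
freezing their curvature and direction. Under a rotating driver the frozen
part accumulates a stored helical arrangement — the package quantifies
this with `planarity_deviation()` (smallest singular value of the centered
centerline, normalized by length) rather than asserting any smallness
threshold for when the helix is noticeable, since the raw quantities
($C$, $L_{gz}$, $R$) are what an experimentalist can compare.

### 3D reconstruction

The centerline is reconstructed by propagating a frame (tangent $t$,
directors $d_1, d_2$) from the clamped base (origin, $t = +z$,
$d_1 = +x$; gravity is $-z$ and the "horizontal plane" is $(x,y)$). Within
a segment the curvature is constant, so the frame is advanced by the exact
rotation of a circular arc — reconstruction error is purely a
discretization-in-$s$ effect (doubling the segment count changes tip
positions well below 1%, a tested refinement property).

The reference director is transported with **zero twist**: the frame
rotation between consecutive points has no component about the tangent.
This choice is forced by the model's no-torsion assumption — surface lines
parallel to the median stay parallel — which is precisely the
parallel-transport condition. Rotating the base director by $\alpha$
rotates the whole shape rigidly about $z$ and shifts every angle by
$\alpha$: a gauge freedom with no observable consequence (tested).

## Driver presets

The endogenous oscillator enters through preset programs for
$(\psi_g, \Delta\!\cdot\!\dot E)$; registry keys follow the interactive
pattern-zoo convention:

| key | rule | pattern |
|-----|------|---------|
| `"2"` | constant $\psi_g$ | alignment, in-plane bending |
| `"circle"` | $\psi_g = \omega_0 t$ | circle |
| `"0"` | $\dot\psi_g = \omega_0(1 + a\cos 2\psi_g)$, $a = 0.5$ | ellipse (rate-modulated) |
| `"1"` | $\Delta\dot E \propto 1 + a\cos 2\psi_g$, $a = 0.5$ | ellipse (amplitude-modulated), axes rotated $\pi/2$ from `"0"` |
| `"3"` | circle + proprioception | single attracting orbit centered on the base |
| `"4"` | circle + whole-organ growth | spiral, per-turn period unchanged |
| `"5"` | circle + subapical growth zone | circle + stored basal helix |
| `"epitrochoid"` / `"hypotrochoid"` | two zones, $\psi_{g,2} = \pm 6\,\omega_0 t$, five-fold drive | looping trochoids |

The rate-modulated rule is integrated as an internal oscillator ODE with
the same time step as the organ (midpoint update, so its closed-form
period $2\pi/(\omega_0\sqrt{1-a^2})$ — exposed as
`rate_modulated_period()` — is met to well under 1%). Except for the
two-zone presets, drivers are uniform in $s$, matching the whole-organ
hypothesis used for tip-track interpretation. Which of the two ellipse
mechanisms belongs to which digit key is ambiguous in the source
convention; the registry documents both explicitly rather than guessing.

### Default scales

Defaults emulate an *Arabidopsis*-like inflorescence/hypocotyl setting,
chosen once and used by every preset:

* rotation period 230 min ($\omega_0 = 2\pi/13800$ rad/s) — the scale
  reported for Arabidopsis nutation;
* organ radius $R = 0.5$ mm, initial length $L_0 = 10$ mm;
* drive sized for a steady curvature-vector amplitude
  $|\boldsymbol\kappa| = \Delta\dot E/\omega_0 = 0.01$, i.e.
  $C L \approx 0.2$: tip excursions of $\sim 1$ mm, firmly in the
  small-curvature regime where the tip estimators are quantitative;
* elongation, where a preset uses it, $\dot E = 1\text{–}5\times 10^{-6}$
  s$^{-1}$ (0.4–1.8 %/h);
* proprioceptive preset: damping rate $\gamma\dot E/R$ set equal to
  $\omega_0$, with $\dot E$ small enough that total elongation over the
  run stays at a few percent (the damping needs a nonzero elongation rate
  to act — growth is what implements the reaction);
* explicit Euler, $dt$ = driver period / 1000 (capped so that
  $dt \times$ fastest rate $< 10^{-2}$; per-step $|\Delta\kappa| \le
  10^{-3}$), horizon 5 driver periods, states saved every 5 steps. A
  midpoint scheme is available (`method = "midpoint"`); the test suite
  verifies first- vs second-order convergence.
* The $(1 - C^2R^2)$ prefactor on the in-plane component is neglected by
  default (the working regime has $CR \le 0.01$) and retained behind
  `keep_quadratic`, where the aligned-driver solution
  $CR(t) = \tanh(\Delta\dot E\,t)$ is used as a closed-form check.

Rotating presets start on the *centered periodic orbit*
(`centered_initial_kappa()`): the rotating solution is a circle in
$\boldsymbol\kappa$-space whose center is fixed by the initial condition;
centering it on the origin centers the apical pattern on the base, which
is the configuration the stability analysis singles out and the one
observed after proprioceptive transients die out.

## Inverting apical-tip tracks

Experiments mostly record the tip's horizontal projection
$(x_a(t), y_a(t))$. Under the whole-organ hypotheses — uniform curvature
in a single plane, same variation along the organ, elongation neglected —
the polar view maps to posture as $\psi_c = \theta$ and
$\rho = (1-\cos CL)/C$, and the growth driver is estimated directly:

* $\hat\psi_g(t)$ = direction of the smoothed tip velocity,
  $\operatorname{atan2}(\dot y_a, \dot x_a)$, full-quadrant, unwrapped. (A
  printed-convention variant referenced to the $y$-axis exists behind
  `convention = "printed"`; any constant reference offset cancels in every
  rate, period and phase difference.)
* $\widehat{\Delta\dot E}(t) = \dfrac{2R}{L^2}\sqrt{\dot x_a^2+\dot y_a^2}$.
  The prefactor follows from substituting the small-curvature relation
  $C = 2\rho/L^2$ into the exact inversion (below); without $R$ and $L$
  the estimate is returned up to the prefactor and flagged qualitative.
* $T_r = 2\pi/\langle d\psi_g/dt\rangle$, and independently $T_o$ = mean
  time between *alternate* maxima of the rate series (consecutive maxima
  sit half a rotation apart).

Numerical choices: derivatives use Savitzky–Golay local polynomials
(`signal::sgolayfilt`), window defaulting to one tenth of the dominant
period found by autocorrelation; one window is masked at each series end;
samples with tip speed below 1% of the median speed are masked (direction
is meaningless at a stationary tip); unwrapping is the standard $\pm\pi$
jump correction. Summary rates are measured over an exact whole number of
rotations (interpolated phase crossing) after discarding one provisional
period at each end, so the periodic part of $\psi_g(t)$ contributes no
endpoint bias. The exact arc inversion $\rho \mapsto C$
(`curvature_from_tip()`) is solved on the monotone branch
$CL < 2.3311$ (the root of $u = \tan(u/2)$, where the tip starts folding
back toward the base and uniqueness is lost); the small-curvature proxy
$C = 2\rho/L^2$ ships alongside it, and both are exposed rather than
asserting either as canonical.

With full 3D data the inversion is exact rather than approximate
(`invert_from_3d()`): per material segment,
$$\psi_g - \psi_c = \operatorname{atan2}\!\bigl(CR\,\dot\psi_c,\
  \tfrac{d(CR)}{dt}\bigr), \qquad
  \Delta\dot E = \sqrt{\bigl(\tfrac{d(CR)}{dt}\bigr)^2 +
  (CR\,\dot\psi_c)^2},$$
with material (Lagrangian) time derivatives by central differences, and
samples where both rate components vanish masked. Round-tripping the
simulator's own stored fields recovers the driver to $10^{-3}$ relative
(tested) — the error is purely the finite-difference stencil.

### What the tip estimators can and cannot see

* Plots of rate or drive against $\psi_g$ assume the organ does not
  rotate about its own axis (no torsion); under torsion the phase
  reference is shifted and such plots mislead, though time-domain
  periodicity survives. The package therefore treats the no-torsion case
  only (material torsion is also excluded from the model itself, being
  too slow to drive nutation).
* When two organ zones oscillate at different rates, the tip sees one
  *effective* oscillator: the recovered mean rate takes the sign and
  approximate magnitude of the faster zone's rate (tested on the
  trochoid presets); the two underlying rates cannot be separated from
  the tip track alone.
* The drive estimate is nonnegative by construction, so variation of the
  median elongation cannot be distinguished from variation of the
  differential-growth fraction.

## A worked pattern-class example

```{r example, eval = FALSE}
sim <- simulate_organ(preset = "0")        # rate-modulated ellipse
fit <- fit_nutation(sim$track, R = 0.5, L = 10)
coef(fit)
plot(fit)                                  # track + phase plots
```

The fitted rate series dips at $\psi_g = \pm\pi/2$ (the driver lingers
there, letting the organ curve out further), while the drive series stays
flat — the signature separating this ellipse mechanism from the
amplitude-modulated one, whose drive series peaks on the modulation axis
while its rate stays flat, and whose pattern is rotated by $\pi/2$.

## Synthetic data

`generate_track()` produces analytic tracks (circle, ellipse, epi-/
hypotrochoids as sums of two rotating vectors, line) with optional
Gaussian position noise (a stated fraction of the pattern scale, fixed
seed, RNG state restored). These emulate the *pattern classes* of real
tip recordings and the noise floor of centroid tracking; they do not
emulate torsion, tracking dropouts, drift of the camera frame, or
amplitude trends from organ growth — so estimator tests passing on them
demonstrate correctness of the inversion chain under the model's
hypotheses, not robustness to every artifact of real footage. Parameter
recovery on the simulator's own output (1% position noise, mm-scale
patterns, 230-min period) is the package's acceptance-level check.

## Problem sizes

Tests and the acceptance script run the simulator at 100 segments,
roughly 1000 steps per driver period and 4–5 period horizons; refinement
checks use up to 4000 segments for geometry closed forms. These sizes put
every discretization error one to two orders below the tolerances being
asserted while keeping a full run in tens of seconds.

## Known limitations

* Purely kinematic: no elasticity, self-weight, buckling, or contact;
  gravitropic and phototropic terms are out of scope by design.
* No material torsion, neither as a mechanism nor as a measurement
  correction.
* The tip estimators inherit the whole-organ hypotheses; they are
  quantitative only in the small-curvature regime ($CL \lesssim 0.3$ for
  the stated tolerances) and up to the $2R/L^2$ prefactor when geometry
  is unknown.
* Drivers are deterministic; stochastic or circadian-gated oscillators
  are not modelled.
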