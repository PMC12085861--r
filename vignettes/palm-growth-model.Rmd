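---
title: "Modelling coconut palm growth and measuring it from a climbing robot"
author: "palmrod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coconut palm growth and measuring it from a climbing robot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmrod)
```

## The problem

Coconut palms are an awkward fit for the standard tree-growth machinery.
They have no branches and no cambium: height comes from continuous apical
growth at a single crown, and girth from diffuse expansion of parenchyma
tissue rather than annual rings. Their slender, top-heavy geometry makes
them unusually sensitive to wind, and their growth direction is steered by
gravitropism (growth against gravity) and phototropism (growth toward
light). `palmrod` models this system as a *growing Cosserat rod* — a base
curve carrying an orthonormal director triad $(f_1, f_2, f_3)$ — combined
with an exponential trunk taper anchored at the diameter at breast height
(DBH), and pairs the model with the signal-processing chain needed to
measure real trunks from a sensor-equipped climbing robot.

## Growth kinematics

Material is laid down at the apex: the trunk length $k(t)$ is non-decreasing
and, at constant apical velocity $a_v$, $k(t) = a_v t$; the material point at
arc coordinate $r$ appeared at time $f(r) = r/a_v$ (`growth_schedule()`
also accepts a monotone length table). Along the rod the directors obey the
Serret–Frenet-type system

$$\partial_r f_i = y \times f_i, \qquad \partial_r s = w_1 f_1 + w_2 f_2 + w_3 f_3,$$

with curvature/twist vector $y$ and stretch vector $w$; the reference
values are $y^0 = (0, \beta^0, \gamma^0)$ and $w^0 = (0,0,1)$.
`integrate_frame()` integrates this with a fixed-step 4th-order
Runge–Kutta scheme (default grid 0.01 m) followed by Gram–Schmidt
re-orthonormalisation at every step. The renormalisation is the cheap,
robust way to keep the triad on the rotation group without Lie-group
integrators; the tests hold it to $10^{-9}$ and the constant-curvature arc
to $10^{-6}$ relative error at 1 mm steps.

## Tropism: steering the new material

New material is seeded so that the tangent turns toward a preferred
direction. Gravitropism alone gives $f_p$; sunlight and wind modify it to
$f_{p}^{*}$, and the final direction is built from the orthogonal pair

$$f_p^{\gamma} = \frac{f_p \times f_p^{*}}{\lVert f_p \times f_p^{*}\rVert},
\qquad f_p^{\beta} = f_p^{\gamma} \times f_p^{*},$$

as $f_p^{F} = \operatorname{normalize}(f_p\cos\theta + f_p^{\beta}\sin\theta)$.
We read this composition as the rotation of $f_p$ toward $f_p^{\beta}$ — the
vector *sum* — because the literal cross product of the two scaled terms
vanishes at $\theta \in \{0, \pi/2\}$ and cannot reproduce the $\theta = 0$
identity the construction requires. A `strict_literal` flag keeps the
cross-product variant available for comparison. Parallel $f_p, f_p^{*}$
leave $f_p^{\gamma}$ undefined and raise an error.

With projections $c_i = f_p^F \cdot f_i$, the seeded strains are

$$\beta^0 = \operatorname{sgn}(c_1)\,\tfrac{\beta_{max}}{2}\sqrt{2(1-c_3)},
\qquad
\frac{d\beta^0}{dr} = \tfrac{\beta_{max}^2}{2}\left(c_1 -
\operatorname{sgn}(c_1)\sqrt{2(1-c_3)}\right),$$

and $\gamma^0 = \operatorname{sgn}(c_1)\beta_{max} c_2/\sqrt{2(1-c_3)}$
(zero when $\beta^0 = 0$). These are the closed-form solutions of a
second-order Taylor expansion requiring the tangent to reach the target
after a look-ahead arc $\Delta$. A point worth recording: substituting the
closed forms back into the projection system makes it an identity *exactly
when* $\beta_{max} = 2/\Delta$ — the curvature scale needed to turn through
a finite angle within $\Delta$. For a fixed $\beta_{max}$ and a fixed
finite-angle target the residuals have an $O(1)$ floor; second-order decay
in $\Delta$ is recovered for targets whose angular offset shrinks
proportionally to $\Delta$. The test suite checks both regimes: exact
consistency (residuals at machine precision, bounded by $C\Delta^2$) at the
matched scale over 1,000 random unit targets, and empirical order $\ge 2$
of the tangential residual in the proportional-offset regime.

Numerical guards: the square-root argument $2(1-c_3)$ is clamped to
$[0, 4]$ — its full range for a unit target, protecting only against
$|c_3| > 1$ from rounding — and $\operatorname{sgn}(0)$ is $+1$. (A
narrower clamp at 2 would silently truncate every backward-pointing target
and break the exactness property above.)

## The apical small-deflection system

Per time step the planar apical system advances four fields on the material
grid:

* contact couple, integrated inward from the free tip:
  $\partial_r q = -p_y \cos\theta$, $q(k(t), t) = 0$;
* relaxed curvature: $\partial_t \beta^* = \partial_t(YI)\, q/(YI)^2$, plus
  the differential-maturation rate
  $p = (2 v^{\gamma}/s^2)\,\alpha\,\sin(\theta_p^f - \theta)$;
* angle field, outward from the clamped base:
  $\partial_r \theta = \beta^* + q/YI$, $\theta(0,t) = \theta_0$;
* linearised base curve:
  $\partial_r s = \big(\cos\theta_0,\ \sin\theta_0 + (\theta -
  \theta_0)\cos\theta_0\big)$, $s(0,t) = 0$.

Newly appeared material receives
$\beta^*(r, f(r)) = \beta_{max}\sin\!\big((\theta_p^f - \theta_0)/2\big)$.
Integration is trapezoidal in $r$ and explicit Euler in time (default
$dt = 0.05$ y, $dr = 0.01$ m) — the boundary data (tip condition inward,
clamped base outward) dictate the sweep directions, and the system is far
from stiff at these scales.

**The lateral load $p_y$.** The model leaves the distributed lateral load
unspecified; the dominant mechanical stimuli in palms are self-weight and
wind. A perfectly vertical trunk's self-weight is purely axial, so we
default to the *lateral projection* of self-weight,
$p_y(r) = \rho'''(r)\, g\, \sin\theta(r)$, plus an optional constant wind
line load (`p_y_wind`). This makes the unloaded vertical state an exact
fixed point of `apical_step()` — at the reference parameter set
($\beta_{max} = 0$, $\theta_0 = 0$) a 40-year run is exactly vertical with
height $a_v t = 18.4$ m — while still bending inclined trunks under their
own weight.

## Wind and sunlight

Sunlight availability is the sum
$TAS = OMS + PFS + VS(H) + E$ (dimension-agnostic scalars; the model takes
the resulting deflection angle $\theta_S$ as an input and exposes $TAS$ as
a diagnostic), and angles compose additively:
$\theta_p^f = \theta + \theta_S + \theta_w$.

The wind response treats the trunk as a cantilevered conical frustum with
density-weighted second moment

$$I = \frac{\rho' \pi k}{10}\,
\frac{\lvert x_{top}^5 - x_{base}^4 x_{top} + x_{base}^5\rvert}
     {\lvert x_{top} - x_{base}\rvert},$$

tip deflection $D = F k^3 / (3 Y I)$ and deflection angle
$\theta_w = \arccos\!\big(k/(D + x_{top})\big)$ with the argument clamped
to $[-1, 1]$ (so $\theta_w = 0$ whenever $k > D + x_{top}$; the arccos form
is dimensionally loose, and clamping keeps it total without inventing a
replacement). Absolute values in $I$ are deliberate: the raw quotient is
negative for every tapered trunk ($x_{top} < x_{base}$), and a negative
rigidity is unphysical. Note the formula is *not* symmetric under swapping
the radii, and it is singular at equal radii (a cylinder needs a perturbed
radius). The density weighting means $YI$ carries nonstandard units;
internal consistency across the constitutive relation
$\beta = \beta^* + q/(YI)$ and its frustum-expanded overload (tested equal
to $10^{-12}$ relative) is the contract, not SI orthodoxy.

## Secondary growth: taper, DBH and radial velocity

Integrating the bulk-modulus pressure–volume relation down the trunk gives
the exponential taper

$$x(k_h) = \sqrt{\lambda\, e^{-a k_h}}, \qquad a = \frac{\rho' g}{B},
\qquad \lambda = \frac{-\rho' g}{B \pi} c',$$

with base radius $x(0) = \sqrt{\lambda}$ and DBH $= 2 x(1.4\,\text{m})$.
Because the bulk modulus carries a sign convention and only the composites
$a$ and $\lambda$ enter the law, validity is enforced as $\lambda > 0$
rather than constraining $B$ and $c'$ separately. `calibrate_taper()`
solves the two-point problem exactly (base radius plus one anchor radius),
and the round trip is machine-exact. The radial growth velocity is the
chain-rule derivative through the moving tip,
$V^r = -\tfrac{a}{2} x\, a_v$ — negative, because the radius *at the
growing tip* narrows as the tree gains height. An equivalent substituted
closed form ($\Gamma = e^{-ak}$, $\zeta = \lambda$) is provided and agrees
to $10^{-12}$; we note that a naive transcription of that substitution
drops a $1/B$ factor, which the implementation restores so the two routes
are genuinely the same quantity. Within this model the height profile
$x(k_h)$ is static, so the simulated DBH series is constant once the trunk
passes breast height (and `NA` before) — girth dynamics beyond the anchored
taper are outside the model's scope.

Cultivar differences (West Coast Tall vs Chowghat Green Dwarf) are pure
parameter presets shipped as two config files under `inst/extdata/`; the
dwarf apical velocity (0.25 m/y) and all taper anchor radii (WCT
0.175/0.160 m, CGD 0.150/0.135 m at 1.4 m) are *synthetic*,
field-realistic defaults, chosen once — no measured anchors are published.

## Key parameters

| name | meaning | unit | default |
|---|---|---|---|
| `a_v` | apical growth velocity | m/y | 0.46 (WCT) |
| `beta_max` | maximum tropic curvature | 1/m | 0 |
| `theta0` | initial trunk angle | rad | 0 |
| `theta_p`, `theta_pf` | trunk movement / final deflection angle | rad | $\pi/2$, $0.61\pi$ |
| `rho`, `g`, `Y` | wood density, gravity, elastic modulus | kg/m³, N/kg, Pa | 600, 9.8, 1.14e10 |
| `V_r`, `s_param`, `alpha` | maturation velocity, section scale, max DMS strain | m/y, m, m/m | 0.01, 0.01, 0.001 |
| `x_base`, `x_dbh` | taper anchor radii | m | 0.175, 0.160 |
| `breast_height` | DBH anchor height | m | 1.4 |

The reference set also prints both `s0 = 0.01` m and `s = 0.01` m; the two
are carried as distinct named entries (`s0` positional offset, `s_param`
cross-section scale in the maturation rate) since the source set is
ambiguous about their roles. Time is in years throughout the growth
modules and in seconds in the sensor modules; the boundary is explicit.

## The sensor chain

A climbing robot logs a 9-axis IMU (accelerometer, gyroscope,
magnetometer) and two opposed ultrasonic rangers on a rigid frame of known
span. `measure_tree()` runs:

1. **Wavelet denoising** (`wavelet_denoise()`): periodised orthogonal
   Daubechies DWT (db4, 4 levels by default), per-level soft thresholding
   with the threshold minimising Stein's Unbiased Risk Estimate, capped at
   the universal threshold; noise scale from the finest detail level as
   MAD/0.6745. The transform is implemented in the package (energy-exact,
   round trip to $10^{-10}$); db4 is the common SURE-denoising default, and
   db2 is available.
2. **EKF fusion** (`ekf_fuse()`): per-axis degree-3 polynomial
   (constant-jerk) state transition — state (position, velocity,
   acceleration, jerk) — plus (heading, heading rate). Measurements: the
   lateral and gravity-compensated vertical accelerometer channels, the
   magnetometer heading (absolute, unwrapped against the running
   estimate), and the gyroscope yaw rate. Diagonal initial state and
   measurement covariances; Joseph-form updates keep the covariance
   symmetric PSD (tracked per step). The filter output (not a smoother) is
   used downstream.
3. **Drift closure**: height from double-integrated acceleration is a
   random walk in the noise. Climbs end stationary by construction, so the
   residual terminal velocity estimate is removed by subtracting the
   quadratic position error it implies — the standard zero-velocity end
   correction of dead reckoning. This is what keeps 10 m climbs within a
   few percent.
4. **Diameter** (`diameter_from_ultrasonic()`): span minus the two ranges;
   geometrically impossible samples are flagged, not fatal.
5. **Rectification** (`rectify_anomalies()`): Hampel filter (window 11,
   3 MAD) repairs scar/wedge spikes in the diameter; isotonic regression
   (pool-adjacent-violators) projects the height onto the non-decreasing
   cone — climbing height must steadily increase.
6. **Extraction** (`extract_tree_parameters()`): diameter is resampled
   onto the height axis (0.1 m steps); DBH is read at 1.4 m (the robot
   mounts at breast height), total height is the top of the climb.

## The synthetic generator

`synth_climber_trace()` emulates a climb kinematically: a smooth
ramp–cruise–ramp velocity profile (0.2 m/s, 50 Hz defaults — desk-scale
runtimes), vertical acceleration derived from the *actual* height
trajectory (so injected slips propagate consistently into the IMU),
gravity on the vertical channel, constant heading on gyro/magnetometer,
and ultrasonic ranges read off the taper at the instantaneous height.
Artefacts: slip events (smooth transient height dips) and scar spikes
(short one-sided ultrasonic outliers). One global seed fans out to
per-channel substreams, so every channel is independently reproducible and
traces are bit-identical per seed; the global RNG stream is left
untouched. `synth_growth_observations()` adds seeded i.i.d. Gaussian noise
to simulated growth series for metric tests.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about field data: IMU bias instability and scale-factor
error, temperature drift, ultrasonic beam geometry and multi-path, frame
flex and mounting misalignment, heading-dependent trunk eccentricity, and
non-vertical climbs. Recovery results on synthetic traces are a
correctness check of the chain, not a field-accuracy claim.

## Comparison metrics

`compare_series()` reports MAE, RMSE, $R^2$ and the *variance of the
prediction–observation error* (population form) — the only reading of a
"variance between prediction and data" that is a single number in squared
units; a `scale` argument reports metre series in centimetres (variance in
cm²) where that convention is expected. Unequal abscissae are aligned by
linear interpolation of the prediction onto the observation grid.

## Problem sizes and runtime choices

The shipped tests use 40-year simulations at $dt = 0.05$–0.1 y and
$dr = 0.01$ m, 1,000 random tropism targets, 100-set taper consistency
sweeps, and 10-seed sensor recoveries on 10 m climbs at 50 Hz — sizes
chosen so the whole suite runs in well under a minute on one core while
exercising every code path at meaningful resolution.

## Known limitations

* The apical system is planar (small-deflection); full 3-D wind loading
  and large-deflection statics are out of scope, as are sway dynamics,
  turbulence spectra and canopy shading geometry.
* The tropism strains feed the reference configuration; the planar
  simulator uses the printed relaxed-curvature seed and records the 3-D
  strain triple as a diagnostic.
* DBH is constant over time within the model (static height profile); the
  taper's two anchors absorb cultivation-practice variation but cannot
  express girth dynamics.
* How the sunlight total converts into a deflection angle is not
  specified by the model; $\theta_S$ is an input.
* The frustum second moment is density-weighted and asymmetric in its
  radii; it is used as printed, under the absolute-value convention.
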