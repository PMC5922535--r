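---
title: "Critically balanced network dynamics: model, solvers, and experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Critically balanced network dynamics: model, solvers, and experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`critnet` simulates a network of complex-valued neural amplitudes
$x \in \mathbb{C}^N$ evolving under the normal-form equation

$$\dot x_i = \sum_j A_{ij} x_j - |x_i|^2 x_i + I_i(t),$$

where $A$ is a real *skew-symmetric* coupling matrix, the cubic
nonlinearity is purely local (it never couples distinct neurons), and
$I(t)$ is the external drive.  Skew-symmetry is the model's one structural
assumption and carries all of its content: every eigenvalue of $A$ is
purely imaginary, $\lambda = i\omega$, so every eigenmode sits exactly at
the edge of instability.  The linearization neither decays nor grows —
the center manifold is full-dimensional — and the system's effective
spatial range, gain, and relaxation times are set by the *input* through
the nonlinearity rather than by the linear circuitry.  This is the
dynamical-criticality picture of primary visual cortex: receptive-field
size, lateral integration, and response latency all become functions of
stimulus contrast.

The standard topology is a 1-D chain of alternating excitatory and
inhibitory neurons with equal-strength nearest-neighbour connections,

$$A_{ij} = (-1)^j\, s\, (\delta_{i,j+1} + \delta_{i,j-1}),
  \qquad i, j = 0, \dots, N-1,$$

with activity pinned to zero outside the chain (Dirichlet boundary).
Indices are 0-based throughout the package because the alternating sign
$(-1)^j$ is defined that way.  The eigenfrequencies follow the cosine
band $\omega_k = 2s\cos(k\pi/(N+1))$ — the test suite checks this closed
form to $10^{-10}$ — so the default $s = 1$ puts the spectral edge at
$\omega = 2$ and, for $N = 64$, places the 2nd/4th/6th-largest
eigenfrequencies at 1.99, 1.96, 1.92.  A ring variant with periodic
boundaries (orientation space) and optional long-range skew couplings is
also provided, as are user-supplied matrices, which are accepted only if
skew-symmetric within $10^{-12}$ — criticality is the model, so
dissipative matrices are rejected rather than repaired.

Odd-sized skew matrices always have a zero eigenvalue, so odd-$N$
networks carry an exact DC mode: direct-current input of the kind used in
physiological experiments where the stimulus is not flashed.

## Forced limit cycles by harmonic balance

For monochromatic drive $I(t) = F e^{i\omega t}$ the ansatz
$X(t) = Z e^{i\omega t}$ reduces the ODE to the algebraic balance

$$0 = (A - i\omega I)Z - |Z|^2 \circ Z + F,$$

solved by multivariable Newton–Raphson on the realified system
($\tilde Z = [\mathrm{Re}\,Z; \mathrm{Im}\,Z]$, analytic $2N \times 2N$
Jacobian).  Numerical choices, all exposed as arguments:

* **Tolerance** $10^{-10}$ on the residual max-norm of the realified
  system; **iteration budget** 100.  These are package defaults chosen to
  leave ample margin against the $10^{-8}$-level assertions in the tests.
* **Seeding.**  Newton cannot start at $Z = 0$ when $\omega$ is an
  eigenfrequency — the Jacobian is exactly singular there (resonance).
  The default seed is the componentwise signed cube root
  $Z^{(0)}_k = |F_k|^{1/3}\mathrm{phase}(F_k)$, which solves the resonant
  balance $|Z|^2 Z = F$ exactly in the uniform-mode limit
  ($|Z| = (NB)^{1/3}|v|$ on a fully driven ring; $|Z| = B^{1/3}$ for a
  single oscillator — the cubic-root compression of a critical Hopf
  oscillator).
* **Damping.**  A full Newton step is halved (up to 20 times) whenever it
  fails to reduce the residual max-norm; accepted full steps reproduce
  the undamped iteration.
* **Degenerate forcing.**  Point forcing at a node of the driving
  eigenvector leaves the resonant operator essentially unperturbed and
  the Jacobian numerically singular at the seed.  `newton_solve()` raises
  a typed error by default (`regularize = FALSE`); the continuation sweep
  retries such cells with a Levenberg–Marquardt step, which escapes the
  singular origin and then converges quadratically.
* **DC mode.**  For $\omega = 0$ with real forcing the iteration runs on
  the $N$-dimensional real subsystem, and the returned amplitude is
  exactly real.
* **Branch selection.**  The cubic balance can admit multiple solutions.
  The canonical branch is the one reached by continuation from weak
  forcing: `continuation_sweep()` warm-starts each (strength,
  half-length) cell from its nearest solved neighbour, ascending in both
  coordinates.  Stability is verified per cell — by forward integration
  of a perturbed state (the defining check, `method = "integrate"`) or by
  the sign of the realified Jacobian spectrum (`method = "eigen"`, the
  experiment default; at a hyperbolic fixed point the two agree, and the
  linearized check is orders of magnitude cheaper on a grid of thousands
  of cells).

## Transients in the rotating frame

The lab-frame ODE is stiff: the drive injects fast oscillations at
$\omega$ on top of slow amplitude relaxation.  The substitution
$x = y e^{i\omega t}$ makes the system autonomous,

$$\dot y = (A - i\omega I) y - |y|^2 \circ y + F,$$

and non-oscillatory in the quantities of interest, since
$|x_i| \equiv |y_i|$.  Integration uses `deSolve::zvode` (variable-order
BDF for complex systems) at `rtol` $10^{-9}$, `atol` $10^{-12}$.
Transients start from rest, $x(0) = 0$ — a stimulus-onset experiment —
and stop early once every neuron's modulus is within the numerical floor
$\max(10^{-10}, 10^{-8}\max_i |Z_i|)$ of the limit cycle.  A lab-frame
integrator is included purely as a cross-check; the test suite verifies
frame-independence of the moduli to $10^{-6}$.

## Measuring decay constants

Response latency is quantified by the exponential decay constants of
$r(t) = \bigl||x_c(t)| - |Z_c|\bigr|$.  The fitter (`fit_decay_segments`)
works on $\log r(t)$ and deals with three artefacts of real traces:

1. **Interference nulls.**  Network transients are mode mixtures, so
   $|x_c(t)|$ repeatedly crosses $|Z_c|$, sending $\log r$ to $-\infty$
   at isolated times.  Segments are therefore fit on the *upper envelope*
   of $\log r$ (samples not exceeded within a short look-ahead window),
   which tracks the decay amplitude through the nulls.
2. **Integrator noise floor.**  Once $r$ reaches the numerically
   resolvable level, $\log r$ flattens into noise.  The fit stops when
   the envelope first comes within 1.5 natural-log units of its eventual
   minimum.
3. **Rate blending.**  A straight line through a *sum* of exponentials
   blends the rates near the changepoint.  After the exhaustive
   single-changepoint search (least total squared error), the early rate
   is refined by classical curve peeling: subtract the extrapolated late
   component and refit on the positive remainder.  The refinement
   auto-skips when the subtraction leaves too few points, e.g. for an
   onset transient whose late segment is the *faster* one.

A two-segment model is accepted only if it beats the single line, both
slopes are negative, each segment keeps `min_segment_points` samples,
and the slope magnitudes differ by at least 1.5×; `"fast"`/`"slow"`
labels go by slope magnitude.  `synthetic_trace()` generates
seed-deterministic multi-exponential fixtures with known ground truth for
validating the fitter (pure and noisy sums, piecewise-continuous
segments); the test suite requires recovery within 1–5%.

For a single oscillator the linearization at $z^* = B^{1/3}$ has rates
$3B^{2/3}$ (amplitude direction) and $B^{2/3}$ (phase direction), in
exact ratio 3.  A subtlety worth recording: the *modulus* observable sees
the phase mode frequency-doubled ($|z^* + ib e^{-\sigma t}| - z^* \propto
e^{-2\sigma t}$), so the ratio-3 statement is tested on the state-space
distance $|y(t) - Z|$, while from rest (real forcing) the phase direction
is never excited at all and the trace shows the single $3B^{2/3}$ regime.

## The experiments and their presets

All experiment conditions are fixed choices shipped as presets; none is
randomised, and the only randomness anywhere in the package is the
seed-controlled noise of the fixture generator.

**Length–response (`length_response`).**  $N = 64$, $s = 1$, centre
neuron 32, eigenvector-patterned input windows of $2l+1$ neurons
($l = 0..32$, clipped at the boundary; reported length is the covered
count), strengths $B = 2^i$, $i = -10..2$ — spanning "very weak" to
"strong" on the base-2 grid, since input strength is taken linear in
stimulus contrast.  Driving modes of rank 1–6 cover the top of the
cosine band including the strongly suppressing eigenfrequencies
1.92/1.96/1.99.  Every plotted point is a converged,
stability-verified steady state; the package asserts that the weakest
curve rises monotonically over the whole length range and that the peak
length is non-increasing in strength.

**Suppression map (`suppression_map`).**  The $\omega \approx 1.92$ mode
at strong drive $B = 4$.  Readout centres are chosen programmatically
from the eigenvector-modulus profile (`mode_extrema`): its zeros, its
antinodes, and intermediate positions.  The suppression index of a curve
is defined here as the drop from its maximum to its value at the longest
input, relative to the maximum (zero for monotone curves) — the package's
own formalisation of "suppression beyond the maximum".  Neurons near
modulus zeros suppress most; antinode neurons stay below 0.05.

**Decay scan (`decay_scan`).**  $N = 32$, near-network-size input length
29 ($l = 14$) centred at neuron 16, strengths $2^{-10}..2^{2}$.  The
driving eigenfrequency is not dictated by the phenomenon, and we use the
rank-1 (band-edge, $\omega \approx 1.99$) mode: the $B^{2/3}$ law is an
asymptotic statement about the linearized rates, and the band edge gives
the cleanest two-regime traces over this strength range, whereas
mid-band modes mix more interfering eigendirections and bias the fitted
exponents low.  The integration horizon adapts per strength to ~28
e-foldings of the slowest linearized rate read off the Jacobian
spectrum.  Log–log regression of the fitted constants against $B$ is done
separately for the fast and slow regimes; slopes are base-invariant.

**Orientation ring (`orientation_ring`).**  Ring of 32 neurons, $s = 1$,
plus one long-range coupling at offset 2 (strength 1), driving mode
rank 2, strengths $2^{-4}..2^{2}$, readout at the minimum of the driving
eigenvector's modulus.  The reasoning: the plain alternating ring admits
a *signed shift* symmetry (a one-step translation composed with a gauge
sign pattern; the package constructs it explicitly to disambiguate
degenerate eigenpairs), so its eigenvector moduli are uniform and no
position is special — suppression indices are equal at every centre and
essentially nil.  An even-offset long-range coupling breaks the signed
shift, splits the travelling-wave pairs into standing waves with modulus
zeros, and surround suppression in orientation space appears; odd
offsets preserve the symmetry.  Forcing windows wrap around the ring
(orientation space is periodic) instead of clipping.

## What the simulations do and do not show

Everything here is self-generating: the "data" are trajectories and
fixed points of the model itself, so passing tests demonstrate that the
implementation realises the model's mathematics (closed forms, scaling
covariances, gauge invariance, the $2/3$ exponents), not that cortex
obeys the model.  The contact with experiment is qualitative:
contrast-dependent summation length, suppression tied to a spatial
pattern, latency shrinking with contrast as a power law.  In particular
the input is strictly monochromatic and eigenvector-shaped; realistic
stimuli are broadband in space and time.  Noise is absent from the
dynamics; the fixture generator's multiplicative noise exists to
exercise the fitter, not to model biology.  The suppression index and
the decay-segment acceptance rules are measurement conventions of this
package; other conventions would shift numbers but not the structure of
the results.

## Problem sizes and determinism

The shipped configurations run on one CPU in well under an hour: the
full length-response grid (6 modes × 13 strengths × 33 lengths of
$2N = 128$-dimensional Newton solves) in ~20 s, the decay scan (13 stiff
integrations of an $N = 32$ complex system, horizons up to ~8000 time
units at the weakest strength) in ~5 s, the suppression map in ~7 s.
Every experiment is deterministic; `write_outputs()` records the full
effective configuration in a JSON manifest alongside CSVs printed at 12
significant digits, and re-running a configuration reproduces the CSV
numeric content exactly.

## Known limitations

* The dispersion fit reports the elliptical form
  $\omega^2 = \mathrm{scale} - c^2 k^2$ with its $R^2$; on the finite
  Dirichlet chain the relation is cosine-shaped, so the ellipse is an
  approximation whose adequacy the caller must judge (for $N = 64$,
  $R^2 \approx 0.94$ as computed by the `dispersion` CLI subcommand).
* Spatial frequency is read off the modulus envelope; modes $k$ and
  $N+1-k$ share an envelope, so the assignment is unambiguous only for
  the $\omega > 0$ half-band kept by `eigenmodes()`.
* The changepoint fitter considers at most two regimes; traces mixing
  three or more well-separated rates would need the peeling generalised.
* `verify_stability(method = "integrate")` certifies return to within
  $10^{-6}$ along one deterministic perturbation direction; it is a
  strong practical check, not a basin proof.
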