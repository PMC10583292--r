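---
title: "Double-rotation gradient waveforms: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-rotation gradient waveforms: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dorwave)
```

## The problem this package addresses

Diffusion NMR and MRI encode translational motion with time-dependent
magnetic field gradients $\mathbf{g}(t)$.  Two largely independent axes of
experimental design have emerged.  *Oscillating-gradient* methods tune the
temporal frequency content of the encoding to read out the
frequency-dependent diffusivity $D(\omega)$ of restricted compartments:
slow encoding sees the long-time, restricted diffusivity, fast encoding
approaches the bulk value.  *Tensor-valued* (b-tensor) methods shape the
encoding tensor
$\mathbf{b} = \int \mathbf{q}(t)\mathbf{q}(t)^{\mathsf T}\,\mathrm dt$,
where $\mathbf{q}(t) = \gamma \int_0^t \mathbf{g}\,\mathrm dt'$ is the
dephasing vector, to disentangle microscopic anisotropy from orientation
dispersion: linear ($b_\Delta = 1$), spherical ($b_\Delta = 0$) and planar
($b_\Delta = -1/2$) encodings weight anisotropic domains differently even
in a powder.

`dorwave` implements a waveform family that spans both axes with one
closed-form parameterization: a *double rotation* (DOR) of the q-vector
direction, borrowed from solid-state NMR, where the magic-angle cone
averages second-rank anisotropy.  The unit vector

$$\mathbf{u}(t) = R_z(\psi_2)\,R_y(\zeta_2)\,R_z(\psi_1)\,R_y(\zeta_1)
\,\hat{\mathbf z},$$

with active $Z$–$Y$ rotations applied right to left, two inclinations
$\zeta_1,\zeta_2$ and coupled rotation angles $\psi_1 = n\,\psi_2$, sweeps
the q vector on a two-cone trajectory.  The scalar magnitude $q(t)$ comes
from a conventional dephase/rephase lobe pair $g_{1\mathrm D}(t)$, and the
outer angle grows with the accumulated squared dephasing,
$\psi_2(t) = \Delta\psi_2 \int_0^t q^2 \mathrm dt' / b$, so rotation is
fastest where encoding power is concentrated.  Differentiating
$q(t)\mathbf u(t)$ gives the playable gradient as a sum of oscillations at
$(n\pm1)\psi_2$ and $n\psi_2$ with amplitudes

$$a_0 = \cos\zeta_1\cos\zeta_2,\quad a_1 = \sin\zeta_1\sin\zeta_2,\quad
a_2 = \cos\zeta_1\sin\zeta_2,\quad
a_\pm = \tfrac{1}{2}\sin\zeta_1(\cos\zeta_2 \pm 1).$$

At $\zeta_1 = 90°$, $\zeta_2 = -\arccos(1/\sqrt3) \approx -54.74°$ and
integer $n > 1$ the time-averaged tensor
$\int \mathbf u \mathbf u^{\mathsf T} \mathrm dt$ is isotropic, and
component-wise rescaling by $\sqrt{1 - b_\Delta(1+b_\eta)}$,
$\sqrt{1 - b_\Delta(1-b_\eta)}$, $\sqrt{1 + 2 b_\Delta}$ then dials any
admissible anisotropy $b_\Delta$ and asymmetry $b_\eta$ while preserving
the trace $b$ and the per-axis frequency content.  Varying $n$ moves the
spectral content (the centroid frequency $\omega_\mathrm{cent}$, the first
moment of the one-sided trace of the encoding spectrum
$\mathbf b(\omega) = \mathbf q(\omega)\mathbf q(-\omega)^{\mathsf T}/2\pi$)
while $b_\Delta$ moves the tensor shape — a 2D acquisition space from a
handful of trigonometric expressions.

Forward signal models close the loop: the general attenuation exponent is
$\beta = \int \mathbf b(\omega) : \mathbf D(\omega)\,\mathrm d\omega$,
with $\mathbf D(\omega)$ built from the Lorentzian expansion of restricted
diffusion in planar, cylindrical or spherical compartments
($\Gamma_k = \xi_k^2 D_0 / r^2$, $w_k = 2/(\xi_k^2 + 1 - d)$, roots of
$\xi J_{d/2-1}(\xi) = (d-1) J_{d/2}(\xi)$), or from frequency-independent
axisymmetric tensors.  For randomly oriented axisymmetric Gaussian domains
the orientation average has the closed form

$$\bar S = S_0 e^{-b D_\mathrm{iso}} \frac{\sqrt{\pi}}{2}
e^{A/3} \frac{\operatorname{erf}\sqrt{A}}{\sqrt{A}},
\qquad A = 3 b D_\mathrm{iso} b_\Delta D_\Delta.$$

A Monte Carlo random-walk engine with phase tracking validates the
Gaussian-phase signal expression $E = \exp(i\alpha - \beta)$, with
$\alpha = \mathbf q_v \cdot \langle\mathbf v\rangle$ (flow) and $\beta$
half the phase variance, against the spectral $\beta$ above.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `tau` | single-waveform duration (s) | 25 ms | benchmark protocol duration |
| `n_ratio` | rotation frequency ratio | 0–5 in the grid | sets $\omega_1 = n\Delta\psi_2/\tau$, $\omega_\pm = (n\pm1)\Delta\psi_2/\tau$ |
| `b_delta`, `b_eta` | encoding anisotropy/asymmetry | grid $\{-0.5, 0, 0.5, 1\}$, $\eta = 0$ | tensor shape |
| `dpsi2` | total outer rotation (deg) | 360 | must be a multiple of 360 for a refocused, isotropic-capable rotation |
| `eps_up`, `eps_down` | quarter-sine / half-cosine ramp fractions | 0.03 / 0.12 (grid), 0.015 / 0.06 (worked example) | hardware-realistic lobes; their finiteness causes all "non-ideality" deviations below |
| `zeta1`, `zeta2` | rotation-axis inclinations (deg) | $0, +54.7356$ for $n=0$; $90, -54.7356$ otherwise | exact magic angle $\arccos(1/\sqrt3)$; see below |
| `g_max` | peak gradient (T/m) | 3 | high-gradient microimaging hardware |
| `n_samples` | time grid | $2^{15}$ | see numerics |
| `K` | Lorentzian truncation | 50 | raw weights sum to $1 - O(10^{-3})$; renormalized so $D(0) = D_\infty$ exactly |
| `n_spins`, `dt` | walker ensemble | $10^4$, $\tau/10^4$ | desk-scale runtimes; step guards enforce $\ge 50$ steps per oscillation and step length $\le r/5$ |

Angles are degrees at every interface and radians internally; frequencies
are rad/s internally and Hz in every report.  Everything else is SI.

## The synthetic world, and what a green test does not establish

`synth_phantom()` emulates three benchmark samples with well-defined
diffusion properties:

* `two_iso` — two isotropic Gaussian components (water plus a saturated
  brine), defaults $D = 2.0$ and $0.4\,\mu\mathrm m^2/\mathrm{ms}$ with a
  0.6 fast fraction.  Its signal depends on $b$ only, so all 24 waveforms
  must collapse onto one master curve — a sharp test that the identical-$b$
  normalization is real.
* `lamellar_powder` — randomly oriented planar domains,
  $D_\parallel = 0$, $D_\perp = 1.5\,\mu\mathrm m^2/\mathrm{ms}$
  ($D_\Delta = -1/2$), generated from the closed-form powder average with
  each waveform's *recomputed* $b_\Delta$.  Signals stratify by $b_\Delta$
  and ignore $\omega_\mathrm{cent}$.
* `yeast` — spherically restricted intracellular water ($r = 2.5\,\mu$m,
  $D_0 = 1.0\,\mu\mathrm m^2/\mathrm{ms}$, impermeable walls, fraction
  0.55) plus free extracellular water
  ($1.2\,\mu\mathrm m^2/\mathrm{ms}$); the restricted exponent is the
  numerical integral of each waveform's trace encoding spectrum against
  the Lorentzian spectrum, so signals depend strongly on
  $\omega_\mathrm{cent}$.

Defaults were chosen once as field-realistic values (aqueous diffusivities
at room temperature, yeast-cell radii) and are not tuned.  Noise is
additive Gaussian on the normalized signal (Rician optional), the same for
every entry.  The generator deliberately omits relaxation weighting,
imaging gradients and their cross-terms, exchange, permeable walls in the
walker, gradient nonlinearity, and eddy currents.  A green recovery test
therefore establishes the self-consistency of the synthesis–analysis chain
(waveform → spectrum → forward model → fit) under the stated noise — not
robustness to the systematic effects a spectrometer adds.

## Numerical choices

* **Time grid** — uniform, $2^{15}$ samples per waveform, trapezoidal
  (cumulative) integration.  The narrowest supported ramp ($0.015\tau$)
  is then resolved by ~500 points and all stated $10^{-6}$ consistency
  tolerances hold with margin; $2^{14}$ is enough for the standard-grid
  ramps but marginal for the narrow ones.
* **Gradient construction** — the closed trigonometric form is the exact
  derivative of $q(t)\mathbf u(t)$ once its sign conventions are fixed,
  which this implementation did symbolically; a fourth-order
  finite-difference derivative of the trajectory is kept as an independent
  oracle (`dor_numeric_gradient()`) and the two agree to better than
  $10^{-6}$ relative max-norm across the waveform grid.  The closed form
  is emitted because finite differences overshoot at the corners of the
  degenerate rectangular lobes.
* **Magic angle** — the printed inclination "54.7°" is a rounding; using
  it leaves a residual $b_\Delta \approx 4\times10^{-4}$.  Defaults use
  $\arccos(1/\sqrt3)$ exactly (`magic_angle()`).
* **Spectra** — FFT with 8-fold zero padding under the
  $e^{+i\omega t}$ transform convention; only the one-sided grid is
  stored with weights that restore two-sided integrals.  The two-sided
  first moment of a real waveform's power spectrum is identically zero,
  so $\omega_\mathrm{cent}$ is the one-sided moment ratio
  $\int_0^\infty \omega\,b(\omega)\mathrm d\omega /
   \int_0^\infty b(\omega)\mathrm d\omega$, which recovers the carrier of
  a narrowband waveform.
* **Haeberlen ordering** — eigenvalues ordered by deviation from the
  isotropic mean; degenerate deviations broken by descending eigenvalue,
  and $b_\eta := 0$ at the isotropic point where its ratio is singular.
* **Identical-b normalization** — each grid waveform is generated at unit
  amplitude, the attainable $b \propto (g_\mathrm{max}/\max|g|)^2$ is
  computed per waveform (as a bracketing pair, which doubles $b$), and
  the whole set is scaled to the minimum — the most gradient-demanding
  member ($n = 5$, $b_\Delta = 1$) pins the protocol at about
  $6.43\times10^9\,\mathrm{s\,m^{-2}}$ for $\tau = 25$ ms at 3 T/m.
* **Bracketing** — the effective gradient changes sign after the
  refocusing pulse; the pair's dephasing trajectory is assembled from the
  exact single-waveform trajectory so refocusing is exact; default gap 0
  (the pulse duration is not modeled), configurable.
* **Powder average** — the $A \to 0$ limit is series-expanded below
  $|A| < 10^{-4}$; $A < 0$ (mixed-sign $b_\Delta D_\Delta$) uses the
  analytic continuation through the imaginary error function, computed by
  a cancellation-free Maclaurin series with an asymptotic tail.
* **Spectral compression for fitting** — the padded trace spectra
  (~$10^5$ bins) are compressed to $\le 1024$ quadrature nodes per
  waveform that conserve per-bin power and first moment; the restricted
  spectrum is smooth on that scale, so fitted exponents are unaffected
  while each objective evaluation stays at ~$10^6$ flops.
* **Fitting** — box-constrained quasi-Newton (L-BFGS-B) from 8 seeded
  random starts, with diffusivities in $10^{-9}\,\mathrm m^2/\mathrm s$
  and radii in $\mu$m so every parameter is $O(1)$ for the numerical
  gradients.  The anisotropy fit adds three deterministic coarse-grid
  seeds because the powder objective has a local minimum of opposite-sign
  anisotropy.  Residuals are on the *linear* signal: this is the Gaussian
  maximum-likelihood objective, and log-residuals were found to bias the
  lamellar isotropic diffusivity by tens of percent at 1 % noise because
  the planar-encoded powder signal falls to the noise floor at high $b$.
* **Walker engine** — compiled (Rcpp) specular reflection with sub-step
  backtracking, uniform initial positions, phases by trapezoidal
  integration of $-\gamma\,\mathbf g\cdot\mathbf r$, driven by R's RNG so
  `set.seed()` governs reproducibility.

## Open design points, decided

* $\Delta\psi_2$ applies per waveform of a bracketing pair (each copy
  completes a full rotation); the pair's centroid frequency agrees with
  the single waveform's to ~1 %.
* Protocol $b$ shells are linear, $b_\mathrm{max}\cdot k/8$, with the
  reference signal taken separately at $b = 0$; the source protocol does
  not print its shell spacing.
* The 15 protocol orientations and the $10^4$-orientation powder oracle
  use a deterministic Fibonacci sphere covering (quasi-uniform,
  reproducible without an RNG); an electrostatic-repulsion set would
  differ only in the third decimal of powder averages.
* The Lorentzian truncation order for the restricted fit is exposed
  (`K`, default 50) since the reference analysis does not state its
  value.

## Known limitations

The $n = 1$ grid member sits outside the exact-isotropy condition
($n > 1$): its recomputed $b_\Delta$ deviates from the request by up to
0.034 (others stay within 0.02), and the single-waveform flow
compensation at $(n = 1, b_\Delta = 1)$ is only approximate for finite
lobes — the bracketing pair, however, nulls the flow vector exactly for
every member.  Spectral main peaks sit at the plateau instantaneous
frequency, a factor $q_\mathrm{max}^2\tau/b \approx 1.13$ above the
idealized $(n\pm1,n)\,\Delta\psi_2/\tau$ for the standard ramps.  Slew
rate and duty cycle are not constrained; concomitant fields, eddy
currents and cross-terms with imaging gradients are out of scope, as are
exchange and surface relaxation in both the analytic spectra and the
walker.
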