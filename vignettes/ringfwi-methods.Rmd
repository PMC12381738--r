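---
title: "Frequency-domain full waveform inversion for ring-array ultrasound tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain full waveform inversion for ring-array ultrasound tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The imaging problem

Ring-array ultrasound tomography surrounds the breast with a circular
transducer array in a water bath and reconstructs the tissue's sound-speed
map from transmitted ultrasound. Clinically deployed systems use a single
ring and reconstruct one axial slice at a time with two-dimensional
frequency-domain full waveform inversion (FWI); the resulting volumes are
sharp in-plane but blurred in elevation, because a single row of receivers
cannot sample the out-of-plane wavefield. `ringfwi` implements the
fully three-dimensional alternative: a multi-row ring array (by default 32
rows of 256 elements, 22 cm diameter, 2.4 mm row pitch — 8192 elements)
fired as *cylindrical waves* — the same circumferential element in every
row pulsing simultaneously — and a volumetric 3D FWI that inverts all 8192
channels per transmit at once, together with the slicewise 2D baseline it
is compared against.

## Forward model

Single-frequency acoustics in a medium with slowness $s(\mathbf x) = 1/c(\mathbf x)$
obeys the Helmholtz equation

$$(\nabla^2 + \omega^2 s^2)\, u = \delta,$$

abbreviated $A(\omega, s)\,u = \delta$ after discretization on a Cartesian
grid. The array only observes $p = K u$, where $K$ samples the field at the
element positions, treating elements as ideal points; off-grid elements are
handled with a trilinear (bilinear in 2D) stencil, and the *same* stencil
deposits sources, so $K$ and $K^T$ are exact transposes by construction.

### Discretization

$A$ is the second-order central-difference Laplacian plus the diagonal
$\omega^2 s^2$, on the field grid extended by an absorbing layer and closed
periodically. In the layer the squared wavenumber acquires an imaginary
part rising with a cosine-squared taper to `absorption` $\times\,k_{\rm bg}^2$
at the boundary, where $k_{\rm bg}$ comes from a *fixed* layer slowness
(`pad_slowness`, by default the median boundary slowness; inversions pin it
to the starting model so the layer does not move with the model and
gradients stay exact). The grid must be isotropic and is checked for at
least 4 points per minimum wavelength. Padded extents are rounded up to
5-smooth integers for FFT efficiency.

### Convergent Born series

`solve_helmholtz()` solves the discrete system with the convergent Born
series: writing $A = M + V$ with $M = \nabla^2_h + k_0^2 + i\varepsilon$
and $V = \operatorname{diag}(k^2) - k_0^2 - i\varepsilon$, the
preconditioned fixed-point iteration

$$u \leftarrow u + \tfrac{i}{\varepsilon} V\,\big[M^{-1}(\delta - V u) - u\big]$$

contracts whenever $\varepsilon \ge \max_x |k^2(x) - k_0^2|$. $M^{-1}$ is
applied exactly by FFT using the *finite-difference* symbol
$-\tfrac{4}{h^2}\sum_d \sin^2(\pi m_d / N_d)$, so the series converges to
the solution of the identical sparse matrix the oracle assembles — this is
what makes solver cross-checks meaningful at $10^{-6}$ rather than at
discretization error. Defaults: $k_0^2$ at the midpoint of the range of
$\mathrm{Re}\,k^2$, $\varepsilon$ at 1.05 times the contraction bound,
relative-residual tolerance $10^{-6}$ (relaxed in inversion loops, below),
at most 1000 iterations, residual checked every 4 iterations.

The adjoint system $A^H \lambda = r$ is solved through the complex-symmetry
identity $A^T = A$ (symmetric stencil, diagonal potential):
$\lambda = \overline{A^{-1} \bar r}$, so one solver serves both directions
and the identity is testable to machine precision.

### The direct oracle

`assemble_direct_operator()` returns the explicit sparse triplets of the
same padded operator and refuses grids beyond direct-factorization size.
`method = "direct"` solves it by a sparse Cholesky factorization of the
Hermitian positive-definite normal matrix $A^H A$ (real symmetric
positive-definite $2n$ embedding, CHOLMOD supernodal), followed by
iterative refinement against the stored triplets until the true residual
reaches machine level, so the squared conditioning of the normal equations
does not limit accuracy. On every oracle-sized problem we use (up to
$24^3$ discrete unknowns in 3D including the layer, up to $64^2$ in 2D)
the refined solutions agree with the series to better than $10^{-6}$ and
reach residuals near $10^{-14}$.

## Inversion

Per frequency, FWI minimizes the waveform misfit
$E(\omega, s) = \tfrac12 \sum_i \lVert p_i - p_{\mathrm{obs},i}\rVert^2$
over cylindrical-wave transmits $i$. Because the physical excitation's
amplitude and phase are unknown, each iteration first estimates a complex
per-transmit source scale by least-squares projection,
$\gamma_i = (p_i^H p_{\mathrm{obs},i}) / (p_i^H p_i)$, and rescales
$\delta_i, u_i, p_i$ by $\gamma_i$. The adjoint-state gradient is then

$$\nabla_s E = -\sum_i \mathrm{Re}\!\left[\overline{(2\omega^2 s \odot u_i)}
\odot \big(A^{-H} K^T (p_i - p_{\mathrm{obs},i})\big)\right],$$

one forward and one adjoint solve per transmit. The gradient is zeroed
outside a cylindrical support mask at the ring radius: outside the array
no data constrain the model, and the absorbing layer is internal to the
solver and never part of the model vector.

Updates use Polak–Ribière+ nonlinear conjugate gradients restarted at each
frequency (and whenever the direction fails to descend), with a
backtracking Armijo line search ($c = 10^{-4}$, shrink 0.5, at most 20
trials). The first trial step at each frequency is scaled so the largest
sound-speed change is `max_dc_first` (10 m/s); accepted steps seed the next
search optimistically at twice the accepted step. After every trial the
model is clipped to 1300–1700 m/s. The optimization variable is slowness
throughout; conversion to m/s happens only at output. Frequencies are swept
low to high (default 200–800 kHz in 50 kHz steps, 5 iterations each), each
warm-starting from the previous frequency's model — the standard multiscale
continuation that builds long-wavelength structure before detail.

`run_slicewise_fwi()` is the 2D baseline: assuming no elevational
sound-speed variation, each receiver row is treated as sampling one axial
slice; per row, a 2D inversion uses only that row's receivers per transmit
and a single-point 2D source at the transmit azimuth, and the slice
reconstructions are stacked into a volume by nearest-row assignment of the
grid's z levels. The per-transmit source scales absorb the gross amplitude
and phase mismatch between 2D and 3D propagation, but not its range
dependence — which is precisely the modelling error that makes the
volumetric inversion win when out-of-plane structure is present.

## Synthetic phantoms and data

`phantom_spec()`/`generate_phantom()` build a parametric numerical breast:
a water bath (1500 m/s) containing an ellipsoidal breast of subcutaneous
fat (1440 m/s), an optional skin shell (1600 m/s), smooth fibroglandular
blobs (1560 m/s) and spherical lesions (1580 m/s), rasterized and smoothed
with a Gaussian (default 2 mm) before conversion to slowness. All tissue
speeds sit inside the 1400–1600 m/s window conventional for breast
sound-speed display; random blob placement is reproducible from the seed.
These phantoms emulate the *structure* of anthropomorphic numerical
breasts — piecewise tissue classes with smooth interfaces and out-of-plane
variation — but not their anatomical realism; passing recovery tests on
them demonstrates correctness of the physics and optimization, not
clinical image quality.

`simulate_observed_data()` synthesizes channel data directly in the
frequency domain, one Helmholtz solve per transmit and frequency
($p = K A^{-1}\delta_i$); a broadband time-domain pulse is deliberately not
modelled, since the inversion operates per frequency and the source
projection absorbs any per-frequency spectrum. By default data are
simulated on the inversion grid (the classic inverse crime); `sim_refine`
simulates on a 2× finer grid instead, and the resulting data perturbation
is reported by the test suite rather than asserted, as it mixes genuine
discretization convergence with stencil dispersion. `add_noise()` adds
circular complex Gaussian noise calibrated so its total power sits
`level_db` below the mean signal power of each frequency's matrix
(−20 dB ⇒ noise-to-signal power ratio 0.01, i.e. 20 dB SNR), applied
per frequency and reproducible per seed; the reference power is global per
frequency rather than per channel, a deliberate convention choice. One
caveat specific to desk-scale experiments: the toy acquisitions collect
only a few times as many data values as the model has voxels, so an
unregularized inversion can fit −20 dB noise nearly exactly instead of
averaging it away as the full 256 × 8192 acquisition does; the package's
inversion studies therefore run on noiseless data, and the noise model is
validated by its calibration property separately.

## Evaluation

`evaluate_reconstruction()` reports root-mean-square error (m/s) and
Pearson's correlation coefficient between reconstructed and true
sound-speed volumes. The default region is the whole inversion volume
(there is no absorbing layer to exclude — it lives inside the solver);
an optional mask restricts to tissue. PCC is undefined for constant
inputs and errors rather than returning NA.

## Desk-scale study conditions

The full-scale acquisition (256 transmits × 8192 receivers, 200–800 kHz,
three anthropomorphic phantoms) is cluster-scale computing. The package's
own studies, run by the test suite and `scripts/acceptance.R`, are sized
for a single CPU while preserving every structural feature of the method:

* **2D recovery benchmark** — 64² grid (1.5 mm voxels), 32-element ring of
  4 cm radius, 8 cylindrical transmits, a +2 % Gaussian inclusion,
  100/150/200 kHz with 5 NCG iterations each. The reconstruction reduces
  whole-image RMSE by well over the factor 2 required of it.
* **3D versus slicewise study** — 36³ inversion grid (2.5 mm voxels, 9 cm
  aperture) plus a 6-voxel absorbing layer, i.e. a 48³ solver domain;
  8 rows × 32 elements (3.3 cm radius, 4.5 mm pitch), 16 cylindrical
  transmits, 70 and 100 kHz with 2 NCG iterations each, solver tolerance
  $10^{-3}$; the phantom contains a fibroglandular blob and a lesion both
  displaced in z, so the no-elevational-variation assumption of the
  slicewise baseline is genuinely violated. Volumetric 3D FWI attains
  lower RMSE and higher PCC than the slicewise reconstruction — the same
  ordering reported for full-scale multi-row systems — and on this toy the
  slicewise baseline degrades severely, consistent with unfocused
  cylindrical-wave illumination being a worst case for 2D modelling.
* **Oracle checks** — solver-versus-direct agreement on ≤ 64² (2D) and
  ≤ 24³ (3D, layer included) discrete systems; gradient-versus-finite-
  difference agreement on a 16² toy with the direct solver; adjoint inner-
  product identities; the 3D free-space Green's-function limit
  $|u| \to |e^{ikr}/4\pi r|$ within 5 % at 3–10 voxel radii.

Numerical conventions worth knowing when extending the package: solver
tolerances are relative residuals against the *discrete* operator;
inversion loops relax the solve tolerance (10⁻³–10⁻⁴) since gradient
directions are insensitive to the last digits of the field, while oracle
tests keep 10⁻⁶; line-search failures flag the frequency and move on
rather than aborting; a transmit whose simulated traces are identically
zero is a configuration error and raises immediately; and all randomness
(phantom geometry, noise) flows from explicit integer seeds, never from
the global RNG state, which the generators save and restore.

## Known limitations

Attenuation, density variation and elasticity are outside the model;
slowness is real. Element directivity, finite aperture and cross-talk are
not modelled (elements are reciprocal ideal points). The absorbing layer
is a few-percent-reflection design, adequate for inversion consistency but
not for high-dynamic-range scattering studies; widen `pad_width` and
`absorption` for those. The slicewise baseline models the 2D source as a
single point at the transmit azimuth — the natural 2D restriction of a
cylindrical wave, but one of several defensible conventions. Finally, the
default same-grid simulation commits the inverse crime by design (it is
what makes fixed-point tests exact); use `sim_refine = 2` when the question
is robustness rather than correctness.
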