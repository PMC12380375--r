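# chemholo

Forward and inverse optical models for phase-sensitive mid-infrared
chemical holography, in R.

Mid-infrared spectroscopic imaging measures absorbance, which only probes
the extinction coefficient κ of a sample's complex refractive index
n = m + iκ. Pairing a coherent mid-IR source with an interferometer turns
the same instrument into a holographic one: stepping the reference-arm path
length modulates each pixel sinusoidally, and a small linear system per
pixel recovers the *complex* transmitted field — amplitude and phase. With
phase available, degeneracies that absorbance imaging cannot resolve fall
apart: a layer's real index m and thickness d become separately measurable
once their product (the optical path length P = m·d) is known, and the
ill-conditioned inverse Mie problem of recovering a sphere's (a, m, κ)
becomes markedly easier for a learned regressor.

The package implements, for researchers in quantitative phase and
vibrational imaging:

* a **coupled-wave solver** for plane waves crossing stacks of homogeneous
  layers (continuity of tangential E and H plus per-wave transversality;
  6(L−1) equations for L layers), validated against Fresnel and thin-film
  closed forms;
* a **scalar Mie model**: partial-wave coefficients
  B_t = (2t+1) i^t [j_t(ka) j_t′(kna) n − j_t(kna) j_t′(ka)] /
  [j_t(kna) h_t′(ka) − h_t(ka) j_t′(kna) n], 2-D fields, 1-D radial far
  fields, order-0 discrete **Hankel transforms** on the Bessel-zero grid,
  and annular **numerical-aperture band-limiting** (fl = NA_in/λ,
  fu = NA_out/λ);
* **interferogram synthesis and reconstruction**: I(m) = |E_S|² + |E_R|² +
  E_S E_R* e^(−ikΔ_m) + c.c., consecutive-difference least squares via the
  Moore–Penrose inverse, E_S = u / (E_R (e^(−ikδ) − 1)); three frames
  suffice;
* a **grid-search layered inversion** recovering (m, d) by wrapped-phase
  matching over candidates with m_i d_i = P, then κ by amplitude matching;
* an **inverse-Mie network pipeline**: 27,000-sphere factorial corpora,
  a 5-hidden-unit tanh network (Glorot init, Adam, 400 epochs, batch 200)
  trained on complex vs. square-root-intensity representations, per-label
  relative RMSE ε_R, and Gaussian-noise / aperture / two-sphere robustness
  sweeps.

## Worked example

Simulate a hologram of a 1 µm sphere (n = 1.5 + 0.03i, λ = 1 µm, 16 µm
field of view, 32 phase steps over 2 µm), reconstruct the complex field
from the first three frames, then invert a layered sample from its optical
path length:

```r
library(chemholo)

sph <- mie_sphere(1, 1.5 + 0.03i)
fld <- scattered_field_2d(sph, wavelength = 1, n_pixels = 128, fov = 16,
                          plane = "horizontal", total = TRUE)
ig  <- simulate_interferogram(fld, e_ref = 1 + 0i, deltas = (0:31) * 2 / 32)
ig
#> <interferogram> 32 frames of 128 x 128, step 0.0625 um, lambda 1 um

rec <- reconstruct_field(ig, e_ref = 1 + 0i, n_frames_used = 3)
rec
#> <reconstructed_field> 128 x 128 from 3 frames, max residual 2.341e-16
```

The mean absolute error against the simulated ground-truth field is
`1.51e-15` — the reconstruction is exact up to floating-point rounding, and
any window of at least three frames gives the same answer (two frames leave
the per-pixel system underdetermined).

```r
meas <- simulate_layered_measurement(m = 1.65, d = 1.67, kappa = 0.03,
                                     z_detector = 5.67, wavelength = 1)
prob <- layered_inverse_problem(opl = 1.65 * 1.67, z_detector = 5.67,
                                measured = meas, wavelength = 1)
fit_layered(prob)
#> <layered_estimate> m = 1.65, d = 1.67 um, kappa = 0.03 (phase cost 0.000e+00 rad)
```

All three layer parameters come back exactly (the truth lies on the search
grid): the phase at a detector beyond the stack breaks the m–d degeneracy
that the optical path length alone cannot, and the amplitude then fixes κ.

The network benchmark — corpus generation, paired complex/intensity
training over seeds, held-out relative RMSE per label — runs as

```r
bench <- mie_ann_benchmark(levels_per_feature = 30, seeds = 1:10)
bench$means
```

and takes a few minutes; the complex representation beats the intensity
representation on all three labels. See the methods vignette
(`vignettes/chemical-holography-methods.Rmd`) for the models, conventions
and the numbers to expect.

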