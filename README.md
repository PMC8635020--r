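# myodisarray

Three-dimensional cardiomyocyte orientation mapping and myocyte-disarray
quantification from volumetric fluorescence images of α-actinin–stained
cardiac tissue.

Cardiomyocytes are striated: their sarcomere Z-bands repeat every
1.6–2.0 µm perpendicular to the cell's long axis. In a two-photon stack of
cleared, α-actinin–stained myocardium this periodicity shows up as a pair of
symmetric peaks in the 3D power spectrum of any small tissue block. The
package exploits that: it virtually dissects a volume into 16 µm cubic
chunks, takes each chunk's 3D FFT (zero-padded along the coarse Z axis to a
cubic, near-isotropic frequency grid), band-passes the power spectrum with a
spherical shell matched to the sarcomere band (|f| ≈ 0.5–0.625 µm⁻¹), and
reads the local myocyte axis off the spectral peak. Each chunk gets a
reliability score

  Sratio = Σ S*ₓₓf / Σ S*ₓₓ

(the in-band share of spectral energy, min–max normalized per sample; chunks
above 0.14 are *reliable*). The reliable vectors form a vector field over
the sample from which local disarray is computed in macrovoxels **g** of
m × m × m vectors:

  d_g = (1 − |v̄_g|) × 100    (1 − mean resultant length, in %)
  a_g = mean(v_y)             (alignment with the strip's traction axis)

with global disarray **D** and alignment **A** their means over valid
macrovoxels, at five spatial scales (32–96 µm). Local disarray distributions
(LDDs) are fitted with log-normal models (mode = exp(μ − σ²), the omnibus
D'Agostino–Pearson test on ln d checks log-normality). Because no real
imaging data ship with the package, it also provides:

* a **striated phantom generator** (known ground-truth axis, tunable period,
  duty cycle, PSF blur and noise) and a rotation-accuracy experiment over a
  13 × 13 grid of (θ, φ) rotations, reproducing the ~23° elevation limit set
  by axial sampling (θ_lim = asin(T / (2.3 · z-step)));
* a **virtual tissue simulator**: lattices of 80 × 20 × 20 µm virtual cells
  cut from a striated base volume, each rotated by angles drawn from
  N(θ̄, σθ), N(φ̄, σφ) — sweeping σ calibrates the disarray statistic
  against true cellular misalignment.

## Worked example

```r
library(myodisarray)

# a synthetic striated strip, axis tilted 6 deg out of plane, 14 deg azimuth
ph <- make_striated_volume(phantom_spec(extent_um = c(48, 144, 144),
                                        theta = 6, phi = 14, noise_sd = 6))
field <- analyze_volume(ph$volume, ph$mask, run_config())
field
#> <vector_field> grid 3 x 9 x 9 chunks (16 um); 243 tissue, 207 reliable of 243

dm <- disarray_map(field, m = 3)
glance(dm)
#> # A tibble: 1 x 5
#>       m side_um   N_v        D     A
#>   <int>   <dbl> <int>    <dbl> <dbl>
#> 1     3      48     9 0.000658 0.966
```

The reliable chunks recover the phantom's axis to a mean angular error of
0.8°, and the aligned sample yields a global disarray D under 0.001% —
effectively zero, as expected for parallel fibres. A dispersion sweep shows
how D rises with true cell misalignment:

```r
dispersion_sweep(c(0, 10, 20), analysis_resolution_um = 64, seed = 1,
                 spec = virtual_sample_spec(sample_um = c(320, 120, 100)))
#> sigma = 0:  D ~ 0       mode ~ 0
#> sigma = 10: D ~ 1.3%
#> sigma = 20: D ~ 4-6%
```

A command-line front end covering the whole pipeline
(`preprocess`, `orient`, `disarray`, `stats`, `simulate`, `validate`) is in
`inst/cli/myodisarray`.

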