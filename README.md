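# pemfdose

Computational dosimetry for pulsed electromagnetic field (PEMF)
neurostimulation of the head, aimed at dose–response assessment for
ischemic-stroke neuroprotection studies. The package is for researchers in
bioelectromagnetics and computational dosimetry who need a fully
reproducible, self-contained version of the clinical analysis chain:

1. **Coil model** — a single-turn rectangular stimulation coil
   (0.14 × 0.106 m, 240 A equivalent peak current), with analytic
   finite-segment Biot–Savart fields `B` and vector potentials `A`, and the
   coil-based `d/f/t` analysis frame.
2. **Pulsed signal** — a 75 Hz train of 1.3 ms pulses decomposed into its
   harmonic comb; per-voxel field time courses are recomposed by
   superposition, `x(t) = dc + Σ_k Re[a_k H_k e^{j2πf_k t}]`.
3. **Induced fields** — a scalar-potential finite-difference (SPFD) solver
   for the magneto-quasistatic problem
   `∇·(σ*(∇φ + jωA)) = 0`, `J·n = 0` on the conductor–air boundary,
   `E = −jωA − ∇φ`, `J = σ*E`, with dispersive complex conductivities
   `σ* = σ + jωε₀ε_r` per tissue.
4. **Synthetic phantom** — a layered spherical head (skin/skull/CSF/grey/
   white) with a seeded random hyperintense lesion, MRI-like rendering,
   region-growing segmentation, and a ground-truth lesion evolution law
   (voxel-wise retention probability `min(1, (M/100)e^{aB})`) for
   closed-loop validation.
5. **Dose–response analysis** — exposure histograms over the lesion,
   coil-frame slicing, pre/post volume ratios by exposure range and by
   lower-bound threshold, and the pooled exponential fit `f(x) = M e^{ax}`
   returned as a classed model object with `print`, `summary`, `coef`,
   `predict`, `plot` and `residuals` methods.

The methods vignette (`vignettes/pemf-dosimetry.Rmd`) documents the model,
its assumptions, the numerical choices and the known limitations.

## Worked example

```r
library(pemfdose)

# analytic check: field at the coil center at the 240 A signal peak
coil <- coil_geometry()
1e3 * sqrt(sum(biot_savart_B(coil, matrix(0, 1, 3), current = 240)^2))
#> [1] 2.2719        # mT; closed form: mu0 I sqrt(a^2+b^2)/(pi a b)

# end-to-end synthetic run: phantom -> lesion -> segmentation -> coil ->
# fields -> evolved lesion -> exposure-conditioned ratios -> fit
res <- run_pipeline(demo_run_config(seed = 7), out_dir = "run7")
res$exposure
#> Exposure over 3646 voxels (29168 mm^3): min 1.3, mode 2.02, max 2.35
res$b_table
#>   range_low range_high v_pre_mm3 v_post_mm3     ratio
#> 1       1.0        1.3        24          8 0.3333333
#> 2       1.3        1.7      9752       6568 0.6735029
#> 3       1.7        2.0      9856       6592 0.6688312
#> 4       2.0        Inf      9536       5856 0.6140940
summary(res$fit)
#> Exponential dose-response fit over 8 pooled points
#>   M = 75.899 (SE 1.567)  [percent ratio at zero exposure]
#>   a = -0.1071 (SE 0.0117) [per exposure unit]
```

Reading the output: the whole lesion sits above the ~1 mT level associated
with biological effects; every occupied exposure range has a post/pre
volume ratio below 1 (the lesion shrank everywhere), and the fitted
exponential summarises how the shrinkage deepens with exposure. The run
directory contains the masks and field volumes as NIfTI, the tables as CSV,
the fit as JSON, the resolved configuration and an MD5 manifest.

`dose_response_recovery(seed)` runs one closed-loop validation replicate:
a lesion is evolved under a known law (default `M = 80`, `a = −0.3`) and
the analysis refits it from narrow exposure-band ratios; medians over 20
seeds land within a few percent of the truth.

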