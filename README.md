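# psmp4rage

Quantitative T1 relaxometry for MP2RAGE / MP4RAGE acquisitions at
ultra-high field, for MR physicists and neuroimagers who want accurate
whole-brain T1 maps rather than protocol-dependent ones.

## Why

MP2RAGE converts its UNI image (the normalized combination of two
gradient-echo trains after an adiabatic inversion) into T1 through a
forward signal model that classically assumes an inversion efficiency of
f_inv = 0.96. In brain tissue at 7T the *apparent* efficiency — the
fraction of longitudinal magnetization that a monoexponential model sees
inverted — is far lower (~0.73 in white matter, ~0.84 in gray matter),
because magnetization transfer rapidly redistributes the inversion to the
macromolecular pool and the adiabatic sweep loses magnetization to T2
decay. The result is a systematic T1 underestimation, worst in white
matter.

This package implements the correction end to end:

* a **forward steady-state signal model** of the MP*n*RAGE cycle
  (inversion scaling by −f_inv, free relaxation, closed-form RAGE-train
  propagation; every step affine in m_z, so the periodic steady state is
  an exact fixed point);
* **PS-MP4RAGE fitting**: phase-sensitive processing of four consecutive
  RAGE trains — reference phase from the late trains, signed signals
  S(TI) = S_ss − (S_ss − S_start) exp(−TI/T1\*), voxelwise
  Levenberg–Marquardt fitting, f_inv = −S_start/S(t_C), and
  T1 = [1/T1\* − (fT·α)²/(2·TR)]⁻¹ using an auxiliary B1+ map;
* **robust calibration** of the linear law f_inv = a·R1 + b (CSF and
  globus pallidus excluded, 5th/95th-percentile trimming, cross-subject
  pooling, bisquare IRLS);
* **look-up-table T1 mapping** from UNI images with either a constant or
  the calibrated R1-dependent efficiency, per-fT tables for B1+
  correction;
* a **seeded synthetic brain phantom** (WM/GM/CSF ellipsoids, smooth B1+
  and receiver-phase fields, complex Gaussian noise) for end-to-end
  validation, plus NIfTI I/O and a command-line interface
  (`inst/cli/psmp4rage.R`).

## Worked example

Simulate a phantom acquisition, fit it voxelwise, calibrate the f_inv
law, and map a white-matter voxel's T1 with and without it:

```r
library(psmp4rage)

ph   <- make_phantom(phantom_spec(seed = 1))
acq  <- simulate_acquisition(ph, protocol_psmp4rage(), snr = 200)
maps <- psmp4rage_fit(acq, b1 = ph$fT, mask = parenchyma_mask(ph))
summary(maps)
#> PS-MP4RAGE voxelwise fit
#>   27082 voxels fitted, 27082 valid
#>   quantiles over valid voxels:
#>               q05    median       q95
#> t1      1303.1637 1883.6375 2066.2185
#> t1_star 1194.1710 1644.3149 1823.6445
#> f_inv      0.6984    0.7984    0.8456

cal <- calibrate_pipeline(
  list(maps), list(array(ph$labels %in% c(0L, 3L, 4L), dim(ph$labels))))
print(cal)
#> Calibrated inversion-efficiency model: f_inv = -0.3713 * R1 + 1.0058
#>   n = 21747 pairs (5335 trimmed), IRLS converged in 16 iterations
```

The T1 and f_inv quantiles reproduce the phantom's WM/GM ground truth
(1365/1965 ms; efficiencies ~0.73/0.81 from the generating TR-FOCI law),
and the calibrated slope/intercept sit close to that law (−0.3987,
1.0214) — a single noisy subject attenuates the slope slightly; pooling
subjects and raising SNR closes the gap.

Now the look-up-table comparison for a white-matter voxel (T1 = 1365 ms)
whose true efficiency follows the TR-FOCI line:

```r
p <- protocol_mp2rage(1)
f <- finv_evaluate(finv_model_trfoci(), 1000 / 1365)   # 0.729
s <- cycle_steady_state(p, tissue(1365), f)
u <- uni_combine(s[1], s[2])                            # UNI = 0.3822

lut_invert(lut_build(p, 1, finv_constant(0.96)), u)     # 1132 ms
lut_invert(lut_build(p, 1, finv_model_trfoci()), u)     # 1360 ms
```

The constant-efficiency table underestimates white-matter T1 by about
230 ms; the calibrated R1-dependent table recovers it to within a grid
step.

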