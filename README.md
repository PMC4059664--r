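# mp2rage

Robust MP2RAGE T1-weighted image combination, forward simulation and T1
mapping, for people working with high-field (7T) structural brain MRI.

The MP2RAGE sequence acquires two gradient-echo readouts (GRE_TI1, GRE_TI2)
at different inversion times in one magnetization-prepared cycle. The
standard **uniform** image

```
S = Re(s1* s2) / (|s1|^2 + |s2|^2)   in [-0.5, 0.5]
```

cancels proton density, T2\* weighting and receive-field bias, but is
numerically unstable at low signal: the background of the image fills the
whole intensity range with salt-and-pepper noise (for pure complex Gaussian
noise the value is exactly uniformly distributed on [-0.5, 0.5]), which
breaks registration and automatic segmentation. The **robust** combination
regularizes the ratio with a constant beta in squared raw-signal units,

```
S_beta = (Re(s1* s2) - beta) / (|s1|^2 + |s2|^2 + 2*beta),
```

which reduces to the uniform image at beta = 0, forces exactly -0.5 at zero
signal (background darker than CSF), always stays in [-0.5, 0.5], and trades
a small, spatially varying intensity bias — confined to voxels whose signal
power is comparable to beta — for numerical stability.

The package implements both combinations with automatic beta selection from
a robust background-noise estimate, a Bloch steady-state forward model of
the sequence, a digital head phantom with B1+/B1- inhomogeneity and a
poor-inversion region, lookup-table T1 mapping from the uniform image,
evaluation metrics (background statistics, robust/uniform bias-ratio maps,
tissue contrast, repeat-scan volumetric reproducibility), and a NIfTI
command-line interface.

## Worked example

```r
library(mp2rage)

ph   <- makePhantom(c(64, 64, 64), seed = 7)       # digital head phantom
pair <- simulateAcquisition(ph, seed = 7)          # complex GRE_TI1/GRE_TI2
uimg <- uniformCombination(pair)
rimg <- robustCombination(pair, beta = "auto")
betaValue(rimg)
#> [1] 5.34784e-06

bg <- tissueMask(ph, "background")
backgroundStats(uimg, bg)[c("mean", "std")]
#> $mean [1] 0.000457    $std [1] 0.289
backgroundStats(rimg, bg)[c("mean", "std")]
#> $mean [1] -0.499      $std [1] 0.00119
```

The uniform background is centred noise with standard deviation 0.289 (the
uniform-law value 1/sqrt(12)); the robust background collapses onto -0.5.
The bias this buys is local and small where signal is strong:

```r
biasRatio(rimg, uimg, mask = brainMask(ph), labels = phantomLabels(ph))$summary
#>       CSF        GM        WM
#> 1.0000408 1.0144073 0.9407506
```

CSF sits at the regularization's inert point (-0.5), so it is unchanged; WM,
whose uniform intensity is near zero under this protocol, shows a ~6% median
shift. T1 maps come from the uniform image via the forward-model lookup
table:

```r
lut <- buildLookupTable(defaultProtocol())
monotoneRange(lut)                       # invertible T1 range (s)
#> [1] 0.13 4.28
t1 <- t1FromUniform(imageData(uimg), lut)
median(t1[tissueMask(ph, "WM")], na.rm = TRUE)   # truth: 1.2 s
#> [1] 1.167153
```

(The small WM offset is the uncorrected B1+ variation; `t1FromUniformB1()`
corrects it when a transmit map is available.) Repeat-scan volumetry uses
the symmetric relative difference:

```r
volumetricReproducibility(c(A = 100, B = 50), c(A = 100, B = 60))
#> $per_structure  A 0.00000  B 18.18182
#> $mean_pct       9.090909
#> $worst_case_pct 18.18182
```

## Command line

```sh
inst/cli/mp2rage simulate --shape 64,64,64 --seed 7 -o phm
inst/cli/mp2rage combine --inv1 phm_inv1_mag.nii.gz --phase1 phm_inv1_phase.nii.gz \
    --inv2 phm_inv2_mag.nii.gz --phase2 phm_inv2_phase.nii.gz \
    --beta auto --mode robust -o robust.nii.gz
inst/cli/mp2rage t1map --uniform uniform.nii.gz -o t1.nii.gz
inst/cli/mp2rage evaluate --uniform uniform.nii.gz --robust robust.nii.gz \
    --labels phm_labels.nii.gz -o report.json
```

Every run writes a JSON sidecar with the resolved parameters (including the
effective beta, which is tied to the raw intensity scale of the inputs) so a
run is reproducible from the sidecar alone.

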