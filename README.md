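# cortigap

Detection of cortical interruptions and their underlying trabecular void
volume in HR-pQCT images of finger joints, with the reproducibility
statistics needed to interpret change over time.

## Why

In early rheumatoid arthritis, inflammation erodes the cortical shell of
the metacarpophalangeal joints. On high-resolution peripheral
quantitative CT (82 µm isotropic voxels) these erosions appear as
**cortical interruptions** — gaps in the cortex — typically with an
abnormal **trabecular void** in the marrow beneath. `cortigap`
implements a semi-automated 3D detection pipeline for both, plus the
agreement statistics (ICC, RMS precision errors, least significant
change) used to decide whether a measured change exceeds measurement
noise.

## The method in brief

Within a 4-voxel (0.328 mm) cortical peel of the filled periosteal
contour, non-bone components that span the peel and whose maximum
inscribed-sphere diameter

$$d = 2\,(\max_{x \in C} \mathrm{EDT}_{\neg\text{bone}}(x) - 0.5)\cdot v
\;\ge\; 0.41\ \text{mm}$$

are labelled interruptions. Each is dilated by a Euclidean ball of 48
voxels (3.936 mm) to form an ROI inside the bone; marrow with local
thickness ≥ 0.738 mm is selected as void, eroded by 2 voxels (severing
connections ≤ 0.328 mm so voids cannot leak into the trabecular
network), filtered for connectivity to an interruption, and restored by
geodesic reconstruction. Per joint the pipeline reports the number of
interruptions, their surface (mm²) and the combined interruption + void
volume (mm³).

Precision of paired measurements is summarized by single-measure
ICC(2,1) (two-way random effects, absolute agreement, McGraw–Wong 95%
CI), Glüer RMS errors ($SD_j = |x_1-x_2|/\sqrt2$,
$SD_{RMS} = \sqrt{\overline{SD_j^2}}$) and the least significant change
$LSC = 1.96\sqrt2 \cdot SD_{RMS}$ (or $CV_{RMS}$ for the percentage
form).

A synthetic joint phantom (cortical shell + rod lattice + drilled
channels and cavities of known size, blur and noise, repositioned
"re-scan" variants) provides ground truth for every stage; no scanner
data are required to validate an installation.

## Worked example

```r
library(cortigap)

# a phantom joint with three defects: 0.6/0.8/1.2 mm channels over
# 2/4/8 mm^3 voids, imaged with blur and noise
ph  <- make_joint_phantom(phantom_spec(
         interruptions = reference_interruptions(), seed = 7))
res <- run_joint(ph$volume)
res$metrics
#> <joint_metrics> n = 3, surface = 2.483 mm^2, volume = 13.880 mm^3
res$interruptions$per_component
#>   id voxel_count surface_mm2 max_inscribed_diameter_mm truncated
#> 1  1         778    1.307818                 1.1231490     FALSE
#> 2  2         439    0.737959                 0.6695424     FALSE
#> 3  3         260    0.437060                 0.5316318     FALSE
```

All three defects are recovered; the measured total volume (13.88 mm³)
is within 3% of the carved ground truth (14.28 mm³), and the inscribed
diameters reflect the drilled channel sizes after segmentation. The
decoy cavity the phantom hides at the joint centre is correctly rejected
by the connectivity filter.

Precision statistics work on any paired per-joint table:

```r
set.seed(99)
m1 <- c(2, 5, 1, 8, 3, 6, 4, 9, 2, 7) + rnorm(10, 0, 0.4)
m2 <- m1 + rnorm(10, 0, 0.6)
precision_report(paired_measurements(sprintf("J%02d", 1:10), m1, m2))
#> <precision_report> n = 10
#>   ICC 0.949 (95% CI 0.816 - 0.987), excellent
#>   SD_RMS 0.6153, LSC_SD 1.705; CV_RMS 24.09%, LSC_CV% 66.78%
#>   Bland-Altman mean diff 0.3596, LoA [-1.277, 1.997]
#>   paired t = 1.361 (df 9), p = 0.2065
```

Read: two measurements of the same joint must differ by more than
LSC_SD = 1.705 (here, units of the endpoint) before the change is
distinguishable from measurement noise at 95% confidence.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/cortigap.R", package = "cortigap"))')
Rscript $CLI phantom --seed 7 --with-defects --out vol.mha --truth truth.json
Rscript $CLI segment --in vol.mha --out-bone bone.mha \
        --out-contour contour.mha --out-cortex cortex.mha
Rscript $CLI detect  --bone bone.mha --cortex cortex.mha \
        --contour contour.mha --out-labels lab.mha --out-table lab.csv
Rscript $CLI voids   --bone bone.mha --contour contour.mha \
        --labels lab.mha --out-final final.mha --out-metrics joint.json
```

## Layout

- `R/`, `src/` — pipeline modules and the Rcpp morphology kernel
  (separable Euclidean distance transform, connected components, local
  thickness, Gaussian blur).
- `vignettes/cortigap-methods.Rmd` — the model, parameter rationale,
  phantom design, numerical conventions and limitations.
- `tests/testthat/` — unit, property and end-to-end suites, including
  brute-force oracles for the distance transform, local thickness and
  ICC.
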