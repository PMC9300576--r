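# nsafit

Automatic measurement of the femoral neck-shaft angle (NSA) from
region-labeled point clouds of single femurs.

The NSA — the angle between the longitudinal axis of the femoral neck and
that of the femoral shaft, roughly 120-140° in adults — drives prosthesis
selection and preoperative planning in total hip arthroplasty, and screens
for coxa vara/valga. Manual measurement on radiographs is poorly
repeatable, and 2D projections and direct 3D reconstructions do not
obviously agree. `nsafit` implements two fully automatic measurement routes
on a segmented femoral point cloud (head / neck / shaft, labels 0/1/2, in
mm), plus the evaluation machinery to compare them, and a parametric
synthetic femur generator with analytically known ground truth so the whole
pipeline is testable without clinical CT data.

## Methods

Given a labeled cloud, both routes build the same anatomy:

* **Head centre** `c`: least-squares sphere fit. With mean-centred
  coordinates `u_i = x_i - x̄` (etc.) the centre solves the 3×3 normal
  equations `(Σu_i²)u₀ + (Σu_iv_i)v₀ + (Σu_iw_i)w₀ = Σ(u_i³ + u_iv_i² + u_iw_i²)/2`
  (and cyclic permutations); the radius is the RMS distance
  `R = sqrt( Σ_i ‖p_i − c‖² / N )`.
* **Neck centroid** `p_c = (1/n) Σ p_i` over the neck-labeled points.
* **Shaft parameterization**: dominant principal axis of the shaft points,
  oriented proximal→distal by the head centre; axial slabs are fractions of
  the shaft's extent along this axis.

**3D route** (`measure_nsa_3d`): the neck axis connects the neck centroid
to the head centre; the shaft axis connects the centroids of the 60-70% and
70-80% axial slabs (away from the lesser trochanter and the bowed
mid-diaphysis). The NSA is the vector angle
`θ = arccos( A·B / (|A||B|) )` of the two directions. Because the two
fitted axes are generally *skew*, their closest-approach distance is
reported as a diagnostic.

**2D route** (`measure_nsa_2d`): simulates the standard hip anteroposterior
radiograph. A projection plane `Ax + By + Cz + D = 0` is constructed
through the head centre, the neck centroid and the centroid of the distal
10% of the shaft (this choice counterbalances femoral anteversion, as
internal rotation of the limb does on the real radiograph). Every point is
dropped to its foot of perpendicular `p' = p − t(A,B,C)`,
`t = (Ax + By + Cz + D)/(A² + B² + C²)`. The projected head silhouette is a
disc whose rim is fitted by RANSAC circle consensus (trial count
`S = log(1−P)/log(1−ρᴷ)`, adaptive, locally optimized); the neck axis runs
from the fitted circle centre to the projected neck centroid, the shaft
axis through the projected slab centroids, and the same vector-angle
formula gives the in-plane NSA.

Evaluation helpers implement the Dice coefficient
`2|X∩Y|/(|X|+|Y|)` and mean intersection-over-union `TP/(TP+FP+FN)` per
class for segmentation agreement, per-pair angle error `|NSA_m − NSA_a|`
and accuracy `(1 − |(NSA_m − NSA_a)/NSA_m|)·100%`, the pooled two-sample
Student t-test, and the cross-entropy of probabilistic labels.

## Worked example

```r
library(nsafit)

fem <- generate_femur(femur_spec(nsa_true = 131, anteversion = 12, seed = 42))
fem$cloud
#> <labeled_cloud> 'synthetic_seed42': 2048 points (head 476, neck 196, shaft 1376)

measure_nsa_3d(fem$cloud)
#> <nsa_result> 'synthetic_seed42' (3d method): neck-shaft angle 130.05 deg
#>   axis closest approach: 2.71 mm (neck and shaft axes are generally skew)

measure_nsa_2d(fem$cloud, ransac_config(seed = 42))
#> <nsa_result> 'synthetic_seed42' (2d method): neck-shaft angle 129.99 deg
#>   projection plane: 0.212x + -0.977y + -0.001z + -0.032 = 0
```

The true angle is 131°; with 0.5 mm surface noise on 2048 points both
routes land within a degree of it, agree with each other to 0.06°, and the
fitted axes pass 2.7 mm apart — the skewness that motivates the projection
route in the first place. Batch runs return a tidy table:

```r
sw <- sweep_femurs(lapply(1:10, function(i) femur_spec(nsa_true = 115 + 3 * i, seed = i)))
glance(sw)
#>    n n_ok mean_err_3d_deg mean_err_2d_deg mean_err_2d_3d_deg accuracy_3d_pct accuracy_2d_pct accuracy_2d_3d_pct
#> 1 10   10           0.622           0.578              0.184          99.521          99.555             99.859
```

`autoplot()` draws a measured femur in its projection plane or a sweep's
measured-vs-true scatter; `tidy()`/`glance()` return the axes and headline
numbers as tibbles; `read_cloud()`/`write_cloud()` handle labeled PLY
(ascii and binary little-endian), XYZ and CSV; `write_result()` emits a
JSON record of the full measurement. A command-line front end is installed
at `system.file("cli", "nsafit", package = "nsafit")` with `measure`,
`synth` and `eval` subcommands.

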