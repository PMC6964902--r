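# arnav

Geometry and accuracy evaluation for augmented-reality surgical navigation
with an optically tracked endoscope.

In endoscopic skull-base surgery, an augmented-reality navigation system can
fuse an intraoperative cone-beam CT (CBCT) volume onto the live endoscopic
view: an optical tracking system (OTS) reports 3D marker positions in a world
frame, the endoscope carries a tracked marker disc (EM), the patient carries
surface markers forming a *virtual reference grid* (VRG), and the overlay is
driven entirely by rigid-transform algebra.  Writing transforms as
`target <- source`, with `T_MO` the tracked EM pose (`O <- M`), `T_CM` the
hand-eye calibration (`M <- C`) and `T_PO` the tracked patient pose
(`O <- P`), the camera pose is

```
T_CO = T_MO · T_CM
```

and the patient model is carried into the camera frame by

```
T_CP = T_PO⁻¹ · (T_MO · T_CM)
```

`arnav` implements this chain end to end, in plain R, together with
everything needed to exercise it without hardware:

* **Rigid-transform algebra** over named coordinate frames (composition,
  inversion, frame graphs, rotation representations).
* **Camera model** — distorted pinhole projection, iterative undistortion,
  and planar intrinsic calibration (Zhang's method: homographies, closed-form
  intrinsics, joint Levenberg–Marquardt refinement).
* **Pose estimation** — Grunert P3P with candidate disambiguation and
  refinement over a 25-marker calibration plate.
* **Hand-eye calibration** — direct per-sample averaging (both poses live in
  the same world frame) plus the classical AX = XB relative-motion path as a
  cross-check.
* **Tracking & registration** — closed-form rigid point-set registration with
  reflection guard, VRG construction, and marker-based motion compensation.
* **Simulator** — the sphere-grid accuracy phantom (13 spheres of 2 mm
  diameter in the central 20×20 mm of a 60×60 mm plate, 11 border markers), a
  checkerboard, the 25-marker plate, a noisy 3D marker sensor, and an
  endoscope image renderer (2590×1942 px sensor, scalable).
* **Evaluation** — target registration error (TRE) of the overlay, converted
  from pixels to millimeters through the known sphere diameter
  (`TRE[mm] = TRE[px] · Ø[mm] / Ø[px]`), with per-distance statistics,
  spatial error maps, and one-way ANOVA with Tukey–Kramer post-hoc tests.

## Worked example

Simulate the accuracy protocol of the sphere grid at the six working
distances (5–30 mm), with a marker sensor jitter of 0.1 mm, and evaluate the
overlay error of the full chain:

```r
library(arnav)

K     <- default_endoscope_intrinsics(scale = 0.25)   # 648 x 486 px working scale
proto <- run_accuracy_protocol(distances_mm = c(5, 10, 15, 20, 25, 30),
                               n_positions = 100, intrinsics = K,
                               sigma_marker_mm = 0.1, seed = 1)
recs  <- evaluate_accuracy(proto)    # re-estimates T_PO and T_MO per frame
summarize_tre(recs, K)
```

```
TRE overall: 0.303 +/- 0.165 mm, median 0.283 mm, IQR 0.181-0.406 mm, max 1.182 mm (n = 5096)
per working distance:
  distance_mm    n   mean     sd median     q1     q3    min    max
1           5  216 0.2392 0.1171 0.2264 0.1548 0.3254 0.0059 0.6157
2          10  654 0.2620 0.1377 0.2488 0.1540 0.3478 0.0103 0.7323
3          15  896 0.2915 0.1609 0.2808 0.1660 0.3901 0.0241 1.1817
4          20 1047 0.2934 0.1487 0.2701 0.1825 0.3927 0.0067 0.9093
5          25 1112 0.3445 0.1560 0.3354 0.2230 0.4548 0.0219 0.8943
6          30 1171 0.3167 0.1974 0.2916 0.1652 0.4121 0.0166 1.1544
one-way ANOVA across distances: F = 32.788, p = 4.98e-33
```

Each record pairs a real sphere circle with its overlaid rendering; `tre_mm`
is their center distance re-expressed in object-plane millimeters.  With the
noise switched off (`sigma_marker_mm = 0`) the same run returns a maximum
TRE of about `4e-14` mm — the chain is exact up to floating-point rounding.

Calibration from simulated data:

```r
views <- simulate_calibration_views(K, n_views = 15, seed = 1)
cal   <- calibrate_intrinsics(views, width = K$width, height = K$height)
cal$rms_px                       # 3.73e-14 px (noiseless corners)

samples <- simulate_handeye_samples(n = 20, motion = "moving", seed = 1)
solve_hand_eye(samples, method = "direct")$TCM
```

A thin command-line front-end is installed at `exec/arnav`
(`simulate-rig`, `calibrate-intrinsics`, `calibrate-handeye`, `run-accuracy`,
`report`).

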