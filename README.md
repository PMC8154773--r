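# fasciata

Semi-automated 3D segmentation of the **fascia lata** (FL) of the thigh in
T1-weighted MRI, and quantification of **intermuscular adipose tissue**
(IMAT) volume and muscle fat fraction from Dixon fat-fraction (FF) maps.

## The problem

The fascia lata is the thin fibrous sheath around the thigh muscle
ensemble and the anatomical boundary between subcutaneous fat (SAT) and
IMAT. Quantifying IMAT therefore needs an FL segmentation — but the FL is
a ~1–2 mm dark sheet that is easy to confuse with other fibrous structures
(notably the saphenous fascia) and hard to trace slice by slice. Many
studies fall back on a tight envelope of the muscle ensemble (ME), which
misses the perimuscular fat between the muscle surface and the FL — a
systematic underestimate that grows with adiposity.

`fasciata` implements a multi-step 3D pipeline:

1. **Bias correction** — iterative log-domain polynomial fit of the
   multiplicative field (k-means class assignment ↔ least-squares field
   fit).
2. **Fuzzy c-means clustering** of voxel intensity into four clusters
   (bone/background, fibrous tissue, muscle, adipose tissue):
   `u_ik = [Σ_j (|x_k−v_i|/|x_k−v_j|)^{2/(m−1)}]^{−1}`,
   `v_i = Σ_k u_ik^m x_k / Σ_k u_ik^m`; morphological extraction of the
   thigh surface (skin removed) and the femur.
3. **Muscle envelope** — a discrete geodesic-active-contour front
   contracts from the thigh surface and stops on the muscle-membership
   edge map `g = exp(−s·|∇u_muscle|)`, excluding veins and other SAT
   structures.
4. **FL evidence** — Frangi-style *sheetness* of the fibrous cluster
   outside ME from scale-normalised Hessian eigenvalues
   (`|λ1| ≤ |λ2| ≤ |λ3|`, dark-plate polarity `λ3 > 0`):
   `w = exp(−R_sheet²/2α²)·exp(−R_blob²/2β²)·(1−exp(−S²/2c²))`.
5. **FL surface** — a second front contracts with `g = 1 − w`, locked
   outside ME, closing the plate fragments into the intra-fascia (IF)
   VOI; fragments that do not form a closed surface (the saphenous decoy)
   are bypassed.
6. **Scriptable livewire refinement** — exact A* shortest paths on a cost
   map `w_edge·(1−G) + w_fascia·(1−w)`, with seed propagation over the
   next 10 slices.
7. **Quantification** — `IMAT_FL` (adipose voxels in IF minus femur, cm³)
   and `IMAT_ME`; masked mutual-information rigid registration of T1w to
   the Dixon FF volume; muscle tissue segmented at the minimum of the
   log-scaled FF histogram inside IF; `FF_MT` = mean FF over muscle
   tissue (scanner scale 0–1000 ↔ 0.0–100.0 %).
8. **Precision statistics** — RMS-SD and RMS-CV over repeated analyses.

Because no clinical images ship with the package, a **synthetic thigh
phantom** generator (`phantom_spec()` / `make_phantom()`) produces T1w +
FF volume pairs with exhaustive voxel-level ground truth: star-convex
thigh outline, SAT, drifting FL sheet, perimuscular fat ring,
intramuscular fat streaks, femur (cortex + marrow), skin, saphenous-fascia
decoy arc, polynomial bias field, Gaussian noise, and a known rigid offset
between the two volumes.

## Worked example

```r
library(fasciata)

ph  <- make_phantom(phantom_spec(rng_seed = 1))
res <- run_pipeline(ph$t1w, ph$ff)
res$report
#> <quant_report>
#>   Volume_total :    44.20 cm^3
#>   IMAT_FL      :    13.90 cm^3
#>   IMAT_ME      :     1.16 cm^3
#>   dIMAT        :    12.74 cm^3
#>   FF_MT        :     6.72 %
#>   MT threshold :    535.0 (0-1000)
#>   slices       : 11
```

`Volume_total` is the intra-fascia volume without the femur over the
analysed slices (first/last 3 trimmed). `IMAT_FL` is the adipose-tissue
volume inside the fascia lata; `IMAT_ME` the same measurement inside the
tight muscle envelope — the difference `dIMAT` is the perimuscular fat
that envelope-based analyses miss (this phantom emulates a high-adiposity
subject). `FF_MT` is the mean Dixon fat fraction of muscle tissue, with
the muscle/adipose threshold (here 535 on the 0–1000 scanner scale) found
at the minimum of the log-scaled FF histogram. Against this phantom's
ground truth the run recovers the muscle envelope with Dice 0.99, the IF
VOI with Dice > 0.999 and IMAT_FL to well within 5 %.

A thin command-line wrapper is installed at `inst/cli/fasciata.R`
(`phantom`, `preprocess`, `run`, `precision` subcommands).

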