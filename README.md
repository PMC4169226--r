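# masweep

Quantification of left-ventricular **diastolic function** from routinely
acquired long-axis cine cardiac MR images, by 3D volume tracking of the
mitral annulus (MA).

Echocardiographic tissue Doppler (TDI) measures the early (e′) and late
(a′) diastolic velocities of the mitral annulus at single sites; their
ratio reverses in diastolic dysfunction. CMR acquires the same anatomy in
every clinical exam — two-, three- and four-chamber cine views — but
without a velocity readout. `masweep` turns those cine views into a global
diastology measurement:

1. **AVJ tracking.** The two atrioventricular-junction points in each view
   are tracked across all cardiac phases by normalized cross-correlation
   (NCC) template matching: a 21-px template centered on the current point
   is matched inside a 41-px search region of the next phase; the
   correlation peak is the new location. Tracking is chained through the
   cycle, with scriptable manual correction and re-tracking.
2. **3D reconstruction.** The six tracked pixel trajectories are mapped
   into patient coordinates with the DICOM plane geometry
   (ImagePositionPatient / ImageOrientationPatient / PixelSpacing) and
   interpolated per phase with a closed periodic cubic spline — a 3D
   reconstruction of the annulus at every phase.
3. **Sweep volume.** Between consecutive phases the annular disk sweeps an
   incremental volume `V_n = (A_{n-1} + A_n)/2 · d_n`, with `A` the
   annular area and `d_n` the signed axial displacement of its centroid.
   The running sum from end-diastole is the **sweep-volume curve**; its
   maximum is the end-systolic sweep volume (ESSV), used to normalize
   across heart sizes.
4. **Diastolic parameters.** The normalized curve and its rate are
   segmented into systole, early diastole (ED), diastasis, and atrial
   systole (AS), yielding:
   - `PSR_E`, `PSR_A` — normalized peak sweep rates in ED and AS (s⁻¹),
     and `PSR_E/PSR_A`, the CMR analogue of TDI e′/a′;
   - percentage (and absolute) sweep-volume recovery per interval;
   - `AT_SV`, `DT_SV` — acceleration/deceleration times of the E wave
     (DT by linear extrapolation of the descending rate limb to baseline);
   - `DSVRT_50` — time after end-systole to recover 50 % of ESSV, as % of
     the RR interval.

A **synthetic three-view phantom** (annular ring with systolic descent,
biphasic E/A recovery, saddle shape, tilt and sway, trackable texture at
the junction points, optional noise/blur) provides analytic ground truth
for every stage, and **cohort utilities** cover the associated reporting
statistics (Spearman correlation, ROC with accuracy-optimal cutoff,
Bland–Altman, ICC).

## Worked example

Render the default phantom (25 phases, RR 857 ms, 15 mm ring descending
12 mm, 70 % early recovery), track it from the true phase-0 seed points
and compute the parameters:

```r
library(masweep)
res <- analyze_phantom(phantom_spec(seed = 1))
res$params
#> <diastolic_params>
#>   PSR_E 7.74 /s  PSR_A 3.56 /s  PSR_E/PSR_A 2.18
#>   recovery ED 73.2%  AS 26.6%   ESSV 8.3 cm3
#>   AT_SV 69 ms  DT_SV 100 ms  DSVRT_50 10.5 %RR
res$curve
#> <sweep_curve> 25 phases, ESSV 8.28 cm3 at phase 8, closure residual 0.82 cm3
res$segmentation
#> <interval_segmentation> (automatic) ES 309 ms | ED 309-480 | MD 480-686 | AS 686-857 ms
```

A normalized peak early-diastolic sweep rate of 7.74 s⁻¹ with an E/A
ratio of 2.18 is a normal pattern (the phantom's analytic truth is
PSR_E = 8.17 s⁻¹, ratio 2.33; the difference is the pixel-resolution
tracking error at 1.4 mm spacing). The closure residual (0.82 cm³ against
an ESSV of 8.28 cm³) is the tracking-drift diagnostic: the amount by which
the curve fails to return to baseline over one cycle.
`plot_sweep_curve(res$curve, res$rate, res$segmentation)` draws the
normalized curve and rate with the intervals shaded.

Real studies enter either as DICOM series (`load_dicom_view()`, explicit
or implicit VR little endian) or in the plain fixture format (16-bit TIFF
frames + `geometry.json`), and run through `track_study()` /
`analyze_study()`, or from the shell:

```sh
exec/masweep phantom --out ph --seed 5          # demo inputs
exec/masweep analyze --config cfg.yaml          # full pipeline
exec/masweep report  --input subjects.csv --out metrics.json
```

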