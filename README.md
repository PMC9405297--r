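# zebraheart

Cardiac physiology of zebrafish embryos from markerless landmark tracking.

Pose-estimation tools such as DeepLabCut can track eight labelled points on
the boundary of the beating ventricle in bright-field video. **zebraheart**
turns those per-frame coordinate tables into a seven-parameter cardiac
panel plus heart-rate-variability indices, for researchers doing cardiotoxicity
screening or cardiac phenotyping in embryonic zebrafish.

## The model

Points 1 and 5 span the ventricular short axis $D_s$, points 3 and 7 the
long axis $D_l$. Treating the ventricle as a prolate spheroid,

$$V = \frac{\pi}{6}\, D_l D_s^2 .$$

Diastolic peaks of the volume trace segment the record into cardiac cycles
(prominence-based peak detection with a physiological separation
constraint). Per cycle and then averaged:

- end-diastolic / end-systolic volume (EDV, ESV) — volume at the peak / trough,
- stroke volume $SV = EDV - ESV$,
- heart rate $HR = \overline{60/\mathrm{IBI}}$ (inter-beat intervals between diastolic peaks),
- cardiac output $CO = SV \times HR$,
- ejection fraction $EF = SV/EDV \times 100\%$,
- shortening fraction $SF = (D_{sd} - D_{ss})/D_{ss} \times 100\%$.

Rhythm variability comes from the Poincaré plot of consecutive intervals:
$sd1 = \sqrt{\mathrm{Var}(\mathrm{IBI}_n - \mathrm{IBI}_{n+1})/2}$
(instantaneous) and
$sd2 = \sqrt{\mathrm{Var}(\mathrm{IBI}_n + \mathrm{IBI}_{n+1})/2}$
(long-term), with a 0.95-confidence ellipse overlay.

A fully ground-truthed synthetic beating-heart simulator (pulsatile
spheroid, AR(1) interval jitter, tracking noise, likelihood dropouts, slide
drift, sudden displacements, treatment-effect presets) makes the whole
pipeline testable without any video.

## Worked example

```r
library(zebraheart)

sim <- simulate_track(preset_spec("control", seed = 1))  # 60 s @ 30 fps
fit <- heart_scan(sim$track)                             # full pipeline
print(fit)
#> Cardiac physiology fit (heart_scan)
#>   1800 frames @ 30 fps, 148 cardiac cycles
#>   heart rate 150.5 bpm, EF 50.1%, SF 26.2%
round(coef(fit), 3)
#>   heart_rate          EDV          ESV           SV           CO
#>      150.451   401341.767   200112.208   201229.558 30275130.888
#>           EF           SF          sd1          sd2
#>       50.107       26.195        0.030        0.050
```

The fitted heart beats 150.5 times per minute; each beat fills the
ventricle to ~4.0×10⁵ px³ and ejects half of it (EF 50.1%), moving
~3.0×10⁷ px³ of blood per minute. The short axis shortens by 26% per beat,
and beat-to-beat timing varies by ~30 ms (sd1) against a long-term spread
of ~50 ms (sd2) — all matching the simulator's generating parameters
(150 bpm, EDV 4×10⁵, ESV 2×10⁵, EF 50%).

Real tracking tables are analyzed the same way
(`heart_scan("fish1.csv", fps = 30)`), batches with `run_analysis()`, and
group tables with `summarize_groups()`. A thin command-line wrapper with
`analyze` / `simulate` / `summarize` verbs lives at `inst/cli/zebraheart.R`.

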