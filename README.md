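# taetofts

Pharmacokinetic modeling for DCE-MRI acquisitions that **time-average** the
signal — radial, spiral and PROPELLER trajectories that oversample the
center of k-space, so each frame of duration Δt measures the *mean*
contrast-agent concentration over its window rather than a snapshot.

Fitting the conventional extended Tofts model

&nbsp;&nbsp;&nbsp;&nbsp;C(t) = v<sub>p</sub> C<sub>p</sub>(t) + K<sup>trans</sup> ∫₀ᵗ C<sub>p</sub>(τ) e<sup>−k<sub>ep</sub>(t−τ)</sup> dτ,&nbsp;&nbsp; K<sup>trans</sup> = k<sub>ep</sub> v<sub>e</sub>,

to frame means biases the estimates, worst for the plasma fraction
v<sub>p</sub>. The corrected forward model convolves C with a unit-area
rect of width Δt, which — because convolution is associative — equals
evaluating the same extended Tofts expression with the rect-averaged
arterial input function C<sub>p</sub>′:

&nbsp;&nbsp;&nbsp;&nbsp;C′(t) = (1/Δt) rect(t/Δt) ∗ C(t) = C(t, u, C<sub>p</sub>′).

The package provides, all in closed form for the analytical (Orton
raised-cosine) population AIF:

* `aifConcentration()`, `averagedAifConcentration()`, `bloodToPlasma()` —
  the AIF layer (population parameters a<sub>B</sub> 2.84, μ<sub>B</sub>
  22.8 /min, a<sub>G</sub> 1.36, μ<sub>G</sub> 0.171 /min; hematocrit 0.42);
* `toftsConcentration()`, `averagedToftsConcentration()`,
  `averagedToftsViaConvolvedAif()` — the instantaneous and time-averaged
  tissue models;
* `spgrSignal()`, `signalToConcentration()`, `averagedSignal()` — the
  spoiled gradient-echo signal layer and signal-domain averaging;
* `fitCurve()`, `fitImage()` — box-constrained Levenberg–Marquardt
  estimation of (v<sub>p</sub>, v<sub>e</sub>, k<sub>ep</sub>) for curves
  and voxelwise NIfTI maps, under the conventional, time-averaged or
  signal-domain variant;
* `sampleParameters()`, `generateDataset()`, `runExperiment()`,
  `summarizeErrors()`, `compareConditions()`, `countSignificant()`,
  `meanAbsoluteDifference()` — a paired Monte Carlo harness with the
  accuracy/precision statistics (paired Wilcoxon signed-rank,
  Levene/Brown–Forsythe) and comparison bookkeeping;
* a command-line interface (`inst/scripts/taetofts`) with `simulate`,
  `fit`, `reproduce` and `report` subcommands.

The methods vignette (`vignettes/time-averaged-tofts.Rmd`) documents the
models, the simulation design (including the frame-grid alignment choice),
all numerical decisions and the known limitations.

## Worked example

A noiseless 15 s/frame time-averaged curve, fitted with and without the
correction:

```r
library(taetofts)
u     <- PKParameters(vp = 0.025, ve = 0.3, kep = 1.5)
theta <- AIFParameters()                      # population AIF
tt    <- seq(7.5, 292.5, by = 15)             # frame centers, 5 min
y     <- averagedToftsConcentration(tt, u, theta, dt = 15)

fitCurve(tt, y, "time_averaged", theta, dt = 15)
#> FitResult (time_averaged, dt = 15 s)
#>   vp = 0.025, ve = 0.3, kep = 1.5 /min, Ktrans = 0.45 /min
#>   RSS = 6.1106e-30, converged = TRUE, evaluations = 7

fitCurve(tt, y, "conventional", theta)
#> FitResult (conventional)
#>   vp = 0.016635, ve = 0.30745, kep = 1.5018 /min, Ktrans = 0.46174 /min
#>   RSS = 1.5853e-07, converged = TRUE, evaluations = 7
```

The corrected model recovers the ground truth exactly; ignoring the
averaging underestimates v<sub>p</sub> by a third even without noise. At
scale, a paired Monte Carlo condition (noisy, SNR 20):

```r
r <- runExperiment("exp2", dt = 15, n = 200, seed = 7)
summarizeErrors(r)
#>   parameter   mean_error    sd_error   n
#> 1    Ktrans -0.000692412 0.048362241 200
#> 2        vp  0.001235473 0.009323923 200
#> 3        ve  0.001431929 0.027342716 200
```

Mean errors near zero show the corrected fit is unbiased; the SD column is
the precision at this frame duration. The same numbers come from the shell:

```sh
Rscript inst/scripts/taetofts reproduce --experiment exp2 --dt 15 --n 200 --seed 7 --out out/
```

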