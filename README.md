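# sersquant

Quantitative chemometrics for surface-enhanced Raman spectroscopy (SERS) of
trace contaminants — built around the working example of pyrene, a
carcinogenic polycyclic aromatic hydrocarbon (PAH), measured in edible oil
after thin-layer-chromatography separation on a plasmonic substrate. The
package is aimed at analytical spectroscopists who need a full, reproducible
path from labelled spectra to a predicted concentration, and at method
developers who want a controlled synthetic test bed for nonlinear SERS
calibration.

## What it does

SERS band intensity is not linear in concentration: the signal saturates as
analyte molecules fill the adsorption sites of the plasmonic substrate,
approximately following a Langmuir isotherm

    A(c) = I_max * K * c / (1 + K * c),

and replicate spots scatter multiplicatively (typical relative standard
deviation near 10%). Over a working range spanning four decades
(0.01–70 ppm) an ordinary calibration line fails. The pipeline here:

1. **Synthetic spectra** (`generateDataset()`) — Gaussian bands on a
   wavenumber grid, Langmuir concentration response, per-spectrum lognormal
   replicate factor (CV 9.6%), additive white noise, polynomial baseline;
   fully seeded. The pyrene quantitation band sits at 586 cm⁻¹.
2. **Peak fitting** (`fitGaussianPeak()`) — four-parameter Gaussian + offset
   least squares per window; height, FWHM and the analytic area
   height·FWHM·√(π/(4 ln 2)).
3. **Region selection** (`selectRegion()`) — the spectrum is segmented into
   four windows (350–405, 410–490, 500–600, 1190–1250 cm⁻¹), each window
   gets a mean-centred PCA, and the window whose leading component explains
   the largest variance fraction ("variance contribution") is selected;
   the 586 cm⁻¹ band makes 500–600 cm⁻¹ the expected winner.
4. **PCA-BP regression** (`trainPcaBp()`, `predictConcentration()`) — the
   top-16 window PCA scores, conditioned by a monotone variance-stabilising
   transform, feed a small 1-D convolutional network — conv stages
   (32,4), (64,4), (128,2), (256,1), dense layers 400/200/100/50, sigmoid
   output with log10 concentration scaling — trained by full-batch Adam with
   L2 weight decay. Implemented from scratch in R (forward, backprop, Adam).
5. **PLSR comparator** (`fitPlsr()`) — deterministic PLS1 on the same window
   as the linear baseline the network is judged against.
6. **Calibration and LOD** (`fitCalibration()`, `computeLod()`, `rsd()`) —
   univariate line of the 586 cm⁻¹ band height, blank-noise estimate, and
   the limit of detection at signal-to-noise ratio 3 (LOD = 3σ_blank/slope,
   inverted through the axis transform).

`runSimulate()` / `runQuantify()` / `runPredict()` tie the stages into an
end-to-end workflow with JSON configs, CSV spectra/manifests and a JSON
report bundle; `inst/cli/sersquant.R` is a thin Rscript front end with the
same three subcommands.

## Worked example

```r
library(sersquant)
res <- runQuantify(defaultConfig(seed = 11))
#> region selection: 500-600 cm-1 (350-405: 0.998; 410-490: 0.996;
#>                                 500-600: 1.000; 1190-1250: 0.999)
res$selected_window            # "500-600"
res$pcabp$r_squared_log10      # 0.9962
res$plsr$r_squared_log10       # 0.5630
res$calibration$lod_ppm        # 0.0805
```

Reading the numbers: the four values after "region selection" are each
window's leading-PC variance fraction — 500–600 cm⁻¹ wins because the
concentration-responsive pyrene band dominates it. The PCA-BP network
explains 99.6% of the log-concentration variance on the held-out test split,
while the linear PLSR baseline, which cannot represent the Langmuir
saturation, reaches 0.56; the univariate calibration puts the SNR = 3
detection limit at 0.08 ppm. The report also carries the raw-ppm R², RMSE
in ppm, the prediction-versus-true line, the per-level calibration table and
full provenance (config + seed), so a run can be reproduced exactly.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the complete default pipeline (simulate → segment → select region →
train PCA-BP and PLSR → evaluate → calibrate → LOD) from the installed
package under the given master seed, logs the headline quantities to stderr,
and writes the JSON result file.
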