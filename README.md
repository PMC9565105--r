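# vegdyn

Per-pixel analysis of vegetation dynamics from annual growing-season
NDVI raster time series, for ecologists and remote-sensing analysts who
need to answer three questions about a greening (or browning) landscape:

1. **Where is vegetation changing, and how fast?** Closed-form OLS trend
   of NDVI on the time index i = 1..n,

       slope = (n·Σ i·NDVIᵢ − Σi·ΣNDVIᵢ) / (n·Σi² − (Σi)²),

   with a two-sided t test (df = n−2) and a five-class label at cuts
   ±0.001 and ±0.005 NDVI/yr.
2. **Was it climate or people?** Residual analysis: a per-pixel binary
   regression `NDVI_pre = a·T + b·P + c` on annual mean temperature and
   precipitation; the trend of the predicted series is the climate-change
   (CC) signal, the trend of the residual series `NDVI_obs − NDVI_pre`
   the human-activity (HA) signal. A six-condition scheme turns the three
   trend signs into percentage contributions (proportional shares when
   all signs agree; 100/0 splits when they do not).
3. **Will it continue?** Rescaled-range (R/S) Hurst exponent per pixel —
   the slope of ln(R/S) on ln r over non-overlapping windows — with a
   seven-class persistence label, a combined past-trend × future-persistence
   classification (15 cases in practice), and hotspot masks for
   significant degradation that will persist and significant improvement
   that will not.

Because causal ground truth does not exist for real rasters, the package
ships a synthetic-scenario generator (`generate_scenario()`) with a known
climate/human split and an exact fractional-Gaussian-noise simulator
(`generate_fgn()`, Davies–Harte) with prescribed H, so every estimator is
validated against scenarios where the right answer is known. Rasters are
read and written as plain-text ESRI ASCII grids; tables as CSV; legends,
manifests and reports as JSON; run configs as YAML.

## Worked example

```r
library(vegdyn)

sc <- generate_scenario(scenario_config())   # 21 yr x 20 x 25 default scenario
report <- run_analyze(sc$ndvi, sc$temp, sc$precip)
report
#> vegdyn_report: 500 valid pixels
#>   mean NDVI slope 0.002432 /yr; 95.0% slope>0; 43.2% significant
#>   mean CC 52.45% / HA 47.55% (0 undefined)
#>   Hurst: mean 0.681 (min 0.384, max 0.900); 95.4% persistent
#>   hotspots: 0 sustained degradation, 9 unsustained improvement
```

The default scenario plants a mean NDVI trend of 2.4 × 10⁻³/yr, half
from a cooling-and-wetting climate and half from a deterministic human
"restoration" rate — and the report recovers that: nearly all pixels
green (95.0% positive slopes), and the attribution splits the change
52.45% / 47.55% between climate and human drivers. The Hurst analysis
says the dynamics are persistent on 95.4% of pixels (mean H = 0.681), so
the greening should continue; the dominant combined classes are
improvement with medium (44.4%) and weak (23.0%) sustainability. Nine
pixels green significantly but with anti-persistent dynamics — the kind
of area a management plan would watch.

How trustworthy is the attribution under noise? Recovery against the
generator's ground truth:

```r
run_recover(scenario_config())
#>   noise_sd n_compared       mae     bias
#> 1     0.00        500  4.719998 4.719998
#> 2     0.01        500  9.960775 4.629536
#> 3     0.03        500 19.221321 7.812573
```

Mean absolute error of the estimated CC share is ~5 points even
noise-free (the finite-sample price of regressing out climate at n = 21;
see the methods vignette), ~10 points at realistic NDVI noise.

Single series work too:

```r
hurst_exponent(generate_fgn(2048, 0.8, seed = 1), window_sizes = 2^(4:8))
#> hurst_result: H = 0.7545 ( medium_sust ), 5 window sizes
```

See `vignettes/vegetation-dynamics.Rmd` for the model, parameter and
design discussion.

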