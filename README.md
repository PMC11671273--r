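# laminarGamma

Laminar gamma-oscillation analysis for trial-structured multielectrode
recordings from visual cortex — and a synthetic cortical column to validate
every stage against known ground truth.

## The problem

Linear probes inserted perpendicular to the cortical surface record the
local field potential (LFP) simultaneously across all layers of a column.
Whether the neurons of a column participate in one shared gamma rhythm or in
several layer-specific rhythms is a question about the *laminar
organization* of gamma-band activity, and answering it requires a chain of
signal-processing steps with sharp contracts:

1. **Current source density (CSD)** by the spline inverse CSD (iCSD)
   method: the LFP is modelled as arising from disc-shaped current sources
   (radius *R* = 500 µm, conductivity *σ* = 0.4 S/m) whose density varies
   smoothly with depth as a cubic spline; inverting the forward model per
   time sample yields a time-resolved CSD with far better spatial
   resolution than the LFP. The kernel of a disc at distance Δz is
   *k*(Δz) = (1/2σ)(√(Δz² + R²) − |Δz|).
2. **Layer identification**: the layer-III/IV border from the polarity
   inversion (source over sink) of the stimulus-evoked CSD, refined by the
   block structure of baseline (< 15 Hz) CSD correlations; channels are
   labelled supragranular (SG), granular (G, border to border + 0.5 mm) and
   infragranular (IG).
3. **Gamma-power hotspots**: per-domain peak channels of the 1/f-corrected
   Morlet-wavelet CSD power in the gamma band, with a gradient-based
   "hidden peak" fallback and a 2.5× stimulus-vs-baseline inclusion rule.
4. **Dominant gamma frequency** as the reciprocal median trough-to-trough
   cycle period of above-median-amplitude gamma episodes (band-pass 35–120
   Hz, Hilbert phase, π-crossings by linear interpolation).
5. **Bias-corrected phase coherence (PhC)**: the phase-locking value
   between a hotspot's CSD and the entire spiking activity (ESA) or CSD at
   every depth, minus the random-phase expectation EV(N) = √π/(2√N).
6. **Nonparametric statistics**: Kruskal–Wallis → Dunn → one-sided rank-sum
   for independent groups; Friedman → Tukey–Kramer-corrected signed-rank
   for paired conditions; rank-sum poolability gates; Pearson correlations
   with Bonferroni correction.

Because no public dataset with the required trial structure is available,
the package includes a **synthetic column generator** with three laminar
gamma oscillators (attention-dependent power and frequency), an evoked
onset response, phase-locked spiking, correlated baseline activity and 1/f
noise. The generator shares the volume-conductor model with the inversion,
so every pipeline stage has a recoverable target. See the methods vignette
(`vignettes/laminar-gamma-methods.Rmd`) for models, parameters and design
decisions.

## Worked example

```r
library(laminarGamma)

gt   <- buildGroundTruth(list(seed = 5L))          # package defaults
sess <- simulateSession(gt, c(attend_in = 30, attend_away = 30))
res  <- analyzeSession(sess, list(withPhc = FALSE))   # ~1.5 min on one core

res$border
#> [1] 550
res$hotspots
#>   domain channel     method    power included
#> 1     SG       4 local_peak 152.7601     TRUE
#> 2      G       9 local_peak 145.7560     TRUE
#> 3     IG      15 local_peak 127.3389     TRUE
str(res$frequencies$G)
#> List of 2
#>  $ pooled     : num 70.7
#>  $ byCondition: Named num [1:2] 70.9 70.5
#>   ..- attr(*, "names")= chr [1:2] "attend_in" "attend_away"
sapply(res$attention, function(a) a$powerPctIn)
#>       SG        G       IG
#> 31.82665 27.85184 14.99083
```

Reading: the layer-III/IV border is recovered at 550 µm (the generator's
truth); one gamma hotspot is found per laminar domain at channels 4, 9 and
15 (the oscillators sit at 300, 800 and 1300 µm — each detection within one
contact pitch); the granular dominant frequency is 70.7 Hz with essentially
no attention effect, while attend-in raises gamma power by ~32% at the
supragranular hotspot, ~28% at the granular and ~15% at the infragranular
hotspot (generator targets 38.1 / 28.5 / 16.0% — the residuals are sampling
noise at 30 trials per condition).

Sessions round-trip through a plain directory format (JSON manifest +
float32 binaries): `writeSession()` / `readSession()` /
`runFullPipeline(sessionDir, outDir)`, the latter writing CSV tables and a
JSON report. `inst/scripts/simulate_session.R` is a command-line wrapper
around the generator.

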