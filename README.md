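# etqrs

Real-time QRS-complex detection for single-lead ECG, built around an
**exponential transform** (ET) and a **proportional-derivative (PD)
controlled adaptive threshold** — plus the tooling to evaluate it and a
seeded synthetic annotated-ECG generator so the whole pipeline is testable
without downloading any database.

**Who it is for:** anyone who needs R-peak positions from a raw ECG sample
series — for heart-rate estimation, RR-interval analysis, or as the fiducial
anchor for downstream delineation — with a detector simple enough to audit
and port to hardware.

## The algorithm

Five stages over the sample series $x(n)$ (millivolts, sampling rate $f_s$):

1. **Band-pass** — 41-tap Hamming FIR, 5–15 Hz, group delay
   $(41-1)/2 = 20$ samples (compensated at report time);
2. **Difference** — $d(n) = f(n+1) - f(n)$, the pipeline's real
   low-frequency rejection;
3. **Exponential transform + accumulation** —
   $e(n) = |d(n)|\,e^{-|d(n)|}$ (compresses large slopes, equalising QRS
   heights), then $s(n) = \sum_{i=n-\lfloor q/2 \rfloor}^{n+\lfloor q/2 \rfloor} e(i)$
   over one QRS duration ($q = \lfloor 0.120 f_s \rfloor$);
4. **Extreme points + PD threshold** — consecutive 260 ms windows; a point
   is an extreme iff $(f(n)-f(n+j))(f(n)-f(n-j)) > 0$ for all
   $j \le \lfloor q/2 \rfloor$; the per-window threshold follows
   $TH[w] = TH[w-1] - a(TH[w-1]-TH_{\min}) - b\,\Delta TH$ with
   $a{=}0.5$, $b{=}0.1$, $TH_{\min}{=}0.15$, and a candidate must beat
   $M{=}1.5$ times its interpolated threshold;
5. **Tall-T rejection** — kept candidates closer than
   $\overline{RR}/K$ ($K{=}3$) are a QRS/tall-T pair: the larger-$s$ one
   survives.

Evaluation uses the standard beat-matching metrics
$Se = \frac{TP}{TP+FN}$, $P^+ = \frac{TP}{TP+FP}$,
$Acc = \frac{TP}{TP+FP+FN}$.

## Worked example

```r
library(etqrs)

sim <- generate(synth_preset("noisy", duration_s = 120, seed = 42))  # 10 dB SNR + wander
det <- detect(sim$record)
det
#> <qrs_detection 'synthetic': 144 beats @ 360 Hz>
#>   stages: 1626 extremes -> 264 candidates; 24 refractory, 0 tall-T rejected

compute_metrics(match_beats(detection_annotations(det), sim$truth$annotations,
                            tolerance = floor(0.150 * 360)))
#> <qrs_metrics: TP=144 FP=0 FN=0 | Se=100.00% P+=100.00% Acc=100.00%>

head(det$beat_indices)       # 0-based raw sample positions of the R peaks
#> [1]  125  446  738 1043 1352 1658
```

Reading it: of 1626 window extremes, 264 cleared the adaptive threshold; 24
duplicates within the 260 ms refractory were merged; all 144 true beats were
recovered with no false positives at 150 ms tolerance, and the implied mean
rate is 72 bpm — the generator's configured heart rate.

Real records work the same way via `read_record(path, "wfdb")` (MIT-BIH
`.hea`/`.dat`, formats 212/16/80) or two-column CSV, and
`read_annotations(path, "wfdb" | "text")`.  A command-line front end ships
at `inst/cli/etqrs` (`detect` / `eval` / `synth`).

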