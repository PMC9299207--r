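# ppgdtw — boosted subsequence DTW for PPG beat segmentation

`ppgdtw` segments a streaming photoplethysmogram (PPG) into cardiac cycles
and simultaneously locates the three fiducial points used for beat-by-beat
physiology — the pulse onset/endpoint (EP), the maximum-slope point (MS) and
the systolic peak (SYS). It is aimed at wearable-sensing work where interbeat
intervals (IBI), heart rate and downstream hemodynamic estimates must be
extracted from waveforms whose morphology varies between subjects and drifts
with respiration, without per-subject threshold tuning or training data.

## The method

Each sample `x_t` of the stream `X` receives an endpoint likelihood that
fuses a minimal domain heuristic with a morphology comparison against an
annotated single-cycle template `Y`:

    P(e_t) = P(c_t | x_t) * exp(-gamma * d(x_t, y_m))

* **Candidate heuristic.** Candidate endpoints `c_t` are the local minima of
  the band-passed signal; `P(c_t|x_t) = (g_t - min X') / (max X' - min X')`
  where `g_t` is the height of the upstroke peak that follows the candidate
  in the first derivative `X'`, min–max scaled per batch. Steep upstrokes
  mark plausible onsets.
* **Morphology likelihood.** `d(x_t, y_m)` is the running subsequence-DTW
  distance between the putative cycle (from its start to `x_t`) and the full
  template; `exp(-gamma * d)` maps it to (0, 1].
* **Search window.** The average cycle length `l_X = fs / f*` comes from the
  dominant pulsatile frequency of each 60-s batch. From a cycle start, a
  candidate arriving before `alpha * l_X` may reset the start; the endpoint
  is the candidate in `[alpha * l_X, beta * l_X]` with the greatest `P(e_t)`;
  if the window is empty the search restarts after `beta * l_X`. Defaults
  `alpha = 0.7`, `beta = 1.3`, `gamma = 5000`.
* **Fiducial mapping.** Template annotations transfer to each accepted cycle
  through the DTW warping path, then snap to the named landmark (minimum,
  derivative maximum, maximum) on a low-passed copy of the raw signal.
* **Dynamic template.** An ensemble of up to `k` templates adapts to evolving
  morphology: after each analysis region, a DTW-barycenter-average (DBA)
  consensus of the detected cycles is annotated from the prime template and
  added; when the ensemble is full and the prime is no longer optimal, the
  least frequently used template is evicted.
* **Baseline.** The original SPRING subsequence matcher (report a match when
  the running template-end distance is a confirmed minimum below a threshold)
  is included for comparison; it shares every stage except the endpoint rule.

A seeded synthetic PPG generator with exact ground-truth fiducials
(two-Gaussian beats with diastolic runoff, five morphology presets,
respiratory amplitude/baseline/frequency modulation, additive noise) makes
the whole pipeline testable without any data download.

## Worked example

```r
library(ppgdtw)

spec <- simulation_spec(duration_s = 60, fs = 300, hr_bpm = 72,
                        am_depth = 0.2, bw_depth = 0.2, fm_depth = 0.1,
                        noise_sd = 0.03, seed = 42)
sim      <- simulate_ppg(spec)          # stream + exact ground truth
template <- make_prime_template(spec)   # one annotated typical cycle
template
#> <annotated_template 'prime'> 249 samples @ 300 Hz; onset=1 MS=51 SYS=85; used 0

seg <- segment_stream(sim$stream, template, ppg_config())
seg
#> <ppg_segmentation> method=boosted_st, 71 cycles, 214 fiducials

evaluate_fiducials(seg$fiducials, sim$truth)
#>   label tp fp fn precision recall    f1 rmse_ms
#> 1    EP 72  0  1         1  0.986 0.993    7.61
#> 2    MS 71  0  1         1  0.986 0.993    6.99
#> 3   SYS 71  0  1         1  0.986 0.993    2.27

evaluate_ibi(seg$fiducials, sim$beat_times)
#>   source mae_ms pearson_r  n
#> 1     EP   6.85     0.996 71
#> 2     MS   8.15     0.986 70
#> 3    SYS   3.09     0.998 70
```

The 60-s recording holds 72 beats; the final beat is incomplete and is
discarded, so 71 cycles are reported. Every matched fiducial lies within the
30 ms tolerance (precision 1, recall 0.986 — the one miss per class is the
discarded trailing beat), timestamps are accurate to a few milliseconds
RMSE, and the beat-to-beat intervals derived from the systolic peaks agree
with the true beat times to 3.1 ms mean absolute error with correlation
0.998.

For a stream whose morphology drifts, use the dynamic ensemble or the
baseline instead:

```r
dt <- segment_stream_dynamic(sim$stream, template, ppg_config(k = 3))
sp <- spring_segment(sim$stream, template, ppg_config())
```

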