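# pambaleen

A tested, reusable R pipeline for shelf-scale passive acoustic monitoring
(PAM) of baleen whales, exercisable entirely on synthetic data.

PAM surveys moor autonomous recorders on the seafloor for months to years
and infer the daily acoustic presence of vocal species from their
stereotyped calls: right whale upsweeping "upcalls" (71–224 Hz,
0.3–1.5 s), humpback song and social-call units, fin whale 20-Hz notes,
sei whale downsweeps (34–82 Hz, about 1.4 s), and blue whale A–B song
phrases (15–19 Hz). `pambaleen` implements every stage of such an
analysis for audiences who need to build, validate, or stress-test one
without access to multi-terabyte field recordings:

* **synthetic soundscapes** — spectrally shaped, vessel-noise-dominated
  ambient sound with calls injected at controlled band SNR and exact
  ground-truth annotations (`generate_ambient_noise()`,
  `synthesize_call()`, `inject_calls()`), plus a daily Bernoulli presence
  simulator with cyclic seasonal structure, survey-year effects, site
  random effects and AR1 latent correlation
  (`simulate_presence_dataset()`);
* **detectors** — spectrogram template cross-correlation
  (`detect_template_xcorr()`), waveform matched filtering
  (`detect_matched_filter()`), upsweep contour tracing
  (`detect_upcall()`), band-energy/tonality unit detection
  (`detect_humpback_units()`), co-occurrence screening and 1-in-k-hour
  review schedules;
* **validation** — daily-scale true positive rate against ground truth:
  a calendar day is a TP day when at least one detection overlaps a
  ground-truthed signal in both time and frequency, and
  `TPR = TP / (TP + FN)` (`daily_tpr()`);
* **presence aggregation** — detected / not-detected / missing daily
  tables, season and survey-year summaries with integer percentages
  (`daily_presence()`, `summarize_presence()`, `pool_season_summary()`);
* **seasonal model** — a Bernoulli GAM
  `logit p = β₀ + f_cyc(month) + year + site`, with a cyclic spline over
  calendar month, survey-year factor, site random effect, and an AR1
  working-correlation adjustment; back-transformed estimated marginal
  means and Tukey-adjusted pairwise year contrasts
  (`fit_presence_gam()`, `estimated_marginal_means()`,
  `pairwise_year_contrasts()`);
* **ambient noise** — calibrated 10-minute band L_eq (1-s Hann frames,
  1-Hz resolution) in species 1/3-octave bands, with 5th/50th/95th
  percentile noise conditions (`leq()`, `noise_percentiles()`);
* **detection range** — the passive sonar equation `RL = SL − TL` with
  the hybrid spreading model `TL = 20·log10 H + 17·log10(R/H)` beyond the
  spherical regime, solved to the SNR = 0 range along eight bearings and
  averaged (`solve_detection_range()`, `bearing_averaged_range()`).

Everything takes and returns tidy tibbles (audio lives in a light
`waveform` object), chains with the pipe, and exposes `tidy()`,
`glance()` and `autoplot()` methods for the fitted objects.

## Worked example

Build a ten-minute synthetic scene, detect the injected fin whale notes,
and score the detector:

```r
library(pambaleen)
library(tibble)

fs <- 400                                    # decimated fin-band stream
noise <- generate_ambient_noise(600, fs, shelf_spectrum(75), seed = 51)
calls <- tibble(
  time = seq(5, 590, length.out = 50),
  wave = lapply(1:50, function(i)
    synthesize_call("fin", fs, seed = 5100 + i, jitter = 0.3)),
  species = "fin")
scene <- inject_calls(noise, calls, snr_db = 10)

kernel <- synthesize_call("fin", fs, jitter = 0)
events <- detect_matched_filter(scene$wave, kernel)
matched <- match_detections(events, scene$annotations)
mean(matched$matched)
#> [1] 1
range(events$score)
#> [1] 0.5374608 0.7978516
```

All 50 notes injected at 10 dB band SNR are recovered; scores are
normalised correlations, so the default threshold (0.45, calibrated to a
false-alarm rate below one per ten minutes on noise-only audio) transfers
across recordings. The same scene grammar drives the other detectors, the
daily-TPR evaluation, and `run_pipeline()`, which chains
simulate → detect → validate → presence → model → noise → range into a
reproducible artifact directory:

```r
res <- run_pipeline(default_scenario(seed = 1), "demo_out")
tidy(res$validation)
#> # A tibble: 1 × 5
#>   species tp_days fn_days   tpr n_evaluated
#>   <chr>     <int>   <int> <dbl>       <int>
#> 1 fin           6       0     1           6
```

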