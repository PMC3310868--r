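# gcdoa

Granger-causality features for discriminating the **awake** from the
**anesthetized** brain state in multichannel EEG.

## The problem

A depth-of-anesthesia monitor must, at minimum, tell an awake patient from
an anesthetized one — quickly, and from the EEG alone. Spectral features do
this imperfectly because they track drug-specific surface phenomena rather
than the disruption of consciousness itself. A more mechanism-adjacent
marker is *effective connectivity*: when consciousness is lost, directed
influence from frontal onto posterior brain regions increases sharply, and
the change reverses at recovery. `gcdoa` implements the complete analysis
that extracts this marker and classifies brain state from it, together with
a synthetic-EEG generator that lets every stage be validated without
patient data.

## The statistic

For two windowed series the package fits, over identical effective samples,
a univariate AR(p) model of `x1` (residual variance Γ₁) and a bivariate
VAR(p) of `(x1, x2)` (residual variance Σ₁₁ for the `x1` equation).
Granger causality from `x2` to `x1` is Geweke's log variance ratio

```
GC_{2→1} = ln(Γ₁ / Σ₁₁)  ≥ 0
```

with the off-diagonal bivariate residual covariance reported as
*instantaneous causality*. The pipeline around it:

* five region averages (LF, RF, LP, RP, Z) over the 19-channel 10/20
  montage, with signal-based bad-channel exclusion;
* 4-s windows sliding by 1 s, admitted only if they pass KPSS level
  stationarity (1% level), Durbin–Watson residual whiteness, ≥ 70% model
  consistency, and an 8-MAD amplitude artifact gate;
* AR order 6 (or BIC-selected), GC for all 10 region pairs in both
  directions, trailing 10-window moving-average smoothing;
* significance thresholds from 19 phase-randomized surrogates (max rule,
  one-sided 5%), and a volume-conduction control via SOBI source-shift
  surrogates scored by the goodness of fit of the line y = x (negative r²
  ⇒ the observed GC is not explained by instantaneous mixing);
* bootstrap classification (B = 200) of the four smoothed
  frontal→posterior GC features with LDA, linear SVM and RBF SVM,
  reporting specificity, sensitivity and average accuracy (awake =
  positive class), plus one-way ANOVA comparisons between classifiers and
  between induction (LOC) and recovery (ROC) conditions.

## Worked example

```r
library(gcdoa)

cfg <- pipeline_config(
  sim  = sim_config(durations = c(awake_pre = 120, anesth = 480, awake_post = 120),
                    coupling_anesth = 0.4, seed = 7),
  pairs = "frontal_posterior", B = 100, n_significance_windows = 5,
  seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
Pipeline result
===============
AR order: 6
Attrition: total=588, admitted=559, non_stationary=19, dw_failed=4, inconsistent=5, artifact=1

Condition LOC
Bootstrap study: B = 100, N_train = 90 (awake 113, anesthetized 171)
  LDA    SP 1.000+-0.000  SE 1.000+-0.000  Acc 1.000+-0.000
  SVM_L  SP 1.000+-0.000  SE 1.000+-0.000  Acc 1.000+-0.000
  SVM_NL SP 1.000+-0.000  SE 1.000+-0.000  Acc 1.000+-0.000

Condition ROC
Bootstrap study: B = 100, N_train = 84 (awake 105, anesthetized 170)
  LDA    SP 1.000+-0.000  SE 1.000+-0.000  Acc 1.000+-0.000
  ...

Volume-conduction check: r^2 = -2.711 (volume-conduction-rejected)
```

Reading the output: of 588 candidate windows, 559 pass the four admission
gates (29 excluded, mostly by the stationarity test). The mean smoothed
frontal→posterior GC is ≈ 0.23 in the anesthetized windows versus ≈ 0.006
awake — the directed coupling switching on — and all three classifiers
separate the states perfectly on this synthetic recording at both the
induction and the recovery boundary. The negative volume-conduction r²
says the source-shift surrogate (which preserves instantaneous mixing but
destroys lagged interaction) does *not* reproduce the observed GC, i.e.
the detected connectivity reflects genuine lagged coupling.

A command-line wrapper with `simulate`, `gc`, `classify`, `run` and
`check-volume-conduction` subcommands is installed at
`inst/scripts/gcdoa`; see its header for usage.

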