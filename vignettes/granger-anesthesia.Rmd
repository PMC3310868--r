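---
title: "Granger-causality features for awake versus anesthetized EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-causality features for awake versus anesthetized EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During general anesthesia the clinically important question is binary: is
the patient awake or anesthetized? A robust electrophysiological marker of
that distinction is a change in *effective connectivity* — directed,
causal-style influence between brain regions — rather than any particular
spectral feature of the EEG. The most characteristic change is a sharp
increase of directed influence from frontal onto posterior scalp regions
when consciousness is lost, which reverses at recovery. `gcdoa` implements
the full analysis chain that turns a multichannel EEG recording with
induction (LOC) and recovery (ROC) markers into that marker and into a
classified awake/anesthetized state sequence.

## Granger causality in the time domain

For two windowed series $X_1, X_2$ the package fits, by OLS with an
intercept, a univariate AR model of order $p$

$$x_1(t) = c + \sum_{k=1}^{p} a_k\, x_1(t-k) + u(t), \qquad
\Gamma_1 = \widehat{\mathrm{var}}(u),$$

and a bivariate model over the *same effective samples*

$$x_1(t) = c' + \sum_{k=1}^{p} a'_k\, x_1(t-k) + \sum_{k=1}^{p} b'_k\, x_2(t-k) + e_1(t), \qquad
\Sigma_{11} = \widehat{\mathrm{var}}(e_1).$$

Granger causality from $X_2$ to $X_1$ is the Geweke log-ratio

$$GC_{2 \to 1} = \ln\!\frac{\Gamma_1}{\Sigma_{11}} \ge 0 ,$$

and symmetrically for the other direction. The off-diagonal
$\Sigma_{12}$ of the bivariate residual covariance is the *instantaneous
causality*: dependence not explained by either lag structure (a common
driver or volume conduction signature). It is computed and reported but is
not a classification feature.

Three conventions are fixed so that results are exactly reproducible:

* the natural logarithm (Geweke's standard form) is used;
* residual variances use divisor $n_\mathrm{eff} = N - p$; GC is a ratio of
  variances over a shared sample, so only consistency of the convention
  matters;
* because the univariate regressors are a subset of the bivariate ones on
  identical samples, $\Sigma_{11} \le \Gamma_1$ in exact arithmetic; tiny
  negative GC from round-off (above $-10^{-12}$) is clipped to zero.

For the benchmark system ($x_2$ white, $x_1(t) = c\,x_2(t-1) + \varepsilon$,
unit variances) the asymptotic value is $\ln(1 + c^2)$, which the test
suite verifies against a brute-force normal-equations oracle.

## The pipeline

1. **Ingest.** Recordings are read from a delimited channel-matrix text
   file or 16-bit EDF (each with a JSON sidecar carrying sampling rate,
   markers and, for synthetic data, ground truth). Labels are matched
   case-insensitively against the 19-electrode 10/20 set. No frequency
   filtering is applied at any point of the default path: filtering
   perturbs the timing relations GC measures.
2. **Bad channels.** Hardware impedance is unavailable from file, so a
   signal proxy excludes channels that are flat (variance below `flat_tol`)
   or saturated (≥ `clip_fraction` of samples at an extreme).
3. **Region averaging.** Five regions — LF (Fp1, F7, F3, T3, C3), RF (Fp2,
   F8, F4, C4, T4), LP (T5, P3, O1), RP (T6, P4, O2), Z (Fz, Cz, Pz) — are
   the arithmetic means of their non-excluded members. A region with no
   usable electrode is *absent*: GC pairs involving it are skipped and the
   feature dimensionality shrinks accordingly, rather than averaging
   nothing silently.
4. **Windows.** 4-second windows sliding by 1 s. Awake windows come from
   before LOC and after ROC; anesthetized windows start 300 s after LOC
   (discarding intubation artifacts and any not-yet-unconscious data) and
   immediately before ROC, capped at 300 per condition. Windows never
   straddle a marker; sample indices are 0-based and windows half-open.
5. **Admission gates** (all four must pass):
   * *KPSS level stationarity* at critical level 0.01, truncation lag
     $\lfloor 4 (n/100)^{1/4}\rfloor$, on every region series; the level
     (not trend) variant because short EEG windows carry no deterministic
     trend model. An exactly constant window is stationary by convention.
   * *Durbin–Watson* on the univariate AR residuals of every region.
     The decision rule is sample-size aware: flag when the implied lag-1
     autocorrelation $|1 - DW/2|$ exceeds $2/\sqrt{n_\mathrm{eff}}$
     (the approximate 95% whiteness band) rather than a table lookup.
   * *Model consistency* (Ding-style): simulate the fitted bivariate VAR
     once at the window's own length, innovations resampled jointly from
     the fit residuals, and compare stacked auto-/cross-correlations up to
     lag $p$: $100\,(1 - \lVert R_{sim} - R_{data}\rVert / \lVert
     R_{data}\rVert)$, clipped to $[0, 100]$; windows under 70% are
     excluded, an unstable fitted VAR scores 0. The per-window flag is the
     minimum over the four frontal→posterior pairs. When consistencies of
     *different orders* are compared, the correlation lag range must be
     fixed across fits (`lag_max`), otherwise the lower order is scored
     against an easier target.
   * *Artifacts*: any sample beyond 8 MAD of its marker-delimited segment
     (pre-LOC / LOC–ROC / post-ROC, per region) marks the window. The
     envelope is segment-local deliberately: the two states legitimately
     differ in amplitude, and a global envelope would flag one state
     wholesale. Residual outliers are further damped by the trailing
     moving-average smoother.
6. **AR order.** Fixed at 6 by default; `ar_order = "bic"` instead
   minimizes the bivariate BIC ($n_\mathrm{eff}\ln\det\Sigma + k\ln
   n_\mathrm{eff}$, $k = 2(2p+1)$) summed over a sample of windows. The
   fixed order is the default because order 6 does not degrade model
   consistency while keeping every window comparable.
7. **GC series.** All 10 region pairs (both directions) per admitted
   window, plus instantaneous causality. A trailing moving average of 10
   windows smooths each directed pair independently within each
   (condition, state) block — trailing, not centered, because the intended
   use is prompt detection of state changes.
8. **Significance.** 19 phase-randomized surrogates per tested window:
   amplitudes kept, independent uniform phases (DC/Nyquist real, conjugate
   symmetry enforced). The per-direction maximum surrogate GC is the
   significance level, a one-sided 5% test by the max rule
   ($1/(n_{surr}+1)$). Surrogates run through *identical* fitting as the
   real data; exchangeability of the null requires identical processing.
9. **Volume conduction.** The source-shift surrogate: SOBI (whitening +
   Jacobi joint diagonalization of symmetrized lagged covariances, lags
   1–20, chosen to exceed the AR order) unmixes the channels; source $n$ is
   circularly shifted by $(n-1)\,T$ samples ($T = 100$, far beyond the
   autocorrelation time; circular so second-order statistics survive);
   the estimated mixing matrix remixes. Instantaneous structure survives,
   lagged cross-source structure does not. With $x$ the original GC values
   and $y$ the surrogate ones, the fixed line $y = x$ is scored by
   $r^2 = 1 - SS_{res}/SS_{tot}$ (no fitted parameters, so $r^2 < 0$ is
   possible and meaningful). Verdict: volume conduction *cannot be
   excluded* iff $r^2 \ge 0$ — the criterion is the sign.
10. **Classification.** Feature vector per admitted window: the four
    smoothed frontal→posterior GC values (LF→LP, RF→LP, LF→RP, RF→RP).
    Awake is the positive class. Per bootstrap repetition,
    $N_{train} = \min(\lfloor 0.8 N_{aw}\rfloor, \lfloor 0.8
    N_{an}\rfloor, 100)$ windows per class are drawn *without* replacement
    for training and the remaining windows are the test set; B = 200
    repetitions provide the resampling distribution. (Drawing without
    replacement within a repetition is the only reading under which "the
    remaining windows" is well defined; the repetitions carry the
    bootstrap resampling.) Classifiers: Fisher LDA with pooled covariance
    and equal priors (ridge 1e-6 on a singular pooled covariance), linear
    SVM, and RBF SVM with kernel $\exp(-\lVert u-v\rVert^2/2\sigma^2)$,
    $\sigma = 1$ on features standardized by training-set mean and scale —
    standardization is what makes a unit kernel radius meaningful across
    recordings, given large between-subject GC scale differences. SVM cost
    C = 1 (conventional default, exposed in config). Metrics:
    $SE = TruP/TotP$, $SP = TruN/TotN$, and *average accuracy*
    $(SE+SP)/2$ — the balanced form, because sensitivity and specificity
    are equally important for an awareness monitor and the class sizes are
    unequal. Classifier-vs-classifier and LOC-vs-ROC comparisons use a
    two-group one-way ANOVA F-test at $\alpha = 0.05$ (degenerate case:
    zero within-group variance with equal means gives F = 0, p = 1).

## The synthetic generator

Real recordings of this kind are not redistributable, so `sim_config()` /
`generate_recording()` define the study conditions for every test:

* five regional *sources* follow stable AR(6) dynamics (an alpha resonance
  near 10 Hz, modulus ≈ 0.9; a weak beta pair near 20 Hz; two small real
  poles), mildly varied across regions. Persistence is deliberately
  moderate: the generator must emulate data whose 4-s windows are
  level-stationary and AR-representable, which is exactly what the
  admission gates assume. Strong pole mass near DC would make the KPSS
  gate reject large fractions of perfectly synthetic windows and would
  emulate a violation of the analysis' assumptions instead;
* during the anesthetized span both frontal sources drive both posterior
  sources with lag-1 coefficient `coupling_anesth` (default 0.4; awake
  default 0). The switch happens exactly at the LOC/ROC markers and is
  recorded in `truth`. The defaults are chosen for clear state separation —
  no quantitative per-patient effect size is available to calibrate
  against, and between-subject variability in real GC magnitudes is large;
* every electrode observes its region's source plus independent sensor
  noise (SD 0.5 against unit innovation SD), so region averaging is a
  genuine denoising step;
* optional nuisance structure: 50-Hz line noise (pure sinusoid, random
  phase per channel — the simplest model that makes the notch-filter
  comparison meaningful), Poisson bursts of high-amplitude artifact
  (≤ 0.5 s, all channels), near-constant DC-offset bad channels, and an
  instantaneous mixing matrix for volume-conduction experiments;
* stability of the generating VAR (spectral radius of the companion matrix
  < 1) is verified at configuration time, and identical config + seed is
  bit-identical.

What the generator does *not* emulate: 1/f background spectra, a dipole
forward model, non-Gaussian innovations, burst suppression, or
drug-kinetics-driven gradual transitions. Passing tests therefore
demonstrate that the *pipeline* recovers the structure it targets under
its own assumptions — not that real EEG satisfies those assumptions.

## Numerical and design choices

* **Seeding.** One global seed; every stochastic stage draws a substream
  seed from a 31-bit multiplicative hash of (seed, stage tag). Entire runs
  are byte-reproducible.
* **Singular fits** (collinear or constant windows) are window-level
  `undefined` flags, never run-aborting exceptions; surrogate singular
  fits are redrawn a bounded number of times, then counted and skipped.
* **SOBI convergence.** Rotation tolerance defaults to $0.01/\sqrt{n}$:
  with more channels than sources the noise subspace is nearly degenerate
  and Jacobi rotations there converge linearly into statistical noise, so
  demanding machine precision would never terminate; 200 sweeps suffice at
  this tolerance.
* **Notch filter** (optional, default off): a second-order IIR biquad at
  50 Hz with unit DC/Nyquist gain and a 1-Hz −3 dB bandwidth. The output
  is flagged so filtered and unfiltered GC can be compared.
* **Problem sizes.** The test suite and the acceptance script size their
  simulations for a desk machine: the analytic-limit check averages 200
  windows of 1024 samples; the null-calibration check uses 500 (tests) or
  200 (script) windows with 19 surrogates each; the end-to-end
  classification study uses the default 10 min awake / 20 min anesthetized
  / 10 min awake recording at 256 Hz; diagnostic power/size use 100–200
  replicates; the volume-conduction discrimination uses 3-channel systems
  with 20 × 512-sample windows. These are the package's documented study
  conditions for its own validation.

## Known limitations

* Pairwise (not conditional or blockwise) GC: common-driver effects appear
  as bidirectional GC plus instantaneous causality and are controlled only
  through the surrogate machinery.
* The consistency statistic uses a single stochastic replicate at window
  length, so it carries sampling noise of a few percent; its role is a
  gate at 70%, not a precise goodness-of-fit measure.
* The EDF support is the plain continuous 16-bit subset (no EDF+
  annotations); markers travel in the JSON sidecar.
* Classification is per recording; no cross-subject transfer or pooling.
* **Evaluation optimism under dependence.** Windows slide by 1 s with 4-s
  length and are smoothed over 10 windows, so neighbouring feature vectors
  are nearly identical, while the bootstrap splits train and test *at the
  window level*. A test window therefore usually has a same-class training
  window seconds away, and a local classifier (the σ = 1 RBF SVM
  especially) can exploit that temporal adjacency: on a zero-coupling
  recording, where the two classes are exchangeable by construction, the
  measured average accuracy sits well above chance (about 0.55–0.70
  depending on classifier) instead of at 0.5. Disabling smoothing and
  overlap restores chance-level nulls, confirming the mechanism is
  train/test contamination through dependent windows rather than any
  spurious class signal. The near-ceiling accuracies under genuine coupling
  are driven by true class separation, but absolute accuracy values from
  this window-level evaluation scheme should be read as optimistic, and a
  chance-level null should not be expected from it.
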