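---
title: "hemowatch: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemowatch: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The monitoring problem and the pipeline's assumptions

Progressive central hypovolemia is compensated by autonomic reflexes that
hold heart rate and blood pressure near normal until shortly before
cardiovascular collapse. The detectable signature of the compensating state
lives in subtler properties of the ECG: the distribution of beat-to-beat
(R–R) intervals, small shifts in P-QRS-T morphology, and the beat-amplitude
modulation imposed by respiration. The pipeline therefore assumes:

* a single continuous ECG lead, nominally sampled at 500 Hz;
* sinus rhythm — no arrhythmia or ectopy handling is attempted;
* analysis windows defined by a fixed *count of beats* (default 120), not a
  fixed duration, so that no feature carries heart rate directly (heart
  rate generalizes poorly across subjects);
* per-subject ordered stress stages (baseline first), with class labels
  derived by splitting each subject's stages in half and excluding the
  final pre-collapse stage.

## 2. Preprocessing

**Windowing.** Tumbling (non-overlapping) windows of `beats_per_window`
complete beats. Beat positions must exist before beat-count windows can be
cut, so a provisional R-detection pass runs on the full record first; the
per-window processing then repeats filtering and detection inside the
window. Windows straddling stage boundaries are labeled by the stage
containing their midpoint sample — the boundary-straddling rule is not
dictated by the problem, and the midpoint is the least biased single-point
rule.

**Baseline removal.** Each window is fit with a degree-6 least-squares
polynomial (orthogonal basis for conditioning) and the fit subtracted.
The residual is orthogonal to the polynomial space, making the operation
idempotent — a property the tests assert. The fit is per-window: a single
degree-6 polynomial cannot track wander over a whole record, and per-window
fitting is what makes the degree-6 default sensible.

**Smoothing.** Savitzky–Golay with polynomial order 2. The frame length is
not fixed by the method; the default of 15 samples (30 ms at 500 Hz) is
chosen to suppress wideband noise while leaving QRS complexes (80–120 ms)
essentially untouched; both parameters are configurable.

**Low-frequency removal.** A 10-level periodized Daubechies-4 DWT with the
level-10 approximation *and* level-10 detail coefficients zeroed, then
inverse transformed. At 500 Hz this suppresses content below roughly
`fs/2^11 ≈ 0.24 Hz` (baseline wander, drift) with no phase distortion of
the QRS. The DWT is implemented in the package (periodized, FFT-based
circular convolution); with orthonormal filters the transform matrix is
orthogonal, so reconstruction and energy bookkeeping are exact to machine
precision rather than approximately.

## 3. Fiducial detection

The R detector rectifies the dominant polarity, band-limits with a 24 ms
moving average, squares the derivative and integrates it over 120 ms —
a slope-energy transform in the Pan–Tompkins tradition. QRS complexes have
far steeper slopes than P/T waves, so the transform separates them by more
than an order of magnitude; an adaptive threshold (0.25 of an exponentially
tracked peak estimate) with a 200 ms refractory period selects events, and
each event is refined to the signal extremum within ±60 ms.

P/Q/S/T delineation searches physiologic windows relative to each R peak
(Q: minimum in (R−80 ms, R); S: minimum in (R, R+120 ms); T: maximum in
(R+80 ms, R+0.6·RR); P: maximum in (R−0.35·RR, R−100 ms)). These window
constants are standard interval physiology, not derived quantities, and are
configurable. An extremum must rise above a prominence floor (4% of the
mean R amplitude) or the wave is marked missing; missing waves are imputed
from the previous beat's R-relative offset scaled by the ratio of the
current to previous R–R interval (leading gaps fill from the next beat with
the reciprocal scaling). Amplitude normalization subtracts the window
median and divides by the mean R amplitude, making every amplitude feature
invariant to positive affine rescaling of the raw signal.

## 4. Feature families

The full enumeration (748 names) is frozen in `feature_manifest()`. The
printed family sizes in the source study (839 peak-based, 64 taut-string,
198 DTCWT, and a stated total of 1117) cannot be reconstructed exactly —
the study's own counts are mutually inconsistent (839+64+198+10 = 1111) and
the feature lists are elided ("etc."). This implementation therefore
enumerates each family from its stated construction rule and treats the
printed counts as soft anchors:

* **Interval ratios (210).** Ten intra-beat intervals {PQ, …, ST} and five
  beat-to-beat same-wave intervals {PP, …, TT}; for every ordered pair the
  mean over beats of the per-beat ratio. Mean-of-ratios (not
  ratio-of-means) matches the defining formula of the `t_qt/rr` prototype.
  All are dimensionless and invariant to global time rescaling — the
  property tests multiply all fiducial times by a constant and assert
  equality to 1e-12.
* **Amplitude features (330).** Fifteen base series (ten intra-beat pairwise
  differences, five beat-to-beat differences), their means, all ordered
  pairwise mean-of-ratio features, and all unordered pairwise
  mean-of-product interactions.
* **Spectral extras (14).** Dominant frequency and power, median (50%
  cumulative power) and edge (95%) frequency of the R–R periodogram; the
  spread, dominant/median/edge frequencies of the ECG-derived respiration
  signal and of its first difference. EDR uses the R-amplitude-modulation
  variant (detrended beat-wise R amplitudes, cubic-spline resampled at
  4 Hz); the QRS-area variant is out of scope.
* **Taut string (64).** See §5.
* **DTCWT (120).** See §6.
* **Traditional HRV (10).** SDNN, SDSD, RMSSD, pNN50, LF and HF band
  powers, HF/LF, mean, skewness, kurtosis. Three deliberate literalisms:
  SDSD is implemented exactly as the source prints it — the population SD
  of the *absolute* successive differences about their mean — with a
  `conventional = TRUE` switch for the textbook sample-SD-of-differences;
  the LF band starts at 0.004 Hz as printed (conventional HRV uses 0.04;
  configurable); pNN50 counts differences *strictly* greater than 50 ms.
  Kurtosis is non-excess everywhere (normal = 3).

## 5. Taut-string decomposition

For the R–R series `z` and tube half-width ε, the taut string `x` is the
unique minimizer of the squared roughness `Σ (x_{i+1} − x_i)²` subject to
`|x_i − z_i| ≤ ε`. Geometrically it is a string pulled taut inside the tube
`[z − ε, z + ε]`; it simultaneously minimizes every convex symmetric
function of the increments, including the ℓ1 norm of the discrete second
derivative. The implementation is the greedy segment-fixing (funnel)
algorithm: extend the longest feasible straight segment from the current
anchor; when the feasible slope window closes, bend at the barrier contact
that defined the binding slope (upper contacts produce convex knots, lower
contacts concave knots), and re-anchor. Endpoints are free, which makes the
string enter and leave horizontally; when an entire flat line fits in the
tube the midline of the final feasibility window is returned (the unique
choice is otherwise degenerate). Correctness is not argued, it is tested:
200 random instances against an independent box-constrained QP solve
(L-BFGS-B) at 1e-6 relative objective tolerance, plus an LP oracle
(`scipy.optimize.linprog` through the system `python`) for the
second-derivative-ℓ1 equivalence, plus hard tube-feasibility assertions on
every call.

Per ε the features are mean/SD/skewness/kurtosis of `x`, SD and kurtosis of
the residual `y = z − x`, the inflection count of `x` (sign changes of the
second difference, zero runs collapsed), and the variability index
`v(ε) = mean |Δy|`. The specification of this family was internally
inconsistent (a ten-statistic list versus an 8 × 8 = 64 layout); the 64
layout was kept and the two least informative residual statistics — mean
and skewness of a bounded, near-zero-mean residual — were dropped. The ε
grid {4, 8, 16, 32, 64, 128, 256, 512} ms is a doubling sweep around the
one disclosed value, ε = 32 ms. `v(32)` is the "taut string 32" index: it
captures R–R variability of amplitude ≤ 32 ms, and its median across
simulated severity stages decreases monotonically (tested over 100 seeds).

## 6. Dual-tree complex wavelet features

Two parallel orthonormal periodized DWTs form the real (tree A) and
imaginary (tree B) parts of five complex subbands. Level 1 uses db4 with
tree B's input delayed one sample — after decimation the two trees hold
exactly the even and odd phases of one filtered signal, so the half-sample
inter-tree offset at level 1 is exact. Levels 2–5 use the published 14-tap
q-shift filter and its time reverse; the orientation (tree A takes the
reversed filter) is the one whose per-level delay differences telescope
with the level-1 offset into the required half-period offset at every
level, and was confirmed empirically — the opposite orientation degrades
level-2/3 shift invariance by an order of magnitude. The q-shift
coefficients were re-projected onto their exact orthonormality constraints
(maximum coefficient change 1.2e-7) so that each tree is an exactly
orthogonal transform: perfect reconstruction to ~1e-12 and exact energy
conservation, both asserted on 100 random windows.

The design deviates from the classical biorthogonal 13/19-tap first stage:
no trustworthy 19-tap coefficient table was available in this build
environment, and the orthonormal-db4-plus-delay construction delivers the
same contracts with *exact* level-1 shift invariance. Measured approximate
shift invariance under a one-sample shift (50 ECG windows): mean per-level
magnitude-energy change 0% / 2.5% / 1.3% / 0.2% / 0.07% for levels 1–5;
single-window worst cases reach ~8% at level 2, the known analyticity limit
of a 14-tap q-shift pair.

Features: mean, SD, skewness, kurtosis, energy, and mean absolute first
difference for each level's real, imaginary and magnitude coefficient
sequences (90), and for each cumulative lowpass remainder waveform
(level-k residual = signal minus the reconstruction of detail levels 1..k;
30). The two features the downstream model singles out are
`dtcwt_res3_kurt` (kurtosis of the level-3 residual; equals 3 on white
Gaussian input, the acceptance anchor) and `dtcwt_res5_mean` (mean of the
final residual). "Residual" here is the cumulative-reconstruction
remainder, not the subband itself — the other reading of an ambiguous
phrase; the subband statistics are present in the family regardless, so
nothing is lost by the choice.

## 7. Feature selection

Stage 1 computes per-subject feature–feature Pearson correlation matrices
over that subject's windows and averages their absolute values across
subjects (absolute, because an anti-correlated duplicate is exactly as
redundant as a correlated one). Features are removed greedily — most
above-0.9 partners first, counts updated after each removal, ties broken by
manifest order — until no pair remains at or above 0.9. An exhaustive
post-hoc rescan in the tests confirms the terminal state.

Stage 2 is forward stepwise selection: starting from the intercept-only
model, add the candidate maximizing the mean training-fold R² across 10
subject-wise folds; stop at k = 10. The response defaults to the quantized
severity index (the final reported model is a linear regression onto
severity); a binary-label mode exists. The final all-rows refit reports
coefficients, standard errors, t-ratios, p-values and VIFs
(`1/(1 − R²_j)`), and the report carries the held-out R² of the selected
model. Subject-wise folds are non-negotiable: window-level folds would leak
a subject's idiosyncratic morphology between train and validation.

## 8. Labeling, severity and the classifier

For a subject with `L` ordered stages (baseline = 0; recovery is never
simulated or accepted), stages `0..⌈L/2⌉−1` are *normal*, stages up to
`L−2` are *abnormal*, and stage `L−1` — the stage in which decompensation
occurs — is excluded from labeled data. The continuous severity index
`stage/(L−1)` is quantized half-up to {0, 0.2, 0.4, 0.6, 0.8} and capped at
0.8; for all cohort-relevant stage counts (`L ≥ 5`) the final retained
stage maps to 0.8. For `L = 4` it maps to 0.6 — a degenerate case flagged
in the documentation rather than silently repaired.

The classifier is a linear SVM in primal squared-hinge form
(`½‖w‖² + C · mean(max(0, 1 − y f)²)`), solved by L-BFGS. The original
implementation used LIBSVM's hinge loss; the squared hinge is the
deterministic, dependency-free member of the same family and its decision
boundary is indistinguishable on separable and near-separable data — the
regime the acceptance criteria test. Averaging the loss over samples (not
summing) makes fold metrics exactly invariant to row duplication, a tested
invariant. Evaluation is nested: outer 10-fold subject-wise CV; inner
10-fold CV over the cost grid `2^{−6}, 2^{−4}, …, 2^{8}` scored by mean
AUC; refit on all non-validation rows with the winning C; standardization
statistics computed from non-validation rows only. Reported metrics are
fold means with Student-t 95% confidence intervals (the CI method is not
specified by the source; t over 10 folds is the standard choice), the
positive class is *abnormal*, and feature-set comparisons use two-sided
(exact where possible) Mann–Whitney U tests on fold-level metrics at
α = 0.01. Fold-level rather than window-level comparison was chosen because
windows within a subject are strongly dependent; a window-level test would
overstate significance.

## 9. The synthetic cohort: what it is and is not

`simulate_cohort()` states a world once and keeps it:

| parameter | default | source of the value |
|---|---|---|
| baseline HR | U[50, 80] bpm | lowest baseline HR in the study cohort is stated as 50 bpm |
| stage length | 300 s | the LBNP protocol's 5-minute stages |
| final stage | truncated U(150, 300) s | decompensation occurs mid-stage |
| stages tolerated | 4–8, probabilities 56/55/47/16/4 ÷ 178 | the study's printed tolerance distribution |
| HF (RSA) depth | U[25, 55] ms at U[0.18, 0.32] Hz | physiologic RSA in healthy adults |
| LF (Mayer) depth | U[15, 35] ms at 0.1 Hz | physiologic Mayer-wave power |
| broadband jitter | U[5, 12] ms SD | residual HRV broadband |
| severity slope | U[0.2, 0.4] per stage | free choice; produces clearly learnable but imperfect separation |
| ECG SNR | 20 dB (10 dB in detector stress tests) | typical monitor-quality ECG |

Severity acts multiplicatively on all three HRV amplitudes (oscillatory
*and* broadband — total R–R variability falls during central hypovolemia)
and additively on the T-wave amplitude; the R-amplitude respiratory
modulation shallows with the same factor. Beat templates are five Gaussian
bumps (P, Q, R, S, T) placed at beat times from a continuous train whose
R–R model parameters switch at stage boundaries without phase or time
discontinuities; baseline wander is a 0.05 Hz sinusoid plus a low-order
polynomial drift; noise is white Gaussian at the configured SNR. Ground
truth (every fiducial time and amplitude) is carried in the record.

With this world, 178 simulated subjects windowed at 120 beats and filtered
to labeled rows yield on the order of 2.3–2.5 thousand table rows — within
the stated 20% band of the study's 2085 — without any parameter having been
moved toward that number.

What the generator does *not* emulate: real P/T morphology (Gaussian bumps
have no asymmetry or notching), arrhythmia and ectopy, electrode artifacts,
non-stationary respiration, inter-subject morphology covariance, or any
hemodynamic (pressure/flow) signal. Consequently a green pipeline
establishes *algorithmic* correctness — formulas, optimality, invariances,
leak-free evaluation, qualitative severity response — and does **not**
establish clinical performance; the study's AUC table is explicitly out of
reach without its restricted human recordings.

## 10. Numerical choices and degenerate inputs

* Taut string: tube feasibility is enforced by a final clamp at ~1e-12
  scale; ε = 0 returns `x = z` exactly; constant series return zero
  residuals and zero inflections; skewness/kurtosis of constant vectors are
  `NA` (0/0), never fabricated.
* Periodized wavelet transforms reflection-pad to the required dyadic
  multiple and truncate on inversion; filters longer than the subband are
  folded modulo the length (the standard periodization), keeping
  orthogonality exact at all depths.
* `psd_rr()` requires 8 intervals, and flags (rather than refuses) windows
  shorter than 30 intervals / 60 s, because the 30-beat end of the window
  sweep necessarily produces 29-interval windows.
* Fold assignment reshuffles with an incremented seed when an outer fold
  lacks a class, logging the fact; after 50 attempts it proceeds with a
  warning rather than looping forever.
* All seeds derive from a single user seed through a fixed integer map kept
  below 2^31.

## 11. Known limitations

* The enumeration of the morphology and DTCWT families (554/120) is one
  consistent reading of an under-specified construction; the printed counts
  (839/198) are not reachable from the stated rules.
* Level-2 shift invariance of the DTCWT is limited by the 14-tap q-shift
  pair (~8% worst-case single-window energy change); longer q-shift filters
  would improve it but no trusted coefficient table was available offline.
* The greedy taut-string implementation is amortized linear time in R; for
  very long series (≫10⁴ points) a compiled implementation would be
  preferable.
* The SVM is squared-hinge, not hinge; on heavily overlapping classes the
  two can differ slightly in the decision boundary, which is irrelevant to
  the rank-based AUC reported here but worth knowing before comparing raw
  accuracies against LIBSVM output.
* `evaluate_window_size_sweep()` re-extracts features per size; on large
  cohorts this is the pipeline's dominant cost and is trivially
  parallelizable across records, which the implementation does not do.
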