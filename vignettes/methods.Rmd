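---
title: "Turn-taking, prosodic synchrony and dyad-aware classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turn-taking, prosodic synchrony and dyad-aware classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## What the package computes

`dyadsync` analyses two-party conversations given (a) speaking-instance
annotations for each interactant (Praat TextGrid interval tiers or RTTM
diarization) and (b) frame-level prosody tracks (pitch in Hz with unvoiced
frames missing, intensity in dB) on a uniform 10 ms grid. From these it
derives:

* **turn structure** — a turn is all speaking instances of one interactant up
  to the end of the instance preceding the other interactant's next instance,
  so speakers alternate strictly by construction;
* **individual speech features** per participant and task: articulation rate
  (syllable nuclei per second of phonation), number of pauses and syllables,
  phonation time, variance of pitch and of intensity, and turn-based
  adaptation of pitch, intensity and articulation rate;
* **dyadic interactional features** per conversation: number of turns, mean
  signed turn-taking gap, silence-to-turn ratio, speech rate, and
  windowed-cross-lagged-correlation (WCLC) synchrony of pitch and intensity;
* **surrogate (pseudo) nulls** for every coordination measure, via segment
  shuffling, compared with one-sided paired Jeffreys--Zellner--Siow (JZS)
  Bayes factors;
* a **dyad-aware nested stratified cross-validated linear SVM** that
  classifies each individual as belonging to a mixed (autistic + non-autistic)
  or non-autistic dyad, with a dyad-level label permutation test;
* **Bayes-factor group comparisons** on the logarithmic Jeffreys scheme.

Because no conversation audio is shipped, a synthetic-conversation generator
with known ground truth stands in for recordings; every downstream stage is
tested against it.

## Turn segmentation and its conventions

Intervals are half-open `[start, end)` in seconds from conversation start.
Turn-taking gaps are *signed*: a negative gap means the new speaker started
while the previous turn was still running. The silence-to-turn ratio uses as
numerator the total non-speech time of the whole conversation (leading and
trailing silence included) and as denominator the summed turn spans; the
measure is glossed in the literature as "silence versus talking", and since
its operationalisation is not fully standardised there, the package fixes
this reading and documents it. Simultaneous onsets are
resolved deterministically: the speaker holding the floor loses it.

Two open choices deserve note. Overlapped speech retains its full duration
for both speakers (no overlap apportioning), and "number of pauses" counts
silences of at least 0.3 s between a speaker's own consecutive segments
*within one of their own turns* — silences across turn boundaries are gaps,
not pauses.

## Syllable nuclei

Articulation rate needs syllable counts. Nuclei are detected from the
intensity contour the way speech-rate scripts in the phonetics literature do
it: local intensity maxima inside the speaker's speaking segments that
(1) exceed the median intensity of voiced frames, (2) are separated from the
previous accepted peak by a dip of at least 2 dB, and (3) coincide with a
voiced (pitch-bearing) frame. Peak picking is plateau-aware: a candidate
needs a strict rise before and a strict fall after it, so flat stretches and
segment-boundary frames never count. The 2 dB dip, median threshold and
0.3 s minimum pause follow the defaults of the cited nucleus-detection
tradition, since no settings are published for the data this mirrors.

## WCLC synchrony

Synchrony uses windowed cross-lagged correlations with a 16 s window, 8 s
step and ±2 s lag range (whole frames, lag 0 included). Within each window,
for every lag, the Pearson correlation is computed over pairwise-present
frame pairs whose members both fall inside the window; the per-window peak
(default: largest *signed* correlation, treating synchrony as in-phase
similarity; an absolute-peak rule is available since some tooling aggregates
absolute values) is averaged over usable windows. Windows are skipped when
fewer than `min_valid_fraction` (default 0.5) of the possible pairs exist at
every lag, or when no lag has usable variance. The implementation computes
all windows and lags via FFT cross-correlation on masked series and is tested
to agree with a naive loop to 10^-10.

**Missing-data convention.** Pitch exists only where a speaker produces
voiced speech. Intensity, however, is a property of the recording channel: a
per-speaker microphone reports the room noise floor during silence, so the
generator emits a dense intensity track (speech level inside own segments,
noise floor elsewhere) and the intensity WCLC runs at the default validity
floor. Pitch series of two alternating speakers overlap only incidentally,
so the feature pipeline computes pitch WCLC with a lower validity floor
(0.05); with the default floor almost every window of an alternating
conversation would be skipped. Both floors are configuration.

**What the surrogate null does and does not test.** Pseudosynchrony shuffles
one partner's series in window-length (16 s) segments, keeping a trailing
partial segment in place, and recomputes the statistic; pseudoadaptation
permutes the partner's turn-feature sequence. One hundred surrogates per
value is the default. It is important to be explicit about the null this
construction embodies: shuffling destroys *all* cross-partner timing,
including the turn-taking alternation itself. Two speakers who politely
alternate have anti-phase intensity contours; after shuffling, blocks of
speech land at random positions relative to the partner, and the best-lag
correlation of two independent quasi-periodic on/off patterns is typically
*larger* than the observed in-phase correlation of strictly alternating ones.
Consequently, for dyads with no planted prosodic coupling the observed
summary sits systematically *below* the surrogate mean — the test is
conservative for detecting in-phase synchrony on alternating-speech
contours, not calibrated to zero. The package's calibration check reports
this honestly; with coupling at the generator's default (reported-direction)
gains the observed value exceeds the surrogate mean in essentially all
dyads, which is the qualitative ordering the surrogate comparison is used
for.

## Paired Bayes factors and evidence grading

Observed-versus-pseudo comparisons use a one-sided (observed greater) paired
JZS Bayes factor: a Cauchy prior with scale √2/2 on the standardised effect,
marginal likelihood integrated numerically with the noncentral-t likelihood,
reported as a natural logarithm. The test suite checks the routine against an
independent fixed-grid quadrature to within 1% on the Bayes-factor scale.
Evidence grades follow the logarithmic scheme with symmetric thresholds 1.1
(moderate), 2.3 (strong), 3.4 (very strong) and 4.6 = ln 100 (decisive), the
sign giving direction.

The repeated-measures group comparisons (one within factor, task; one between
factor, diagnosis or dyad type) are *BIC-approximate*: the candidate model
set {null, +task, +group, +task+group, full} is fitted by maximum likelihood
with a subject random intercept, each model's marginal likelihood is
approximated by exp(−BIC/2), and inclusion Bayes factors compare matched
models. The rank-based two-group Bayes factor applies the two-sample JZS
formula to rank-transformed data. Both are labelled approximations: the
default-prior and sampling-based Bayes factors of point-and-click Bayesian
software are not reproduced, and no attempt is made to match any published
Bayes-factor value numerically, since those depend on raw data that were
never deposited.

## Classification

The feature matrix has one row per individual and, by default, the nine
individual plus six dyadic features of each task concatenated (30 columns;
dyadic values repeated for both members; mixed is the positive class).
Whether the original analysis concatenated or averaged tasks is not stated;
concatenation is the default and a mean-over-tasks option exists.

The model is a linear SVM with squared-hinge loss and a squared-norm
penalty, minimised directly in the primal (the objective is smooth and
convex) by L-BFGS with an analytic gradient; class weights are inversely
proportional to class frequencies ("hyperplane weighting"). The
cross-validation structure is nested and dyad-aware: dyads, never
individuals, are assigned to folds, stratified so each outer fold's class
mix stays within one dyad of the global ratio; the outer loop is 7 folds ×
10 permutations, the inner loop 10 folds × 1 permutation. Inside every outer
training partition, median imputation, [−1, 1] scaling and zero-variance
pruning are estimated on training rows only; the inner loop picks the
penalty from the grid 2^−6 … 2^6 by pooled out-of-fold balanced accuracy;
and the decision threshold is shifted to the Youden-J optimum of the inner
out-of-fold scores — the package's reading of "post-hoc ROC optimisation",
a phrase with no single standard definition. Per-individual decision scores
are averaged over the outer permutations and labels decided by majority
vote. Reported metrics: balanced accuracy (exactly the mean of sensitivity
and specificity), sensitivity, specificity, and a rank-based AUC.

Significance uses dyad-level label permutations (both members relabelled
together) with the fold structure held fixed and the full pipeline re-run per
permutation; p = (1 + #{permuted BAC ≥ observed}) / (1 + n_perm). The study
design's scale is 5,000 permutations with a Bonferroni-corrected α of 0.007;
desk-scale runs use fewer permutations, and for large permutation batches a
lean pipeline configuration (single penalty value, no threshold shift) is
available — the same configuration is then used for the observed statistic,
so the test stays valid.

## The synthetic world

The generator emulates the study conditions: per dyad one conversation per
task (hobbies, meal planning), 600 s each; 26 mixed and 14 non-autistic
dyads by default (the analysed sample: 26 autistic participants, each paired
with a non-autistic partner, plus 14 non-autistic pairs). Turn lengths are
log-normal with median 1.8 s and gaps log-normal with median 0.2 s — the
medians reported for unstructured stranger conversation — with log-SDs 0.9
and 0.7 chosen
once to give the heavy right tail of natural conversation. Within-turn
pauses occur at 0.1 per second of turn span with log-normal lengths (median
0.5 s). Prosody: per-speaker pitch baselines drawn from a bimodal 120/220 Hz
range; AR(1) contours (coefficient 0.95 for pitch; 0.995 for intensity,
which is low-passed by its analysis window in real extraction); syllable
bumps as ≥3 dB raised-cosine intensity peaks at the speaker's articulation
rate; a 40 dB channel noise floor during silence. Turn-level offsets carry
the adaptation process (own offset = gain × partner's previous offset +
innovation), and lagged intensity coupling (default lag 1 s, inside the 2 s
WCLC bound) is added to the receiver's non-speech frames, as microphone
cross-talk physically is; variance features, computed over own speech frames
only, are therefore not confounded by the coupling.

Planted effects are ratios (`effect_multipliers`); 1 means no effect, and
`null_world()` sets them all to 1. Defaults follow the reported effect
directions — autistic speakers: pitch-variability ratio 0.6, intensity 0.75,
articulation 0.85; mixed dyads: gap ratio 1.6, pausing 1.5, coupling 1.5 —
with magnitudes chosen once so that standardised differences land in the
1–2 range after realistic between-speaker (log-SD 0.25) and between-dyad
(log-SD 0.3) heterogeneity. Small task effects (slightly faster articulation
in meal planning, more coupling in hobbies, extra mixed-dyad gap inflation
in meal planning) give the task factor something to find.

What the generator does **not** emulate: lexical content, waveform acoustics,
voice quality, backchannels and overlap dynamics, filled pauses, room or
equipment covariates, and any real between-site variability. Passing tests
therefore show that the pipeline measures what it defines and recovers what
the generator plants — not that real autistic and non-autistic conversation
differs by these amounts.

## Numerical choices and problem sizes

Deterministic seeds flow through every stochastic step (generation,
surrogates, CV plans, permutations); R's default Mersenne-Twister generator
is used throughout. WCLC correlations are computed after global mean
centring to avoid cancellation in the raw-moment formula; windows with
fewer than three pairs or near-zero variance at a lag yield no correlation
for that lag. The SVM solver runs to an L-BFGS factr of 10^4 (about 10^-12
relative objective tolerance); penalty ties resolve to the smaller penalty.
Degenerate inputs error loudly: zero phonation, all-constant features,
fewer than three adaptation pairs, infeasible stratifications.

The shipped analyses and checks use desk-scale problem sizes chosen as the
package's own defaults: the full synthetic study corpus (40 dyads × 2 tasks ×
600 s) for feature extraction, classification and the coordination table
(25 surrogates per value there; 100 is the function default); 200
single-conversation dyads for surrogate calibration; 20 replicate null-world
corpora of 14 dyads for the chance-level check; and 50 replicates × 200
permutations on 24-dyad null feature sets for permutation-test calibration
(fewer dyads make the balanced accuracy of the held-out individuals too
coarse and the permutation test conservative). All run on one CPU core.

## Known limitations

* The surrogate null is conservative on alternating-speech intensity
  contours (see above); between-dyad comparisons of observed synchrony are
  unaffected, but observed-minus-pseudo differences should not be read as
  unbiased coupling estimates.
* The BIC and rank approximations to Bayes factors are systematically more
  conservative than default-prior Bayes factors at these sample sizes.
* Turn-based adaptation, being a correlation, inherits asymmetries in the
  partners' turn-level variability: a speaker adapting to a highly variable
  partner shows a larger correlation at the same adaptation gain. In the
  synthetic world this lets group contrasts in adaptation emerge indirectly
  from the planted variance effects even though no adaptation difference is
  planted — worth remembering when reading the demo group comparisons.
* Pitch WCLC on alternating speakers rests on few pairwise-present frames
  per window; its absolute level is inflated by max-over-lags selection and
  should only be compared against its own surrogate distribution.
* The SVM solver is exact for the stated objective but is not a reimplementation
  of any particular toolbox's solver; decision-score scales are therefore not
  comparable across implementations.
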