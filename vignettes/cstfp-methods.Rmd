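---
title: "Common spatio-time-frequency patterns: model, optimization, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common spatio-time-frequency patterns: model, optimization, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cstfp)
```

## The decoding problem

Cue-based brain–machine interfaces classify short multichannel EEG epochs
(trials) into one of two mental states, typically imagined movements. The
discriminative signal is a band-power change (event-related
desynchronization/synchronization) that is confined to **a spatial pattern**
(which electrodes), **a frequency band** (e.g. the mu rhythm), and **a time
interval** (when, relative to the cue, the subject actually performs the
task). Classic common spatial patterns (CSP) learns only the spatial part and
leaves the band and the interval to be fixed by hand. This package learns all
three jointly from labeled trials.

## Signal-extraction model

A trial is a matrix $X \in \mathbb{R}^{M \times N}$ ($M$ channels, $N$
samples). One *pattern triple* consists of spatial weights
$w \in \mathbb{R}^M$, FIR filter taps $h \in \mathbb{R}^P$, and a binary time
window $b \in \{0,1\}^K$ over the $K = N - P + 1$ valid filtered samples. The
extracted scalar signal is

$$\tilde{x}_n = w^\top A_n h, \qquad
  [A_n]_{m,p} = X_{m,\,n+P-p},$$

i.e. the channels are combined with $w$ and convolved with $h$ (the lagged
matrix $A_n$ makes the bilinear structure explicit). Its *windowed variance*

$$\alpha_X(w, h, b) = \frac{1}{\lVert b \rVert_0}
  \sum_{n=1}^K b_n \bigl(\tilde{x}_n - \mu_b\bigr)^2, \qquad
  \mu_b = \frac{1}{\lVert b \rVert_0} \sum_n b_n \tilde{x}_n,$$

is the band-power feature restricted to the active window. With $F$ triples
and a bank of $2r$ CSP eigenvectors per filter, a trial maps to the
$2rF$-dimensional log-variance feature vector classified by a Fisher
discriminant with a midpoint threshold.

### Normalization conventions

Two denominators are defensible in the averages above: the active-sample
*count* $\lVert b \rVert_0$ (giving a true sample variance) and the
*Euclidean norm* $\lVert b \rVert_2 = \sqrt{\lVert b \rVert_0}$ of a binary
vector. The package uses the count for every averaging denominator (default
`norm = "count"`, with `"euclidean"` available as a switch), because only the
count makes $\alpha$ a variance; the window-length reward in the objective
(below) uses the Euclidean norm. The discriminative *ratio* is invariant to
this choice — only the reward term and the absolute scale of $\alpha$ change.

A second convention concerns centering: the canonical form centers by the
windowed mean $\mu_b$ (so $\alpha$ is invariant to constant offsets on the
active region). A debug variant (`centering = "global"`) instead applies the
window first and centers by the plain mean over all $K$ samples; it exists
for comparison only and is not used anywhere in the pipeline.

## The design criterion

For target class $c \in \{1, 2\}$ the per-triple objective is

$$\max_{w, h, b}\;
  \hat{J} + \frac{\epsilon}{K}\lVert b \rVert, \qquad
  \hat{J} = \frac{E_{X \in \mathcal{C}_c}[\alpha_X]}
       {E_{X \in \mathcal{C}_1}[\alpha_X] + E_{X \in \mathcal{C}_2}[\alpha_X]}
  \in [0, 1],$$

a CSP-style variance ratio plus a reward $\propto \epsilon$ for longer
windows. The reward matters: without it the exhaustive window search favors
very short windows, which both overfit the finite-sample ratio and — more
subtly — suppress the variance of narrowband-filtered noise (adjacent
filtered samples are strongly correlated, so a short centered window sees
almost none of it), admitting degenerate high-ratio solutions. The default is
$\epsilon = 0.1$; much smaller values permit short-window degeneracies,
while very large values force the all-ones window.

$F$ triples are designed **sequentially**. Filter $i$ is constrained to the
orthogonal complement of the deflation subspace spanned by all previously
accepted filters *and their one-sample circular shifts*
($h'[k] = h[(k \bmod P) + 1]$). A circularly shifted FIR has the same
magnitude response, so deflating the shift direction (approximately the
quadrature component at the filter's center frequency) prevents the next
filter from re-extracting the same band with a different phase. The
`shifts = "last"` option restricts the shift vectors to the most recent
filter only.

## Alternating optimization

Each triple is optimized by block-coordinate ascent; every block update is
*exact*, so the objective trace is non-decreasing (a property the test suite
verifies to $10^{-12}$ slack on seeded problems):

* **Spatial weights:** with $(h, b)$ fixed, $\alpha$ is a quadratic form
  $w^\top R w$ in the per-class scatter of the filtered, window-centered
  channels, and the maximizing $w$ is the top generalized eigenvector of
  $R_c w = \lambda (R_1 + R_2) w$.
* **Filter taps:** with $(w, b)$ fixed, $\alpha = h^\top Q h$ for the
  analogous lag-domain scatter $Q_d$, maximized under the linear constraint
  $V^\top h = 0$ ($V$ spans the deflation subspace). Rather than forming the
  oblique projector of the stationarity conditions, the pencil is projected
  onto an orthonormal basis of the complement of $\mathrm{span}(V)$
  (dimension $P - D_i$), the reduced symmetric-definite problem is solved
  there, and the solution mapped back — equivalent and numerically stable.
* **Window:** with $(w, h)$ fixed, $\tilde{x}$ is computed once per trial
  and the objective is evaluated for *every* candidate window in one
  vectorized pass; the argmax is exact. Ties go to the first candidate in
  the deterministic candidate ordering.

Iteration stops when the objective changes by less than `tol` ($10^{-5}$ by
default) between sweeps, or after `max_iter` (100) sweeps with a warning.
The filter is initialized as a seeded random vector orthogonalized against
the deflation subspace; the window starts as all-ones. The sweep order
(`w`, `h`, `b`) is exposed in the configuration. All randomness flows from a
single integer seed, and the caller's RNG state is restored afterwards.

Generalized eigenproblems are solved by whitening the right-hand matrix;
if its condition number exceeds $10^{10}$ a ridge
$10^{-10}\,\mathrm{tr}(B)/\mathrm{dim}$ is added. Eigenvectors are unit
length with the largest-magnitude entry positive, which fixes every sign
convention in the model deterministically.

### Window candidate sets

Two schemes construct the finite candidate set searched by the window step:

* `window_block_candidates(K, D, J)`: $J$ disjoint blocks of length $D$ and
  all $2^J - 1$ nonzero block combinations (1023 candidates at the
  protocol scale $K = 60$, $D = 6$, $J = 10$) — windows may be
  non-contiguous.
* `window_contiguous_candidates(K, step, min_len)`: runs of ones with
  offset and length drawn from an arithmetic grid
  $\{0, \text{step}, \dots, K\}$, subject to length $> \text{min\_len}$
  — the configuration used for real recordings, defaulting to step 5 and
  minimum length 50.

Candidates with fewer than two active samples cannot define a variance and
are rejected at construction time.

## What the synthetic generator emulates

`simulate_trials()` draws two-class trials
$x[n] = \sum_i s_i[n]\, a_i^{(d)} + \eta$ from narrowband sources
$s_i[n] = t_i[n]\,\Re\bigl[\sum_k S_i[k] e^{j\theta} e^{j2\pi k n/N}\bigr]$
with a fresh uniform phase per trial and source (a `shared_theta` mode ties
the phase across sources within a trial), a source-specific activity window
$t_i$, class-dependent spatial amplitudes $a_i^{(d)}$, and i.i.d. Gaussian
sensor noise (default variance $0.1$). Only sub-Nyquist spectrum bins are
populated; the real-part operator supplies conjugate symmetry implicitly
(populating mirrored bins too would double amplitudes).

`default_sim_config()` is the reference validation problem: 10 channels,
100 samples at 100 Hz, 100 trials per class, four sources at 8, 14, 22, and
30 Hz. These spectra, windows, and amplitudes are **parametric stand-ins**,
chosen once as follows:

* *Spectra* are Gaussian bumps with 0.5 Hz standard deviation. The width is
  deliberately below the resolution of a 41-tap filter: the deflation
  subspace removes two directions per accepted filter (the filter and its
  shift), which exhausts a band only if the band is essentially one
  resolution cell wide. Wider sources leave re-extractable residual energy
  and later filters revisit earlier bands.
* *Windows* are rectangular (one source missing the first 25 samples, one
  full-length, one missing the last 25, one mid-trial), mirroring the
  qualitative design of the validation experiment this emulates. A `ramp`
  option adds raised-cosine edges for experiments where onset transients
  should be suppressed.
* *Amplitudes* differ between classes in **pattern**, not only in scale:
  each source's class-2 bump sits over different channels than its class-1
  bump. This is what makes each band strongly discriminative — the spatial
  step can null the opposing class — and it is the regime in which the
  sequential design cleanly assigns one filter per source. (With class
  amplitudes that are merely scaled copies, every band carries the same
  ratio and the criterion has no reason to isolate individual sources.)

What the generator does **not** emulate: volume-conducted backgrounds with
$1/f$ spectra, artifacts, non-stationary noise, inter-trial variability of
source frequency, or electrode-level correlations. Passing the recovery and
decoding tests therefore demonstrates correctness of the optimization and
pipeline on the model the method assumes, not performance on real EEG.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact combinatorial values (1023 window candidates at $K=60, D=6, J=10$;
  $K = 60$ filtered samples for $N = 100$, $P = 41$);
* agreement of the matrix-form variance with an explicit filtering-path
  evaluation ($10^{-10}$ relative, 100 random cases);
* ALS monotonicity on 50 seeded problems ($M=4$, $N=60$, $P=8$, 10 trials
  per class);
* agreement of multi-start fits (10 seeds) with exhaustive-window × dense
  random-search maximization on tiny instances ($M=2$, $P=3$, $L=7$) within
  $10^{-3}$;
* band/pattern recovery on the four-source problem: over 20 seeds, at least
  18 must match all four filter peak frequencies to distinct true centers
  within $\pm 2$ Hz, and 18 must reach $\ge 0.9$ absolute correlation
  between every class-1 amplitude vector and some designed spatial weight
  (the quantitative analogue of the near-unity correlation such validation
  experiments report);
* end-to-end $5 \times 5$ cross-validated decoding on a separable
  two-source problem (30 trials per class, $F=4$, $r=1$,
  $\epsilon = 0.1$): mean accuracy $\ge 90\%$, and $50\% \pm 10\%$ after
  label permutation. Thirty trials per class keeps a 50-fit experiment
  comfortably within a desktop run while leaving each training fold with 24
  trials per class.

## Practical guidance

* `P = 41` taps at 100 Hz gives ~2.4 Hz frequency resolution; shorter
  filters trade resolution for more usable window length ($K = N - P + 1$).
* `epsilon` is the main tuning knob. If designed windows collapse to a few
  samples, increase it; if every window is all-ones, decrease it.
* `n_filters` beyond the number of genuinely discriminative bands costs
  little: later filters settle in noise bands with ratios near 0.5 and the
  discriminant weighs them down.
* Degenerate inputs fail loudly: all-zero trials (undefined ratio), windows
  with fewer than two active samples, filter orders exceeding the trial
  length, and singular pencils (handled by the ridge, or reported if
  irreparable) all raise classed conditions.

## Known limitations

* Two classes only; no multiclass extension.
* The sequential design is greedy: triples are not re-optimized jointly
  after later filters are added, and block-coordinate ascent converges to a
  local maximum — multi-start over `seed` and `init_window` is the remedy on
  hard problems.
* The window is restricted to the finite candidate set by design; learned
  continuous tapers are out of scope.
* Feature extraction assumes the trial grid (channels, samples, rate) of
  the fitted model.
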