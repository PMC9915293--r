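---
title: "Lossless ECG compression by adaptive linear prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless ECG compression by adaptive linear prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpcodec)
```

## The problem

Long-term ECG monitoring produces integer-quantized sample streams —
typically 250–1000 Hz at 11–16 bits — that must be stored or transmitted
without any reconstruction error, because diagnostic features (ST
deviations, subtle morphology changes) cannot tolerate lossy artifacts.
`alpcodec` implements a lossless codec built from two pieces: an adaptive
linear predictor that shrinks each sample to a small signed residual, and a
Golomb–Rice entropy coder that spends few bits on small residuals. Both
pieces are parameter-free at run time: nothing has to be trained or tuned
per database, which is what makes the method robust across acquisition
setups.

## Prediction

Each sample $x(n)$ is predicted by the four fixed binomial-coefficient
predictors

$$\hat x_p(n) = \sum_{i=1}^{p} a_p(i)\, x(n-i), \qquad
a_1 = (1),\; a_2 = (2,-1),\; a_3 = (3,-3,1),\; a_4 = (4,-6,4,-1),$$

whose residuals $e_p(n) = x(n) - \hat x_p(n)$ are exactly the $p$-th
backward differences of the signal. An order-$p$ predictor therefore
annihilates any polynomial of degree $p-1$: order 1 is best in flat
segments, order 3–4 in steep QRS slopes. Per sample the codec keeps the
residual of smallest magnitude, $e(n) = \min_p |e_p(n)|$ (sign retained),
with ties broken toward the smallest order. All arithmetic is exact
integer arithmetic; intermediate order-4 predictions can exceed the input
bit range, so residuals are carried at 64-bit width internally.

### Who picks the order — the one genuinely open design point

The minimum over $p$ uses the *current* sample, which the decoder has not
seen yet, so a decoder cannot replay that choice from the bitstream alone.
The package resolves this with two explicit modes, recorded in the
container header:

* **`side_info`** — per-sample optimal selection, with the chosen order
  transmitted as 2 extra bits per sample. Guaranteed faithful to the
  minimum-residual rule; costs a fixed 2 bits/sample.
* **`causal`** (default) — the order for sample $n$ is the one that would
  have minimized the magnitude at sample $n-1$, computed from all four
  predictor residuals at the previous, already-decoded sample (ties to
  the lowest order; order 2 for the first coded sample). No side
  information at all.

On every corpus we generate, the causal mode wins: ECG regions change
slowly relative to the sampling rate, so yesterday's best order is almost
always today's, and the 2 bit/sample overhead of `side_info` outweighs its
slightly smaller residuals. That overhead-free bitrate is also the only
accounting under which published compression ratios for this family of
codecs are attainable, which is why `causal` is the default.

## Entropy coding

Signed residuals are interleaved to non-negative integers
($e \ge 0 \mapsto 2e$, $e < 0 \mapsto 2|e|-1$) and Rice-coded: value $M$
with parameter $k$ becomes $\lfloor M/2^k \rfloor$ one-bits, a zero
separator, then $k$ remainder bits MSB-first — $\lfloor M/2^k\rfloor + 1 + k$
bits in total, self-delimiting by construction.

The parameter adapts causally: $k(n) = \lfloor \log_2 \mathrm{MAE} \rfloor$
where MAE is the mean absolute value of the three most recently coded
residuals. Numerical conventions, chosen so encoder and decoder run
bit-identical integer arithmetic with no floating point:

* the MAE itself is integer-floored (`(|e1|+|e2|+|e3|) %/% 3`);
* $\mathrm{MAE} \le 1$ gives $k = 0$ (the log would be undefined or
  negative; flat regions get 1-bit codes);
* $k$ is clamped to `bits + 2` — a larger $k$ never shortens codes for
  residuals representable at that width;
* the residual window starts as $(0,0,0)$, so the first coded sample uses
  $k = 0$.

There is no escape code for pathological quotients: a residual spike
right after a flat region (where $k = 0$) is coded in unary and can cost
up to $2|e|+1$ bits for that one sample. That worst case is the price of
keeping the code structure exactly as defined; the adaptation recovers
within three samples.

## Container and losslessness

The first four samples of each lead are stored raw (the order-4 predictor
needs them), then the coded residual stream follows. The binary container
(`ALPC` magic, version, mode flag, resolution, sampling frequency in
milli-Hz, sample and lead counts, per-lead name, initial samples, exact
payload bit length, byte-padded payload) is deterministic: the same record
and configuration always serialize to identical bytes. The decoder
reconstructs $x(n) = \hat x_p(n) + e(n)$ from the four most recent
*reconstructed* samples, which equal the originals by induction, so the
round trip is exact and PRD $\equiv 0$; the suite asserts the decoder's
internal $k(n)$ and order sequences equal the encoder's sample by sample.
The encoder-side accounting reports two compression ratios,
$\mathrm{CR} = B_0/B_C$ with $B_0 = N b$: a per-lead coding cost
($4b$ raw bits + payload) as codec results are conventionally quoted, and
a file-level CR that charges the container header too.

## Coefficient estimation

The companion toolkit answers "are the fixed integer coefficients any
good?" for a given corpus. `lp_fit()` implements the autocorrelation
method: a biased ($1/N$) raw autocorrelation, then the Yule–Walker system
solved by a hand-rolled Levinson–Durbin recursion (cross-checked in the
tests against a dense Toeplitz solve at $10^{-9}$). Conventions worth
stating:

* coefficients are reported in the prediction convention
  ($\hat x(n) = \sum a_i x(n-i)$, so a near-random-walk ECG gives
  $a_1 \approx +1$), matching how database-wide averages are tabulated in
  the literature;
* the $1/N$ (biased) estimator keeps the Toeplitz matrix positive
  semi-definite, so the recursion cannot divide by a negative variance;
  genuine degeneracy (constant signal after demeaning) raises an error;
* mean removal is **off** by default — quantized ECG carries a DC offset
  and the codec's fixed predictors act on the raw ADU signal; it is
  exposed as a flag for stationarity analyses;
* per-record fits use the full record; database averages are unweighted
  across records, and `lp_round()` rounds to integers under
  round-half-to-even, the convention under which the published rounded
  tables for the three reference databases are reproduced exactly from
  their printed averages.

On every synthetic corpus this package generates, the pooled order-2
average rounds to $(2, -1)$ — the classic second-difference predictor —
consistent with the long-standing finding that order 2 is sufficient for
ECG, and the fitted order-2 one-step MAE is within 5% of the order-4
fit's.

## The synthetic generator: what it emulates, and what it does not

Real evaluation corpora (MIT-BIH Arrhythmia, European ST-T, PTB
Diagnostic) are not redistributable inside a package, so every test runs
on synthetic records from `synth_ecg()`. Three presets mirror the
acquisition setups of those databases: 360 Hz/11-bit/200 ADU/mV
(MITDB-like), 250 Hz/12-bit/200 ADU/mV (EDB-like) and 1000
Hz/16-bit/2000 ADU/mV (PTBDB-like).

A beat is a sum of five Gaussian bumps (P, Q, R, S, T; amplitudes in mV,
centers as beat fractions, widths in seconds — defaults are a plausible
sinus-rhythm lead-II shape, U wave omitted). On top: optional sinusoidal
baseline wander at 0.33 Hz (respiratory band) and band-limited Gaussian
noise. The noise is AR(1)-correlated with pole 0.9 rather than white:
acquired ECG noise (muscle artifact, mains, electrode motion) is
band-limited by the anti-alias chain, and wideband noise at Nyquist would
make differencing predictors look far worse than they are on real
records. Everything is scaled by the preset gain, rounded to integers and
clipped to the preset resolution — clipping warns, because silent
wraparound would corrupt lossless tests. Generation is deterministic per
seed and leaves the caller's RNG stream untouched.

What passing tests on this corpus shows: exact losslessness, correct
state replication, plausible CR ordering across setups (the 16-bit/1000
Hz preset sees larger ADU residuals and hence lower CR, matching the
known direction on real data), and coefficient averages that round to
$(2,-1)$. What it does not show: CRs numerically equal to published
per-database averages — those depend on real morphology variety,
arrhythmic beats and artifact content that a Gaussian-bump generator does
not model. The WFDB reader (`read_record(..., format = "wfdb")`, signal
formats 212 and 16, digital samples only) exists precisely so the same
pipeline can be pointed at the real databases when they are on disk.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
nine 30 s fixtures (three presets × clean/noisy/wandering) plus ~1000
randomized round trips for the lossless contract; the full
$M \in [0, 65535] \times k \in [0, 12]$ grid for entropy-coder exactness;
1000 random PSD systems up to order 8 for the Levinson–Durbin oracle
check; AR parameter recovery at $N = 10^5$; and per-preset synthetic
databases of four 30 s records for the evaluation pipeline. These sizes
were chosen as the smallest at which each property is exercised at
realistic scale.

## Known limitations

* The codec is specialized to ECG-like signals: on uniform random input
  it expands slightly (CR just below 1), by design — there is no fallback
  raw mode.
* No error resilience beyond truncation detection: a flipped payload bit
  desynchronizes the remainder of the affected lead.
* Multi-lead records are compressed lead-independently; inter-lead
  decorrelation is out of scope.
* The WFDB reader handles the common single-file format-212/16 layouts of
  the three reference databases, not the full format zoo.
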