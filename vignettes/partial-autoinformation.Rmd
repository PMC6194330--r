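---
title: "Partial autoinformation: diagnosing the Markov order of symbolic sequences"
author: "painf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial autoinformation: diagnosing the Markov order of symbolic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painf)
```

## The problem and the model

A symbolic time series $(X_n)$ takes values in a finite alphabet of $L$
symbols. Its temporal structure is summarized by the joint distributions
of $k$-histories $X_n^{(k)} = (X_n, X_{n-1}, \dots, X_{n-k+1})$, whose
Shannon entropies $H_k$ (in bits; all logarithms are base 2) generate
three derived quantities:

* the finite-history **entropy rate**
  $h_k = H(X_{n+1} \mid X_n^{(k)}) = H_{k+1} - H_k$, the surprise per
  emitted symbol given $k$ steps of context;
* the **active information storage**
  $a_k = I(X_{n+1}; X_n^{(k)}) = H_1 + H_k - H_{k+1}$, the information
  about the next symbol actually stored in the context, with the
  conservation identity $H_1 = a_k + h_k$;
* the **autoinformation function (AIF)**
  $\alpha_k = I(X_{n+k}; X_n)$, lagged mutual information, the symbolic
  analogue of the autocorrelation function; and
* the **partial autoinformation function (PAIF)**
  $\pi_k = I(X_{n+k}; X_n \mid X_{n+k-1}, \dots, X_{n+1})$, the
  conditional mutual information that removes the influence of the
  intermediate symbols — the analogue of the partial autocorrelation
  function. Lags 0 and 1 have no intermediates and are defined as the
  corresponding AIF values.

In stationary plug-in form $\pi_k = h_{k-1} - h_k = a_k - a_{k-1}
= -(H_{k+1} - 2H_k + H_{k-1})$: the PAIF is minus the second difference
of the entropy sequence. For a stationary Markov process of order $M$,
$h_k$ is constant for $k \ge M$, so $\pi_k = 0$ for every $k > M$. That
vanishing tail is the diagnostic: plotted against a surrogate confidence
band, the last significant PAIF lag estimates the Markov order, exactly
as the last significant PACF lag estimates the AR order of a metric
series.

## Estimators and their two modes

All estimators are plug-in (maximum likelihood): probabilities are
window frequencies, entropies are $-\sum p \log_2 p$ with
$0 \log 0 = 0$. No bias correction is applied; finite-sample inflation
of joint entropies is a documented limitation (below), not something the
estimators try to hide. Window counting encodes each $k$-window as a
base-$L$ integer (most recent symbol in the lowest digit) and tabulates
densely while $L^k$ fits a preset cap, switching to code-keyed sparse
counting beyond it; both paths count every one of the $N-k+1$ contiguous
windows exactly once.

Two estimation modes propagate through every derived quantity:

* **windowed** (default): each $H_k$ comes from its own full window
  count. Because $h_k$ and $a_k$ are assembled from the *same* shared
  estimates, the conservation identity and the difference identities
  hold to floating-point rounding here too; individual PAIF
  coefficients, however, are differences of separately estimated
  conditional entropies and can come out slightly negative. They are
  reported as-is (plots may clip for display; tables never do).
* **marginal**: for a requested lag $k$, the single empirical
  $(k+1)$-window distribution is estimated once and every lower-order
  entropy is obtained by marginalizing it. The PAIF is then a genuine
  conditional mutual information of one empirical distribution —
  non-negative by construction and equal, term by term, to the direct
  triple-summation definition (the test suite checks this against a
  brute-force oracle).

The AIF at lag $k$ uses the $N-k$ aligned pairs, with marginals taken
over the aligned subsets, which makes each coefficient a valid
(non-negative) mutual information and renders the profile exactly
invariant under time reversal.

## Surrogate confidence bands

The iid null band is built by randomly permuting the sequence
(preserving the marginal distribution, destroying all temporal order),
recomputing the profile per surrogate, and taking empirical
$\alpha/2$ and $1-\alpha/2$ percentiles per lag (default 100 surrogates,
$\alpha = 0.05$). Percentile bands make no distributional assumption;
whether a parametric band would match is unknowable from a published
figure, so the nonparametric choice is the safer default. Crucially, the
surrogates carry the same finite-sample plug-in bias as the data, so the
band automatically absorbs the positive offset that small samples give
to mutual-information estimates.

The surrogate count of 100 is also used for the conditional-entropy
order test below; the band default simply reuses it.

## The conditional-entropy Markov-order test

For each candidate order $M = 0..M_{\max}$ (default 5) the test fits the
maximum-likelihood order-$M$ transition model, draws 100 surrogate
sequences of the data's own length from it (equal lengths keep the
plug-in bias comparable), and computes $h_k$ for $k = 1..k_{\max}$ on
each. The identified order is the smallest $M$ whose per-$(M,k)$
percentile intervals contain all of the data's $h_k$; if none qualifies
the result is the sentinel "none $\le M_{\max}$", the signature of
extended or non-Markovian memory. $k_{\max} = M_{\max}+1$ is the default:
the smallest range that can still separate order $M_{\max}$ from
$M_{\max}-1$ while limiting the $L^{k+1}$ cost. The conjunction rule
("all $k$ inside") is the test's own multiple-testing handling; no
further correction is applied.

Surrogate sampling follows the inverse-CDF rule on cumulative transition
rows, with the first $M$ symbols drawn from the recorded history
distribution. A surrogate chain can reach a history that never occurred
in the data (its transition row is unknown); such rows are flagged
invalid at estimation time, and the sampler redraws the current history
from the history distribution, counting the event. This restart rule is
a documented convention for an edge the method description leaves open.

The classical likelihood-ratio (Kullback) tests of orders 0–2 are
provided alongside: G statistics on pair/triple/quadruple counts with
asymptotic degrees of freedom $(L-1)^2$, $L(L-1)^2$, $L^2(L-1)^2$ and
zero cells contributing zero. Degrees-of-freedom conventions vary across
old tables; the standard asymptotic values are used and stated.

## The validation processes and their defaults

The package ships every process used to validate the method, so all
experiments are reproducible from seeds alone.

* **Two-state chain** (rates $p, q$): closed forms
  $H = \psi(p_A)$, $h = p_A\psi(p) + p_B\psi(q)$, $a = H - h$ with
  $\psi(x) = -x\log_2 x - (1-x)\log_2(1-x)$,
  $p_A = q/(p+q)$ — the analytic yardstick for the golden-mean machine.
* **Random order-$M$ chains**: transition rows are normalized iid
  uniform variates (a flat-Dirichlet draw would be equivalent in
  spirit); the history distribution is the stationary distribution of
  the lifted chain so samples start in equilibrium.
* **Lag-skipping chain**: order 3 with the next symbol depending only on
  $X_{n-2}$; default $L = 3$, where the period-3 autoinformation is most
  legible. The $L$ conditional rows are rejection-sampled to at least
  0.2 total-variation separation — without enforced separation a random
  draw can make the dependence statistically invisible, defeating the
  construction's purpose.
* **Hidden Markov machines**: the even process (ones in even blocks, no
  finite order), the 2-state golden-mean machine (first-order, matrix
  $[[1/2,1/2],[1,0]]$), and a 7-state golden-mean-family machine. The
  published 7-state topology exists only as a figure in its source, so
  the shipped machine is a synthetic reconstruction satisfying the
  documented properties: binary, no consecutive ones, exactly
  fourth-order (ones separated by at least four zeros; the three
  free-phase states are observationally equivalent and exist to realize
  the seven-state presentation). It lives in a plain-text edge-list file
  so an alternative presentation can be swapped in without code changes.
  Machines start from the stationary distribution of their hidden chain,
  removing transients.
* **2D Ising model**: raster-scan Gibbs sweeps on a periodic square
  lattice (default side 50), one recorded site value per sweep,
  $10^4$ burn-in sweeps. The critical temperature is the exact value
  $2/\ln(1+\sqrt2) \approx 2.269$. At $T = 5$ the site series loses its
  memory within a few lags; at $T_c$ the autoinformation stays above the
  band for tens of lags (near-linear in log-log coordinates).
* **Double-well ion channel**: Euler steps
  $X_{n+1} = X_n + (aX_n - bX_n^3)\,dt + \xi_n$ with per-step Gaussian
  noise. Defaults $a = b = 500$, $dt = 10^{-3}$, $\sigma = 0.17$: minima
  stay at $\pm 1$, and because $a\,dt = 0.5$ the relaxation time is
  comparable to the sampling interval, so threshold crossings resolve in
  a few samples and wells switch every $\sim 10^4$ steps. This choice is
  deliberate: a bistable diffusion sampled much faster than it relaxes
  spends hundreds of samples "flickering" through the threshold per
  crossing, and that flicker is genuine higher-order memory — no
  slow-relaxation parameterization yields a binary output that a
  surrogate test at $N = 10^6$ would call first-order. With fast
  relaxation the flicker information is small enough that the order test
  returns 1 at moderate sample sizes (18 of 20 seeds at $N = 10^5$ in
  our calibration), while at $N = 10^6$ the band test still resolves the
  residual crossing memory; there the honest statement, and the one the
  acceptance suite asserts, is that PAIF coefficients beyond lag 1 are
  below 1% of $\pi_1$ — vanishing at plotting resolution.
  Exact threshold hits map to the closed state; ties are a measure-zero
  event fixed for determinism. No subsampling is applied before
  thresholding.
* **AR(p)**: the linear recursion with Gaussian innovations, zero
  initial values and $10p$ discarded transients; ACF with biased ($1/N$)
  normalization, PACF by Durbin–Levinson on the sample ACF, classical
  $\pm z_{1-\alpha/2}/\sqrt N$ bands.

## What the synthetic generators do and do not emulate

Every experiment in the package runs on sequences from these generators:
stationary, ergodic, exactly specified processes with known orders. Real
label sequences — EEG microstates above all — add what the generators
deliberately omit: non-stationarity (drifting transition probabilities),
observation noise in the labelling step, and oscillatory structure
inherited from an underlying continuous signal. Passing tests therefore
demonstrate that the estimators and tests recover known structure under
the stated conditions, not that a given empirical sequence satisfies
them; for real data the stationarity assumption must be argued
separately.

## Numerical conventions and limitations

* History coding: base-$L$ integers, most-recent symbol in the lowest
  digit; serialized tables state the convention in their header. Window
  labels print newest-first, matching the $k$-history definition.
* A warning (never an error) flags likely undersampling when
  $L^k > (N-k+1)/10$; PAIF estimation refuses outright only past a
  configurable hard cap on $L^{k+1}$ (default $2^{26}$ bins). The
  undersampling phenomenon is visible in any 4-symbol sequence of
  $\sim 10^5$ samples as spuriously increasing PAIF coefficients beyond
  lag $\approx 8$ — an intrinsic limitation of joint-entropy estimation,
  not of the PAIF specifically, and the reason `max_lag` defaults to 8.
* Default lags: AIF 50, PAIF 8. Default surrogates: 100. All samplers
  take an explicit seed and draw through R's RNG, so `set.seed`-style
  reproducibility holds across the compiled paths too.
* The test suite runs its property checks at reduced problem sizes
  ($N = 10^4$–$5\times10^5$, 20–60 surrogates) chosen so that each
  property is still well-resolved; the acceptance experiments and the
  reproduction script use the full $N = 10^6$ / 100-surrogate
  conditions.
* Known limitations: no entropy bias correction (by design), no
  continuous-alphabet estimators, no directional measures (the AIF is
  symmetric), no HMM inference — the machines are generators, not
  models to be fit.
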