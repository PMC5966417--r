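---
title: "Methods: the coevolution model and its two analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coevolution model and its two analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`coevolang` simulates gene–culture coevolution of language in a
one-dimensional *linguistic space*. A position on the axis encodes
expressiveness: the fitness benefit one successful communication using a
language at that position confers. Two kinds of entities live on the axis:

* **Agents** (fixed number `N`). Agent $i$ carries two genotypes: an innate
  language ability $a_i \ge 0$ (the language it can use at zero learning
  cost) and a plasticity half-width $p_i \ge 0$. It can use any language in
  $[a_i - p_i,\, a_i + p_i]$, at a cost that grows with both plasticity and
  ability.
* **Languages** (variable number). Language $x$ is a point $l_x \ge 0$.
  Languages carry stable lineage identifiers that survive cultural change
  and are re-keyed on division and fusion.

One generation executes, in order:

1. **Communication.** Every unordered pair of agents whose plasticity
   intervals jointly contain at least one language communicates
   successfully; one shared language is drawn uniformly for the pair and
   recorded symmetrically for both partners.
2. **Fitness.** $f_i = W_1 \sum_{j \in SC_i} l_{i,j} -
   W_2\,(p_i + 1)^{a_i}$, where $SC_i$ is the set of partners agent $i$
   communicated with and $l_{i,j}$ the position of the language the pair
   used. The cost term grows exponentially with innate ability: maintaining
   both high ability and high plasticity is expensive.
3. **Reproduction.** $N$ offspring, each copying a parent drawn by
   roulette-wheel selection; each genotype mutates independently with
   probability $P_m$ by a Gaussian increment of variance `mut_var`
   (default 2), clamped at 0.
4. **Cultural change / division.** Every agent that used language $x$ pulls
   it by $F / n_i$ toward its own $a_i$ ($n_i$ = number of languages in
   agent $i$'s interval). The one-sided totals $d_{x+} \ge 0$ and
   $d_{x-} \le 0$ give a net move of $d_{x+} + d_{x-}$; if
   $\min(d_{x+}, |d_{x-}|) > F_d$ the language instead splits into children
   at $l_x + d_{x+}$ and $l_x + d_{x-}$.
5. **Extinction.** Languages nobody used this generation are removed
   (same-generation division children are exempt).
6. **Fusion.** While two languages are closer than $T_f$, the closest pair
   merges at its midpoint.

The reference parameterisation is `N = 2000`, `W1 = 3`, `W2 = 10`,
`Pm = 0.001`, `F = 0.001`, `Fd = 0.008`, `Tf = 0.02`, 10000 generations,
with $a_i$, $p_i$, $l_x$ initialised i.i.d. uniform on $[0, 1]$. At this
setting division and fusion occur continuously and the run cycles through
the characteristic coevolutionary phases: tight low-plasticity clustering,
neutral scattering of abilities, takeover by high-ability/low-plasticity
agents, languages catching up by cultural displacement.

## Design choices where the model statement is open

* **Sign convention.** The negative-direction pull sum is stored
  non-positive, so the net displacement is simply $d_{x+} + d_{x-}$ and a
  division child at $l_x + d_{x-}$ lands below its parent. The division
  threshold compares magnitudes, $\min(d_{x+}, |d_{x-}|)$.
* **Negative fitness under roulette selection.** The raw fitness is
  routinely negative early in a run. Selection weights are the
  rank-preserving shift $f_i - \min_j f_j$ plus a small absolute floor
  (`fitness_floor`, default $10^{-6}$) so weights stay strictly positive.
  An absolute floor was chosen over one scaled to the per-generation weight
  range: behaviour is identical in all non-degenerate cases and the floor's
  meaning does not drift from generation to generation. When every agent
  has equal fitness, selection is uniform.
* **Initial language count.** Not part of the model statement; exposed as
  `init_num_languages` (default 100, large enough that fusion, division and
  extinction act from generation one). The long-run behaviour is
  insensitive to it: any initial set is fused down to roughly
  `1/Tf`-spaced languages within a generation or two.
* **Boundary rule.** Genotypes and positions are clamped at 0 after
  mutation/displacement (not reflected). Clamping is the simplest rule
  consistent with the non-negativity constraints; it can transiently pile
  probability mass at 0, which the rate analysis handles by excluding
  non-positive endpoints.
* **Fusion order.** "Close pairs merge" is realised as greedy nearest-pair
  merging (ties broken toward lower positions) until all gaps are
  $\ge T_f$; this is order-independent up to ties and always terminates.
* **One draw per pair.** The pair's single randomly chosen shared language
  is used for both partners' fitness and counts both partners into the
  language's user set $SA_x$; $n_i$ is evaluated on the pre-change language
  positions, since culture moves only after reproduction.
* **RNG discipline.** One generator per run, seeded from `params$seed`;
  draws occur in a fixed order (initialisation; per-pair language choices
  in lexicographic pair order; selection; mutation masks; mutation
  increments), so a run is a pure function of its parameters. The compiled
  pair loop consumes `unif_rand()` in exactly the order the plain-R
  reference implementation consumes `runif()`, and the two paths are
  bit-identical (tested).

## A known divergence from the reported high-`F` collapse

With the displacement unit raised to $F = 10^{-4}$ (and $F_d = 300F$), the
source experiments report all populations losing every language within
roughly ten generations. This implementation does not reproduce that
collapse: across replicates and across initial language counts from 2 to
100, runs instead stabilise with a few surviving languages that the agent
population keeps within reach, because agents who cannot communicate have
strictly lower fitness and are selected away before coverage abandons a
used language. For the reported mechanism ("languages displaced outside
the plasticity range") to fire at this $F$, the one-sided pull sums would
need to reach order $0.1$, which the stated equations do not produce for
any initial language count. The corresponding acceptance test is
implemented exactly as stated and deliberately left failing rather than
hidden behind a loosened threshold: a red check that reports a genuine
divergence is more useful than a green one that does not.

# Evolutionary rates in darwins

A *darwin* is one $e$-fold of change per unit time; the time unit here is
one generation (the model has no calendar mapping). For trait values
$v_1, v_2 > 0$ measured $\Delta t$ apart,
$d = (\ln v_2 - \ln v_1)/\Delta t$.

* **Biological series:** population mean innate ability per generation,
  sampled over non-overlapping windows for each $\Delta t$ (overlapping
  windows would double-count autocorrelated changes).
* **Cultural samples:** per cultural event — change contributes one
  $(v_1, v_2)$ pair, division two (each child vs the parent), fusion two
  (the merged language vs each parent), extinction none. Each event pair is
  re-evaluated at every $\Delta t$ on the grid: the event is treated as the
  change observed over a measurement window of that length. This is what
  turns a single event log into a rate-versus-interval curve and produces
  the mechanical $1/\Delta t$ dependence that the analysis is designed to
  expose — fluctuating change looks fast on short scales and slow on long
  ones, whereas a directional trend (exponential growth) yields the same
  rate at every interval.
* Magnitudes $|d|$ are reported (signed rates are kept internally);
  endpoint pairs with a non-positive value are excluded and tallied, since
  positions clamped at 0 have no logarithm.

`rate_interval_sweep()` reports per-interval medians and quartiles by
source plus the Spearman correlation between $\Delta t$ and the median
cultural rate.

# Directional effects via effective transfer entropy

To ask which evolutionary stream drives which, the two per-generation mean
series (language position $L$, innate ability $B$) are discretized and
compared by transfer entropy:

1. **Discretization** (`discretize_series`): cut the series into windows of
   length $\Delta t$, average each, take the relative change
   $(w_k - w_{k-1})/w_{k-1}$ of consecutive window means, and bin it into 5
   equal-width levels spanning the observed min–max of that sequence.
   "Rate of change" is read as *relative* change (the natural reading for
   growth series, and scale-free); the equal-width bins adapt per series
   because no fixed range is part of the statement. A constant series
   degenerates to the constant middle symbol with a warning.
2. **Transfer entropy** (`transfer_entropy`): plug-in estimate of
   $T_{Y \to X} = \sum p(x_{t+1}, x_t^m, y_t^l)
   \log_2 \frac{p(x_{t+1} \mid x_t^m, y_t^l)}{p(x_{t+1} \mid x_t^m)}$
   with empirical frequencies, $m = l = 1$ by default. Bits (base 2) are
   the default; natural log is a switch. The plug-in estimator is biased
   upward on finite samples, which is exactly what the next step corrects.
3. **Effective transfer entropy** (`effective_transfer_entropy`):
   $ET_{Y\to X} = T_{Y \to X} - \operatorname{mean}(T_{Y_{rand} \to X})$
   over `n_shuffles` (default 100) uniformly random permutations of the
   source symbols. Permutation preserves the source's symbol distribution
   while destroying its timing, so the subtracted mean is the finite-sample
   bias under the no-coupling null. $ET$ can be slightly negative when the
   true coupling is null.
4. **Across replicates** (`directional_analysis`): per $\Delta t$, medians
   of $ET_{L \to B}$ and $ET_{B \to L}$ and a two-sided Wilcoxon rank-sum
   test between the two samples. The rank-sum (unpaired) form is used
   deliberately, matching the analysis this package reproduces, although
   the samples are paired by trial.

Estimator checks: on tiny inputs the implementation agrees with a
term-by-term brute-force enumeration to floating-point accuracy; on the
lag-1 copy channel it recovers the analytic $\log_2 5 \approx 2.32$ bits,
and on the noisy copy channel the closed form
$\log_2 5 - H(\text{channel})$ across noise levels.

# Synthetic fixtures: what a green test establishes

`make_pair()` and `make_trend()` generate processes with known answers:
i.i.d. uniform pairs (zero TE), lag-1 copy and noisy-copy channels
(closed-form TE), exponential trends (interval-independent darwin rate
$r$), alternating series (rate $\propto 1/\Delta t$), constants (zero
rate). These verify the *analysis stages* independently of the simulator.
They do not mimic simulator output distributions — a green fixture test
establishes estimator correctness, not that the model produces any
particular dynamical regime; the latter is what the replicate-based
acceptance checks probe, at a reduced scale (smaller `N`, shorter runs,
fewer replicates) chosen to keep the suite inside its runtime budget. The
full-scale experiment (10^4 generations, N = 2000, 38 trials) is stated in
the package's documentation as the reference configuration but is not run
by the tests.

# Numerical and degenerate-input conventions

* Languages with no users experience zero displacement and no change
  event; an empty language population is a legal, stagnant state (the run
  continues; language statistics become `NA`).
* `discretize_series` errors on a zero window mean (relative change
  undefined); `directional_analysis` skips such trace/interval
  combinations with a warning rather than failing a whole batch.
* Transfer entropy uses the convention $0 \log 0 = 0$ and is clamped at 0
  against floating-point cancellation; the entropy-decomposition identity
  keeps it exactly non-negative in exact arithmetic.
* Intervals with fewer than 4 symbols are skipped in the directional
  analysis: a 5-symbol alphabet with 3 transitions cannot populate a
  contingency table meaningfully.

# Limitations

* All-pairs interaction only; no spatial or network structure.
* The per-event $\Delta t$ re-evaluation of cultural rates is one reading
  of an under-specified analysis; absolute-difference discretization and
  fixed-range binning are plausible alternatives (the binning alternative
  is exposed as a configuration switch in spirit via `n_levels`/`alphabet`
  arguments, the range convention is not).
* Darwin rates use the generation as the time unit; no mapping to calendar
  time is attempted.
* The high-`F` collapse reported for the source experiments is not
  reproduced (see above).
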