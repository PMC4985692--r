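---
title: "Endpoint-conditioned likelihoods for selection inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint-conditioned likelihoods for selection inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selbridge)
```

## The problem

A time series of allele counts — say from ancient DNA — records the number
$N_B(t)$ of copies of allele $B$ among $N$ alleles across generations.  Two
forces shape it: natural selection, summarized by a single selection
coefficient, and genetic drift, the sampling noise of a finite population.
The standard estimator multiplies the one-step transition probabilities of
a population-genetic Markov chain along the observed record and maximizes
over the selection coefficient $s$:

$$\log L(s) \;=\; \sum_{i,j} n(\{i,j\}) \log P_{ij}(s),$$

where $n(\{i,j\})$ counts observed transitions from count $i$ to count $j$.
That likelihood is the right tool when the data are an *ensemble* of
trajectories free to explore the state space, as in experimental evolution.
A single historical record is different: it is pinned at both ends.  We
observe it *because* it ended where it ended — at the frequency seen at
present time.  A single trajectory is representative of the bundle of paths
sharing its initial *and* final value, so the correct likelihood multiplies
endpoint-conditioned transition probabilities,

$$\log L_c(s) \;=\; \sum_t \log P_{i(t)\,j(t)\,|\,k}(s),
\qquad
P_{ij|k}(s) = P_{ij}(s)\,\phi_{ij|k}(s),$$

with $\phi_{ij|k}$ the Doob $h$-transform factor determined by the
conditioning endpoint $k = N_B(T_F)$.  The two likelihoods are linked by
$L_c(s) = \Phi(s)\,L(s)$ with $\Phi$ the product of the per-step factors;
the package verifies this identity to $10^{-10}$ on every evaluated curve.

## The two chains

Both models track $N_B \in \{0, \dots, N\}$ with absorbing boundaries
($0$: loss of $B$; $N$: fixation of $B$).  `model_spec()` fixes the family,
$N$ (even) and $s \ge 0$; $s = 1$ is neutral and $s > 1$ favors $A$.

* **Moran** (haploid, overlapping generations): one fitness-weighted birth
  and one uniform death per step.  With $W_B = 1$, $W_A = s$,
  $$P_i = \frac{i}{(N-i)s + i}\cdot\frac{N-i}{N},\qquad
    Q_i = \frac{(N-i)s}{(N-i)s + i}\cdot\frac{i}{N},$$
  so $P_i/Q_i = 1/s$: the count drifts up when $B$ is the fitter type.
  The chain moves at most one step per generation — the "slow" chain.
* **Wright–Fisher** (diploid, non-overlapping generations, codominance
  $W_{AB}/W_{BB} = (1+s)/2$): the gamete-pool frequency $p'_B(i)$ follows
  the deterministic selection map and the next generation is a
  $\mathrm{Binomial}(N, p'_B(i))$ draw — the "fast" chain, whose one
  generation corresponds to roughly $N$ Moran steps.

Only fitness *ratios* matter, so fitnesses are normalized internally
($W_B = 1$; $W_{BB} = 1$).

## Conditioning: finite horizons and the asymptotic limit

Four observation geometries cover the practically relevant records
(`case_spec()`):

| case | final time $T_F$        | final value $k$    | transform |
|------|-------------------------|--------------------|-----------|
| I    | $T+1$ (ends at present) | intermediate       | finite-horizon bridge |
| II   | $T+1$                   | fixation ($N$)     | finite-horizon bridge |
| III  | $\gg T$ (gap, no data)  | intermediate       | quasi-stationary limit |
| IV   | $\gg T$                 | fixation ($N$)     | absorption-conditioned limit |

For finite horizons the factor is the ratio of hitting probabilities,
$\phi_{ij|k}(m) = (P^{m-1})_{jk} / (P^m)_{ik}$ with $m = T_F - t$ steps
remaining.  Rather than forming matrix powers, `hitting_logprofile()` runs
the backward recursion $h_m = P h_{m-1}$ from the indicator of $k$ with a
per-step max-renormalization, accumulating the log scale; this yields exact
log hitting probabilities for horizons of many hundreds of steps without
underflow, and every conditioned row normalizes to one identically because
$\sum_j P_{ij} h_{m-1}(j) = h_m(i)$.

For the distant-endpoint cases the factors lose their time dependence:

* $k$ transient: $\phi_{ij} = w_0(j) / (\lambda_0 w_0(i))$, where
  $(\lambda_0, w_0)$ is the Perron eigenpair of the submatrix over the
  transient states $1..N-1$.  We read "largest non-trivial eigenvalue" as
  the Perron root of that block: the trivial eigenvalue $1$ belongs to the
  absorbing boundaries, and Perron–Frobenius on the irreducible transient
  block guarantees $0 < \lambda_0 < 1$ and a strictly positive $w_0$,
  making the transform well defined.  The factor is independent of which
  transient endpoint is used.
* $k$ absorbing: $\phi_{ij|k} = u_{jk} / u_{ik}$ with $u_{ik}$ the
  probability of eventual absorption in $k$.

Cases III/IV use these limits directly; no finite stand-in for the gap
length is chosen, since the geometry specifies only that the gap is long.
Should the leading eigenpair come back complex or sign-indefinite from the
dense solver, `spectral_data()` falls back to power iteration at tolerance
$10^{-12}$ and warns.

Absorption probabilities for tridiagonal (birth–death) chains use the
classical ladder solution evaluated with log-sum-exp, which keeps
probabilities as small as $10^{-300}$ relatively accurate; dense chains use
a rescaled monotone power iteration for the same reason.  A naive linear
solve loses any component below about $10^{-16}$ of the leading scale,
which would corrupt conditioned rows at strong selection.

Bridges that are impossible — an endpoint unreachable in the allotted
steps, relevant for the one-step-at-a-time Moran chain — raise an explicit
`infeasible bridge` error at construction, never silent `NaN`s.  During
likelihood evaluation a zero-probability transition yields `-Inf` as a
*value*, so grid maximization survives partial infeasibility.

## The generator and what it emulates

`simulate_conditioned()` draws trajectories from the h-transformed chain
itself: time-dependent rows for cases I/II (the path hits $k$ at $T_F$ by
construction) and the time-homogeneous transformed kernel for cases III/IV.
Defaults of `experiment_config()` are the canonical study conditions:
$N = 54$ alleles, $N_B(0) = 27$, generating $s = 2$, endpoint $k = 40$ for
intermediate cases, ensembles of 100 trajectories, $T = 500$ generations
for Moran and $T = 100$ for Wright–Fisher, whose fixation cases use the
near-fixation endpoint $k = N - 1$ because the fast chain otherwise fixes
too early to leave informative records.  One root seed drives everything;
trajectory `idx` uses the derived stream `seed + idx`, so ensembles are
reproducible end to end.

The generator emulates exact, error-free counts at every consecutive
generation.  Real ancient-DNA data add binomial sampling noise at each
observation, missing generations inside the record, uncertain $N$, and
model misspecification; none of these are modeled, so passing tests show
correctness of the conditioning machinery under the stated chains, not
robustness to observational noise.

## Estimation choices

`maximize()` evaluates the chosen log-likelihood on 200 log-spaced points
in $s \in [0.05, 20]$ — bracketing both the generating value 2 and the
near-neutral biased estimates — then refines the best grid point by
golden-section search on $\log s$ to relative tolerance $10^{-5}$.  The
conditional likelihood can be bimodal (one mode governed by $L$, one by
$\Phi$), so the *global* maximum is reported, all grid-local maxima are
retained, and a `multimodal` flag is set; `boundary` flags maxima at the
search bounds and `failed` flags flat curves (e.g. a record sitting at an
absorbing state, which carries no information about $s$).

Ensembles are summarized by the mode of a Gaussian kernel density estimate
computed on $\log \hat s$ with Silverman's bandwidth — the log scale
respects the multiplicative nature of a fitness ratio — and by empirical
2.5%/97.5% quantiles.  Boundary and failed fits are excluded from the
summary (they would pile degenerate KDE mass at the search bounds) but are
counted and reported.

## Problem sizes used by the test suite

The exact suites run on small chains where brute force is feasible:
path-law checks enumerate all bridges on $N = 4$, horizons $\le 4$;
sampler checks compare against vectorized rejection sampling on $N = 6$;
spectral/absorption limits are checked against long finite horizons
($m$ up to 600).  The recovery checks run the full study design (100
trajectories per ensemble) for Moran and Wright–Fisher case I, Moran case
III, and reduced ensembles of 30 for the directional case-II and
short-record Wright–Fisher comparisons.

## Known limitations

* No observational (sampling) noise; the likelihoods assume exact counts.
* Mutation, migration, dominance other than codominance, and varying $N$
  are out of scope.
* The asymptotic transform assumes the gap to the present is long relative
  to the chain's relaxation time; for moderately long gaps a finite-horizon
  bridge over the gap would interpolate, which the package does not do.
* The KDE mode/CI summary is one reasonable choice among several; with
  strongly bimodal ensembles the mode can sit on either lobe, which is why
  all local maxima and flags are kept per trajectory.
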