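---
title: "Temporal signal, best-fitting roots, and tip diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal signal, best-fitting roots, and tip diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiptempo)
```

## The model

Heterochronous sequence data — sequences sampled at evolutionarily distinct
time points — let us estimate phylogenies on a natural timescale, but only
when there is enough *temporal signal*: measurable substitution between
sampling times. Before committing to a full molecular-clock analysis it pays
to check this with a simple regression. For each tip $i$ of a rooted tree
whose branch lengths are genetic distances (substitutions/site), let $t_i$
be its sampling time (decimal years) and $d_{r,i}$ the sum of branch lengths
from the root to the tip. Under a strict clock with rate $u$,

$$ \mathbb{E}[d_{r,i}] = u\,(t_i - t_r), $$

so an ordinary least-squares fit of $d_{r,i}$ on $t_i$ estimates the
substitution rate $u$ as its slope and the root date $t_r$ as its
x-intercept. A tight linear trend supports a strict clock; the same trend
with more scatter suggests a relaxed clock; no trend (or a negative slope)
means the data are unsuitable for clock-based inference. A negative slope is
therefore a *result*, never an error, and the package reports it with a
warning.

One caveat shapes the whole interface: the points share phylogenetic
ancestry and are not independent, so the regression's $r^2$, p-values and
confidence limits are not valid statistical estimates. tiptempo consequently
emits no p-values or confidence intervals anywhere and labels $r$ and $r^2$
as informal dispersion measures. This is a data-exploration tool, not a
hypothesis test.

```{r basic}
sim <- simulate_clock_tree(simulation_config(n_tips = 40, rate = 3e-3,
                                             rate_noise = 0.1, seed = 7))
fit <- fit_root_to_tip(sim$dates, root_to_tip_distances(sim$tree))
fit
```

## The best-fitting root

Distance-based and likelihood trees usually arrive arbitrarily rooted, and
the regression depends on where the root is. The search treats every point
on every edge as a candidate root: a placement is an edge (identified by its
child node) plus a fraction $x \in [0,1]$ measured from the **parent** end.
When the root sits at $x b$ along an edge of length $b$, each tip's
root-to-tip distance is affine in $x$ — $\delta_i + (1-x)b$ for tips below
the edge, $\gamma_i + x b$ for the rest — and both rooting criteria

* **rss** — the residual sum of squares of the regression (heterochronous
  data), and
* **variance** — the population variance of root-to-tip distances
  (isochronous data, where the regression is undefined)

depend on the distances only through $\sum d$, $\sum d^2$ and $\sum d t$, so
each is an *exact quadratic* in $x$ on every edge. `find_best_root()`
assembles the per-edge coefficients in $O(E)$ via two traversals (postorder
subtree sums, then preorder all-tips sums), evaluates each quadratic exactly
at $x \in \{0, \tfrac12, 1\}$, and minimizes it in closed form — no
iterative search, fully deterministic, and practical far beyond the tree
sizes where an explicit reroot-and-refit scan becomes slow. The input
rooting is itself a candidate (fraction 0 on a root-child edge), so the
returned objective never exceeds the starting one. Ties are broken by
preorder edge index, then the smaller fraction; zero-length edges report
fraction 0.

```{r bestroot}
shuffled <- random_reroot(sim$tree, seed = 99)$tree   # lose the true root
br <- find_best_root(shuffled, sim$dates, "rss")
br$placement
c(rate = br$fit$slope, root_time = br$fit$x_intercept)
```

Rerooting itself (`reroot_at()`) preserves the unrooted metric exactly:
tip-tip path lengths are unchanged, the old root is suppressed whenever it
is left with degree 2, and a fraction of exactly 0 or 1 lands on the
existing node rather than creating a zero-length edge. The one corner the
placement grammar allows but the tree model cannot honour literally is
fraction 1 on a *terminal* edge — a labelled tip cannot serve as the root —
so there a root node is created at the tip's position with a zero-length
terminal edge.

## Tip dates

Dates can be decimal years, ISO dates, year-months or bare years; partial
dates map to the midpoint of the stated period (a bare year to year + 0.5),
which minimizes the worst-case dating error but does shift root-time
estimates relative to a year-start convention — worth knowing when comparing
to other tools. ISO dates convert leap-aware as
$\mathrm{year} + (\mathrm{doy} - 0.5)/\mathrm{days\ in\ year}$. Dates come
from tab-delimited tables (`load_dates_table()`, header auto-detected) or
from tip labels (`extract_dates_from_labels()`, by delimiter/field or
regular expression, with *all* non-matching labels reported at once).
Ancient-DNA style ages use `direction = "backward"` (years before present);
internally the analysis always runs on the forward scale $t_i =
-\mathrm{YBP}_i$, so slopes and $r^2$ are identical under either convention.
Tips without dates are an error by default; `drop_undated = TRUE` excludes
them with a logged list, because silently dropping tips hides exactly the
data-quality problems the diagnostics exist to surface.

## Diagnostics: residuals and ancestor traces

Two anomaly geometries matter when screening data:

* a large **y-residual** — the tip is far above or below the line: more (or
  less) divergence than its date warrants. Causes include sequencing or
  assembly error, alignment problems, recombination, hypermutation, or
  excessive passaging.
* a large **x-displacement** — the tip is far left or right of the line at
  its divergence level, $t_i - (t_r + d_{r,i}/u)$: the *date* does not match
  the divergence. Causes include mislabelled sampling dates, contamination
  from another time point, and archived or vaccine strains dated at
  sequencing rather than storage time (a "frozen" strain accrues no
  divergence in the freezer and plots below the line, left of its date).

`classify_tips()` reports both quantities for every tip, assigns the side of
the line (a residual of exactly 0 counts as "below", a stated convention for
determinism), and flags tips whose |y-residual| exceeds `k` sample standard
deviations (default `k = 3`; the threshold is a convenience, raw residuals
are always included so users can judge for themselves). `ancestor_traces()`
connects each tip's point to the point on the fitted line whose divergence
equals the tip's immediate ancestral node's root-to-tip distance $d_p$ — the
trace point is $(t_r + d_p/u,\; d_p)$, always exactly on the line, with
$d_p \le d_{r,i}$. A long horizontal trace marks a dating problem; a long
vertical gap marks a divergence problem. The parent-divergence rule is
applied uniformly to all tips. `residual_summary()` adds the histogram
(Freedman–Diaconis rule, minimum 5 bins; a degenerate all-equal residual
vector gets one bin) and the (fitted, residual) scatter.

```{r diag}
inj <- inject_anomaly(sim$tree, sim$dates,
                      list(type = "frozen", tip = "tip07", years = 12))
fit2 <- fit_root_to_tip(inj$dates, root_to_tip_distances(inj$tree))
flags <- classify_tips(fit2)
flags[flags$tip == "tip07", c("tip", "residual", "x_displacement", "side")]
```

## The simulator

`simulate_clock_tree()` exists so every claim above is testable against
known truth without external data. It draws tip times uniformly in a
sampling window, builds a genealogy by random pairwise joins backward in
time with exponential waiting times (a serial-sample coalescent with
timescale `ne`, default 5 years — chosen so a decade-wide window yields
TMRCAs a few years before the window, typical of a fast-evolving virus),
and converts branch durations to genetic lengths at rate `u` times a
lognormal(0, `rate_noise`) per-branch multiplier — the relaxed-clock scatter
seen in real regressions. `root_time` is a floor: when the coalescent's
TMRCA lands later, the root node is pushed back to it by lengthening both
root-child durations equally, which keeps the genealogy exactly clock-like.
With `rate_noise = 0` the construction guarantees $r^2 = 1$, slope $= u$ and
x-intercept $=$ the realized root date to numerical precision — the anchor
for the exactness tests. Defaults (50 tips, $u = 3\times10^{-3}$
subs/site/year, window 2000–2010) emulate a measurably evolving RNA-virus
gene data set.

What the simulator does *not* emulate: phylogenetic estimation error,
alignment artefacts, rate variation correlated with the tree structure
(local clocks), recombination, or non-uniform sampling. Passing tests
demonstrate the *method* is implemented correctly under its own model; they
do not certify behaviour on trees inferred from real alignments, where the
regression remains an exploratory screen.

Anomalies are injected with known truth: `frozen` adds storage years to the
date only, `misdated` shifts the date, `divergent` lengthens the terminal
branch. On a noise-free tree their induced residuals follow OLS leverage
algebra exactly (e.g. a frozen tip's residual is $-u s (1 - h_{jj})$ for
storage $s$ and leverage $h_{jj}$), which the tests assert against an
independent linear-model fit.

## Numerical choices

* OLS uses centered sums (means first, then centered second moments); the
  naive $\sum x^2$ form loses precision at $10^5$ tips with decade-scale
  year values.
* Degenerate conventions are fixed, not backend-dependent: zero slope gives
  an undefined (NaN) x-intercept; zero distance variance gives $r^2 = 0$;
  identical dates in heterochronous mode raise an error pointing to the
  isochronous analysis.
* Negative branch lengths are rejected by default; `clamp_negative = TRUE`
  clamps them to 0 with a warning. Missing branch lengths parse as 0 with a
  warning (they are common on root edges).
* The per-edge quadratic is fitted through exact evaluations, so it agrees
  with direct objective computation to ~1e-14 in practice; the test suite
  keeps a brute-force explicit-reroot grid oracle for independent
  confirmation.
* Newick output carries 15 significant digits, so a read–write round trip
  is idempotent and preserves the metric to double precision.

## Problem sizes in the test and acceptance runs

The bundled checks use 10–100-tip simulations, 100-replicate anomaly
screens at 50 tips and noise 0.05, a 2001-point-per-edge brute-force root
oracle on 12-tip trees, and 100 random reroots on a 30-tip tree — sizes at
which the exact search and the grid oracle can be compared to 1e-8 in
seconds while still exercising every code path. The algorithms themselves
scale far beyond this (the root scan is linear in the number of edges).

## Limitations

The regression assumes the tree's branch lengths are genetic distances on a
correctly inferred topology; it cannot repair a wrong tree, only flag tips
that look inconsistent on it. Rate estimates from the regression are
exploratory — for publishable rates and dates, use a full probabilistic
clock model after this screen. Isochronous mode summarizes rate variation
only through root-to-tip distance spread. No nexus input, no multi-tree
batch processing, and no automated attribution of anomaly causes: the
diagnostics provide clues, the judgement stays with the investigator.
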