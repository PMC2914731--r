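---
title: "Robust median-spline permutation testing for time-course expression"
author: "qsperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust median-spline permutation testing for time-course expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsperm)
```

## The problem and the model

A grouped time-course experiment measures the expression of $m$ genes in
$K \ge 2$ groups at $L$ common time-points $t_1 < \dots < t_L$, with
$n_{kl} \ge 1$ observations for group $k$ at time $l$. For gene $j$ the
expression in group $k$ at time $t$ is modelled through its conditional
**median** trajectory $g_{kj}(t)$, and the question of interest is whether
the trajectory depends on the group:

$$H_j : g_{1j} = \dots = g_{Kj} \quad \text{versus} \quad
  \bar H_j : g_{kj} \ne g_{k'j} \text{ for some } k, k'.$$

Fitting conditional medians instead of conditional means is the robustness
device. Microarray and sequencing intensities are notoriously prone to
heavy-tailed artefacts; a least-squares trajectory chases a single aberrant
observation, whereas the median trajectory ignores any contamination that
is symmetric about the curve. Throughout, trajectories are restricted to a
shared $p$-dimensional spline space, so every gene and every
group is fitted with the same degrees of freedom.

## Trajectory fits as linear programs

Each fit minimises the absolute-error sum
$\sum_i \lvert y_i - W(t_i)^\top\beta \rvert$ over the spline coefficients
$\beta$, optionally plus a roughness penalty
$\lambda \cdot \mathrm{TV}(g')$ (the total variation of the fitted
function's derivative, the $L_1$ analogue of the usual integrated squared
second derivative). Both the loss and the penalty are piecewise linear, so
the optimisation is a finite linear program.

The package ships its own exact solver (`src/l1fit.cpp`): a primal simplex
on the residual-splitting formulation, plus a much faster
interpolation-set exchange algorithm used when all rows carry equal weight
(an optimal absolute-error fit always interpolates $p$ affinely
independent observations; the algorithm walks from vertex to vertex by
weighted-median line searches, strictly decreasing the objective, and
falls back to the simplex on numerically pathological instances). Two
consequences matter for inference:

* the **attained objective** (the residual absolute-error sum) is unique
  at the optimum and exact up to round-off, even though the coefficient
  vector of an $L_1$ fit need not be unique — all downstream statistics
  use only the objective;
* observed and permuted datasets go through the identical code path and
  solver settings, so permutation comparisons are internally consistent.

`lambda = 0` (the default) gives a plain regression spline, which is how
the test is normally run; with `lambda > 0` the penalty enters the same
linear program as auxiliary rows. For the default degree-1 basis the
penalty operator is exact; for higher degrees second differences of the
B-spline coefficients stand in for it, the standard surrogate.

## The shared basis

`makeSplineBasis()` builds a degree-1 (piecewise-linear) B-spline basis of
dimension $p = 4$ by default, with boundary knots at the extremes of the
pooled per-sample observation times and interior knots at their empirical
quantiles — levels $1/(p-1), \dots, (p-2)/(p-1)$ for degree 1, generalised
to $i/(p-d)$ for degree $d$ so that the dimension stays $p$. Quantiles use
the linear-interpolation convention (R's `type = 7`); the convention
matters only through knot placement and is recorded in the basis object.
The design matrix carries an explicit intercept and drops the first
B-spline column (the B-splines sum to one), keeping exactly $p$ columns of
full rank. Tied quantiles collapse with a warning and reduce the effective
dimension; a design whose distinct times cannot support $p$ parameters is
an error, never a silent repair. Evaluation outside the knot span is
refused — the fitted class is not meant to extrapolate.

$p = 4$ with degree 1 is deliberately coarse: four parameters per curve on
a ten-hour grid resist overfitting the 3–4 replicates typically available
per group and time-point, and the shared basis makes per-gene degrees of
freedom identical, which the multiplicity adjustment below exploits.

## The F-type statistic

With $\mathrm{RAE}_{0j}$ the residual absolute-error sum of the single
curve fitted to all observations of gene $j$ (group labels ignored) and
$\mathrm{RAE}_{kj}$ the group-$k$ fit's residual error, the package scores

$$F_j \;=\; \frac{\mathrm{RAE}_{0j} - \sum_k \mathrm{RAE}_{kj}}
                 {\sum_k \mathrm{RAE}_{kj}} \;\ge\; 0,$$

the classical goodness-of-fit ratio (nesting guarantees nonnegativity: the
pooled curve is a feasible candidate for every group fit). Degrees-of-freedom
constants are omitted on purpose: every gene shares one basis and one
design, so any strictly monotone, gene-common rescaling of $F$ leaves both
the per-gene permutation p-values and the maxT adjustment unchanged — the
adjustment depends only on within-permutation comparisons of a common
statistic. If the group fits interpolate while the pooled fit does not,
$F_j = \infty$, which ranks above every finite value; if both residual
errors vanish, $F_j = 0$. Residual errors agreeing to within square-root
machine precision are treated as the same value when these sentinels are
assigned, and solver round-off can make the numerator microscopically
negative, in which case it is clamped at zero.

Running the same machinery with squared-error loss (`loss = "mean"`)
reproduces the non-robust mean-regression pipeline, used here as the
comparator in the benchmark. A one-sample variant (`oneSample = TRUE`)
tests $g_j \equiv c_j$ against any time dependence; its null residual uses
the sample median under median loss (the loss-consistent centre, the
default) or the sample mean under squared loss, and `center = "mean"`
swaps in the mean if wanted.

Genes that differ between groups only by a constant vertical offset — a
typical batch artefact — can be neutralised beforehand with
`center = "group-mean"` (subtract each group's per-gene mean; idempotent).

## Permutation inference and multiplicity

Under $H_j$ for all genes, observations at the same time-point are
exchangeable across groups, so the null is generated by permuting
observations **within each time-point**. The exact null has
$\prod_l n_{\cdot l}! / \prod_k n_{kl}!$ atoms (`countPermutations()`),
astronomically many for realistic designs, so $B$ random permutations
approximate it. One permutation per replicate is applied to **all genes
jointly** — columns move together — preserving the gene–gene correlation
that the maxT adjustment needs. For the one-sample test all observations
of a gene are exchangeable and the permutation is unrestricted.

Two exact invariances make the sweep cheap: the pooled fit only sees the
(expression, time) pairs, which a within-time-point permutation does not
change, so $\mathrm{RAE}_{0j}$ is computed once; and each group occupies a
fixed multiset of design rows ($n_{kl}$ is constant), so only the response
columns assigned to each group change per replicate.

P-values follow the plain frequency definition with ties counted as
extreme: $p_j = B^{-1} \sum_b 1\{F^*_{bj} \ge F_j\}$, and the single-step
maxT adjustment compares every gene against the replicate maxima
$M_b = \max_j F^*_{bj}$:
$\tilde p_j = B^{-1} \sum_b 1\{M_b \ge F_j\}$. Consequences of these
conventions, all deliberate and all switchable or documented:

* $p_j$ can be exactly 0; `floorPvalues = TRUE` substitutes the
  conservative $(\#+1)/(B+1)$ estimator whose minimum is $1/(B+1)$;
* significance is called at $\tilde p_j \le \alpha$ (ties-to-significant);
  the strict-inequality reading differs only on the boundary atom;
* $\tilde p_j \ge p_j$ always, and $\tilde p$ is monotone in $F$ across
  genes within one analysis.

Benjamini–Hochberg FDR-adjusted p-values (`p_fdr`, via `p.adjust`) are
reported alongside for analyses that prefer FDR control to FWER control.

Reproducibility: one seeded RNG stream drives all permutation draws,
recorded in the result's metadata; results are single-threaded and
byte-stable for fixed inputs and seed.

## The synthetic benchmark generator

`simConfig()`/`simulateDataset()` emulate a two-group dauer-style
time-course: 11 time-points $\{0,\dots,8,10,12\}$ hours, 4 replicates per
group per time-point, and expressions

$$y \;=\; \mu_{k}(t) \;+\; a \;+\; \varepsilon,$$

with standard normal $\varepsilon$, an outlier shift $a \in \{-4, 0, +4\}$
with probabilities $\pi/2,\, 1-\pi,\, \pi/2$ (model 1: at every
time-point; model 2: only at the first and last), and, for prognostic
genes, a group-2 trajectory $\mu_2(t) = 1.5\,e^{-t}$ against a flat group
1. Gene–gene error correlation is block-exchangeable: within blocks of 10
genes a shared factor per observation gives correlation $\rho$
($\varepsilon = \sqrt{\rho}\, z_{\text{block}} +
\sqrt{1-\rho}\, e_{\text{gene}}$), independent across observations and
across blocks. The outlier term is independent of $\varepsilon$ and
uncorrelated across genes. Prognostic genes are placed in distinct blocks
(the first gene of each leading block). The contamination is symmetric, so
the median of the error law is zero for every $\pi$ — the median-spline
estimand is untouched by outliers while the variance (hence the mean
pipeline) inflates as $1 + 16\pi$; this is the premise the test exploits
and the property suite verifies.

`estimateFWER()` (no prognostic genes) and `estimatePower()` (some) run
the full pipeline on $N$ generated datasets and report the proportion with
at least one rejection — the family-wise error rate under the global null,
the global power otherwise — with the binomial Monte-Carlo standard error
$\sqrt{v(1-v)/N}$. Several methods can be evaluated in one pass, in which
case they analyse identical datasets with identical permutation draws, the
right footing for loss-function comparisons. `runScenarioGrid()` sweeps a
scenario grid with one derived seed per cell;
`scripts/full_simulation.R` runs the complete grid at full scale
($m = 200$, $N = 200$, $B = 200$).

What the generator does **not** emulate: intensity-dependent variance,
missing values, unbalanced or gene-specific time grids, asymmetric
contamination, and correlation between time-points within a subject. A
clean bill from the benchmark therefore speaks to outlier robustness and
error control under the stated error law, not to those aspects of real
data.

## Problem sizes and numerical choices

The test-suite and acceptance scenarios run at a reduced scale chosen to
keep a full Monte-Carlo sweep comfortably within a desk session while
leaving the per-dataset analysis untouched: $m = 100$ genes, $N = 100$
datasets and $B = 100$ permutations per scenario cell, with 5 prognostic
genes among 95 null for power cells (the same 5% prognostic fraction as
the full-scale design). Rejection proportions at this scale carry a
binomial standard error of at most $0.05$.

At the generator's default effect amplitude (1.5 decaying as $e^{-t}$
against unit noise, i.e. appreciable signal at only the first two or three
time-points), per-gene signal is modest and the global power measured by
the acceptance runs is correspondingly low for both losses; power climbs
steeply with the amplitude (the suite checks that a large-amplitude effect
is detected in every dataset), and the median-versus-mean power ordering
under contamination emerges clearly only once per-gene power leaves the
noise floor.

Other numerical choices, collected: solver feasibility/optimality
tolerance $10^{-9}$ with Bland's anti-cycling rule as fallback; ratio-test
ties broken toward the smallest basic index; rank-deficient designs fitted
on a pivoted full-rank column subset and flagged; the permutation stream
pre-drawn from the seeded RNG so results do not depend on any execution
interleaving; `countPermutations()` returns a double (exact below
$2^{53}$, documented, since realistic counts like $70^{11}$ exceed any
integer type worth the dependency).

## Limitations

* $K$-group testing is supported, but the benchmark machinery is written
  for the two-group design.
* No automatic selection of $p$ or $\lambda$: the basis is a modelling
  choice, made once per analysis.
* Quantile levels other than the median are out of scope; the robustness
  story here is specifically the conditional median.
* The maxT adjustment is single-step; step-down refinements would be
  sharper but are not implemented.
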