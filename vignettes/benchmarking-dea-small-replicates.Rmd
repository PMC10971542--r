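---
title: "Benchmarking differential expression analysis under small biological replication"
author: "scDEbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential expression analysis under small biological replication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scDEbench)
```

# Motivation

Differential expression analysis (DEA) asks which genes change expression
between two conditions. Single-cell RNA-seq experiments are expensive, so
two to five biological replicates per group remain common — exactly the
regime where variance estimation per gene is hardest and where DEA methods
diverge most. `scDEbench` provides a controlled laboratory for this regime:
a count simulator with known ground truth, six per-gene statistics spanning
the main methodological families, a metric panel for calls and rankings,
and a composite score that aggregates the panel per method.

# The simulation model

Counts are drawn from the Tweedie family with power index
$1 < \rho < 2$, the compound Poisson-Gamma model: a gene's count in one
sample is a sum of $N \sim \mathrm{Poisson}(\lambda)$ Gamma-distributed
bursts, with

$$\lambda = \frac{\mu^{2-\rho}}{\Phi\,(2-\rho)}, \qquad
\text{shape} = \frac{2-\rho}{\rho-1}, \qquad
\text{scale} = \Phi\,(\rho-1)\,\mu^{\rho-1},$$

so the draw has mean $\mu$, variance $\Phi \mu^{\rho}$, and an exact point
mass $e^{-\lambda}$ at zero. This captures the two salient features of
read counts — overdispersion (variance above the mean, since
$\Phi\mu^{\rho-1} > 1$ for all default parameter sets) and a zero mass —
without modelling UMI sampling or dropout mechanisms explicitly. The
sampler refuses $\rho$ outside $(1,2)$: the Poisson and Gamma limits are
different distributions and the compound representation does not apply.

The default two-group design holds 10,000 genes: 9,000 null genes with
$(\rho, \mu, \Phi) = (1.2, 20, 2)$ in both groups, 500 up-regulated genes
whose control group is raised to $(\mu, \Phi) = (40, 2.2)$, and 500
down-regulated genes whose control group is lowered to $(10, 1.8)$, with
$K \in \{2,\dots,5\}$ replicates per group. The shifted parameters sit in
the *control* group by design; the class labels record the scheme, not a
sign convention. These defaults are the study conditions of the benchmark
and are not tuned per run.

Two generator choices were genuinely open and are fixed as follows.
*Rounding*: Tweedie draws are continuous with a point mass at zero; by
default they are rounded to the nearest nonnegative integer so that the
matrix is a valid count table for the count-based statistics
(`roundToInteger = FALSE` keeps raw draws, which some tests use to obtain
tie-free data). *Library sizes*: all samples share the same expected
depth; per-sample depth variation is left to the normalization steps to
handle and is not separately simulated.

What the simulator does *not* emulate: UMI/dropout mechanics, batch
effects, correlated genes, more than two conditions, or empirically fitted
parameter distributions. Passing benchmarks here therefore demonstrate
behaviour under idealized overdispersed counts, not performance on any
particular real dataset.

# The six statistics

All methods score every gene; "score" always means larger = stronger
evidence.

**Welch t** (`statTTest`). On log-CPM values
($\log_2(\mathrm{cpm} + 1)$),
$t = (\bar x_1 - \bar x_2)/\sqrt{s_1^2/N_1 + s_2^2/N_2}$ with
Welch–Satterthwaite degrees of freedom. When both group variances vanish
the convention is $p = 1$ for equal means and $p = 0$ otherwise.

**Wilcoxon rank-sum** (`statWilcoxon`). On raw counts; exact enumeration
when the design has at most 10 samples and the gene has no ties, otherwise
the midrank normal approximation with tie and continuity corrections. With
$K \le 3$ the smallest attainable exact two-sided p-value is
$2/\binom{2K}{K} > 0.05$, so the exact test cannot reject at the 5% level —
the structural failure mode that motivates comparing alternatives at small
$K$.

**NB Wald** (`statNBWald`). Counts are scaled by median-of-ratios size
factors (the ratio of each count to its gene's geometric mean, median over
genes per sample). Per-gene NB dispersion comes from the method of moments
within groups, pooled with degree-of-freedom weights, floored at zero, and
shrunk 50/50 toward a log-log linear mean–dispersion trend — a simplified
information-borrowing step standing in for a full empirical-Bayes
dispersion model (the weight is configurable, 0 disables it). The Wald
statistic is the log2 fold change of scaled group means over its
delta-method standard error from $\mathrm{Var} = \mu + \Phi\mu^2$,
referred to the standard normal. A plug-in-variance z-test at $n \le 10$
samples is mildly anticonservative (it rejects at roughly 6–7% rather than
5% under the null here); this is a property of the normal-reference Wald
construction itself and is deliberately not patched, since it is exactly
the small-sample behaviour the benchmark is meant to expose.

**Moderated t** (`statModeratedT`). The empirical-Bayes hierarchical
variance model: per-gene residual variances $s_j^2$ (with $d_j = n - 2$)
are shrunk toward a prior,
$\tilde s^2 = (d_0 s_0^2 + d_j s_j^2)/(d_0 + d_j)$, and
$\tilde t = \hat\beta/(u\,\tilde s)$ is referred to a t distribution with
$d_0 + d_j$ degrees of freedom. The hyperparameters are estimated by the
classical method of moments on $\log s_j^2$ (mean and excess variance of
$e_j = \log s_j^2 - \psi(d_j/2) + \log(d_j/2)$, inverting the trigamma
function). When the moment estimate diverges — residual variances
essentially homogeneous — $d_0$ is capped at ten times the gene count and
$s_0^2$ is set to the geometric mean of the $s_j^2$, making homogeneous
variances an exact fixed point of the shrinkage. With $d_0 = 0$ the
statistic reduces to the ordinary pooled-variance t. No precision-weight
(voom-style) step is applied; the linear model runs directly on log-CPM.

**Regularized t** (`statRegularizedT`). The SAM-style statistic
$t = (\bar x_A - \bar x_B)/(s_0 + s(i))$ with the pooled spread $s(i)$ and
a damping constant $s_0$. $s_0$ is chosen by searching the 0th–100th
percentiles (step 5) of $\{s(i)\}$ for the value minimizing the
coefficient of variation of the statistic's median absolute deviation
across 100 spread-ordered gene windows — the flat-variance criterion — with
a simpler median rule available. P-values come from a pooled label-permutation
null: all distinct group assignments when there are at most 500 (always the
case for $K \le 5$), pooled across genes, so even six permutations at
$K = 2$ yield finely graded p-values.

**DEF entropy** (`statDEFEntropy`). The label-free entropy statistic:
counts are divided by their sample totals, each gene's normalized values
become proportions $p_j$ over the $n$ samples, and
$\mathrm{Ent} = 1 - H(p)/\log n \in [0,1]$ — zero for uniform expression,
one for expression concentrated in a single sample. The log base cancels.
Genes with zero total count are skipped (NA score, never called). Because
no p-value exists, calling uses the top-P rule (default $P = 1000$ in the
simulation design). The formulation is deliberately label-free: the
statistic measures concentration across samples, which under a balanced
two-group design is driven by between-group shifts. A consequence worth
knowing: its deterministic signal for a two-fold shift *decreases* with
the number of samples while its noise also decreases, so its ranking AUC
(not its raw score) is the quantity that improves with replication. On
the default design its top-1000 false positive rate sits near 0.07–0.08
(see the acceptance checks) — the per-sample entropy deficit of a two-fold
shift is comparable to the sampling noise of null genes at this
overdispersion level, so the statistic's practical false-positive control
here is weaker than ideal.

# Decision rules and evaluation

P-value methods call genes at $p < \alpha$ (strict, default
$\alpha = 0.05$); the DEF statistic calls the top $P$ scores with stable
input-order tie-breaking. Against ground truth the panel comprises TPR,
FPR, FDR $= \mathrm{FP}/(\mathrm{FP}+\mathrm{TP})$, F1, ranking AUC
(Mann–Whitney form, ties counting one half — tested against brute-force
pair enumeration), and the rank-based pair Mean-Rank / MRSR. Mean-Rank is
the average within-predicted-list rank of the true positives and

$$\mathrm{MRSR} = \frac{\mathrm{MeanRank}}{(TP+1)/2} \ \ge 1,$$

equal to 1 exactly when the true positives occupy the top ranks. Dividing
by $TP$ (rather than by the predicted-list size) is what gives MRSR its
$[1, \infty)$ range and its attained lower bound; the predicted-list
variant is kept behind `denominator = "predicted"` for sensitivity
analysis. Zero-denominator metrics are reported as missing, never as
silent zeros, and aggregation records how many repetitions contributed to
each cell.

For data without ground truth (`runReal`), reference genes are defined by
$|\log_2 \mathrm{FC}| > 1$ (strict) on size-factor-scaled group means, and
the same panel is computed against that reference set.

# Composite scoring

The entropy weight method turns the per-K method-by-metric panel (TPR, F1,
AUC as benefit; FPR, MRSR as cost) into one score per method: min-max
normalize each column in its beneficial direction, compute each column's
Shannon entropy over methods, weight columns by one minus entropy
(metrics that discriminate more count more), and min-max rescale the
weighted sums to 0–100 per K, so the best and worst methods pin the scale.
Constant columns carry no information and get weight zero; missing cells
are imputed with the column's worst observed value. These normalization
choices are the package's own (the method family admits several variants);
they satisfy row-permutation equivariance, dominance (a method best on
every metric scores 100), and per-column scale invariance, all of which
are tested.

# Reproducibility and problem sizes

Every simulated dataset is a pure function of its `SimulationConfig`,
including the seed. The benchmark derives the seed for repetition $(K, r)$
as $(\mathrm{masterSeed} + 1000K + r) \bmod (2^{31}-1)$, so any single
cell of the design can be regenerated in isolation, and the whole report
is byte-reproducible from the config. The bundled acceptance script runs
the full 10,000-gene design with 10 repetitions per condition — enough for
the stochastic quantities it reports to stabilize to well within their
comparison slack — and the test suite uses smaller gene counts for the
distributional properties where full scale adds nothing.

# Known limitations

* The NB-Wald dispersion trend is a deliberately simple stand-in for a
  full empirical-Bayes dispersion model; it borrows information across
  genes but does not weight by precision.
* The regularized-t permutation null pools across genes, which assumes
  approximately exchangeable null distributions after the $s_0$ damping.
* The DEF statistic's false-positive behaviour under top-P calling depends
  strongly on the overdispersion level; see the discussion above.
* The simulator's idealizations (no dropout model, independent genes,
  equal expected depth) mean results transfer to real data only
  qualitatively.
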