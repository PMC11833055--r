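---
title: "Cross-model transcriptome concordance: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-model transcriptome concordance: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcconcord)
```

## The scientific question

Ground-based analogues of spaceflight — a 3D clinostat that continuously
randomizes the gravity vector, or hindlimb unloading by tail suspension —
are only useful insofar as they reproduce the biology of actual flight.
One quantitative handle is the brain transcriptome: each model yields a
per-gene log2 fold change against its own control group, and models can be
compared by how similar those fold-change profiles are. `fcconcord`
implements that comparison as a pipeline of small, independently testable
steps.

## The distance statistic

Given studies aligned on the set of genes detected in all of them, the
distance between studies $a$ and $b$ is the L1 norm of the difference of
their log2 fold-change vectors:

$$S_{a/b} = \sum_{g \in \text{shared}} \left| \mathrm{FC}_a(g) - \mathrm{FC}_b(g) \right|,$$

with $\mathrm{FC}$ in log2 units. Every shared gene contributes — there is
no significance filter or winsorizing — so $S$ reflects the whole profile,
not only the extreme tail. $S$ inherits the metric axioms from the L1 norm
(non-negativity, zero iff identical profiles, symmetry, triangle
inequality), which the test suite verifies exhaustively on random inputs.
Because $S$ is a raw sum, it grows with the number of shared genes;
`l1_fc_distance()` therefore also reports `s_per_gene = S / n_genes` for
comparisons across differently sized gene sets, but the raw value is the
primary statistic. `gene_contributions()` decomposes $S$ into its per-gene
terms (they sum exactly to $S$), which is how one inspects *which* genes
drive a divergence.

Ranking uses ascending $S$ to a designated reference profile; ties are
broken lexicographically by label so output is deterministic.

## Shared-gene alignment

"Detected in all models" is operationalized as: a gene enters the
shared-gene matrix iff it appears with finite log2 fold change and p-value
in every study's table. Rows with missing or non-finite values are dropped
at read time (with a warning count), not imputed; matching is exact,
case-sensitive string equality on gene identifiers, with no ortholog or
alias mapping — appropriate when all studies report the same species'
gene symbols, which is the intended use. Genes are ordered
lexicographically and the intersection is exact, so the matrix is
reproducible regardless of input row order.

## DEG calling and set comparison

A gene is called differentially expressed when its raw p-value is below
0.05 **and** its linear fold change $2^{\mathrm{FC}}$ exceeds 1.5 or falls
below the down threshold. Choices worth stating explicitly:

- **Strict inequalities.** A gene sitting exactly at $p = 0.05$ or at a
  fold-change bound is *not* called; the thresholds are written with
  `<`/`>` and the code follows them literally.
- **Down threshold.** The default is the exact reciprocal $1/1.5 =
  0.6\overline{6}$, symmetric in log space, rather than the conventional
  rounded 0.667. The difference matters only for genes within about 7e-4
  of the bound (at most a one-gene-scale discrepancy on real tables);
  `deg_criteria(literal_0.667 = TRUE)` reproduces the rounded bound.
- **Raw p-values.** The calling rule uses unadjusted P. The Welch engine
  can emit Benjamini–Hochberg adjusted values (`adjust = "BH"`) but that is
  off by default.
- **Compound condition.** "P < 0.05 and FC > 2 or FC < 0.5" is read as
  $p < 0.05 \wedge (\mathrm{FC} > 2 \vee \mathrm{FC} < 0.5)$; the
  alternative parse would call every gene with FC < 0.5 regardless of
  significance, which is not a defensible rule.
- **Venn membership is directionless.** The three-way partition counts a
  gene as shared between two models if both call it, even with opposite
  signs; direction can be recovered by classifying per study.

The heatmap panel uses the same classifier with the stricter thresholds
(FC > 2 or < 0.5), restricted to the shared-gene matrix, keeping genes
significant in at least one model, in lexicographic order.

## The differential-expression engine

The pipeline needs a calibrated source of per-gene fold changes and
p-values for simulated counts. The engine is deliberately minimal:

1. **CPM normalization** — each sample scaled to one million total counts.
2. **Fold change** — $\log_2\!\big((\bar{\mathrm{CPM}}_{trt} + c) /
   (\bar{\mathrm{CPM}}_{ctl} + c)\big)$ with pseudocount $c = 0.5$
   (configurable). The pseudocount is the main small-count bias knob: it
   shrinks fold changes of low-expression genes toward zero.
3. **Significance** — a two-sided Welch (unequal-variance) t-test on
   $\log_2(\mathrm{CPM} + c)$ per gene, vectorized across genes with the
   Welch–Satterthwaite degrees of freedom; a unit test checks it against
   `stats::t.test` gene by gene. Genes constant within both groups get
   $p = 1$ when the group means coincide (no evidence), $p = 0$ otherwise
   (a degenerate exact difference).

This is not a negative-binomial model with dispersion shrinkage; it is a
transparent engine whose type-I error on null NB counts sits near the
nominal level (checked at $\alpha = 0.05$ in the acceptance suite). Real
studies analysed with a dedicated DE tool should enter the pipeline as
precomputed tables via `read_profile()` rather than through this engine.

## The simulator and what it emulates

`sim_config()` describes a panel of two-group studies sharing a reference
effect vector:

- A fraction `f_de` of genes (default 0.1) is differential in the
  reference, with log2 effects $\beta^{ref} \sim N(0, \sigma_\beta^2)$,
  $\sigma_\beta = 1$ by default (a 2-fold typical effect).
- Study $s$'s planted effect on a DE gene is
  $\beta_s = \rho_s \beta^{ref} + \sqrt{1 - \rho_s^2}\,\eta$ with
  $\eta \sim N(0, \sigma_\beta^2)$, so $\rho_s \in [0, 1]$ *is* the
  correlation of the study's true effects with the reference — the
  study-level concordance. $\rho = 1$ reproduces the reference exactly.
  Non-DE genes have zero effect in every study; study-private DE genes are
  not generated (the simplest structure under which "which model is closer
  to the reference" is well-posed).
- Counts are negative binomial with mean $\mu_g 2^{\beta_s x}$ ($x = 1$ for
  treated samples) and variance $\mu + \phi \mu^2$ — i.e.
  `rnbinom(mu, size = 1/phi)`; the parameterization is stated to avoid
  drift. Default $\phi = 0.3$, a moderate bulk RNA-seq dispersion.
  Baselines $\mu_g$ are log-normal (natural-log mean 5, SD 1.5), spanning
  single-digit to tens-of-thousands counts as in brain bulk RNA-seq.
- Defaults: 5000 genes, 6 animals per group (the cohort size of the study
  design this mirrors), three studies at $\rho = (1, 0.8, 0.2)$ — a
  reference plus one close and one distant ground model.

For DE genes the difference $\beta_s - \beta^{ref}$ is Gaussian with
variance $2\sigma_\beta^2(1 - \rho)$, so
$E\left|\beta_s - \beta^{ref}\right| =
2\sigma_\beta\sqrt{(1-\rho)/\pi}$ — the folded-Gaussian closed form against
which the simulator is checked (Monte-Carlo mean within three standard
errors at ≥ 500 DE genes). Expected true-effect distance to the reference
is monotone decreasing in $\rho$, which is what makes the end-to-end
ranking test meaningful: with $\rho_A = 0.8$ and $\rho_B = 0.2$ the
pipeline must place A before B in at least 19 of 20 independent seeds.

**Determinism.** One master seed; the reference effects, the baseline
means, each study's idiosyncratic effects and each study's counts are drawn
from separate substreams keyed by a deterministic hash of (seed, label), so
adding a study to a config never perturbs the studies already present.

**What the simulator does not emulate.** Library-size variation between
samples, gene–gene correlation, batch effects, length/GC biases, and
study-private differential genes (available conceptually but off). Passing
tests therefore demonstrate the pipeline's *logic* — thresholding, set
algebra, the distance and its ranking behavior under known concordance —
not performance on any particular real dataset; applying it to real
studies means supplying their published per-gene tables.

## Behavioral indices

The same study design scores behavior with simple ratio indices, included
so event-level inputs can be scored reproducibly:

- **Recognition index** $= 100\,T_N/(T_N + T_F)$, requiring positive total
  exploration time; satisfies the complement identity
  $RI(t_n, t_f) + RI(t_f, t_n) = 100$ and is invariant to time units.
- **Spontaneous alternation** $= 100 \cdot \text{alternations}/(\text{entries} - 2)$,
  where an alternation is a window of three *consecutive* entries visiting
  three distinct arms. Windows overlap (A,B,C,A,B,C scores 4): with the
  $(\text{entries}-2)$ denominator only overlapping counting makes 100%
  attainable, so the two conventions are consistent with each other.
  Consecutive re-entries count as entries but break alternations. At least
  three entries are required; fewer is an error, not a zero.
- **Elevated plus maze**: open-arm entries over total entries ×100, and
  open-arm time over total session time ×100. A single combined
  "anxiety index" mixing times and entries admits several non-equivalent
  formulas, so only the two unambiguous components are provided.

All indices are on the 0–100 percent scale and raise errors on undefined
denominators rather than returning NA silently.

## Numerical and testing choices

- Problem sizes: the acceptance suite uses 200 random matrices for the
  metric axioms, 100 random instances per brute-force oracle comparison,
  2000-gene simulations for the closed-form and type-I checks, and twenty
  5000-gene panels for ranking recovery — large enough for stable
  Monte-Carlo behavior while keeping the whole suite under a minute of
  compute on a single core.
- Oracles in the test helpers are written as plain nested loops sharing no
  code with the implementation.
- Tolerances: set operations and classifications are compared exactly;
  accumulated floating-point sums at 1e-9; Monte-Carlo quantities at three
  standard errors of their own sample.
- Determinism: every stochastic test fixes its seed; the simulator is
  bit-reproducible given its config.

## Limitations

- The L1 distance has no inferential wrapper by default: it is a
  descriptive statistic, and its scale depends on the shared gene set, so
  raw values are comparable only within one shared-gene matrix.
- The Welch engine is a pragmatic stand-in at simulation scale, not a
  replacement for a dispersion-modeling DE method on real counts.
- Gene matching is string-exact; cross-species or cross-annotation
  comparisons require the user to harmonize identifiers first.
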