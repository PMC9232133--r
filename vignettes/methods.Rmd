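---
title: "Separating structural zeros from dropouts in single-cell Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating structural zeros from dropouts in single-cell Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scHiCzero)
```

## The problem

Single-cell Hi-C contact matrices are extremely sparse: at typical per-cell
sequencing depths most locus pairs show zero contacts. Those zeros are of two
biologically distinct kinds. A *structural zero* (SZ) is a pair of loci that
truly never touch in that cell — a real feature of its 3D genome. A *dropout*
(DO, or sampling zero) is a pair that does interact, but whose contacts were
missed because sequencing was too shallow. Smoothing methods that treat all
zeros alike blur this distinction; downstream analyses such as cell-type
clustering and subtype discovery benefit from imputing dropouts while leaving
structural zeros at zero.

`scHiCzero` models the two kinds of zeros explicitly, classifies each
observed zero, and imputes the dropouts.

## The model

For cells $k = 1,\dots,K$ on a common set of $n$ bins, let $Y_{ijk}$ be the
observed count at pair $i < j$. Diagonal entries are stored but excluded from
the model and all metrics. With per-cell depth $T_k = \sum_{i<j} Y_{ijk}$,
normalization target $T$ (the maximum $T_k$ by default, or a fixed level such
as 300{,}000) and proportionate depth $\lambda^k = T_k / T$, the hierarchy is

$$
\begin{aligned}
Y_{ijk} \mid S_{ijk} &\sim
  \begin{cases} \delta_0 & S_{ijk} = 1 \\
  \mathrm{Poisson}(\lambda^k \mu_{ijk}) & S_{ijk} = 0 \end{cases} \\
S_{ijk} &\sim \mathrm{Bernoulli}(\pi_{ij}), \qquad
\pi_{ij} \sim \mathrm{Beta}(a,\, b_{ij}) \\
\mu_{ijk} &\sim \mathrm{Normal}^+(\mu_{ij}, \sigma^2_{ij}), \qquad
\mu_{ij} \sim \mathrm{Gamma}\!\big(\alpha,\ \alpha / m_{0,ij}\big) \\
a &\sim \mathrm{Gamma}(1, 1), \qquad \alpha \sim \mathrm{Gamma}(1, 1).
\end{aligned}
$$

Three sources of side information enter through the priors:

* **Zero pattern across cells.** $b_{ij} = a (1 - m_{ij}) / m_{ij}$, where
  $m_{ij}$ is the observed proportion of zeros at the pair across cells,
  clipped to $[\varepsilon, 1 - \varepsilon]$ with $\varepsilon = 1/(2K)$, so
  the Beta prior mean equals the zero proportion: positions that are mostly
  zero are a priori more likely structural.
* **The lattice neighborhood.** Windows
  $\Omega(i,j) = \{(i',j') : \max(|i-i'|, |j-j'|) \le 2\}$ (clipped at the
  borders, center included) supply both the dispersion
  $\sigma^2_{ij}$ — the squared sample standard deviation of the nonzero
  counts pooled over the window and over cells, floored at 1 — and the Gamma
  prior mean $m_{0,ij}$.
* **Bulk data, when available.** With a bulk matrix normalized to depth $T$,
  $m_{0,ij}$ is the bulk window mean re-weighted by the ratio of the local
  single-cell window mean to the grand single-cell mean: a locally rich
  single-cell neighborhood boosts the (more reliable) bulk level, a poor one
  shrinks it. Without bulk, $m_{0,ij}$ is the single-cell window mean alone.
  Either way it is floored at a small $\varepsilon_0 = 0.01$ so the Gamma
  prior stays proper.

The indicator is sampled per cell and pair ($S_{ijk}$), with the mixing
probability $\pi_{ij}$ shared across cells; this reconciles the pair-level
mixture with the fact that cell-specific structural zeros exist, and the
classification rule below operates on $\hat\pi_{ij}$ either way.

## Inference and calls

The posterior is explored by Metropolis-within-Gibbs:

* $S_{ijk}$ — exact Bernoulli full conditional
  $P(S{=}1 \mid \cdot) = \pi_{ij} \big/ \big(\pi_{ij} + (1-\pi_{ij})
  e^{-\lambda^k \mu_{ijk}}\big)$ for zero observations; a nonzero observation
  forces $S_{ijk} = 0$ at every iteration.
* $\pi_{ij}$ — conjugate
  $\mathrm{Beta}(a + \textstyle\sum_k S_{ijk},\; b_{ij} + K - \sum_k S_{ijk})$.
* $\mu_{ijk}$, $\mu_{ij}$, $a$, $\alpha$ — Gaussian random walks on the log
  scale (with Jacobian), proposal scales adapted in batches of 50 during
  burn-in toward 20–50% acceptance and frozen afterwards.

Defaults are 3000 iterations with 1500 burn-in, thin 1, one chain; all
configurable, and full traces of selected pairs can be kept for diagnostics
(`trace_pairs`). The sampler is written in C++ (via Rcpp) because the
parameter count is $O(n^2 K)$; it draws from R's RNG, so a fit is
bit-reproducible given a seed.

An observed zero of cell $k$ is called a structural zero when
$\hat\pi_{ij} > 0.5$ (posterior mean; the Bayes decision rule), strictly.
Imputed matrices set called structural zeros to exactly 0 and replace every
other entry — dropout zeros and observed nonzeros alike — with the posterior
mean of $\lambda^k \mu_{ijk}$, on the observed count scale. Sweeping the
threshold instead of fixing 0.5 yields the ROC analyses below.

## Reference smoothers

Three standard data-quality-improvement methods serve as comparisons, each
adapted to zero classification by calling an observed zero structural when
its smoothed value falls strictly below 0.5 (a rule borrowed from the
scRNA-seq imputation literature):

* **2DMF** — unweighted mean over the radius-2 Chebyshev window;
* **2DGK** — Gaussian-weighted window mean (sd 1 bin, renormalized at
  borders);
* **RW3S** — three steps of the row-normalized random walk, rescaled to the
  original row sums and symmetrized.

The window radius matches the model's neighborhood radius and the Gaussian
bandwidth is 1 bin; the comparison methods' original bandwidths are not
fixed by their descriptions, so these are package defaults, and the
threshold sweep (ROC) removes the dependence on any single cutoff.

## The synthetic-data generator

Ground-truth labels only exist in simulation, so the package ships the full
generative process as first-class code:

1. a 3D chain for the cell type — a seed-parameterized helix (default) or a
   smoothed random walk. These stand in for structures reconstructed from
   real cells; reported robustness of the original analyses to the
   underlying structure motivates the substitution, but conclusions at exact
   reproduction level should not be expected from a stand-in chain;
2. pairwise distances $d_{ij}$ and intensities
   $\log \lambda_{ij} = \alpha_0 - \log d_{ij} + 0.9 \log(x_{l,i} x_{l,j}) +
   0.9 \log(x_{g,i} x_{g,j}) + 0.9 \log(x_{m,i} x_{m,j})$, with per-locus
   covariates (fragment length, GC, mappability surrogates) drawn
   $\mathrm{Uniform}(0.2, 1)$ — a positive range chosen so the log terms are
   finite; the sources describing this design state uniform covariates
   without ranges;
3. the matrix is rescaled so $\sum_{i<j} \lambda_{ij}$ equals the target
   depth (7000 / 4000 / 2000 are the depths studied here). The scale
   coefficients $\alpha_0 \in \{5.7, 6.3, 6.8\}$ label the three cell types;
   because depth is pinned separately, type identity is carried by the
   structure (distinct chain seeds per type), and the rescale is the
   package's way of honoring both the $\alpha_0$ values and the stated
   depths, which their source lists as independent knobs;
4. structural zeros: among the $\lfloor \gamma P \rfloor$ lowest-intensity
   pairs ($P = n(n-1)/2$; $\gamma = 0.10$ by default), a random half become
   candidates; $\lfloor \eta \cdot \rfloor$ of those ($\eta = 0.80$) are
   common structural zeros shared by all cells of the type; the rest are
   per-cell candidates zeroed independently per cell with probability 1/2.
   Floor rounding applies at every stage, so with $n = 61$:
   $1830 \to 183 \to 91 \to 72$ common SZs and 19 per-cell candidates;
5. counts are independent Poisson draws from the per-cell $\lambda^*$;
   every observed zero is thereby exactly one of SZ ($\lambda^* = 0$) or DO
   ($\lambda^* > 0$).

A pooled bulk companion (`bulk = "pooled"`) sums 180 simulated cells from
each of the three types, mirroring how a bulk experiment aggregates a
heterogeneous population.

What the generator does **not** emulate: genomic-distance-dependent biases
beyond the power law, ICE-type normalization artifacts, restriction-site
structure, or the heavy cell-to-cell depth variation of real protocols
(every simulated cell shares one expected depth). Passing the synthetic
benchmarks therefore demonstrates correctness of the machinery and the
qualitative ordering of methods, not real-data performance.

## Evaluation

Against simulation truth the package computes, per method: PTSZ (sensitivity
of SZ detection), PTDO (specificity; dropouts left uncalled), AEOA / AEOZ
(mean absolute imputation error over all observed entries / observed zeros),
CIEA / CIEZ (imputed-expected Pearson correlation on the same masks), SEVI /
SOVI scatter data, and ROC / AUC over the call-threshold sweep (score:
$\hat\pi_{ij}$ for the model, negated smoothed value for the comparison
methods). Error and correlation metrics are computed per cell and averaged
unweighted, with the standard error across cells reported, matching the
mean-(SE) presentation convention; an alternative would pool entries across
cells, which weights deep cells more. Because PTSZ and PTDO trade off along
the threshold, methods are also compared at a calibrated operating point:
the smallest sensitivity at or above PTSZ = 0.95, reporting PTDO there.

## Downstream analyses

`cluster_features()` rescales cells to a common total, applies `log1p`, and
vectorizes upper triangles; `embed_and_kmeans()` optionally embeds with
t-SNE (perplexity $\min(30, (K-1)/3)$, seed-controlled) and clusters with
K-means (25 restarts), reporting the within-cluster sum of squares for
$k = 1..k_{\max}$ and, when reference labels exist, the adjusted Rand index.
K-means runs on the 2D embedding by default for parity with how such
analyses are usually displayed; `use_tsne = FALSE` clusters the raw feature
vectors, which is more robust for very small cell numbers. Subtype
inspection uses `top_variable_positions()` (default 500 highest-variance
positions), two-way complete-linkage dendrograms (`hclust_dendrogram()`,
newick-exportable) and per-cluster `mega_matrices()` normalized to a common
total and min-max scaled to $[0,1]$.

## Numerical choices and degenerate inputs

* Zero-proportion clip $\varepsilon = 1/(2K)$ keeps both Beta shapes finite
  at all-zero and no-zero pairs.
* $\sigma^2_{ij}$ falls back to 1 when fewer than two nonzero counts exist
  in the pooled window or their sd is 0. The source phrase for this
  quantity names a standard deviation where a variance is expected; the
  package squares the pooled sd. Results are insensitive at the depths
  studied because the floor dominates sparse regions either way.
* The Gamma prior mean is floored at 0.01 so empty neighborhoods keep a
  proper prior.
* $\pi$ draws are clipped to $[10^{-12}, 1 - 10^{-12}]$ before the
  hyperparameter likelihood, guarding the $\log\pi$ terms.
* Ties in the ROC: equal scores collapse to one operating point, making the
  trapezoid AUC equal to the Mann–Whitney probability with ties counted
  half.
* Zero rows in the random-walk smoother become uniform transition rows,
  keeping the chain stochastic on very sparse cells.
* All-zero cells are rejected at group construction (a depth-0 group has no
  usable normalization).

## Problem sizes used in the shipped checks

The package's own validation runs at what one desk CPU handles comfortably:
61-bin matrices, 10 cells per group at depths 4000 and 7000 with a pooled
540-cell bulk, 3000 MCMC iterations, and 5 replicates for the clustering
comparison — the same shapes the simulation design above describes, with
replicate counts kept small. The MCMC correctness checks instead run on
3-bin toy groups, where the collapsed posterior can be integrated
numerically and compared to the sampler exactly.

## Limitations

* The hyperprior constants and proposal-tuning schedule are package
  defaults (weakly-informative Gamma(1,1), adaptive log-scale walks);
  inference at very low $K$ is prior-dominated.
* The structural-zero probability is shared across cells at a pair;
  genuinely cell-private structural zeros at otherwise active pairs are
  detected only through their cell's own zero.
* No multi-chromosome joint modeling, no matrix balancing, no read-level
  simulation; real-data ingestion is limited to the two text formats.
* MCMC convergence is not assessed automatically; inspect `mcmc_traces()`
  for selected pairs when in doubt.
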