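---
title: "Network-image classification of tumor transcriptomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-image classification of tumor transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

netimg turns a cohort of bulk expression profiles into per-sample *network
images* — a fixed 2D layout of the protein–protein interaction (PPI)
network colored by each sample's expression — and classifies them with a
small convolutional network. This vignette explains the statistical model
behind each stage, the tunable parameters and their defaults, what the
synthetic data emulate (and do not), and the numerical conventions the
implementation commits to.

## The moderated t-statistic

Differential expression between a cancer's tumors and its normals is
assessed on log2(x+1)-transformed values. For gene $g$ with group sizes
$n_A, n_B$, the pooled residual variance $s_g^2$ has $d = n_A + n_B - 2$
degrees of freedom. Under the empirical-Bayes model the true variances are
drawn from a scaled inverse-chi-square prior with parameters $(d_0,
s_0^2)$, giving the posterior (shrunken) variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

and the moderated statistic $t_g = \Delta_g / (\tilde s_g
\sqrt{1/n_A + 1/n_B})$ is referred to a t distribution on $d + d_0$
degrees of freedom. The hyperparameters are fitted by method of moments on
$z_g = \log s_g^2$, using the digamma/trigamma moments of log-chi-square
variables; when the observed dispersion of $z$ does not exceed chi-square
sampling noise the prior degrees of freedom are infinite and every gene
shares the common variance $\overline{s^2}$. `prior_df` can be forced: 0
recovers the ordinary pooled t exactly, `Inf` uses $s_0^2$ everywhere.
(The test suite cross-checks the fit against limma's on toy matrices; the
one deliberate difference is that with an infinite prior we keep $d + d_0
= \infty$ total degrees of freedom where limma caps at the pooled residual
df, which shifts p-values by a few thousandths in that regime.)

A gene enters the DEG union if, in **at least one** cancer type, $|\log_2
FC| \ge 1$ (fold change $\ge 2$, boundary included) **and** the
Benjamini–Hochberg adjusted p-value is $< 0.01$ (boundary excluded). Fold
change is defined on the log2(x+1) scale; the pseudocount makes zeros
well-behaved for RNA-Seq-style data. Both thresholds are arguments of
`deg_union()`.

## Spectral embedding of the DEG subnetwork

The DEG union induces a subgraph of the PPI network; `max_subnetwork()`
keeps its largest connected component (ties broken toward the component
containing the lexicographically smallest symbol, so runs are
reproducible). On that component the combinatorial Laplacian $L = D - A$
is symmetric positive semidefinite with row sums zero; because the graph
is connected, 0 is a simple eigenvalue and the next two eigenpairs are
well-defined. Their eigenvectors supply x (Fiedler vector) and y
coordinates — the classical spectral layout that keeps densely
interconnected genes near each other.

Numerical conventions, all chosen for determinism rather than inferred
from any reference:

* **Zero tolerance.** "Non-zero eigenvalue" means $\lambda > 10^{-8}
  \cdot \max_i \deg(i)$ — a relative cutoff, since Laplacian spectra scale
  with degree. Two numerically-zero eigenvalues mean the input was
  disconnected and the error message points at `max_subnetwork()`.
* **Sign fixing.** An eigenvector's sign is arbitrary; we flip so the
  largest-magnitude entry is positive, ties resolved by the earliest node
  in sorted order. Coordinates are therefore invariant to the order edges
  were read in.
* **Degenerate eigenvalues.** For graphs with symmetry (e.g. the 4-cycle,
  spectrum $\{0, 2, 2, 4\}$) the selected eigen*values* are well-defined
  but the eigen*vectors* are not unique; only non-degenerate graphs are
  used where tests assert coordinates.
* **Binning.** Each axis is affinely min–max scaled to $[0,1]$ and cut
  into $G$ equal bins, the maximum landing in the last bin
  (`min(floor(uG), G-1)`); a constant axis maps everything to bin 0. Row
  = y bin, column = x bin, 0-based. Quantile binning was considered and
  rejected: it equalizes cell occupancy but destroys the geometric
  meaning of distance in the spectral plane.

The embedding is computed **once** from the cohort-wide DEG subnetwork and
reused for every sample, so images differ only in intensity, never in
layout. The eigendecomposition is dense (LAPACK via `eigen()`), which is
exact and entirely adequate up to a few thousand nodes; the tests
cross-check coordinates against an independent SVD route.

## Image rendering

Per sample, each occupied cell holds the arithmetic mean of log2(x+1)
expression over the genes binned there ("overlapping genes are
averaged"); unoccupied cells are exactly 0. Two choices deserve comment:

* **Intensity scale.** Raw RSEM-scale magnitudes (up to 10^5) would
  saturate any fixed-scale CNN input, so images are log-transformed and
  max-normalized per image to $[0,1]$ by default. Both knobs are exposed
  (`normalize`, `log_transform`) for users who want raw intensities.
* **Missing genes.** An embedded gene absent from a sample's profile
  contributes nothing to its cell's mean (absence, not zero), so a
  partially measured cell is not diluted toward 0.

## The classifier

The architecture is fixed by `cnn_spec()`: three valid (unpadded)
convolution stages of 64 kernels (5×5, then 3×3, 3×3), each followed by
ReLU and 2×2 stride-2 max pooling, then dense ReLU layers of 1000, 800
and 60 neurons and a softmax output — one class per cancer type plus
normal. For a 100×100 input the spatial side runs 96→48, 46→23, 21→11:
**ceil-mode** pooling (odd sides round up) is the only convention that
produces the 11×11×64 = 7744 flattened feature vector this chain implies;
floor-mode ends at 10 and is rejected by the shape-contract test. Shapes
are validated at construction and errors name the failing stage.

Training is plain Adam (defaults: learning rate 10^-3, batch 32, 100
epochs) on categorical cross-entropy, with an internal 75/25
class-stratified train/test split for the accuracy curves. No dropout or
weight decay is applied by default. Everything stochastic —
initialization (He-scaled), the stratified split, batch shuffling — flows
from one integer seed through R's RNG, so runs are bit-reproducible; the
engine itself (im2col convolutions, pooling with first-scanned-wins tie
breaks, backprop) is hand-written C++ via RcppArmadillo whose analytic
gradients are checked against finite differences in the test suite.

## Evaluation design

`make_split()` generalizes the repeated-validation design: per cancer,
half the normals (rounded up — the per-cancer normal count rule is not
derivable from the published totals, so "half" is the package's choice,
configurable via `normal_fraction`) train together with exactly
`tumor_per_normal` (default 3) times as many randomly drawn tumors;
everything else validates. Accuracy is (TP+TN)/(TP+TN+FP+FN) on the
binary normal-vs-tumor collapse of the multi-class confusion matrix; a
tumor predicted as the *wrong cancer* still counts as a tumor there, but
counts as a misjudgment in the per-sample error frequency. Mean-r class
similarity excludes the query sample from its own class.

The survival table counts, per cancer, unique validation tumors that were
ever misclassified, those misjudged into normal, and — among
dead patients — those who nonetheless survived ≥ 730 days, in the
misjudged-into-normal versus correctly identified groups. The summary
statistic $(a/m)/(b/c)$ is a **risk ratio** (ratio of proportions); the
quantity is sometimes labeled an odds ratio in this literature, but only
the proportion ratio reproduces the published values, so that is what
`survival_ratio()` computes, under the honest name `ratio`. Counting is
by unique sample across experiments by default (`per_experiment = TRUE`
switches to event counting); the day convention for "≥ 2 years" is fixed
at 730 days.

## What the synthetic data emulate

`make_graph()`/`make_cohort()` generate the statistical structure the
pipeline assumes: a connected PPI-like graph (Erdős–Rényi, scale-free, or
a planted partition whose dense communities coincide with the class
signatures — mirroring the premise that functionally related genes
cluster in the network); lognormal baseline expression (per-gene log2
mean ~ N(6, 2), right-skewed like RSEM quantifications); class signatures
shifted by `effect_log2fc` in that class's tumors only; Gaussian log-scale
noise; uniform survival times with a configurable death rate. The
defaults (200 genes, 3 classes, 15 tumors + 5 normals per class,
signatures of 20 genes, effect 4, noise 0.5) are deliberately
well-separated: they are the regime in which the pipeline *should* reach
high accuracy. Two deliberate fixtures depart from it: a null
configuration (`effect_log2fc = 0`) for chance-level calibration, and a
confusability fixture in which two classes share 80% of their signature
genes under higher noise (sd 1.2), emulating histologically related tumor
types; there the confusion matrix must show the shared pair confused with
each other and not with unrelated classes — a directional assertion, not
a fixed count.

What the synthetic data do **not** model: batch effects, library-size
variation, isoform structure, gene–gene correlation beyond the planted
block structure, and any coupling between expression and survival.
Passing the synthetic end-to-end tests therefore demonstrates that the
machinery is correct and the design separable-in-principle, not that any
particular real cohort will reach a given accuracy.

## Problem sizes

The shipped tests and examples run the full chain at desk scale, chosen
so the whole suite completes in about a minute: 200-gene graphs, 60–75
sample cohorts, 32×32 grids, 10–20 epochs, and 2–4 repeated experiments
(the repeated-split design generalizes to any count via `run_repeats()`).
The architecture contract is always verified at the full 100×100 input
size, which is also what `scripts/acceptance.R` instantiates.

## Known limitations

* Dense eigendecomposition limits embeddings to networks of a few
  thousand nodes; a sparse (Lanczos) path would be needed beyond that.
* The CNN engine is single-threaded CPU code built for small images and
  cohorts; it is not a deep-learning framework.
* Survival analysis is purely descriptive (contingency ratios); no
  censoring model or significance test is attached, by design.
* The DEG model assumes two-group comparisons per cancer; paired designs
  and covariates are out of scope.
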