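---
title: "Metabolic lesion mapping and glioma subtype prediction with mrsport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic lesion mapping and glioma subtype prediction with mrsport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proton MR spectroscopy of the brain acquired as 2D chemical-shift imaging
(CSI) yields one spectrum per spatial voxel, from which the amplitudes of
the major metabolites (NAA, creatine, choline compounds, lactate,
myo-inositol, lipid and macromolecule bands, and others) can be fitted.
These metabolite profiles carry diagnostic information: healthy
("normal-appearing") matter is dominated by NAA and creatine; necrotic and
hypoxic tumor tissue by lactate, lipids and macromolecules; edema by
myo-inositol; and the glioma molecular subtypes differ systematically, with
IDH-wildtype tumors enriched in lactate/lipids/macromolecules and
IDH-mutant tumors (with or without 1p/19q codeletion) in
glycerophosphocholine.

`mrsport` implements a complete voxel-wise analysis of such data:

1. **Quantitation stand-in** — non-negative linear least-squares fit of a
   peak-template basis to each (baseline-corrected) spectrum, with a
   residual-based quality filter.
2. **Denoising** — a mirrored sigmoid autoencoder compresses the
   min-max-normalized voxels-by-metabolites matrix through a narrow
   bottleneck and reconstructs it; the reconstruction is the denoised
   profile.
3. **Unsupervised characterization** — PCA with parallel-analysis selection
   of non-trivial components, shared-nearest-neighbor (SNN) clustering,
   UMAP embedding, and per-cluster marker-metabolite enrichment.
4. **Supervised prediction** — a two-layer multiclass Fisher LDA: layer 1
   labels each voxel's lesion class and produces a tumor mask; layer 2
   scores only masked voxels for the molecular subtype
   (wt / IDH / LOH); the patient-level classifier score is the mean
   calibrated subtype score over the mask.

Because clinical CSI cohorts are not freely redistributable, the package
ships a first-class synthetic generator (`generate_phantom()`,
`generate_cohort()`) with known ground truth against which every stage is
tested.

## The denoising autoencoder

The normalized input $x \in [0,1]^{34}$ passes through encoder layers
$z_\varphi = \sigma(W_\varphi A_{\varphi-1} + b_\varphi)$ with widths
$32, 16, 8$, a bottleneck of 6 sigmoid units, and a mirrored decoder
$A'_{\varphi-1} = \sigma'(W'_\varphi z_\varphi + b'_\varphi)$ back to 34
outputs, where $\sigma(x) = 1/(1+e^{-x})$. Training minimizes the mean
squared reconstruction error
$L(x, x') = \lVert x - \sigma'(W'\,\sigma(Wx+b)+b') \rVert^2$
with Adam (learning rate $10^{-3}$, minibatch 32), a 2/3–1/3
train/held-out row split, 500 epochs, dropout 0.1 on the hidden-layer
activations during training only, and batch normalization on the three
encoder hidden layers (after the affine map, before the sigmoid). Encoder
and decoder parameters are unrelated; all training is bit-reproducible
given a seed on a single thread.

Implementation notes:

* The loss is the *mean* over matrix entries rather than the raw squared
  norm so that thresholds are independent of matrix size.
* Batch-norm inference uses running statistics (momentum 0.1); dropout is
  inverted (activations rescaled by $1/(1-p)$ during training) so no
  rescaling is needed at inference.
* Weights start from a symmetric scaled-uniform (Glorot) initializer,
  biases at zero.
* Training epochs matter: the subtype contrasts survive denoising only
  once the reconstruction error has plateaued. Underspecified training
  (an order of magnitude fewer epochs) visibly collapses between-class
  differences; the package default is 500 epochs, and the smaller values
  used in some unit tests exercise mechanics, not accuracy.

**Bottleneck selection.** `bottleneck_search()` retrains the model for
bottleneck widths 4–10 and scores each by the share of variance carried by
the first two principal components of the denoised matrix — the same
statistic used to verify that denoising concentrates variance. Widths that
reach or exceed the last encoder width (8) drop trailing encoder layers so
the funnel stays strictly decreasing. Ties resolve toward the smaller
(more compressive) width.

## Normalization and quality control

Metabolite columns are min-max normalized, $\mathrm{norm}(x) =
(x - \min x)/(\max x - \min x)$, the natural input scaling for a sigmoid
output layer. Constant columns map to all-zeros (an absent metabolite sits
at the low end of the sigmoid range) and are flagged. Normalization
statistics are learned on training data only and reapplied (with clipping
to $[0,1]$) to held-out data, preventing leakage.

Voxel quality control follows the fitted-residual idea: a voxel passes if
its basis-fit residual RMS is at most `threshold` (default 3) times the
study median. A relative rule is the only automatable form of a
residual-based exclusion and is invariant to global intensity rescaling;
failing voxels are relabeled EXCLUDED.

Baseline correction is an iteratively reweighted asymmetric polynomial
fit: 10 iterations, weight 1 below the current fit and 0.01 above, so
positive-going peaks are progressively ignored while the smooth baseline
is tracked. The polynomial order (default 2) matches the generator's
default baseline order. One inherent ambiguity is worth noting: the
long tails of overlapping Lorentzian peaks form a smooth pedestal that no
baseline algorithm can distinguish from a genuine baseline, so
sub-percent baseline recovery is only achievable for fast-decaying
(Gaussian-like) lineshapes; with Lorentzian crowding, a percent-level
bias between peaks is irreducible.

## Component selection, clustering, embedding

PCA reports the first 30 components of the column-centered matrix with a
deterministic sign convention (largest-magnitude loading positive).
Non-trivial components are chosen by parallel analysis: each column of the
matrix is permuted independently (marginals kept, correlation destroyed) 20
times, and a component is retained while its eigenvalue exceeds the 95th
percentile of the corresponding randomized eigenvalues. The 95th
percentile — rather than the ensemble mean — is the standard
parallel-analysis convention; the mean would retain a first "component"
from pure noise about half the time, since for signal-free data the
observed eigenvalues share the randomized ensemble's distribution. A fixed
component count can be forced via `pipeline_config(n_components = ...)`
when a deterministic dimensionality is preferred over the adaptive rule.

SNN clustering builds neighbor sets of size `k = 20` (each point plus its
19 nearest Euclidean neighbors), connects every pair of points sharing at
least one neighbor with an edge weighted by the Jaccard overlap of their
neighbor sets, prunes weights below 1/15, and partitions the graph with
Louvain community detection at resolution 0.2. The low resolution is a
deliberate choice: a k-nearest-neighbor graph over any geometric point
cloud contains fine sub-communities (the resolution limit of modularity
works in reverse on sparse geometric graphs), and at resolution 1 Louvain
fragments even perfectly separated clusters. Resolution 0.2 recovers
macroscopic, tissue-scale structure; disconnected groups can never merge
regardless of resolution, so well-separated populations are always kept
apart. Exact duplicate points (e.g. a degenerate all-identical input) are
collapsed before the kNN search and re-expanded afterwards.

The 2D embedding is UMAP (via `uwot`), run single-threaded so that a seed
fully determines the layout. Marker metabolites per cluster are found by
two-sided Wilcoxon rank-sum tests of in-cluster versus all other voxels
with Benjamini–Hochberg adjustment across all (cluster, metabolite) pairs;
a marker requires adjusted $p < 0.05$ and a positive log2 ratio of means.

## The two-layer discriminant model

The multiclass Fisher LDA maximizes
$S = \frac{w^\top \Sigma_b w}{w^\top \Sigma w}$, with the between-class
scatter the unweighted average
$\Sigma_b = \frac{1}{C}\sum_{i=1}^{C} (\mu_i - \mu)(\mu_i - \mu)^\top$
over class means and the within-class scatter the pooled covariance. The
discriminant directions are the leading $C-1$ eigenvectors of
$(\Sigma + \lambda' I)^{-1} \Sigma_b$ with a small relative ridge
$\lambda' = 10^{-4}\,\mathrm{tr}(\Sigma)/p$, which keeps the solve well
posed when a small synthetic cohort leaves $\Sigma$ rank deficient.
Prediction assumes homoscedastic Gaussian classes in the projected space
(shared pooled covariance, equal priors); a softmax over the per-class
discriminants yields posterior-like probabilities. Ties in any argmax
resolve to the earlier class in the class-set order.

Scores are calibrated against a reference distribution (the training tumor
voxels): per class, a Gaussian is fitted and scores are z-scored with the
fitted mean and SD. Calibration is monotone per class — it never reorders
voxels within a class — and its parameters are stored for reuse on new
studies. The patient-level classifier score for class $n$ is
$sc_n = \mathrm{mean}(S_c)$ over the predicted tumor voxels, and the
predicted subtype is its argmax.

The two layers: layer 1 is an LDA over region classes (NAM, LESION,
TUMOR, METASTASIS; segmentation labels collapse onto these, with
VENTRICLE treated as non-lesional and FLAIR as non-tumor pathology), and
the tumor mask is all voxels with layer-1 tumor probability above 0.5.
Layer 2, an LDA over wt/IDH/LOH, scores masked voxels only. A patient
with an empty mask gets an explicit "no tumor detected" outcome, never a
numeric score. The single-layer variant (subtype LDA applied to every
voxel) is retained behind the `single_layer` flag of `run_predict()`
because it quantifies the motivation for masking: on healthy tissue it
assigns confident subtype scores everywhere, while the two-layer model
assigns almost none.

Features fed to both layers are the autoencoder-denoised normalized
metabolite vectors, not the latent code: the reconstruction lives in the
interpretable metabolite space, is approximately Gaussian per tissue class
(supporting the LDA model), and makes the learned discriminant loadings
readable as metabolite contrasts.

## The synthetic generator

`generate_phantom()` emulates one CSI session on a 16×16 grid (256
voxels, the nominal size of one study): an NAM background, a ventricle
rectangle, and a lesion built from a FLAIR annulus, a tumor disc, a
contrast-enhancing rim, and — in IDH-wildtype phantoms, where central
necrosis is typical — a necrotic core. Each tissue has a 34-metabolite
mean profile encoding the canonical contrasts described above; the
wt/IDH/LOH subtype modulates the tumor and contrast profiles
(lactate/lipids/macromolecules up for wt; glycerophosphocholine up for
IDH and LOH, with additional glutamine/alanine/glycine elevation marking
the codeleted subtype). Voxel-to-voxel variation is log-normal around the
tissue mean with a mean-preserving parameterization (default coefficient
of variation 0.2) — metabolite amplitudes are positive and right-skewed,
which a Gaussian would violate. Measured tables add multiplicative
log-normal jitter (SD 0.05 on the log scale at the default `noise_sd`);
optional raw spectra are Lorentzian peak sums plus a random polynomial
baseline and white noise. Cohorts jitter tumor center and radius per
patient, deterministically from the cohort seed.

What the generator does **not** emulate: J-coupling multiplets, T1/T2
relaxation and echo-time dependence, field-inhomogeneity and shim
artifacts, partial-volume mixing at tissue boundaries, spatial
correlation of noise, and between-patient covariance structure beyond
geometry jitter. Passing tests therefore demonstrate that the algorithms
are implemented correctly and behave as designed under controlled
conditions — not that the pipeline reaches any particular accuracy on
clinical data, where effect sizes are smaller and artifacts abound.

The default effect sizes were chosen once so that tumor subtypes are
separable by a linear discriminant on the true tumor voxels (a property
asserted in the test suite); they represent a clean, well-shimmed study
rather than a difficult clinical case.

## Problem sizes and numerical choices

The validation suite and the acceptance script exercise, among others: a
30-patient cohort (10 per subtype, 256 voxels each, patient-level 2/3–1/3
split) for end-to-end subtype recovery; 20-seed trials of the denoising
benchmark on 200×34 planted low-rank matrices (200 training epochs there,
where the signal is far simpler than a full phantom); 100-trial
parallel-analysis experiments on 100×20 matrices with three
equal-strength orthonormal spikes at 20× the unit noise (equal-strength
spikes, because random Gaussian spike directions produce wildly unequal
eigenvalues whose weakest member is not detectably different from
permuted marginal variance); 300-point three-blob SNN recovery; and exact
small-sample enumeration oracles for the rank-sum test and the
Mann–Whitney AUC. Determinism is verified byte-for-byte on every written
artifact.

Known limitations: the quantitation stand-in is a frequency-domain linear
fit (no lineshape, phase or frequency-shift estimation, no water-reference
scaling); the quality filter is a stated automatable surrogate for
supervised residual review; Louvain's resolution is a tunable convention,
and the emergent cluster count is data-dependent rather than fixed; and
patient-level accuracy estimates from 10 held-out synthetic patients are
coarse-grained by construction.
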