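---
title: "Methods: histology-fused super-resolution and spatial ligand-receptor discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histology-fused super-resolution and spatial ligand-receptor discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finespot)
```

# The problem

Spot-based spatial transcriptomics (Visium and relatives) measures one
transcriptome per ~55 µm spot, while ligand-receptor (LR) signaling acts at
cellular range. `finespot` raises the effective resolution by exploiting the
co-registered histology image: a spot's 112 × 112-pixel patch is divided
into an 8 × 8 grid of 14-pixel tiles (about one cell each), a pluggable
extractor turns each tile into an embedding, and a bimodal model learns to
translate tile embeddings into expression. The super-resolved expression
then feeds bivariate spatial statistics that rank LR pairs by spatial
co-expression, decompose each pair into per-location sender/receiver
contributions, cluster the local interaction maps into communication
patterns, and interpret the patterns through pathway enrichment and
L→R→TF→TG network extraction.

# The model

## Geometry

All pixel bookkeeping uses 0-based coordinates, `(x = column, y = row)`,
and half-open windows. A spot at $(x, y)$ owns the patch
$[y - P/2, y + P/2) \times [x - P/2, x + P/2)$ with $P = 112$ by default;
the patch splits into a $g \times g$ grid of $t$-pixel tiles
($g = 8$, $t = 14$). Spots whose patch would cross the image border are
excluded with a warning rather than padded — padding would fabricate tissue
for the feature extractor. Gap coverage augments the $n$ probed spots with
*between-spot* centers: the Voronoi face centers of the lattice, i.e.
neighbor midpoints on a hexagonal lattice and edge midpoints plus cell
corners on a square lattice. On a large interior lattice this yields
$m \approx 4n$ centers in total. Nucleus-centered tiles use the same
window convention around externally supplied nuclei coordinates, with each
nucleus assigned to its nearest spot (ties to the lower index).

## Feature extraction

The extractor is an interface: a profile declares its embedding dimension
and tile size (`virchow2`: 1280-d at 14 px; `vit256`: 384-d at 16 px) and
heavyweight backends plug in as functions. The built-in stub is a
deterministic featurizer — per-channel means and variances, low-order
moments of the mean-centered grayscale, and a seeded random projection of
the mean-centered tile — chosen so that (i) identical pixels give identical
rows, (ii) the map is Lipschitz in pixel values, and (iii) distinct
cell-type textures remain linearly separable, which is what the downstream
model needs from any real extractor. Fine-tuning the extractor is
deliberately out of scope.

## The contrastive autoencoder

Four maps are trained jointly: an image encoder $g_1 : \mathbb{R}^C \to
\mathbb{R}^h$ and decoder $f_1$, and an expression encoder $g_2 :
\mathbb{R}^{\hat p} \to \mathbb{R}^h$ and decoder $f_2$ whose softplus
output keeps predictions non-negative. Each is a two-layer perceptron with
one tanh hidden layer of width $2h$ ($h = 128$ by default; the smallest
family that passes the rank-recovery checks below). The objective combines

* two reconstruction losses, each the mean row cosine distance plus mean
  column cosine distance between input and reconstruction (a row or column
  with zero norm contributes 1 — its cosine is defined as 0);
* an InfoNCE alignment loss on L2-normalized projections: the image side of
  spot $k$ is the normalized sum of its tile latents, the expression side
  its normalized expression latent; temperature $\tau = 0.03$. As
  implemented, the positive pair is excluded from the denominator, so the
  loss can be negative; a flag restores the conventional denominator;
* a cross-modal loss: the cosine loss between measured spot expression and
  the sum over the spot's tiles of $f_2(g_1(\cdot))$ — the quantity that
  matters at inference time.

The weights $w_1 = w_2 = w_3 = w_4 = 1$ by default, batch size $K = 64$
(Visium; 640 for VisiumHD square bins), and each optimization step draws
$K/2$ spots as positives against all cross pairs. Training uses Adam
(learning rate $10^{-3}$, 500 epochs by default), a seeded 80/20 spot
split, and returns the parameters with the best held-out cross-modal loss.
Backpropagation is hand-derived; the test suite compares every analytic
gradient against central differences at $10^{-4}$ relative tolerance.

The prose convention for the expression autoencoder is ambiguous between a
cosine and an MSE reconstruction; the cosine form is the default here and
MSE sits behind `expr_loss = "mse"`.

## Imputation

A tile's final expression blends the image arm with neighborhood evidence:
$$ Y^{ij}_k = \alpha\, f_2(g_1(f_0(X^{ij}_k))) + (1 - \alpha)
   \sum_{s \in \mathcal{N}} w_s Y_s, $$
where $\mathcal{N}$ holds the $\kappa$ nearest measured spots
($\kappa = 6$ hex, 4 square; ties at the boundary broken toward the lower
index), $w_s \propto d_s^{-1}$ normalized to 1 (a zero distance collapses
all weight onto that spot), and $\alpha = 0.5$ by default (exposed for
weaker smoothing, e.g. 0.02). The output is therefore a per-gene convex
combination of the prediction and the neighbor values, and is invariant to
translating all coordinates. Measured expression must be on the same scale
as the model output; mixing scales is an error by contract.

## Bivariate Moran statistics

For each LR pair with ligand field $L$ and receptor field $R$ on $M$
locations (multi-subunit complexes averaged over subunits; minimum by
flag):
$$ R^{Global} = \frac{\sum_{k,s} w_{ks} (L_k - \bar L)(R_s - \bar R)}
   {\lVert L - \bar L \rVert \, \lVert R - \bar R \rVert}, \qquad
   R^{Local}_k = \frac{(L_k - \bar L) \sum_s w_{ks} (R_s - \bar R)
   + (R_k - \bar R) \sum_s w_{ks} (L_s - \bar L)}{\sigma_L\,\sigma_R}, $$
with population standard deviations, which makes
$\sum_k R^{Local}_k = 2 M R^{Global}$ an exact identity (verified
numerically to 1e-8). The weights are a Gaussian kernel
$\exp(-d^2 / 2\ell^2)$ truncated to each location's `cutoff` nearest
neighbors (default 6), symmetrized by the elementwise maximum, zero
diagonal; $\ell$ defaults to 1.2 × the median nearest-neighbor distance.

Significance uses the *exact* first two moments of both statistics under
independent random relabeling of the two fields. For centered unit-norm
fields the permutation covariance of entries is
$1/M$ (diagonal) and $-1/(M(M-1))$ (off-diagonal), giving
$$ \mathrm{Var}_0(R^{Global}) = \frac{S_{w^2}}{(M-1)^2}
   - \frac{S_r + S_c}{M (M-1)^2} + \frac{S_0^2}{M^2 (M-1)^2}, $$
with $S_{w^2} = \sum w_{ks}^2$, $S_r, S_c$ the summed squared row/column
sums and $S_0$ the total weight; the local analogue is per-location. Only
the final upper-tail normal approximation is approximate; a Monte-Carlo
permutation fallback (`n_perm`) is built in, and the suite checks
analytic-vs-permutation agreement within 0.02 for ≥ 95% of random pairs.
Pair selection applies Benjamini–Hochberg across all tested pairs at FDR
0.05; a location is *interacting* when its local one-sided p is below
0.05, and pairs interacting in fewer than 3 locations are flagged out of
the pattern analysis (default `min_interacting = 3`, configurable, since
conventions between "more than two" and "more than three" differ across
descriptions of this filter).

## Pattern clustering

Eligible pairs enter as rows of either the binary local-significance
matrix or the continuous `1 - p_local` matrix. Patterns are a mixture of
Gaussian-process surfaces: pattern $c$ has mean $\mu_c \sim
\mathcal{GP}(0, K)$ with squared-exponential kernel plus a noise floor
(default $10^{-5}$), and pair rows deviate from their pattern mean with
isotropic variance $s^2$. MAP-EM alternates responsibilities with
closed-form updates of $\mu_c$ (a GP posterior), $s^2$ and mixing weights;
the penalized objective is non-decreasing by construction and the suite
asserts it on every fixture. Initialization is seeded k-means on the input
rows; argmax ties break toward the lower pattern index; the number of
patterns is user-set (2–3 in typical analyses).

Two consequences of this model are worth knowing. First, the fitted
pattern mean is the GP *posterior* mean — a smoothed, slightly shrunk
version of the raw per-location average (they coincide only in the
small-noise limit). Second, responsibilities are effectively hard: the
log-density gaps between patterns grow with $M$, so the softmax saturates
even on unstructured input. Responsibility spread is therefore not a
usable null diagnostic; label stability across seeds is.

The sparse variant partitions locations into spatially contiguous blocks
of about `group_size` (default 16) by seeded k-means on coordinates and
drops all cross-block covariance, reducing the per-iteration solve cost
from $O(M^3)$ to $O(M \cdot \text{group\_size}^2)$ (asserted by
operation-count accounting, not wall clock). With a single block it
reproduces the full model exactly; on a separable two-blob fixture at
$M = 400$ the two variants agree in labels (ARI ≥ 0.9 asserted, observed
1.0). A per-block low-rank cap on the kernel (default 30) and the noise
floor are exposed as passthrough parameters matching published usage; the
cap never binds at the default block size.

## Downstream interpretation

Pathway enrichment is a one-sided Fisher exact test (upper-tail
hypergeometric) per pathway over a 2 × 2 table; the universe defaults to
all *tested* pairs so the test conditions on the gene panel (the full
database is available by flag), and no multiplicity correction is applied
by default (BH by flag). Network extraction follows the chain: pattern
pairs → unique ligands/receptors → R→TF edges (receptors matched by
complex name or subunit) → TF→TG edges; a receptor with no TF entry keeps
its L→R edge. Cell-type co-localization reuses the global bivariate Moran
statistic on abundance fields, and per-pattern cell abundance weights
per-location type abundances by the pattern's clipped, normalized mean
surface.

## Evaluation metrics

Fine-resolution predictions are summed back to their parent spots, then
compared per gene by Pearson correlation and by SSIM. For SSIM each gene's
field is rasterized onto a regular grid inferred from the coordinate pitch
(colliding locations averaged, empty cells zero), min-max scaled to [0, 1],
and compared with data range 1, a uniform 7 × 7 window (shrunk to the
largest odd size that fits), $K_1 = 0.01$, $K_2 = 0.03$, sample
covariances, over fully contained windows. A gene constant in either field
is reported as missing rather than 0 or 1. The SSIM implementation is
hand-rolled (no installed R package provides it) and was cross-checked
against the standard scikit-image reference on shared inputs; an 8 × 8
checkerboard vs its inverse is frozen as a regression value.

# The synthetic test bed

`make_slide()` generates a complete slide with known truth: a 20 × 20
hexagonal spot lattice (pitch 64 px at the fixed rendering scale of 1 px =
0.5 synthetic µm), ~1500 cells placed uniformly with smooth type-density
territories for 3 types, an RGB rendering of each cell as a type-hued
Gaussian blob on an eosin-like background, 60 genes and a 15-pair LR
database with 5 *planted* pairs. Type markers (30 genes) differ by cell
type, so the image carries real expression signal; LR genes are spatially
*flat* except that a planted pair's ligand and receptor are boosted 6-fold
inside two hotspot disks of radius 3 pitches (~15% of the tissue
combined), making the unplanted pairs a genuine spatial null. Per-cell
rates get log-normal jitter (sd 0.3); spot counts are Poisson draws of the
summed member-cell rates, and the per-tile truth sums *exactly* to the
pre-noise spot rate. The boost and hotspot size were chosen so the planted
co-expression is a clearly detectable effect at the fixture's desk-scale
resolution of 400 spot-level locations — far smaller than the tens of
thousands of sub-spot locations a real analysis would use, where weaker
effects are recoverable. `make_null_slide()` removes hotspots and shuffles
types spatially for calibration studies.

What the generator does *not* emulate: real H&E texture (stain variation,
nuclei morphology), segmentation errors in nuclei centers, platform
artifacts (spot swapping, diffusion), compositional library-size biases
beyond what total-count normalization induces, and multi-subunit complex
stoichiometry. Passing tests therefore demonstrate internal correctness
and statistical calibration of the machinery, not performance on real
tissue.

# Problem sizes and numerical choices

The shipped test and acceptance workloads use: 100 random instances at
$M \le 50$ for the Moran oracle; 3 null slides of $M = 200$ locations ×
500 pairs for calibration; 20 generator seeds of the default fixture for
power; one 120-epoch training run of the default slide (stub embeddings,
$C = 32$, $h = 32$) shared across the model, retrieval and imputation
checks; and the $M = 400$ two-blob fixture for pattern clustering. These
sizes keep a full run in a couple of minutes on one CPU while leaving
every statistical margin wide.

Other numerical choices: softplus is computed in its overflow-safe form;
InfoNCE uses log-sum-exp with max subtraction; EM convergence is declared
at an objective change below $10^{-5}$ (cap 200 iterations) with a
variance floor of $10^{-12}$; zero-variance expression vectors skip their
pair with $p = 1$ rather than producing NaN; duplicate coordinates are
allowed in the spatial weights (duplicate *all-identical* coordinates are
not); and k-means initializations are seeded everywhere, making every
pipeline stage reproducible from `(config, seed)`.

# Known limitations

* The stub extractor is a featurizer, not a histology foundation model;
  absolute imputation quality on real slides depends on the plugged-in
  backend.
* The normal tail on the exact permutation moments slightly miscalibrates
  in extreme tails at small $M$; use the permutation fallback there.
* Total-count normalization can induce mild compositional co-expression
  among non-interacting genes when a few genes dominate a region's
  counts; the calibration suite bounds this effect at the fixture's
  conditions.
* AEH responsibilities saturate (see above); interpret pattern labels, not
  responsibility magnitudes.
* `fit_aeh_full` is guarded to $M \le 5000$ by its dense covariance; use
  the block-sparse variant beyond that.
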