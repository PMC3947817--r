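---
title: "Palm-vein verification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palm-vein verification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinverify)
```

## The problem

Palm-vein verification decides whether a near-infrared palm image belongs to
a claimed identity. Vein patterns sit under the skin, are stable over a
lifetime, and are hard to forge, which makes them attractive biometrics. A
verification system compares a probe image against enrolled samples and
accepts or rejects the claim at a score threshold; its quality is summarized
by the trade-off between the false acceptance rate (FAR) and the false
rejection rate (FRR), and in particular by their crossing point, the equal
error rate (EER).

`veinverify` implements the full chain — vessel enhancement, two
complementary feature channels, graph-based dimensionality reduction,
nearest-neighbour matching, score fusion, and FAR/FRR/EER evaluation — plus
a synthetic image generator so the chain can be exercised, tested and
benchmarked without access to license-gated palm databases.

## Matched-filter enhancement

In NIR transillumination, vessels appear as dark curvilinear ridges whose
cross-sections are approximately Gaussian. The enhancement stage exploits
this with a bank of oriented matched filters. With rotated coordinates
$x' = x\cos\theta + y\sin\theta$, $y' = -x\sin\theta + y\cos\theta$, the
kernel at orientation $\theta$ is

$$g_{\theta,\sigma}(x,y) = -\exp\!\left(-\frac{x'^2}{\sigma^2}\right) - m,
  \qquad |x'| \le 3\sigma,\; |y'| \le L/2,$$

and zero outside the support box. The constant $m$ is chosen as the mean of
the first term over the *discretized* support, which makes every kernel
exactly zero-sum: constant backgrounds produce zero response, so only
structure survives. Six orientations $\theta_j = j\pi/6$, $j = 0,\dots,5$,
are applied and the per-pixel maximum response over orientations (and over
scales, when several $\sigma$ are configured) is kept, then min-max rescaled
to $[0,1]$.

Numerical choices:

* **Exponent convention.** The filter profile uses $x'^2/\sigma^2$, the
  convention of the matched-filter vessel-extraction literature, rather than
  the usual Gaussian $x'^2/(2\sigma^2)$. The `gaussian_convention` switch in
  `matched_filter_params()` selects either.
* **Defaults $\sigma = 2$, $L = 9$.** No canonical values exist; these sit in
  the range typical of retinal matched filtering at comparable resolutions
  and match the generator's default vessel width, and both are configurable.
* **Border handling.** Reflective (half-sample symmetric) padding avoids the
  dark halos that zero padding would create at the frame; convolution is
  FFT-based and the convention is correlation (the kernels are centrally
  symmetric, so correlation and convolution coincide).
* **Zero-sum enforcement.** Subtracting the support mean on the discrete
  grid, not analytically: the rasterized support would otherwise break the
  property.
* **Single scale by default**; a vector of `sigmas` enables multi-scale max.

The enhancement output stays grayscale; no binarization or skeletonization
is applied, as the downstream texture features consume the response image
directly.

## Feature channels

### Global channel: wavelet approximation (WLPP)

Each enhanced image is decomposed three levels deep with two orthogonal
wavelets, `db2` and `sym2`, and only the approximation (LL) band is kept — a
low-resolution, smooth summary of the vein layout that is robust to small
registration errors. The two coefficient arrays are flattened row-major,
Z-normalized per dimension with statistics estimated **on the enrollment
split only** (test data must not leak into normalization), and concatenated
(db2 block first). One honest caveat documented here: at two vanishing
moments the Symlet and Daubechies constructions coincide, so `db2` and
`sym2` share identical filter taps and the two blocks duplicate the same
information; the pipeline keeps both blocks because the channel is defined
that way, and the duplication is harmless (distances scale by $\sqrt2$).

The DWT uses half-sample symmetric boundary extension; coefficient counts
per level follow the closed form $\lfloor (n + L - 1)/2 \rfloor$ with filter
length $L = 4$, so feature lengths are a deterministic function of the image
size (for $96\times96$ inputs the level-3 band is $14\times14$, giving a
$2 \times 196$-dimensional raw channel). Z-normalization uses the population
standard deviation (denominator $n$); zero-variance dimensions map to 0.

### Local channel: LBP variance histograms (LBPV)

The local binary pattern of a pixel thresholds $P$ circular neighbours at
radius $R$ against the center gray value,

$$\mathrm{LBP}_{P,R} = \sum_{p=0}^{P-1} s(g_p - g_c)\,2^p,\qquad
  s(x) = \mathbf{1}[x \ge 0],$$

with neighbour $p$ at $(-R\sin(2\pi p/P),\, R\cos(2\pi p/P))$, bilinearly
interpolated off-grid. LBPV weighs each pixel's histogram contribution by
the variance of its ring samples,
$\mathrm{VAR}_{P,R} = \frac1P\sum_p (g_p - u)^2$, so high-contrast
(vessel-edge) patterns dominate. The histogram has $2^P$ bins (plain codes,
no uniform/rotation-invariant mapping), is training-free, and by
construction sums to the total ring variance of the valid region — a
conservation law the tests assert.

Choices worth noting:

* $(P, R) = (8, 1)$ defaults, configurable; histogram length 256.
* Ring samples that tie with the center only up to floating-point rounding
  count as ties ($g_p \ge g_c - 10^{-9}$); bilinear interpolation makes
  exact-zero differences representation-dependent otherwise.
* Border pixels without a complete ring are skipped (margin
  $\lceil R\rceil + 1$), not padded — padding would fabricate neighbours.
* The channel stacks three histograms: enhanced image, db2 LL, sym2 LL.
  Wavelet coefficient arrays are min-max scaled to $[0,1]$ per image before
  LBP so the three variance scales are commensurate; codes are scale-
  invariant but VAR is quadratic in intensity.
* Histograms are Z-normalized per source (enrollment statistics) and
  concatenated; no L1 normalization is applied before Z-scoring (a
  documented toggle point — Z-scoring alone keeps the variance information
  that distinguishes LBPV from plain LBP).

## Locality preserving projections

Both raw channels are high-dimensional and redundant. LPP learns a linear
map that preserves neighbourhood structure: build a graph on the enrollment
samples (k-nearest-neighbour, OR-symmetrized, $k = 5$ default; or an
$\epsilon$-ball variant), weight edges with the heat kernel
$W_{ij} = \exp(-\|x_i - x_j\|^2/t)$ (or 0/1 weights), and solve

$$X L X^{\top} a = \lambda\, X D X^{\top} a,$$

with $D_{ii} = \sum_j W_{ji}$ and $L = D - W$ the graph Laplacian, keeping
the eigenvectors of the $l$ smallest eigenvalues; samples embed linearly as
$y = A^{\top}x$, so the map extends to unseen probes.

Design choices:

* **PCA pre-projection** (retaining 98% variance by default) before the
  eigenproblem: with more dimensions than samples $X D X^\top$ is singular;
  this is the standard practice in the Laplacian-embedding lineage. The
  graph itself is built in the original feature space.
* **Heat bandwidth auto-rule** $t = $ mean squared pairwise training
  distance: scale-free and parameterless.
* **Cholesky reduction** of the generalized problem to a symmetric standard
  one; eigen-residuals are asserted below $10^{-6}$ in the tests.
* **Sign convention**: each eigenvector's largest-magnitude entry is made
  positive, so serialized models and embeddings are reproducible
  bit-for-bit; the embedding is otherwise defined only up to per-column
  sign.
* **Embedding dimension.** `lpp_fit()` defaults to
  $l = \min(100, \mathrm{rank}, m-1)$. The *pipeline* instead defaults to
  the number of enrolled identities (capped by enrollment size and rank):
  with $C$ subjects the between-identity structure spans roughly $C$
  directions — on fragmented neighbourhood graphs these are the
  near-zero-eigenvalue component indicators — while later coordinates are
  unit-normalized within-class noise. Empirically (see the benchmark below)
  carrying those extra coordinates degrades the WLPP EER by an order of
  magnitude, which is why the pipeline's adaptive default exists; pass an
  explicit `l` to override.

## Matching, fusion and evaluation

Verification scores are plain dissimilarities between LPP embeddings, under
four metrics: Euclidean, Manhattan, cosine ($1 - \cos$), and correlation
($1 - r$). Genuine scores are all (test, enrolled-same-subject) pairs;
impostor scores all cross-subject pairs; a min-per-claim alternative (the
minimum distance to the claimed subject's gallery) is available behind the
`score_rule` flag. Identification uses the globally nearest enrolled sample
(ties broken by lowest subject id then sample index, for determinism).

FAR/FRR are step functions of the threshold swept over the observed scores;
the EER is read off at the FAR$-$FRR sign change by linear interpolation of
both curves (so the interpolated FAR and FRR agree exactly at the reported
point), and is reported in percent. The implementation is sort-based and is
tested against a literal all-thresholds counting oracle.

The two channel distance matrices are min-max normalized to $[0,1]$ — they
live on incommensurate scales, and the weighted sum is only meaningful after
normalization, which is EER-neutral per channel since it is strictly
monotone — and fused as $w\,d_1 + (1-w)\,d_2$ with $w$ searched exhaustively
over $\{0, 0.01, \dots, 1\}$ (a single loop; the two-weight simplex
collapses to one free parameter). Ties prefer the smallest $w$. Because the
endpoints are in the grid, fused EER never exceeds either channel's EER.

## The synthetic generator, and what it does not emulate

`make_dataset()` renders, per subject, `n_vessels` smoothed random-walk
centerlines (unit step, bounded turning angle) as dark ridges with Gaussian
cross-section (depth 0.5, width $\sigma = 2$ px) on a 0.85 background, then
derives each sample by a random similarity jitter (shift $\le 2$ px,
rotation $\le 3^\circ$, gain $\pm 10\%$; bilinear resampling with reflective
boundaries, so no black borders pollute the texture statistics) plus
$N(0, 0.05^2)$ pixel noise, clipped to $[0,1]$. The default benchmark is 50
subjects $\times$ 12 samples of $96 \times 96$ px, the first 6 samples per
subject enrolled and the last 6 held out for testing. Everything is a pure
function of the configuration (including the seed): regenerating a dataset
reproduces it bit for bit.

These defaults were chosen once, as a dataset a practitioner would call
moderately perturbed: jitter of a couple of pixels and a few degrees is what
survives a reasonable ROI registration step, 5% noise is substantial for an
8-bit-equivalent image, and ten vessels give the texture channels something
to work with at $96\times96$. The sizes keep the full benchmark with all
four ablations within a few minutes on a single CPU.

What the generator deliberately does **not** model: real vasculature
topology (no branching, no width variation along a vessel), illumination
physics and shading fields, skin texture, ROI localization errors beyond
rigid jitter, and sensor artifacts. Passing the benchmark therefore
certifies the pipeline's mechanics — enhancement selectivity, feature
stability under jitter and noise, embedding quality, correct evaluation
arithmetic — not field performance on real palms, and the absolute EERs
reported on synthetic data are not comparable to EERs published on real
databases.

## Degenerate inputs and numerical corners

* Constant images: zero matched-filter response (an all-zero enhanced image
  with a warning), all-ones LBP codes with an empty LBPV histogram, constant
  wavelet approximations with gain $2$ per 2-D level.
* Zero-variance feature dimensions Z-normalize to 0 rather than NaN.
* Zero-norm vectors under cosine/correlation get distance 1 with a warning.
* Constant distance matrices min-max normalize to zeros with a warning.
* A disconnected neighbourhood graph is reported via a message; each extra
  component contributes one zero Laplacian eigenvalue.
* A singular $X D X^\top$ after pre-projection raises an error advising a
  lower `l` or `pca_keep`.

## The benchmark and ablations

```{r benchmark, eval = FALSE}
ds <- make_dataset(synth_config(seed = 7))
report <- run_experiments(ds, pipeline_config())
print(report)
```

`run_experiments()` reports, for each of the four metrics, the two channel
EERs, the fused EER and the fusion weight, for five experiments: the full
system and four ablations (no enhancement, no LPP, each channel alone).
Enhancement is computed once and shared across the runs that use it. The
qualitative pattern on the default benchmark: the global WLPP channel is
strong, the local LBPV channel is markedly weaker on $96\times96$ synthetic
images (its wavelet-band histograms see only $14\times14$ coefficient
arrays), and fusion tracks the better channel or improves on it. On
noise-free, jitter-free data every channel reaches EER $= 0$ exactly, since
test samples duplicate enrolled templates.

All empirical claims above are computed by the package's own test suite and
by `scripts/acceptance.R`; the vignette states no number the code does not
produce.

## Limitations

* The two wavelet blocks are informationally identical (db2 $\equiv$ sym2 at
  this order); swapping one for a genuinely different wavelet (e.g. `db4`)
  would require adding its filter taps.
* LPP is unsupervised; with very few samples per identity the neighbourhood
  graph fragments and embedding quality depends on the adaptive dimension
  rule described above.
* The generator's intra-class variation is rigid-body plus gain/noise;
  non-rigid palm deformation is out of scope.
* EER confidence intervals are not computed; on small datasets the score
  sets are small and the EER is correspondingly coarse.
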