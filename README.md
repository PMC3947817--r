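# veinverify

Palm-vein biometric verification in R: matched-filter vessel enhancement,
dual global/local feature extraction, locality preserving projections,
nearest-neighbour matching, weighted-sum score fusion, and FAR/FRR/EER
evaluation — with a synthetic vein-image generator so the whole pipeline can
be exercised and benchmarked without access to license-gated palm-vein
databases.

## Who this is for

Researchers and engineers building or studying vein-pattern biometric
systems who need a tested, reproducible reference implementation of the
classic enhancement → texture/subspace features → score fusion chain, and a
controllable phantom generator for validating each stage in isolation.

## The method

**Enhancement.** Vessel cross-sections in NIR palm images are approximately
Gaussian, so a bank of oriented zero-sum matched filters

```
g_θ,σ(x, y) = −exp(−x′² / σ²) − m,   |x′| ≤ 3σ, |y′| ≤ L/2,
x′ = x cos θ + y sin θ,  y′ = −x sin θ + y cos θ
```

is applied at six orientations θ_j = jπ/6; `m` is the support mean, so every
kernel sums to zero and constant backgrounds give zero response. The
per-pixel maximum over orientations is the enhanced image.

**Features.** Two complementary channels, each Z-normalized on the
enrollment split and reduced by locality preserving projections (LPP), the
linear embedding solving `X L Xᵀ a = λ X D Xᵀ a` on a k-nearest-neighbour
heat-kernel graph:

* **WLPP** (global): level-3 wavelet approximation coefficients (db2 and
  sym2), flattened and concatenated.
* **LBPV_LPP** (local): variance-weighted local binary pattern histograms
  (`LBP_{8,1}`, 256 bins, each bin accumulating the ring variance
  `VAR_{8,1}`) of the enhanced image and of both wavelet approximation
  arrays.

**Matching and evaluation.** Test-versus-enrolled distance matrices under
Euclidean, Manhattan, cosine and correlation metrics; genuine scores are
same-subject pairs, impostor scores cross-subject pairs; FAR/FRR threshold
sweep with linearly interpolated equal error rate (EER, in percent); the two
channel matrices are min-max normalized and fused as `w·d₁ + (1−w)·d₂` with
`w` searched exhaustively on a 0.01 grid. Identification uses the nearest
enrolled sample.

## Worked example

```r
library(veinverify)

# 50 subjects x 12 samples (6 enrolled / 6 test), 96x96 px, moderate
# jitter and noise -- the package's default benchmark conditions
ds <- make_dataset(synth_config(seed = 7))
report <- run_experiments(ds, pipeline_config())
print(report)
```

```
    experiment      metric eer_wlpp eer_lbpv_lpp eer_final fusion_weight
          full   euclidean   0.3889      41.0385    0.3889          0.80
          full   manhattan   0.0000      40.6111    0.0000          0.81
          full      cosine   0.1111      26.1100    0.1111          0.68
          full correlation   0.1111      26.7177    0.1111          0.67
    no_enhance   euclidean   0.0000      37.5000    0.0000          0.73
        no_lpp   euclidean   0.6111      41.4444    0.6111          0.88
     wlpp_only   euclidean   0.3889           NA    0.3889            NA
 lbpv_lpp_only   euclidean       NA      41.0385   41.0385            NA
 ...
```

Reading the table: each row is one experiment/metric pair; `eer_wlpp` and
`eer_lbpv_lpp` are the single-channel equal error rates in percent,
`eer_final` the EER after weighted-sum fusion at the reported
`fusion_weight` (the weight on the WLPP channel). On this synthetic
benchmark the global WLPP channel is strong (EER ≤ 0.4%), the local LBPV
channel much weaker (its wavelet-band histograms see only 14×14 coefficient
arrays at this image size), and fusion never does worse than the better
channel. Rank-1 identification on the full system (`report$runs$full$id_accuracy$final`)
is 100%. Absolute numbers on synthetic phantoms are not comparable to EERs
published on real palm databases.

Lower-level entry points follow the same grammar: `enhance_image()`,
`wavelet_approx()`, `lbpv_histogram()`, `lpp_fit()`/`lpp_transform()`,
`distance_matrix()`, `far_frr()`, `fuse_and_search()`. A thin CLI over these
lives at `inst/cli/veinverify.R` (`synth`, `enhance`, `run`, `eval`
subcommands).

## Documentation

The methods vignette (`vignettes/palm-vein-verification.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, numerical
corner cases, and known limitations.
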