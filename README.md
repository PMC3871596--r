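# mrsnmf

Semi-supervised extraction of tumor type-specific source spectra from
single-voxel ¹H-MR spectroscopy (SV-MRS) data, with a fully unsupervised
Convex-NMF baseline.

## The problem

An in-vivo MR spectrum summarizes the metabolic fingerprint of one tissue
voxel. Brain-tumor voxels are heterogeneous: a glioblastoma voxel mixes
actively proliferating tissue (high choline at 3.21 ppm) with necrotic
tissue (mobile lipids at 1.29/0.90 ppm, lactate at 1.33 ppm), and a
metastasis can look almost identical. Under the linear-mixture assumption
each observed spectrum is a weighted combination of a few *source* spectra.
Unsupervised factorization recovers the shared constituent tissue patterns;
the clinically interesting object, however, is often a source specific to a
tumor *type* — astrocytoma grade II (A2), glioblastoma (GL), metastasis
(ME). This package is for researchers in MRS-based tumor characterization
and for anyone studying semi-supervised matrix factorization on spectral
data.

## The method

The core factorization is **Convex-NMF**: `X ≈ X W H` with `W ≥ 0`,
`H ≥ 0`, where `X` is d frequencies × n cases and may contain negative
values (long-echo-time spectra have inverted doublets). Sources `S = X W`
are near-convex combinations of observed cases — interpretable as cluster
prototypes — and `H` mixes them back. Fitting uses multiplicative updates
on the positive/negative parts of `XᵀX` from a smoothed K-means indicator
initialization, stopping when the reconstruction error changes by < 1e-5.

The **semi-supervised** variant lets class labels shape the geometry before
the factorization runs:

1. a small softmax network fitted on a stratified 2/3 split estimates the
   class posteriors `p(c|x)`, which induce the Fisher Information metric
   `J(x) = Σ_c p(c|x) ∇log p(c|x) ∇log p(c|x)ᵀ + εI` on the data space;
2. pairwise geodesic distances under `J` are approximated by shortest paths
   on a k-nearest-neighbor graph (MST-augmented, midpoint-rule edge
   quadrature) and embedded in a low-dimensional Euclidean space by Sammon
   mapping, SMACOF metric MDS, or a parametric iterative-majorization map
   (IMA) with Gaussian bases of Fisher distance;
3. Convex-NMF runs on the latent coordinates; the learned unmixing matrix,
   applied to the original spectra, yields class-prototype sources, and the
   mixing matrix labels every case unsupervisedly (argmax per column).

Sources are matched to classes by Pearson correlation with the class mean
spectra (exhaustively optimal matching); results are scored by per-class
and total accuracy and the balanced error rate (BER, the mean per-class
error rate). Independent test cases are labeled under *fixed* training
sources via the mixing-matrix-only update, after out-of-sample extension
of the distances and the embedding.

Because real clinical SV-MRS cohorts of this kind are not redistributable,
the package includes a seeded generator of MRS-like datasets (195-point
4.24–0.50 ppm axis, metabolite peak prototypes, Dirichlet constituent
mixing, echo-time-dependent sign structure, class overlap and outlier
controls) with full ground truth, so every stage is testable end to end.

## Worked example

Two heavily overlapping aggressive tumor classes (class-mean correlation
0.96), 20 cases each:

```r
library(mrsnmf)

protos <- make_prototype_sources(mrs_axis(), "STE")
gen <- generate_dataset(protos[c("gl", "me")], c(gl = 20, me = 20),
                        noise_sd = 0.01, overlap = 0.6, seed = 7)

run_unsupervised(gen$dataset, k = 2, seed = 7)
#> mrs_run (convex, k = 2)
#> source -> class: 1:gl (r=0.988), 2:me (r=1.000)
#> training set:
#> Total  87.5% (35/40)
#> gl     75.0% (15/20)
#> me     100.0% (20/20)
#> BER    0.125

run_semisupervised(gen$dataset, "ima", k = 2, seed = 7)
#> mrs_run (ima, k = 2)
#> source -> class: 1:gl (r=0.992), 2:me (r=0.999)
#> training set:
#> Total  100.0% (40/40)
#> gl     100.0% (20/20)
#> me     100.0% (20/20)
#> BER    0.000
```

The unsupervised factorization mislabels a quarter of the glioblastoma-like
cases because its sources track constituent tissue types; with the Fisher
metric and IMA embedding in front, the sources become class prototypes and
the same labeling rule becomes error-free. Accuracy cells print as
`percent% (correct/total)` and BER is the mean per-class error rate, so the
numbers are directly comparable across imbalanced problems.

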