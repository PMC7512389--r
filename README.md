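# nlmseg

Bilevel (two-class) segmentation of grayscale images by **thresholding the
joint histogram of original and non-local-means filtered gray levels** with a
minimum relative-entropy criterion.

Classical histogram thresholding (Otsu, Kapur, minimum cross entropy) looks
only at the 1D gray-level histogram and ignores where pixels sit relative to
their neighbors, so images with identical histograms but different spatial
structure get the same threshold. Two-dimensional histogram methods fix this
by pairing each pixel's gray level `i` with the gray level `j` of a smoothed
companion image, and thresholding the joint distribution `p_ij` with a vector
`(s, t)`. The classical companion is a local 3×3 mean, which blurs edges and
fine structures; `nlmseg` instead uses a **non-local means (NLM)** companion,
which averages each pixel with pixels anywhere in its search window whose
surrounding patches look similar,

```
w(i,j) = exp( -||X(N_i) - X(N_j)||² / (h²σ²) ) / Z(i),   Y(i) = Σ_j w(i,j) X(j),
```

so edges and small objects survive the smoothing and the joint histogram
separates classes more cleanly. This is aimed at bilevel problems such as
binarizing bacteria/cell micrographs or defect images.

## The criterion

A threshold vector `(s, t)` splits the `L×L` joint histogram into quadrant 1
(`i ≤ s, j ≤ t`, background), quadrant 3 (`i > s, j > t`, object), and the
off-quadrants 2/4 (edges and noise). With class masses
`P0, P1`, class first moments `m_k = (m_ki, m_kj)` and class mean vectors
`μ_k = m_k / P_k`, the selected vector minimizes the relative entropy between
the image and its two-class approximation, which reduces to

```
D(s,t) = M − m0i·log μ0i − m0j·log μ0j − m1i·log μ1i − m1j·log μ1j,
M = Σ_ij ( i·p_ij·log i + j·p_ij·log j )      (a constant of the image)
```

— the two-dimensional analogue of the Li–Lee minimum cross-entropy
criterion (natural logs; 0·log 0 = 0). The search is an exhaustive `O(L²)`
scan made `O(1)` per vector with prefix-sum tables. Pixels in quadrants 2/4
are assigned to the class with the nearer mean vector. Segmentations are
scored by the misclassification error `ME = 1 − (|B_o∩B_T| + |F_o∩F_T|) /
(|B_o| + |F_o|)`, i.e. the fraction of pixels labeled unlike the ground
truth (0 = perfect).

The package also ships the four comparison baselines (Otsu, Kapur maximum
entropy, 1D minimum cross entropy, and the local-mean 2D variant "2DMCE" —
identical criterion, local 3×3 mean instead of NLM), plus a deterministic
generator of synthetic two-class scenes with exact ground-truth masks.

## Worked example

```r
library(nlmseg)

# a 64x64 scene: disk (gray 180) on background (gray 60), Gaussian noise sd 10
sc <- generate_scene(scene_spec(
  shape = c(64, 64), bg_level = 60, fg_level = 180, noise_sigma = 10,
  objects = list(scene_disk(32, 32, 16)), seed = 42))

res <- nlm_segment(sc$image, nlm_params(search_radius = 5))
res$threshold
#> 2D threshold vector (s, t) = (96, 96)
#>   criterion D = 1.485670
#>   background: P0 = 0.8054, mean (59.71, 59.71)
#>   object:     P1 = 0.1946, mean (180.23, 180.23)

misclassification_error(sc$mask, polarity_align(sc$mask, res$mask))
#> [1] 0

compare_methods(sc$image, sc$mask, params = nlm_params(search_radius = 5))
#>    method  s   t objective         me
#>  proposed 96  96  1.485670 0.00000000
#>     2DMCE 96 117  2.246366 0.00000000
#>       MCE 96  NA        NA 0.00000000
#>      Otsu 96  NA        NA 0.00000000
#>     Kapur 77  NA        NA 0.02954102
```

The selected vector `(96, 96)` sits between the two class means (≈60 and
≈180 in both coordinates), the recovered classes carry 80.5% / 19.5% of the
pixels, and the binarized mask matches the ground-truth disk exactly
(ME = 0). On this well-separated scene the cross-entropy family all succeed,
while Kapur's entropy criterion picks a threshold inside the background mode
and mislabels ~3% of pixels.

A thin command-line wrapper is installed with the package
(`system.file("scripts", "nlmseg", package = "nlmseg")`), with subcommands
`segment`, `compare` and `synth`.

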