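---
title: "Methods: two-dimensional histogram thresholding with a non-local means companion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-dimensional histogram thresholding with a non-local means companion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmseg)
```

## The model

`nlmseg` segments a grayscale image into exactly two classes (background and
object) under the classical thresholding assumption: the two classes occupy
distinct gray-level ranges, so a well-chosen cut separates them. Pure 1D
thresholding discards all spatial context. The package restores context by
pairing each pixel's gray level $i$ in the original image $I$ with the level
$j$ of a smoothed companion image $J$ and working with the joint
distribution

$$p_{ij} = n_{ij} / (MN), \qquad i, j \in \{0, \dots, L-1\},$$

where $n_{ij}$ counts pixels with $I(x,y) = i$ and $J(x,y) = j$. Interior
pixels of either class have $j \approx i$ and concentrate near the diagonal;
edge and noise pixels land off-diagonal.

The companion is produced by **non-local means**: pixel $i$ becomes the
weighted average $Y(i) = \sum_j w(i,j) X(j)$ with

$$w(i,j) \propto \exp\!\left( -\frac{\lVert X(N_i) - X(N_j) \rVert^2}{h^2
\sigma^2} \right),$$

the squared distance taken between the square gray-level patches centered at
$i$ and $j$, and the weights normalized to sum to one (the self term $j = i$
is included and always carries the maximal unnormalized weight $e^0$). Unlike
a local mean, NLM averages a pixel with *patch-similar* pixels anywhere in
its search window, so it smooths within-class noise while preserving edges —
exactly the property that keeps class clusters in the joint histogram
compact and separated.

## The threshold criterion

A threshold vector $(s, t)$ splits the histogram support into quadrant 1
($i \le s$, $j \le t$; background), quadrant 3 ($i > s$, $j > t$; object) and
the off-quadrants 2/4 (edges, noise). Writing $P_0, P_1$ for the quadrant
masses, $m_0, m_1$ for the quadrant first-moment vectors and
$\mu_k = m_k / P_k$ for the class mean vectors, the selected vector
minimizes

$$D(s,t) = M - m_{0i}\log\mu_{0i} - m_{0j}\log\mu_{0j}
             - m_{1i}\log\mu_{1i} - m_{1j}\log\mu_{1j},
\qquad M = \sum_{ij}\left( i\,p_{ij}\log i + j\,p_{ij}\log j \right),$$

the two-dimensional analogue of the Li–Lee minimum cross-entropy criterion:
$D$ is the relative entropy between the image's moment distribution and a
two-class approximation in which each class is represented by its mean
vector. $M$ depends only on the image, never on $(s,t)$, so the search
effectively maximizes $\sum_k m_k \log \mu_k$.

**Why the reduced form is the objective.** One can also write a
quadrant-limited divergence
$\sum_{Q_1} i p_{ij} \log(i/\mu_{0i}) + \dots + \sum_{Q_3} \dots$ that sums
only over quadrants 1 and 3. The two forms coincide exactly when quadrants
2/4 carry no mass, and their difference is precisely the moment-entropy mass
$\sum_{Q_2 \cup Q_4}(i p_{ij}\log i + j p_{ij}\log j)$ of the off-quadrant
cells. That makes the quadrant-limited form unusable as a search objective:
each of its class sums is non-negative and vanishes for point-mass classes,
so its minimizer can always carve two tiny single-cell "classes" out of the
histogram corners, dump everything else into quadrants 2/4 at zero cost, and
reach $D \approx 0$ — a degenerate segmentation. (We verified this
numerically: on dense random histograms the quadrant-limited argmin lands on
extreme corner vectors.) The reduced form charges every unit of mass
excluded from the two classes its full $m \log \mu$ contribution, so the
optimum keeps the off-quadrant mass small and splits the diagonal clusters.
The test suite pins the algebra down from both directions: the reduced form
equals a term-by-term direct summation (class divergences over quadrants 1/3
plus the off-quadrant moment terms) up to floating-point error — an identity
that breaks if the class-1 moments are normalized by $P_0$, or if the
constant uses $\log p_j$ in place of $\log j$ — and the prefix-sum search
returns the same argmin as a naive full scan.

Binarization labels quadrant-1 pixels background, quadrant-3 pixels object,
and assigns each quadrant-2/4 pixel to the class whose mean vector is nearer
in the $(i, j)$ plane (ties to background). This rule is our choice; any
convention for these pixels affects only the thin edge band.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `patch_radius` | 2 | half-width of the comparison patch (5×5), in pixels; larger patches are more discriminative but smear small structures |
| `search_radius` | 10 | half-width of the candidate window, pixels; `"full"` is the literal all-pairs definition but costs $O((MN)^2)$ |
| `h` | 10 | filtering degree, gray levels; the weight decays on the scale $h^2\sigma^2$ of squared patch distance |
| `sigma` | 1 | Gaussian kernel scale; enters only through the product $h^2\sigma^2$, so `h` and `sigma` are not separately identifiable — they are exposed separately for compatibility with common NLM parameterizations |
| `pad_mode` | reflect | border handling for patches and the local mean (`edge` available) |
| `window` (2DMCE) | 3 | local-mean window of the baseline companion |

The defaults follow common non-local-means practice (5×5 patches, 21×21
search window, `h` of the order of the noise standard deviation for
moderately noisy 8-bit images). Because only $h^2\sigma^2$ matters, tuning
`h` alone suffices in practice. Guidance: `h` well below the noise level
leaves the companion close to the original (the joint histogram collapses to
the diagonal and the method degenerates gracefully to 1D minimum cross
entropy); `h` of the order of `10 * noise sd` smooths aggressively, which
helps on very noisy images but can round small objects.

All criteria use natural logarithms (the argmin is base-invariant), the
convention $0 \log 0 = 0$, and terms with gray level 0 contribute 0. A
threshold vector that leaves either class empty is *infeasible*: the
objective returns `NA` there and the search skips it; if no vector is
feasible (e.g. a constant image) `select_threshold()` raises a
degenerate-input error. Exact ties in any criterion are broken toward the
smallest threshold ($s$ first, then $t$). Filter output is rounded half-up
and clipped to $[0, L-1]$ so the companion is a valid histogram index; the
pre-rounding values are a convex combination of input levels and therefore
already lie in range.

## The synthetic-scene generator

`generate_scene()` draws two-class scenes: foreground primitives (disks by
pixel-center rasterization, inclusive rectangles) at one mean gray level on
a uniform background at another, plus i.i.d. additive Gaussian noise,
rounded and clipped. The ground-truth mask is the exact noiseless class
assignment, and the whole scene is a deterministic function of its spec,
including the seed (the caller's RNG state is left untouched). Named suites
fix the benchmark conditions: `"noisy"` is ten 64×64 scenes at contrast 120
(levels 60/180) with noise sd 10; `"clean"`, `"small-objects"` and
`"low-contrast"` vary shape, scale and contrast. Gaussian noise is the
generator's only noise model: patch-based averaging is well suited to it,
whereas impulse (salt-and-pepper) noise defeats patch comparison and is a
known weak spot of NLM-based smoothing, so no claims are made for it.

What these scenes do *not* emulate: textured backgrounds, illumination
gradients, partial-volume (mixed) edge pixels, and multi-modal foregrounds.
Passing the suites therefore demonstrates correctness of the machinery and
noise robustness in the favorable regime, not performance on arbitrary real
micrographs.

## Numerical and testing choices

Histograms are stored dense ($L \times L$ doubles, 512 KB at $L = 256$).
The criterion surface uses cumulative prefix-sum tables, $O(1)$ per vector
after $O(L^2)$ setup; feasibility uses a $10^{-12}$ mass floor to absorb
prefix-subtraction round-off. Oracle tests compare against
literal-definition implementations: a quadruple-loop NLM on 16×16 scenes
(agreement to $10^{-6}$ before rounding), indicator-matrix direct summation
of every region sum at $L = 256$ for the full-scan search equivalence, and
loop-based counting for histograms and local means. Benchmark tests run the
ten-scene noisy suite with `search_radius = 5`; at these sizes the whole
suite completes in well under a minute. On that suite the proposed method's
polarity-aligned ME stays at or below 0.02 per scene and its mean ME is no
worse than each 1D baseline — with contrast 120 and noise sd 10 the classes
are ~6 sd apart, so every cross-entropy-family method is essentially
perfect and Kapur's entropy criterion is the one that occasionally
misplaces its threshold.

## Limitations

- Exactly two classes; no multi-level extension.
- Exhaustive $O(L^2)$ search only; no metaheuristic acceleration (at
  $L = 256$ the scan is already instantaneous next to the filter).
- NLM is quadratic in window size and, with `"full"` search, in image size;
  no fast approximations (integral-image/FFT) are provided — correctness
  over speed.
- Single-channel 8-bit-style images only; multi-channel files are rejected
  rather than silently converted.
- Impulse noise is out of the method's favorable regime, as discussed above.
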