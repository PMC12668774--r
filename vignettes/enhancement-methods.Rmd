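---
title: "Enhancing sparse single-cell Hi-C matrices: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing sparse single-cell Hi-C matrices: model, simulator and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schicenhance)
```

## The problem

Single-cell Hi-C (scHi-C) measures chromatin contacts in individual cells,
but per-cell sequencing depth is so low that most entries of a binned
contact matrix are zero. Enhancement (imputation) methods infer the missing
contacts so that downstream structure — A/B compartments, TAD-like domains,
loops — can be called per cell. The standard failure mode of enhancers is
*over-smoothing*: spreading signal indiscriminately fills the background
with false-positive contacts, blurs fine structure and erases cell-to-cell
variability.

This package implements a supervised GAN enhancer built around two ideas:

1. **Rank-one feature extraction and reconstruction.** A contact matrix is
   symmetric, and its informative structure is organized by genomic
   distance rather than local image texture. Instead of relying only on
   square kernels, each branch collapses its $n \times n$ feature maps with
   an $n \times 1$ convolution into per-channel length-$n$ vectors
   (refined by two 1-D convolutions, kernel 3), and reconstructs feature
   maps as weighted outer products $w_c\, v_c v_c^\top$. Every
   reconstructed channel is *exactly* symmetric and has rank 1, so
   symmetry is built into the architecture rather than imposed by a loss.
2. **Squeeze-and-excitation (SE) channel attention.** Not all feature
   channels carry signal; indiscriminate channel summation is one driver of
   over-smoothing. An SE block global-average-pools each channel, passes
   the pooled vector through a two-layer perceptron and sigmoid, and
   rescales each channel by its gate in $(0,1)$, letting the network
   suppress noisy channels.

The generator is dual-branch: one branch sees a $w \times w$ context window
cut along the diagonal, the other its central $k \times k$ crop. Outputs are
aligned to $k \times k$, concatenated, fused by two $1\times1$ convolutions,
symmetrized as $(X + X^\top)/2$ and passed through a softplus clamped at
1.2. Only the central block of each tile is written back, which avoids edge
artifacts when tiles are merged. Because central blocks at stride $k$ are
disjoint, whole-matrix enhancement runs a second pass with anchors offset by
$k/2$ whose blocks cover the rectangles between consecutive blocks; the
union is a seam-free diagonal band (without this, the 9-fold intensity step
between enhanced blocks and raw cross-block entries creates artificial
insulation dips at every tile seam). Entries outside the assembled band are
copied verbatim from the input, because the network never sees those
genomic distances and inventing values there would be unsupported
extrapolation. A PatchGAN-style discriminator with a least-squares (LSGAN)
objective supplies the adversarial signal.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `window` $w$, `central` $k$ | 40, 28 bins | 6-bin context flank on each side; divides typical fixture sizes cleanly. The published per-resolution sizes are not recoverable from the main text, so these are package defaults. |
| stem `channels` | 16, 32 | smallest stack exhibiting all mechanisms; ~50k parameters total, CPU-trainable. |
| `n_rank_one_channels` | 16 per branch | the two concatenated branches give a 32-channel fused stack, fused 32→16→1. |
| `se_reduction` $r$ | 4 | SE bottleneck $C \to C/r \to C$. |
| `final_cap` | 1.2 | output softplus clamp: nonnegative counts after denormalization without hard saturation at 1. |
| `lambda_rec`, `lambda_adv` | 10, 1 | loss $= \lambda_{rec}\,L_1 + \lambda_{adv}\,\mathrm{LSGAN}$; with $\lambda_{adv}=0$ training is plain supervised regression. |
| optimizer | Adam, lr $10^{-3}$ | both networks, one discriminator step per generator step. At desk scale (tens of epochs, a few thousand optimizer steps) $10^{-4}$ demonstrably under-converges the generator, leaving over-smoothed outputs; $10^{-3}$ is the conventional small-GAN default and converges cleanly here. |
| normalization cap | $\log(1+q_{99.9})$ | `log1p` counts clipped at the 99.9th percentile of non-zero training counts and scaled to $[0,1]$; stored in the checkpoint so training and prediction share the scale. |
| insulation `window_bins`, `band_bins` | 10, 20 | a 1-Mb diamond and the 2-Mb genomic-distance band at 100-kb resolution. The band is from the study design; the window and the 0.1 prominence threshold are package choices. |

Design choices that were genuinely open, and how they were settled:

* **Transpose invariance.** The contract `generator(M^T) == generator(M)`
  cannot hold for a convolution stack on arbitrary inputs, so the generator
  symmetrizes its input tiles first; with the final symmetrization this
  makes the invariance exact, bitwise.
* **SE identity testing.** Exact sigmoid saturation is unreachable with
  finite weights, so `se_bypass` forces all gates to exactly 1 for identity
  tests.
* **Skip connections** are additive from each branch's (SE-recalibrated)
  stem through a $1\times1$ projection to the rank-one reconstruction, so
  information that does not survive the rank-one bottleneck is not lost.
* **Branch fusion** is channel concatenation followed by $1\times1$ convs
  (whether the published model concatenates or adds is not stated in the
  main text; concatenation lets the fusion learn its own mixing).
* **Macro-F1 binarization** uses an inclusive threshold (`>= tau`, the
  smallest non-zero truth value) so that the truth binarized against itself
  reproduces its own support and self-comparison scores exactly 1.
* **Boundary prominence.** Insulation-dip boundaries are plateau-aware
  local minima whose prominence (the smaller climb to the nearest higher
  flanking maxima; segment edges count as maxima) exceeds a threshold.
  Missing bins near chromosome ends cannot host boundaries.
* **Cohort similarity aggregation.** "Average scores across cells" is
  ambiguous between per-cell scores averaged and the score of cell-merged
  matrices; `evaluate_cohort(mode = "per_cell")` and `mode = "merged"`
  provide both, and neither is asserted to be the published reading.

## The synthetic world

All tests run on a built-in simulator, because the real cohorts behind the
study are not redistributable here. The planted intensity for one
chromosome is

$$\Lambda_{ij} \propto (1+|i-j|)^{-\alpha}\,
  \bigl(1 + c\,[\text{same compartment}]\bigr)\,
  \bigl(1 + t\,[\text{same TAD}]\bigr)\,
  \bigl(1 + \textstyle\sum_\ell s_\ell K_\ell(i,j)\bigr),$$

normalized over the upper triangle. Defaults describe a 12-Mb region at
100-kb resolution: decay $\alpha = 1$; alternating 15-bin A/B blocks with
$c = 0.6$ (about 1.6-fold checkerboard contrast); an irregular tiling of
8–17-bin TAD blocks with $t = 1$ (the canonical ~2-fold within-domain
enrichment); a few loops with $s = 4$ on a 3×3 plateau (so 2× downsampling
cannot erase a single-pixel loop); and a Poisson-randomized per-cell depth
(default 30 000 upper-triangle contacts, leaving most entries zero, as in
real scHi-C). The `(1+d)` offset keeps the diagonal finite. Cells are
multinomial draws from $\Lambda$; reduced sequencing depth is emulated by
binomial thinning of the upper triangle with $p = 1/\text{ratio}$, mirrored
to keep symmetry.

What a green test does establish: the architecture's symmetry and shape
contracts; that supervised + adversarial training on downsampled pairs
recovers signal (held-out MAE below the sparse input's) without the
over-smoothing signature (macro F1 above a matched-MAE Gaussian blur); and
that planted compartments and domain boundaries are recovered from
high-depth matrices and are not degraded by enhancement. What it does not
establish: performance on real scHi-C data, with its experimental biases,
trans contacts, haplotype structure and non-multinomial noise — none of
which the simulator emulates — nor any of the published benchmark numbers,
which require the original datasets and full-scale models.

## Numerical choices and degenerate inputs

* Normalization is $x \mapsto \min(\log(1+x), \text{cap})/\text{cap}$; its
  inverse is exact below the cap, and values above the cap saturate at 1 by
  design (they are rarer than 1 in 1000 in training data).
* Distance strata with zero variance are skipped in the stratum-adjusted
  correlation; if every stratum is degenerate the comparison errors rather
  than returning a fabricated score. Observed/expected maps zero-mean
  strata to 0.
* Row-normalization in the graph concordance leaves all-zero rows at zero,
  and the denominator counts bins with any contact.
* Greedy one-to-one matching (boundaries and loops) sorts candidate pairs
  by distance, breaking ties by predicted index, so results are
  deterministic.
* All randomness flows from explicit seeds; one CLI seed is split per stage
  by hashing stage names. Reruns are byte-identical in single-threaded
  mode.
* Degenerate cases are first-class: depth 0 gives an all-zero cell, ratio 1
  returns the input unchanged, `epochs = 0` returns an initialized
  checkpoint, bins with empty rows get compartment label 0.

## Known limitations

* The exact layer counts, loss weights and training schedules of the
  published model live in supplementary material and are replaced here by
  configurable defaults; numeric agreement with the published benchmark
  tables is out of scope.
* Only the dual-size branch pair is implemented (no resolution-pyramid
  branch); no trans contacts, no matrix balancing, no loop *calling* (only
  loop-list matching); the compartment caller is a leading-eigenvector
  stand-in for Higashi's algorithm.
* Training is CPU-only and desk-scale by design; the autodiff engine
  implements exactly the operations this architecture needs and is not a
  general-purpose framework.
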