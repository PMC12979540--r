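---
title: "Structural compression of convolutional classifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural compression of convolutional classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmppm)
```

## The problem

Convolutional classifiers that perform well on leaf-disease photo
benchmarks are routinely far too large for field deployment.  This package
implements a purely *structural* compression pipeline -- no data, no weight
magnitudes, no fine-tuning schedules are involved in deciding what to
remove -- consisting of three composable rewrites of a network's layer
graph:

1. **Global channel pruning.**  Every convolution (and every dense layer
   except the classifier) with output width $C$ satisfying the guard
   $C/N > 1$ is narrowed to $\lfloor C/N \rfloor$, for a single integer
   divisor $N$ applied network-wide.  Layers failing the guard keep their
   width, which prevents collapsing already-narrow layers (a conv with 3
   output channels survives $N = 16$ untouched).  All downstream widths --
   consumer in-channels, batchnorm widths, dense in-features, junction
   widths -- are repropagated, and the rewrite aborts if repropagation
   breaks an add junction (that topology is declared unsupported rather
   than silently mangled).
2. **Depthwise-separable conversion.**  Every standard convolution with
   kernel $k > 1$ and a single group is replaced by a depthwise
   convolution ($C_{in} \to C_{in}$, original kernel/stride/padding,
   groups $= C_{in}$, bias-free) followed by a $1 \times 1$ pointwise
   convolution ($C_{in} \to C_{out}$, stride 1, inheriting the bias flag).
   Parameters drop from $k^2 C_{in} C_{out}$ to $k^2 C_{in} + C_{in} C_{out}$.
   $1 \times 1$ convolutions are left alone -- converting them would *add*
   parameters -- and no batchnorm is inserted inside the pair.  The rewrite
   is architectural, not a factorization: trained weights are not carried
   over.
3. **Multi-path expansion.**  The feature extractor (everything before the
   classifier, optionally excluding a shared stem) is replicated into $E$
   structurally identical parallel paths; path outputs are concatenated on
   the channel dimension and a single fresh classifier is attached to the
   $E$-fold width.  With weights attached, path 1 keeps the original
   weights and paths $2 \dots E$ are re-initialized under a recorded seed;
   before re-initialization all $E$ paths are numerically identical, a
   property the test suite asserts to floating-point equality.

The composition, in the fixed order prune $\to$ convert $\to$ expand, is
`applyLmpPm(g, N, E)`.  Because a single classifier spans the concatenated
features, the total parameter count is *affine in $E$*: each added path
costs a constant (the path itself plus one path-width slice of the
classifier).  The test suite asserts this exactly.

## Cost accounting

`countParams` and `countMacs` follow one frozen convention:

* conv parameters $k^2 (C_{in}/g) C_{out} (+ C_{out}$ if biased$)$;
  batchnorm $2C$; dense $C_{in} C_{out} (+ C_{out})$;
* conv multiply-accumulates $k^2 (C_{in}/g) C_{out} H_{out} W_{out}$ at
  batch 1; dense $C_{in} C_{out}$; batchnorm, activations, pooling and
  junctions count zero.

Counts are exact integers (held in doubles far below $2^{53}$), itemized
per layer, and every built or transformed model is cross-checked in the
tests against a brute-force enumeration of instantiated weight-tensor
element counts -- the counter never trusts its own arithmetic.

Applied to the canonical 101-layer bottleneck residual classifier with a
61-way head, the pipeline reproduces the published compression column at
two-decimal millions rounding (half-up; `formatMillions`):

```{r resnet-table}
g <- buildResNet101(61)
cells <- rbind(c(1, 1), c(2, 1), c(2, 4), c(4, 1), c(4, 4),
               c(8, 1), c(8, 2), c(16, 1), c(16, 4))
data.frame(N = cells[, 1], E = cells[, 2],
           M = apply(cells, 1, function(ne)
             formatMillions(countParams(applyLmpPm(g, ne[1], ne[2])))))
```

The baseline itself counts `r format(countParams(g), big.mark = ",")`
parameters (42.63 M) and the 1000-class variant recovers the canonical
44,549,160.

## The OMNet family

The package's native architecture family is a deliberately high-capacity
baseline built from three kinds of blocks:

* **TBP block** ("three-branch parallel"): two stacked-convolution
  branches, each $1{\times}1 \to k{\times}k \to 1{\times}1 \to$ batchnorm
  $\to$ relu with channel-preserving widths, plus a normalization-only
  identity branch, concatenated channel-wise.  With branch width equal to
  the input width the concat triples the width.  The identity branch
  requires stride 1 (the builder rejects anything else).
* **Residual unit**: two $3{\times}3$ convolutions with batchnorm/relu and
  an identity skip.
* **SE gate**: global average pool $\to$ one width-preserving dense layer
  $\to$ sigmoid $\to$ channel-wise multiply.  The single-dense form is the
  family's definition; every gate lies strictly in $(0,1)$.

A network is: a stem (one $3{\times}3$ stride-2 convolution plus
$2{\times}2$ max pooling, so the main structure sees a quarter of the
input side), four stages of TBP $\to$ fusion conv $\to$ residual units
(SE on stages 3 and 4, two TBP blocks in stage 4), then a $1{\times}1$
head convolution, adaptive average pooling, flatten, dense classifier.
All widths, repeats, branch kernels, head width and pool size are
`omnetConfig()` fields.

Two scope rules matter for cost parity with the printed family tables:
the stem is *pruned but never depthwise-converted* (it sits outside the
compressed feature extractor), and it is *shared* across expanded paths,
whereas the generic residual-network pipeline converts its stem and
replicates everything before the classifier.  Builders encode this as a
per-layer `convertible` attribute and section labels, not as special
cases inside the transforms.

LMNet, the deployable member of the family, is exactly
`applyLmpPm(buildOMNet(cfg), N = 4, E = 2)` with the shared stem.

### Calibration of the printed cost tables

The published family tables pin the configuration down numerically rather
than diagrammatically, and their internal structure decomposes exactly:

* the parameter and MAC columns are affine in the path count $E$ for
  $E \ge 2$, with per-path increments of 2,839,248 / 844,904 / 278,772
  parameters (and 194,294,656 / 50,517,440 / 13,601,248 MACs) at
  $N = 4/8/16$ -- six overdetermined exact fits;
* the $E$-independent remainder is exactly $1000 + 1792/N$ parameters and
  $21{,}676{,}032/N$ MACs, which uniquely identifies a biased,
  batchnorm-free $3{\times}3$ stem convolution of width $64/N$ profiled
  at $112^2$ output resolution, plus a 1000-wide classifier bias -- the
  printed cost columns therefore correspond to a 1000-class profiling
  head, not to the 38- or 61-class heads used for accuracy, and cost
  reports in this package always state their `class_count`;
* the per-path cost is an exact polynomial $a/N + b/N^2$ in the pruning
  divisor with zero constant term, so no layer is guard-protected in the
  printed range and every pruned width is divisible by 16;
* the single-path rows at $N = 4$ and $N = 8$ exceed the affine structure
  implied by their own multi-path rows by exactly $2{,}052{,}096/N$
  parameters and $2{,}312{,}192/N$ MACs, while the $N = 16$ single-path
  row lies exactly on it: those two cells are internally inconsistent
  with the rest of the tables.

The affine law, the stem/head identification, the shared-stem scope and
the transform order hold by construction for every `omnetConfig`.  The
remaining free numbers -- stage widths, branch widths, residual repeats,
head width, pool size, downsampling plan -- are constrained by six exact
integer equations.  An exhaustive exact search over the architecture
families expressible by this package (width-preserving, reduced and
expanded branch widths; branch kernel sets (3,3), (3,5), (3,5,7),
(3,3,3); with and without the identity branch; second stage-4 block
widths tied to the concat, the stage input or the branch; 0--60 residual
convolutions per stage; every monotone downsampling plan including
pooled-between-stages layouts; head variants with and without batchnorm;
pool sides 1/2/4/7; biased and bias-free depthwise stages; widths 16--2048)
found no configuration satisfying all six equations simultaneously.  The
package therefore ships `omnetConfig()` defaults that are representative
of the family at the published scale, documents the decomposition above
as the family's verified structural fingerprint, and leaves the
printed-total checks failing rather than adjusting any number toward
them.  The residual-network compression column, which is fully
specified, reproduces to the printed precision.

## The synthetic leaf-image generator

`generateLeafDataset` writes directory-per-class PNG folders
(train/val/test) of procedurally rendered leaves: an elliptical leaf mask
over a dark backdrop, seeded value-noise texture (bilinear interpolation
of a coarse random lattice -- no external texture assets), vein strokes,
and class-motif lesions.  Each class's motif fixes lesion count, radius
range, hue, saturation and ring-versus-blotch shape.  The default motifs
render a severe-disease appearance -- many large, strongly colored lesions
with well-separated hues -- so that classes differ as visibly as the
species/disease classes of real leaf photo benchmarks do; all class
signal flows through the lesions, so setting `lesion_contrast = 0`
removes it entirely (a trained classifier is then statistically
indistinguishable from chance, which the tests check with a binomial
test).  Generation is bit-deterministic in (spec, seed); class imbalance
is available through a per-class count vector.

What the generator does *not* emulate: photographic nuisance variation
(lighting, pose, camera), mixed symptoms, background clutter, and the
fine-grained within-class heterogeneity of real surveys.  Passing the
desk-scale tests therefore demonstrates that the pipeline's mechanics --
data loading, training, evaluation, cost bookkeeping -- are sound, not
that any model generalizes to real disease imagery.

## Training and evaluation harness

The recipe is the study's: AdamW (decoupled weight decay on convolution
and dense weight matrices only), learning rate $10^{-4}$, weight decay
$5 \times 10^{-2}$, cross-entropy, 100 epochs by default, no pre-trained
weights; optional augmentations are random resized crop, rotation in
$[-10^\circ, 10^\circ]$, horizontal flip with probability 0.5; pixel
values are scaled to $[0,1]$ with no mean/std standardization.  "Epochs"
is the reading of the recipe's iteration count, consistent with the
training-curve descriptions.  Batch size is not part of the published
recipe; the package default is 32, and smoke-scale runs on the 120-image
synthetic training split use 8 or 4 (at batch 32 an epoch is only 4
gradient steps, degenerate both for batch-norm statistics and for step
counts).  The augmentation stack is applied to one benchmark in the study
and explicitly not to the other; smoke runs use the no-augmentation mode,
and "train accuracy" in the overfitting check means accuracy on the train
split evaluated after training (eval-mode batchnorm), not the running
accuracy over augmented batches.

Evaluation computes overall sample accuracy, one-vs-rest per-class
TP/FP/FN/TN, precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, F1 as their
harmonic mean, macro averages (micro available via a flag -- the tables'
distinct accuracy and precision values imply per-class aggregation, and
macro is the adopted reading), the confusion matrix, and per-class
ROC/PR curves with trapezoidal AUC.  All of it is cross-checked against
a brute-force pair-counting oracle and, for AUC, against an independent
implementation.

The executor behind training is a plain im2col-based reference
implementation (R arrays + BLAS); gradients of every layer kind are
verified against numeric differentiation in the tests.  It is sized for
the desk-scale models: the smoke model is the $N=2, E=2$ derivative of
`omnetTinyConfig()` (16-channel stem, stages 16/16/32/32, 256-wide head
pooled to $2 \times 2$), which reaches $\ge 95\%$ train-split accuracy in
15 epochs on the default 4-class synthetic set.

## Numerical choices and degenerate inputs

* Counts use doubles as exact integers (all quantities $\ll 2^{53}$);
  ratios are reported as $100 \cdot \text{variant}/\text{base}$ rounded
  half-up to two decimals, and "M" formatting is value$/10^6$ rounded
  half-up to two decimals (plain `round` would round half to even).
* Pruning uses the real-valued guard $C/N > 1$ and floors the quotient;
  width-1 results are representable but unreachable through the guard.
* Batchnorm uses $\epsilon = 10^{-5}$; with unit statistics it is the
  identity up to that epsilon.
* The adaptive average pool follows the floor/ceil region convention, so
  any input side is valid; max pooling with fractional output sides is
  rejected during shape propagation.
* Degenerate graphs -- junction width mismatches, non-positive spatial
  sizes, grouped-but-not-depthwise convolutions -- fail loudly with the
  offending layer named.

## Known limitations

* The executor is a reference implementation; it is not intended for
  224-resolution training of the full-width family on CPU.
* Magnitude-based or data-driven pruning is out of scope by design: the
  pipeline's point is that the rule is purely structural.
* Weight transplantation between pruned and unpruned widths is not
  supported; after structural rewrites, training restarts from fresh
  initialization (path expansion is the one exception, by construction).
* The two inconsistent single-path cells of the published family tables,
  discussed above, are not reproduced.
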