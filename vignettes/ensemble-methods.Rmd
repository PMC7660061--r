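---
title: "Ensemble CNN triage of endoscopy frames: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble CNN triage of endoscopy frames: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EndoEnsemble)
```

## The problem

Gastrointestinal endoscopy produces long streams of still frames, most of
which show unremarkable tissue. Triaging frames into *with* and *without a
pathological site* (PS) — a polyp or a region of complex vascular pattern —
lets clinicians concentrate on the frames that matter. EndoEnsemble
implements a full desk-scale version of such a triage pipeline:

1. **Background removal.** Endoscopic frames carry a dark, uninformative
   border around the bright tissue foreground. The per-row and per-column
   mean gray levels (projection profiles) are thresholded at a fraction of
   their own maximum, and the frame is cropped to the spanned region.
2. **Three CNN classifiers.** A VGG-style linear convolution stack, an
   inception-style network (parallel 1x1 / 3x3 / 5x5 convolutions plus
   max-pool, concatenated), and a DenseNet-style network (each layer fed by
   the concatenation of all preceding outputs). Each ends in the same head:
   flatten, dropout, and a dense layer to 2 units with a softmax, producing
   a score vector \(S_i = (S_{0i}, S_{1i})\).
3. **Score fusion.** MAX (argmax of the largest single entry across
   members), AVERAGE (argmax of the component-wise mean), and VOTING
   (majority of member decisions, each member voting \(w_i = +1\) when its
   argmax is class 1 and \(-1\) otherwise).
4. **Evaluation.** Sensitivity \(=100\,TP/(TP+FN)\), specificity
   \(=100\,TN/(TN+FP)\) and accuracy \(=100\,(TP+TN)/(TP+TN+FP+FN)\) per
   patient-disjoint fold, combined across the two folds by a
   testing-size-weighted average; ROC curves plot GAR \(=100-\mathrm{FRR}\)
   against FAR, averaged over folds on a common FAR grid.
5. **Explanation.** Gradient-weighted class activation maps highlight the
   image regions driving a decision.

A synthetic endoscopy-frame generator stands in for real data, so every
stage of the pipeline — including training — runs in seconds to minutes on
one CPU.

## A note on the voting rule

Written literally as a sign over \(\sum_i w_i \cdot \mathrm{argmax}(S_i)\),
every negative vote would be annihilated (\(w_i \cdot 0 = 0\)) and a single
positive member would always win. The rule is, however, a majority vote:
the package computes \(\mathrm{sign}\left(\sum_i w_i\right)\). A zero sum —
possible only for even ensemble sizes — falls back to the AVERAGE rule on
the same score vectors. Argmax ties anywhere in the pipeline resolve to the
positive class by default (`tieBreak = "positive"`): for a screening tool a
spurious positive is cheaper than a missed lesion. Both choices are
configurable.

## Paper-scale and tiny model profiles

`buildClassifier()` exposes two scales.

**Paper scale** builds the canonical published feature extractors on
224x224x3 inputs — the VGG16 convolution stack (13 biased 3x3 convolutions,
output 7x7x512), the DenseNet-121 extractor (bias-free convolutions, batch
norm with scale/shift and moving statistics, output 7x7x1024) and the
Inception-v3 extractor (bias-free convolutions, scale-free batch norm,
output 5x5x2048 at this input size). These models exist for *architecture
accounting*: they are built shape-only, and `countParameters()` counts
every stored array, including non-trainable batch-norm moving statistics —
the convention under which the published sizes (14,714,688 / 7,037,504 /
21,802,784 parameters, heads of 50,178 / 100,354 / 102,402) are stated and
which the package reproduces exactly.

```{r}
vgg <- buildClassifier("vgg", scale = "paper")
countParameters(vgg)
```

**Tiny scale** builds trainable models on 64x64 inputs from the same three
motifs: a four-convolution linear stack; a stack containing a naive
inception block (branch widths 8/8/8 over 16 input channels); and a stack
containing a dense block (growth 8, four layers). All three end at a 4x4x32
feature map so the heads have identical capacity (512 inputs to 2 units).
The training engine (im2col convolutions, Adam, softmax cross-entropy,
backprop through the concatenation blocks) is implemented in the package
with Rcpp/Armadillo and is verified against finite-difference gradients in
the test suite.

## Training recipe and its desk-scale adaptation

`trainConfig()` defaults to the published recipe: Adam, 30 epochs, initial
learning rate \(10^{-4}\), batch size 32, and a time-decay schedule
\(\mathrm{lr}(e) = \mathrm{lr}_0 / (1 + d\,e)\) applied every epoch. The
decay constant is not fixed by that recipe; the default is \(d = 0.1\).

The published runs processed thousands of minibatches; a 200-frame
desk-scale run sees only about 200. Two adaptations make the tiny profile
trainable in that budget, decided once during engine bring-up:

* built classifiers center their \([0,1]\) inputs to \([-0.5, 0.5]\) before
  the first convolution (the `inputCenter` slot), and
* desk-scale runs pass `initialLr = 3e-3` — roughly scaling the rate by the
  reduction in optimizer steps, with every other recipe field unchanged.

With both in place, all three tiny architectures reach over 99% training
accuracy on 200 synthetic frames in 30 epochs; without them the same runs
plateau near chance.

## The synthetic generator: what it emulates, and what it does not

Each generated frame has a dark border band (mean gray level below 15/255
of full scale) around a bright noisy interior (default mean 150, sd 15 on
the 0-255 scale), mimicking the low-illumination background of endoscopic
stills; a luma-preserving reddish tint gives the frames an endoscopy cast
without disturbing any gray-level contract. Positive frames carry one of
two lesion phenotypes inside a recorded bounding box: a polyp-like bright
elliptical blob with a Gaussian profile (amplitude 30-60 gray levels above
the local mean) or 3-8 vascular-like dark random-walk strokes (30-60 levels
below). Frames are grouped into sequences with one tab-separated annotation
file per sequence (`frame_id x y w h`, negatives as `-1 -1 -1 -1`), and
generation is keyed per frame by (seed, sequence, frame index), so datasets
are byte-reproducible and any frame can be regenerated alone.

The generator deliberately does **not** model photorealistic tissue
texture, specular highlights, motion blur, video compression, instrument
shadows, or the trapezoidal field masks of real capture devices — its
border is rectangular, which suffices to exercise projection-profile
cropping. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that the protocol arithmetic is exact; they do
not certify classification performance on real endoscopy data, whose
difficulty (ambiguous lesions, inter-patient variation) the generator does
not reproduce.

## Numerical choices

* **Grayscale** uses BT.601 luma (0.299, 0.587, 0.114).
* **Profile threshold** defaults to 0.10 of each axis's own profile
  maximum; per-axis thresholds make the crop robust to exposure
  differences. A frame with an all-zero profile falls back to the full
  frame with a flag. Raising the fraction can only shrink the crop.
* **Crop coordinates** are 0-based and half-open; resizing is bilinear;
  intensities are kept as x/255 in \([0,1]\). Residual dark corners inside
  the crop are tolerated.
* **Rounding** of reported metrics is half-up to three decimals; all
  internal arithmetic is unrounded. Fold averages weight sensitivity by the
  folds' positive test counts, specificity by the negative counts and
  accuracy by the totals — the only weighting under which the average of
  fold metrics equals the metrics of the pooled confusion counts (an
  identity the tests assert).
* **ROC scores** for the discrete rules: AVERAGE uses the mean \(S_1\);
  MAX the \(S_1\) of the member holding the globally largest entry; VOTING
  maps the vote sum onto \([0,1]\) as \((\sum w_i + n)/(2n)\).
* **Grad-CAM** draws from the model's last convolutional stage by default
  (configurable by layer name), uses the raw class logit as the target
  score, rectifies the weighted sum before upsampling, and min-max
  normalizes; an identically zero rectified map is returned as zeros with a
  flag rather than divided by zero.

## The two-fold protocol

Sequences are ordered; fold 1 trains on the first half and tests on the
second, fold 2 exchanges them. Because one sequence is one patient, no
patient ever straddles a split. `runTwoFold()` refuses folds whose test
partition contains a single class, trains each member per fold, applies
each rule, and reports per-fold rows plus the weighted averages:

```{r, eval = FALSE}
dir <- tempfile()
generateDataset(10, 20, positiveFraction = 0.5, seed = 1, outDir = dir)
report <- runTwoFold(dir, config = trainConfig(initialLr = 3e-3, seed = 1))
reportTable(report)
```

The default desk-scale problem size used throughout the package's checks is
10 sequences of 20 frames (200 frames, half positive), the size at which
the whole two-fold run with three members trains in a few minutes on one
CPU.

## Known limitations

* Paper-scale models are not meant to be trained here: no pretrained
  weights are shipped, and a 21.8M-parameter forward pass in this engine is
  slow. They serve accounting, shape propagation and, if materialized,
  small numeric checks.
* The engine is single-threaded and CPU-bound; it is sized for tiny models
  on 64x64 inputs, not for GPU-scale replication of published accuracies on
  real data.
* `accuracyFromRates()` applied to 3-decimal printed rates carries up to
  0.001 of rounding error relative to count-level accuracy; comparisons at
  that precision must allow for it.
* The voting fallback makes even-sized ensembles depend on the AVERAGE
  rule in tied cases; odd ensemble sizes (the default three) never hit it.
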