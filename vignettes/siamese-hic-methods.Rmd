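---
title: "Replicate-aware Siamese metric learning for differential chromatin conformation"
author: "SiameseHiC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware Siamese metric learning for differential chromatin conformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Hi-C and Micro-C contact maps carry high, spatially non-uniform noise, so
naive image-similarity metrics struggle to tell technical variation from
biological change. SiameseHiC learns the distinction from the data itself:
two identical convolutional encoders with shared weights embed co-located
map windows, and contrastive learning pulls *replicate pairs* (two
replicates, one biological condition; label 0) together while pushing
*condition pairs* (two different conditions; label 1) beyond a margin. The
learnt Euclidean embedding distance is then a noise-calibrated dissimilarity
over the genome.

The encoder is a LeNet-style stack: two convolutional stages (6 and 16
filters of 5x5, each followed by 2x2 max pooling), then fully connected
layers 120 -> 84 -> `embed_dim`. GeLU activations replace ReLU because
contact-map windows are sparse and ReLU units die. The diagonal band
`|i - j| < mask_bins` (default 3 bins, i.e. 3R = 30 kb at R = 10 kb) is
zeroed at the model input: the near-diagonal is dominated by signal that is
uninformative for comparing windows.

Training minimises `2*L1 + L2`, where `L1` is the standard contrastive loss
on the embedding distance `d` (label 0: `d^2`; label 1: `max(0, m - d)^2`)
and `L2` is a binary cross-entropy on a single linear head over the signed
embedding difference `e_a - e_b`, used as a regulariser and symmetrised by
averaging both pair orderings. Batches of 128 pairs are drawn from training
chromosomes; chromosome 18 is held out for validation and chromosome 2 for
testing. Training runs at least 5 epochs and halts when the validation
contrastive loss exceeds 1.1x the best value seen; the best-validation
weights are restored.

## Data processing

Windows of `window_bins` bins (default 256, span `S = window_bins * R`) are
cut along the diagonal with a stride of `window_bins/16` bins by default
(160 kb for a 2.56 Mb window at 10 kb), so the number of anchors is
conserved across a resolution sweep. Uncleaned windows are filtered: a
window is dropped when its missing-value count exceeds its nonzero count or
when more than 10% of its rows are entirely missing-or-zero ("positions with
no information"); surviving windows are cleaned by zeroing missing values
and dividing by the window maximum. Filtering precedes cleaning because
cleaning destroys the missing-value counts the filter needs.

Contact matrices are read from a dense whitespace matrix with a JSON
side-car header. There are no R HDF5 bindings in the supported environment,
so `.cool`/`.mcool` containers are not read directly; export to dense text
(e.g. `cooler dump`) first. Raw counts can be ICE-balanced in-package
(iterative correction to equal row sums, zero-coverage bins masked); KR/VC
balancing is consumed only as precomputed values, since the method is
insensitive to the normalisation choice.

## Evaluation statistics

Distances for an evaluation split are summarised two ways:

* **Mean performance.** A classification threshold is fit where the
  replicate and condition KDE densities cross, using train+validation
  distances only, then frozen. On the evaluation split, the replicate rate
  (fraction of replicate distances below threshold) and condition rate
  (fraction above) are averaged unweighted, which corrects the 1:2 imbalance
  between replicate and condition pair counts.
* **Separation index.** One minus the overlap integral
  `integral(min(p_rep, p_cond))` of the two KDE densities: 1 for disjoint
  distributions, 0 for identical ones.

KDEs use Scott's rule bandwidths per sample and a shared 512-point grid
spanning both samples padded by three bandwidths; the overlap integral is
trapezoidal. Degenerate (zero-variance) samples fall back to the midpoint
rule for the threshold. These estimator details are package choices — the
statistics themselves do not pin them down — and are recorded here so that
reported numbers are reproducible.

Per-locus distance tracks pool label-0 and label-1 distances at each anchor
with percentile-bootstrap 95% confidence intervals (1,000 resamples,
seeded). Peak-density stratification counts user-supplied intervals (e.g.
cohesin ChIP-seq peaks) per window span and compares high- versus
low-density loci with a two-sided two-sample t-test.

## Feature extraction

Each window passes through the convolutional stages only; co-located
windows' stage-2 feature maps (16 maps of side 61 for a 256-bin window) are
subtracted, averaged over filters, mapped back to genome scale, and
amalgamated across overlapping windows by coverage-weighted averaging. The
label-0 pairings average into a *replicate map* (what pure technical noise
produces under the identical pipeline) and the label-1 pairings into a
*condition map*, oriented second-condition-minus-first so the sign of a
feature means gained or lost.

The condition map is thresholded at the 95th percentile of the absolute
replicate map; connected components (8-connectivity) are filtered by the
size rules (drop if smaller than 50 kb in both dimensions, or larger than
2.56 Mb — the window span — in either); convex hulls regularise the shapes;
hull masks are rescaled (aspect-preserving, nearest-neighbour, centred in a
32x32 image) and clustered by seeded k-means with k = 10. Cluster mean
images are written for manual grouping into domain-like /
asymmetric-domain-like / stripe categories; an automated heuristic
(bounding-box aspect ratio >= 3 -> stripe; transpose-symmetric image ->
domain-like; else asymmetric) is opt-in and labelled as a heuristic.

Two numerical choices deserve note. The conv-to-genome back-mapping is not
determined by the architecture; the package anchors each conv cell at its
receptive-field centre (cumulative stride 4, receptive field 16 for the
default stack) and interpolates bilinearly between anchors. Bilinear rather
than nearest-neighbour matters: block-replicating each conv cell quantises
single-cell noise into 4x4-bin (40 kb) squares that slip past the 50 kb size
filter, flooding a null comparison with spurious features. The "0.95th
percentile" of the published recipe is read as the 95th percentile — a
0.95th percentile would flag essentially every cell.

## The synthetic stated world

The generator builds multi-replicate, multi-condition experiments from an
expected-contact model: power-law distance decay `(|i - j| + 1)^-alpha`
with `alpha = 1`, multiplicative planted features (domains, asymmetric
domains, stripes, loops), and independent Poisson sampling of each
replicate at a stated sequencing depth (seeds derived deterministically per
condition/replicate/chromosome from one master seed). Poisson counting
noise is the simplest model that reproduces depth-dependent sparsity;
overdispersion can be emulated by lowering depth.

Defaults describe a deliberately strong, cohesin-loss-like perturbation:
three 1,000-bin chromosomes at 10 kb (chr1 trains, chr18 validates, chr2
tests), 1e6 contacts per replicate and chromosome, background TADs tiling
each chromosome in both conditions, and five differential features per
chromosome (four large domains, 1.1-1.2 Mb, fold change 2, alternating
gained/lost; one gained stripe) at fixed fractional positions jointly
covering ~86% of window anchors. This mirrors the regime where the method's
published benchmark is strongest — loss of a cohesin loading factor changes
domains across most of the genome — and it is the regime in which a
desk-scale network can be expected to separate conditions. The generator
does *not* emulate A/B compartment plaids, GC/mappability bias, or
translocations; a green synthetic test therefore establishes that the
pipeline learns planted conformation differences over Poisson noise, not
that it handles every artefact of real libraries.

With 64-bin windows (the desk-scale default), ~14% of test anchors overlap
no differential feature, so condition pairs there are statistically
replicates; the separation index on the full test split is bounded near
0.86 by construction, and measured values around 0.8 reflect that ceiling
plus KDE smoothing, not a training failure.

## Optimisation choices

The published recipe fixes learning rate 0.01 and batch 128 but not the
optimiser, margin, initialisation or embedding dimension. Package defaults:

* **Optimizer: Adam (0.9/0.999), lr 0.01.** With fan-in uniform
  initialisation, GeLU and max-normalised sparse inputs, the embedding
  distances start collapsed near zero; plain SGD at lr 0.01 moves the
  validation contrastive loss by ~1e-4 over 15 epochs — it cannot leave the
  plateau at any feasible budget. Adam trains in a handful of epochs. SGD
  (with optional momentum) remains available via `trainConfig(optimizer =
  "sgd")` for fidelity experiments.
* **Margin 1.0.** Cleaned inputs lie in [0, 1], keeping distances O(1).
* **Embedding dimension 8.** The terminal 10-way LeNet layer is a
  classifier head, not an embedding; a small dimension keeps the Euclidean
  metric well-behaved. Configurable.
* **Early-stop baseline: best validation loss so far** (robust reading of
  "increases by more than 10%"); comparison to the previous epoch is a
  config switch.
* **Initialisation: fan-in uniform** `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
  with a recorded seed.

## Degenerate inputs and tie-breaks

All-zero windows clean to all-zero (no division by zero) and embed to a
finite vector. Zero-variance distance samples use the midpoint threshold.
In the contrastive gradient the hinge coefficient at `d = 0` is taken as 0
(subgradient). Max-pool ties resolve to the first maximum in column-major
order. k-means uses 10 restarts under a recorded seed; when fewer distinct
shapes than clusters exist, each distinct shape gets its own cluster and the
rest stay empty.

## Known limitations

Interchromosomal contacts and separations beyond the window span are out of
scope, as are `.hic` containers, KR/VC balancing, integrated-gradient
attribution and compartment/TAD callers used for orthogonal validation in
the source study. The depth-robust pairing mode prevents the network from
*separating* groups by sequencing depth, but an efficient optimiser can
still shrink the contrastive loss toward its inseparable-mixture optimum by
inflating all distances uniformly — non-learning controls should therefore
be judged on the separation index, not on the raw loss trace.
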