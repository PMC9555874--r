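---
title: "Reference-free genotype imputation with segment autoencoders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free genotype imputation with segment autoencoders: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daeimpute)
```

## The problem

Genotype imputation infers the genotypes of unobserved variant sites from a
small assayed subset (typically 1–5% of known sites, as on genotyping
arrays), exploiting linkage disequilibrium (LD): nearby variants are
inherited together in haplotype blocks, so a handful of observed markers
carries information about thousands of neighbors. The standard tools are
hidden-Markov-model methods that need runtime access to a large sequenced
reference panel. `daeimpute` takes the alternative route of training one
sparse denoising autoencoder per genomic segment on the reference panel
once; imputation afterwards needs only the trained weights. The model file
is small, portable, fast to evaluate, and — because the panel is only seen
at training time — free of the privacy and logistics burden of shipping
reference genotypes.

## Genotype encoding

Each bi-allelic SNP contributes two binary input nodes recording the
presence of the reference and the alternate allele:

| genotype | encoding |
|---|---|
| hom-ref  | (1, 0) |
| het (either order) | (1, 1) |
| hom-alt  | (0, 1) |
| missing / masked | (0, 0) |

The (0,0) null pattern doubles as the corruption state of the denoising
task. The output layer mirrors the input under a sigmoid, giving a
presence probability pair `(p_ref, p_alt)` per site. These are split into
three genotype scores — hom-ref `p_ref (1 - p_alt)`, het `p_ref p_alt`,
hom-alt `(1 - p_ref) p_alt` — and normalized to class probabilities. Two
constructions were open here. First, a softmax could normalize the three
outputs; since the sigmoid outputs are already
probability-scaled, exponentiating them again double-squashes the scores,
so the default is proportional normalization and a `softmax = TRUE` switch
provides the exponential construction. Second, the fourth product
`(1 - p_ref)(1 - p_alt)` corresponds to the null state and is dropped
before normalizing: imputation must emit a genotype. Alternate-allele
dosage is `P(het) + 2 P(hom-alt)`.

Phase is ignored throughout: inputs are unphased and no pre-phasing is
performed.

## Penalized focal loss

Reference alleles vastly outnumber alternate alleles at the rare-variant
sites that dominate sequencing panels, so plain cross-entropy lets the
network earn most of its reward by predicting "reference everywhere". The
reconstruction loss is therefore a focal loss: with `q_t` the probability
the model assigns to output node `t`'s truth class,

$$FL = -\sum_t \alpha_t (1 - q_t)^{\gamma} \log q_t$$

The modulating factor `(1 - q_t)^gamma` down-weights well-classified
nodes; `gamma = 0` recovers cross-entropy exactly. The factor is applied
to the truth-class probability `q_t`, not to the raw presence output:
for truth bit 1 the two coincide, and for truth bit 0 only the
truth-class form has the defining focal property of down-weighting
well-classified nodes monotonically. `alpha_t` is set per node to the batch frequency of that
node's truth class; note this *down*-weights rare truth classes, the
opposite of the usual focal-loss convention, so
`alpha_mode = "inverse"` provides the conventional variant.

The full objective adds three penalties encouraging simple, sparse models:

$$SFL = FL + \beta\, S(\rho \| \hat\rho) + \lambda_1 \lVert W \rVert_1 + \lambda_2 \lVert W \rVert_2$$

where `S` is the Bernoulli KL divergence between a target mean hidden
activation `rho` and the observed batch mean `rho_hat` (summed over
batches), and the weight penalties are the absolute and squared sums over
all weight matrices (biases excluded). The L2 term is implemented as the
sum of squares (ridge), matching its description as ridge regularization
even though the formula's norm notation could be read as the square root.
`rho_hat` pools all hidden layers; tanh activations are affinely mapped to
[0, 1] before the KL, and unbounded activations (relu, softplus) are
clamped into (0, 1) by the penalty's epsilon guard. Gradients of every
term, including the sparsity path through the batch-mean activation, are
analytic and verified against central finite differences at tolerance
1e-4 in the test suite.

## Network architecture and training

Each segment's autoencoder is fully connected: input width `2m` for `m`
variants, an encoder of `n_hidden_layers` layers each
`round(previous * size_ratio)` wide (floor 2), a mirrored decoder sharing
the bottleneck, and a sigmoid output of width `2m`. Weights are seeded
uniform Glorot-style; optimizers are adam, rmsprop, or plain sgd, with the
learning rate multiplied by `lr_decay` every 500 epochs (`lr_decay = 0`
is treated as "no decay": a literal zero multiplier would freeze training
after the first 500 epochs, which cannot be the intended meaning of a
decay grid that pairs 0 with long runs).

Training follows an escalating-masking curriculum. Each cycle of
`epochs_per_cycle` epochs masks, per sample and per batch draw, a fresh
uniform subset of variants to the null encoding at the cycle's rate; rates
rise linearly from 0.80 in cycle 1 to `(m - 5)/m` in the final cycle, so
the hardest cycles leave only five variants observed. Masks are re-drawn at every batch and per sample — the maximal
augmentation granularity. Training stops early when a cycle's mean total
loss fails to strictly improve on the previous cycle's — note that because
later cycles are intrinsically harder, this stop can fire while the
network is still improving at fixed difficulty; its role is to bound
compute, not to locate an optimum. The escalation is linear by default with a
geometric option.

## Genome tiling

Whole chromosomes are too wide for one dense network, and LD structure is
approximately block-diagonal anyway, so the genome is tiled at
recombination hotspots. On common variants (MAF ≥ 0.5%), Pearson
correlations of dosage vectors are computed for all pairs within a 500-SNP
half-window and thresholded at |r| ≥ 0.45 (strength, not sign). Each SNP's
*box count* — the number of retained pairs wholly inside its window —
measures local LD strength; hotspots appear as deep local minima. Against
count noise the curve is smoothed with a centered moving average (width
11 SNPs), plateau minima collapse to their midpoint, and a minimum
qualifies as a hotspot only if its smoothed count falls below
`hotspot_frac` (default 0.25) of the smaller adjacent region peak, with
minima closer than one box half-width merged to the deeper one. This
prominence rule is the package's noise policy for minima detection, and
is what makes segment counts match planted block counts on synthetic
panels.

Each segment is a high-LD core plus the adjacent weak-LD flanks, a flank
extending from the hotspot minimum outward while counts stay below 10% of
the neighboring core's peak; neighboring segments therefore overlap on the
shared weak region. Segments beyond 6000 SNPs are split at their deepest
internal minima, and any remainder is sliced into fixed 6000-SNP windows
advancing by 3500 (2500-SNP overlap). Rare variants, excluded from the
correlation stage, are assigned to the segment(s) of their nearest common
variant so that every modeled site is covered.

## Offspring augmentation

Training panels are expanded with simulated offspring. Unphased parents
are pseudo-phased once (random phase per heterozygous site, seeded); each
offspring draws two distinct parents, and each transmitted gamete is a
recombinant mosaic of that parent's two haplotypes with a
Poisson(total cM / 100) crossover count placed uniformly on the genetic-map
(cM) scale — no interference, matching the behavior of standard pedigree
simulators at this scale. Offspring are re-collapsed to unphased
genotypes and merged with the originals. Recombination can only break
associations, so offspring LD is bounded by parental LD while allele
frequencies are preserved in expectation — both properties are tested.

## Hyperparameter search and the performance meta-model

A coarse random grid search draws distinct combinations from the default
grid's value lists (L1/L2 scales 1e-8…1e-1, sparsity scale 0…10, target
activation 0.001…1, four activation functions, learning rates 1e-6…100,
gamma 0…5, three optimizers, two loss types, 1–8 hidden layers, size
ratios 0.2…1, decay ratios 0…0.9999) and scores each by mean per-variant
dosage r² on a masked validation panel. Because training every candidate
everywhere is wasteful, a gradient-boosted regression forest (XGBoost,
default settings, 100 rounds, 10-fold CV with folds stratified by
segment) learns to predict validation r² from the one-hot-encoded
hyperparameters plus segment descriptors: variant count, mean
recombination rate, mean absolute pairwise correlation, MAF-bin
proportions and the rare/common split, the number of principal components
for 90% of dosage variance, the variance explained by the first two
components, unique haplotype and diplotype counts, and mean
heterozygosity. The top 10 predicted candidates plus the best observed
combination (deduplicated) advance to fine-tuning. The feature binning is configurable; the default reuses the eight
evaluation bins plus a <0.5% rare bin.

## Evaluation

Accuracy is the squared Pearson correlation between imputed and true
dosages per variant (undefined for zero-variance vectors — such variants
are excluded from means but counted), aggregated overall, per segment,
and across the eight MAF bins
[0.001,0.005), [0.005,0.01), [0.01,0.05), [0.05,0.1), [0.1,0.2),
[0.2,0.3), [0.3,0.4), [0.4,0.5] (half-open, last closed; below 0.001
reported separately as ultra-rare; MAF is computed on the truth panel).
Hard calls are additionally scored by concordance and by F1 macro-averaged
over the three genotype classes — the stricter F1 variant for imbalanced
genotype data.
Method comparisons count per-segment wins, test the two accuracy samples
with a two-sided Wilcoxon rank-sum test, and compare win fractions with a
pooled two-proportion z-test.

At inference, observed markers are matched to model variants by exact
(chrom, pos, ref, alt) identity — no strand-flip rescue, since silent
strand errors corrupt imputation — unobserved model variants enter as
nulls, and variants covered by several overlapping segments average their
class probabilities before renormalization — the arithmetic mean is the
neutral combination rule for equally trusted overlapping models.
Observed genotypes pass through to the output unchanged and are flagged
`genotyped`; written VCFs carry GT, GP (three probabilities, six decimals,
residual-corrected so each printed triple sums to exactly one), DS, and an
`IMPUTED` INFO flag.

## The synthetic panel generator

All tests and the acceptance script run on synthetic panels, so the
generator defines the study conditions. Haplotypes are built per LD block
from a two-founder split: an exact fraction `q` of haplotypes (drawn per
block from U(0.15, 0.5)) carries one founder pattern, and independent
per-site noise at rate `(1 - sqrt(r2))/2` tunes the expected pairwise
correlation to the requested within-block r² (`r2 = 1` gives perfect LD).
A configurable fraction of block sites (default 0.4) are instead
independent rare variants with MAF drawn from a Beta(0.4, 8)-shaped
spectrum truncated to [0.001, 0.05], reproducing the rare-heavy site
frequency spectrum of sequencing panels; blocks are separated by
independent common "gap" variants forming LD-free hotspot regions.
Carrier counts are drawn exactly (rounded `f x H` carriers) so realized
frequencies sit tight on their targets. Array-style masking keeps a
MAF-biased subset observed, as real arrays tag common SNPs.

What this emulates — block LD, hotspots, skewed MAF, array masking — is
what the method's machinery consumes. What it does not emulate: gradual
LD decay within blocks, mutation/genotyping error, population structure
and admixture, multi-founder haplotype diversity. Passing tests therefore
demonstrate the correctness of the algorithms and the presence of the
learning signal, not field accuracy on human cohorts.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with comfortable margins: tiling recovery on
2–5-block panels of 40-variant blocks and 200 haplotypes with a 12-SNP box
half-width; the end-to-end benchmark on 1000 haplotypes x 200 variants
(four blocks, r² 0.9), training a single-hidden-layer relu/adam
cross-entropy autoencoder for up to five 60-epoch cycles at batch 256 and
imputing 100 held-out samples from a 95% mask; offspring checks with 3000
simulated genomes over 30 variants; and a 300-point response surface for
the meta-model. Probabilities entering logs are clamped at 1e-7; ties in
output genotypes break toward fewer alternate alleles; fixed seeds flow
from a single root through named substreams, and identical seeds
reproduce byte-identical artifacts and manifests.

## Known limitations

Bi-allelic SNPs only; no indels, no multi-allelic sites, no phasing, no
chromosome-X/ploidy handling. The default focal-loss alpha follows the
truth-class-frequency convention, whose direction is arguably inverted
relative to common focal-loss practice; both conventions are available. The
early-stop rule compares cycles of different masking difficulty. Training
is single-threaded CPU R — appropriate for the package's segment sizes
and for methodological study, not for chromosome-scale production
training.
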