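---
title: "Modeling 3' cleavage and alternative polyadenylation with polyacode"
author: "polyacode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 3' cleavage and alternative polyadenylation}
  %\VignetteEncoding{UTF-8}
---

# Scope

polyacode is a desk-scale toolkit for sequence-based modeling of 3'-end
cleavage and polyadenylation (pA). Its core is a dilated residual
convolutional network that maps a 205-nt polyadenylation signal (PAS) to a
base-resolution 206-way cleavage distribution, where the last bin carries
the total isoform mass of a far-away distal competitor. Around that core sit
the standard layers of a variant-interpretation workflow: isoform log odds
ratio (LOR) scoring of wildtype/variant pairs, pairwise and masked-softmax
multi-PAS isoform regression, condition-specific residual models,
mask-based ("scrambling") attribution of variant effects, population-scale
saturation screening, and UMI-based quantification of 3'-end MPRA reads.

Everything is trainable and testable without external data: a synthetic
module generates all inputs under a known ground-truth cleavage law, so
every downstream fit can be scored against planted parameters. This
vignette documents the models, the choices behind the defaults, and what
the synthetic benchmarks do and do not establish about real data.

# The cleavage model

A PAS sequence is one-hot coded as $x \in \{0,1\}^{205\times4}$ and passed
through `n_groups` residual groups of `blocks_per_group` residual blocks.
Each block applies two batch-normalized, ReLU-activated dilated
convolutions and adds the block input back through an unweighted skip; all
blocks in a group share one dilation rate. At the defaults the network has
7 groups of 4 blocks (28 blocks) with dilation schedule 1, 2, 4, 8, 4, 2, 1,
32 channels and width-3 filters, so the receptive field covers the full
input window. After each group an extra skip connection feeds the
accumulated feature map to the output head.

The head produces one logit per sequence position through a width-1
convolution, plus a distal logit from global average pooling, and adds a
learned positional bias and a per-sub-library additive intercept
($W \in \mathbb{R}^{206\times13}$; the MPRA that motivates this design
mixed 13 reporter 3' UTR contexts, and the library term absorbs their
context-specific baselines without touching the sequence pathway). A
softmax over the 206 logits yields the cleavage distribution $\hat y$. The
library enters additively on the logit scale only: the difference of logits
between two library settings is independent of the sequence, which the test
suite asserts.

Two head choices deserve a note. The zero-initialized head makes an
untrained model output the uniform distribution over 206 bins, which gives
training a calibrated starting point and gives tests an exact anchor. The
learned positional bias supplies the coordinate information that a purely
convolutional (translation-equivariant) trunk lacks; with all training
records aligned at a fixed core-hexamer (CSE) offset, the positional
profile of cleavage is then learnable even by small trunks.

## Loss

Training minimizes, per record, the KL divergence between the measured and
predicted 206-way distributions,
$\sum_k y_k \log(y_k/\hat y_k)$, plus a binary-KL consistency term on the
summed isoform mass over a fixed window (0-based positions 79-109; all
printed 1-based coordinates - the CSE at position 70, the reporting window
77-127, the consistency window 80-110 - are converted to 0-based indices in
exactly one place, `lossWindows()`). Predictions are clamped to $\ge
10^{-12}$ inside logarithms and $0\log 0$ is treated as zero, so targets
with empty bins are handled exactly. The proximal isoform proportion is
reported either as the sum over the 0-based 76-126 window ("windowed") or
as everything except the distal bin ("any_not_distal"); variant scoring
uses whichever convention the downstream dataset defines.

## Training

Mini-batch Adam (batch 64, learning rate $10^{-3}$, 5 epochs by default)
on count-derived empirical proportions. All forward/backward passes are
hand-written on top of BLAS matrix products with compiled kernels for the
shifted convolutions and fused batch-norm/ReLU; the unit tests validate
every gradient against central finite differences. Batch norm uses batch
statistics during training and running statistics (momentum 0.9) in
evaluation; the mode is explicit in the API.

Joint shift augmentation (`shiftAugment`, up to 15 nt either way) moves
the sequence and the 205 positional target bins together, leaving the
distal bin fixed. The source leaves boundary behavior open, so: vacated
sequence positions are filled with seeded random bases, and target mass
shifted out of range is accumulated on the nearest retained edge bin,
preserving normalization. Augmentation is off by default because the
default generator plants the CSE at a fixed offset; it is the right tool
when the CSE position varies (`cse_jitter > 0`).

# The ground-truth law and the synthetic MPRA

The generator's law is deliberately the simplest process that makes every
downstream method exercisable with analytic oracles: PAS strength is
additive in logit space over a 6-position CSE weight matrix (consensus
AATAAA, with ATTAAA as a strong variant) and positional motif effects (an
upstream TGTA enhancer +0.6, a downstream T-rich enhancer +0.8, a G-run
silencer -0.5), in competition with a distal signal of fixed strength 6.5.
Cleavage mass is laid over a Gaussian-shaped kernel spanning offsets +7 to
+57 nt downstream of the CSE start (peak near +21). Because the kernel is
normalized, the law-implied proximal proportion has the closed form
$\sigma(\text{strength} - \text{distal baseline})$, which is the oracle
used throughout the tests; with these defaults it spans most of (0, 1)
across random library members. Counts are multinomial at the stated read
depth (Dirichlet-multinomial overdispersion is available but off by
default). Sequences with more than 75% adenine in any 12-20-bp window are
rejected and resampled, mirroring the internal-priming artifact filter
that the real assay requires.

Every generator draws from a private stream derived by hashing (root seed,
operation name), so outputs are byte-reproducible and adding one generator
call never perturbs another's stream.

What passing these benchmarks shows: the architecture, losses, gradients,
and estimation machinery are correct and can learn a planted additive
cis-regulatory code at desk scale. What it does not show: performance on
real polyadenylation data, whose regulatory code is deeper (cooperative
RBP motifs, secondary structure, competing cryptic sites) and whose noise
is not multinomial. Numbers obtained here are correctness checks, not
accuracy claims about biological data.

A reduced reference benchmark (2 groups x 2 blocks, 16 channels, 5 epochs
on 20,000 records of depth 200) reaches held-out Spearman correlation
$\ge 0.6$ between predicted and law-implied proximal proportions; the
problem sizes were chosen so the whole benchmark suite runs comfortably on
one CPU. One characteristic of this reduced regime is worth knowing: the
global-average-pooled distal head aggregates features uniformly over
positions, which favors translation-invariant signals (motif counts) over
position-pinned ones (the identity of the hexamer at offset 69, whose
evidence is diluted by the pooling). After 5 epochs the reduced model
therefore recovers the correct sign of planted motif variants with
attenuated magnitude, while single-base core-hexamer variants are
underestimated; ranking across a library, which mixes both sources, still
clears the benchmark bar. The full-scale architecture with longer training
does not share the capacity constraint, but closing that gap is outside
the desk-scale scope.

# Variant scoring

For a wildtype/variant pair the effect is the natural-log odds ratio of
the two predicted proximal proportions; the log base is a convention
choice (a `base2` flag converts for reporting). Proportions are clamped at
$10^{-6}$ before logits to keep saturated measurements finite. A variant
is "disruptive" when its absolute odds ratio exceeds 2 (strictly,
$|\text{LOR}| > \ln 2$). Effect sizes on native isoform usage come from
shifting the baseline usage's odds by the predicted LOR
(`deltaUsage`), and aQTL-style effect sizes from the same transform of the
mean distal usage index with an orientation sign $\lambda$: +1 within 150
bp of the annotated transcript end, -1 otherwise, with an optional
extension assigning +1 within 500 bp when the variant creates a canonical
CSE hexamer de novo. Saturation mutagenesis (`ism`) scores all 3L
substitutions of a PAS; the linear CSE hexamer baseline regresses measured
LORs on one-hot hexamer features with reference coding against AATAAA, so
its intercept is the consensus prediction.

# Multi-PAS isoform regression

Endogenous 3'-seq tables pass the standard filters first (pairwise task:
total count $\ge 500$, sites 100-4000 bp apart, no run of more than 7
adenines; multi-PAS task: at most 10 PASs, at least 10 counts, adjacent
sites 50-40,000 bp apart, no run of more than 13 adenines). Measured
pairwise logits use a 0.5 pseudo-count; the zero-count corner of that
formula is infinite, so proportions are clamped to $[10^{-4}, 1-10^{-4}]$
before the logit.

The multi-PAS model predicts the distal isoform proportion as a masked
softmax over a gene's existing PASs: the distal-most PAS is scored with a
distal-role linear function $f_d$ and all others with a proximal-role
$f_{p,i}$, each combining the PAS logit score, 4 stability-embedding
principal components, the cumulative log distance to the proximal-most
PAS, and a bias. The denominator scores the distal PAS with its own role,
so a two-PAS gene reduces exactly to a logistic model in $f_d - f_{p}$ - a
property the tests assert algebraically. Because a shared shift of both
role biases cancels in the softmax, the proximal bias is pinned at 0 for
identifiability (in the generator and the fit alike). Fitting minimizes
the mean per-gene binary KL divergence between observed and predicted
distal proportions by L-BFGS; the named optimizer is fixed but the
likelihood is a design choice, so a squared-error objective is selectable.
Ensembles of weight sets (e.g. one per stability-model fold) average the
predicted proportions. Parameter recovery from 500 synthetic genes is
within 10% relative error for every planted weight; the planted magnitudes
(all $\ge 0.25$) and per-gene depth (800) were chosen once so that the
least-identified coefficients (the distal-role bias and the low-variance
embedding PCs) are estimable at that sample size.

Isotonic calibration (`isotonicCalibrate`) provides the standard monotone
recalibration of absolute predicted effect sizes against held-out
measurements (pool-adjacent-violators, constant extrapolation).

# Condition-specific residual models

Differential APA between a reference condition and a target condition is
modeled as a residual on top of the baseline logits: a small CNN (2
convolutional layers, 16 filters, width 8, global average pooling), shared
across PAS slots, emits a 2-channel residual score per PAS - channel 1 for
the reference condition, channel 2 for the target. Per-slot regression
weights combine baseline logit plus residual with the log distance under a
masked softmax. How the two channels map to conditions is an open design
point; this package scores each condition's proportions with its own
channel, which trains both channels and makes the variant-effect scaling
below natural.

Training is two-phase. Phase 1 freezes the CNN, forces residuals to zero,
and fits only the regression weights by L-BFGS on the summed KL divergence
of both conditions - so the phase-1 result is provably independent of CNN
initialization. Phase 2 unfreezes the CNN under a margin loss: only PASs
whose measured between-condition proportion difference exceeds 0.2
contribute $\max(\mathrm{sign}(\Delta)(\Delta-\hat\Delta), 0)$. The gate
keeps the CNN from spending capacity re-predicting the shared mean
instead of the (small) differential signal. The phase-2 optimizer is not
specified by the design, so Adam (learning rate 0.01, 25 epochs) is used;
the dense output layer starts at small random values so the convolutional
pathway receives gradient from the first step.

Condition-scaled variant effects multiply the baseline variant odds ratio
by a condition odds ratio $e^{\gamma(\hat s^{var}_{tissue} - \hat
s^{var}_{ref})}$; with a zero residual difference or $\gamma = 0$ the
expression reduces exactly to the baseline scaling (asserted to
$10^{-12}$). The shared scale $\gamma$ is tuned on a grid to maximize the
median Spearman correlation against measured effects across condition
sets, ties resolving to the smallest candidate.

The synthetic benchmark plants a GT-rich 6-mer (TGTGTG) whose carriers
gain +2 logits in the target condition only. A 6-mer was chosen because
4-mers occur by chance in over half of random 205-mers, which dilutes the
label; the effect size was chosen so that a usable fraction of PASs clears
the 0.2 margin. A 2-model ensemble trained on 300 genes recovers the
planted effect on held-out genes (ensemble residual difference vs. motif
presence, Spearman $\ge 0.5$). Real tissue-differential APA signals are
weaker and more distributed; this benchmark establishes the training
machinery, not tissue-level accuracy.

# Mask-based variant interpretation

To explain why a variant changes the prediction, the scrambler searches
for the smallest set of wildtype positions that, kept intact while
everything else is randomized, still reconstructs the predicted LOR. Per
position an unconstrained parameter vector $w$ is instance-normalized
(epsilon $10^{-3}$) and softplus-transformed into retention scores $s > 0$;
the mutated position is pinned to a large cap ($10^4$, numerically
equivalent to $+\infty$ for the softmax and excluded from the entropy
term). The scores interpolate position-wise between the one-hot wildtype
($s \to \infty$) and a Laplace-smoothed background $(x+1)/5$ (wildtype
base 0.4, others 0.2) through a softmax-relaxed PSSM. Discrete samples are
drawn with the Gumbel trick; variant samples are constructed from the same
wildtype sample by swapping the mutated base, so both share one randomized
background. Gradients pass through a straight-through estimator.

The objective is the mean squared error between sampled and target LOR
plus an entropy term: during a warmup (30 of 300 Adam iterations at
learning rate 0.01, 32 samples per step) the mean per-position KL to the
background is pulled toward a small target (0.25 nats), after which
entropy is maximized unbounded. The warmup length, entropy weight (0.5)
and KL target were set by a small grid on the surrogate suite and are all
configurable. Multiple restarts average the per-restart masks and report
the best-reconstructing restart's diagnostics.

On linear surrogates with planted same-sign interactions the converged
mask ranks the interacting positions first and reconstructs the LOR within
10%. A known limitation: when a variant's effect is composed of
*opposite-sign* interactions, the expected-loss landscape from a
mid-entropy start can push one partner toward the background before the
joint optimum is visible (retaining it only helps once the other partner
is mostly retained), and the mask may then under-rank that partner while
still reconstructing the mean LOR. Multi-restart optimization mitigates
but does not remove this; interpretations of antagonistic motif pairs
should be read with that caveat.

For trained networks the scorer exposes analytic input gradients
(evaluation-mode backpropagation to the one-hot input), validated against
finite differences.

# Population screening

`saturationScreen` imputes all 3 per-position substitutions of a PAS
catalog and records each variant's LOR and induced usage change against a
per-PAS baseline (the caller supplies the baseline, e.g. mean wildtype
usage across conditions). `afEnrichment` compares the fraction of
disruptive variants (usage change strictly below -0.15) per allele
frequency class against singletons, with rank-sum p-values.

`eliminateProtected` encodes the "protected PAS" heuristic: a cohort
variant is dropped when its PAS carries common background variants
(AF above 0.01% by default) with strictly larger - or, under the fold
rule, at least 1.5-fold - absolute effect sizes. A five-bin mode first
bins a PAS's background variants by effect size into 5 equal-width bins
and aggregates allele counts, so several rare variants with comparable
effects can jointly act as one common variant; the bin's largest absolute
effect represents it (bin edges and the representative are unspecified
design points, resolved here as equal-width and maximum). A neighbour
rule removes variants in PASs with a downstream neighbour within 200 nt,
and variants overlapping several PASs are first assigned to the PAS with
the largest predicted effect. Every removal is logged with its rule and
trigger, and removal is monotone in the AF cutoff.

`cohortCompare` reports rank-sum statistics, the gain-of-function fold
enrichment and a Fisher exact test on the 2x2 of cohort by
threshold-exceedance. The gain-of-function threshold is not pinned by the
source analyses, so it is configurable with default $+\ln 2$ (the same
magnitude as the disruptive rule). On synthetic cohorts with a planted
3-fold enrichment (300 cases, 300 controls, background gain-of-function
rate 0.1), the median recovered fold across 100 seeds lies in [2, 4] and
the Fisher test is significant at 0.05 in at least 90% of seeds.

# Read processing

Paired 3'-end MPRA reads are quantified by (i) mapping read 1 to a
reference via its upstream anchor (first 30 nt by default - the anchor
length is unspecified upstream, so it is a parameter) allowing at most 2
substitutions, ambiguous best hits unmapped; (ii) scanning 5' to 3' for
the first window of 20 bases with at most 2 non-adenines, whose offset in
reference coordinates is the cleavage site, reads without such a window
being distal; (iii) collapsing identical (reference, UMI, replicate)
tuples to one molecule, keeping the first-seen site and logging
conflicting duplicates; replicates can be pooled. Isoform proportions sum
UMI counts over a window downstream of the CSE start, and variant pairs
are scored only when both members pass the replicate filter (mean UMI
count above 200 in at least 5 replicates by default; both thresholds are
parameters so small designs can relax them).

Two coordinate subtleties are made explicit rather than left implicit.
First, cleavage immediately after templated adenosines is unidentifiable
from the read, so the generator records truth sites in their 5'-most
equivalent representation (trailing A's folded into the poly(A) run);
with that convention and a strict (0-mismatch) poly(A) search, error-free
reads are recovered exactly - the mismatch-tolerant default shifts calls
up to 2 nt 5' at non-adenine junctions and is intended for error-bearing
reads. Second, the generator's cleavage kernel occupies poly(A)-offset
coordinates +8..+58 relative to the 0-based CSE start (one past the
kernel's +7..+57 bin support), so truth-table comparisons use that
window; the conventional +0..+50 reporting window remains the default for
real-style data.

# Degenerate inputs and numerical policy

All probability clamps are stated at their definition sites: $10^{-12}$
inside training-loss logarithms, $10^{-6}$ for proportion logits,
$10^{-4}$ for pseudo-counted endogenous logits. `N` bases one-hot encode
to all-zero rows. Empty filter inputs return empty outputs with zeroed
reports. Genes with a single PAS have a degenerate softmax and contribute
zero KL. Rank-deficient regression designs warn and fall back to the
pseudoinverse. Non-finite training losses abort with a diagnostic rather
than propagate.

# Limitations

Beyond the synthetic-vs-real caveats above: the full-scale architecture is
constructed and validated structurally, but training it to published
accuracy requires the original multi-million-record assay and is out of
scope; the scrambler's opposite-sign limitation is documented above; and
the CLI (`inst/scripts/polyacode`) is a convenience wrapper - the R API is
the primary interface.
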