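---
title: "Predicting cytosine methylation from sequence, annotations and neighboring levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cytosine methylation from sequence, annotations and neighboring levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In plants, 5-methylcytosine occurs in three sequence contexts — CG, CHG and
CHH (H = A, C or T, read 3' of the cytosine on its own strand) — maintained by
distinct molecular pathways. Whole-genome bisulfite sequencing measures the
methylation level of each cytosine as the fraction of reads supporting
methylation, but uneven coverage leaves many cytosines uncalled. This package
implements, in R, a family of classifiers that predict the *binary*
methylation status of a cytosine from

* the one-hot encoded DNA window around it, optionally augmented with
  per-base binary annotation channels (gene on each strand, repeat), via a
  small convolutional network (`build_amps_cnn()`);
* the methylation levels of its nearest covered neighbors, via a multilayer
  perceptron (`build_neighbor_mlp()`);
* both inputs combined (`build_combined()`);
* a bagged-tree baseline on the flattened window bits
  (`build_random_forest()`).

It also provides the supporting machinery: Bismark-style cytosine-report and
FASTA/GFF3/BED/RepeatMasker parsers, balanced training-set construction with
an 80/10/10 split, gene-body methylation metaprofiles, cross-context and
cross-species evaluation grids, Grad-CAM importance scoring with FASTA export
of candidate motif windows, and a fully reproducible methylome simulator that
the test suite is built on.

## Calling rules

A cytosine covered by 10 or fewer reads has *unknown* status and is excluded
from training, testing and the neighbor vectors. Otherwise its level is
`meth_reads / total_reads`, and it is called *methylated* when the level is at
least 0.5 — the threshold is inclusive, so a level of exactly 0.5 counts as
methylated (the source convention states "at least 0.5" and we take it
literally). Context is always recomputed from the genome; the context column
of a report file is advisory, and cytosines whose two downstream bases include
N or run past the chromosome end have undefined context and are dropped.

## Input encodings

**Sequence windows.** A window of `W_s` bases (default 3200, the value used at
full scale) centered on the candidate is one-hot encoded into a
`W_s x (4 + a)` binary matrix with column order A, C, G, T; an N base gives an
all-zero row. With annotations enabled, `a = 3` extra columns carry the gene
forward-strand, gene reverse-strand and repeat bits at each window position.
Minus-strand candidates are reverse-complemented so the center reads C in its
own 5'→3' orientation; the annotation rows are reversed accordingly and the
two gene channels are swapped (standard practice; the source is silent on
strand handling). Windows that would run past a chromosome end are rejected,
not padded — with the full-scale 3.2 kb window this loses only chromosome
ends.

**Neighbor vectors.** `W_p = 20` methylation levels: the 10 nearest covered
cytosines (more than 10 reads, any context, either strand) on each side of the
candidate, ordered by genomic coordinate, the center itself excluded.
Candidates with fewer than 10 covered cytosines on a side are rejected. The
vector carries levels only; distances are deliberately out of scope.

**Balance.** Because context-specific methylation rates are extremely skewed
(a constant classifier can exceed 99% accuracy for CHH in some species),
training sets are balanced exactly: `n/2` methylated and `n/2` unmethylated
for a single context, and `n/6` per (context, label) cell for the mixed
"ALL" setting. If any cell has fewer candidates than its quota, all quotas
shrink to the minimum availability so the set stays balanced. The 80/10/10
train/validation/test split deduplicates identical window sequences first, so
no sequence appears in more than one partition, and stratifies by label so
every partition keeps the designed balance.

## Architectures and training

All networks end in a single sigmoid node read as P(methylated), with calls at
the inclusive 0.5 threshold, mirroring the level rule.

* **Sequence CNN**: one 1D convolution across positions with kernel size
  `4 + a` spanning all input columns, 16 channels, stride 1, no padding,
  ReLU; flatten; dense 128 + ReLU + dropout 0.5; dense 1 + sigmoid.
* **Neighbor MLP**: dense layers of widths 20, 16, 8, 1 with ReLU and dropout
  0.5 on the hidden layers.
* **Combined**: two convolutions (16 channels each; the second kernel spans
  16 positions — the channel counts and kernel of the second layer are not
  specified upstream and are mirrored from the first, documented here as an
  assumption), flatten, concatenate the neighbor vector, then dense 16, 8
  (ReLU, dropout 0.5) and the sigmoid node.
* **Forest baseline**: 50 bagged CART trees, unlimited depth, Gini splits,
  `sqrt(p)` features per node, on the flattened binary window. It is
  implemented in the package (no forest library is assumed by the runtime
  environment); splits are binary feature tests, exact for 0/1 inputs.

The engine itself (`R/nn.R`) is written on BLAS matrix products — the
convolution is an im2col gather plus one GEMM — with gradients verified
against central finite differences in the test suite.

Training minimizes binary cross-entropy with minibatch SGD, batch size 32, 20
epochs. Validation accuracy is recorded each epoch and the weights of the best
epoch are kept (the 10% validation partition has no other published use;
earliest epoch wins ties). A non-finite loss aborts with a diagnostic rather
than propagating NaNs.

Two numerical choices deserve emphasis:

* **Input centering** (`center_input = TRUE` in the builders): a fixed 0.25 is
  subtracted from every window bit (0.5 from level vectors) before the first
  layer. This is an affine reparameterization — the representable function
  class is unchanged — but it removes the large common-mode component of
  sparse one-hot inputs and markedly improves SGD conditioning. Disable it for
  analyses that assume raw bits (the constructed-model Grad-CAM tests do).
* **Desk-scale optimization regime.** The published regime (learning rate
  0.001, plain SGD) is stated for full-scale training on 500 000 examples —
  about 25x more SGD steps than the simulation-scale experiments here. At desk
  scale that regime cannot leave the chance plateau within 20 epochs, so the
  package's experiments and tests pass `learning_rate = 0.05, momentum = 0.9`
  explicitly (momentum is a free, configurable parameter; `train_config()`
  keeps the published defaults). This is an optimization-schedule choice, not
  a change to any architecture, data or threshold.

## Gene-body metaprofiles

For each gene, the 2 kb flanks and the gene body are split into 5 bins each —
15 bins ordered 5'→3' along the gene (flank bins are 400 bp; body bins are a
fifth of the gene, floor division with the remainder in the last bin,
documented so the brute-force test oracle matches). Within bin `r` of gene
`i`, `m(r, i)` is the ratio of methylated cytosines over all *called*
cytosines of the requested context on the chosen strand, and `l(r, i)` is the
bin length in bp (truncated at chromosome ends). The species profile is the
length-weighted average

$$M(r) = \frac{\sum_i m(r,i)\, l(r,i)}{\sum_i l(r,i)}$$

over genes whose bin contains at least one called cytosine; bins empty in all
genes are `NA`. Unknown-status cytosines are excluded from the denominator,
consistent with the coverage rule. The *nontemplate* orientation is the gene's
annotated (mRNA-like) strand; *template* is the transcribed complement. The
ratio uses binary calls; a mean-level mode exists behind the `mode` flag for
exploration only.

## Grad-CAM and motif candidates

For a trained convolutional model, `gradcam()` computes the gradient of the
class score — the pre-sigmoid logit, negated when the predicted class is
unmethylated — with respect to the post-ReLU activation maps of the last
(for the sequence CNN, only) convolutional layer, averages gradients over
positions into per-channel weights, takes the channel-weighted sum of the
activation maps, rectifies it, and upsamples to input resolution by
nearest-neighbor repetition (all documented so the closed-form test oracle is
reproducible). `select_candidates()` takes correctly classified examples of
each class, slides a 50 bp window (stride 1) along each importance profile,
and reports the window with the highest mean score; ties break leftmost, and
window sums are computed exactly per window rather than by cumulative-sum
differences, so flat profiles really do tie. Candidates export to FASTA with
self-describing headers for downstream motif discovery (running MEME/TOMTOM
is out of scope).

## The simulator: what it emulates and what it does not

`sim_config()`/`simulate_genome()`/`simulate_methylome()` generate an i.i.d.
background sequence at a configurable GC fraction (default 0.36, a typical
plant value), non-overlapping stranded genes and independently placed repeats
(densities 0.35 and 0.15 by default, in the range of compact plant genomes),
optional planted motif instances, and a methylome in which each cytosine's
methylation probability is a logistic function of its context base rate,
gene/repeat membership, motif proximity and an AR(1) latent field over
consecutive cytosines. Read depth is Poisson (default mean 15, within the
5-21x range of real BS-Seq studies); methylated-read counts are binomial at
level 0.9 for truly methylated and 0.1 for truly unmethylated cytosines, so
the >=0.5 call recovers the true state with high probability at that depth.
Context base rates default to CG 0.30, CHG 0.15, CHH 0.05 — the ordering and
magnitudes observed across plant species.

The canned fixtures state the worlds the tests assert about:

* `motif_driven`: the state is *exactly* "within 50 bp of a planted 8-mer"
  (`motif_deterministic = TRUE`), a noiseless rule with Bayes accuracy 1, at
  depth 30 and emission levels 0.95/0.05 so call noise is negligible.
* `annotation_driven`: P(methylated) is 0.9 inside genes and 0.1 outside; the
  sequence itself is i.i.d. and carries essentially no signal, so the gap
  between the `a = 3` and `a = 0` models isolates the value of annotations.
* `neighbor_driven`: the state is the sign of a strongly autocorrelated
  latent field (`state_rule = "latent_sign"`, rho 0.995). The label is
  *determined* by the field, hence predictable from neighboring levels but
  not from the i.i.d. sequence. (A Bernoulli draw on top of the field was
  rejected: it caps the attainable accuracy near 0.9 and makes the label only
  correlated with, not determined by, the neighbors.)
* `divergent_pair`: two "species" with different planted 8-mers (neither the
  other's reverse complement) for cross-species grids.

What the simulator does **not** emulate: real genome composition (isochores,
CpG islands, repeat families), bisulfite conversion error, mapping bias,
correlated read sampling, or the biological coupling between CG/CHG/CHH
pathways. A green test therefore establishes that the implementation recovers
planted, known structure under its stated assumptions — not that the
architectures reach any particular accuracy on real plant methylomes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; report/GFF3/RepeatMasker I/O
  converts from their 1-based conventions; BED is taken as is.
* A level of exactly 0.5 is methylated; coverage must strictly exceed 10.
* Strand-"." gene features set both gene channels (symmetric treatment; the
  convention upstream is unstated).
* Bins or metric denominators that would be 0/0 are reported as `NA` and
  flagged, never silently 0.
* Balanced sampling with an empty required cell raises; window-boundary
  candidates are rejected before sampling so balance is exact after encoding.
* All randomness flows through explicit integer seeds (`withr::with_seed`);
  the same seed reproduces simulations byte-identically and training runs
  weight-identically.

## Known limitations

* The engine is CPU-only, single-threaded R + BLAS; full-scale runs
  (W_s = 3200, n = 500 000) are possible but slow — the design target is
  desk-scale simulation studies and method development.
* The forest baseline accepts binary features only.
* Grad-CAM for the combined model attributes only the sequence branch.
* `run_cross_grid()` retrains one model per row and reuses it across columns;
  whether the original analysis retrained per cell is unknowable from the
  text, and the choice is documented in the function's help.

## Pipeline and CLI

`run_pipeline()` executes simulate → tracks → dataset → train → evaluate →
profile → explain from a JSON config with one root seed, writes a manifest
(config digest, per-stage timings, output MD5s, package version), and skips
stages whose outputs already exist under an identical config. A thin CLI at
`system.file("cli", "methpred.R", package = "methpred")` exposes `simulate`,
`tracks`, `profile`, `pipeline` and `explain` subcommands.
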