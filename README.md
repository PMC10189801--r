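# methpred

Context-specific prediction of plant cytosine methylation from DNA sequence,
genomic annotations, and the methylation levels of neighboring cytosines.

## The problem

Whole-genome bisulfite sequencing reads out 5-methylcytosine at single-base
resolution, but uneven coverage leaves many cytosines uncalled, and in plants
methylation occurs in three sequence contexts — CG, CHG and CHH (H = A, C or
T) — maintained by distinct pathways. `methpred` provides classifiers that
predict the binary methylation status of a cytosine (level &ge; 0.5 at
coverage &gt; 10 reads) per context:

- **Sequence (+annotation) CNN** — the window of `W_s` bases around the
  cytosine, one-hot encoded into a `W_s x (4 + a)` binary matrix where the
  `a = 3` optional extra channels mark gene (per strand) and repeat membership
  at each base; one 1D convolution (kernel `4 + a`, 16 channels, ReLU), a
  dense layer of 128 with dropout 0.5, and a sigmoid output node.
- **Neighbor MLP** — the methylation levels of the 10 nearest covered
  cytosines on each side (any context, either strand), through dense layers
  20-16-8-1.
- **Combined network** — two convolutions over the window, flattened and
  concatenated with the neighbor vector, through dense layers 16-8-1.
- **Bagged-tree baseline** — 50 CART trees, unlimited depth, on the flattened
  window bits.

Training sets are balanced exactly (n/2 per label; n/6 per context-label cell
for the mixed "ALL" setting) and split 80/10/10 with sequence deduplication,
because the heavily skewed context-specific methylation rates would otherwise
make trivial classifiers look excellent. Networks train with minibatch SGD
(batch 32, 20 epochs) on binary cross-entropy, keeping the weights of the
best validation epoch.

Around the classifiers the package implements: Bismark-style cytosine-report
I/O with genome-recomputed contexts, FASTA/GFF3/BED/RepeatMasker parsers,
per-base annotation bit tracks, gene-body methylation metaprofiles

M(r) = &Sigma;<sub>i</sub> m(r,i) l(r,i) / &Sigma;<sub>i</sub> l(r,i)

over 15 bins (5 per 2 kb flank, 5 per gene body; m = methylated / called
cytosines in the bin, l = bin length), cross-context and cross-species
accuracy grids, window-size and dataset-size sweeps, Grad-CAM importance
scoring with export of the best 50-mer per correctly classified input as
FASTA (MEME-ready), a fully seeded methylome simulator, and a JSON-config
pipeline with run manifests. Everything — including the neural-network
engine — is plain R on BLAS; no deep-learning runtime is required.

## Worked example

```r
library(methpred)

# simulate a small plant-like methylome where genes drive methylation
fx <- make_fixture("annotation_driven", seed = 1)

# per-base annotation channels from the simulated features
tracks <- build_tracks(fx$features, fx$genome)
#> annotation_tracks over 1 chromosome(s), a = 3
#>   chr1: gene_fwd 43537 bp, gene_rev 43047 bp, repeat 0 bp

# balanced CG dataset of 1200 one-hot windows (100 bp) + annotation channels
ds <- build_sequence_dataset(fx$genome, fx$calls, context = "CG", n = 1200,
                             W_s = 100, tracks = tracks, seed = 2)
split <- split_80_10_10(ds, seed = 3)
#> meth_split: train 960 / validation 120 / test 120 (seed 3)

# train the sequence+annotation CNN (desk-scale optimization regime)
model <- train_model(build_amps_cnn(W_s = 100, a = 3, seed = 4), split,
                     train_config(learning_rate = 0.05, momentum = 0.9,
                                  epochs = 5, seed = 4))

# evaluate on the held-out test partition
pred <- predict(model, split$test)
compute_metrics(split$test$y, pred$call)
#> accuracy 0.9083 | precision 0.9153 | recall 0.9 | F1 0.9076 (TP 54 FP 5 FN 6 TN 55)
```

On this fixture methylation probability is 0.9 inside genes and 0.1 outside
while the sequence itself is random, so the ~0.91 test accuracy is carried by
the annotation channels — the package's central qualitative claim (the same
architecture with `a = 0` stays near chance; the acceptance suite asserts a
lift of at least 5 accuracy points).

The gene-body metaprofile of the same fixture shows the planted biology: low
methylation in the flanks rising sharply inside gene bodies.

```r
prof <- gene_profile(fx$calls,
                     fx$features[fx$features$feature_type == "gene"],
                     context = "CG")
head(prof[prof$orientation == "nontemplate"], 8)
#>    context orientation   bin         M genes total_length
#> 1:      CG nontemplate     1 0.4172658    33        13200
#> 2:      CG nontemplate     2 0.4044770    33        13200
#> 3:      CG nontemplate     3 0.3341284    33        13200
#> 4:      CG nontemplate     4 0.2563006    33        13200
#> 5:      CG nontemplate     5 0.1309130    33        13200
#> 6:      CG nontemplate     6 0.9009665    33        17304
#> 7:      CG nontemplate     7 0.8957500    33        17304
#> 8:      CG nontemplate     8 0.8930457    33        17304
```

(Bins 1-5: upstream flank approaching the gene; bins 6-10: gene body. The
elevated flank values come from flanks that overlap neighboring genes.)

Motif discovery input from a trained model:

```r
cand <- select_candidates(model, split$test, n_per_class = 100, width = 50)
export_fasta(cand, "candidates.fa")
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "methpred.R", package = "methpred"))')
Rscript "$CLI" simulate --profile motif_driven --seed 7 --out fixture/
Rscript "$CLI" profile --report fixture/cytosine_report.tsv \
    --fasta fixture/genome.fa --gff fixture/features.gff3 \
    --context CG --out profile.tsv
Rscript "$CLI" pipeline --config config.json   # full stage pipeline
```

## Documentation

See the methods vignette (`vignettes/methylation-prediction.Rmd`) for the
model assumptions, the calling and balancing rules, what the simulator does
and does not emulate, numerical choices, and known limitations.
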