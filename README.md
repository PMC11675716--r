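# seq2expr

Predicting per-gene expression levels from long genomic windows around
transcription start anchors, using pooled DNA language-model embeddings and
a multi-branch convolutional regressor.

## The problem

How much of a gene's (median, cross-tissue) expression level is encoded in
the sequence around its dominant transcription start position? Answering
this quantitatively requires a regression model from a long genomic window
— 10.5 kb up to 50 kb around the CAGE peak — to an expression value, scored
by the coefficient of determination

R² = 1 − SS_res / SS_tot.

One-hot encodings ignore the relationships between neighbouring
nucleotides, while fine-tuning genomic transformers on such long inputs is
blocked by their 512-token cap. `seq2expr` takes the middle road: windows
are *fragmented*, each fragment is embedded by a pre-trained-style backend
and mean-pooled, and the resulting fixed-shape matrix of pooled fragment
embeddings is regressed with a small convolutional network. The package is
aimed at regulatory-genomics researchers who want a fully testable,
self-contained implementation of this pipeline — including a deterministic
mock embedding backend and a planted-signal simulator, so every stage runs
and is verifiable without external data or pre-trained weights.

## The method

For a window of length L (canonically 7,000 bp upstream + 3,500 bp
downstream of the anchor, strand-aware, N-padded at chromosome edges):

* **k-mer chunk route** — overlapping 6-mers give L − 5 tokens
  (10,500 bp → 10,495), split greedily into 500-token chunks
  (→ 20 × 500 + 1 × 495). Each chunk is embedded to `[n_tokens × 768]` and
  mean-pooled, stacking to a `[21 × 768]` matrix.
* **bp window route** — sliding 2,000-bp windows at a 500-bp step
  (10,500 bp → 18 fragments) embedded and pooled to `[18 × 768]`.

Each matrix enters a branch: conv1d over the fragment axis (64 channels,
kernel 3; kernel 5 on ±25-kb branches), batch norm, GELU, dropout, global
max over positions. Branch vectors are concatenated with optional auxiliary
features (8 mRNA half-life values, 181 binary TF-target indicators), passed
through a 64-unit dense layer (batch norm, GELU, dropout) and a linear
output. Training: Adam on MSE, batch 128, lr 0.002 stepped to 0.0002 after
epoch 10, early stopping with patience 20, 10 × repeated runs reported as
min/avg/max R², plus k-fold splitting and per-tissue (57-label) modes.

The network (including backprop and Adam) is implemented in base-R matrix
algebra and gradient-checked against finite differences in the test suite.

## Worked example

Simulate a 500-gene dataset with a planted 30-bp regulatory element
(Poisson-placed copies, known effect sizes, noise set so the full signal
explains 80% of label variance), embed it with the mock backend, and train:

```r
library(seq2expr)

spec <- synthSpec(nGenes = 500, upBp = 2000, downBp = 1000, seed = 42)
plantedR2Ceiling(spec, "dna")   # 0.3456221  <- sequence-only ceiling
plantedR2Ceiling(spec)          # 0.8        <- all features

gt <- synthGeneTable(simulateDataset(spec))
gt
#> GeneTable: 500 genes, 1 label column(s)
#>   window 'main': 2000 bp upstream + 1000 bp downstream
#>   half-life: 8 features; TF targets: 181 features

be   <- mockEmbedder("token_chunk", dim = 16, seed = 0)
data <- assembleBundles(gt, list(list(backend = be, window = "main")),
                        features = c("halflife", "tf"))
dim(data$branches[[1]])         # 500 6 16  (genes x fragments x dim)

model <- buildModel10500(useDnabert = TRUE, useDnabert2 = FALSE,
                         auxDims = c(8L, 181L),
                         dnabertShape = dim(data$branches[[1]])[2:3], seed = 1)
model
#> ExpressionCNN: 1 branch(es), 189 aux feature(s), 1 output(s)
#>   branch 1: [6 x 16] -> conv(64 ch, k=3) -> BN -> GELU -> drop 0.6 -> max
#>   head: fc(64) -> BN -> GELU -> drop 0.2 -> linear(1)
#>   trainable parameters: 19713

fit <- trainModel(model, data, trainConfig(epochs = 30, seed = 1))
fit$report$testR2               # 0.461653
```

The held-out R² of 0.46 sits between the sequence-only ceiling (0.35) and
the all-feature ceiling (0.8), as it should for a model that sees the
sequence plus both auxiliary groups but trains on only 400 genes; at the
reference scale of 2,000 genes the experiments in `scripts/acceptance.R`
recover a larger fraction of the explainable variance. Repeated-run
ablations come from `runExperiment()`, which reports min/avg/max R² per
feature set or per tissue label.

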