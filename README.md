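# casguide

Cross-variant CRISPR/Cas9 sgRNA activity modeling in R.

## The problem

Picking efficient single-guide RNAs (sgRNAs) is central to CRISPR/Cas9
experiment design, and sequence-based activity predictors are standard
practice for wild-type SpCas9. Engineered Cas9 variants — SpCas9-HF1,
eSpCas9(1.1), HypaCas9, SniperCas9, evoCas9, xCas9 — shift sequence
preferences, but their activity datasets are small or absent, so
per-variant models generalize poorly. `casguide` implements a dual-input
regression model that conditions on **both** the 59-nt guide record
(20-nt protospacer + 3-nt NGG PAM + 36-nt scaffold) and the variant's
**protein sequence**, so one pooled model can transfer sequence-activity
structure from data-rich variants to data-poor or unseen ones.

The model, in brief:

* **sgRNA branch** — one-hot 59×5 input through a dual-path CNN (a single
  conv layer in parallel with a three-layer conv stack; kernel 5,
  padding 2, 64 sigmoid filters each, so both paths emit 59×64), then
  flatten (7552) → 2048-unit layer → linear 256-wide representation
  *H*<sub>rna</sub>.
* **protein branch** — per-residue embeddings (1280-wide by default, the
  width of the 650M-parameter ESM2 protein language model; a
  deterministic offline stub backend is the default) through a
  multi-scale TextCNN (kernels {5, 9, 13} × 128 ReLU filters, global max
  pooling, 384→256 sigmoid layer) giving *H*<sub>pt</sub>.
* **dynamic weight fusion** — a gate network emits a per-sample scalar
  *w* ∈ (0,1); the head regresses activity from
  *w*·*H*<sub>rna</sub> + (1−*w*)·*H*<sub>pt</sub> through 256→128→1
  with a final sigmoid. Training: Adam, MSE, lr 1e-4, batch 256, cosine
  annealing with 5-epoch restarts; model selection by validation
  Spearman ρ (rank correlation, average ties).

The package also ships the surrounding machinery: Cas9 variant
construction from point-mutation tokens ("R661A") with a built-in
seven-variant registry, 7:1:2 splits and the three deployment scenarios
(well-established / newly-identified / newly-discovered variants),
variant-specific vs cross-variant training protocols, a 175-feature
handcrafted guide descriptor (k-mer counts, GC, nearest-neighbour
melting temperatures, positional indicators), pLogo-style position-wise
binomial motif enrichment, and a seeded synthetic-data generator with
planted, recoverable signal. Everything runs offline and
deterministically under explicit seeds.

## Worked example

```r
library(casguide)

# synthetic parent protein + two engineered variants
parent <- make_parent(seed = 1)                 # 1368 aa, registry-compatible
reg <- builtin_registry()
reg[["SpCas9-HF1"]]
#> Cas9 variant 'SpCas9-HF1': N497A, R661A, Q695A, Q926A
backend <- embedder_backend("stub", width = 64, seed = 1)
embs <- embed_variants(parent, reg[c("WT-SpCas9", "SpCas9-HF1")], backend)

# synthetic guides with planted GC / motif / variant effects
sim <- generate_dataset(sim_config(n_guides = 300,
                                   variants = names(embs), seed = 1))
sp <- split_712(sim$records, seed = 1)

fit <- train_model(sp$train, embs,
                   training_config(epochs = 10, seed = 1), val = sp$val)
pred <- predict(fit, sp$test, embs, rescale = FALSE)
spearman(pred, sp$test$activity)
#> Spearman rho = 0.8827 (n = 120)

# which nucleotides mark high-activity guides?
top_enriched(enrichment(median_split(sim$records)), 3)
#>    position nucleotide     score significant
#> 32        9          C 22.489102        TRUE
#> 50        4          G 15.126613        TRUE
#> 16       16          A  9.055415        TRUE
```

The recovered Spearman ρ says the model ranks held-out guides largely in
the planted activity order, and the enrichment table recovers exactly
the planted motif cells (G at protospacer position 4, C at 9, A at 16)
as the strongest high-vs-low activity skews.

A command-line wrapper covers the same workflow
(`simulate | build-variant | features | train | predict | evaluate |
motif`):

```sh
Rscript exec/casguide simulate --out-dir data --seed 1
Rscript exec/casguide train --data data/all_records.csv --out-dir model --epochs 10
```

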