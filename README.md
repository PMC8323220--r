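# critens

Ensemble metric-learning classification of imbalanced short clinical
text, in R.

## The problem

Clinical-trial eligibility criteria are short, informally written
sentences ("Age > 80", "severe hearing or visual impairment") that must
be sorted into dozens of semantic categories before candidate
participants can be screened automatically. Such corpora are
feature-sparse (short, unsegmented text full of symbols and units) and
severely imbalanced (head categories outnumber tail categories by
orders of magnitude), and the real corpora are usually not
redistributable. `critens` is for researchers who want to study — and
reuse — a character-level ensemble classifier built for this regime,
with a synthetic-corpus generator standing in for the private data.

## The method

Each of K ensemble members is a character-level convolutional
classifier: trainable character embeddings (the encoder contract is
`text -> L x dim` matrix, so pre-trained encoders can be plugged in),
parallel convolutions of widths 3/4/5 with rectifier and masked
max-pooling giving a feature representation `r` (d = 96 by default),
then a fully connected layer and softmax `p_t = exp(x_t) / Σ_j exp(x_j)`.

Members are trained with the combined objective

```
L = FocalLoss + μ · L_metric
FocalLoss      = −(1 − p_t)^γ log p_t                       (γ = 2)
D(r_i, r_j)    = (1/d) ‖r_i − r_j‖²
L_intra(k)     = [2/(|S_k|² − |S_k|)] Σ_{i<j ∈ S_k} D(r_i, r_j)
L_inter(p, q)  = [1/(|S_p||S_q|)] Σ_{i∈S_p, j∈S_q} max(0, m − D(r_i, r_j))
L_metric       = Σ_k { L_intra(k) + λ Σ_{i≠k} L_inter(k, i) }   (λ = 0.1, m = 0.1, μ = 1)
```

Focal loss concentrates gradient on hard (typically minority-class)
samples; the metric loss pulls same-class feature representations
together and pushes different-class ones beyond the margin `m`.
Optimization is Adam over shuffled mini-batches (batch 128, 12 epochs,
seeded and exactly reproducible), with the best-validation-macro-F1
checkpoint retained. Member softmax outputs are combined by equal-weight
**soft voting**: `O = argmax (1/K) Σ_i M^i`. Evaluation reports
accuracy, macro precision/recall and macro F1 from one-vs-rest
confusion counts, plus a paired t-test on per-class F1 for model
comparison. See `vignettes/eligibility-ensemble.Rmd` for the full
account.

## Worked example

Generate an imbalanced synthetic corpus (Zipf-distributed classes,
class-indicative tokens plus 30% shared noise tokens), train a 3-member
diverse-seed ensemble, and soft-vote:

```r
library(critens)
corp <- generate_synthetic_corpus(synthetic_spec(
  n_classes = 6, total_samples = 900, imbalance_exponent = 1.5,
  noise_rate = 0.3, seed = 7))
class_distribution(corp)
#> C01 C02 C03 C04 C05 C06
#> 489 167  94  65  47  38
fits <- train_ensemble(corp, n_members = 3, base_seed = 0)
models <- lapply(fits, `[[`, "model")
out <- predict_ensemble(models, corp, "test")
rep <- evaluate_predictions(out$y_true, out$pred, corpus_schema(corp)$n)
c(macro_f1 = rep$macro_f1, accuracy = rep$accuracy)
#> ensemble macro F1: 0.9554  accuracy: 0.9831
sapply(models, function(m) evaluate_model(m, corp, "test")$macro_f1)
#> member macro F1: 0.9593 0.9017 0.9675
rep$per_class
#> # A tibble: 6 × 4
#>   class precision recall    f1
#> 1     1     1      1     1
#> 2     2     0.971  1     0.985
#> 3     3     1      0.944 0.971
#> 4     4     1      0.923 0.96
#> 5     5     1      0.889 0.941
#> 6     6     0.778  1     0.875
```

The class distribution shows the generated imbalance (489 vs 38
records); soft voting lifts the ensemble (0.9554) well above the mean
member (0.9428), and the per-class table shows where residual errors
sit (the rarest class). Numbers are exactly reproducible from the seeds
shown.

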