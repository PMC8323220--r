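#' Training hyperparameters
#'
#' Defaults for the reference trainable-embedding encoder: learning rate
#' 1e-2 (randomly initialized embeddings need step sizes that converge in
#' 12 epochs at a few hundred Adam steps; 2e-5 is the documented setting
#' when fine-tuning pre-trained weights), batch size 128, 12 epochs, seed
#' 0, weight decay 1e-4, gradient clipping at global norm 5.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training split.
#' @param seed Seed governing weight initialization and batch shuffling.
#' @param weight_decay L2 coefficient applied to weight matrices.
#' @param clip_norm Global gradient-norm clip (Inf disables).
#' @return An object of class `critens_train_config`.
#' @export
train_config <- function(learning_rate = 1e-2, batch_size = 128L,
                         epochs = 12L, seed = 0L, weight_decay = 1e-4,
                         clip_norm = 5) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            weight_decay >= 0, clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 weight_decay = weight_decay, clip_norm = clip_norm),
            class = "critens_train_config")
}

# ---- parameter flattening + Adam ----------------------------------------

flatten_params <- function(model) {
  out <- list(embedding = model$embedding)
  for (i in seq_along(model$conv)) {
    out[[paste0("conv", i, ".W")]] <- model$conv[[i]]$W
    out[[paste0("conv", i, ".b")]] <- model$conv[[i]]$b
  }
  out$fc.W <- model$fc$W
  out$fc.b <- model$fc$b
  out
}

flatten_grads <- function(grads) {
  out <- list(embedding = grads$embedding)
  for (i in seq_along(grads$conv)) {
    out[[paste0("conv", i, ".W")]] <- grads$conv[[i]]$W
    out[[paste0("conv", i, ".b")]] <- grads$conv[[i]]$b
  }
  out$fc.W <- grads$fc$W
  out$fc.b <- grads$fc$b
  out
}

unflatten_params <- function(model, flat) {
  model$embedding <- flat$embedding
  for (i in seq_along(model$conv)) {
    model$conv[[i]]$W <- flat[[paste0("conv", i, ".W")]]
    model$conv[[i]]$b <- flat[[paste0("conv", i, ".b")]]
  }
  model$fc$W <- flat$fc.W
  model$fc$b <- flat$fc.b
  model
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# Gradient of the mean focal loss at the logits. For sample s with true
# class t: dFL/dx_j = g_s * p_t * (delta_tj - p_j), with
# g_s = gamma (1-p_t)^(gamma-1) log(p_t) - (1-p_t)^gamma / p_t
# (g_s = -1/p_t at gamma = 0, recovering the cross-entropy gradient).
focal_grad_logits <- function(probs, y, gamma) {
  B <- nrow(probs)
  pt <- clamp_prob(probs[cbind(seq_len(B), y)])
  onem <- pmax(1 - pt, 1e-12)
  g <- if (gamma == 0) -1 / pt
       else gamma * onem^(gamma - 1) * log(pt) - onem^gamma / pt
  coef <- g * pt / B
  dZ <- -coef * probs
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] + coef
  dZ
}

#' Train one single model with the combined objective
#'
#' Full training loop: builds the character vocabulary from the training
#' split, initializes a seeded model, and optimizes the combined focal +
#' metric objective with Adam over shuffled mini-batches (metric loss
#' computed within each batch over the classes present there). The epoch
#' checkpoint with the best validation macro F1 is returned (ties to the
#' earliest epoch). Deterministic given corpus, configs and seed.
#'
#' @param corp A [corpus()] with non-empty train and valid splits.
#' @param encoder An [encoder_config()] (per-member variation in seed or
#'   dimension is the source of ensemble diversity).
#' @param loss A [loss_config()].
#' @param train A [train_config()]; its seed drives initialization and
#'   shuffling.
#' @param filters_per_width Filters per kernel width (feature dimension is
#'   3x this).
#' @return A `critens_fit`: list with the best `model`, a `history`
#'   tibble (epoch, loss, focal, metric, val_macro_f1), and `best_epoch`.
#' @export
train_single_model <- function(corp, encoder = encoder_config(),
                               loss = loss_config(), train = train_config(),
                               filters_per_width = 32L) {
  schema <- corpus_schema(corp)
  tr <- corpus_split(corp, "train")
  va <- corpus_split(corp, "valid")
  if (nrow(tr) == 0 || nrow(va) == 0)
    stop("training requires non-empty train and valid splits")
  vocab <- build_vocabulary(tr$text)
  cfg <- model_config(filters_per_width = filters_per_width,
                      n_classes = schema$n)
  model <- init_model(vocab, schema, encoder, cfg, seed = train$seed)
  tk_tr <- tokenize_batch(tr$text, vocab, encoder$max_length)
  tk_va <- tokenize_batch(va$text, vocab, encoder$max_length)
  N <- nrow(tr)
  flat <- flatten_params(model)
  state <- adam_init(flat)
  history <- vector("list", train$epochs)
  best <- list(f1 = -Inf, flat = flat, epoch = 0L)

  with_local_seed(train$seed, {
    for (epoch in seq_len(train$epochs)) {
      perm <- sample.int(N)
      starts <- seq(1L, N, by = train$batch_size)
      ep_focal <- ep_metric <- ep_total <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- perm[starts[bi]:min(starts[bi] + train$batch_size - 1L, N)]
        ids <- tk_tr$ids[, idx, drop = FALSE]
        y <- tr$label[idx]
        fwd <- forward_batch(model, ids, tk_tr$len[idx], want_cache = TRUE)
        fl <- focal_loss(fwd$probs, y, loss$gamma)
        ml <- metric_loss(fwd$r, y, loss)
        total <- fl + loss$mu * ml
        if (!is.finite(total))
          stop("non-finite loss at epoch ", epoch, ", batch ", bi,
               " (focal=", fl, ", metric=", ml, ")")
        ep_focal[bi] <- fl; ep_metric[bi] <- ml; ep_total[bi] <- total
        dZ <- focal_grad_logits(fwd$probs, y, loss$gamma)
        dR <- if (loss$mu > 0) metric_loss_grad(fwd$r, y, loss) else NULL
        grads <- flatten_grads(backward_batch(model, fwd, dZ, dR))
        if (train$weight_decay > 0) {
          for (nm in c("embedding", grep("\\.W$", names(grads), value = TRUE)))
            grads[[nm]] <- grads[[nm]] + train$weight_decay * flat[[nm]]
          grads$embedding[1L, ] <- 0
        }
        if (is.finite(train$clip_norm)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
          if (gn > train$clip_norm)
            grads <- lapply(grads, function(g) g * train$clip_norm / gn)
        }
        upd <- adam_step(flat, grads, state, train$learning_rate)
        flat <- upd$flat
        state <- upd$state
        model <- unflatten_params(model, flat)
      }
      val <- forward_batch(model, tk_va$ids, tk_va$len)
      val_pred <- max.col(val$probs, ties.method = "first")
      val_f1 <- evaluate_predictions(va$label, val_pred, schema$n)$macro_f1
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(ep_total), focal = mean(ep_focal),
        metric = mean(ep_metric), val_macro_f1 = val_f1)
      if (val_f1 > best$f1) best <- list(f1 = val_f1, flat = flat, epoch = epoch)
    }
  })
  structure(list(model = unflatten_params(model, best$flat),
                 history = do.call(rbind, history),
                 best_epoch = best$epoch,
                 val_macro_f1 = best$f1),
            class = "critens_fit")
}

#' @export
print.critens_fit <- function(x, ...) {
  cat("<critens_fit> best epoch ", x$best_epoch, ", validation macro F1 ",
      round(x$val_macro_f1, 4), "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained model on one corpus split
#'
#' @param model A trained `critens_model` (or a `critens_fit`).
#' @param corp A [corpus()].
#' @param split Split to evaluate (default `"test"`).
#' @return The [compute_metrics()] report.
#' @export
evaluate_model <- function(model, corp, split = "test") {
  if (inherits(model, "critens_fit")) model <- model$model
  part <- corpus_split(corp, split)
  pred <- predict_probs(model, part$text)$pred
  evaluate_predictions(part$label, pred, model$schema$n)
}

#' Uniformly subsample the training split
#'
#' Draws the requested fraction of training records without replacement;
#' validation and test splits are untouched. Warns if a class present in
#' the original training split vanishes from the subsample.
#'
#' @param corp A [corpus()].
#' @param fraction Fraction in `(0, 1]` of training records to keep.
#' @param seed Seed for the draw.
#' @return A reduced [corpus()].
#' @export
subsample_training_set <- function(corp, fraction, seed = 0) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(corp)
  schema <- corpus_schema(corp)
  tr_idx <- which(corp$split == "train")
  n_keep <- max(1L, round(fraction * length(tr_idx)))
  keep <- with_local_seed(seed, sort(sample_from(tr_idx, n_keep)))
  gone <- setdiff(unique(corp$label[tr_idx]), unique(corp$label[keep]))
  if (length(gone))
    warning("class(es) ", paste(schema$names[gone], collapse = ", "),
            " vanished from the training split at fraction ", fraction)
  rows <- sort(c(keep, which(corp$split != "train")))
  corpus(corp$text[rows], corp$label[rows], corp$split[rows], schema)
}

#' Data-volume ablation: macro F1 vs training-set fraction
#'
#' Trains one model per (encoder, fraction) pair on a uniformly
#' subsampled training split and scores the untouched test split,
#' quantifying how performance degrades with less training data.
#'
#' @param corp A [corpus()].
#' @param fractions Training fractions; must include 1.0 (the full-data
#'   reference) and be non-empty.
#' @param encoders List of [encoder_config()] objects, one per variant.
#' @param loss A [loss_config()].
#' @param train A [train_config()].
#' @return Tibble with columns `encoder_id`, `fraction`, `macro_f1`.
#' @export
run_data_volume_experiment <- function(corp, fractions,
                                       encoders = list(encoder_config()),
                                       loss = loss_config(),
                                       train = train_config()) {
  if (length(fractions) == 0) stop("fractions must be non-empty")
  if (!any(abs(fractions - 1) < 1e-12))
    stop("fractions must include 1.0 as the full-data reference")
  rows <- list()
  for (enc in encoders) {
    for (f in fractions) {
      sub <- subsample_training_set(corp, f, seed = train$seed)
      fit <- train_single_model(sub, enc, loss, train)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        encoder_id = enc$encoder_id, fraction = f,
        macro_f1 = evaluate_model(fit, corp, "test")$macro_f1)
    }
  }
  do.call(rbind, rows)
}

#' Train a diverse-seed ensemble
#'
#' Trains `K` members that differ only in their seed (hence in their
#' initial embedding table and batch order) — the desk-scale stand-in for
#' heterogeneous pre-trained input representations — and returns the
#' fitted members ready for [predict_ensemble()].
#'
#' @param corp A [corpus()].
#' @param n_members Number of members `K` (default 5).
#' @param seeds Member seeds (default `base_seed + 0:(K-1)`).
#' @param base_seed First member seed.
#' @param encoder,loss,train Shared configurations; each member gets
#'   `encoder_id` suffixed with its seed and `train$seed` replaced.
#' @return List of `critens_fit` objects.
#' @export
train_ensemble <- function(corp, n_members = 5L, seeds = NULL, base_seed = 0L,
                           encoder = encoder_config(), loss = loss_config(),
                           train = train_config()) {
  if (is.null(seeds)) seeds <- base_seed + seq_len(n_members) - 1L
  lapply(seeds, function(s) {
    enc <- encoder
    enc$encoder_id <- paste0(encoder$encoder_id, "-s", s)
    tcfg <- train
    tcfg$seed <- as.integer(s)
    train_single_model(corp, enc, loss, tcfg)
  })
}
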