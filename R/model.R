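#' Single-model architecture configuration
#'
#' One member model is: character embeddings -> parallel 1-D convolutions
#' of widths 3, 4, 5 -> rectifier -> masked max-pooling -> concatenated
#' feature representation `r` (dimension `d = length(kernel_widths) *
#' filters_per_width`) -> fully connected layer -> softmax over the `n`
#' categories. `r` doubles as the representation the metric losses act on.
#'
#' @param kernel_widths Convolution window widths (default `c(3, 4, 5)`).
#' @param filters_per_width Filters per width (default 32, so `d = 96`).
#' @param n_classes Number of categories.
#' @return An object of class `critens_model_config`.
#' @export
model_config <- function(kernel_widths = c(3L, 4L, 5L),
                         filters_per_width = 32L, n_classes) {
  stopifnot(all(kernel_widths >= 1), filters_per_width >= 1, n_classes >= 2)
  structure(list(kernel_widths = as.integer(kernel_widths),
                 filters_per_width = as.integer(filters_per_width),
                 n_classes = as.integer(n_classes)),
            class = "critens_model_config")
}

#' Initialize an untrained single model
#'
#' Weights are drawn from a seeded generator: the embedding table (PAD row
#' frozen at zero), one weight matrix and bias per kernel width, and the
#' fully connected output layer. Two models with different seeds start
#' from different embeddings — the mechanism behind ensemble diversity.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param schema A [category_schema()].
#' @param encoder An [encoder_config()].
#' @param config A [model_config()]; `n_classes` defaults to `schema$n`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `critens_model`.
#' @export
init_model <- function(vocab, schema, encoder = encoder_config(),
                       config = model_config(n_classes = schema$n), seed = 0) {
  stopifnot(inherits(vocab, "critens_vocabulary"),
            inherits(schema, "critens_schema"),
            encoder$max_length >= max(config$kernel_widths),
            config$n_classes == schema$n)
  dm <- encoder$embedding_dim
  Fw <- config$filters_per_width
  d <- length(config$kernel_widths) * Fw
  params <- with_local_seed(seed, {
    conv <- lapply(config$kernel_widths, function(w) {
      list(W = matrix(stats::rnorm(w * dm * Fw, sd = sqrt(2 / (w * dm))),
                      w * dm, Fw),
           b = numeric(Fw))
    })
    fc <- list(W = matrix(stats::rnorm(d * config$n_classes, sd = sqrt(1 / d)),
                          d, config$n_classes),
               b = numeric(config$n_classes))
    E <- matrix(stats::rnorm(vocab$size * dm, sd = 0.1), vocab$size, dm)
    E[1L, ] <- 0
    list(embedding = E, conv = conv, fc = fc)
  })
  structure(c(params,
              list(vocab = vocab, schema = schema, encoder = encoder,
                   config = config, seed = as.integer(seed),
                   feature_dim = d)),
            class = "critens_model")
}

#' @export
print.critens_model <- function(x, ...) {
  cat("<critens_model> encoder=", x$encoder$encoder_id,
      " dim=", x$encoder$embedding_dim, " L=", x$encoder$max_length,
      " d=", x$feature_dim, " n=", x$config$n_classes,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Softmax over a logit vector
#' @param x Numeric vector of scores.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Convolution + masked max-pooling of one embedded sequence
#'
#' For each kernel width `w`, every window of `w` consecutive positions
#' lying fully inside the real (non-PAD) region is convolved, rectified,
#' and the maximum over those valid windows taken per filter. When the
#' real region is shorter than the kernel, the single window anchored at
#' the first real position is used instead (so every non-empty input has
#' a valid window). Because the valid-window set depends only on the real
#' content, the representation is invariant to appending PAD positions —
#' a tested property. The pooled outputs of all widths are concatenated
#' into the feature representation `r`.
#'
#' @param embedded `L x embedding_dim` matrix (see [embed_tokens()]).
#' @param mask Binary vector of length `L` marking real positions.
#' @param model A `critens_model` providing the convolution weights.
#' @return Numeric feature vector `r` of length `feature_dim`.
#' @export
sequence_encode <- function(embedded, mask, model) {
  L <- nrow(embedded)
  if (sum(mask) == 0) stop("all-PAD input: no valid convolution window")
  widths <- model$config$kernel_widths
  out <- vector("list", length(widths))
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    W <- model$conv[[wi]]$W
    b <- model$conv[[wi]]$b
    P <- L - w + 1
    valid <- vapply(seq_len(P), function(p) all(mask[p:(p + w - 1)] == 1), logical(1))
    if (!any(valid)) {
      # real region shorter than the kernel: anchor one window at the
      # first real position (clipped to fit the buffer)
      valid[min(min(which(mask == 1)), P)] <- TRUE
    }
    acts <- vapply(which(valid), function(p) {
      z <- drop(crossprod(as.vector(t(embedded[p:(p + w - 1), , drop = FALSE])), W)) + b
      pmax(z, 0)
    }, numeric(length(b)))
    out[[wi]] <- apply(matrix(acts, nrow = length(b)), 1, max)
  }
  unlist(out, use.names = FALSE)
}

#' Classify a feature representation
#'
#' Applies the fully connected layer, `x = W'r + b`, and the softmax,
#' `p_t = exp(x_t) / sum_j exp(x_j)`.
#'
#' @param r Feature vector from [sequence_encode()].
#' @param model A `critens_model`.
#' @return List with logits `x` and probabilities `p`.
#' @export
classify <- function(r, model) {
  if (any(!is.finite(r))) stop("non-finite feature representation")
  x <- drop(crossprod(model$fc$W, r)) + model$fc$b
  list(x = x, p = softmax(x))
}

# ---- batched forward / backward (training + prediction hot path) --------
#
# Layout: ids is L x B (samples in columns); the embedded matrix X is
# (L*B) x dim with per-sample blocks contiguous. Window unrolling turns
# each width-w conv into one (P*B) x (w*dim) by (w*dim) x F matrix product.
# Texts are left-aligned by tokenize(), so the fully-inside windows of
# sample s are p <= len[s] - w + 1, with the single window p = 1 as the
# short-text fallback.

forward_batch <- function(model, ids, len, want_cache = FALSE) {
  L <- nrow(ids); B <- ncol(ids)
  dm <- model$encoder$embedding_dim
  Fw <- model$config$filters_per_width
  widths <- model$config$kernel_widths
  X <- model$embedding[as.vector(ids), , drop = FALSE]
  r <- matrix(0, B, model$feature_dim)
  caches <- if (want_cache) vector("list", length(widths))
  for (wi in seq_along(widths)) {
    w <- widths[wi]
    P <- L - w + 1L
    base <- rep((seq_len(B) - 1L) * L, each = P) + rep(seq_len(P), B)
    Win <- matrix(0, P * B, w * dm)
    for (o in 0:(w - 1L))
      Win[, o * dm + seq_len(dm)] <- X[base + o, , drop = FALSE]
    C <- Win %*% model$conv[[wi]]$W
    C <- C + rep(model$conv[[wi]]$b, each = P * B)
    A <- C
    A[A < 0] <- 0
    thr <- ifelse(len >= w, len - w + 1L, 1L)
    invalid <- rep(seq_len(P), B) > rep(thr, each = P)
    # every sample keeps window 1 (non-empty text), so a max always exists
    A[invalid, ] <- -Inf
    dim(A) <- c(P, B * Fw)
    amax <- max.col(t(A), ties.method = "first")
    pooled <- A[cbind(amax, seq_len(B * Fw))]
    r[, (wi - 1L) * Fw + seq_len(Fw)] <- matrix(pooled, B, Fw)
    if (want_cache)
      caches[[wi]] <- list(Win = Win, C = C, amax = amax, P = P, base = base)
  }
  logits <- r %*% model$fc$W
  logits <- logits + rep(model$fc$b, each = B)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(r = r, logits = logits, probs = probs,
       cache = if (want_cache) list(widths = caches, X_ids = as.vector(ids),
                                    L = L, B = B))
}

# Backward pass: dZ is the gradient at the logits (B x n), dR_extra the
# direct gradient at the feature representation from the metric term
# (B x d or NULL). Returns gradients matching the parameter structure.
backward_batch <- function(model, fwd, dZ, dR_extra = NULL) {
  B <- fwd$cache$B; L <- fwd$cache$L
  dm <- model$encoder$embedding_dim
  Fw <- model$config$filters_per_width
  widths <- model$config$kernel_widths
  dWfc <- crossprod(fwd$r, dZ)
  dbfc <- colSums(dZ)
  dR <- tcrossprod(dZ, model$fc$W)
  if (!is.null(dR_extra)) dR <- dR + dR_extra
  dX <- matrix(0, L * B, dm)
  gconv <- vector("list", length(widths))
  for (wi in seq_along(widths)) {
    cw <- fwd$cache$widths[[wi]]
    P <- cw$P
    dRw <- dR[, (wi - 1L) * Fw + seq_len(Fw), drop = FALSE]
    j <- seq_len(B * Fw)
    rows <- ((j - 1L) %% B) * P + cw$amax
    cols <- (j - 1L) %/% B + 1L
    dA <- matrix(0, P * B, Fw)
    dA[cbind(rows, cols)] <- as.vector(dRw)
    dC <- dA * (cw$C > 0)
    gconv[[wi]] <- list(W = crossprod(cw$Win, dC), b = colSums(dC))
    dWin <- tcrossprod(dC, model$conv[[wi]]$W)
    for (o in 0:(widths[wi] - 1L)) {
      idx <- cw$base + o
      dX[idx, ] <- dX[idx, ] + dWin[, o * dm + seq_len(dm), drop = FALSE]
    }
  }
  gE <- matrix(0, nrow(model$embedding), dm)
  agg <- rowsum(dX, group = fwd$cache$X_ids)
  gE[as.integer(rownames(agg)), ] <- agg
  gE[1L, ] <- 0  # PAD frozen
  list(embedding = gE, conv = gconv, fc = list(W = dWfc, b = dbfc))
}

#' Predict class probabilities with a single model
#'
#' Tokenizes each sentence with the model's own vocabulary and maximum
#' length, runs the forward pass, and returns the softmax matrix plus the
#' argmax predictions (ties to the lowest class index).
#'
#' @param model A trained `critens_model`.
#' @param texts Character vector of sentences.
#' @return List with `probs` (`length(texts) x n` matrix) and integer
#'   `pred`.
#' @export
predict_probs <- function(model, texts) {
  tk <- tokenize_batch(texts, model$vocab, model$encoder$max_length)
  fwd <- forward_batch(model, tk$ids, tk$len)
  list(probs = fwd$probs, pred = max.col(fwd$probs, ties.method = "first"))
}
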