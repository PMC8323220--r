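# Independent brute-force oracles, written as literal loops over the
# printed formulas; deliberately naive and kept apart from the package's
# vectorized implementations.

oracle_distance <- function(r_i, r_j) {
  s <- 0
  for (t in seq_along(r_i)) s <- s + (r_i[t] - r_j[t])^2
  s / length(r_i)
}

oracle_intra <- function(S) {
  n <- nrow(S)
  if (n < 2) return(0)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    acc <- acc + oracle_distance(S[i, ], S[j, ])
  2 / (n^2 - n) * acc
}

oracle_inter <- function(S_p, S_q, m) {
  if (nrow(S_p) == 0 || nrow(S_q) == 0) return(0)
  acc <- 0
  for (i in seq_len(nrow(S_p))) for (j in seq_len(nrow(S_q)))
    acc <- acc + max(0, m - oracle_distance(S_p[i, ], S_q[j, ]))
  acc / (nrow(S_p) * nrow(S_q))
}

oracle_metric <- function(R, labels, lambda, m) {
  classes <- sort(unique(labels))
  total <- 0
  for (k in classes) {
    Sk <- R[labels == k, , drop = FALSE]
    inter_sum <- 0
    for (i in classes) {
      if (i == k) next
      Si <- R[labels == i, , drop = FALSE]
      inter_sum <- inter_sum + oracle_inter(Sk, Si, m)
    }
    total <- total + oracle_intra(Sk) + lambda * inter_sum
  }
  total
}

oracle_focal <- function(p, y, gamma) {
  vals <- numeric(length(y))
  for (s in seq_along(y)) {
    pt <- min(max(p[s, y[s]], 1e-12), 1)
    vals[s] <- -(1 - pt)^gamma * log(pt)
  }
  mean(vals)
}

# Closed-form paired t-test.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1))
}

# Per-sample recomputation of the four metrics, looping classes.
oracle_metrics <- function(y_true, y_pred, n) {
  prec <- rec <- f1 <- numeric(n)
  for (k in seq_len(n)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(y_true == y_pred) / length(y_true),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# Brute-force masked conv + max-pool for one width: slide every window
# fully inside the real region (or the one anchored at the first real
# position if the text is shorter than the kernel), rectify, take the
# max per filter.
oracle_pool <- function(embedded, mask, W, b, w) {
  L <- nrow(embedded)
  starts <- Filter(function(p) all(mask[p:(p + w - 1)] == 1), seq_len(L - w + 1))
  if (length(starts) == 0) starts <- min(min(which(mask == 1)), L - w + 1)
  best <- rep(-Inf, length(b))
  for (p in starts) {
    v <- as.vector(t(embedded[p:(p + w - 1), , drop = FALSE]))
    z <- pmax(drop(v %*% W) + b, 0)
    best <- pmax(best, z)
  }
  best
}

random_prob_matrix <- function(n_samples, n_classes) {
  x <- matrix(stats::runif(n_samples * n_classes), n_samples)
  x / rowSums(x)
}

# Bag-of-tokens nearest-centroid classifier over the generator's
# 3-character pseudo-tokens; perfect on noise-free corpora by design.
centroid_classify <- function(corp) {
  toks <- function(s) substring(s, seq(1, nchar(s), 3), pmin(seq(3, nchar(s) + 2, 3), nchar(s)))
  tr <- corp[corp$split == "train", ]
  te <- corp[corp$split == "test", ]
  vocab <- sort(unique(unlist(lapply(tr$text, toks))))
  bow <- function(texts) {
    M <- matrix(0, length(texts), length(vocab))
    for (i in seq_along(texts)) {
      tb <- table(factor(toks(texts[i]), levels = vocab))
      M[i, ] <- as.numeric(tb)
    }
    M
  }
  n <- corpus_schema(corp)$n
  Mtr <- bow(tr$text)
  centroids <- matrix(0, n, length(vocab))
  for (k in seq_len(n)) if (any(tr$label == k))
    centroids[k, ] <- colMeans(Mtr[tr$label == k, , drop = FALSE])
  Mte <- bow(te$text)
  sims <- Mte %*% t(centroids)
  list(pred = max.col(sims, ties.method = "first"), truth = te$label)
}
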