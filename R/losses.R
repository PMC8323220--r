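#' Objective hyperparameters
#'
#' The combined training objective is `L = FocalLoss + mu * L_metric`,
#' where the metric loss is `L_metric = sum_k { L_intra(k) +
#' lambda * sum_{i != k} L_inter(k, i) }` over the classes present in a
#' batch. Defaults follow the values used for the eligibility-criteria
#' task: `gamma = 2`, `lambda = 0.1`, `mu = 1`, margin `m = 0.1`. The
#' margin can be set per ensemble member, as its best value depends on the
#' embedding method.
#'
#' @param gamma Focusing exponent of the focal loss (`gamma = 0` recovers
#'   cross-entropy on the true class).
#' @param lambda Weight of the inter-class term inside the metric loss.
#' @param mu Weight of the metric loss in the combined objective.
#' @param margin Desired minimum inter-class feature distance `m`.
#' @return An object of class `critens_loss_config`.
#' @export
loss_config <- function(gamma = 2, lambda = 0.1, mu = 1, margin = 0.1) {
  stopifnot(is.finite(gamma), gamma >= 0, is.finite(lambda), lambda >= 0,
            is.finite(mu), mu >= 0, is.finite(margin), margin > 0)
  structure(list(gamma = gamma, lambda = lambda, mu = mu, margin = margin),
            class = "critens_loss_config")
}

#' Normalized squared Euclidean feature distance
#'
#' `D(r_i, r_j) = (1/d) * ||r_i - r_j||_2^2` with `d` the feature
#' dimension. Symmetric, non-negative, zero iff the representations
#' coincide.
#'
#' @param r_i,r_j Numeric feature vectors of equal dimension.
#' @return Non-negative scalar.
#' @export
feature_distance <- function(r_i, r_j) {
  if (length(r_i) != length(r_j)) stop("feature dimension mismatch")
  mean((r_i - r_j)^2)
}

# Pairwise distance matrix D_ij = (1/d) ||r_i - r_j||^2 for rows of R.
pairwise_feature_distance <- function(R) {
  sq <- rowSums(R^2)
  D <- (outer(sq, sq, "+") - 2 * tcrossprod(R)) / ncol(R)
  D[D < 0] <- 0
  D
}

#' Intra-class loss
#'
#' Mean normalized squared distance over all unordered pairs within one
#' class set: `[2 / (|S|^2 - |S|)] * sum_{i<j} D(r_i, r_j)`. Sets with
#' fewer than two members contribute 0 (the pair mean is undefined there).
#'
#' @param S Matrix with one member representation per row.
#' @return Non-negative scalar.
#' @export
intra_class_loss <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) < 2) return(0)
  D <- pairwise_feature_distance(S)
  sum(D[upper.tri(D)]) * 2 / (nrow(S)^2 - nrow(S))
}

#' Inter-class margin loss
#'
#' Mean hinge penalty over all cross pairs of two class sets:
#' `[1 / (|S_p| |S_q|)] * sum_{i in S_p, j in S_q} max(0, m - D(r_i, r_j))`.
#' Cross pairs farther apart than the margin `m` contribute zero; an empty
#' set yields 0.
#'
#' @param S_p,S_q Matrices with one member representation per row.
#' @param margin Margin `m > 0`.
#' @return Non-negative scalar.
#' @export
inter_class_loss <- function(S_p, S_q, margin) {
  S_p <- as.matrix(S_p); S_q <- as.matrix(S_q)
  if (nrow(S_p) == 0 || nrow(S_q) == 0) return(0)
  if (ncol(S_p) != ncol(S_q)) stop("feature dimension mismatch")
  sqp <- rowSums(S_p^2); sqq <- rowSums(S_q^2)
  D <- (outer(sqp, sqq, "+") - 2 * tcrossprod(S_p, S_q)) / ncol(S_p)
  D[D < 0] <- 0
  mean(pmax(0, margin - D))
}

#' Total metric loss of a labeled batch
#'
#' Sums, over every class `k` present in the batch, the intra-class loss
#' plus `lambda` times the inter-class losses against every other present
#' class: `sum_k { L_intra(k) + lambda * sum_{i != k} L_inter(k, i) }`.
#' The inner sum runs over ordered class pairs, so each unordered pair
#' contributes twice — the formula is applied exactly as written, with
#' `lambda` absorbing the constant factor.
#'
#' @param R Matrix of feature representations, one sample per row.
#' @param labels Integer class index per row.
#' @param config A [loss_config()].
#' @return Non-negative scalar.
#' @export
metric_loss <- function(R, labels, config) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == length(labels))
  classes <- sort(unique(labels))
  groups <- lapply(classes, function(k) R[labels == k, , drop = FALSE])
  total <- 0
  for (a in seq_along(classes)) {
    total <- total + intra_class_loss(groups[[a]])
    for (b in seq_along(classes)) {
      if (b == a) next
      total <- total + config$lambda *
        inter_class_loss(groups[[a]], groups[[b]], config$margin)
    }
  }
  total
}

#' Cross-entropy loss
#'
#' `-log p_y` for the true class `y` (one-hot reading of the multi-class
#' cross entropy, natural logarithm). For a matrix of probability vectors
#' the mean over samples is returned. Probabilities are clamped to
#' `[1e-12, 1]` inside the logarithm.
#'
#' @param p Probability vector, or matrix with one probability vector per
#'   row.
#' @param y True class index (vector of indices for a matrix `p`).
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(p, y) {
  focal_loss(p, y, gamma = 0)
}

#' Focal loss
#'
#' `-(1 - p_t)^gamma * log(p_t)` with `p_t` the predicted probability of
#' the true class. The modulation coefficient `(1 - p_t)^gamma` shrinks
#' the contribution of easy, well-classified samples so training focuses
#' on hard ones under class imbalance; `gamma = 0` recovers cross-entropy.
#' For a matrix of probability vectors the mean over samples is returned.
#'
#' @param p Probability vector, or matrix with one row per sample.
#' @param y True class index (vectorized for a matrix `p`).
#' @param gamma Focusing exponent `>= 0`.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(p, y, gamma = 2) {
  stopifnot(gamma >= 0)
  if (is.matrix(p)) {
    stopifnot(nrow(p) == length(y))
    pt <- clamp_prob(p[cbind(seq_len(nrow(p)), y)])
  } else {
    pt <- clamp_prob(p[y])
  }
  mean(-(1 - pt)^gamma * log(pt))
}

#' Combined training objective
#'
#' `L = FocalLoss + mu * L_metric`: the mean focal loss of the batch plus
#' `mu` times the batch metric loss on the feature representations.
#'
#' @param p Matrix of predicted probability vectors (one row per sample).
#' @param y True class indices.
#' @param R Matrix of feature representations (one row per sample).
#' @param labels Class indices grouping `R` (normally identical to `y`).
#' @param config A [loss_config()].
#' @return Non-negative scalar.
#' @export
combined_loss <- function(p, y, R, labels = y, config = loss_config()) {
  focal_loss(p, y, config$gamma) + config$mu * metric_loss(R, labels, config)
}

# Gradient of mu * metric_loss w.r.t. the representation rows. Built from
# the symmetric per-pair coefficient matrix T' (dLoss/dD_ij): c_k for an
# intra pair of class k, -2*lambda/(|S_p||S_q|) for an active (< margin)
# inter pair. dL/dr_i = (2/d) sum_j T'_ij (r_i - r_j).
metric_loss_grad <- function(R, labels, config) {
  B <- nrow(R)
  if (B < 2) return(matrix(0, B, ncol(R)))
  D <- pairwise_feature_distance(R)
  same <- outer(labels, labels, "==")
  sizes <- table(factor(labels, levels = sort(unique(labels))))
  cnt <- as.numeric(sizes[as.character(labels)])
  Tp <- matrix(0, B, B)
  # intra: classes with >= 2 members, coefficient 2/(|S|^2-|S|)
  intra_ok <- same & cnt >= 2
  Tp[intra_ok] <- (2 / (cnt^2 - cnt))[row(Tp)[intra_ok]]
  # inter: active hinge pairs, coefficient -2*lambda/(|S_p||S_q|)
  inter_act <- !same & D < config$margin
  Tp[inter_act] <- -2 * config$lambda /
    (cnt[row(Tp)[inter_act]] * cnt[col(Tp)[inter_act]])
  diag(Tp) <- 0
  g <- (2 / ncol(R)) * (rowSums(Tp) * R - Tp %*% R)
  config$mu * g
}
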