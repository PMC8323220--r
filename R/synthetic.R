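#' Specification of a synthetic imbalanced short-text corpus
#'
#' The generator emulates the structure of a multi-category
#' eligibility-criteria corpus: many categories with a Zipf-like long-tailed
#' class distribution, short unsegmented character sequences, and per-class
#' indicative vocabulary mixed with shared noise tokens. Defaults describe
#' the study corpus used throughout the package's experiments: 8 classes,
#' 2,000 sentences, Zipf exponent 1.5, 30% noise tokens.
#'
#' @param n_classes Number of categories (>= 2).
#' @param total_samples Total number of sentences.
#' @param imbalance_exponent Zipf exponent `s >= 0` over class sizes: class
#'   `k` has expected share proportional to `k^-s`; 0 gives a balanced
#'   corpus.
#' @param class_vocab_size Number of class-indicative pseudo-tokens private
#'   to each class.
#' @param shared_vocab_size Number of noise pseudo-tokens shared by all
#'   classes.
#' @param noise_rate Probability in `[0, 1]` that a token position draws
#'   from the shared pool instead of the class-private pool.
#' @param length_range Integer `(min, max)` sentence length in tokens
#'   (each pseudo-token is 3 characters; sentences are space-free
#'   concatenations, mirroring unsegmented text).
#' @param split_fractions Train/valid/test fractions summing to 1.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return An object of class `critens_synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 8, total_samples = 2000,
                           imbalance_exponent = 1.5, class_vocab_size = 20,
                           shared_vocab_size = 50, noise_rate = 0.3,
                           length_range = c(4L, 12L),
                           split_fractions = c(0.6, 0.2, 0.2), seed = 0) {
  stopifnot(n_classes >= 2, total_samples >= 1, imbalance_exponent >= 0,
            class_vocab_size >= 1, shared_vocab_size >= 1,
            noise_rate >= 0, noise_rate <= 1,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            length(split_fractions) == 3, all(split_fractions >= 0))
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  structure(list(n_classes = as.integer(n_classes),
                 total_samples = as.integer(total_samples),
                 imbalance_exponent = imbalance_exponent,
                 class_vocab_size = as.integer(class_vocab_size),
                 shared_vocab_size = as.integer(shared_vocab_size),
                 noise_rate = noise_rate,
                 length_range = as.integer(length_range),
                 split_fractions = split_fractions,
                 seed = as.integer(seed)),
            class = "critens_synthetic_spec")
}

#' Normalized Zipf class weights of a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return Numeric vector of class probabilities (length `n_classes`).
#' @export
zipf_class_weights <- function(spec) {
  w <- seq_len(spec$n_classes)^(-spec$imbalance_exponent)
  w / sum(w)
}

# Deterministic 3-letter pseudo-token for a global token index (base-26).
token_string <- function(idx) {
  letters3 <- letters
  i <- idx - 1L
  paste0(letters3[i %/% 676L + 1L], letters3[(i %/% 26L) %% 26L + 1L],
         letters3[i %% 26L + 1L])
}

#' Generate a synthetic imbalanced corpus
#'
#' Class sizes are one multinomial draw over the normalized Zipf weights.
#' Each sentence of class `k` is a concatenation of 3-character
#' pseudo-tokens: with probability `noise_rate` a token comes from the
#' shared pool, otherwise from class `k`'s private pool. Private pools are
#' disjoint across classes and from the shared pool, so at `noise_rate = 0`
#' the classes are perfectly separable by token occurrence — the
#' upper-bound fixture. Splits are stratified per class (classes with fewer
#' than 3 records go entirely to train). Identical specs yield
#' byte-identical corpora.
#'
#' @param spec A [synthetic_spec()].
#' @return A [corpus()] with schema names `C01`, `C02`, ...
#' @export
generate_synthetic_corpus <- function(spec) {
  stopifnot(inherits(spec, "critens_synthetic_spec"))
  K <- spec$n_classes
  if (spec$total_samples < K)
    stop("total_samples < n_classes: cannot stratify every class")
  schema <- category_schema(sprintf("C%02d", seq_len(K)))
  cv <- spec$class_vocab_size
  shared_pool <- spec$n_classes * cv + seq_len(spec$shared_vocab_size)

  with_local_seed(spec$seed, {
    sizes <- as.integer(stats::rmultinom(1, spec$total_samples,
                                         zipf_class_weights(spec)))
    text <- character(spec$total_samples)
    label <- integer(spec$total_samples)
    split <- character(spec$total_samples)
    pos <- 0L
    for (k in seq_len(K)) {
      nk <- sizes[k]
      if (nk == 0L) next
      private_pool <- (k - 1L) * cv + seq_len(cv)
      texts_k <- vapply(seq_len(nk), function(i) {
        len <- sample_from(spec$length_range[1]:spec$length_range[2], 1)
        from_shared <- stats::runif(len) < spec$noise_rate
        ids <- integer(len)
        ids[from_shared] <- sample_from(shared_pool, sum(from_shared), replace = TRUE)
        ids[!from_shared] <- sample_from(private_pool, sum(!from_shared), replace = TRUE)
        paste(token_string(ids), collapse = "")
      }, character(1))
      idx <- pos + seq_len(nk)
      text[idx] <- texts_k
      label[idx] <- k
      split[idx] <- stratified_split_tags(nk, spec$split_fractions)
      pos <- pos + nk
    }
    keep <- seq_len(pos)
    corpus(text[keep], label[keep], split[keep], schema)
  })
}

# Split tags for one class: shuffled partition by fractions; tiny classes
# (< 3 records) go entirely to train, and train always keeps >= 1 record.
stratified_split_tags <- function(nk, fractions) {
  if (nk < 3L) return(rep("train", nk))
  n_va <- floor(fractions[2] * nk)
  n_te <- floor(fractions[3] * nk)
  n_tr <- nk - n_va - n_te
  tags <- rep(c("train", "valid", "test"), c(n_tr, n_va, n_te))
  tags[sample.int(nk)]
}
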