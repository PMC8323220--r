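#' Build a character vocabulary from training texts
#'
#' Every character occurring in the training split receives a dense id.
#' Ids 1 and 2 are reserved for PAD and UNK; characters start at id 3,
#' ordered by first occurrence (deterministic across calls). Characters
#' unseen at training time tokenize to UNK.
#'
#' @param texts Character vector of training-split sentences.
#' @return An object of class `critens_vocabulary` with fields `chars`
#'   (named integer map character -> id), `size`, `pad_id`, `unk_id`.
#' @export
build_vocabulary <- function(texts) {
  if (length(texts) == 0) stop("cannot build a vocabulary from an empty training set")
  chars <- unique(unlist(strsplit(enc2utf8(texts), "", fixed = TRUE), use.names = FALSE))
  ids <- seq_along(chars) + 2L
  names(ids) <- chars
  structure(list(chars = ids, size = length(chars) + 2L,
                 pad_id = 1L, unk_id = 2L),
            class = "critens_vocabulary")
}

#' @export
print.critens_vocabulary <- function(x, ...) {
  cat("<critens_vocabulary> ", x$size, " ids (", x$size - 2L,
      " characters + PAD + UNK)\n", sep = "")
  invisible(x)
}

#' Serialize / load a vocabulary as JSON
#' @param vocab A [build_vocabulary()] result.
#' @param path JSON file path.
#' @return `path` (write) or the vocabulary (read).
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$chars), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  m <- jsonlite::read_json(path)
  ids <- vapply(m, as.integer, integer(1))
  structure(list(chars = ids, size = length(ids) + 2L, pad_id = 1L, unk_id = 2L),
            class = "critens_vocabulary")
}

#' Tokenize text to a fixed-length id sequence
#'
#' Characters map to vocabulary ids (UNK for unseen characters); sequences
#' longer than `L` keep the first `L` characters (left edge); shorter
#' sequences are right-padded with PAD, with the mask marking real
#' positions. Empty text yields a single UNK position so tokenization is
#' total.
#'
#' @param text One character string.
#' @param vocab A [build_vocabulary()] result.
#' @param L Fixed output length (>= 5, the largest convolution width).
#' @return List with integer `ids` and binary `mask`, both length `L`.
#' @export
tokenize <- function(text, vocab, L = 64L) {
  stopifnot(inherits(vocab, "critens_vocabulary"), L >= 5)
  ch <- strsplit(enc2utf8(text), "", fixed = TRUE)[[1]]
  ids <- unname(vocab$chars[ch])
  ids[is.na(ids)] <- vocab$unk_id
  if (length(ids) == 0) ids <- vocab$unk_id
  if (length(ids) > L) ids <- ids[seq_len(L)]
  n_real <- length(ids)
  list(ids = c(ids, rep(vocab$pad_id, L - n_real)),
       mask = c(rep(1L, n_real), rep(0L, L - n_real)))
}

# Tokenize a vector of texts into L x B id and mask matrices (one sample
# per column; column-major layout matches the conv unrolling downstream).
tokenize_batch <- function(texts, vocab, L) {
  B <- length(texts)
  ids <- matrix(vocab$pad_id, nrow = L, ncol = B)
  len <- integer(B)
  for (b in seq_len(B)) {
    tk <- tokenize(texts[b], vocab, L)
    ids[, b] <- tk$ids
    len[b] <- sum(tk$mask)
  }
  list(ids = ids, len = len)
}

#' Encoder configuration
#'
#' The encoder contract is: text -> `L x embedding_dim` real matrix. The
#' reference implementation is a trainable character-embedding lookup
#' table; ensemble diversity comes from independently seeded (and
#' optionally differently sized) tables, one per member, standing in for
#' heterogeneous pre-trained input representations. External pre-trained
#' encoders satisfying the same contract can be plugged in.
#'
#' @param embedding_dim Embedding dimension (default 16).
#' @param max_length Fixed sequence length `L` (default 64; criteria
#'   sentences are short). Must be at least the largest kernel width (5).
#' @param encoder_id Name of the encoder variant.
#' @return An object of class `critens_encoder_config`.
#' @export
encoder_config <- function(embedding_dim = 16L, max_length = 64L,
                           encoder_id = "char-emb") {
  stopifnot(embedding_dim >= 1, max_length >= 5)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 max_length = as.integer(max_length),
                 encoder_id = as.character(encoder_id)),
            class = "critens_encoder_config")
}

# Seeded embedding table: vocab_size x dim, PAD row frozen at zero.
init_embedding <- function(vocab_size, dim, seed) {
  E <- with_local_seed(seed,
    matrix(stats::rnorm(vocab_size * dim, sd = 0.1), vocab_size, dim))
  E[1L, ] <- 0
  E
}

#' Embed a token sequence
#'
#' Looks up each position's id in the model's embedding table. PAD rows are
#' the frozen all-zero PAD embedding, so padding carries no signal into the
#' convolution stack.
#'
#' @param tokens A [tokenize()] result.
#' @param model A trained or initialized `critens_model`.
#' @return An `L x embedding_dim` real matrix.
#' @export
embed_tokens <- function(tokens, model) {
  ids <- tokens$ids
  if (any(ids < 1L | ids > nrow(model$embedding)))
    stop("token id outside the embedding table")
  model$embedding[ids, , drop = FALSE]
}
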