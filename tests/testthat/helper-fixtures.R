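# Small in-code fixtures shared across test files.

tiny_corpus <- function() {
  schema <- category_schema(c("Age", "Gender", "Sign"))
  corpus(text = c("年龄 > 80岁", "男、女不限", "严重听力或视力障碍",
                  "年龄18 ~ 70岁", "性别不限", "听力障碍"),
         label = c(1L, 2L, 3L, 1L, 2L, 3L),
         split = c("train", "train", "train", "test", "test", "test"),
         schema = schema)
}

# Fast-training corpus: small, separable-ish, used where the test is about
# the training loop's mechanics rather than its accuracy.
small_train_corpus <- function(seed = 0, noise = 0.2, n = 400, classes = 4) {
  generate_synthetic_corpus(synthetic_spec(
    n_classes = classes, total_samples = n, imbalance_exponent = 1,
    class_vocab_size = 10, shared_vocab_size = 20, noise_rate = noise,
    length_range = c(3L, 8L), seed = seed))
}

fast_train_config <- function(epochs = 6, seed = 0, batch_size = 64) {
  train_config(epochs = epochs, seed = seed, batch_size = batch_size)
}
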