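#' Soft voting over member probability matrices
#'
#' Averages the members' softmax outputs per sample and predicts the class
#' of the maximum averaged probability: `O = argmax (1/K) sum_i M^i`.
#' All members are weighted equally. Argmax ties go to the lowest class
#' index, making predictions deterministic.
#'
#' @param member_probabilities List of `K >= 1` matrices, each samples
#'   x classes, rows summing to 1 within `1e-6`.
#' @return List with `pred` (integer predictions) and `probs` (the
#'   averaged matrix, itself row-stochastic).
#' @export
soft_vote <- function(member_probabilities) {
  stopifnot(is.list(member_probabilities), length(member_probabilities) >= 1)
  dims <- lapply(member_probabilities, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("member probability matrices differ in shape")
  for (M in member_probabilities) {
    if (any(abs(rowSums(M) - 1) > 1e-6))
      stop("member rows must be probability vectors summing to 1")
  }
  avg <- Reduce(`+`, member_probabilities) / length(member_probabilities)
  list(pred = max.col(avg, ties.method = "first"), probs = avg)
}

#' Ensemble prediction on a corpus split
#'
#' Runs every member's forward pass on the chosen split, assembles the
#' per-member probability matrices, and applies [soft_vote()]. Members
#' must share one category schema.
#'
#' @param models List of trained `critens_model` objects.
#' @param corp A [corpus()].
#' @param split Which split to predict (default `"test"`).
#' @return List with `pred`, `probs` (averaged), `member_probs`,
#'   `y_true`, and the schema.
#' @export
predict_ensemble <- function(models, corp, split = "test") {
  stopifnot(length(models) >= 1)
  schemas <- lapply(models, function(m) m$schema$names)
  if (!all(vapply(schemas, identical, logical(1), schemas[[1]])))
    stop("ensemble members disagree on the category schema")
  part <- corpus_split(corp, split)
  member_probs <- lapply(models, function(m) predict_probs(m, part$text)$probs)
  vote <- soft_vote(member_probs)
  list(pred = vote$pred, probs = vote$probs, member_probs = member_probs,
       y_true = part$label, schema = models[[1]]$schema)
}
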