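#' Category schema
#'
#' An ordered set of category names with stable dense indices. Labels are
#' stored as strings on disk and as integer indices `1..n` in memory; index
#' assignment is by lexicographic sort of the distinct names, so a schema is
#' reproducible from the corpus itself without a side-channel file.
#'
#' @param names Character vector of unique category names.
#' @return An object of class `critens_schema` with fields `names` and `n`.
#' @export
category_schema <- function(names) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("category names must be unique")
  structure(list(names = names, n = length(names)), class = "critens_schema")
}

#' @export
print.critens_schema <- function(x, ...) {
  cat("<critens_schema> ", x$n, " categories: ",
      paste(utils::head(x$names, 8), collapse = ", "),
      if (x$n > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Build a labeled corpus object
#'
#' A corpus is a tibble of records (`text`, `label`, `split`) carrying a
#' [category_schema()] as the `"schema"` attribute. `label` is the 1-based
#' index into `schema$names`; `split` is one of `"train"`, `"valid"`,
#' `"test"`.
#'
#' @param text Character vector of raw sentences (non-empty after trimming).
#' @param label Integer vector of category indices in `1..schema$n`.
#' @param split Character vector of split tags (recycled if length 1).
#' @param schema A [category_schema()].
#' @return A `critens_corpus` tibble.
#' @export
corpus <- function(text, label, split = "train", schema) {
  stopifnot(inherits(schema, "critens_schema"))
  label <- as.integer(label)
  n_rec <- length(text)
  split <- rep_len(as.character(split), n_rec)
  if (n_rec > 0) {
    if (any(!nzchar(trimws(text)))) stop("corpus text must be non-empty")
    if (any(label < 1L | label > schema$n)) stop("label index out of schema range")
    if (!all(split %in% c("train", "valid", "test")))
      stop("split must be one of train/valid/test")
  }
  out <- tibble::tibble(text = as.character(text), label = label, split = split)
  attr(out, "schema") <- schema
  class(out) <- c("critens_corpus", class(out))
  out
}

#' Extract the schema of a corpus
#' @param x A `critens_corpus`.
#' @return The attached `critens_schema`.
#' @export
corpus_schema <- function(x) {
  s <- attr(x, "schema", exact = TRUE)
  if (is.null(s)) stop("object carries no category schema")
  s
}

#' Subset a corpus to one split
#' @param x A `critens_corpus`.
#' @param split One of `"train"`, `"valid"`, `"test"`.
#' @export
corpus_split <- function(x, split = c("train", "valid", "test")) {
  split <- match.arg(split)
  corpus(x$text[x$split == split], x$label[x$split == split], split,
         corpus_schema(x))
}

#' Read a labeled corpus from TSV or JSON-lines
#'
#' TSV dialect: UTF-8, no header, two or three columns
#' `text<TAB>label[<TAB>split]`. JSON-lines: one object per line with keys
#' `text`, `label`, and optional `split`. Records missing the split tag
#' default to `"train"`. The schema is built from the sorted distinct label
#' strings, so index assignment is deterministic across runs.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"jsonl"`; default inferred from the extension.
#' @return A [corpus()] (empty, with an empty schema and a warning, for an
#'   empty file).
#' @export
read_corpus <- function(path, format = c("tsv", "jsonl")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(format)) {
    format <- if (grepl("\\.jsonl?$", path)) "jsonl" else "tsv"
  }
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty corpus file: ", path)
    return(corpus(character(), integer(), character(), category_schema(character())))
  }
  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf < 2 | nf > 3)
    if (length(bad))
      stop("line ", bad[1], ": expected 2 or 3 tab-separated fields, got ", nf[bad[1]])
    text <- vapply(fields, `[[`, character(1), 1)
    lab <- vapply(fields, `[[`, character(1), 2)
    split <- vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "train",
                    character(1))
  } else {
    recs <- lapply(seq_along(lines), function(i) {
      r <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("line ", i, ": invalid JSON: ",
                                             conditionMessage(e), call. = FALSE))
      if (is.null(r$text) || is.null(r$label))
        stop("line ", i, ": record must have 'text' and 'label' fields")
      r
    })
    text <- vapply(recs, function(r) as.character(r$text), character(1))
    lab <- vapply(recs, function(r) as.character(r$label), character(1))
    split <- vapply(recs, function(r) {
      if (is.null(r$split)) "train" else as.character(r$split)
    }, character(1))
  }
  empty <- which(!nzchar(trimws(text)))
  if (length(empty)) stop("line ", empty[1], ": empty text field")
  schema <- category_schema(sort(unique(lab), method = "radix"))
  corpus(text, match(lab, schema$names), split, schema)
}

#' Write a corpus to TSV or JSON-lines
#'
#' Labels are written as the schema's name strings. For TSV, records whose
#' text contains a tab or newline are rejected with an error (no escaping is
#' applied), keeping `read_corpus(write_corpus(x))` an exact round-trip.
#'
#' @param x A [corpus()].
#' @param path Output file.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  schema <- corpus_schema(x)
  lab <- schema$names[x$label]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "tsv") {
    if (any(grepl("[\t\n\r]", x$text)))
      stop("TSV output cannot represent text containing tabs or newlines; use jsonl")
    lines <- paste(x$text, lab, x$split, sep = "\t")
  } else {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      jsonlite::toJSON(list(text = x$text[i], label = lab[i], split = x$split[i]),
                       auto_unbox = TRUE)
    }, character(1))
  }
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Per-class record counts
#'
#' Tallies records per category over the full schema, including classes with
#' zero records; the counts sum to the corpus size. This is the diagnostic
#' used to inspect class imbalance before training.
#'
#' @param x A [corpus()].
#' @param split Optional split to restrict to; default all records.
#' @return Integer vector of length `schema$n`, named by category.
#' @export
class_distribution <- function(x, split = NULL) {
  schema <- corpus_schema(x)
  lab <- if (is.null(split)) x$label else x$label[x$split == split]
  counts <- tabulate(lab, nbins = schema$n)
  names(counts) <- schema$names
  counts
}
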