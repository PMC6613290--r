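#' Configuration for paragraph-vector document embeddings
#'
#' Settings follow the original paragraph-vector literature rather than any
#' task-specific tuning: 300 dimensions, context window 5, 20 epochs, minimum
#' term count 5, distributed-bag-of-words variant with 5 negative samples.
#'
#' @param dimension Embedding dimensionality (>= 2).
#' @param context_window Context window (used by the distributed-memory
#'   variant).
#' @param epochs Training epochs (>= 1).
#' @param min_term_count Minimum corpus frequency for a term to enter the
#'   vocabulary.
#' @param variant `"dbow"` (distributed bag-of-words, default) or `"dm"`
#'   (distributed memory, mean-of-context).
#' @param negative Number of negative samples per prediction.
#' @param alpha,min_alpha Initial and floor learning rates (linear decay).
#' @param infer_epochs Epochs used when inferring a vector for a new document
#'   (defaults to `epochs`).
#' @param seed Integer seed for vector initialisation and negative sampling.
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(dimension = 300, context_window = 5, epochs = 20,
                             min_term_count = 5, variant = c("dbow", "dm"),
                             negative = 5, alpha = 0.025, min_alpha = 1e-4,
                             infer_epochs = epochs, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(dimension >= 2, epochs >= 1, min_term_count >= 1,
            context_window >= 1, negative >= 1, alpha > 0)
  structure(list(dimension = as.integer(dimension),
                 context_window = as.integer(context_window),
                 epochs = as.integer(epochs),
                 min_term_count = as.integer(min_term_count),
                 variant = variant, negative = as.integer(negative),
                 alpha = alpha, min_alpha = min_alpha,
                 infer_epochs = as.integer(infer_epochs),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

# coerce input documents to a named list of token vectors
as_token_docs <- function(documents) {
  if (is.character(documents)) documents <- tokenize(documents)
  stopifnot(is.list(documents))
  documents
}

# word2vec-style unigram table: draw negatives proportional to count^0.75
build_neg_table <- function(counts, table_size = 1e5L) {
  p <- counts^0.75
  p <- p / sum(p)
  rep.int(seq_along(counts) - 1L, round(p * table_size) + 1L)
}

#' Train a paragraph-vector embedding model
#'
#' Learns fixed-length document representations from a token corpus in a
#' fully unsupervised way — outcome labels are never seen by this stage, so
#' the training corpus may (and ideally should) be larger than the set of
#' admission documents under analysis, e.g. all clinical notes of a site.
#'
#' @param corpus A list of token vectors (or a character vector of raw texts,
#'   tokenized with the shared tokenizer). Names, if present, are kept as
#'   document ids.
#' @param config An [embedding_config()].
#' @return A `pv_model`: vocabulary, output (and, for the distributed-memory
#'   variant, input) word matrices, the negative-sampling table, the training
#'   document vectors, and the configuration.
#' @export
train_embedding <- function(corpus, config = embedding_config()) {
  docs <- as_token_docs(corpus)
  if (length(docs) == 0L || all(lengths(docs) == 0L))
    stop("embedding training corpus is empty", call. = FALSE)

  counts <- table(unlist(docs, use.names = FALSE))
  counts <- counts[counts >= config$min_term_count]
  if (length(counts) == 0L)
    stop("no terms reach min_term_count; corpus too small", call. = FALSE)
  vocab <- sort(names(counts))
  counts <- as.integer(counts[vocab])

  ids <- lapply(docs, function(toks) {
    m <- match(toks, vocab)
    as.integer(m[!is.na(m)] - 1L)
  })
  neg_table <- build_neg_table(counts)

  fit <- pv_train_cpp(ids, length(vocab), neg_table,
                      dim = config$dimension, window = config$context_window,
                      epochs = config$epochs, negative = config$negative,
                      alpha = config$alpha, min_alpha = config$min_alpha,
                      dm = config$variant == "dm", seed = config$seed)

  doc_vectors <- t(fit$doc_vectors)
  rownames(doc_vectors) <- names(docs)
  structure(list(vocab = vocab, counts = counts,
                 word_out = fit$word_out, word_in = fit$word_in,
                 neg_table = neg_table, doc_vectors = doc_vectors,
                 config = config),
            class = "pv_model")
}

#' Infer document vectors from a trained embedding model
#'
#' Produces one vector per document, in input order, by gradient steps on a
#' fresh document vector against the frozen word matrices. Inference is
#' deterministic for a fixed seed and epoch count. Documents with no
#' in-vocabulary tokens yield the (random) inference prior and are flagged
#' with a warning.
#'
#' @param model A `pv_model` from [train_embedding()].
#' @param documents List of token vectors or character vector of raw texts;
#'   names (or the `ids` argument) become row names.
#' @param ids Optional character ids for the rows.
#' @param seed Integer seed (defaults to the model's training seed).
#' @return A numeric matrix (documents x dimension) with an `oov` attribute
#'   flagging documents that had no in-vocabulary tokens.
#' @export
embed_documents <- function(model, documents, ids = NULL, seed = NULL) {
  stopifnot(inherits(model, "pv_model"))
  docs <- as_token_docs(documents)
  cfg <- model$config
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  doc_seeds <- derive_seeds(seed, max(length(docs), 1L))

  n <- length(docs)
  out <- matrix(NA_real_, n, cfg$dimension)
  oov <- logical(n)
  for (i in seq_len(n)) {
    widx <- match(docs[[i]], model$vocab)
    widx <- as.integer(widx[!is.na(widx)] - 1L)
    oov[i] <- length(widx) == 0L
    out[i, ] <- pv_infer_cpp(widx, model$word_out, model$word_in,
                             model$neg_table, window = cfg$context_window,
                             epochs = cfg$infer_epochs,
                             negative = cfg$negative, alpha = cfg$alpha,
                             min_alpha = cfg$min_alpha,
                             dm = cfg$variant == "dm", seed = doc_seeds[i])
  }
  if (any(oov))
    warning(sprintf("%d document(s) had no in-vocabulary tokens; returned the inference prior",
                    sum(oov)))
  rownames(out) <- ids %||% names(docs)
  attr(out, "oov") <- oov
  out
}

#' @export
print.pv_model <- function(x, ...) {
  cat("<pv_model> ", x$config$variant, " paragraph vectors\n", sep = "")
  cat(sprintf("  vocabulary %d terms; dimension %d; %d training documents\n",
              length(x$vocab), x$config$dimension, nrow(x$doc_vectors)))
  invisible(x)
}
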