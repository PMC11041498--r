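#' Training hyperparameters for the embedding engine
#'
#' Validated container for the tunable training configuration. Ranges follow
#' the conventional tuning grid for claims-code corpora: the vocabulary
#' frequency floor (`min_count`) and the vector size are held fixed during
#' tuning, everything else is searchable.
#'
#' @param vector_size embedding dimension M (>= 1).
#' @param window context half-width, integer in `[1, 10]`.
#' @param epochs training passes over the corpus, integer in `[1, 20]`.
#' @param negative number of negative samples per update, integer in
#'   `[0, 20]`; 0 disables negative sampling.
#' @param ns_exponent smoothing exponent of the noise distribution, in
#'   `[-5, 5]` (negative values oversample rare codes).
#' @param hs logical; add the hierarchical-softmax path loss (may be
#'   combined with negative sampling, in which case both updates apply).
#' @param dm logical; `TRUE` = distributed memory (document vector and
#'   context code vectors jointly predict the target code), `FALSE` =
#'   distributed bag of words (document vector alone predicts each code,
#'   with interleaved skip-gram code-code updates).
#' @param alpha initial learning rate, in `[0.001, 0.1]`; decays linearly
#'   to `alpha/100` over all scheduled updates.
#' @param min_count vocabulary frequency floor.
#' @param sample downsampling parameter; 0 (the default, and the setting
#'   that works best on claims corpora) disables downsampling, otherwise
#'   each token is kept with probability
#'   `min(1, (sqrt(f/sample) + 1) * sample / f)` at corpus frequency `f`.
#' @param seed integer seed for initialization, shuffling, window reduction
#'   and noise draws.
#' @param reduce_window logical; draw the effective window uniformly from
#'   `1..window` at each position (the reference behaviour). Disable for
#'   exact-window analyses.
#' @param static_documents logical; freeze the within-quarter document
#'   shuffle instead of redrawing it each epoch (only relevant when fitting
#'   from claims).
#' @return object of class `patvec_params`.
#' @export
patvec_params <- function(vector_size = 100L, window = 5L, epochs = 5L,
                          negative = 5L, ns_exponent = 0.75, hs = FALSE,
                          dm = FALSE, alpha = 0.025, min_count = 100L,
                          sample = 0, seed = 1L, reduce_window = TRUE,
                          static_documents = FALSE) {
  p <- list(vector_size = as.integer(vector_size), window = as.integer(window),
            epochs = as.integer(epochs), negative = as.integer(negative),
            ns_exponent = as.numeric(ns_exponent), hs = isTRUE(hs),
            dm = isTRUE(dm), alpha = as.numeric(alpha),
            min_count = as.integer(min_count), sample = as.numeric(sample),
            seed = as.integer(seed), reduce_window = isTRUE(reduce_window),
            static_documents = isTRUE(static_documents))
  class(p) <- "patvec_params"
  validate_patvec_params(p)
  p
}

validate_patvec_params <- function(p) {
  chk <- function(cond, msg) if (!cond) stop("patvec_params: ", msg, call. = FALSE)
  chk(p$vector_size >= 1L, "vector_size must be >= 1")
  chk(p$window >= 1L && p$window <= 10L, "window must be in [1, 10]")
  chk(p$epochs >= 1L && p$epochs <= 20L, "epochs must be in [1, 20]")
  chk(p$negative >= 0L && p$negative <= 20L, "negative must be in [0, 20]")
  chk(p$ns_exponent >= -5 && p$ns_exponent <= 5,
      "ns_exponent must be in [-5, 5]")
  chk(p$alpha >= 0.001 && p$alpha <= 0.1, "alpha must be in [0.001, 0.1]")
  chk(p$min_count >= 1L, "min_count must be >= 1")
  chk(p$sample >= 0, "sample must be >= 0")
  chk(p$negative > 0L || p$hs,
      "at least one of negative sampling (negative > 0) or hierarchical softmax (hs) must be active")
  invisible(p)
}

#' @export
print.patvec_params <- function(x, ...) {
  cat(sprintf("patvec hyperparameters: M=%d, %s, window=%d, epochs=%d, negative=%d (exp %.2f), hs=%s, alpha=%g, min_count=%d, sample=%g, seed=%d\n",
              x$vector_size, if (x$dm) "DM" else "DBOW", x$window, x$epochs,
              x$negative, x$ns_exponent, x$hs, x$alpha, x$min_count, x$sample,
              x$seed))
  invisible(x)
}

downsample_keep_prob <- function(vocab, sample) {
  if (sample <= 0) return(numeric(0))
  f <- vocab$count / vocab$total_kept_tokens
  pmin(1, (sqrt(f / sample) + 1) * sample / f)
}

#' Downsample a document by corpus frequency
#'
#' With `sample > 0`, each token is kept independently with probability
#' `min(1, (sqrt(f/sample) + 1) * sample / f)` where `f` is the token's
#' relative corpus frequency; `sample = 0` returns the document unchanged.
#' (Training applies the same rule internally, redrawing per epoch.)
#'
#' @param doc character token vector (already vocabulary-filtered).
#' @param vocab a [build_vocabulary()] result.
#' @param sample downsampling parameter (>= 0).
#' @param seed integer seed.
#' @return character token vector.
#' @export
downsample <- function(doc, vocab, sample, seed = 1L) {
  stopifnot(sample >= 0)
  if (sample == 0) return(doc)
  keep <- downsample_keep_prob(vocab, sample)
  idx <- match(doc, vocab$token)
  with_local_seed(seed, doc[runif(length(doc)) < keep[idx]])
}

resolve_claims <- function(x) {
  if (inherits(x, "patvec_cohort")) x$claims else x
}

#' Fit a patient/code embedding model
#'
#' Trains code vectors and per-patient document vectors on a claims corpus
#' with a shallow predictive network (Doc2Vec family). In distributed-memory
#' mode the mean of the patient vector and the in-window code vectors
#' predicts each target code; in distributed-bag-of-words mode the patient
#' vector alone predicts each code of the document, and skip-gram code-code
#' updates are interleaved so code vectors are trained as well. The loss per
#' update is the negative-sampling logistic loss (with `negative` draws from
#' the smoothed noise distribution, target excluded) and/or the
#' hierarchical-softmax Huffman-path loss; both are summed when both are
#' active. The learning rate decays linearly from `alpha` to `alpha/100`
#' across all scheduled token positions. Training is single-threaded and
#' bit-reproducible for a fixed seed.
#'
#' @param x training input: a claims data.frame (`patient_id`, `quarter`,
#'   `case_id`, `place_id`, `code`, `confirmed`), a `patvec_cohort`, or a
#'   ready-made corpus (named list of token vectors, e.g. from
#'   [build_corpus()]). When claims are given, documents are rebuilt with a
#'   fresh within-quarter shuffle every epoch unless
#'   `params$static_documents` is `TRUE`.
#' @param params a [patvec_params()] configuration.
#' @param quarter_window optional quarter window (`"2016Q1:2018Q4"` or label
#'   vector) applied when building documents from claims.
#' @return object of class `patvec`: list with `code_vectors` (V x M, row
#'   names = codes), `doc_vectors` (N x M, row names = patient ids),
#'   `context_weights`, `hs_weights`, `vocab`, `noise`, `huffman`, `params`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 80, seed = 3))
#' fit <- patvec(cohort, patvec_params(vector_size = 8, epochs = 2,
#'                                     min_count = 2, negative = 3))
#' fit
#' head(predict(fit, cohort$claims[cohort$claims$patient_id == "P000001", ]))
#' @export
patvec <- function(x, params = patvec_params(), quarter_window = NULL) {
  stopifnot(inherits(params, "patvec_params"))
  validate_patvec_params(params)
  from_claims <- is.data.frame(x) || inherits(x, "patvec_cohort")
  claims <- if (from_claims) resolve_claims(x) else NULL
  corpus <- if (from_claims)
    build_corpus(claims, window = quarter_window,
                 seed = mix_seed(params$seed, 11L, 1L))
  else x
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)

  vocab <- build_vocabulary(corpus, params$min_count)
  if (length(vocab$token) == 0L)
    stop("vocabulary is empty after the min_count filter", call. = FALSE)
  noise <- build_noise_distribution(vocab, params$ns_exponent)
  huffman <- if (params$hs && length(vocab$token) >= 2L)
    build_huffman_tree(vocab) else NULL
  if (params$hs && is.null(huffman))
    stop("hierarchical softmax needs a vocabulary of size >= 2", call. = FALSE)

  docs_idx <- index_corpus(corpus, vocab)
  if (length(docs_idx) == 0L)
    stop("no document survives vocabulary filtering", call. = FALSE)
  ids <- names(docs_idx)
  V <- length(vocab$token); M <- params$vector_size

  code_vec <- cpp_init_matrix(V, M, 0.5 / M, mix_seed(params$seed, 12L))
  doc_vec <- cpp_init_matrix(length(ids), M, 0.5 / M, mix_seed(params$seed, 13L))
  ctx_vec <- matrix(0, V, M)
  hs_vec <- matrix(0, max(V - 1L, 1L), M)
  keep_prob <- downsample_keep_prob(vocab, params$sample)
  cdf <- cumsum(noise$prob)

  total_positions <- params$epochs * sum(lengths(docs_idx))
  processed <- 0
  for (ep in seq_len(params$epochs)) {
    if (ep > 1L && from_claims && !params$static_documents) {
      corpus_ep <- build_corpus(claims, window = quarter_window,
                                seed = mix_seed(params$seed, 11L, ep))
      docs_ep <- index_corpus(corpus_ep, vocab)[ids]
    } else docs_ep <- docs_idx
    processed <- cpp_train_epoch(
      docs_ep, seq_along(ids) - 1L, code_vec, ctx_vec, hs_vec, doc_vec,
      cdf, keep_prob,
      if (is.null(huffman)) NULL else huffman$points,
      if (is.null(huffman)) NULL else huffman$bits,
      params$dm, params$window, params$reduce_window, params$negative,
      params$alpha, params$alpha / 100, processed, total_positions,
      mix_seed(params$seed, 14L, ep))
  }
  rownames(code_vec) <- vocab$token
  rownames(doc_vec) <- ids
  structure(list(code_vectors = code_vec, doc_vectors = doc_vec,
                 context_weights = ctx_vec, hs_weights = hs_vec,
                 vocab = vocab, noise = noise, huffman = huffman,
                 params = params, call = match.call()),
            class = "patvec")
}

#' @export
print.patvec <- function(x, ...) {
  cat("Patient embedding model (Doc2Vec-style)\n")
  losses <- c(
    if (x$params$negative > 0)
      sprintf("negative sampling (%d draws, exponent %.2f)",
              x$params$negative, x$params$ns_exponent),
    if (x$params$hs) "hierarchical softmax")
  cat(sprintf("  mode: %s + %s\n",
              if (x$params$dm) "distributed memory" else "distributed bag of words",
              paste(losses, collapse = " + ")))
  cat(sprintf("  vocabulary: %d codes (min_count %d); patients: %d; dimensions: %d\n",
              length(x$vocab$token), x$params$min_count,
              nrow(x$doc_vectors), x$params$vector_size))
  invisible(x)
}

#' @export
summary.patvec <- function(object, ...) {
  dn <- sqrt(rowSums(object$doc_vectors^2))
  cn <- sqrt(rowSums(object$code_vectors^2))
  out <- list(params = object$params,
              n_codes = length(object$vocab$token),
              n_patients = nrow(object$doc_vectors),
              doc_norms = summary(dn), code_norms = summary(cn))
  class(out) <- "summary.patvec"
  out
}

#' @export
print.summary.patvec <- function(x, ...) {
  print(x$params)
  cat(sprintf("codes: %d, patients: %d\n", x$n_codes, x$n_patients))
  cat("patient-vector norms:\n"); print(x$doc_norms)
  cat("code-vector norms:\n"); print(x$code_norms)
  invisible(x)
}

#' @export
coef.patvec <- function(object, ...) object$code_vectors

#' @export
as.matrix.patvec <- function(x, ...) x$doc_vectors

#' Infer embedding vectors for (possibly unseen) patients
#'
#' Embeds new diagnosis profiles with the trained model: code, context and
#' hierarchical-softmax weights are frozen, a fresh document vector is
#' initialized from the seeded stream and updated for `epochs` passes over
#' the document with the training loss and the same linear learning-rate
#' decay. This is how calibration/validation/test patients -- never seen by
#' the vectorization training -- obtain their vectors.
#'
#' @param object a fitted [patvec()] model.
#' @param newdata a claims data.frame (any number of patients), a named list
#'   of token vectors, or a single character token vector.
#' @param epochs inference passes; defaults to the training epochs.
#' @param alpha initial inference learning rate; defaults to the training
#'   alpha.
#' @param seed integer seed for the inference stream.
#' @param quarter_window optional quarter window applied when `newdata` is a
#'   claims table.
#' @param ... unused.
#' @return numeric matrix (patients x M) with patient ids as row names.
#'   Patients whose documents are empty after vocabulary filtering are
#'   dropped; their ids are in attribute `"skipped"`.
#' @export
predict.patvec <- function(object, newdata, epochs = NULL, alpha = NULL,
                           seed = 1L, quarter_window = NULL, ...) {
  p <- object$params
  if (is.null(epochs)) epochs <- p$epochs
  if (is.null(alpha)) alpha <- p$alpha
  corpus <- if (is.data.frame(newdata) || inherits(newdata, "patvec_cohort"))
    build_corpus(resolve_claims(newdata), window = quarter_window,
                 seed = mix_seed(seed, 21L))
  else if (is.list(newdata)) newdata
  else list(doc = as.character(newdata))
  if (is.null(names(corpus))) names(corpus) <- sprintf("doc%04d", seq_along(corpus))

  keep_prob <- downsample_keep_prob(object$vocab, p$sample)
  cdf <- cumsum(object$noise$prob)
  M <- p$vector_size
  out <- matrix(NA_real_, length(corpus), M,
                dimnames = list(names(corpus), NULL))
  skipped <- character(0)
  for (i in seq_along(corpus)) {
    m <- match(corpus[[i]], object$vocab$token)
    idx <- as.integer(m[!is.na(m)] - 1L)
    if (length(idx) == 0L) { skipped <- c(skipped, names(corpus)[i]); next }
    out[i, ] <- cpp_infer_doc(
      idx, object$code_vectors, object$context_weights, object$hs_weights,
      cdf, keep_prob,
      if (is.null(object$huffman)) NULL else object$huffman$points,
      if (is.null(object$huffman)) NULL else object$huffman$bits,
      p$dm, p$window, p$reduce_window, p$negative, as.integer(epochs),
      alpha, alpha / 100, mix_seed(seed, 22L, str_hash(names(corpus)[i])))
  }
  keep <- !rownames(out) %in% skipped
  structure(out[keep, , drop = FALSE], skipped = skipped)
}

# --- plain-text serialization ----------------------------------------------

write_vec_txt <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  keys <- rownames(mat)
  if (is.null(keys)) keys <- sprintf("row%d", seq_len(nrow(mat)))
  for (i in seq_len(nrow(mat)))
    writeLines(paste(keys[i], paste(sprintf("%.17g", mat[i, ]),
                                    collapse = " ")), con)
  invisible(path)
}

read_vec_txt <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1L)
  mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  stopifnot(nrow(mat) == hd[1], ncol(mat) == hd[2])
  rownames(mat) <- keys
  mat
}

#' Save / load a fitted model as plain text
#'
#' The model directory holds `code_vectors.txt`, `doc_vectors.txt`,
#' `context_weights.txt` and `hs_weights.txt` in the word2vec text format
#' (`"V M"` header, then one `key v1 ... vM` line per row) plus `meta.json`
#' with the hyperparameters and vocabulary counts, from which the noise
#' distribution and Huffman tree are rebuilt on load.
#'
#' @param model a fitted [patvec()] model.
#' @param dir model directory (created if missing).
#' @return `write_patvec()` returns `dir` invisibly; `read_patvec()` the
#'   restored `patvec` object.
#' @export
write_patvec <- function(model, dir) {
  stopifnot(inherits(model, "patvec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_vec_txt(model$code_vectors, file.path(dir, "code_vectors.txt"))
  write_vec_txt(model$doc_vectors, file.path(dir, "doc_vectors.txt"))
  ctx <- model$context_weights
  rownames(ctx) <- model$vocab$token
  write_vec_txt(ctx, file.path(dir, "context_weights.txt"))
  write_vec_txt(model$hs_weights, file.path(dir, "hs_weights.txt"))
  meta <- list(params = unclass(model$params),
               vocab = list(token = model$vocab$token,
                            count = model$vocab$count,
                            min_count = model$vocab$min_count))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_patvec
#' @export
read_patvec <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  params <- do.call(patvec_params, meta$params[setdiff(names(meta$params), NULL)])
  vocab <- structure(list(token = meta$vocab$token,
                          count = as.integer(meta$vocab$count),
                          index = seq_along(meta$vocab$token) - 1L,
                          min_count = as.integer(meta$vocab$min_count),
                          total_kept_tokens = sum(meta$vocab$count)),
                     class = "patvec_vocab")
  code_vec <- read_vec_txt(file.path(dir, "code_vectors.txt"))
  ctx <- read_vec_txt(file.path(dir, "context_weights.txt"))
  rownames(ctx) <- NULL
  structure(list(code_vectors = code_vec,
                 doc_vectors = read_vec_txt(file.path(dir, "doc_vectors.txt")),
                 context_weights = ctx,
                 hs_weights = unname(read_vec_txt(file.path(dir, "hs_weights.txt"))),
                 vocab = vocab,
                 noise = build_noise_distribution(vocab, params$ns_exponent),
                 huffman = if (params$hs) build_huffman_tree(vocab) else NULL,
                 params = params, call = NULL),
            class = "patvec")
}
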