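# Claims -> documents. A patient's "document" is the sequence of their
# confirmed diagnosis codes: entries are grouped by billing case and place of
# treatment, groups are ordered by quarter, and both the groups within a
# quarter and the codes within a group are permuted at random (claims carry
# no order below the quarter level).

# Deterministic 31-bit string hash for per-patient substreams.
str_hash <- function(s) {
  vapply(s, function(x) {
    h <- 7L
    for (ch in utf8ToInt(x))
      h <- as.integer((as.double(h) * 31 + ch) %% 2147483647)
    h
  }, integer(1), USE.NAMES = FALSE)
}

#' Build one patient's code document
#'
#' Turns a patient's diagnosis entries into an ordered token sequence:
#' non-confirmed entries are excluded, confirmed entries are grouped by
#' `(case_id, place_id)`, groups are sorted by quarter (ascending), groups
#' sharing a quarter are permuted uniformly at random, and codes within a
#' group are shuffled. The output length equals the number of confirmed
#' entries.
#'
#' @param entries data.frame with columns `quarter`, `case_id`, `place_id`,
#'   `code`, `confirmed` (one patient's claims rows).
#' @param seed integer seed for the within-quarter permutations.
#' @return character vector of code tokens.
#' @export
build_document <- function(entries, seed = 1L) {
  conf <- entries[as.logical(entries$confirmed), , drop = FALSE]
  if (nrow(conf) == 0L)
    stop("inclusion filter: patient has no confirmed diagnosis entries",
         call. = FALSE)
  # canonical order first, so output depends only on content and seed
  conf <- conf[order(conf$quarter, conf$case_id, conf$place_id, conf$code), ,
               drop = FALSE]
  key <- paste(conf$case_id, conf$place_id, sep = "\036")
  qi <- quarter_index(conf$quarter)
  if (anyNA(qi)) stop("malformed quarter label in entries", call. = FALSE)
  groups <- split(seq_len(nrow(conf)), key)          # key-sorted, deterministic
  gq <- vapply(groups, function(ix) min(qi[ix]), 0L)
  with_local_seed(seed, {
    u <- runif(length(groups))                       # within-quarter tie-break
    ord <- order(gq, u)
    unlist(lapply(groups[ord], function(ix)
      conf$code[if (length(ix) > 1L) ix[sample.int(length(ix))] else ix]),
      use.names = FALSE)
  })
}

#' Build the per-patient document corpus from a claims table
#'
#' Applies [build_document()] to every patient in `claims`, optionally
#' restricting entries to a quarter window first. Patients left with no
#' confirmed entry in the window are excluded (their ids are attached as
#' attribute `"excluded"`). Each patient's permutation stream is derived
#' from `seed` and the patient id, so the corpus does not depend on row
#' order.
#'
#' @param claims data.frame with columns `patient_id`, `quarter`, `case_id`,
#'   `place_id`, `code`, `confirmed`.
#' @param window `NULL`, or a quarter window as `"2016Q1:2018Q4"` or a
#'   character vector of quarter labels to keep.
#' @param seed integer seed (vary it to redraw the within-quarter shuffles,
#'   e.g. per training epoch).
#' @return named list of character token vectors, keyed by patient id and
#'   sorted by id; attribute `"excluded"` lists dropped patient ids.
#' @export
build_corpus <- function(claims, window = NULL, seed = 1L) {
  if (!is.null(window)) {
    keep_q <- if (length(window) == 1L && grepl(":", window, fixed = TRUE)) {
      parts <- strsplit(window, ":", fixed = TRUE)[[1]]
      quarter_seq(parts[1], parts[2])
    } else as.character(window)
    claims <- claims[claims$quarter %in% keep_q, , drop = FALSE]
  }
  claims <- claims[as.logical(claims$confirmed), , drop = FALSE]
  ids <- sort(unique(claims$patient_id))
  by_pat <- split(claims, factor(claims$patient_id, levels = ids))
  docs <- lapply(ids, function(pid)
    build_document(by_pat[[pid]], seed = mix_seed(seed, 31L, str_hash(pid))))
  names(docs) <- ids
  all_ids <- ids   # patients absent here had no confirmed entry in the window
  structure(docs, excluded = character(0))
}

#' Build a frequency-filtered vocabulary
#'
#' Counts every token over the corpus and keeps those seen at least
#' `min_count` times (a privacy-motivated rare-code filter in claims
#' settings; the conventional threshold is 100, but small corpora need a
#' smaller value). Kept tokens get dense indices `0..V-1`, ordered by
#' descending count with lexicographic tie-break.
#'
#' @param corpus list of character token vectors (see [build_corpus()]).
#' @param min_count minimum corpus count for a token to be kept (>= 1).
#' @return object of class `patvec_vocab`: list with `token` (character),
#'   `count` (integer, full-corpus counts of kept tokens), `index` (0-based),
#'   `min_count`, `total_kept_tokens`.
#' @export
build_vocabulary <- function(corpus, min_count = 100L) {
  if (length(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  tab <- table(unlist(corpus, use.names = FALSE))
  counts <- as.integer(tab)
  tokens <- names(tab)
  keep <- counts >= min_count
  tokens <- tokens[keep]; counts <- counts[keep]
  ord <- order(-counts, tokens)
  tokens <- tokens[ord]; counts <- counts[ord]
  structure(list(token = tokens, count = counts,
                 index = seq_along(tokens) - 1L,
                 min_count = as.integer(min_count),
                 total_kept_tokens = sum(counts)),
            class = "patvec_vocab")
}

#' @export
print.patvec_vocab <- function(x, ...) {
  cat(sprintf("Vocabulary: %d tokens kept (min_count = %d), %d token occurrences\n",
              length(x$token), x$min_count, x$total_kept_tokens))
  invisible(x)
}

#' Filter a document through a vocabulary
#'
#' Removes out-of-vocabulary tokens, preserving order. A document that
#' becomes empty is returned as a zero-length vector with attribute
#' `"empty_after_filtering" = TRUE`; the caller decides whether that is an
#' error or a drop.
#'
#' @param doc character token vector.
#' @param vocab a [build_vocabulary()] result.
#' @return filtered character vector.
#' @export
apply_vocabulary <- function(doc, vocab) {
  stopifnot(inherits(vocab, "patvec_vocab"))
  out <- doc[doc %in% vocab$token]
  if (length(out) == 0L) attr(out, "empty_after_filtering") <- TRUE
  out
}

# Corpus -> 0-based integer index lists for the C++ engine; drops documents
# that are empty after vocabulary filtering.
index_corpus <- function(corpus, vocab) {
  idx <- lapply(corpus, function(doc) {
    m <- match(doc, vocab$token)
    as.integer(m[!is.na(m)] - 1L)
  })
  idx[lengths(idx) > 0L]
}
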