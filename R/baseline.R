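# Top-M binary encoding: the baseline representation the embedding is
# calibrated against.

#' Rank the most common diagnosis codes
#'
#' Sorts confirmed diagnosis codes by the number of distinct patients
#' carrying them (not raw occurrence count) within a reference period and
#' returns the top `M`. Ties are broken lexicographically (ascending) so the
#' ranking is reproducible. Ranking by raw occurrences is available via
#' `by = "occurrences"` for sensitivity analysis.
#'
#' @param claims claims data.frame (`patient_id`, `quarter`, `code`,
#'   `confirmed`, ...).
#' @param M number of top codes to return.
#' @param period optional quarter window (`"2019Q1:2019Q4"` or label vector)
#'   restricting the ranking; the ranking period may differ from the
#'   encoding period.
#' @param by ranking statistic: distinct patients (default) or occurrences.
#' @return object of class `top_codes`: character vector of length `M` with
#'   attributes `counts` (the ranking statistic) and `period`.
#' @examples
#' claims <- data.frame(patient_id = c("P1","P1","P1","P2","P3","P3"),
#'                      quarter = "2018Q1", case_id = "c", place_id = "s",
#'                      code = c("a","a","b","a","b","c"), confirmed = TRUE)
#' rank_top_codes(claims, M = 2)   # a and b tie on 2 patients; a first
#' @export
rank_top_codes <- function(claims, M, period = NULL,
                           by = c("patients", "occurrences")) {
  by <- match.arg(by)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  x <- claims[as.logical(claims$confirmed), , drop = FALSE]
  if (!is.null(period)) {
    keep_q <- if (length(period) == 1L && grepl(":", period, fixed = TRUE)) {
      parts <- strsplit(period, ":", fixed = TRUE)[[1]]
      quarter_seq(parts[1], parts[2])
    } else as.character(period)
    x <- x[x$quarter %in% keep_q, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no confirmed diagnoses in the ranking period",
                          call. = FALSE)
  counts <- if (by == "patients") {
    u <- unique(x[, c("patient_id", "code")])
    table(u$code)
  } else table(x$code)
  if (length(counts) < M)
    stop(sprintf("requested top %d codes but only %d distinct codes available",
                 M, length(counts)), call. = FALSE)
  ord <- order(-as.integer(counts), names(counts))
  top <- names(counts)[ord][seq_len(M)]
  structure(top, counts = as.integer(counts)[ord][seq_len(M)],
            period = if (is.null(period)) "all" else paste(period, collapse = ","),
            class = "top_codes")
}

#' @export
print.top_codes <- function(x, ...) {
  cat(sprintf("Top %d diagnosis codes (period: %s)\n", length(x),
              attr(x, "period")))
  print(head(data.frame(code = unclass(x), n = attr(x, "counts")), 10))
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

#' Binary-encode patient profiles over the top codes
#'
#' Builds the N x M presence/absence matrix: entry `(i, j)` is 1 iff patient
#' `i` has at least one confirmed entry with code `j` in the encoding
#' period (presence, not a count).
#'
#' @param claims claims data.frame.
#' @param top a [rank_top_codes()] result (or plain character vector of
#'   codes).
#' @param period optional quarter window for the encoding (independent of
#'   the ranking period).
#' @param ids optional character vector of patient ids defining the rows
#'   (patients without any top code get all-zero rows); defaults to the
#'   patients present in `claims`.
#' @return integer matrix of 0/1 with patient ids as row names and codes as
#'   column names.
#' @export
binary_encode <- function(claims, top, period = NULL, ids = NULL) {
  x <- claims[as.logical(claims$confirmed), , drop = FALSE]
  if (!is.null(period)) {
    keep_q <- if (length(period) == 1L && grepl(":", period, fixed = TRUE)) {
      parts <- strsplit(period, ":", fixed = TRUE)[[1]]
      quarter_seq(parts[1], parts[2])
    } else as.character(period)
    x <- x[x$quarter %in% keep_q, , drop = FALSE]
  }
  codes <- as.character(top)
  if (is.null(ids)) ids <- sort(unique(claims$patient_id))
  mat <- matrix(0L, length(ids), length(codes),
                dimnames = list(ids, codes))
  x <- x[x$code %in% codes & x$patient_id %in% ids, , drop = FALSE]
  if (nrow(x) > 0L)
    mat[cbind(match(x$patient_id, ids), match(x$code, codes))] <- 1L
  mat
}
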