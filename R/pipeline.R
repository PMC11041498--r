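# End-to-end calibration study: split a cohort, train the embedding on the
# vectorization split, embed the held-out patients by inference, build the
# binary baselines, and score everything against the top-`ref_M` reference.

#' Run a full calibration study on a cohort
#'
#' Reproduces the calibration design at cohort scale: patients are split by
#' id hash into a vectorization-training set, a calibration-training set and
#' a validation set. The embedding model is trained on the first split only;
#' calibration and validation patients get their vectors by frozen-weight
#' inference (they are never seen in training). The binary baselines (top-M
#' and top-`ref_M` codes, ranked by distinct patients over the whole claims
#' table) are encoded for the same held-out patients. Each feature set is
#' evaluated on the four calibration outcomes ([evaluate_matrix()]) and
#' normalized by the top-`ref_M` reference report ([total_score()]).
#'
#' @param cohort a `patvec_cohort` (or list with `claims` and `outcomes`).
#' @param params [patvec_params()] for the embedding (its `vector_size` is
#'   the M under comparison).
#' @param ref_M size of the reference baseline (conventionally 100).
#' @param train_window quarter window for vectorization training (`NULL` =
#'   all quarters).
#' @param eval_window quarter window for the held-out patients' profiles
#'   (embedding inference, code ranking and binary encoding); the default
#'   `"last-year"` uses the quarters of the most recent calendar year in
#'   the claims, mirroring the usual design of training the vectorization
#'   on the full history but calibrating on current-year profiles.
#' @param fractions three named split fractions (`vec_train`, `calib`,
#'   `valid`).
#' @param seed seed for inference and the boosted learners.
#' @param gbt_opts gradient-boosted learner settings.
#' @return object of class `patvec_calibration`: list with the fitted
#'   `model`, reports `embedding_report`, `baseline_report`,
#'   `reference_report`, scores `embedding_score`, `baseline_score`,
#'   `reference_score` (the latter exactly 1), and the id `split`.
#' @export
calibration_study <- function(cohort, params = patvec_params(vector_size = 16L,
                                                             min_count = 2L),
                              ref_M = 100L,
                              fractions = c(vec_train = 0.5, calib = 0.3,
                                            valid = 0.2),
                              train_window = NULL, eval_window = "last-year",
                              seed = 1L, gbt_opts = default_gbt_opts()) {
  claims <- cohort$claims; outcomes <- cohort$outcomes
  eval_window <- resolve_eval_window(claims, eval_window)
  ids <- sort(unique(outcomes$patient_id))
  grp <- split_patients(ids, fractions)
  vec_claims <- claims[claims$patient_id %in% grp$vec_train, , drop = FALSE]
  model <- patvec(vec_claims, params, quarter_window = train_window)

  eval_ids <- c(grp$calib, grp$valid)
  eval_claims <- claims[claims$patient_id %in% eval_ids, , drop = FALSE]
  if (!is.null(eval_window))
    eval_claims <- eval_claims[eval_claims$quarter %in% eval_window, ,
                               drop = FALSE]
  emb <- predict(model, eval_claims, seed = mix_seed(seed, 41L))

  M <- params$vector_size
  top_ref <- rank_top_codes(eval_claims, ref_M)
  top_m <- rank_top_codes(eval_claims, M)
  keep <- intersect(eval_ids, rownames(emb))
  ref_feat <- binary_encode(eval_claims, top_ref, ids = keep)
  base_feat <- binary_encode(eval_claims, top_m, ids = keep)
  emb_feat <- emb[keep, , drop = FALSE]
  colnames(emb_feat) <- sprintf("dim%03d", seq_len(ncol(emb_feat)))

  split <- list(train = intersect(grp$calib, keep),
                valid = intersect(grp$valid, keep))
  ref_rep <- evaluate_matrix(ref_feat, outcomes, split, gbt_opts, seed)
  base_rep <- evaluate_matrix(base_feat, outcomes, split, gbt_opts, seed)
  emb_rep <- evaluate_matrix(emb_feat, outcomes, split, gbt_opts, seed)

  structure(list(model = model,
                 embedding_report = emb_rep, baseline_report = base_rep,
                 reference_report = ref_rep,
                 embedding_score = total_score(emb_rep, ref_rep),
                 baseline_score = total_score(base_rep, ref_rep),
                 reference_score = total_score(ref_rep, ref_rep),
                 split = grp, M = M, ref_M = ref_M,
                 features = list(embedding = emb_feat, baseline = base_feat,
                                 reference = ref_feat)),
            class = "patvec_calibration")
}

#' @export
print.patvec_calibration <- function(x, ...) {
  cat(sprintf("Calibration study (M = %d, reference = top %d codes)\n",
              x$M, x$ref_M))
  cat(sprintf("  embedding total score: %.4f\n", x$embedding_score$value))
  cat(sprintf("  top-%d baseline score: %.4f\n", x$M, x$baseline_score$value))
  cat(sprintf("  reference self-score:  %.4f\n", x$reference_score$value))
  invisible(x)
}

# "last-year" -> the quarters of the most recent calendar year present.
resolve_eval_window <- function(claims, eval_window) {
  if (is.null(eval_window)) return(NULL)
  if (identical(eval_window, "last-year")) {
    q <- unique(claims$quarter)
    yr <- max(substr(q, 1, 4))
    return(sort(q[substr(q, 1, 4) == yr]))
  }
  if (length(eval_window) == 1L && grepl(":", eval_window, fixed = TRUE)) {
    parts <- strsplit(eval_window, ":", fixed = TRUE)[[1]]
    return(quarter_seq(parts[1], parts[2]))
  }
  as.character(eval_window)
}
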