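# Hyperparameter search over the standard tuning grid, plus the two
# robustness experiments (diagnosis dropout, reduced training-sample size).

#' The standard embedding search space
#'
#' The tunable training configuration: window 1-10, epochs 1-20, negative
#' samples 0-20, noise exponent -5..5, hierarchical softmax on/off, DM vs
#' DBOW, and log-uniform alpha 0.001-0.1. Vector size, min_count and the
#' downsampling parameter are held fixed during tuning (attribute
#' `"fixed"`).
#'
#' @param vector_size,min_count,sample the fixed fields.
#' @return named list of parameter descriptors (type/lower/upper/log), with
#'   attribute `fixed`.
#' @export
embedding_search_space <- function(vector_size = 100L, min_count = 100L,
                                   sample = 0) {
  structure(list(
    window = list(type = "int", lower = 1, upper = 10),
    epochs = list(type = "int", lower = 1, upper = 20),
    negative = list(type = "int", lower = 0, upper = 20),
    ns_exponent = list(type = "real", lower = -5, upper = 5),
    hs = list(type = "bool"),
    dm = list(type = "bool"),
    alpha = list(type = "real", lower = 0.001, upper = 0.1, log = TRUE)),
    fixed = list(vector_size = vector_size, min_count = min_count,
                 sample = sample))
}

sample_one <- function(desc) {
  switch(desc$type,
    real = if (isTRUE(desc$log))
      exp(runif(1, log(desc$lower), log(desc$upper)))
    else runif(1, desc$lower, desc$upper),
    int = as.integer(floor(runif(1, desc$lower, desc$upper + 1))),
    bool = runif(1) < 0.5,
    stop("unknown parameter type ", desc$type, call. = FALSE))
}

sample_config <- function(space) lapply(space, sample_one)

# TPE-style proposal for one numeric parameter: candidates drawn from a
# kernel density over the good trials, ranked by the good/bad density ratio.
propose_numeric <- function(desc, good, bad, n_cand = 24L) {
  tr <- function(x) if (isTRUE(desc$log)) log(x) else as.numeric(x)
  inv <- function(x) if (isTRUE(desc$log)) exp(x) else x
  g <- tr(good); b <- tr(bad)
  lo <- tr(desc$lower); hi <- tr(desc$upper)
  bw <- max(bw.nrd0(g), (hi - lo) / 25)
  cand <- g[sample.int(length(g), n_cand, replace = TRUE)] +
    rnorm(n_cand, 0, bw)
  cand <- pmin(pmax(cand, lo), hi)
  dens <- function(x, pts) rowMeans(outer(x, pts, function(u, v)
    dnorm(u, v, bw)) + 1e-12)
  ratio <- dens(cand, g) / dens(cand, if (length(b)) b else g)
  x <- inv(cand[which.max(ratio)])
  if (desc$type == "int") as.integer(round(x)) else x
}

propose_config <- function(space, trials_params, scores, n_cand = 24L) {
  ok <- !is.na(scores)
  n_good <- max(2L, ceiling(0.25 * sum(ok)))
  ord <- order(scores[ok], decreasing = TRUE)
  good_idx <- which(ok)[ord[seq_len(min(n_good, sum(ok)))]]
  bad_idx <- setdiff(which(ok), good_idx)
  out <- list()
  for (nm in names(space)) {
    desc <- space[[nm]]
    gvals <- vapply(trials_params[good_idx], function(p) p[[nm]], numeric(1))
    bvals <- vapply(trials_params[bad_idx], function(p) p[[nm]], numeric(1))
    out[[nm]] <- if (desc$type == "bool") {
      pg <- (sum(gvals) + 1) / (length(gvals) + 2)
      pb <- (sum(bvals) + 1) / (length(bvals) + 2)
      # pick the value with the larger good/bad odds ratio
      if (pg / pb >= (1 - pg) / (1 - pb)) TRUE else FALSE
    } else propose_numeric(desc, gvals, bvals, n_cand)
  }
  out
}

#' Hyperparameter search
#'
#' Maximizes `objective` over a parameter space, with either a
#' tree-structured-Parzen-style Bayesian sampler (default: candidates are
#' drawn from a kernel density over the best quartile of past trials and
#' ranked by the good/bad density ratio) or a pre-drawn seeded random
#' search. A failing objective records the error and the search continues.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a single numeric score (larger = better).
#' @param space parameter space as from [embedding_search_space()] (each
#'   entry `list(type, lower, upper, log)`).
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed; in random mode all configurations are drawn up
#'   front, so the trial sequence is a pure function of the seed and
#'   invariant to evaluation order.
#' @param method `"tpe"` (default) or `"random"`.
#' @param n_startup random trials before the TPE proposals begin.
#' @return list with `best` (list: `params`, `score`, `trial`) and `trials`
#'   (data.frame of all parameter values, scores and error messages).
#' @export
patvec_search <- function(objective, space = embedding_search_space(),
                          n_trials = 25L, seed = 1L,
                          method = c("tpe", "random"), n_startup = 10L) {
  method <- match.arg(method)
  stopifnot(n_trials >= 1L)
  params_list <- vector("list", n_trials)
  scores <- rep(NA_real_, n_trials)
  errors <- rep(NA_character_, n_trials)

  configs <- if (method == "random")
    with_local_seed(mix_seed(seed, 51L),
                    lapply(seq_len(n_trials), function(i) sample_config(space)))
  else NULL

  for (i in seq_len(n_trials)) {
    cfg <- if (method == "random") configs[[i]] else
      with_local_seed(mix_seed(seed, 51L, i), {
        if (i <= n_startup || sum(!is.na(scores)) < 5L) sample_config(space)
        else propose_config(space, params_list[seq_len(i - 1L)],
                            scores[seq_len(i - 1L)])
      })
    params_list[[i]] <- cfg
    res <- tryCatch(objective(cfg), error = function(e) e)
    if (inherits(res, "error")) errors[i] <- conditionMessage(res)
    else scores[i] <- as.numeric(res)
  }
  tdf <- do.call(rbind, lapply(params_list, function(p)
    as.data.frame(p, stringsAsFactors = FALSE)))
  tdf$score <- scores
  tdf$error <- errors
  if (all(is.na(scores))) stop("all trials failed", call. = FALSE)
  best <- which.max(scores)
  list(best = list(params = params_list[[best]], score = scores[best],
                   trial = best),
       trials = tdf)
}

# --- robustness experiments -------------------------------------------------

round_half_up <- function(x) floor(x + 0.5)

#' Randomly drop a fraction of a patient's diagnosis codes
#'
#' Drops `k = min(round_half_up(rate * n), n - 1)` of the patient's `n`
#' confirmed codes, chosen uniformly without replacement; at least one
#' confirmed code is always kept, and non-confirmed entries are untouched.
#' Half counts round up (`n = 3, rate = 0.5` drops 2).
#'
#' @param entries one patient's claims rows.
#' @param rate dropout fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return the entries with the dropped confirmed rows removed.
#' @export
dropout_codes <- function(entries, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  conf <- which(as.logical(entries$confirmed))
  n <- length(conf)
  if (n <= 1L || rate == 0) return(entries)
  k <- min(round_half_up(rate * n), n - 1L)
  if (k == 0L) return(entries)
  drop <- with_local_seed(seed, conf[sample.int(n, k)])
  entries[-drop, , drop = FALSE]
}

#' @rdname dropout_codes
#' @param claims a multi-patient claims table; dropout is applied per
#'   patient with independent substreams of `seed`.
#' @export
dropout_claims <- function(claims, rate, seed = 1L) {
  if (rate == 0) return(claims)
  ids <- unique(claims$patient_id)
  parts <- lapply(ids, function(pid)
    dropout_codes(claims[claims$patient_id == pid, , drop = FALSE], rate,
                  seed = mix_seed(seed, 61L, str_hash(pid))))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Subsample the vectorization training corpus
#'
#' Uniform patient-level subsample of `round(fraction * N)` documents (at
#' least 1), deterministic for a given seed.
#'
#' @param corpus named list of documents (see [build_corpus()]).
#' @param fraction fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return the subsampled corpus (original order preserved).
#' @export
subsample_training <- function(corpus, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(corpus)
  n <- max(1L, round(fraction * length(corpus)))
  keep <- with_local_seed(seed, sort(sample.int(length(corpus), n)))
  corpus[keep]
}

#' Dropout / training-size robustness experiment
#'
#' For every combination of diagnosis dropout rate and vectorization
#' training fraction, retrains the embedding on the reduced training split,
#' re-embeds and re-encodes the held-out patients from their dropped-out
#' profiles, and reports total scores against the *unperturbed* top-M
#' baseline reference. At `rate = 0, fraction = 1` the baseline row equals
#' the reference, so its score is exactly 1. Dropout is applied to the
#' evaluation-side profiles; `dropout_training = TRUE` additionally applies
#' it to the vectorization training claims.
#'
#' @param cohort a `patvec_cohort`.
#' @param rates dropout rates in `[0, 1)`.
#' @param fractions training fractions in `(0, 1]`.
#' @param params [patvec_params()] for the embedding; its `vector_size` is
#'   also the baseline M.
#' @param dropout_training also perturb the vectorization training data.
#' @param fractions_split cohort split fractions as in
#'   [calibration_study()].
#' @param train_window,eval_window quarter windows as in
#'   [calibration_study()].
#' @param seed integer seed.
#' @param gbt_opts boosted-learner settings.
#' @return data.frame with columns `fraction`, `rate`, `representation`
#'   (`"embedding"` / `"baseline"`), `total_score`.
#' @export
robustness_experiment <- function(cohort, rates = c(0, 0.1, 0.25, 0.5),
                                  fractions = 1, params, dropout_training = FALSE,
                                  fractions_split = c(vec_train = 0.5,
                                                      calib = 0.3, valid = 0.2),
                                  train_window = NULL, eval_window = "last-year",
                                  seed = 1L, gbt_opts = default_gbt_opts()) {
  claims <- cohort$claims; outcomes <- cohort$outcomes
  eval_window <- resolve_eval_window(claims, eval_window)
  ids <- sort(unique(outcomes$patient_id))
  grp <- split_patients(ids, fractions_split)
  eval_ids <- c(grp$calib, grp$valid)
  eval_claims <- claims[claims$patient_id %in% eval_ids, , drop = FALSE]
  if (!is.null(eval_window))
    eval_claims <- eval_claims[eval_claims$quarter %in% eval_window, ,
                               drop = FALSE]
  M <- params$vector_size
  top_m <- rank_top_codes(eval_claims, M)

  # unperturbed reference: top-M encoding of the untouched profiles
  have <- intersect(eval_ids, unique(eval_claims$patient_id))
  split <- list(train = intersect(grp$calib, have),
                valid = intersect(grp$valid, have))
  ref_feat <- binary_encode(eval_claims, top_m, ids = have)
  ref_rep <- evaluate_matrix(ref_feat, outcomes, split, gbt_opts, seed)

  rows <- list()
  for (f in fractions) {
    vec_ids <- ids_subsample(grp$vec_train, f, mix_seed(seed, 71L))
    vec_claims <- claims[claims$patient_id %in% vec_ids, , drop = FALSE]
    model_clean <- if (!dropout_training)
      patvec(vec_claims, params, quarter_window = train_window) else NULL
    for (r in rates) {
      model <- if (dropout_training && r > 0)
        patvec(dropout_claims(vec_claims, r, mix_seed(seed, 72L)), params,
               quarter_window = train_window)
      else if (!is.null(model_clean)) model_clean
      else patvec(vec_claims, params, quarter_window = train_window)
      ec <- if (r > 0) dropout_claims(eval_claims, r, mix_seed(seed, 73L))
            else eval_claims
      emb <- predict(model, ec, seed = mix_seed(seed, 74L))
      keep <- intersect(have, rownames(emb))
      spl <- list(train = intersect(grp$calib, keep),
                  valid = intersect(grp$valid, keep))
      emb_rep <- evaluate_matrix(emb[keep, , drop = FALSE], outcomes, spl,
                                 gbt_opts, seed)
      base_feat <- binary_encode(ec, top_m, ids = have)
      base_rep <- evaluate_matrix(base_feat, outcomes, split, gbt_opts, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, rate = r,
        representation = c("embedding", "baseline"),
        total_score = c(total_score(emb_rep, ref_rep)$value,
                        total_score(base_rep, ref_rep)$value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ids_subsample <- function(ids, fraction, seed) {
  if (fraction >= 1) return(ids)
  n <- max(1L, round(fraction * length(ids)))
  with_local_seed(seed, sort(sample(ids, n)))
}
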