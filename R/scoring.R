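# Calibration scoring: fit linear/logistic and gradient-boosted learners on
# a feature matrix for the four calibration outcomes, collect the 16
# performance measures, and normalize them by a baseline report.

MEASURE_NAMES <- c(
  "n_cases_linear_r2", "n_cases_linear_cpm", "n_cases_gbt_r2", "n_cases_gbt_cpm",
  "age_linear_r2", "age_linear_cpm", "age_gbt_r2", "age_gbt_cpm",
  "emergency_logistic_auroc", "emergency_logistic_auprc",
  "emergency_gbt_auroc", "emergency_gbt_auprc",
  "gender_logistic_auroc", "gender_logistic_auprc",
  "gender_gbt_auroc", "gender_gbt_auprc")

#' Deterministic patient-level data split
#'
#' Assigns each patient id to a named group by hashing the id (with an
#' optional salt), so splits are reproducible, independent of row order,
#' and stable when patients are added or removed.
#'
#' @param ids character vector of patient ids.
#' @param fractions named numeric vector of group fractions summing to 1,
#'   e.g. `c(vec_train = 0.5, calib = 0.3, valid = 0.2)`.
#' @param salt integer mixed into the hash (change it for an independent
#'   re-split).
#' @return named list of character id vectors, one per group.
#' @export
split_patients <- function(ids,
                           fractions = c(vec_train = 0.5, calib = 0.3,
                                         valid = 0.2),
                           salt = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, !is.null(names(fractions)))
  h <- str_hash(ids)
  u <- vapply(h, function(x) mix_seed(as.integer(salt), 83L, x), 1L) / 2147483647
  edges <- cumsum(fractions)
  grp <- names(fractions)[findInterval(u, c(0, edges[-length(edges)]),
                                       left.open = FALSE)]
  split(ids, factor(grp, levels = names(fractions)))
}

# --- pluggable learners -----------------------------------------------------

# Fixed (untuned) boosted-tree settings, sized for cohorts of a few
# thousand patients: shallow trees, mild shrinkage, row subsampling.
default_gbt_opts <- function() {
  list(nrounds = 100L, eta = 0.05, max_depth = 3L, min_child_weight = 10,
       subsample = 0.8)
}

fit_predict_learner <- function(kind, Xtr, ytr, Xva, gbt_opts = default_gbt_opts(),
                                seed = 1L) {
  Xtr <- as.matrix(Xtr); Xva <- as.matrix(Xva)
  storage.mode(Xtr) <- "double"; storage.mode(Xva) <- "double"
  switch(kind,
    linear = {
      fit <- lm.fit(cbind(1, Xtr), ytr)
      b <- fit$coefficients
      b[is.na(b)] <- 0
      drop(cbind(1, Xva) %*% b)
    },
    logistic = {
      fit <- suppressWarnings(
        glm.fit(cbind(1, Xtr), ytr, family = binomial(),
                control = list(maxit = 50)))
      b <- fit$coefficients
      b[is.na(b)] <- 0
      plogis(drop(cbind(1, Xva) %*% b))
    },
    gbt_regressor = xgb_fit_predict(Xtr, ytr, Xva, "reg:squarederror",
                                    gbt_opts, seed),
    gbt_classifier = xgb_fit_predict(Xtr, ytr, Xva, "binary:logistic",
                                     gbt_opts, seed),
    stop("unknown learner kind: ", kind, call. = FALSE))
}

xgb_fit_predict <- function(Xtr, ytr, Xva, objective, opts, seed) {
  with_local_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(Xtr, label = ytr, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(objective = objective, eta = opts$eta,
                    max_depth = opts$max_depth,
                    min_child_weight = opts$min_child_weight,
                    subsample = opts$subsample, nthread = 1),
      data = dtrain, nrounds = opts$nrounds, verbose = 0)
    predict(booster, xgboost::xgb.DMatrix(Xva, nthread = 1))
  })
}

# --- the 16-measure report --------------------------------------------------

#' Evaluate a feature matrix on the four calibration tasks
#'
#' Fits, for each of the four outcomes, the appropriate pair of learners on
#' the training split and computes two metrics each on the validation
#' split: linear regression and gradient-boosted regression with R-squared
#' and CPM for `n_cases` and `age`; logistic regression and gradient-boosted
#' classification with AUROC and AUPRC for `emergency` and `gender`. The
#' gradient-boosted learners run with fixed default settings (no per-task
#' tuning). The result is the 16-measure report that feeds [total_score()].
#'
#' @param features numeric matrix with patient ids as row names.
#' @param outcomes outcomes data.frame (`patient_id`, `age`, `gender`,
#'   `n_cases`, `emergency`, `drug_cost`).
#' @param split list with character id vectors `train` and `valid`
#'   (disjoint; all present among the feature rows).
#' @param gbt_opts options for the gradient-boosted learners.
#' @param seed seed for the (stochastic) boosted learners.
#' @return object of class `patvec_metrics`: named numeric vector with the
#'   16 canonical measures.
#' @export
evaluate_matrix <- function(features, outcomes, split,
                            gbt_opts = default_gbt_opts(), seed = 1L) {
  ids <- rownames(features)
  if (is.null(ids)) stop("features must have patient ids as row names",
                         call. = FALSE)
  if (length(intersect(split$train, split$valid)) > 0L)
    stop("train and validation splits overlap", call. = FALSE)
  miss <- setdiff(c(split$train, split$valid), ids)
  if (length(miss) > 0L)
    stop("features lack rows for ", length(miss), " split ids", call. = FALSE)
  om <- outcomes[match(ids, outcomes$patient_id), , drop = FALSE]
  if (anyNA(om$patient_id))
    stop("outcomes and features are misaligned: missing patient ids",
         call. = FALSE)
  rownames(om) <- ids
  tr <- split$train; va <- split$valid
  Xtr <- features[tr, , drop = FALSE]; Xva <- features[va, , drop = FALSE]

  out <- setNames(numeric(16), MEASURE_NAMES)
  for (task in c("n_cases", "age")) {
    y_tr <- om[tr, task]; y_va <- om[va, task]
    ph <- fit_predict_learner("linear", Xtr, y_tr, Xva)
    out[paste0(task, "_linear_r2")] <- r2(y_va, ph)
    out[paste0(task, "_linear_cpm")] <- cpm(y_va, ph)
    ph <- fit_predict_learner("gbt_regressor", Xtr, y_tr, Xva, gbt_opts, seed)
    out[paste0(task, "_gbt_r2")] <- r2(y_va, ph)
    out[paste0(task, "_gbt_cpm")] <- cpm(y_va, ph)
  }
  for (task in c("emergency", "gender")) {
    y_tr <- om[tr, task]; y_va <- om[va, task]
    if (length(unique(y_va)) < 2L)
      stop("single-class validation labels for outcome ", task, call. = FALSE)
    ph <- fit_predict_learner("logistic", Xtr, y_tr, Xva)
    out[paste0(task, "_logistic_auroc")] <- auroc(y_va, ph)
    out[paste0(task, "_logistic_auprc")] <- auprc(y_va, ph)
    ph <- fit_predict_learner("gbt_classifier", Xtr, y_tr, Xva, gbt_opts, seed)
    out[paste0(task, "_gbt_auroc")] <- auroc(y_va, ph)
    out[paste0(task, "_gbt_auprc")] <- auprc(y_va, ph)
  }
  structure(out, class = "patvec_metrics")
}

#' @export
print.patvec_metrics <- function(x, ...) {
  cat("16-measure calibration report:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Baseline-normalized total score
#'
#' Divides each of the 16 candidate measures by the same-named reference
#' measure (conventionally the top-100 binary baseline) and returns the
#' arithmetic mean of the 16 ratios. A report scored against itself gives
#' exactly 1. R-squared and CPM can be negative in practice although all 16
#' measures are nominally in (0, 1]; measures are therefore clamped to
#' `[floor, 1]` before ratio formation, which prevents sign flips and
#' division blow-ups. A reference measure at or below the floor is an
#' error (the ratio would be meaningless).
#'
#' @param candidate,reference [evaluate_matrix()] reports (or named numeric
#'   vectors with the same 16 names).
#' @param floor clamp floor (default `1e-6`).
#' @return object of class `patvec_total_score`: list with `value`,
#'   `ratios`, `candidate`, `reference`.
#' @export
total_score <- function(candidate, reference, floor = 1e-6) {
  candidate <- unclass(candidate); reference <- unclass(reference)
  if (!setequal(names(candidate), names(reference)) ||
      length(candidate) != length(reference))
    stop("candidate and reference reports have different measures",
         call. = FALSE)
  reference <- reference[names(candidate)]
  bad <- names(reference)[reference <= floor]
  if (length(bad) > 0L)
    stop("reference measure(s) at or below the clamp floor: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cc <- pmin(pmax(candidate, floor), 1)
  rc <- pmin(pmax(reference, floor), 1)
  ratios <- cc / rc
  structure(list(value = mean(ratios), ratios = ratios,
                 candidate = candidate, reference = reference),
            class = "patvec_total_score")
}

#' @export
print.patvec_total_score <- function(x, ...) {
  cat(sprintf("Total score: %.4f (mean of 16 baseline-normalized measures; baseline = 1)\n",
              x$value))
  invisible(x)
}

#' Predict next-period drug spending
#'
#' The applied prediction task: regress per-patient drug cost on a feature
#' matrix with linear regression and gradient-boosted trees, optionally
#' appending age and gender as extra predictors, and report R-squared, mean
#' absolute error and CPM on the validation split. With `tune_gbt = TRUE`
#' the boosted learner's hyperparameters are tuned by the package's
#' Bayesian-style search on an inner split of the training patients.
#'
#' @inheritParams evaluate_matrix
#' @param add_demographics append `age` and `gender` columns to the
#'   features.
#' @param tune_gbt tune the boosted learner (otherwise default settings).
#' @param n_trials tuning budget when `tune_gbt` is `TRUE`.
#' @return data.frame with one row per learner (`linear`, `gbt`) and
#'   columns `r2`, `mae`, `cpm`.
#' @export
predict_drug_cost <- function(features, outcomes, split,
                              add_demographics = FALSE, tune_gbt = FALSE,
                              n_trials = 20L, seed = 1L,
                              gbt_opts = default_gbt_opts()) {
  ids <- rownames(features)
  om <- outcomes[match(ids, outcomes$patient_id), , drop = FALSE]
  if (anyNA(om$patient_id)) stop("outcomes and features are misaligned",
                                 call. = FALSE)
  rownames(om) <- ids
  X <- features
  if (add_demographics)
    X <- cbind(X, age = om$age, gender = om$gender)
  tr <- split$train; va <- split$valid
  Xtr <- X[tr, , drop = FALSE]; Xva <- X[va, , drop = FALSE]
  y_tr <- om[tr, "drug_cost"]; y_va <- om[va, "drug_cost"]

  if (tune_gbt) {
    inner <- split_patients(tr, c(fit = 0.8, check = 0.2), salt = 97L)
    obj <- function(hp) {
      opts <- default_gbt_opts()
      opts[names(hp)] <- hp
      opts$nrounds <- as.integer(opts$nrounds)
      opts$max_depth <- as.integer(opts$max_depth)
      ph <- xgb_fit_predict(X[inner$fit, , drop = FALSE], om[inner$fit, "drug_cost"],
                            X[inner$check, , drop = FALSE], "reg:squarederror",
                            opts, seed)
      r2(om[inner$check, "drug_cost"], ph)
    }
    space <- list(
      eta = list(type = "real", lower = 0.01, upper = 0.3, log = TRUE),
      max_depth = list(type = "int", lower = 2, upper = 10),
      nrounds = list(type = "int", lower = 50, upper = 300),
      min_child_weight = list(type = "real", lower = 1, upper = 20),
      subsample = list(type = "real", lower = 0.5, upper = 1))
    res <- patvec_search(obj, space, n_trials = n_trials, seed = seed)
    gbt_opts[names(res$best$params)] <- res$best$params
    gbt_opts$nrounds <- as.integer(gbt_opts$nrounds)
    gbt_opts$max_depth <- as.integer(gbt_opts$max_depth)
  }

  ph_lin <- fit_predict_learner("linear", Xtr, y_tr, Xva)
  ph_gbt <- fit_predict_learner("gbt_regressor", Xtr, y_tr, Xva, gbt_opts, seed)
  data.frame(learner = c("linear", "gbt"),
             r2 = c(r2(y_va, ph_lin), r2(y_va, ph_gbt)),
             mae = c(mean(abs(y_va - ph_lin)), mean(abs(y_va - ph_gbt))),
             cpm = c(cpm(y_va, ph_lin), cpm(y_va, ph_gbt)),
             stringsAsFactors = FALSE)
}
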