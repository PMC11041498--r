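# A small aligned feature/outcome fixture for learner plumbing tests.
scoring_fixture <- function() fixture("scoring_fixture", function() {
  co <- generate_cohort(sim_config(n_patients = 600, seed = 77))
  ids <- sort(unique(co$outcomes$patient_id))
  grp <- split_patients(ids, c(train = 0.7, valid = 0.3))
  top <- rank_top_codes(co$claims, 30)
  feat <- binary_encode(co$claims, top, ids = ids)
  list(co = co, ids = ids, split = grp, feat = feat)
})

test_that("a leaked outcome column yields AUROC 1 for that outcome", {
  fx <- scoring_fixture()
  om <- fx$co$outcomes[match(fx$ids, fx$co$outcomes$patient_id), ]
  leak <- cbind(fx$feat, leak = om$emergency)
  rep <- evaluate_matrix(leak, fx$co$outcomes, fx$split, seed = 1)
  expect_gt(rep[["emergency_logistic_auroc"]], 0.999)
  expect_gt(rep[["emergency_gbt_auroc"]], 0.999)
})

test_that("constant features are uninformative: R2 <= 0, AUROC about 0.5", {
  fx <- scoring_fixture()
  const <- matrix(1, nrow(fx$feat), 3,
                  dimnames = list(rownames(fx$feat), c("c1", "c2", "c3")))
  rep <- evaluate_matrix(const, fx$co$outcomes, fx$split, seed = 1)
  expect_lte(rep[["n_cases_linear_r2"]], 1e-8)
  expect_lte(rep[["age_linear_r2"]], 1e-8)
  expect_lt(abs(rep[["emergency_logistic_auroc"]] - 0.5), 0.05)
  expect_lt(abs(rep[["gender_logistic_auroc"]] - 0.5), 0.05)
})

test_that("evaluate_matrix validates alignment and split sanity", {
  fx <- scoring_fixture()
  expect_error(evaluate_matrix(unname(fx$feat), fx$co$outcomes, fx$split),
               "row names")
  bad_split <- list(train = fx$split$train,
                    valid = c(fx$split$valid, fx$split$train[1]))
  expect_error(evaluate_matrix(fx$feat, fx$co$outcomes, bad_split), "overlap")
  ghost <- list(train = fx$split$train, valid = c(fx$split$valid, "PXXXX"))
  expect_error(evaluate_matrix(fx$feat, fx$co$outcomes, ghost), "split ids")
  oc <- fx$co$outcomes
  oc$emergency <- 0L
  expect_error(evaluate_matrix(fx$feat, oc, fx$split), "single-class")
})

test_that("total score identities: self-score 1, homogeneity, hand mean", {
  fx <- scoring_fixture()
  rep <- fixture("scoring_report", function()
    evaluate_matrix(fx$feat, fx$co$outcomes, fx$split, seed = 1))
  expect_identical(total_score(rep, rep)$value, 1)

  cand <- setNames(runif(16, 0.1, 0.5), patvec:::MEASURE_NAMES)
  expect_equal(total_score(cand, cand / 2)$value, 2, tolerance = 1e-12)

  cand <- setNames(rep(c(0.12, 0.08), each = 8), patvec:::MEASURE_NAMES)
  ref <- setNames(rep(0.1, 16), patvec:::MEASURE_NAMES)
  expect_equal(total_score(cand, ref)$value, 1)
})

test_that("total score clamps candidates but rejects degenerate references", {
  ref <- setNames(rep(0.5, 16), patvec:::MEASURE_NAMES)
  cand <- ref; cand[["n_cases_linear_r2"]] <- -3   # clamped to the floor
  ts <- total_score(cand, ref)
  expect_equal(ts$ratios[["n_cases_linear_r2"]], 1e-6 / 0.5)
  bad_ref <- ref; bad_ref[["age_gbt_cpm"]] <- -0.2
  expect_error(total_score(cand, bad_ref), "age_gbt_cpm")
  expect_error(total_score(cand, ref[-1]), "different measures")
})

test_that("total score is scale-equivariant within the clamp bounds", {
  ref <- setNames(runif(16, 0.2, 0.4), patvec:::MEASURE_NAMES)
  cand <- ref * 0.8
  s1 <- total_score(cand, ref)$value
  s2 <- total_score(cand * 1.2, ref)$value
  expect_equal(s2 / s1, 1.2, tolerance = 1e-12)
})

test_that("gradient-boosted trees keep up with the linear learner on embeddings", {
  fit <- two_disease_fit()
  co <- two_disease_cohort()
  ids <- intersect(rownames(fit$doc_vectors), co$outcomes$patient_id)
  grp <- split_patients(ids, c(train = 0.7, valid = 0.3))
  feat <- fit$doc_vectors[ids, , drop = FALSE]
  colnames(feat) <- sprintf("d%02d", seq_len(ncol(feat)))
  rep <- evaluate_matrix(feat, co$outcomes, grp, seed = 2)
  expect_gte(rep[["n_cases_gbt_r2"]], rep[["n_cases_linear_r2"]] - 0.05)
})

test_that("drug-cost prediction reports the three regression measures", {
  fx <- scoring_fixture()
  res <- predict_drug_cost(fx$feat, fx$co$outcomes, fx$split, seed = 1)
  expect_equal(res$learner, c("linear", "gbt"))
  expect_true(all(is.finite(res$r2)))
  expect_true(all(res$mae > 0))
  expect_true(all(res$cpm <= 1))

  # appending constant "age"/"gender" columns leaves linear metrics unchanged
  om <- fx$co$outcomes
  om$age <- 1; om$gender <- 1
  res_const <- predict_drug_cost(fx$feat, om, fx$split,
                                 add_demographics = TRUE, seed = 1)
  base <- predict_drug_cost(fx$feat, om, fx$split, seed = 1)
  expect_equal(res_const[1, c("r2", "mae", "cpm")],
               base[1, c("r2", "mae", "cpm")], tolerance = 1e-6)
})

test_that("the mean predictor scores zero on cpm and r2 in the drug-cost task", {
  fx <- scoring_fixture()
  om <- fx$co$outcomes[match(fx$ids, fx$co$outcomes$patient_id), ]
  yv <- om$drug_cost[match(fx$split$valid, om$patient_id)]
  expect_equal(cpm(yv, rep(mean(yv), length(yv))), 0)
  expect_equal(r2(yv, rep(mean(yv), length(yv))), 0)
})

test_that("hash splitting is deterministic, disjoint and roughly proportional", {
  ids <- sprintf("Q%05d", 1:3000)
  g1 <- split_patients(ids)
  g2 <- split_patients(ids)
  expect_identical(g1, g2)
  expect_equal(sum(lengths(g1)), 3000)
  expect_length(intersect(g1$vec_train, g1$calib), 0)
  expect_lt(abs(length(g1$vec_train) / 3000 - 0.5), 0.05)
  g3 <- split_patients(ids, salt = 1L)
  expect_false(identical(g1$vec_train, g3$vec_train))
  # membership is stable under cohort growth
  g_sub <- split_patients(ids[1:1000])
  expect_true(all(g_sub$calib %in% g1$calib))
})
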