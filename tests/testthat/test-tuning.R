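# The integer-arithmetic half-up dropout oracle lives in helper-oracles.R.

test_that("dropout counts match the exhaustive half-up/keep-one table", {
  rates <- list(c(1L, 10L), c(1L, 4L), c(1L, 2L))   # 0.1, 0.25, 0.5
  for (r in rates) {
    rate <- r[1] / r[2]
    for (n in 1:50) {
      e <- data.frame(patient_id = "P", quarter = "2018Q1",
                      case_id = paste0("c", 1:n), place_id = "s",
                      code = paste0("x", 1:n), confirmed = TRUE)
      kept <- nrow(dropout_codes(e, rate, seed = n))
      expect_identical(n - kept, as.integer(dropout_oracle(n, r[1], r[2])),
                       label = sprintf("n=%d rate=%s", n, rate))
    }
  }
})

test_that("dropout keeps at least one code and spares non-confirmed entries", {
  e1 <- data.frame(patient_id = "P", quarter = "2018Q1", case_id = "c1",
                   place_id = "s", code = "x", confirmed = TRUE)
  expect_equal(nrow(dropout_codes(e1, 0.9, seed = 1)), 1)   # n = 1: keep it
  e4 <- data.frame(patient_id = "P", quarter = "2018Q1",
                   case_id = paste0("c", 1:5), place_id = "s",
                   code = paste0("x", 1:5),
                   confirmed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- dropout_codes(e4, 0.25, seed = 3)     # 4 confirmed -> drop exactly 1
  expect_equal(sum(out$confirmed), 3)
  expect_true("x5" %in% out$code)              # non-confirmed untouched
  e3 <- e4[1:3, ]
  out3 <- dropout_codes(e3, 0.5, seed = 1)     # round_half_up(1.5) = 2 dropped
  expect_equal(nrow(out3), 1)
})

test_that("claims-level dropout is per-patient deterministic and order-invariant", {
  co <- small_cohort()
  d1 <- dropout_claims(co$claims, 0.25, seed = 5)
  d2 <- dropout_claims(co$claims, 0.25, seed = 5)
  expect_identical(d1, d2)
  expect_identical(dropout_claims(co$claims, 0, seed = 5), co$claims)
})

test_that("training subsampling sizes and determinism", {
  corpus <- setNames(as.list(letters), paste0("P", 1:26))
  expect_identical(subsample_training(corpus, 1, 1), corpus)
  s100 <- subsample_training(setNames(as.list(1:100), sprintf("P%03d", 1:100)),
                             0.5, seed = 2)
  expect_length(s100, 50)
  expect_identical(subsample_training(corpus, 0.3, 9),
                   subsample_training(corpus, 0.3, 9))
  expect_length(subsample_training(corpus, 0.001, 1), 1)
  # different seeds give different samples with overlap near fraction^2 * N
  a <- names(subsample_training(setNames(as.list(1:200), 1:200), 0.5, 1))
  b <- names(subsample_training(setNames(as.list(1:200), 1:200), 0.5, 2))
  expect_false(identical(a, b))
  expect_lt(abs(length(intersect(a, b)) - 50), 20)
})

test_that("a single-trial search returns that trial as best", {
  res <- patvec_search(function(hp) hp$alpha,
                       n_trials = 1, seed = 3, method = "random")
  expect_equal(res$best$trial, 1)
  expect_equal(res$best$score, res$trials$score[1])
})

test_that("random search draws an identical trial sequence for a fixed seed", {
  space <- embedding_search_space()
  r1 <- patvec_search(function(hp) hp$alpha * hp$window, space,
                      n_trials = 12, seed = 8, method = "random")
  r2 <- patvec_search(function(hp) hp$alpha * hp$window, space,
                      n_trials = 12, seed = 8, method = "random")
  expect_identical(r1$trials, r2$trials)
  expect_true(all(r1$trials$window %in% 1:10))
  expect_true(all(r1$trials$alpha >= 0.001 & r1$trials$alpha <= 0.1))
})

test_that("failed trials are recorded and the search continues", {
  flaky <- function(hp) {
    if (hp$window > 5) stop("backend exploded")
    hp$alpha
  }
  res <- patvec_search(flaky, n_trials = 20, seed = 4, method = "random")
  expect_true(any(!is.na(res$trials$error)))
  expect_true(any(!is.na(res$trials$score)))
  expect_true(res$trials$window[res$best$trial] <= 5)
  expect_equal(grepl("exploded", res$trials$error[!is.na(res$trials$error)]),
               rep(TRUE, sum(!is.na(res$trials$error))))
})

test_that("the TPE sampler finds the top of a unimodal objective", {
  # known analytic objective over (alpha, window); dense-grid oracle
  f <- function(hp) -(log(hp$alpha) - log(0.01))^2 - 0.1 * (hp$window - 6)^2
  grid <- expand.grid(alpha = exp(seq(log(0.001), log(0.1), length.out = 200)),
                      window = 1:10)
  gvals <- sort(-(log(grid$alpha) - log(0.01))^2 - 0.1 * (grid$window - 6)^2,
                decreasing = TRUE)
  top5 <- gvals[ceiling(0.05 * length(gvals))]
  space <- embedding_search_space()[c("alpha", "window")]
  res <- patvec_search(f, space, n_trials = 50, seed = 6, method = "tpe")
  expect_gte(res$best$score, top5)
})
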