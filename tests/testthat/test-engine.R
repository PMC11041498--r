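# The loss/gradient oracles live in helper-oracles.R.

test_that("SGD steps match finite-difference gradients on random configurations", {
  set.seed(101)
  worst_ns <- 0; worst_hs <- 0
  for (rep in 1:120) {
    k <- sample(1:4, 1); M <- sample(2:5, 1); n <- sample(1:5, 1)
    lr <- runif(1, 0.01, 0.5)
    inputs <- matrix(rnorm(k * M, sd = 0.5), k, M)
    outs <- matrix(rnorm(n * M, sd = 0.5), n, M)
    labels <- c(1L, sample(0:1, n - 1, replace = TRUE))[seq_len(n)]
    step <- patvec:::cpp_sgd_step_ns(inputs, outs, labels, lr)
    gi <- fd_gradient(function(m) ns_loss(m, outs, labels), inputs)
    go <- fd_gradient(function(m) ns_loss(inputs, m, labels), outs)
    worst_ns <- max(worst_ns,
                    rel_err((inputs - step$inputs) / lr, gi),
                    rel_err((outs - step$outs) / lr, go))

    bits <- sample(0:1, n, replace = TRUE)
    step <- patvec:::cpp_sgd_step_hs(inputs, outs, bits, lr)
    gi <- fd_gradient(function(m) hs_loss(m, outs, bits), inputs)
    go <- fd_gradient(function(m) hs_loss(inputs, m, bits), outs)
    worst_hs <- max(worst_hs,
                    rel_err((inputs - step$inputs) / lr, gi),
                    rel_err((outs - step$outs) / lr, go))
  }
  expect_lt(worst_ns, 1e-4)
  expect_lt(worst_hs, 1e-4)
})

test_that("a full training update equals the verified SGD step (negative sampling)", {
  M <- 4
  code_vec <- matrix(rnorm(2 * M, sd = 0.3), 2, M)
  ctx_vec <- matrix(rnorm(2 * M, sd = 0.3), 2, M)
  hs_vec <- matrix(0, 1, M)
  doc_vec <- matrix(rnorm(M, sd = 0.3), 1, M)
  alpha <- 0.05
  # one-token document, target token 0; noise cdf forces the negative draw
  # to be token 1, so the update is fully determined
  step <- patvec:::cpp_sgd_step_ns(doc_vec, ctx_vec[c(1, 2), ], c(1L, 0L),
                                   alpha)
  cv <- code_vec + 0; xv <- ctx_vec + 0; hv <- hs_vec + 0; dv <- doc_vec + 0
  patvec:::cpp_train_epoch(list(0L), 0L, cv, xv, hv, dv,
                           c(0, 1), numeric(0), NULL, NULL,
                           TRUE, 2L, FALSE, 1L, alpha, alpha / 100,
                           0, 1, 123L)
  expect_equal(dv, step$inputs, tolerance = 1e-12)
  expect_equal(xv, step$outs, tolerance = 1e-12)
  expect_equal(cv, code_vec)   # no context tokens: code vectors untouched
})

test_that("a full training update equals the verified SGD step (hierarchical softmax)", {
  M <- 3
  v <- vocab_from_counts(c(a = 3, b = 1))
  huff <- build_huffman_tree(v)
  code_vec <- matrix(rnorm(2 * M, sd = 0.3), 2, M)
  ctx_vec <- matrix(0, 2, M)
  hs_vec <- matrix(rnorm(M, sd = 0.3), 1, M)
  doc_vec <- matrix(rnorm(M, sd = 0.3), 1, M)
  alpha <- 0.08
  target <- 0L   # vocab index of token "a"
  step <- patvec:::cpp_sgd_step_hs(doc_vec, hs_vec[huff$points[[1]] + 1, ,
                                                   drop = FALSE],
                                   huff$bits[[1]], alpha)
  cv <- code_vec + 0; xv <- ctx_vec + 0; hv <- hs_vec + 0; dv <- doc_vec + 0
  patvec:::cpp_train_epoch(list(target), 0L, cv, xv, hv, dv,
                           cumsum(c(0.5, 0.5)), numeric(0),
                           huff$points, huff$bits,
                           TRUE, 2L, FALSE, 0L, alpha, alpha / 100,
                           0, 1, 5L)
  expect_equal(dv, step$inputs, tolerance = 1e-12)
  expect_equal(hv[huff$points[[1]] + 1, , drop = FALSE], step$outs,
               tolerance = 1e-12)
})

# Pure-R reference implementation of one deterministic epoch (hierarchical
# softmax only, fixed window, no downsampling): an independent oracle for
# the training loop's window handling, update order and alpha schedule.
r_reference_epoch <- function(docs, code_vec, hs_vec, doc_vec, huff, dm,
                              window, alpha0, alpha_min, total,
                              processed = 0) {
  upd <- function(h, target, lr) {
    pts <- huff$points[[target + 1]] + 1
    bts <- huff$bits[[target + 1]]
    neu1e <- numeric(ncol(code_vec))
    for (d in seq_along(pts)) {
      f <- sum(h * hs_vec[pts[d], ])
      g <- (1 - bts[d] - plogis(f)) * lr
      neu1e <- neu1e + g * hs_vec[pts[d], ]
      hs_vec[pts[d], ] <<- hs_vec[pts[d], ] + g * h
    }
    neu1e
  }
  for (di in seq_along(docs)) {
    doc <- docs[[di]]
    n <- length(doc)
    for (t in seq_len(n)) {
      lr <- max(alpha_min, alpha0 - (alpha0 - alpha_min) *
                             min(1, processed / total))
      processed <- processed + 1
      ctx <- setdiff(seq(max(1, t - window), min(n, t + window)), t)
      if (dm) {
        rows <- doc[ctx] + 1
        h <- (doc_vec[di, ] + if (length(rows))
          colSums(code_vec[rows, , drop = FALSE]) else 0) / (1 + length(rows))
        neu1e <- upd(h, doc[t], lr) / (1 + length(rows))
        doc_vec[di, ] <- doc_vec[di, ] + neu1e
        for (r in rows) code_vec[r, ] <- code_vec[r, ] + neu1e
      } else {
        for (c in ctx) {
          h <- code_vec[doc[t] + 1, ]
          code_vec[doc[t] + 1, ] <- h + upd(h, doc[c], lr)
        }
        doc_vec[di, ] <- doc_vec[di, ] + upd(doc_vec[di, ], doc[t], lr)
      }
    }
  }
  list(code_vec = code_vec, hs_vec = hs_vec, doc_vec = doc_vec,
       processed = processed)
}

test_that("the training loop matches a pure-R reference epoch (DM and DBOW)", {
  set.seed(202)
  v <- vocab_from_counts(c(a = 10, b = 7, c = 5, d = 3, e = 1))
  huff <- build_huffman_tree(v)
  M <- 4
  docs <- list(c(0L, 1L, 2L, 3L, 4L, 0L, 1L), c(2L, 2L, 4L, 0L),
               c(3L, 1L))
  total <- 2 * sum(lengths(docs))
  for (dm in c(TRUE, FALSE)) {
    code_vec <- matrix(rnorm(5 * M, sd = 0.2), 5, M)
    hs_vec <- matrix(rnorm(4 * M, sd = 0.2), 4, M)
    doc_vec <- matrix(rnorm(3 * M, sd = 0.2), 3, M)
    ref <- r_reference_epoch(docs, code_vec, hs_vec, doc_vec, huff, dm,
                             window = 2, alpha0 = 0.025,
                             alpha_min = 0.00025, total = total)
    ref <- r_reference_epoch(docs, ref$code_vec, ref$hs_vec, ref$doc_vec,
                             huff, dm, 2, 0.025, 0.00025, total,
                             processed = ref$processed)

    cv <- code_vec + 0; hv <- hs_vec + 0; dv <- doc_vec + 0
    xv <- matrix(0, 5, M)
    processed <- 0
    for (ep in 1:2)
      processed <- patvec:::cpp_train_epoch(docs, 0:2, cv, xv, hv, dv,
                                            cumsum(rep(0.2, 5)), numeric(0),
                                            huff$points, huff$bits,
                                            dm, 2L, FALSE, 0L,
                                            0.025, 0.00025, processed, total,
                                            7L)
    expect_equal(cv, ref$code_vec, tolerance = 1e-10)
    expect_equal(hv, ref$hs_vec, tolerance = 1e-10)
    expect_equal(dv, ref$doc_vec, tolerance = 1e-10)
  }
})

test_that("hierarchical softmax path probabilities sum to one", {
  set.seed(33)
  for (V in c(3, 8, 16)) {
    v <- vocab_from_counts(setNames(sample(1:40, V), paste0("t", 1:V)))
    huff <- build_huffman_tree(v)
    hs_w <- matrix(rnorm((V - 1) * 4), V - 1, 4)
    h <- rnorm(4)
    p <- vapply(seq_len(V), function(tok) {
      pts <- huff$points[[tok]] + 1
      bts <- huff$bits[[tok]]
      prod(plogis((1 - 2 * bts) * drop(hs_w[pts, , drop = FALSE] %*% h)))
    }, numeric(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("average epoch loss is non-increasing at small constant learning rate", {
  v <- vocab_from_counts(c(a = 12, b = 9, c = 6, d = 4, e = 2, f = 1))
  huff <- build_huffman_tree(v)
  corpus_loss <- function(docs, code_vec, hs_vec, doc_vec, dm, window) {
    tot <- 0
    for (di in seq_along(docs)) {
      doc <- docs[[di]]
      n <- length(doc)
      for (t in seq_len(n)) {
        ctx <- setdiff(seq(max(1, t - window), min(n, t + window)), t)
        h <- if (dm) {
          rows <- doc[ctx] + 1
          (doc_vec[di, ] + if (length(rows))
            colSums(code_vec[rows, , drop = FALSE]) else 0) /
            (1 + length(rows))
        } else doc_vec[di, ]
        tot <- tot + hs_loss(matrix(h, 1),
                             hs_vec[huff$points[[doc[t] + 1]] + 1, ,
                                    drop = FALSE],
                             huff$bits[[doc[t] + 1]])
      }
    }
    tot
  }
  violations <- 0
  for (s in 1:5) {
    set.seed(s)
    docs <- lapply(1:25, function(i)
      sample(0:5, sample(4:9, 1), replace = TRUE, prob = c(12, 9, 6, 4, 2, 1)))
    M <- 6
    cv <- patvec:::cpp_init_matrix(6, M, 0.5 / M, s)
    hv <- matrix(0, 5, M)
    dv <- patvec:::cpp_init_matrix(25, M, 0.5 / M, s + 1000)
    xv <- matrix(0, 6, M)
    losses <- numeric(5)
    for (ep in 1:5) {
      patvec:::cpp_train_epoch(docs, 0:24, cv, xv, hv, dv,
                               cumsum(rep(1 / 6, 6)), numeric(0),
                               huff$points, huff$bits, TRUE, 3L, FALSE, 0L,
                               0.01, 0.01, 0, 1e9, s + ep)
      losses[ep] <- corpus_loss(docs, cv, hv, dv, TRUE, 3)
    }
    violations <- violations + sum(diff(losses) > 0)
  }
  expect_lte(violations, 1)
})

test_that("training is bit-reproducible for a fixed seed", {
  co <- small_cohort()
  p <- patvec_params(vector_size = 6, epochs = 2, min_count = 2,
                     negative = 3, alpha = 0.025, seed = 17)
  f1 <- patvec(co, p)
  f2 <- patvec(co, p)
  expect_identical(f1$doc_vectors, f2$doc_vectors)
  expect_identical(f1$code_vectors, f2$code_vectors)
  expect_identical(f1$context_weights, f2$context_weights)
})
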