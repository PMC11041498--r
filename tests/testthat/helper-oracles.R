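# Independent oracles shared by the unit and acceptance tests.

# Negative-sampling logistic loss and hierarchical-softmax path loss as
# plain R functions of the parameters (hidden activation = mean of inputs).
ns_loss <- function(inputs, outs, labels) {
  h <- colMeans(inputs)
  f <- drop(outs %*% h)
  -sum(labels * log(plogis(f)) + (1 - labels) * log(plogis(-f)))
}

hs_loss <- function(inputs, outs, bits) {
  h <- colMeans(inputs)
  f <- drop(outs %*% h)
  -sum(log(plogis((1 - 2 * bits) * f)))
}

fd_gradient <- function(loss, mat, eps = 1e-5) {
  g <- mat
  for (i in seq_along(mat)) {
    up <- mat; up[i] <- up[i] + eps
    dn <- mat; dn[i] <- dn[i] - eps
    g[i] <- (loss(up) - loss(dn)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

# Worst relative error of the engine's SGD steps against central finite
# differences over n_configs random small configurations.
gradient_worst_errors <- function(n_configs = 120, seed = 101) {
  set.seed(seed)
  worst_ns <- 0; worst_hs <- 0
  for (rep in seq_len(n_configs)) {
    k <- sample(1:4, 1); M <- sample(2:5, 1); n <- sample(1:5, 1)
    lr <- runif(1, 0.01, 0.5)
    inputs <- matrix(rnorm(k * M, sd = 0.5), k, M)
    outs <- matrix(rnorm(n * M, sd = 0.5), n, M)
    labels <- c(1L, sample(0:1, n - 1, replace = TRUE))[seq_len(n)]
    step <- patvec:::cpp_sgd_step_ns(inputs, outs, labels, lr)
    gi <- fd_gradient(function(m) ns_loss(m, outs, labels), inputs)
    go <- fd_gradient(function(m) ns_loss(inputs, m, labels), outs)
    worst_ns <- max(worst_ns, rel_err((inputs - step$inputs) / lr, gi),
                    rel_err((outs - step$outs) / lr, go))
    bits <- sample(0:1, n, replace = TRUE)
    step <- patvec:::cpp_sgd_step_hs(inputs, outs, bits, lr)
    gi <- fd_gradient(function(m) hs_loss(m, outs, bits), inputs)
    go <- fd_gradient(function(m) hs_loss(inputs, m, bits), outs)
    worst_hs <- max(worst_hs, rel_err((inputs - step$inputs) / lr, gi),
                    rel_err((outs - step$outs) / lr, go))
  }
  c(ns = worst_ns, hs = worst_hs)
}

# Exhaustive prefix-tree oracle: minimum weighted depth over all full
# binary trees, by enumerating every sequence of pairwise merges.
min_weighted_depth <- function(weights) {
  if (length(weights) == 1L) return(0)
  best <- Inf
  n <- length(weights)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      merged <- c(weights[-c(i, j)], weights[i] + weights[j])
      best <- min(best, weights[i] + weights[j] + min_weighted_depth(merged))
    }
  }
  best
}

# Brute-force pair-counting AUROC (ties count one half).
auroc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact half-up rounding via integer arithmetic, for rate = num/den.
dropout_oracle <- function(n, num, den) {
  k <- (2L * num * n + den) %/% (2L * den)
  min(k, n - 1L)
}
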