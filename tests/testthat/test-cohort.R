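silhouette2 <- function(points, labels) {
  # two-cluster silhouette, computed directly from the definition
  d <- as.matrix(dist(points))
  mean(vapply(seq_len(nrow(points)), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    oth <- which(labels != labels[i])
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    (b - a) / max(a, b)
  }, numeric(1)))
}

blob_points <- function(n = 60, sep = 8, M = 10, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * M), n, M),
             matrix(rnorm(n * M) + sep / sqrt(M), n, M))
  rownames(x) <- sprintf("P%03d", seq_len(2 * n))
  x
}

test_that("projection maps identical rows to identical points", {
  x <- blob_points()
  x[5, ] <- x[1, ]
  p <- project_2d(x, seed = 1)
  expect_equal(p[1, ], p[5, ], tolerance = 1e-6)
  expect_true(all(is.finite(p)))
  expect_equal(rownames(p), rownames(x))
})

test_that("two separated blobs stay separated in 2D (silhouette > 0.5)", {
  x <- blob_points()
  p <- project_2d(x, seed = 1)
  labels <- rep(1:2, each = 60)
  expect_gt(silhouette2(p, labels), 0.5)
})

test_that("projection rejects tiny inputs and surfaces backend failures", {
  expect_error(project_2d(matrix(rnorm(18), 9, 2)), "at least 10")
  expect_error(project_2d(blob_points(), method = function(x, seed)
    stop("no backend")), "projection backend failed")
  custom <- project_2d(blob_points(), method = function(x, seed)
    x[, 1:2], seed = 1)
  expect_equal(ncol(custom), 2)
})

test_that("density clustering finds two blobs and one degenerate cluster", {
  x <- blob_points()
  p <- project_2d(x, seed = 1)
  labels <- cluster_density(p, min_cluster_size = 10)
  found <- setdiff(unique(labels), -1L)
  expect_length(found, 2)
  truth <- rep(1:2, each = 60)
  expect_gt(abs(cor(labels[labels != -1], truth[labels != -1])), 0.99)

  same <- matrix(1, 30, 2)
  expect_equal(unique(cluster_density(same, min_cluster_size = 5)), 1L)
})

test_that("uniform noise is mostly labelled as noise", {
  set.seed(8)
  u <- matrix(runif(400), 200, 2)
  labels <- cluster_density(u, min_cluster_size = 40, eps = 0.05)
  expect_gt(mean(labels == -1L), 0.5)
})

test_that("overexpressed codes match the hand-computed share differences", {
  cl <- data.frame(patient_id = c("P1", "P2", "P2", "P3"),
                   quarter = "2018Q1", case_id = "c", place_id = "s",
                   code = c("a", "a", "b", "c"), confirmed = TRUE)
  ids <- c("P1", "P2", "P3")
  res <- overexpressed_codes(cl, c(1L, 1L, 2L), ids, k = 2)
  c1 <- res[["1"]]
  expect_equal(c1$code[1], "a")
  expect_equal(c1$diff[1], 1 - 2 / 3)
  expect_equal(c1$diff[c1$code == "b"], 1 / 2 - 1 / 3)
  # cluster = whole cohort -> all differences zero
  all1 <- overexpressed_codes(cl, rep(1L, 3), ids, k = 10)[["1"]]
  expect_true(all(abs(all1$diff) < 1e-12))
  # k larger than distinct codes returns everything
  expect_equal(nrow(all1), 3)
})

test_that("cluster shares of a code average back to the cohort share", {
  co <- small_cohort()
  ids <- co$outcomes$patient_id
  set.seed(2)
  labels <- sample(c(-1L, 1L, 2L, 3L), length(ids), replace = TRUE)
  res <- overexpressed_codes(co$claims, labels, ids, k = 1e6)
  code <- res[["1"]]$code[1]
  shares <- vapply(res, function(df) df$share_cluster[df$code == code],
                   numeric(1))
  sizes <- table(factor(labels, levels = sort(unique(labels))))
  pooled <- sum(shares * as.numeric(sizes)) / length(ids)
  expect_equal(pooled, res[["1"]]$share_cohort[res[["1"]]$code == code],
               tolerance = 1e-12)
  expect_true(all(vapply(res, function(df)
    all(df$diff >= -1 & df$diff <= 1), logical(1))))
})

test_that("code-dimension correlations follow hand examples and conventions", {
  b <- cbind(x = c(1, 1, 0, 0), const = c(1, 1, 1, 1))
  v <- cbind(same = c(2, 2, 0, 0), anti = c(0, 0, 2, 2), noise = c(1, 3, 2, 0))
  cc <- code_dimension_correlation(b, v)
  expect_equal(cc["x", "same"], 1)
  expect_equal(cc["x", "anti"], -1)
  expect_equal(unname(cc["const", ]), c(0, 0, 0))   # constant column convention
  expect_true(all(cc >= -1 & cc <= 1))
  # affine rescaling of a dimension leaves correlations unchanged
  v2 <- v; v2[, "same"] <- 5 * v2[, "same"] - 3
  expect_equal(code_dimension_correlation(b, v2), cc, tolerance = 1e-12)
  expect_error(code_dimension_correlation(b[1:2, ], v[1:2, ]), "at least 3")
})

test_that("cluster summaries cover every label plus None and All", {
  co <- small_cohort()
  ids <- co$outcomes$patient_id
  set.seed(3)
  labels <- sample(c(-1L, 1L, 2L), length(ids), replace = TRUE)
  summ <- summarize_clusters(co$outcomes, labels, ids, claims = co$claims)
  expect_equal(summ$cluster, c("1", "2", "None", "All"))
  expect_equal(sum(summ$share[summ$cluster != "All"]), 1, tolerance = 1e-12)
  expect_equal(summ$n[summ$cluster == "All"], length(ids))
  # a single all-encompassing cluster reproduces the All row
  s1 <- summarize_clusters(co$outcomes, rep(1L, length(ids)), ids)
  expect_equal(s1[s1$cluster == "1", c("mean_age", "female_share",
                                       "mean_n_cases")],
               s1[s1$cluster == "All", c("mean_age", "female_share",
                                         "mean_n_cases")],
               ignore_attr = TRUE)
  # empty noise set renders as missing
  expect_true(is.na(s1$mean_age[s1$cluster == "None"]))
})

test_that("the female-only latent cluster shows up female in summaries", {
  co <- two_disease_cohort()
  only2 <- co$latent$disease_ids == "2"
  labels <- ifelse(only2, 1L, -1L)
  summ <- summarize_clusters(co$outcomes, labels, co$latent$patient_id,
                             claims = co$claims)
  expect_gt(summ$female_share[summ$cluster == "1"], 0.95)
  expect_lt(summ$female_share[summ$cluster == "None"], 0.8)
  # and its distinctive codes come from that disease's pool
  dt <- patvec:::disease_table(co$config)
  top <- strsplit(summ$distinctive_codes[summ$cluster == "1"], ", ")[[1]]
  expect_true(all(top %in% dt$codes[[2]]))
})
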