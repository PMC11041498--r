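# Exploratory cohort layer: 2D projection and density clustering of patient
# vectors (pluggable backends), per-cluster summaries, overexpressed codes,
# and code-dimension correlations.

#' Project patient vectors to 2D
#'
#' Delegates to a pluggable projection backend. The bundled backend is PCA
#' (`prcomp`, first two components); any function
#' `function(x, seed) -> N x 2 matrix` can be supplied instead (e.g. a
#' nonlinear manifold method).
#'
#' @param vectors numeric N x M matrix (N >= 10).
#' @param method `"pca"` or a backend function.
#' @param seed passed to the backend.
#' @return N x 2 numeric matrix, row names preserved.
#' @export
project_2d <- function(vectors, method = "pca", seed = 1L) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 10L)
    stop("projection needs at least 10 rows", call. = FALSE)
  out <- if (is.function(method)) {
    res <- tryCatch(method(vectors, seed), error = function(e)
      stop("projection backend failed: ", conditionMessage(e), call. = FALSE))
    as.matrix(res)
  } else if (identical(method, "pca")) {
    p <- prcomp(vectors, center = TRUE, scale. = FALSE, rank. = 2L)
    s <- p$x
    if (ncol(s) < 2L) s <- cbind(s, 0)   # rank-1 input
    s[, 1:2, drop = FALSE]
  } else stop("unknown projection method", call. = FALSE)
  if (!all(is.finite(out))) stop("projection produced non-finite values",
                                 call. = FALSE)
  rownames(out) <- rownames(vectors)
  colnames(out) <- c("x", "y")
  out
}

#' Density-based clustering of projected points
#'
#' Delegates to a pluggable density-clustering backend; the bundled backend
#' is a plain DBSCAN over Euclidean distances with `min_pts =
#' min_cluster_size` and, unless given, `eps` set to the 90th percentile of
#' the `min_cluster_size`-nearest-neighbour distances. Points in no dense
#' region are labelled `-1` ("noise"), clusters `1..k`.
#'
#' @param points numeric N x d matrix (finite).
#' @param min_cluster_size minimum neighbourhood size for a core point.
#' @param eps neighbourhood radius; `NULL` for the kNN heuristic.
#' @param method `"dbscan"` or a backend function
#'   `function(points, min_cluster_size) -> integer labels`.
#' @return integer vector of length N (`-1` = noise).
#' @export
cluster_density <- function(points, min_cluster_size = 10L, eps = NULL,
                            method = "dbscan") {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite", call. = FALSE)
  if (is.function(method)) {
    labels <- tryCatch(method(points, min_cluster_size), error = function(e)
      stop("clustering backend failed: ", conditionMessage(e), call. = FALSE))
    return(as.integer(labels))
  }
  if (!identical(method, "dbscan"))
    stop("unknown clustering method", call. = FALSE)
  n <- nrow(points)
  d <- as.matrix(dist(points))
  if (is.null(eps)) {
    k <- min(min_cluster_size, n - 1L)
    knn <- apply(d, 1, function(r) sort(r)[k + 1L])
    eps <- as.numeric(quantile(knn, 0.9))
    if (eps <= 0) eps <- 1e-12   # coincident points still form one cluster
  }
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neighbours) >= min_cluster_size
  labels <- rep.int(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      j <- queue[1L]; queue <- queue[-1L]
      if (!core[j]) next
      for (nb in neighbours[[j]]) {
        if (labels[nb] == -1L) {
          labels[nb] <- cl
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

patient_code_presence <- function(claims, ids) {
  x <- claims[as.logical(claims$confirmed) & claims$patient_id %in% ids, ,
              drop = FALSE]
  unique(x[, c("patient_id", "code")])
}

#' Overexpressed codes per cluster
#'
#' For every cluster, ranks codes by the difference between their
#' patient-level share inside the cluster and their share in the whole
#' cohort (`share = fraction of patients with at least one confirmed entry
#' of the code`). Ties break lexicographically.
#'
#' @param claims claims table.
#' @param labels integer cluster labels aligned with `ids`.
#' @param ids patient ids aligned with `labels`.
#' @param k number of top codes per cluster (all codes if fewer).
#' @return named list (one element per cluster label, including `-1`) of
#'   data.frames with columns `code`, `share_cluster`, `share_cohort`,
#'   `diff`.
#' @export
overexpressed_codes <- function(claims, labels, ids, k = 3L) {
  stopifnot(length(labels) == length(ids))
  pres <- patient_code_presence(claims, ids)
  n_all <- length(ids)
  share_all <- table(pres$code) / n_all
  out <- list()
  for (lab in sort(unique(labels))) {
    members <- ids[labels == lab]
    if (length(members) == 0L) stop("empty cluster ", lab, call. = FALSE)
    pc <- pres[pres$patient_id %in% members, , drop = FALSE]
    share_cl <- table(factor(pc$code, levels = names(share_all))) /
      length(members)
    df <- data.frame(code = names(share_all),
                     share_cluster = as.numeric(share_cl),
                     share_cohort = as.numeric(share_all),
                     stringsAsFactors = FALSE)
    df$diff <- df$share_cluster - df$share_cohort
    df <- df[order(-df$diff, df$code), , drop = FALSE]
    rownames(df) <- NULL
    out[[as.character(lab)]] <- head(df, k)
  }
  out
}

#' Correlation between binary code indicators and embedding dimensions
#'
#' Pearson correlation of each binary-encoded code column with each vector
#' dimension over aligned patients; an explainability view of which codes
#' load on which dimensions. Constant columns (either side) yield 0 by
#' convention (their correlation is undefined).
#'
#' @param binary N x K 0/1 matrix (columns = codes).
#' @param vectors N x M numeric matrix (columns = dimensions).
#' @return K x M correlation matrix.
#' @export
code_dimension_correlation <- function(binary, vectors) {
  binary <- as.matrix(binary); vectors <- as.matrix(vectors)
  if (nrow(binary) != nrow(vectors))
    stop("binary and vectors must have aligned rows", call. = FALSE)
  if (nrow(binary) < 3L) stop("need at least 3 patients", call. = FALSE)
  out <- suppressWarnings(cor(binary, vectors))
  out[!is.finite(out)] <- 0
  out
}

#' Per-cluster cohort summaries
#'
#' One row per cluster, plus a `"None"` row for unclustered patients
#' (label -1) and an `"All"` row for the whole cohort: cohort share, mean
#' age, female share, mean number of cases, emergency share, mean drug
#' cost, and (when `claims` is supplied) the top overexpressed codes.
#'
#' @param outcomes outcomes table.
#' @param labels integer cluster labels aligned with `ids`.
#' @param ids patient ids aligned with `labels`.
#' @param claims optional claims table for the distinctive-codes column.
#' @param k number of distinctive codes to list.
#' @return data.frame of class `patvec_cluster_summary`.
#' @export
summarize_clusters <- function(outcomes, labels, ids, claims = NULL, k = 3L) {
  stopifnot(length(labels) == length(ids))
  om <- outcomes[match(ids, outcomes$patient_id), , drop = FALSE]
  if (anyNA(om$patient_id)) stop("ids missing from outcomes", call. = FALSE)
  over <- if (!is.null(claims)) overexpressed_codes(claims, labels, ids, k)
  one <- function(sel, name) {
    n <- sum(sel)
    data.frame(cluster = name, n = n, share = n / length(ids),
               mean_age = if (n) mean(om$age[sel]) else NA_real_,
               female_share = if (n) mean(om$gender[sel]) else NA_real_,
               mean_n_cases = if (n) mean(om$n_cases[sel]) else NA_real_,
               emergency_share = if (n) mean(om$emergency[sel]) else NA_real_,
               mean_drug_cost = if (n) mean(om$drug_cost[sel]) else NA_real_,
               distinctive_codes = if (!is.null(over) && n &&
                                       name %in% c(names(over), "None"))
                 paste(over[[if (name == "None") "-1" else name]]$code,
                       collapse = ", ") else NA_character_,
               stringsAsFactors = FALSE)
  }
  labs <- sort(setdiff(unique(labels), -1L))
  rows <- lapply(labs, function(l) one(labels == l, as.character(l)))
  rows <- c(rows, list(one(labels == -1L, "None"),
                       one(rep(TRUE, length(ids)), "All")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("patvec_cluster_summary", "data.frame")
  out
}

#' @describeIn project_2d `plot` method for fitted models: projects the
#'   trained patient vectors to 2D and scatters them.
#' @param x a fitted [patvec()] model.
#' @param colour_by optional vector aligned with patients (cluster labels
#'   or an outcome) used for point colours.
#' @param ... passed on to [plot_projection()].
#' @export
plot.patvec <- function(x, colour_by = NULL, method = "pca", seed = 1L, ...) {
  p <- project_2d(as.matrix(x), method = method, seed = seed)
  plot_projection(p, colour_by = colour_by, ...)
  invisible(p)
}

#' Plot a 2D cohort projection
#'
#' Base-graphics scatter of a [project_2d()] result, coloured by cluster
#' label or by a numeric/binary outcome.
#'
#' @param x N x 2 projection matrix.
#' @param colour_by vector aligned with rows (cluster labels or outcome).
#' @param ... passed to [graphics::plot()].
#' @export
plot_projection <- function(x, colour_by = NULL, ...) {
  cols <- if (is.null(colour_by)) "grey30" else {
    f <- as.factor(colour_by)
    grDevices::hcl.colors(max(2L, nlevels(f)), "Dark 3")[as.integer(f)]
  }
  graphics::plot(x[, 1], x[, 2], col = cols, pch = 16, cex = 0.5,
                 xlab = "dim 1", ylab = "dim 2", ...)
  invisible(x)
}
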