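# Binary Huffman coding over vocabulary counts, used by the hierarchical
# softmax: each token gets a root-to-leaf path through V-1 internal nodes;
# the path loss replaces the full softmax over V tokens.

#' Build the Huffman tree for hierarchical softmax
#'
#' Constructs the binary Huffman code over token counts with the classic
#' two-queue linear-time merge (leaves sorted by ascending count). Ties are
#' broken deterministically: when a leaf and an already-merged internal node
#' have equal count, the leaf is taken first. Internal nodes are numbered in
#' creation order `0..V-2`; the root is node `V-2`.
#'
#' @param vocab a [build_vocabulary()] result (V >= 2 tokens).
#' @return object of class `patvec_huffman`: list with `points` (per token,
#'   integer vector of internal-node indices from the root down to the
#'   token's parent), `bits` (per token, 0/1 branch choices of equal
#'   length), `lengths` (integer code lengths).
#' @export
build_huffman_tree <- function(vocab) {
  stopifnot(inherits(vocab, "patvec_vocab"))
  V <- length(vocab$token)
  if (V < 2L) stop("hierarchical softmax needs a vocabulary of size >= 2",
                   call. = FALSE)
  ord <- order(vocab$count, vocab$index)     # ascending count, stable
  leaf_count <- vocab$count[ord]
  # nodes 1..V are leaves (in ascending-count order), V+1..2V-1 internal
  count <- c(leaf_count, rep(NA_real_, V - 1L))
  parent <- integer(2L * V - 1L)
  bit <- integer(2L * V - 1L)
  p1 <- 1L                                    # next unused leaf
  p2 <- V + 1L                                # next unused internal node
  for (k in seq_len(V - 1L)) {
    pick <- function() {
      # leaf preferred on ties; internal counts are non-decreasing
      if (p1 <= V && (p2 > V + k - 1L || count[p1] <= count[p2])) {
        i <- p1; p1 <<- p1 + 1L
      } else {
        i <- p2; p2 <<- p2 + 1L
      }
      i
    }
    a <- pick(); b <- pick()
    node <- V + k
    count[node] <- count[a] + count[b]
    parent[a] <- node; parent[b] <- node
    bit[a] <- 0L; bit[b] <- 1L
  }
  points <- vector("list", V); bits <- vector("list", V)
  for (j in seq_len(V)) {
    pth <- integer(0); bts <- integer(0)
    node <- j
    while (parent[node] != 0L) {
      bts <- c(bit[node], bts)
      pth <- c(parent[node] - V - 1L, pth)    # 0-based internal index
      node <- parent[node]
    }
    tok <- ord[j]                             # vocab position of this leaf
    points[[tok]] <- pth
    bits[[tok]] <- bts
  }
  structure(list(points = points, bits = bits,
                 lengths = lengths(points)), class = "patvec_huffman")
}

#' @export
print.patvec_huffman <- function(x, ...) {
  cat(sprintf("Huffman tree: %d leaves, code lengths %d..%d, Kraft sum %.6f\n",
              length(x$points), min(x$lengths), max(x$lengths),
              sum(2^-x$lengths)))
  invisible(x)
}

#' Negative-sampling noise distribution
#'
#' Token sampling probabilities for the negative-sampling loss:
#' `p(token) = count^ns_exponent / sum(count^ns_exponent)`. Exponent 0 gives
#' the uniform distribution, 1 the raw frequency distribution; negative
#' exponents invert the frequency ranking (rare codes sampled more often),
#' which is permitted over the tuning range.
#'
#' @param vocab a [build_vocabulary()] result.
#' @param ns_exponent smoothing exponent (typically in `[-5, 5]`).
#' @return object of class `patvec_noise`: list with `token`, `prob`.
#' @export
build_noise_distribution <- function(vocab, ns_exponent = 0.75) {
  stopifnot(inherits(vocab, "patvec_vocab"))
  if (length(vocab$token) == 0L) stop("empty vocabulary", call. = FALSE)
  w <- as.numeric(vocab$count)^ns_exponent
  structure(list(token = vocab$token, prob = w / sum(w)),
            class = "patvec_noise")
}
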