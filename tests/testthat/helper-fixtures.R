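# Shared fixtures and independent oracles, built in code at test time.

# small cohort with arbitrary (non-round) values
toy_cohort <- function(p = 4, n = 5, seed = 11, id = "toy") {
  set.seed(seed)
  m <- matrix(rnorm(p * n, mean = 8, sd = 2), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  expression_cohort(m, id)
}

# construct a represented_pc directly from a feature set and weights
make_rpc <- function(cohort_id, component_index, features, weights,
                     all_features = features, all_weights = weights) {
  w <- as.numeric(all_weights)
  names(w) <- all_features
  structure(
    list(cohort_id = cohort_id,
         component_index = as.integer(component_index),
         weight_vector = w,
         representative = data.frame(
           feature = features,
           sign = as.integer(sign(weights[match(features, all_features)])),
           r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)),
    class = "represented_pc")
}

# brute-force AUC: concordant pair count with half credit for ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force O(n^3) average-linkage agglomeration: returns merge heights
brute_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# rank-3 planted matrix: 3 orthogonal patterns, per-entry signal sd
# `signal_sd`, isotropic noise sd `noise_sd`
planted_rank3_cohort <- function(n = 60, p = 300, signal_sd = 10,
                                 noise_sd = 1, seed = 1, id = "rank3") {
  set.seed(seed)
  A <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)  # orthogonal activities
  L <- matrix(rnorm(p * 3), p, 3)
  X <- signal_sd * (L %*% t(A)) / sqrt(3) +
    matrix(rnorm(p * n, 0, noise_sd), p, n)
  dimnames(X) <- list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:n))
  expression_cohort(X, id)
}

# z-scale merged matrix drawn from a disjoint-block factor model
# (genes x samples); used to probe derive_ceis in isolation
planted_factor_merged <- function(n_blocks = 3, block_size = 20, n = 200,
                                  loading = 0.8, noise_sd = 0.6, seed = 1) {
  set.seed(seed)
  p <- n_blocks * block_size
  L <- matrix(0, p, n_blocks)
  for (b in seq_len(n_blocks))
    L[((b - 1) * block_size + 1):(b * block_size), b] <-
      loading * sample(c(-1, 1), block_size, replace = TRUE)
  A <- matrix(rnorm(n * n_blocks), n, n_blocks)
  X <- L %*% t(A) + matrix(rnorm(p * n, 0, noise_sd), p, n)
  rownames(X) <- sprintf("g%03d", 1:p)
  rownames(L) <- rownames(X)
  colnames(X) <- sprintf("s%03d", 1:n)
  list(merged = t(scale(t(X))), loadings = L)
}

# best Jaccard of a recovered gene set against a list of planted blocks
best_block_jaccard <- function(genes, blocks) {
  max(vapply(blocks, function(b)
    length(intersect(genes, b)) / length(union(genes, b)), numeric(1)))
}
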