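#' Filter features by coefficient of variation on the anti-log scale
#'
#' For each feature the coefficient of variation CV = sd(2^x)/mean(2^x) is
#' computed over samples on the anti-logarithm of the log2 expression values
#' (sample standard deviation, n-1 denominator). Features with
#' \code{low < CV < high} are retained in their original order; the defaults
#' (1 and 1000) select the highly variable probe sets while excluding
#' pathological dynamic ranges.
#'
#' @param cohort an \code{\link{expression_cohort}} on log2 scale.
#' @param low,high open CV interval bounds (defaults 1 and 1000).
#' @return The filtered \code{\link{expression_cohort}}, with attribute
#'   \code{cv} holding the CV of the retained features.
#' @export
cv_filter <- function(cohort, low = 1, high = 1000) {
  stopifnot(inherits(cohort, "expression_cohort"), low < high)
  y <- 2^cohort$values
  mu <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  cv <- sdv / mu
  keep <- cv > low & cv < high
  if (!any(keep))
    stop("no features survive the CV filter (", low, ", ", high,
         "); review the thresholds or the input scale")
  out <- expression_cohort(cohort$values[keep, , drop = FALSE], cohort$cohort_id)
  attr(out, "cv") <- cv[keep]
  out
}

#' Principal component analysis of an expression cohort
#'
#' SVD of the feature-centered matrix (no scaling to unit variance; the CV
#' filter already equalizes dynamic range). Component sign convention: the
#' largest-magnitude entry of each weight vector is made positive, so
#' results are reproducible across linear-algebra backends.
#'
#' @param cohort an \code{\link{expression_cohort}} (at least 3 samples).
#' @return An object of class \code{cohort_pca}: list with \code{cohort_id},
#'   \code{feature_ids}, \code{sigma} (per-feature sd), \code{omega}
#'   (per-component explained sd, the square root of each eigenvalue),
#'   \code{scores} (samples x components), \code{weights} (features x
#'   components), \code{n}, \code{p}, and \code{k_selected}/\code{nu}
#'   (NA until \code{\link{select_k_bic}} is applied).
#' @export
fit_pca <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  X <- cohort$values
  n <- ncol(X); p <- nrow(X)
  if (n < 3) stop("PCA requires at least 3 samples")
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  r <- min(p, n - 1)  # centered matrix has rank at most n-1
  W <- sv$u[, seq_len(r), drop = FALSE]
  S <- sweep(sv$v[, seq_len(r), drop = FALSE], 2, sv$d[seq_len(r)], `*`)
  # deterministic sign: largest-|weight| entry positive per component
  flip <- vapply(seq_len(r), function(j) {
    i <- which.max(abs(W[, j])); sign(W[i, j])
  }, numeric(1))
  flip[flip == 0] <- 1
  W <- sweep(W, 2, flip, `*`)
  S <- sweep(S, 2, flip, `*`)
  dimnames(W) <- list(rownames(X), paste0("PC", seq_len(r)))
  dimnames(S) <- list(colnames(X), paste0("PC", seq_len(r)))
  structure(
    list(cohort_id = cohort$cohort_id,
         feature_ids = rownames(X),
         sigma = apply(X, 1, stats::sd),
         omega = sv$d[seq_len(r)] / sqrt(n - 1),
         scores = S,
         weights = W,
         k_selected = NA_integer_,
         nu = NA_real_,
         n = n, p = p),
    class = "cohort_pca")
}

#' @export
print.cohort_pca <- function(x, ...) {
  cat("PCA of cohort '", x$cohort_id, "': p = ", x$p, ", n = ", x$n,
      ", components = ", length(x$omega), sep = "")
  if (!is.na(x$k_selected))
    cat(", k_selected = ", x$k_selected, " (nu = ", signif(x$nu, 4), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Select the number of principal components by BIC
#'
#' The likelihood is driven by the fraction of total variance explained:
#' the unexplained variance at k components is the residual sum of squares
#' nu_k = sum_i sigma_i^2 - sum_{j<=k} omega_j^2, and
#' BIC(k) = n*log(nu_k/n) + k*log(n) (Gaussian-residual form). The k
#' minimizing BIC over 1..k_max is returned. A perfect fit (nu_k <= 0) is
#' treated as BIC = -Inf with a warning.
#'
#' @param pca a \code{\link{fit_pca}} result.
#' @param k_max largest k considered (default \code{min(n-1, 20)}).
#' @param form BIC strategy; only \code{"gaussian"} is currently provided,
#'   the argument exists so alternatives can be slotted in.
#' @return Integer k, with attributes \code{bic} (the BIC sequence),
#'   \code{nu_path} (residual sum of squares per k) and \code{nu} (at the
#'   optimum). Use \code{\link{apply_k_selection}} to stamp the choice onto
#'   the \code{cohort_pca} object.
#' @export
select_k_bic <- function(pca, k_max = NULL, form = c("gaussian")) {
  stopifnot(inherits(pca, "cohort_pca"))
  form <- match.arg(form)
  n <- pca$n
  if (is.null(k_max)) k_max <- min(n - 1, 20L)
  k_max <- min(k_max, length(pca$omega))
  if (k_max < 1) stop("k_max must be at least 1")
  total <- sum(pca$sigma^2)
  nu_k <- total - cumsum(pca$omega[seq_len(k_max)]^2)
  nu_k[abs(nu_k) < total * 1e-12] <- 0
  ks <- seq_len(k_max)
  bic <- ifelse(nu_k > 0, n * log(nu_k / n) + ks * log(n), -Inf)
  if (any(nu_k <= 0))
    warning("perfect fit reached at k = ", which(nu_k <= 0)[1])
  k <- which.min(bic)
  structure(as.integer(k), bic = bic, nu_path = nu_k, nu = nu_k[k])
}

#' Stamp a BIC component selection onto a PCA object
#' @param pca a \code{cohort_pca}.
#' @param k result of \code{\link{select_k_bic}} (or a plain integer).
#' @return The \code{cohort_pca} with \code{k_selected} and \code{nu} set.
#' @export
apply_k_selection <- function(pca, k) {
  stopifnot(inherits(pca, "cohort_pca"))
  pca$k_selected <- as.integer(k)
  nu <- attr(k, "nu")
  if (is.null(nu)) nu <- sum(pca$sigma^2) - sum(pca$omega[seq_len(k)]^2)
  pca$nu <- nu
  pca
}

#' Distill a principal component to its representative feature set
#'
#' For each feature, the Pearson correlation r between its expression values
#' and the component scores is tested by Student's t-test
#' (t = r*sqrt(n-2)/sqrt(1-r^2), n-2 df, two-sided). Features with P below
#' \code{alpha} form the representative set, each tagged with the sign of
#' its correlation.
#'
#' @param pca a \code{\link{fit_pca}} result for \code{cohort}.
#' @param cohort the (filtered) \code{\link{expression_cohort}} the PCA was
#'   fitted on.
#' @param component_index which component to distill.
#' @param alpha significance threshold (default 0.01).
#' @return An object of class \code{represented_pc}: list with
#'   \code{cohort_id}, \code{component_index}, \code{weight_vector} (named,
#'   over all filtered features), and \code{representative} (data frame with
#'   \code{feature}, \code{sign}, \code{r}, \code{p}).
#' @export
distill_pc <- function(pca, cohort, component_index, alpha = 0.01) {
  stopifnot(inherits(pca, "cohort_pca"), inherits(cohort, "expression_cohort"))
  if (!identical(pca$feature_ids, cohort$features))
    stop("cohort features do not match the PCA's feature set")
  n <- pca$n
  if (n < 4) stop("distillation needs n >= 4 (t-test df = n-2 >= 2)")
  if (component_index > ncol(pca$scores))
    stop("component_index exceeds the number of computed components")
  s <- pca$scores[, component_index]
  r <- as.vector(stats::cor(t(cohort$values), s))
  r[is.na(r)] <- 0  # zero-variance features cannot correlate
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  keep <- p < alpha
  if (!any(keep))
    stop("empty representative set for component ", component_index,
         "; consider relaxing alpha (currently ", alpha, ")")
  w <- pca$weights[, component_index]
  names(w) <- pca$feature_ids
  structure(
    list(cohort_id = pca$cohort_id,
         component_index = as.integer(component_index),
         weight_vector = w,
         representative = data.frame(
           feature = pca$feature_ids[keep],
           sign = as.integer(sign(r[keep])),
           r = r[keep], p = p[keep],
           stringsAsFactors = FALSE)),
    class = "represented_pc")
}

#' @export
print.represented_pc <- function(x, ...) {
  cat("Represented PC", x$component_index, "of cohort '", x$cohort_id,
      "': ", nrow(x$representative), " representative features\n", sep = "")
  invisible(x)
}

#' Serialize a cohort PCA as a directory of TSVs
#'
#' Writes \code{weights.tsv}, \code{scores.tsv} and \code{summary.tsv}
#' (n, p, k_selected, nu and the omega sequence) under \code{dir}.
#'
#' @param pca a \code{cohort_pca}.
#' @param dir output directory (created if missing).
#' @export
write_cohort_pca <- function(pca, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(feature_id = pca$feature_ids, pca$weights, check.names = FALSE),
    file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$scores, check.names = FALSE),
    file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(key = c("cohort_id", "n", "p", "k_selected", "nu",
                       paste0("omega_", seq_along(pca$omega))),
               value = c(pca$cohort_id, pca$n, pca$p, pca$k_selected, pca$nu,
                         pca$omega)),
    file.path(dir, "summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
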