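#' Fit consistent expression indices across analogous cohorts
#'
#' The central fitting function of the package. For each cohort it filters
#' features by anti-log coefficient of variation, performs PCA, selects the
#' number of components by BIC and distills each selected component to its
#' significantly correlated features. The distilled components of all
#' cohorts are pooled, compared with the Jaccard-cosine dissimilarity and
#' clustered by average linkage; clusters with at least two members are the
#' consistent principal components (CPCs), and genes representative in at
#' least two members of a cluster form the CPC gene set. CPC-gene z-scores
#' are merged across cohorts and a varimax factor analysis with thresholded
#' least-squares coefficients turns each factor into a sign-weighted
#' consistent expression index (CEI).
#'
#' @param cohorts list of \code{\link{expression_cohort}} (gene-level
#'   features; collapse probes first with \code{\link{collapse_probes}}).
#' @param cv_low,cv_high anti-log CV filter bounds (defaults 1 and 1000).
#' @param k_max largest number of components considered per cohort.
#' @param alpha significance threshold for PC distillation (default 0.01).
#' @param cut_height dendrogram cut for CPC clustering (default 0.9).
#' @param n_factors number of factors for CEI derivation; \code{NULL}
#'   (default) uses the number of CPC clusters found, mirroring the practice
#'   of setting the factor count to the number of consistent components.
#' @param threshold coefficient magnitude below which CEI weights are zeroed.
#' @param fa_method \code{"ml"} or \code{"principal"}
#'   (see \code{\link{derive_ceis}}).
#' @param dissimilarity \code{"product"} or \code{"mean"}
#'   (see \code{\link{pc_dissimilarity}}).
#' @return Object of class \code{cei_fit}: per-cohort PCA summaries
#'   (\code{pca}), distilled PCs (\code{pcs}), the CPC clustering
#'   (\code{clustering}), the pooled CPC gene set (\code{cpc_genes}), the
#'   merged z-score matrix (\code{merged}), and the CEI set (\code{ceis}).
#' @seealso \code{\link{predict.cei_fit}} to score new cohorts,
#'   \code{\link{evaluate_ceis}} for clinical association.
#' @export
cei_fit <- function(cohorts, cv_low = 1, cv_high = 1000, k_max = 20,
                    alpha = 0.01, cut_height = 0.9, n_factors = NULL,
                    threshold = 0.1, fa_method = c("ml", "principal"),
                    dissimilarity = c("product", "mean")) {
  fa_method <- match.arg(fa_method)
  dissimilarity <- match.arg(dissimilarity)
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  filtered <- list(); pcas <- list(); pcs <- list()
  for (co in cohorts) {
    f <- cv_filter(co, low = cv_low, high = cv_high)
    pca <- fit_pca(f)
    k <- select_k_bic(pca, k_max = min(k_max, length(pca$omega)))
    pca <- apply_k_selection(pca, k)
    for (j in seq_len(pca$k_selected)) {
      # a late, noise-dominated component can have no significant feature;
      # skip it rather than abort the whole derivation
      rp <- tryCatch(distill_pc(pca, f, j, alpha = alpha),
                     error = function(e) {
                       message("cohort ", co$cohort_id, ": skipping component ",
                               j, " (", conditionMessage(e), ")")
                       NULL
                     })
      if (!is.null(rp)) pcs[[length(pcs) + 1]] <- rp
    }
    filtered[[co$cohort_id]] <- f
    pcas[[co$cohort_id]] <- pca
  }
  clustering <- cluster_pcs(pcs, cut_height = cut_height,
                            method = dissimilarity)
  genes <- cpc_genes(clustering)
  if (is.null(n_factors)) n_factors <- length(clustering$clusters)
  merged <- merge_zscores(cohorts, genes)
  ceis <- derive_ceis(merged, n_factors = n_factors, threshold = threshold,
                      method = fa_method)
  structure(
    list(pca = pcas, pcs = pcs, clustering = clustering,
         cpc_genes = genes, merged = merged, ceis = ceis,
         call = match.call(),
         settings = list(cv_low = cv_low, cv_high = cv_high, k_max = k_max,
                         alpha = alpha, cut_height = cut_height,
                         n_factors = n_factors, threshold = threshold,
                         fa_method = fa_method,
                         dissimilarity = dissimilarity)),
    class = "cei_fit")
}

#' @export
print.cei_fit <- function(x, ...) {
  cat("Consistent expression index fit over", length(x$pca), "cohorts\n")
  ks <- vapply(x$pca, `[[`, integer(1), "k_selected")
  cat("  components selected per cohort:", paste(ks, collapse = ", "), "\n")
  cat("  CPC clusters:", length(x$clustering$clusters),
      "| CPC genes:", length(x$cpc_genes), "\n")
  cat("  CEIs:", length(x$ceis$ceis), "(",
      round(100 * x$ceis$total_variance_explained, 1),
      "% variance explained )\n")
  invisible(x)
}

#' @export
summary.cei_fit <- function(object, ...) {
  per_cohort <- data.frame(
    cohort = names(object$pca),
    n = vapply(object$pca, `[[`, integer(1), "n"),
    p_filtered = vapply(object$pca, `[[`, integer(1), "p"),
    k_selected = vapply(object$pca, `[[`, integer(1), "k_selected"),
    nu = vapply(object$pca, `[[`, numeric(1), "nu"),
    row.names = NULL)
  clusters <- data.frame(
    cluster_id = vapply(object$clustering$clusters, `[[`, integer(1), "cluster_id"),
    members = vapply(object$clustering$clusters, function(c) length(c$members), integer(1)),
    cohorts = vapply(object$clustering$clusters, `[[`, integer(1), "n_cohorts"),
    cpc_genes = vapply(object$clustering$clusters, function(c) length(c$cpc_genes), integer(1)))
  ceis <- data.frame(
    cei_id = vapply(object$ceis$ceis, `[[`, character(1), "cei_id"),
    n_genes = vapply(object$ceis$ceis, function(d) length(d$weights), integer(1)),
    variance_explained = object$ceis$variance_explained)
  out <- list(per_cohort = per_cohort, clusters = clusters, ceis = ceis,
              total_variance_explained = object$ceis$total_variance_explained)
  class(out) <- "summary.cei_fit"
  out
}

#' @export
print.summary.cei_fit <- function(x, ...) {
  cat("Per-cohort PCA:\n"); print(x$per_cohort, row.names = FALSE)
  cat("\nCPC clusters:\n"); print(x$clusters, row.names = FALSE)
  cat("\nConsistent expression indices:\n"); print(x$ceis, row.names = FALSE)
  cat("\nTotal variance explained by the factors: ",
      round(100 * x$total_variance_explained, 1), "%\n", sep = "")
  invisible(x)
}

#' Extract CEI gene weights
#' @param object a \code{cei_fit}.
#' @param ... unused.
#' @return Genes x CEIs integer matrix of weights in {-1, 0, +1}.
#' @export
coef.cei_fit <- function(object, ...) {
  defs <- object$ceis$ceis
  genes <- sort(unique(unlist(lapply(defs, function(d) names(d$weights)))))
  W <- matrix(0L, length(genes), length(defs),
              dimnames = list(genes, vapply(defs, `[[`, character(1), "cei_id")))
  for (d in defs) W[names(d$weights), d$cei_id] <- as.integer(d$weights)
  W
}

#' Score a new cohort on the fitted CEIs
#' @param object a \code{cei_fit}.
#' @param newdata an \code{\link{expression_cohort}} with gene-level features.
#' @param ... unused.
#' @return Score table as from \code{\link{score_cei}} (long format: one row
#'   per sample x CEI).
#' @export
predict.cei_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expression_cohort"))
  score_cei(newdata, object$ceis)
}

#' Plot the pooled-PC dendrogram of a fit
#' @param x a \code{cei_fit}.
#' @param ... passed to \code{plot.hclust}.
#' @export
plot.cei_fit <- function(x, ...) {
  plot(x$clustering$tree, xlab = "distilled principal components",
       ylab = "Jaccard-cosine dissimilarity (average linkage)",
       main = "Consistency of principal components across cohorts", ...)
  graphics::abline(h = x$settings$cut_height, lty = 2)
  invisible(x)
}
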