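#' Jaccard-cosine dissimilarity between two distilled principal components
#'
#' J is the Jaccard index of the two representative feature sets (size of
#' intersection over size of union); C is the cosine correlation between the
#' PC weight vectors restricted to the common representative features. The
#' dissimilarity is d = 1 - J*|C| (the product strategy): 0 iff the sets
#' coincide and the common weights are collinear, 1 for disjoint sets, and
#' invariant to the arbitrary sign of either component. If the intersection
#' is empty, C is undefined and d = 1.
#'
#' @param a,b \code{represented_pc} objects (see \code{\link{distill_pc}}).
#' @param method dissimilarity strategy: \code{"product"} (d = 1 - J*|C|,
#'   default) or \code{"mean"} (d = 1 - (J + |C|)/2).
#' @return The dissimilarity, with attributes \code{J} and \code{C}.
#' @export
pc_dissimilarity <- function(a, b, method = c("product", "mean")) {
  stopifnot(inherits(a, "represented_pc"), inherits(b, "represented_pc"))
  method <- match.arg(method)
  A <- a$representative$feature
  B <- b$representative$feature
  if (length(A) == 0 || length(B) == 0)
    stop("representative sets must be non-empty")
  common <- intersect(A, B)
  J <- length(common) / length(union(A, B))
  if (length(common) == 0)
    return(structure(1, J = 0, C = NA_real_))
  wa <- a$weight_vector[common]
  wb <- b$weight_vector[common]
  den <- sqrt(sum(wa^2)) * sqrt(sum(wb^2))
  C <- if (den == 0) 0 else sum(wa * wb) / den
  d <- switch(method,
              product = 1 - J * abs(C),
              mean = 1 - (J + abs(C)) / 2)
  structure(min(max(d, 0), 1), J = J, C = C)
}

#' Pairwise dissimilarity matrix over pooled distilled PCs
#'
#' @param pcs list of \code{represented_pc} objects (all cohorts pooled).
#' @param method passed to \code{\link{pc_dissimilarity}}.
#' @return List of class \code{pc_distance_matrix}: \code{d}, \code{J},
#'   \code{C} (symmetric matrices, labels \code{cohort:PCk}) and \code{pcs}.
#' @export
pc_distance_matrix <- function(pcs, method = c("product", "mean")) {
  method <- match.arg(method)
  m <- length(pcs)
  labels <- vapply(pcs, function(p)
    paste0(p$cohort_id, ":PC", p$component_index), character(1))
  if (anyDuplicated(labels))
    stop("duplicate cohort:component labels among the pooled PCs")
  d <- matrix(0, m, m, dimnames = list(labels, labels))
  J <- matrix(1, m, m, dimnames = list(labels, labels))
  C <- matrix(1, m, m, dimnames = list(labels, labels))
  if (m >= 2) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      dij <- pc_dissimilarity(pcs[[i]], pcs[[j]], method = method)
      d[i, j] <- d[j, i] <- as.numeric(dij)
      J[i, j] <- J[j, i] <- attr(dij, "J")
      C[i, j] <- C[j, i] <- attr(dij, "C")
    }
  }
  structure(list(d = d, J = J, C = C, pcs = pcs, method = method),
            class = "pc_distance_matrix")
}

#' Cluster pooled PCs and extract consistent principal components
#'
#' Average-linkage hierarchical clustering on the Jaccard-cosine
#' dissimilarity matrix; the tree is cut at \code{cut_height}. Clusters with
#' at least two member PCs are the consistent principal components (CPCs);
#' each cluster's gene set comprises the features representative in at least
#' two of its members. Singleton clusters are discarded. Whether a cluster's
#' members span at least two cohorts is recorded (but not enforced).
#'
#' @param pcs list of \code{represented_pc} (at least 2, from >= 2 cohorts).
#' @param cut_height tree cut height (default 0.9).
#' @param method dissimilarity strategy (see \code{\link{pc_dissimilarity}}).
#' @return Object of class \code{cpc_clustering}: \code{clusters} (list of
#'   \code{cpc_cluster}: cluster_id, members, member_labels, cpc_genes,
#'   n_cohorts), \code{tree} (hclust), \code{assignment}, and \code{dist}
#'   (the \code{pc_distance_matrix}).
#' @export
cluster_pcs <- function(pcs, cut_height = 0.9, method = c("product", "mean")) {
  method <- match.arg(method)
  if (length(pcs) < 2) stop("need at least 2 PCs to cluster")
  cohorts <- unique(vapply(pcs, `[[`, character(1), "cohort_id"))
  if (length(cohorts) < 2) stop("need PCs from at least 2 cohorts")
  dm <- pc_distance_matrix(pcs, method = method)
  tree <- stats::hclust(stats::as.dist(dm$d), method = "average")
  assignment <- stats::cutree(tree, h = cut_height)
  sizes <- table(assignment)
  multi <- as.integer(names(sizes)[sizes >= 2])
  if (length(multi) == 0)
    stop("no cluster with >= 2 members at cut height ", cut_height,
         "; consider a higher cut_height")
  # canonical order: by first (smallest) member label alphabetically
  first_label <- vapply(multi, function(cl)
    min(names(assignment)[assignment == cl]), character(1))
  multi <- multi[order(first_label)]
  clusters <- lapply(seq_along(multi), function(i) {
    cl <- multi[i]
    idx <- which(assignment == cl)
    members <- dm$pcs[idx]
    feats <- unlist(lapply(members, function(p) unique(p$representative$feature)))
    counts <- table(feats)
    genes <- sort(names(counts)[counts >= 2])
    structure(
      list(cluster_id = i,
           members = members,
           member_labels = sort(names(assignment)[idx]),
           cpc_genes = genes,
           n_cohorts = length(unique(vapply(members, `[[`, character(1),
                                            "cohort_id")))),
      class = "cpc_cluster")
  })
  structure(list(clusters = clusters, tree = tree, assignment = assignment,
                 dist = dm, cut_height = cut_height),
            class = "cpc_clustering")
}

#' @export
print.cpc_clustering <- function(x, ...) {
  cat("CPC clustering of", length(x$assignment), "PCs at cut height",
      x$cut_height, "\n")
  for (cl in x$clusters)
    cat("  cluster ", cl$cluster_id, ": ", length(cl$members), " members (",
        cl$n_cohorts, " cohorts), ", length(cl$cpc_genes), " CPC genes\n",
        sep = "")
  invisible(x)
}

#' CPC genes pooled over all clusters
#' @param clustering a \code{cpc_clustering}.
#' @return Sorted character vector of the union of per-cluster CPC genes.
#' @export
cpc_genes <- function(clustering) {
  stopifnot(inherits(clustering, "cpc_clustering"))
  sort(unique(unlist(lapply(clustering$clusters, `[[`, "cpc_genes"))))
}

#' Cross-cohort consistency diagnostic on a fixed gene set
#'
#' PCA is performed separately on each cohort restricted to \code{gene_set}
#' (the intersection with each cohort's features; coverage is checked), and
#' the first two PCs of every cohort are pooled and clustered with the
#' Jaccard-cosine dissimilarity. Consistent cohorts place all their PC1s in
#' one cluster and PC2s in another.
#'
#' @param cohorts list of \code{\link{expression_cohort}} (at least 2).
#' @param gene_set character vector of gene/feature ids (at least 10 after
#'   intersection; coverage below 50% in any cohort raises a warning).
#' @param cut_height tree cut (default 0.5, a diagnostic-tight cut).
#' @param alpha distillation significance threshold.
#' @return A \code{cpc_clustering} over the pooled first-two PCs.
#' @export
compare_pcs_across_cohorts <- function(cohorts, gene_set, cut_height = 0.5,
                                       alpha = 0.01) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  pcs <- list()
  for (co in cohorts) {
    present <- intersect(gene_set, co$features)
    coverage <- length(present) / length(gene_set)
    if (length(present) < 10)
      stop("fewer than 10 genes of the set present in cohort '",
           co$cohort_id, "'")
    if (coverage < 0.5)
      warning("gene set coverage ", round(100 * coverage), "% in cohort '",
              co$cohort_id, "'")
    sub <- expression_cohort(co$values[present, , drop = FALSE], co$cohort_id)
    pca <- fit_pca(sub)
    for (j in 1:2)
      pcs[[length(pcs) + 1]] <- distill_pc(pca, sub, j, alpha = alpha)
  }
  cluster_pcs(pcs, cut_height = cut_height)
}

#' Export the PC dendrogram in newick format
#' @param clustering a \code{cpc_clustering}.
#' @param path output file.
#' @export
write_pc_dendrogram <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("newick export requires the 'ape' package")
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Write CPC clusters and the dissimilarity matrix as TSVs
#' @param clustering a \code{cpc_clustering}.
#' @param dir output directory.
#' @export
write_cpc_report <- function(clustering, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(clustering$clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id,
               member = cl$member_labels,
               n_genes = length(cl$cpc_genes),
               genes = paste(cl$cpc_genes, collapse = ","),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, file.path(dir, "cpc_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  d <- clustering$dist$d
  utils::write.table(data.frame(pc = rownames(d), d, check.names = FALSE),
                     file.path(dir, "pc_dissimilarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
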