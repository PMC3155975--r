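#' Merge per-cohort gene z-scores into one matrix
#'
#' For each cohort the requested genes are z-scored per gene across that
#' cohort's samples (mean 0, sd 1 within each cohort block) and the blocks
#' are concatenated column-wise. Genes absent from any cohort are dropped
#' (logged); genes with zero variance in some cohort are dropped with a
#' warning. Per-cohort z-scoring removes cohort-level location/scale batch
#' effects by construction.
#'
#' @param cohorts list of \code{\link{expression_cohort}}.
#' @param genes character vector of gene ids to merge.
#' @return Numeric matrix genes x (all samples), column names
#'   \code{cohort_id.sample_id}, with attribute \code{blocks} (cohort id per
#'   column).
#' @export
merge_zscores <- function(cohorts, genes) {
  stopifnot(length(cohorts) >= 1, length(genes) >= 1)
  common <- Reduce(intersect, lapply(cohorts, `[[`, "features"), genes)
  dropped <- setdiff(genes, common)
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " gene(s) absent from some cohort")
  if (length(common) == 0) stop("no gene present in every cohort")
  zero_var <- unique(unlist(lapply(cohorts, function(co) {
    m <- co$values[common, , drop = FALSE]
    common[apply(m, 1, stats::sd) == 0]
  })))
  if (length(zero_var) > 0) {
    warning("dropping gene(s) with zero variance in some cohort: ",
            paste(utils::head(zero_var, 5), collapse = ", "))
    common <- setdiff(common, zero_var)
    if (length(common) == 0) stop("all genes degenerate")
  }
  blocks <- lapply(cohorts, function(co) {
    m <- co$values[common, , drop = FALSE]
    z <- t(scale(t(m)))
    colnames(z) <- paste(co$cohort_id, colnames(m), sep = ".")
    z
  })
  out <- do.call(cbind, blocks)
  attr(out, "blocks") <- rep(vapply(cohorts, `[[`, character(1), "cohort_id"),
                             vapply(blocks, ncol, integer(1)))
  out
}

#' Derive consistent expression indices by varimax factor analysis
#'
#' A factor model with \code{n_factors} factors is fit to the merged z-score
#' matrix (genes as variables, samples as observations), rotated by varimax.
#' Per-factor gene coefficients are estimated by least squares (regression of
#' each gene's z-scores on the factor scores); coefficients with absolute
#' value below \code{threshold} are set to zero and the signs of the
#' surviving coefficients become the gene weights of the corresponding CEI.
#' Factors are ordered by post-rotation variance explained, giving stable
#' CEI1..CEIn identities; each factor's sign is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param merged genes x samples matrix from \code{\link{merge_zscores}}.
#' @param n_factors number of factors (default 6).
#' @param threshold coefficient magnitude below which weights are zeroed
#'   (default 0.1).
#' @param method factor extraction: \code{"ml"} (maximum likelihood via
#'   \code{\link[stats]{factanal}}, default) or \code{"principal"}
#'   (iterated principal-axis factoring).
#' @param coef_type \code{"regression"} (least-squares regression of genes on
#'   factor scores, default) or \code{"loadings"} (rotated loadings).
#' @return Object of class \code{cei_set}: list of \code{cei_definition}
#'   (\code{cei_id}, \code{weights} named +/-1 vector, \code{source} with
#'   factor index and variance-explained share), plus \code{n_factors},
#'   \code{threshold}, \code{variance_explained} (per factor) and
#'   \code{total_variance_explained}.
#' @export
derive_ceis <- function(merged, n_factors = 6, threshold = 0.1,
                        method = c("ml", "principal"),
                        coef_type = c("regression", "loadings")) {
  method <- match.arg(method)
  coef_type <- match.arg(coef_type)
  p <- nrow(merged); n <- ncol(merged)
  if (n_factors >= min(p, n))
    stop("n_factors must be smaller than min(genes, samples)")
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be a finite non-negative number",
         if (is.infinite(threshold)) " (infinite threshold zeroes every weight)")
  X <- t(merged)  # samples x genes
  if (method == "ml" && n <= p) {
    message("maximum-likelihood extraction needs more samples than genes ",
            "(", n, " samples, ", p, " genes); using principal-axis factoring")
    method <- "principal"
  }
  if (method == "ml") {
    # default starting uniquenesses need an invertible sample correlation
    # (squared multiple correlations); with more genes than samples fall
    # back to a flat deterministic start
    fit <- tryCatch(
      stats::factanal(X, factors = n_factors, rotation = "varimax",
                      scores = "none"),
      error = function(e)
        tryCatch(
          stats::factanal(X, factors = n_factors, rotation = "varimax",
                          scores = "none", start = rep(0.5, ncol(X))),
          error = function(e2) stop("factor extraction failed to converge: ",
                                    conditionMessage(e2), call. = FALSE)))
    L <- unclass(fit$loadings)         # genes x factors, varimax-rotated
    psi <- fit$uniquenesses
  } else {
    fit <- fa_principal(stats::cor(X), n_factors)
    L <- fit$loadings
    psi <- pmax(1 - fit$communality, 1e-6)
  }
  # Thomson regression factor scores through the model-implied correlation
  # (Woodbury), well defined even when genes outnumber samples
  Z <- scale(X)
  LP <- L / psi
  S <- Z %*% LP %*% solve(diag(n_factors) + crossprod(L, LP))
  B <- if (coef_type == "regression") {
    # least squares of each gene on the factor scores
    Zg <- t(merged)  # samples x genes, already z per cohort block
    t(solve(crossprod(S), crossprod(S, Zg)))  # genes x factors
  } else L
  rownames(B) <- rownames(merged)
  # order by variance explained after rotation; fix factor signs
  ve <- colSums(L^2) / p
  ord <- order(ve, decreasing = TRUE)
  B <- B[, ord, drop = FALSE]; ve <- ve[ord]
  for (j in seq_len(ncol(B))) {
    i <- which.max(abs(B[, j]))
    if (B[i, j] < 0) B[, j] <- -B[, j]
  }
  B[abs(B) < threshold] <- 0
  ceis <- lapply(seq_len(ncol(B)), function(j) {
    w <- sign(B[, j])
    w <- w[w != 0]
    if (length(w) == 0)
      stop("factor ", j, " has no coefficient above the threshold ",
           threshold, "; every CEI needs at least one nonzero weight")
    structure(list(cei_id = paste0("CEI", j),
                   weights = w,
                   source = list(factor_index = j,
                                 variance_explained = unname(ve[j]))),
              class = "cei_definition")
  })
  structure(list(ceis = ceis, n_factors = n_factors, threshold = threshold,
                 method = method, coef_type = coef_type,
                 coefficients = B,
                 variance_explained = unname(ve),
                 total_variance_explained = sum(ve)),
            class = "cei_set")
}

#' @export
print.cei_set <- function(x, ...) {
  cat("Set of", length(x$ceis), "consistent expression indices (",
      x$method, "factor analysis, varimax )\n")
  for (cei in x$ceis)
    cat("  ", cei$cei_id, ": ", sum(cei$weights > 0), " positive / ",
        sum(cei$weights < 0), " negative gene weights (",
        round(100 * cei$source$variance_explained, 1), "% variance)\n",
        sep = "")
  cat("Total variance explained:",
      round(100 * x$total_variance_explained, 1), "%\n")
  invisible(x)
}

# Iterated principal-axis factoring on a correlation matrix. Communalities
# start at the squared multiple correlations and are updated until stable;
# loadings are varimax-rotated.
fa_principal <- function(R, nf, max_iter = 200, tol = 1e-6) {
  p <- nrow(R)
  h2 <- tryCatch(1 - 1 / diag(solve(R)),
                 error = function(e) {
                   # singular correlation (p > n): start from the largest
                   # absolute off-diagonal correlation per variable
                   apply(abs(R - diag(p)), 1, max)
                 })
  for (it in seq_len(max_iter)) {
    Rh <- R; diag(Rh) <- h2
    eig <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(eig$values[seq_len(nf)], 0)
    L <- eig$vectors[, seq_len(nf), drop = FALSE] %*% diag(sqrt(ev), nf)
    h2_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  if (nf > 1) {
    rot <- stats::varimax(L)
    L <- unclass(rot$loadings)
  }
  rownames(L) <- rownames(R)
  list(loadings = L, communality = h2, iterations = it)
}

#' Score a cohort on a consistent expression index
#'
#' The CEI's genes are z-scored within the target cohort and the score of
#' each sample is the sum of the sign-weighted z-scores over the genes
#' present. Missing genes are excluded, not imputed; the fraction of the
#' CEI's genes present (coverage) is reported, with a warning below 50%.
#'
#' @param cohort an \code{\link{expression_cohort}} (gene-level features).
#' @param cei a \code{cei_definition} (or a \code{cei_set}, scoring all).
#' @return Data frame with columns \code{sample_id}, \code{cei_id},
#'   \code{score}, \code{coverage}.
#' @export
score_cei <- function(cohort, cei) {
  stopifnot(inherits(cohort, "expression_cohort"))
  if (inherits(cei, "cei_set"))
    return(do.call(rbind, lapply(cei$ceis, function(d) score_cei(cohort, d))))
  stopifnot(inherits(cei, "cei_definition"))
  genes <- names(cei$weights)
  present <- intersect(genes, cohort$features)
  coverage <- length(present) / length(genes)
  if (coverage == 0)
    stop("none of the genes of ", cei$cei_id, " are present in cohort '",
         cohort$cohort_id, "'")
  if (coverage < 0.5)
    warning(cei$cei_id, " coverage ", round(100 * coverage), "% in cohort '",
            cohort$cohort_id, "'")
  m <- cohort$values[present, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    present <- present[sds > 0]
    m <- m[present, , drop = FALSE]
    if (length(present) == 0) stop("all CEI genes degenerate in the cohort")
  }
  z <- t(scale(t(m)))
  scores <- as.vector(crossprod(z, cei$weights[present]))
  data.frame(sample_id = cohort$samples, cei_id = cei$cei_id,
             score = scores, coverage = coverage,
             stringsAsFactors = FALSE)
}

#' Write CEI definitions as the interchange TSV
#'
#' Format: header \code{cei_id<TAB>gene<TAB>weight}, weights -1/1, one row
#' per nonzero gene weight, genes in alphabetical order within each CEI.
#'
#' @param ceis a \code{cei_set} or list of \code{cei_definition}.
#' @param path output path.
#' @export
write_cei_definitions <- function(ceis, path) {
  defs <- if (inherits(ceis, "cei_set")) ceis$ceis else ceis
  rows <- do.call(rbind, lapply(defs, function(d) {
    g <- sort(names(d$weights))
    data.frame(cei_id = d$cei_id, gene = g,
               weight = as.integer(d$weights[g]), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CEI definitions from the interchange TSV
#' @param path path to a file written by \code{\link{write_cei_definitions}}.
#' @return List of \code{cei_definition}.
#' @export
read_cei_definitions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("cei_id", "gene", "weight") %in% names(tab)))
  if (!all(tab$weight %in% c(-1L, 1L))) stop("CEI weights must be -1 or 1")
  lapply(split(tab, tab$cei_id)[unique(tab$cei_id)], function(d) {
    if (anyDuplicated(d$gene)) stop("duplicate gene in ", d$cei_id[1])
    w <- d$weight; names(w) <- d$gene
    structure(list(cei_id = d$cei_id[1], weights = w,
                   source = list(factor_index = NA_integer_,
                                 variance_explained = NA_real_)),
              class = "cei_definition")
  })
}
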