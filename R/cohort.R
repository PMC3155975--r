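#' Construct an expression cohort
#'
#' An expression cohort holds one study's expression matrix on a log2-like
#' scale (as produced by RMA and similar normalizations), with features
#' (probe sets or gene symbols) in rows and samples in columns. Rows
#' containing any missing value are dropped with a message; feature and
#' sample identifiers must be unique and at least 3 samples are required.
#'
#' @param values numeric matrix, features x samples, with rownames (feature
#'   ids) and colnames (sample ids).
#' @param cohort_id character scalar identifying the cohort.
#' @return An object of class \code{expression_cohort}: a list with elements
#'   \code{cohort_id}, \code{features}, \code{samples} and \code{values}.
#' @export
expression_cohort <- function(values, cohort_id) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- rowSums(!is.finite(values)) > 0
  if (any(bad)) {
    message("dropping ", sum(bad), " feature row(s) with missing values")
    values <- values[!bad, , drop = FALSE]
  }
  if (ncol(values) < 3) stop("cohort must have at least 3 samples")
  if (nrow(values) == 0) stop("no complete feature rows")
  structure(
    list(cohort_id = as.character(cohort_id),
         features = rownames(values),
         samples = colnames(values),
         values = values),
    class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("Expression cohort '", x$cohort_id, "': ", nrow(x$values),
      " features x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$values)

#' Read an expression cohort from tab-delimited text
#'
#' Expects UTF-8 tab-delimited text: first row \code{feature_id<TAB>sample1...},
#' subsequent rows a feature id followed by numeric values. Files ending in
#' \code{.gz} are decompressed transparently. Malformed numeric cells are
#' reported with their row and column.
#'
#' @param path path to the file (optionally gzipped).
#' @param cohort_id cohort identifier; defaults to the file name sans extension.
#' @return An \code{\link{expression_cohort}}.
#' @export
read_cohort <- function(path, cohort_id = NULL) {
  if (is.null(cohort_id))
    cohort_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  raw <- utils::read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("expected at least one sample column in ", path)
  feats <- raw[[1]]
  if (anyDuplicated(feats))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("malformed numeric cell at feature '", feats[bad[1, 1]],
         "', sample '", colnames(body)[bad[1, 2]], "': '",
         body[bad[1, 1], bad[1, 2]], "'")
  dimnames(num) <- list(feats, colnames(body))
  expression_cohort(num, cohort_id)
}

#' Write an expression cohort as tab-delimited text
#'
#' Values are written with 17 significant digits (full double precision), so
#' \code{read_cohort(write_cohort(x))} reproduces the values exactly and a
#' rewrite of the re-read cohort is byte-identical.
#'
#' @param cohort an \code{\link{expression_cohort}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "expression_cohort"))
  m <- cohort$values
  chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  tab <- cbind(feature_id = rownames(chr), as.data.frame(chr, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical outcome table
#'
#' CSV or TSV (sniffed from the header line) with columns
#' \code{sample_id,response,time,event,treatment}; \code{response} is binary
#' (1 = pathologic complete response, 0 = residual disease), \code{time} a
#' non-negative follow-up duration in years, \code{event} a binary event flag.
#' Every row must carry a response or a complete (time, event) pair; time and
#' event must be present together.
#'
#' @param path path to the table.
#' @return A data frame with the columns above (missing optional columns
#'   filled with NA).
#' @export
read_clinical <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  if (!"sample_id" %in% names(tab)) stop("clinical table needs a sample_id column")
  for (col in c("response", "time", "event", "treatment"))
    if (!col %in% names(tab)) tab[[col]] <- NA
  tab <- tab[, c("sample_id", "response", "time", "event", "treatment")]
  tab$sample_id <- as.character(tab$sample_id)
  validate_clinical(tab)
  tab
}

validate_clinical <- function(tab) {
  has_resp <- !is.na(tab$response)
  has_time <- !is.na(tab$time)
  has_event <- !is.na(tab$event)
  if (any(has_time != has_event))
    stop("time and event must be present together (rows: ",
         paste(utils::head(which(has_time != has_event), 5), collapse = ", "), ")")
  if (any(!has_resp & !has_time))
    stop("every clinical row needs response or (time, event); offending rows: ",
         paste(utils::head(which(!has_resp & !has_time), 5), collapse = ", "))
  if (any(has_resp & !tab$response %in% c(0, 1)))
    stop("response must be 0/1")
  if (any(has_time & tab$time < 0)) stop("negative follow-up time")
  if (any(has_event & !tab$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(tab)
}

#' Write a clinical table (TSV)
#' @param tab clinical data frame as returned by \code{\link{read_clinical}}.
#' @param path output path.
#' @export
write_clinical <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV \code{probe_id<TAB>gene_symbol}. A probe may map to at most
#' one gene; a gene may own many probes.
#'
#' @param path path to the map file.
#' @return Data frame with columns \code{probe_id}, \code{gene_symbol}.
#' @export
read_probe_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("probe_id", "gene_symbol")
  probe_map(tab)
}

#' @rdname read_probe_map
#' @param tab data frame with probe_id and gene_symbol columns.
#' @export
probe_map <- function(tab) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(tab)))
  tab <- tab[, c("probe_id", "gene_symbol")]
  if (anyDuplicated(tab$probe_id))
    stop("probe(s) mapping to more than one gene: ",
         paste(unique(tab$probe_id[duplicated(tab$probe_id)]), collapse = ", "))
  tab
}

#' Collapse probe rows to one row per gene
#'
#' For a gene represented by several probe sets, the probe with the largest
#' sample standard deviation of its expression values is retained to
#' represent the gene; values are copied, never averaged. Ties in standard
#' deviation are broken by file (row) order, which makes the collapse
#' deterministic. Probes absent from the map are dropped.
#'
#' @param cohort an \code{\link{expression_cohort}} with probe-level features.
#' @param map a probe map (see \code{\link{read_probe_map}}).
#' @return An \code{\link{expression_cohort}} whose features are gene symbols.
#' @export
collapse_probes <- function(cohort, map) {
  stopifnot(inherits(cohort, "expression_cohort"))
  map <- probe_map(map)
  keep <- map[map$probe_id %in% cohort$features, , drop = FALSE]
  if (nrow(keep) == 0) stop("no probe of the cohort appears in the map")
  vals <- cohort$values[keep$probe_id, , drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  ord <- order(match(keep$probe_id, cohort$features))  # file order
  keep <- keep[ord, ]; sds <- sds[ord]
  # first occurrence wins on ties: stable within gene by file order
  pick <- vapply(split(seq_len(nrow(keep)), keep$gene_symbol)[unique(keep$gene_symbol)],
                 function(idx) idx[which.max(sds[idx])], integer(1))
  out <- cohort$values[keep$probe_id[pick], , drop = FALSE]
  rownames(out) <- keep$gene_symbol[pick]
  expression_cohort(out, cohort$cohort_id)
}

#' Assign receptor subtype by PAM clustering on two marker genes
#'
#' Samples are partitioned by k-medoids (PAM) on the 2-dimensional profile of
#' two marker features (defaults ESR1 and ERBB2 after probe collapse). The
#' double-negative cluster is the one whose medoid has the smallest sum of
#' the two marker values; all other clusters are labelled \code{other_1},
#' \code{other_2}, ... in order of increasing medoid sum.
#'
#' @param cohort an \code{\link{expression_cohort}}.
#' @param marker_features two feature ids (default \code{c("ESR1", "ERBB2")}).
#' @param n_clusters number of PAM clusters (default 4: double-negative,
#'   ER+, HER2+ and double-positive geometry).
#' @return Named character vector of labels per sample, with attribute
#'   \code{medoids} (the marker values at each cluster medoid).
#' @export
assign_subtype <- function(cohort, marker_features = c("ESR1", "ERBB2"),
                           n_clusters = 4) {
  stopifnot(inherits(cohort, "expression_cohort"), length(marker_features) == 2)
  missing <- setdiff(marker_features, cohort$features)
  if (length(missing) > 0) {
    near <- lapply(missing, function(m)
      utils::head(cohort$features[grepl(substr(m, 1, 4), cohort$features,
                                        ignore.case = TRUE)], 5))
    stop("marker feature(s) not found: ", paste(missing, collapse = ", "),
         "; near matches: ", paste(unlist(near), collapse = ", "))
  }
  n <- length(cohort$samples)
  if (n_clusters < 2 || n_clusters > n - 1)
    stop("n_clusters must be in [2, n-1]")
  prof <- t(cohort$values[marker_features, , drop = FALSE])
  if (all(apply(prof, 2, stats::sd) == 0))
    stop("degenerate marker distribution: all samples identical on both markers")
  fit <- cluster::pam(prof, k = n_clusters, metric = "euclidean",
                      cluster.only = FALSE)
  med_sum <- rowSums(fit$medoids)
  rank_by_sum <- order(med_sum)
  labels <- character(n_clusters)
  labels[rank_by_sum[1]] <- "double_negative"
  labels[rank_by_sum[-1]] <- paste0("other_", seq_len(n_clusters - 1))
  out <- labels[fit$clustering]
  names(out) <- cohort$samples
  attr(out, "medoids") <- fit$medoids
  out
}
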