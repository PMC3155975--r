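#' ROC curve and trapezoidal AUC with Wilcoxon rank-sum significance
#'
#' The empirical ROC is traversed over the distinct score thresholds (ties
#' cross simultaneously) and the AUC is computed by the trapezoidal rule;
#' this equals the Mann-Whitney U statistic (with 1/2 credit per tied pair)
#' divided by n_pos*n_neg. Significance is a two-sided Wilcoxon rank-sum
#' test with normal approximation and tie correction.
#'
#' @param scores numeric vector, no missing values.
#' @param labels binary vector (0/1 or logical), both classes present.
#' @return Object of class \code{roc_result}: \code{auc}, \code{direction}
#'   (\code{"positive"} if high scores favor the positive class),
#'   \code{p_value}, \code{n_pos}, \code{n_neg}, and \code{curve}
#'   (data frame of ordered FPR/TPR points, (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present (n_pos = ", n_pos,
         ", n_neg = ", n_neg, ")")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # ties cross the threshold simultaneously
  last_of_tie <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_tie]
  fp <- cumsum(1 - y)[last_of_tie]
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  # trapezoid on the integer TP/FP lattice: sums of integers and halves are
  # exact in double precision, so one final division keeps the AUC
  # bit-identical to the tie-aware concordant-pair count
  tp0 <- c(0, tp); fp0 <- c(0, fp)
  auc <- sum(diff(fp0) * (tp0[-1] + tp0[-length(tp0)]) / 2) / (n_pos * n_neg)
  # Wilcoxon rank-sum, normal approximation with tie correction
  N <- n_pos + n_neg
  rk <- rank(scores)
  U <- sum(rk[labels == 1]) - n_pos * (n_pos + 1) / 2
  ties <- table(scores)
  tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n_pos * n_neg / 12 * ((N + 1) - tie_corr)
  p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs(U - n_pos * n_neg / 2) /
                                                sqrt(sigma2))
  structure(
    list(auc = auc,
         direction = if (auc >= 0.5) "positive" else "negative",
         p_value = min(p, 1),
         n_pos = n_pos, n_neg = n_neg,
         curve = data.frame(fpr = fpr, tpr = tpr)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC = ", round(x$auc, 3), " (favors ", x$direction,
      " class), Wilcoxon P = ", signif(x$p_value, 3),
      " [n+ = ", x$n_pos, ", n- = ", x$n_neg, "]\n", sep = "")
  invisible(x)
}

#' Median-split survival analysis: Kaplan-Meier, Cox and log-rank
#'
#' Follow-up is administratively censored at \code{horizon} years. Samples
#' are stratified into two groups of (as nearly as possible) equal size at
#' the median score: samples with score <= median form the low group, so
#' with odd n the median-valued sample falls low. The hazard ratio
#' (high vs low) comes from a Cox proportional-hazards fit on the group
#' indicator (Efron tie handling); significance is the log-rank test.
#'
#' @param scores numeric vector (the CEI score per sample).
#' @param time follow-up in years.
#' @param event binary event indicator.
#' @param horizon follow-up horizon in years (default 10; 5 and 10 are the
#'   conventional choices).
#' @return Object of class \code{survival_result}: \code{hazard_ratio},
#'   \code{p_value} (log-rank), \code{cox_p}, \code{horizon}, \code{groups}
#'   (per-group n and events), \code{km} (per-group Kaplan-Meier step
#'   functions as a data frame), and \code{fit} (the coxph object).
#' @export
km_cox_median_split <- function(scores, time, event, horizon = 10) {
  if (anyNA(scores) || anyNA(time) || anyNA(event))
    stop("missing scores, times or events")
  stopifnot(length(scores) == length(time), length(time) == length(event),
            horizon > 0)
  over <- time > horizon
  event[over] <- 0
  time[over] <- horizon
  med <- stats::median(scores)
  group <- factor(ifelse(scores > med, "high", "low"),
                  levels = c("low", "high"))
  ev_by <- tapply(event, group, sum)
  if (any(is.na(ev_by)) || any(ev_by == 0)) {
    bad <- names(ev_by)[is.na(ev_by) | ev_by == 0]
    stop("no events in group ", paste(bad, collapse = ", "),
         " within the ", horizon, "-year horizon")
  }
  surv <- survival::Surv(time, event)
  cox <- survival::coxph(surv ~ group, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9))
  lr <- survival::survdiff(surv ~ group)
  p_logrank <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  km <- survival::survfit(surv ~ group)
  strata <- rep(names(km$strata), km$strata)
  structure(
    list(hazard_ratio = unname(exp(stats::coef(cox)[1])),
         p_value = p_logrank,
         cox_p = summary(cox)$coefficients[1, "Pr(>|z|)"],
         horizon = horizon,
         groups = data.frame(group = levels(group),
                             n = as.vector(table(group)),
                             events = as.vector(ev_by)),
         km = data.frame(group = sub("^group=", "", strata),
                         time = km$time, surv = km$surv,
                         n_risk = km$n.risk, n_event = km$n.event),
         fit = cox),
    class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Median-split survival (", x$horizon, "-year horizon): HR = ",
      round(x$hazard_ratio, 2), " (high vs low), log-rank P = ",
      signif(x$p_value, 3), "\n", sep = "")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Evaluate all CEIs against clinical outcome
#'
#' Joins a CEI score table with a clinical table on \code{sample_id} (inner
#' join; dropped ids are logged) and computes, per CEI, either a
#' \code{\link{roc_auc}} against binary treatment response or a
#' \code{\link{km_cox_median_split}} against survival. Raw P values are
#' reported as-is, with an optional Benjamini-Hochberg adjusted column.
#'
#' @param score_table data frame from \code{\link{score_cei}}.
#' @param clinical clinical data frame (see \code{\link{read_clinical}}).
#' @param mode \code{"response"} or \code{"survival"}.
#' @param horizon follow-up horizon in years (survival mode).
#' @param adjust add a BH-adjusted P column (default TRUE).
#' @return Data frame: one row per CEI with \code{cei_id}, \code{mode},
#'   \code{n}, \code{n_events} (responders or events), \code{statistic}
#'   (AUC or HR), \code{p_value}, \code{direction}, and the per-CEI result
#'   objects in attribute \code{results}.
#' @export
evaluate_ceis <- function(score_table, clinical, mode = c("response", "survival"),
                          horizon = 10, adjust = TRUE) {
  mode <- match.arg(mode)
  validate_clinical(clinical)
  cei_ids <- unique(score_table$cei_id)
  results <- list()
  rows <- lapply(cei_ids, function(id) {
    st <- score_table[score_table$cei_id == id, ]
    j <- merge(st, clinical, by = "sample_id")
    dropped <- nrow(st) - nrow(j)
    if (dropped > 0)
      message(id, ": ", dropped, " scored sample(s) without clinical record")
    if (nrow(j) == 0) stop("no overlap between scored and clinical samples")
    if (mode == "response") {
      j <- j[!is.na(j$response), ]
      if (nrow(j) == 0) stop("no response data for mode = 'response'")
      r <- roc_auc(j$score, j$response)
      results[[id]] <<- r
      data.frame(cei_id = id, mode = mode, n = nrow(j),
                 n_events = r$n_pos, statistic = r$auc,
                 p_value = r$p_value, direction = r$direction,
                 stringsAsFactors = FALSE)
    } else {
      j <- j[!is.na(j$time) & !is.na(j$event), ]
      if (nrow(j) == 0) stop("no survival data for mode = 'survival'")
      r <- km_cox_median_split(j$score, j$time, j$event, horizon = horizon)
      results[[id]] <<- r
      data.frame(cei_id = id, mode = mode, n = nrow(j),
                 n_events = sum(r$groups$events), statistic = r$hazard_ratio,
                 p_value = r$p_value,
                 direction = if (r$hazard_ratio >= 1) "high_risk" else "low_risk",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "results") <- results
  out
}
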