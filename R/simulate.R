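#' Configuration for the synthetic cohort-family generator
#'
#' Defaults emulate the regime of multi-cohort microarray studies of a
#' breast-cancer subtype: 5 reference cohorts of 40-80 samples each, ~1000
#' genes of which a minority carry latent-factor structure, shared factors
#' with identical gene loadings across cohorts plus one cohort-private
#' factor each, and clinical outcomes linked to the shared factors.
#'
#' Shared factors are given distinct gene-block sizes (120/60/30) and the
#' private factor a smaller block with weaker loading, so the planted
#' sample eigenvalues are well separated and per-cohort PCA aligns each
#' component with one factor; near-equal factor strengths would leave the
#' leading components an arbitrary rotation of the factor space and the
#' cross-cohort consistency question ill-posed.
#'
#' Loadings (\code{loading}) and noise (\code{noise_sd}) are expressed on
#' the z-score scale; \code{signal_scale} (log2 units) maps the structure
#' onto realistic log2 dynamic range so that a signal gene's anti-log
#' coefficient of variation exceeds 1 (retained by the default CV filter)
#' while flat genes fall below it.
#'
#' @param n_cohorts number of cohorts (>= 2).
#' @param n_genes genes per cohort.
#' @param n_samples samples per cohort (scalar or vector of length n_cohorts).
#' @param shared_block_sizes gene-block size per shared factor.
#' @param private_block_size gene-block size of each cohort-private factor.
#' @param private_loading loading magnitude of the private factors (weaker
#'   than the shared loading so private structure stays subordinate).
#' @param loading loading magnitude on block genes.
#' @param noise_sd residual noise standard deviation.
#' @param signal_scale log2 dynamic-range multiplier for block genes.
#' @param baseline_mean,baseline_sd per-gene baseline log2 level.
#' @param batch_sd sd of per-cohort, per-gene offsets (batch effects).
#' @param response_beta logistic coefficients linking shared-factor activity
#'   to binary treatment response (length = number of shared factors).
#' @param response_intercept logistic intercept.
#' @param hazard_gamma log-hazard coefficients per shared factor.
#' @param baseline_hazard events per year at zero activity.
#' @param censor_max censoring times are uniform on (0, censor_max) years;
#'   the default gives roughly 30% censoring at the default hazard,
#'   resembling 10-year follow-up.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_cohorts = 5, n_genes = 1000, n_samples = 60,
                       shared_block_sizes = c(120, 60, 30),
                       private_block_size = 20, private_loading = 0.6,
                       loading = 0.8, noise_sd = 0.6, signal_scale = 2,
                       baseline_mean = 8, baseline_sd = 1, batch_sd = 0.3,
                       response_beta = c(1.5, 0, 0), response_intercept = 0,
                       hazard_gamma = c(0.5, 0, 0), baseline_hazard = 0.12,
                       censor_max = 25) {
  cfg <- as.list(environment())
  if (cfg$n_cohorts < 2) stop("need at least 2 cohorts")
  if (length(cfg$n_samples) == 1)
    cfg$n_samples <- rep(cfg$n_samples, cfg$n_cohorts)
  stopifnot(length(cfg$n_samples) == cfg$n_cohorts,
            length(cfg$response_beta) == length(cfg$shared_block_sizes),
            length(cfg$hazard_gamma) == length(cfg$shared_block_sizes))
  k_tot <- length(cfg$shared_block_sizes) + 1
  if (any(k_tot >= pmin(cfg$n_genes, cfg$n_samples)))
    stop("infeasible config: factors must be fewer than min(genes, samples)")
  need <- sum(cfg$shared_block_sizes) + cfg$n_cohorts * cfg$private_block_size
  if (need > cfg$n_genes)
    stop("infeasible config: gene blocks exceed n_genes")
  structure(cfg, class = "sim_config")
}

#' Simulate a family of analogous expression cohorts with outcomes
#'
#' Each cohort's log2 expression is baseline + batch offset +
#' signal_scale * (loadings %*% activity + noise). Shared factors have
#' identical loadings in every cohort (drawn once); each cohort additionally
#' carries one private factor on its own disjoint gene block. Binary
#' response is drawn from a logistic link on the shared-factor activities;
#' survival times are exponential with log-hazard linear in the activities,
#' censored by an independent uniform time. All randomness flows from the
#' single \code{seed}; the caller's RNG state is preserved.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed; outputs are bit-reproducible given
#'   (config, seed).
#' @return List with \code{cohorts} (list of \code{expression_cohort}),
#'   \code{clinical} (list of clinical data frames), and \code{truth}
#'   (loadings, per-cohort activities, gene-block membership, link
#'   coefficients, seed).
#' @export
simulate_cohort_family <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  cfg <- config
  n_shared <- length(cfg$shared_block_sizes)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  # disjoint gene blocks: shared factors first, then one block per cohort
  stops <- cumsum(cfg$shared_block_sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  shared_blocks <- Map(function(a, b) genes[a:b], starts, stops)
  priv_start <- stops[n_shared]
  private_blocks <- lapply(seq_len(cfg$n_cohorts), function(c) {
    a <- priv_start + (c - 1) * cfg$private_block_size + 1
    genes[a:(a + cfg$private_block_size - 1)]
  })
  # shared loadings drawn once: magnitude `loading`, random signs
  L_shared <- matrix(0, cfg$n_genes, n_shared,
                     dimnames = list(genes, paste0("F", seq_len(n_shared))))
  for (f in seq_len(n_shared))
    L_shared[shared_blocks[[f]], f] <-
      cfg$loading * sample(c(-1, 1), cfg$shared_block_sizes[f], replace = TRUE)
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  scale_g <- stats::setNames(rep(1, cfg$n_genes), genes)
  scale_g[unlist(c(shared_blocks, private_blocks))] <- cfg$signal_scale

  cohorts <- vector("list", cfg$n_cohorts)
  clinical <- vector("list", cfg$n_cohorts)
  activities <- vector("list", cfg$n_cohorts)
  L_private <- vector("list", cfg$n_cohorts)
  for (c in seq_len(cfg$n_cohorts)) {
    id <- sprintf("cohort%02d", c)
    n <- cfg$n_samples[c]
    samples <- sprintf("%s_s%03d", id, seq_len(n))
    # draw shared + private activities, then decorrelate within the cohort:
    # planted factors are exactly orthogonal in-sample (unit sd, zero mean),
    # so the planted components are identifiable rather than tilted by
    # chance correlation between activity draws
    A_raw <- matrix(stats::rnorm(n * (n_shared + 1)), n, n_shared + 1)
    A_raw <- scale(A_raw, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(A_raw))
    A_all <- scale(Q, center = TRUE, scale = TRUE)
    A_shared <- A_all[, seq_len(n_shared), drop = FALSE]
    dimnames(A_shared) <- list(samples, paste0("F", seq_len(n_shared)))
    a_priv <- A_all[, n_shared + 1]
    l_priv <- numeric(cfg$n_genes); names(l_priv) <- genes
    l_priv[private_blocks[[c]]] <-
      cfg$private_loading * sample(c(-1, 1), cfg$private_block_size, replace = TRUE)
    batch <- stats::rnorm(cfg$n_genes, 0, cfg$batch_sd)
    signal <- L_shared %*% t(A_shared) + outer(l_priv, a_priv)
    noise <- matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                    cfg$n_genes, n)
    X <- baseline + batch + scale_g * (signal + noise)
    dimnames(X) <- list(genes, samples)
    cohorts[[c]] <- expression_cohort(X, id)
    activities[[c]] <- A_shared
    L_private[[c]] <- l_priv
    # outcomes linked to shared-factor activity
    eta <- drop(A_shared %*% cfg$response_beta) + cfg$response_intercept
    response <- stats::rbinom(n, 1, stats::plogis(eta))
    rate <- cfg$baseline_hazard * exp(drop(A_shared %*% cfg$hazard_gamma))
    t_event <- stats::rexp(n, rate)
    t_cens <- stats::runif(n, 0, cfg$censor_max)
    clinical[[c]] <- data.frame(
      sample_id = samples,
      response = response,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      treatment = "simulated",
      stringsAsFactors = FALSE)
  }
  names(cohorts) <- names(clinical) <- names(activities) <-
    vapply(cohorts, `[[`, character(1), "cohort_id")
  truth <- list(loadings_shared = L_shared,
                loadings_private = L_private,
                activities = activities,
                shared_blocks = shared_blocks,
                private_blocks = private_blocks,
                response_beta = cfg$response_beta,
                hazard_gamma = cfg$hazard_gamma,
                config = cfg, seed = seed)
  list(cohorts = cohorts, clinical = clinical, truth = truth)
}

#' Simulate a two-group exponential survival cohort
#'
#' A continuous score is drawn per sample; the median split defines a
#' low-hazard and a high-hazard group with the requested true hazard ratio.
#' Event times are exponential, censoring uniform on (0, censor_max).
#' This is the parameter-recovery harness for
#' \code{\link{km_cox_median_split}}.
#'
#' @param n number of samples.
#' @param hr true hazard ratio (high-score vs low-score group).
#' @param base_rate events per year in the low group.
#' @param censor_max upper bound of the uniform censoring time (years).
#' @param seed integer seed.
#' @return Data frame with \code{score}, \code{time}, \code{event} and the
#'   true \code{group}.
#' @export
simulate_two_group_survival <- function(n = 236, hr = 2.7, base_rate = 0.15,
                                        censor_max = 25, seed = 1) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  score <- stats::rnorm(n)
  high <- score > stats::median(score)
  rate <- ifelse(high, base_rate * hr, base_rate)
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, 0, censor_max)
  data.frame(score = score,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = ifelse(high, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort family to disk
#'
#' Cohorts are written in the expression TSV format, clinical tables as
#' TSVs, and the simulation truth (loadings, activities, blocks) as TSVs
#' under a \code{truth/} subdirectory.
#'
#' @param sim result of \code{\link{simulate_cohort_family}}.
#' @param dir output directory.
#' @export
write_cohort_family <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$cohorts)) {
    write_cohort(sim$cohorts[[id]], file.path(dir, paste0(id, ".tsv")))
    write_clinical(sim$clinical[[id]],
                   file.path(dir, paste0(id, "_clinical.tsv")))
    utils::write.table(
      data.frame(sample_id = rownames(sim$truth$activities[[id]]),
                 sim$truth$activities[[id]], check.names = FALSE),
      file.path(dir, "truth", paste0(id, "_activity.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  L <- sim$truth$loadings_shared
  utils::write.table(data.frame(gene = rownames(L), L, check.names = FALSE),
                     file.path(dir, "truth", "shared_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
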