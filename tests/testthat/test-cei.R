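test_that("merged z-scores have mean 0 and sd 1 within each cohort block", {
  sim <- simulate_cohort_family(sim_config(n_cohorts = 3, n_genes = 300,
                                           n_samples = c(20, 30, 25)),
                                seed = 2)
  genes <- sim$truth$shared_blocks[[1]][1:30]
  m <- merge_zscores(sim$cohorts, genes)
  expect_equal(ncol(m), 75)
  blocks <- attr(m, "blocks")
  for (id in unique(blocks)) {
    sub <- m[, blocks == id, drop = FALSE]
    expect_equal(unname(rowMeans(sub)), rep(0, nrow(sub)), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 1, sd)), rep(1, nrow(sub)), tolerance = 1e-12)
  }
})

test_that("cohorts differing by per-gene constant shifts merge identically", {
  co <- toy_cohort(p = 10, n = 8, seed = 44, id = "a")
  shifted <- expression_cohort(co$values + rnorm(10), "b")
  m <- merge_zscores(list(co, shifted), co$features)
  blocks <- attr(m, "blocks")
  expect_equal(m[, blocks == "a"], m[, blocks == "b"],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("single-cohort merge is ordinary z-scoring; degenerate genes drop", {
  co <- toy_cohort(p = 6, n = 7, seed = 12)
  m <- merge_zscores(list(co), co$features)
  expect_equal(m, t(scale(t(co$values))), ignore_attr = TRUE,
               tolerance = 1e-12)
  flat <- co$values; flat[2, ] <- 5
  co2 <- expression_cohort(flat, "flat")
  expect_warning(m2 <- merge_zscores(list(co2), co2$features), "zero variance")
  expect_false(co$features[2] %in% rownames(m2))
})

test_that("varimax factor analysis recovers planted disjoint blocks", {
  for (seed in 1:3) {
    pf <- planted_factor_merged(n_blocks = 3, block_size = 20, n = 200,
                                loading = 0.8, noise_sd = 0.6, seed = seed)
    ceis <- derive_ceis(pf$merged, n_factors = 3, threshold = 0.1)
    expect_length(ceis$ceis, 3)
    matched <- logical(3)
    for (cei in ceis$ceis) {
      genes <- names(cei$weights)
      ov <- vapply(1:3, function(b) {
        block <- rownames(pf$merged)[pf$loadings[, b] != 0]
        length(intersect(genes, block)) / length(union(genes, block))
      }, numeric(1))
      b <- which.max(ov)
      block <- rownames(pf$merged)[pf$loadings[, b] != 0]
      precision <- mean(genes %in% block)
      recall <- mean(block %in% genes)
      # a null gene's least-squares coefficient behaves like a correlation
      # (sd ~ 1/sqrt(n) = 0.071 at n = 200), so it clears the 0.1 threshold
      # with probability ~0.16 and a handful of the 40 off-block genes leak
      # into each factor; precision is bounded accordingly while recall of
      # the true block is essentially perfect
      expect_gte(precision, 0.8)
      expect_gte(recall, 0.95)
      # signs consistent with planted loadings up to a global factor flip
      common <- intersect(genes, block)
      agree <- sign(pf$loadings[common, b]) == cei$weights[common]
      expect_gte(max(mean(agree), 1 - mean(agree)), 0.95)
      matched[b] <- TRUE
    }
    expect_true(all(matched))
  }
})

test_that("factor count ordering and variance explained are reported", {
  pf <- planted_factor_merged(n_blocks = 3, block_size = 20, n = 200, seed = 9)
  ceis <- derive_ceis(pf$merged, n_factors = 3)
  expect_true(all(diff(ceis$variance_explained) <= 1e-12))
  expect_true(ceis$total_variance_explained > 0.3 &&
              ceis$total_variance_explained <= 1)
  expect_equal(vapply(ceis$ceis, `[[`, character(1), "cei_id"),
               paste0("CEI", 1:3))
})

test_that("six-factor fit on six planted factors explains close to truth", {
  pf <- planted_factor_merged(n_blocks = 6, block_size = 15, n = 300,
                              loading = 0.8, noise_sd = 0.6, seed = 3)
  ceis <- derive_ceis(pf$merged, n_factors = 6)
  # planted share: loading^2/(loading^2 + noise^2) of each gene's variance
  planted_share <- 0.64 / (0.64 + 0.36)
  expect_lt(abs(ceis$total_variance_explained - planted_share), 0.10)
})

test_that("derive_ceis rejects degenerate settings", {
  pf <- planted_factor_merged(n_blocks = 2, block_size = 10, n = 60, seed = 1)
  expect_error(derive_ceis(pf$merged, n_factors = 3, threshold = Inf),
               "finite")
  expect_error(derive_ceis(pf$merged, n_factors = 40), "smaller than")
})

test_that("permuting gene order permutes CEI gene lists identically", {
  pf <- planted_factor_merged(n_blocks = 3, block_size = 15, n = 150, seed = 7)
  set.seed(1)
  perm <- sample(nrow(pf$merged))
  c1 <- derive_ceis(pf$merged, n_factors = 3)
  c2 <- derive_ceis(pf$merged[perm, ], n_factors = 3)
  for (i in seq_along(c1$ceis)) {
    w1 <- c1$ceis[[i]]$weights
    w2 <- c2$ceis[[i]]$weights
    expect_equal(w1[sort(names(w1))], w2[sort(names(w2))])
  }
})

test_that("principal-axis extraction is available and consistent", {
  pf <- planted_factor_merged(n_blocks = 3, block_size = 20, n = 200, seed = 5)
  ml <- derive_ceis(pf$merged, n_factors = 3, method = "ml")
  pa <- derive_ceis(pf$merged, n_factors = 3, method = "principal")
  # the two extractions should agree on the block structure
  for (i in 1:3) {
    g_ml <- names(ml$ceis[[i]]$weights)
    overlap <- vapply(pa$ceis, function(d)
      length(intersect(g_ml, names(d$weights))) /
        length(union(g_ml, names(d$weights))), numeric(1))
    expect_gte(max(overlap), 0.8)
  }
})

test_that("a one-gene CEI scores as that gene's z-scores", {
  co <- toy_cohort(p = 5, n = 10, seed = 66)
  cei <- structure(list(cei_id = "CEI1",
                        weights = c(f03 = 1),
                        source = list(factor_index = 1,
                                      variance_explained = NA)),
                   class = "cei_definition")
  st <- score_cei(co, cei)
  z <- as.vector(scale(co$values["f03", ]))
  expect_equal(st$score, z, tolerance = 1e-12)
  expect_equal(st$coverage, rep(1, 10))
})

test_that("negating all weights negates all scores", {
  co <- toy_cohort(p = 8, n = 12, seed = 3)
  cei <- structure(list(cei_id = "x",
                        weights = setNames(c(1, -1, 1), c("f01", "f04", "f07")),
                        source = list()), class = "cei_definition")
  neg <- cei; neg$weights <- -neg$weights
  expect_equal(score_cei(co, neg)$score, -score_cei(co, cei)$score)
})

test_that("scoring reports coverage and refuses empty overlap", {
  co <- toy_cohort(p = 4, n = 6)
  cei <- structure(list(cei_id = "x",
                        weights = setNames(c(1, 1, -1), c("f01", "zz1", "zz2")),
                        source = list()), class = "cei_definition")
  expect_warning(st <- score_cei(co, cei), "coverage")
  expect_equal(st$coverage, rep(1 / 3, 6))
  none <- cei; names(none$weights) <- c("q1", "q2", "q3")
  expect_error(score_cei(co, none), "none of the genes")
})

test_that("batch offsets leave CEI scores unchanged (z-score robustness)", {
  sim <- simulate_cohort_family(sim_config(n_cohorts = 2, n_genes = 300),
                                seed = 13)
  co <- sim$cohorts[[1]]
  genes <- sim$truth$shared_blocks[[1]][1:20]
  cei <- structure(list(cei_id = "x",
                        weights = setNames(rep(1, 20), genes),
                        source = list()), class = "cei_definition")
  base <- score_cei(co, cei)
  offset <- expression_cohort(co$values + rnorm(nrow(co$values)), "off")
  scaled <- expression_cohort(co$values * 1.7 + 0.3, "sc")
  expect_equal(score_cei(offset, cei)$score, base$score, tolerance = 1e-10)
  expect_equal(score_cei(scaled, cei)$score, base$score, tolerance = 1e-10)
})

test_that("CEI definitions round-trip through the interchange TSV", {
  pf <- planted_factor_merged(n_blocks = 2, block_size = 12, n = 80, seed = 2)
  ceis <- derive_ceis(pf$merged, n_factors = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cei_definitions(ceis, path)
  back <- read_cei_definitions(path)
  expect_length(back, 2)
  for (i in 1:2) {
    w0 <- ceis$ceis[[i]]$weights
    expect_equal(back[[i]]$weights[sort(names(w0))],
                 setNames(as.numeric(w0[sort(names(w0))]), sort(names(w0))))
  }
  tab <- read.delim(path)
  expect_true(all(tab$weight %in% c(-1L, 1L)))
})
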