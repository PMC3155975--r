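test_that("CV filter matches direct computation on the anti-log scale", {
  # feature rows with known anti-log values: {1,1} flat, {1,3} CV ~ 0.707,
  # {1,100} CV ~ 1.386; only the last passes the default (1, 1000) band
  vals <- log2(rbind(flat = c(1, 1, 1),
                     narrow = c(1, 3, 1),
                     wide = c(1, 100, 1)))
  colnames(vals) <- c("s1", "s2", "s3")
  co <- expression_cohort(vals, "c")
  # recompute CVs by hand on the 3-sample anti-log rows
  anti <- 2^co$values
  cv_direct <- apply(anti, 1, sd) / rowMeans(anti)
  expect_lt(cv_direct["flat"], 1e-12)
  out <- cv_filter(co)
  expect_identical(out$features, names(cv_direct)[cv_direct > 1 & cv_direct < 1000])
  expect_equal(attr(out, "cv"), cv_direct[out$features])
  # the two-sample hand values
  expect_equal(sd(c(1, 3)) / mean(c(1, 3)), sqrt(2) / 2)
  expect_equal(sd(c(1, 100)) / mean(c(1, 100)), 70.00357133746822 / 50.5)
})

test_that("CV filter respects bounds, preserves order, errors when empty", {
  co <- toy_cohort(p = 20, n = 10, seed = 5)
  out <- cv_filter(co, low = 0, high = Inf)
  expect_identical(out$features, co$features)  # order preserved
  expect_error(cv_filter(co, low = 1e6, high = 1e7), "no features survive")
  # the CV always matches direct computation on the anti-log values, and
  # since a log2 shift multiplies the anti-log row, the CV is shift-invariant
  # while a log2 rescaling changes it
  shifted <- co$values; shifted[1, ] <- shifted[1, ] + 3
  rescaled <- co$values; rescaled[1, ] <- rescaled[1, ] * 1.5
  cv0 <- attr(cv_filter(co, 0, Inf), "cv")[1]
  cv_shift <- attr(cv_filter(expression_cohort(shifted, "s"), 0, Inf), "cv")[1]
  cv_scale <- attr(cv_filter(expression_cohort(rescaled, "r"), 0, Inf), "cv")[1]
  anti <- 2^rescaled[1, ]
  expect_equal(unname(cv_scale), sd(anti) / mean(anti))
  expect_equal(unname(cv_shift), unname(cv0), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv0, cv_scale)))
})

test_that("PCA conserves total variance and reconstructs the data", {
  co <- toy_cohort(p = 15, n = 8, seed = 3)
  pca <- fit_pca(co)
  expect_equal(sum(pca$omega^2), sum(pca$sigma^2))
  expect_true(all(diff(pca$omega) <= 1e-12))
  # full reconstruction: centered matrix = weights %*% t(scores)
  Xc <- co$values - rowMeans(co$values)
  rec <- pca$weights %*% t(pca$scores)
  expect_lt(max(abs(rec - Xc)) / max(abs(Xc)), 1e-8)
})

test_that("rank-1 data yields a single dominant component", {
  set.seed(9)
  u <- rnorm(30); v <- rnorm(10)
  X <- outer(u, v)
  dimnames(X) <- list(paste0("g", 1:30), paste0("s", 1:10))
  pca <- fit_pca(expression_cohort(X, "r1"))
  expect_lt(pca$omega[2] / pca$omega[1], 1e-8)
})

test_that("permuting sample columns permutes score rows identically", {
  co <- toy_cohort(p = 12, n = 9, seed = 21)
  pca <- fit_pca(co)
  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  co2 <- expression_cohort(co$values[, perm], "p")
  pca2 <- fit_pca(co2)
  expect_equal(pca2$scores, pca$scores[perm, ], tolerance = 1e-10)
  expect_equal(pca2$weights, pca$weights, tolerance = 1e-10)
})

test_that("PCA refuses fewer than 3 samples", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_error(expression_cohort(m, "x"), "at least 3 samples")
})

test_that("BIC selects the planted rank on strong-signal matrices", {
  hits <- 0
  for (seed in 1:5) {
    co <- planted_rank3_cohort(seed = seed)
    k <- select_k_bic(fit_pca(co))
    hits <- hits + (k == 3)
    expect_lte(abs(k - 3), 1)
  }
  expect_gte(hits, 4)
})

test_that("BIC picks a single component for pure isotropic noise", {
  for (seed in 1:3) {
    set.seed(seed + 100)
    X <- matrix(rnorm(300 * 60), 300, 60,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:60)))
    pca <- fit_pca(expression_cohort(X, "noise"))
    k <- select_k_bic(pca)
    expect_equal(as.integer(k), 1L)
    bic <- attr(k, "bic")
    expect_true(all(is.finite(bic[attr(k, "nu_path") > 0])))
  }
})

test_that("more noise never increases the selected rank (planted family)", {
  ks_low <- ks_high <- integer(0)
  for (seed in 1:5) {
    k_lo <- select_k_bic(fit_pca(planted_rank3_cohort(noise_sd = 1, seed = seed)))
    k_hi <- select_k_bic(fit_pca(planted_rank3_cohort(noise_sd = 8, seed = seed)))
    ks_low <- c(ks_low, k_lo); ks_high <- c(ks_high, k_hi)
  }
  expect_lte(median(ks_high), median(ks_low))
})

test_that("perfect fit caps the BIC with a warning", {
  set.seed(2)
  u <- rnorm(20); v <- rnorm(6)
  X <- outer(u, v)
  dimnames(X) <- list(paste0("g", 1:20), paste0("s", 1:6))
  pca <- fit_pca(expression_cohort(X, "exact"))
  expect_warning(k <- select_k_bic(pca), "perfect fit")
  expect_equal(as.integer(k), 1L)
})

test_that("a feature identical to the component score is distilled with sign +1", {
  co <- planted_rank3_cohort(n = 20, p = 50, seed = 4)
  pca <- fit_pca(co)
  # graft a feature that IS the PC1 score onto the cohort
  vals <- rbind(co$values, probe_score = pca$scores[, 1])
  co2 <- expression_cohort(vals, "g")
  pca2 <- fit_pca(co2)
  rp <- distill_pc(pca2, co2, 1)
  row <- rp$representative[rp$representative$feature == "probe_score", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$p, 0)
  expect_true(abs(row$r) > 0.999)
})

test_that("distillation sign symmetry: negating scores flips all signs", {
  co <- planted_rank3_cohort(n = 30, p = 80, seed = 6)
  pca <- fit_pca(co)
  rp <- distill_pc(pca, co, 1)
  neg <- pca
  neg$scores <- -neg$scores
  neg$weights <- -neg$weights
  rp2 <- distill_pc(neg, co, 1)
  expect_identical(rp2$representative$feature, rp$representative$feature)
  expect_identical(rp2$representative$sign, -rp$representative$sign)
})

test_that("distillation t-test P matches a permutation oracle on a toy", {
  set.seed(17)
  n <- 10
  x <- rnorm(n)
  s <- 0.55 * x + rnorm(n, 0, 0.8)
  r_obs <- cor(x, s)
  # brute-force permutation null of |r|
  B <- 100000
  perms <- replicate(B, sample(n))
  Xp <- matrix(x[perms], n, B)
  r_null <- as.vector(cor(Xp, s))
  p_perm <- mean(abs(r_null) >= abs(r_obs))
  t_stat <- r_obs * sqrt(n - 2) / sqrt(1 - r_obs^2)
  p_t <- 2 * pt(-abs(t_stat), n - 2)
  expect_lt(abs(p_perm - p_t), 3 * sqrt(p_t * (1 - p_t) / B) + 0.01)
})

test_that("independent-noise features are rarely distilled (quick check)", {
  set.seed(23)
  n <- 50
  s <- rnorm(n)
  noise <- matrix(rnorm(2000 * n), 2000, n,
                  dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:n)))
  r <- as.vector(cor(t(noise), s))
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(tt), n - 2)
  rate <- mean(p < 0.01)
  expect_gte(rate, 0.0005)
  expect_lte(rate, 0.05)
})

test_that("distillation errors on an empty representative set", {
  set.seed(8)
  X <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  co <- expression_cohort(X, "n")
  pca <- fit_pca(co)
  expect_error(distill_pc(pca, co, 1, alpha = 1e-12), "alpha")
})

test_that("PCA serialization writes the summary TSVs", {
  co <- toy_cohort(p = 6, n = 5)
  pca0 <- fit_pca(co)
  pca <- apply_k_selection(pca0, suppressWarnings(select_k_bic(pca0)))
  dir <- withr::local_tempdir()
  write_cohort_pca(pca, dir)
  expect_true(all(file.exists(file.path(dir,
    c("weights.tsv", "scores.tsv", "summary.tsv")))))
  summ <- read.delim(file.path(dir, "summary.tsv"))
  expect_equal(as.integer(summ$value[summ$key == "n"]), pca$n)
})
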