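test_that("single-predictor LASSO matches the closed-form soft-threshold solution", {
  days <- rep(DEFAULT_SCHEDULE, 3)
  x <- as.numeric(scale(days)) # feature identical to the z-scored response
  features <- matrix(x, ncol = 1, dimnames = list(NULL, "marker"))
  alpha <- 0.01
  n <- length(days)
  xc <- x - mean(x)
  yc <- days - mean(days)
  rho <- sum(xc * yc) / n
  beta_oracle <- sign(rho) * max(0, abs(rho) - alpha) / (sum(xc^2) / n)
  out <- lasso_metrics(features, days, alpha = alpha)
  expect_equal(out$lasso_coef, beta_oracle, tolerance = 1e-4)
  expect_true(out$lasso_selected)
  # the penalty shrinks the coefficient below the OLS slope
  expect_lt(abs(out$lasso_coef), abs(sum(xc * yc) / sum(xc^2)))
})

test_that("a full-shrinkage penalty selects nothing", {
  blk <- noisy_block(seed = 2)
  out <- lasso_metrics(blk$features, blk$response, alpha = 1e6)
  expect_true(all(out$lasso_coef == 0))
  expect_false(any(out$lasso_selected))
})

test_that("pure-noise features fall below the 20% coefficient threshold in most runs", {
  hits <- vapply(1:20, function(s) {
    blk <- noisy_block(n_noise = 5, seed = s)
    out <- lasso_metrics(blk$features, blk$response, alpha = 0.01)
    sel <- out[out$compound != "signal", "lasso_selected", drop = TRUE]
    all(!sel) && out$lasso_selected[out$compound == "signal"]
  }, logical(1))
  expect_gte(sum(hits), 15)
})

test_that("random-forest importances are deterministic under a seed and sum to one", {
  blk <- noisy_block(seed = 4)
  a <- rfr_metrics(blk$features, blk$response, seed = 99)
  b <- rfr_metrics(blk$features, blk$response, seed = 99)
  expect_identical(a, b)
  expect_equal(sum(a$rfr_importance), 1, tolerance = 1e-9)
  expect_true(all(a$rfr_importance >= 0))
  expect_error(rfr_metrics(blk$features, blk$response, seed = 1, n_estimators = 0), "n_estimators")
  expect_error(rfr_metrics(blk$features, blk$response), "seed")
})

test_that("a constant feature gets zero importance and no selection", {
  days <- rep(DEFAULT_SCHEDULE, 3)
  features <- cbind(
    flat = rep(1, length(days)),
    trend = as.numeric(scale(days))
  )
  out <- rfr_metrics(features, days, seed = 5)
  expect_equal(out$rfr_importance[out$compound == "flat"], 0)
  expect_false(out$rfr_selected[out$compound == "flat"])
})

test_that("the single informative feature attains the maximum importance in >= 19/20 seeds", {
  wins <- vapply(1:20, function(s) {
    blk <- noisy_block(n_noise = 9, seed = s)
    out <- rfr_metrics(blk$features, blk$response, seed = s + 100)
    out$compound[which.max(out$rfr_importance)] == "signal"
  }, logical(1))
  expect_gte(sum(wins), 19)
})

test_that("Spearman correlation captures monotone trends and their transforms", {
  days <- rep(DEFAULT_SCHEDULE, 2)
  falling <- 100 * exp(-0.01 * days)
  expect_equal(spearman_metrics(falling, days)$rho, -1)
  rising <- exp(days / 50)
  s <- spearman_metrics(rising, days)
  expect_equal(s$rho, 1)
  expect_equal(s$p, 0)
  # invariance under a strictly monotone transform
  noisy <- falling * exp(rnorm(length(days), 0, 0.1))
  expect_equal(
    spearman_metrics(noisy, days)$rho,
    spearman_metrics(log(noisy), days)$rho
  )
  # degenerate input
  d <- spearman_metrics(rep(1, 10), 1:10)
  expect_true(d$degenerate)
  expect_equal(d$rho, 0)
})

test_that("Spearman matches the brute-force mid-rank formula and cor.test on ties", {
  x <- c(3, 3, 1, 5, 5, 2)
  y <- c(0, 3, 7, 14, 28, 42)
  s <- spearman_metrics(x, y)
  # oracle: Pearson correlation of average ranks, computed directly
  rx <- rank(x)
  ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(s$rho, oracle, tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s$p, ct$p.value, tolerance = 1e-9)
})

test_that("all metrics are invariant to permuting sample order", {
  blk <- noisy_block(n_noise = 3, seed = 6)
  set.seed(8)
  perm <- sample(nrow(blk$features))
  l1 <- lasso_metrics(blk$features, blk$response)
  l2 <- lasso_metrics(blk$features[perm, ], blk$response[perm])
  expect_equal(l1, l2, tolerance = 1e-8)
  # the forest resamples rows, so only the ranking is permutation-stable
  r1 <- rfr_metrics(blk$features, blk$response, seed = 1)
  r2 <- rfr_metrics(blk$features[perm, ], blk$response[perm], seed = 1)
  expect_equal(which.max(r1$rfr_importance), which.max(r2$rfr_importance))
  expect_lt(max(abs(r1$rfr_importance - r2$rfr_importance)), 0.1)
  expect_equal(
    spearman_metrics(blk$features[, 1], blk$response)$rho,
    spearman_metrics(blk$features[perm, 1], blk$response[perm])$rho
  )
})

test_that("exact duplicate columns share their metric values", {
  blk <- noisy_block(n_noise = 3, seed = 9)
  features <- cbind(blk$features, signal2 = blk$features[, "signal"])
  out <- lasso_metrics(features, blk$response)
  # LASSO may split weight between exact duplicates; the summed coefficient
  # matches the single-copy coefficient
  single <- lasso_metrics(blk$features, blk$response)
  dup_sum <- sum(out$lasso_coef[out$compound %in% c("signal", "signal2")])
  expect_equal(dup_sum, single$lasso_coef[single$compound == "signal"],
    tolerance = 1e-3
  )
  s1 <- spearman_metrics(features[, "signal"], blk$response)
  s2 <- spearman_metrics(features[, "signal2"], blk$response)
  expect_identical(s1, s2)
})

test_that("raising a threshold never increases the selected set", {
  blk <- noisy_block(n_noise = 5, seed = 10)
  fracs <- c(0.05, 0.1, 0.2, 0.5, 0.9)
  n_lasso <- vapply(fracs, function(f) {
    sum(lasso_metrics(blk$features, blk$response, threshold_frac = f)$lasso_selected)
  }, integer(1))
  expect_true(all(diff(n_lasso) <= 0))
  n_rfr <- vapply(fracs, function(f) {
    sum(rfr_metrics(blk$features, blk$response,
      threshold_frac = f, seed = 3
    )$rfr_selected)
  }, integer(1))
  expect_true(all(diff(n_rfr) <= 0))
})

test_that("selection_metrics fits per class block and covers every compound", {
  recs <- generate_storage_dataset(toy_profile(), noise_model(0.05, 0.1), seed = 31)
  fm <- preprocess_matrix(pivot_to_matrix(recs, "LS"))
  m <- selection_metrics(fm, pipeline_config(seed = 31))
  expect_equal(sort(m$compound), sort(fm$compound_meta$compound))
  expect_true(all(abs(m$spearman_rho) <= 1))
  # a noiseless monotone decliner has |rho| = 1 on noiseless data
  recs0 <- generate_storage_dataset(toy_profile(), noise_model(0, 0), seed = 1)
  fm0 <- preprocess_matrix(pivot_to_matrix(recs0, "LS"))
  m0 <- selection_metrics(fm0, pipeline_config(seed = 1))
  expect_equal(abs(m0$spearman_rho[m0$compound == "phenolic marker"]), 1)
})
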