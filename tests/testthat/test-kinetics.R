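test_that("the fitter recovers propagation parameters from noiseless model points", {
  days <- c(14, 28, 42)
  # linseed-type propagation: C(t) = 0.08 * exp(0.15 * (t - 14))
  c_ls <- 0.08 * exp(0.15 * (days - 14))
  fit <- fit_pseudo_first_order(days, c_ls, lag_t0 = 14)
  expect_equal(fit$rate_k, 0.15, tolerance = 1e-10)
  expect_equal(fit$amplitude_C0, 0.08, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # hempseed-type: C(t) = 0.11 * exp(0.14 * (t - 14))
  c_hs <- 0.11 * exp(0.14 * (days - 14))
  fit2 <- fit_pseudo_first_order(days, c_hs, lag_t0 = 14)
  expect_equal(fit2$rate_k, 0.14, tolerance = 1e-10)
  expect_equal(fit2$amplitude_C0, 0.11, tolerance = 1e-10)
  # log-linear and nonlinear fits agree on noiseless data
  fit_nls <- fit_pseudo_first_order(days, c_ls, lag_t0 = 14, method = "nls")
  expect_equal(fit_nls$rate_k, fit$rate_k, tolerance = 1e-6)
  expect_equal(fit_nls$amplitude_C0, fit$amplitude_C0, tolerance = 1e-6)
})

test_that("degenerate and invalid kinetic inputs are handled", {
  days <- c(14, 28, 42)
  flat <- fit_pseudo_first_order(days, rep(0.5, 3), lag_t0 = 14)
  expect_equal(flat$rate_k, 0)
  expect_equal(flat$amplitude_C0, 0.5)
  expect_equal(flat$r_squared, 1)
  expect_error(
    fit_pseudo_first_order(days, c(0.1, 0, 0.3), lag_t0 = 14),
    "non-positive concentration at day 28"
  )
  expect_error(
    fit_pseudo_first_order(c(14, 28), c(0.1, NA), lag_t0 = 14),
    "at least 2 usable points"
  )
  expect_error(
    fit_pseudo_first_order(days, rep(1, 3), lag_t0 = 14, window = c(7, 42)),
    "window"
  )
})

test_that("the fit window restricts which points are used", {
  days <- c(14, 28, 42, 56, 84)
  conc <- 0.08 * exp(0.15 * (days - 14))
  conc[4:5] <- conc[4:5] * 0.2 # post-plateau departure from the model
  fit <- fit_pseudo_first_order(days, conc, lag_t0 = 14, window = c(14, 42))
  expect_equal(fit$rate_k, 0.15, tolerance = 1e-10)
  expect_equal(fit$n_points, 3)
})

test_that("prediction evaluates the exponential and refuses pre-lag days", {
  fit <- fit_pseudo_first_order(c(14, 28, 42), 0.08 * exp(0.15 * (c(14, 28, 42) - 14)),
    lag_t0 = 14
  )
  expect_equal(predict_kinetic(fit, 14), 0.08, tolerance = 1e-10)
  expect_equal(predict_kinetic(fit, 42), 0.08 * exp(4.2), tolerance = 1e-9)
  expect_error(predict_kinetic(fit, 7), "undefined before the lag")
  # fit of predicted values returns the same parameters (idempotence)
  t_new <- c(14, 21, 28, 35, 42)
  refit <- fit_pseudo_first_order(t_new, predict_kinetic(fit, t_new), lag_t0 = 14)
  expect_equal(refit$rate_k, fit$rate_k, tolerance = 1e-10)
  expect_equal(refit$amplitude_C0, fit$amplitude_C0, tolerance = 1e-10)
})

test_that("kinetic rate is recovered within 10% in >= 95% of noisy simulations", {
  set.seed(2024)
  days <- c(14, 28, 42)
  truth <- 0.08 * exp(0.15 * (days - 14))
  ok <- vapply(seq_len(500), function(i) {
    noisy <- truth * exp(rnorm(3, 0, sqrt(log(1 + 0.05^2))))
    fit <- fit_pseudo_first_order(days, noisy, lag_t0 = 14)
    abs(fit$rate_k - 0.15) <= 0.1 * 0.15
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("percent decline and fold change reproduce storage-loss arithmetic", {
  expect_equal(round(percent_decline(538.2, 13.2), 1), 97.5)
  expect_equal(round(percent_decline(745.1, 34.8)), 95)
  expect_equal(percent_decline(5, 5), 0)
  expect_equal(fold_change(8, 2), 4)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_equal(fold_change(42.7 * 0.03, 0.03), 42.7)
  expect_error(percent_decline(0, 1), "c_start")
  expect_error(fold_change(1, 0), "c_start")
  # numeric consistency: fold(end, start) = 1 - percent/100
  set.seed(5)
  for (i in 1:20) {
    c0 <- runif(1, 1, 100)
    c1 <- runif(1, 0, c0)
    expect_equal(fold_change(c1, c0), 1 - percent_decline(c0, c1) / 100,
      tolerance = 1e-12
    )
  }
})

test_that("identical groups share one letter; well-separated groups differ", {
  same <- anova_tukey_letters(list(a = c(1, 1.01, 0.99), b = c(1, 1.02, 0.98)))
  expect_equal(same$letters, c("a", "a"))
  two <- anova_tukey_letters(list(lo = c(1, 1.1, 0.9), hi = c(101, 100.9, 101.1)))
  expect_equal(two$letters, c("a", "b"))
  # cross-check the separated pair against the direct Tukey p-value
  df <- data.frame(
    value = c(1, 1.1, 0.9, 101, 100.9, 101.1),
    group = factor(rep(c("lo", "hi"), each = 3))
  )
  p <- stats::TukeyHSD(stats::aov(value ~ group, df))$group[, "p adj"]
  expect_lt(p, 0.05)
  expect_error(anova_tukey_letters(list(a = 1, b = c(1, 2))), "at least 2 values")
})

test_that("letter partitions agree with the pairwise Tukey oracle on random instances", {
  set.seed(99)
  for (i in 1:50) {
    k <- sample(3:5, 1)
    n <- sample(3:6, 1)
    mu <- sample(c(0, 0, 5, 10), k, replace = TRUE)
    groups <- lapply(seq_len(k), function(j) rnorm(n, mu[j], 1))
    names(groups) <- paste0("g", seq_len(k))
    out <- anova_tukey_letters(groups)
    lt <- stats::setNames(out$letters, out$group)

    df <- data.frame(
      value = unlist(groups),
      group = factor(rep(names(groups), each = n))
    )
    fit <- stats::aov(value ~ group, df)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    share <- function(a, b) {
      any(strsplit(lt[[a]], "")[[1]] %in% strsplit(lt[[b]], "")[[1]])
    }
    for (pair_name in rownames(tk)) {
      pair <- strsplit(pair_name, "-", fixed = TRUE)[[1]]
      signif <- anova_p < 0.05 && tk[pair_name, "p adj"] < 0.05
      if (signif) {
        expect_false(share(pair[1], pair[2]), label = pair_name)
      } else {
        expect_true(share(pair[1], pair[2]), label = pair_name)
      }
    }
  }
})

test_that("letters are invariant to group input order up to relabeling", {
  groups <- list(a = c(1, 1.2, 0.8), b = c(10, 10.5, 9.5), c = c(1.1, 0.9, 1.0))
  out1 <- anova_tukey_letters(groups)
  out2 <- anova_tukey_letters(rev(groups))
  m1 <- stats::setNames(out1$letters, out1$group)
  m2 <- stats::setNames(out2$letters, out2$group)
  # partition structure matches: same groups share letters in both runs
  for (x in names(groups)) {
    for (y in names(groups)) {
      s1 <- any(strsplit(m1[[x]], "")[[1]] %in% strsplit(m1[[y]], "")[[1]])
      s2 <- any(strsplit(m2[[x]], "")[[1]] %in% strsplit(m2[[y]], "")[[1]])
      expect_equal(s1, s2)
    }
  }
})

test_that("class totals sum quantified values per bottle with censored entries as zero", {
  recs <- tibble::tibble(
    oil_type = "BC", supplier_id = "S1",
    replicate_id = c("R1", "R1", "R2", "R2"),
    day = 0L,
    compound = rep(c("p-coumaric acid", "quinic acid"), 2),
    compound_class = "phenolic_acid",
    value = c(3, 4, 5, NA),
    unit = "ug/g",
    below_loq = c(FALSE, FALSE, FALSE, TRUE)
  )
  totals <- total_class_content(recs, "phenolic_acid", 0)
  expect_equal(sort(totals$total), c(5, 7))
  expect_error(total_class_content(recs, "phenolic_acid", 28), "no records")
  mixed <- recs
  mixed$unit[1] <- "mg/g"
  expect_error(total_class_content(mixed, "phenolic_acid", 0), "mixed units")
})

test_that("synthetic day-0 class totals match the configured initial content", {
  profiles <- default_oil_profiles()
  recs <- generate_storage_dataset(profiles["BC"], noise_model(0, 0), seed = 1)
  totals <- total_class_content(recs, "polyphenol", 0)
  expect_equal(nrow(totals), 9)
  expect_equal(unique(round(totals$total, 6)),
    round(sum(profiles$BC$polyphenols$initial), 6)
  )
})

test_that("kinetics fit from records reproduces the generator's volatile parameters", {
  recs <- generate_storage_dataset(toy_profile(), noise_model(0, 0), seed = 1)
  fit <- fit_kinetics_records(recs, "LS", "hexanal", lag_t0 = 14, window = c(14, 42))
  expect_equal(fit$rate_k, 0.15, tolerance = 1e-9)
  expect_equal(fit$amplitude_C0, 0.08, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinetics_table(fit, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$rate_k, fit$rate_k)
})
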