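#' Fit the pseudo-first-order propagation model
#'
#' Volatile oxidation products in the propagation phase follow
#' `C(t) = C0 * exp(k * (t - t0))`. The model is exactly linear in log
#' space, so the fit is log-linear least squares of `ln C` on `(t - t0)`
#' restricted to the fit window: the slope is the rate constant `k`
#' (1/day), the exponentiated intercept the amplitude `C0` (ppm), and R^2
#' is computed on the log scale. The lag `t0` is fixed, not estimated
#' (default day 14); a nonlinear least-squares refinement is available via
#' `method = "nls"` and agrees with the log-linear fit on noiseless data.
#'
#' @param times sampling days.
#' @param concentrations concentrations (ppm), same length.
#' @param lag_t0 fixed lag day `t0`.
#' @param window two-day fit window `c(start, end)`; `start` must be
#'   >= `lag_t0`. Defaults to `c(lag_t0, max(times))`.
#' @param method `"loglinear"` (default) or `"nls"` (Levenberg-Marquardt
#'   refinement started from the log-linear estimates).
#' @param compound,oil_type optional labels carried into the fit.
#' @return list of class `"kinetic_fit"`: `amplitude_C0`, `rate_k`,
#'   `lag_t0`, `window`, `r_squared`, `n_points`, plus the labels.
#' @export
fit_pseudo_first_order <- function(times, concentrations, lag_t0 = 14,
                                   window = NULL, method = c("loglinear", "nls"),
                                   compound = NA_character_,
                                   oil_type = NA_character_) {
  method <- match.arg(method)
  stopifnot(length(times) == length(concentrations))
  if (is.null(window)) window <- c(lag_t0, max(times))
  if (window[1] < lag_t0) stop("fit window must start at or after lag_t0", call. = FALSE)
  keep <- times >= window[1] & times <= window[2] & !is.na(concentrations)
  t_fit <- times[keep]
  c_fit <- concentrations[keep]
  if (any(c_fit <= 0)) {
    stop("non-positive concentration at day ", t_fit[which(c_fit <= 0)[1]],
      " inside the fit window",
      call. = FALSE
    )
  }
  if (length(t_fit) < 2) {
    stop("need at least 2 usable points inside the fit window", call. = FALSE)
  }
  x <- t_fit - lag_t0
  y <- log(c_fit)
  fit <- stats::lm(y ~ x)
  rate <- unname(stats::coef(fit)[2])
  amplitude <- exp(unname(stats::coef(fit)[1]))
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot < 1e-14) {
    if (ss_res < 1e-14) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  if (method == "nls") {
    nls_fit <- try(
      stats::nls(
        c_fit ~ C0 * exp(k * x),
        start = list(C0 = amplitude, k = rate),
        # scaleOffset keeps the convergence test defined on zero-residual data
        control = stats::nls.control(warnOnly = TRUE, scaleOffset = 1)
      ),
      silent = TRUE
    )
    if (!inherits(nls_fit, "try-error")) {
      cf <- stats::coef(nls_fit)
      amplitude <- unname(cf["C0"])
      rate <- unname(cf["k"])
    }
  }
  structure(
    list(
      compound = compound, oil_type = oil_type,
      amplitude_C0 = amplitude, rate_k = rate, lag_t0 = lag_t0,
      window = window, r_squared = max(0, min(1, r2)),
      n_points = length(t_fit), method = method
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> C(t) = %.4g * exp(%.4g * (t - %g)), R^2 = %.4f (%d points, days %g-%g)\n",
    x$amplitude_C0, x$rate_k, x$lag_t0, x$r_squared, x$n_points,
    x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Evaluate a fitted propagation model
#'
#' @param fit a `kinetic_fit`.
#' @param t day (>= the fit's `lag_t0`; the model is undefined before the
#'   lag).
#' @return concentration in ppm.
#' @export
predict_kinetic <- function(fit, t) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (any(t < fit$lag_t0)) {
    stop("model undefined before the lag day ", fit$lag_t0, call. = FALSE)
  }
  fit$amplitude_C0 * exp(fit$rate_k * (t - fit$lag_t0))
}

#' Percent decline between two concentrations
#'
#' `100 * (c_start - c_end) / c_start`, the standard storage-loss figure
#' (e.g. 538.2 -> 13.2 ug/g is a 97.5% decline).
#'
#' @param c_start initial concentration (> 0).
#' @param c_end final concentration (>= 0).
#' @return percent decline (negative when the compound increased).
#' @export
percent_decline <- function(c_start, c_end) {
  if (any(c_start <= 0)) stop("`c_start` must be > 0", call. = FALSE)
  if (any(c_end < 0)) stop("`c_end` must be >= 0", call. = FALSE)
  100 * (c_start - c_end) / c_start
}

#' Fold change between two concentrations
#'
#' `c_end / c_start`; satisfies
#' `fold_change(c_end, c_start) = 1 - percent_decline(c_start, c_end)/100`.
#'
#' @param c_end final concentration.
#' @param c_start initial concentration (> 0).
#' @return the fold change.
#' @export
fold_change <- function(c_end, c_start) {
  if (any(c_start <= 0)) stop("`c_start` must be > 0", call. = FALSE)
  c_end / c_start
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Tests whether group means differ (one-way ANOVA); when significant at
#' `level`, all pairwise Tukey HSD comparisons are summarized as a compact
#' letter display: groups sharing a letter are not significantly
#' different. Letters are assigned by the insertion-absorption algorithm,
#' lettering from the smallest group mean.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param level significance level (default 0.05).
#' @return tibble with `group`, `mean`, `sd`, `n`, `letters`, plus the
#'   ANOVA p-value as attribute `"anova_p"`.
#' @export
anova_tukey_letters <- function(groups, level = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs at least 2 values", call. = FALSE)
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups))
  )
  means <- vapply(groups, mean, numeric(1))
  fit <- stats::aov(value ~ group, data = df)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]

  g <- names(groups)
  if (is.na(anova_p) || anova_p >= level) {
    letters_out <- stats::setNames(rep("a", length(g)), g)
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - level)$group
    signif_pairs <- rownames(tk)[tk[, "p adj"] < level]
    pairs <- strsplit(signif_pairs, "-", fixed = TRUE)
    letters_out <- compact_letters(g, pairs, means)
  }
  out <- tibble::tibble(
    group = g,
    mean = unname(means),
    sd = vapply(groups, stats::sd, numeric(1)),
    n = unname(sizes),
    letters = unname(letters_out[g])
  )
  attr(out, "anova_p") <- anova_p
  out
}

# insertion-absorption compact letter display over a significance graph
compact_letters <- function(groups, signif_pairs, means) {
  # drop any column that is a subset (or later duplicate) of another
  absorb <- function(cols) {
    drop <- rep(FALSE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i == j) next
        if (all(cols[[i]] %in% cols[[j]]) &&
          (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    cols[!drop]
  }
  columns <- list(groups)
  for (pair in signif_pairs) {
    a <- pair[1]
    b <- pair[2]
    new_cols <- list()
    for (col in columns) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    columns <- absorb(new_cols)
  }
  # letter columns from the smallest mean upward
  col_min_mean <- vapply(columns, function(col) min(means[col]), numeric(1))
  columns <- columns[order(col_min_mean)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(columns)) {
    lt <- letters[(i - 1) %% 26 + 1]
    for (gname in columns[[i]]) out[gname] <- paste0(out[gname], lt)
  }
  out
}

#' Per-bottle total content of one compound class
#'
#' Sums the quantified concentrations of all compounds of `class` at one
#' sampling day within each bottle (supplier x replicate); below-LOQ
#' entries contribute 0 (censored, not quantified).
#'
#' @param records concentration records.
#' @param class a compound class (or `"polyphenol"` for all polyphenol
#'   classes together).
#' @param day sampling day.
#' @return tibble with `oil_type`, `supplier_id`, `replicate_id`, `total`,
#'   `unit`.
#' @export
total_class_content <- function(records, class, day) {
  records <- validate_records(records, schedule = NULL)
  classes <- if (class == "polyphenol") POLYPHENOL_CLASSES else class
  sub <- records[records$compound_class %in% classes & records$day == day, ]
  if (nrow(sub) == 0) {
    stop("no records for class '", class, "' at day ", day, call. = FALSE)
  }
  if (length(unique(sub$unit)) > 1) {
    stop("mixed units across the requested class", call. = FALSE)
  }
  sub$value[sub$below_loq | is.na(sub$value)] <- 0
  sub |>
    dplyr::group_by(.data$oil_type, .data$supplier_id, .data$replicate_id) |>
    dplyr::summarise(
      total = sum(.data$value),
      unit = .data$unit[1], .groups = "drop"
    )
}

#' Fit propagation kinetics for one compound from records
#'
#' Convenience wrapper: extracts one volatile's mean concentration per day
#' for one oil type and runs [fit_pseudo_first_order()] over the window.
#'
#' @param records concentration records.
#' @param oil_type,compound selection.
#' @param lag_t0,window,method passed to [fit_pseudo_first_order()].
#' @return a `kinetic_fit`.
#' @export
fit_kinetics_records <- function(records, oil_type, compound, lag_t0 = 14,
                                 window = c(14, 42), method = "loglinear") {
  records <- validate_records(records, schedule = NULL)
  sub <- records[records$oil_type == oil_type & records$compound == compound &
    !records$below_loq & !is.na(records$value), ]
  if (nrow(sub) == 0) {
    stop("no quantified records for ", compound, " in ", oil_type, call. = FALSE)
  }
  per_day <- sub |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  fit_pseudo_first_order(per_day$day, per_day$value,
    lag_t0 = lag_t0, window = window, method = method,
    compound = compound, oil_type = oil_type
  )
}

#' Write fitted kinetics as CSV
#'
#' @param fits a `kinetic_fit` or list of them.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_kinetics_table <- function(fits, path) {
  if (inherits(fits, "kinetic_fit")) fits <- list(fits)
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      compound = f$compound, oil_type = f$oil_type,
      amplitude_C0 = f$amplitude_C0, rate_k = f$rate_k, lag_t0 = f$lag_t0,
      window_start = f$window[1], window_end = f$window[2],
      r_squared = f$r_squared, n_points = f$n_points
    )
  }))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
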