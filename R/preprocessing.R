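#' Centered log-ratio transform
#'
#' Maps a composition x to `ln(x_i / g(x))` with `g` the geometric mean,
#' removing the unit-sum constraint of compositional data. Output sums to
#' zero and is invariant to rescaling of the whole composition. Applied in
#' this pipeline to per-sample fatty-acid sub-compositions only.
#'
#' Zeros / below-LOQ entries: non-positive entries are replaced by half
#' the smallest positive entry of the same composition before the
#' transform (`zero_replace = TRUE`, the default); with
#' `zero_replace = FALSE` a non-positive entry is an error.
#'
#' @param composition positive numeric vector, length >= 2.
#' @param zero_replace replace non-positive entries as described above.
#' @return numeric vector of the same length, summing to 0.
#' @export
clr_transform <- function(composition, zero_replace = TRUE) {
  stopifnot(length(composition) >= 2, all(is.finite(composition)))
  nonpos <- composition <= 0
  if (any(nonpos)) {
    if (!zero_replace) {
      stop("non-positive entry in composition (zero replacement disabled)",
        call. = FALSE
      )
    }
    if (all(nonpos)) {
      stop("composition has no positive entry to anchor zero replacement",
        call. = FALSE
      )
    }
    composition[nonpos] <- 0.5 * min(composition[!nonpos])
  }
  lx <- log(composition)
  lx - mean(lx)
}

#' Apply CLR to the fatty-acid block of a feature matrix
#'
#' Each sample's fatty-acid sub-composition is CLR-transformed in place;
#' all other compound classes pass through unchanged.
#'
#' @param fm a `feature_matrix` with no missing fatty-acid values.
#' @inheritParams clr_transform
#' @return the transformed `feature_matrix`.
#' @export
clr_fatty_acids <- function(fm, zero_replace = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  fa_cols <- which(fm$compound_meta$compound_class == "fatty_acid")
  if (length(fa_cols) < 2) return(fm)
  block <- fm$values[, fa_cols, drop = FALSE]
  if (anyNA(block)) {
    stop("fatty-acid block contains missing values; impute first", call. = FALSE)
  }
  fm$values[, fa_cols] <- t(apply(block, 1, clr_transform, zero_replace = zero_replace))
  fm$compound_meta$unit[fa_cols] <- "clr"
  fm
}

#' Column-wise z-score scaling
#'
#' Centers each compound column and divides by its sample (n-1) standard
#' deviation. Constant columns cannot be scaled and are mapped to all
#' zeros with a warning.
#'
#' @param fm a `feature_matrix` without missing values, or a plain
#'   numeric matrix.
#' @return the scaled object, same type as the input.
#' @export
zscore_scale <- function(fm) {
  values <- if (inherits(fm, "feature_matrix")) fm$values else fm
  if (anyNA(values)) {
    stop("matrix contains missing values; impute before scaling", call. = FALSE)
  }
  centered <- sweep(values, 2, colMeans(values))
  sds <- apply(values, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning(
      sum(constant), " constant column(s) mapped to zero: ",
      paste(utils::head(colnames(values)[constant], 3), collapse = ", "),
      call. = FALSE
    )
    sds[constant] <- 1
  }
  scaled <- sweep(centered, 2, sds, "/")
  if (inherits(fm, "feature_matrix")) {
    fm$values <- scaled
    fm
  } else {
    scaled
  }
}

#' Forward- then backward-fill a time-ordered series
#'
#' Missing values (below-LOQ censoring at early or late storage stages)
#' are imputed by carrying the last observation forward, then filling any
#' leading gap backward from the first observation. Observed values are
#' never altered; the operation is idempotent.
#'
#' @param series numeric vector ordered by ascending day within one
#'   (oil, supplier, replicate, compound) series.
#' @param key optional label used in the all-missing error message.
#' @return the completed series.
#' @export
impute_fill <- function(series, key = NULL) {
  if (all(is.na(series))) {
    stop(
      "cannot impute an all-missing series",
      if (!is.null(key)) paste0(": ", key), call. = FALSE
    )
  }
  # forward fill
  idx <- cummax(ifelse(is.na(series), 0L, seq_along(series)))
  out <- ifelse(idx == 0L, NA, series[pmax(idx, 1L)])
  # backward fill the leading gap
  if (anyNA(out)) {
    first_obs <- which(!is.na(out))[1]
    out[seq_len(first_obs - 1)] <- out[first_obs]
  }
  out
}

#' Impute every compound series of a feature matrix
#'
#' Applies [impute_fill()] to each (supplier, replicate, compound) series
#' ordered by day.
#'
#' @param fm a `feature_matrix`.
#' @return the `feature_matrix` with no missing values.
#' @export
impute_matrix <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  bottle <- paste(fm$sample_meta$supplier_id, fm$sample_meta$replicate_id)
  for (b in unique(bottle)) {
    rows <- which(bottle == b)
    rows <- rows[order(fm$sample_meta$day[rows])]
    for (j in seq_len(ncol(fm$values))) {
      series <- fm$values[rows, j]
      if (anyNA(series)) {
        fm$values[rows, j] <- impute_fill(
          series,
          key = paste(b, colnames(fm$values)[j])
        )
      }
    }
  }
  fm
}

# two-sided single-outlier Grubbs critical value
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(1 - alpha / (2 * n), df = n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Grubbs single-outlier screen
#'
#' Two-sided Grubbs test on one replicate group (the values of one
#' compound at one oil x day): `G = max|x - mean| / sd` compared with the
#' critical value at `alpha`. At most one value is flagged per group and
#' pass; a constant group (sd = 0) or a group smaller than 3 yields no
#' flag (the latter with a warning). Flagged values should be set missing
#' and re-imputed.
#'
#' @param group numeric replicate values.
#' @param alpha significance level (default 0.05).
#' @return logical vector: `TRUE` marks the flagged outlier.
#' @export
grubbs_screen <- function(group, alpha = 0.05) {
  flags <- rep(FALSE, length(group))
  obs <- which(!is.na(group))
  if (length(obs) < 3) {
    warning("Grubbs screen skipped: fewer than 3 observations", call. = FALSE)
    return(flags)
  }
  x <- group[obs]
  s <- stats::sd(x)
  if (s == 0) return(flags)
  dev <- abs(x - mean(x))
  g <- max(dev) / s
  if (g > grubbs_critical(length(x), alpha)) {
    flags[obs[which.max(dev)]] <- TRUE
  }
  flags
}

#' Screen a feature matrix for replicate outliers
#'
#' Runs [grubbs_screen()] on every (day, compound) replicate group and
#' sets flagged values to missing.
#'
#' @param fm a `feature_matrix`.
#' @param alpha significance level.
#' @return list with the screened `feature_matrix` (`fm`) and the number
#'   of flagged cells (`n_flagged`).
#' @export
grubbs_screen_matrix <- function(fm, alpha = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  n_flagged <- 0L
  for (d in unique(fm$sample_meta$day)) {
    rows <- which(fm$sample_meta$day == d)
    if (length(rows) < 3) next
    for (j in seq_len(ncol(fm$values))) {
      flags <- suppressWarnings(grubbs_screen(fm$values[rows, j], alpha))
      if (any(flags)) {
        fm$values[rows[flags], j] <- NA_real_
        n_flagged <- n_flagged + sum(flags)
      }
    }
  }
  list(fm = fm, n_flagged = n_flagged)
}

#' Principal component summary
#'
#' PCA of a (z-scored) feature matrix for cluster visualisation and
#' variance bookkeeping. Columns are centered (a no-op after z-scoring);
#' variance fractions are eigenvalue shares of the total variance, so the
#' full-rank set sums to 1 and scores times transposed loadings plus the
#' center reconstructs the input.
#'
#' @param fm a `feature_matrix` or numeric matrix without missing values.
#' @param n_components number of components to keep.
#' @return list of class `"pca_summary"`: `scores`
#'   (n_samples x n_components), `loadings` (n_compounds x n_components),
#'   `variance_fraction`, `center`.
#' @export
pca_summary <- function(fm, n_components = 2L) {
  values <- if (inherits(fm, "feature_matrix")) fm$values else fm
  if (anyNA(values)) stop("matrix contains missing values", call. = FALSE)
  if (n_components > min(dim(values))) {
    stop("n_components exceeds min(n_samples, n_compounds)", call. = FALSE)
  }
  fit <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  structure(
    list(
      scores = fit$x[, keep, drop = FALSE],
      loadings = fit$rotation[, keep, drop = FALSE],
      variance_fraction = fit$sdev[keep]^2 / sum(fit$sdev^2),
      center = fit$center
    ),
    class = "pca_summary"
  )
}

#' Full preprocessing of one oil type
#'
#' The fixed order of operations: below-LOQ entries arrive as missing from
#' [pivot_to_matrix()]; Grubbs outlier screening (so imputed values cannot
#' mask outliers); forward/backward imputation; CLR on the fatty-acid
#' block; z-score scaling. Deterministic throughout.
#'
#' @param fm a `feature_matrix` from [pivot_to_matrix()].
#' @param config a [pipeline_config()].
#' @return the preprocessed `feature_matrix`, z-scored, no missing values.
#' @export
preprocess_matrix <- function(fm, config = pipeline_config()) {
  screened <- grubbs_screen_matrix(fm, alpha = config$alpha_grubbs)
  fm <- impute_matrix(screened$fm)
  fm <- clr_fatty_acids(fm)
  suppressWarnings(zscore_scale(fm))
}
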