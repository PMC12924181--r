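#' LASSO coefficients and selection flags against storage time
#'
#' Fits an L1-penalized linear regression of storage day on the (z-scored)
#' compound concentrations, objective
#' `0.5 * MSE + alpha * sum(|beta|)` with a free intercept, via glmnet
#' (whose gaussian objective matches at `lambda = alpha` with
#' standardization off). A compound is selected when its absolute
#' coefficient reaches `threshold_frac` of the block's maximum absolute
#' coefficient; an all-zero fit selects nothing.
#'
#' @param features numeric matrix (samples x compounds), z-scored, no
#'   missing values.
#' @param response storage day per sample.
#' @param alpha L1 regularization weight (> 0).
#' @param threshold_frac selection threshold as a fraction of the maximum
#'   absolute coefficient.
#' @param cv if `TRUE`, choose `alpha` by 5-fold CV over 10 log-spaced
#'   values around the supplied one (seed the RNG beforehand).
#' @return tibble with `compound`, `lasso_coef`, `lasso_selected`.
#' @export
lasso_metrics <- function(features, response, alpha = 0.01,
                          threshold_frac = 0.20, cv = FALSE) {
  check_block(features, response)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (ncol(features) == 1) {
    # glmnet requires >= 2 columns; pad with a zero column it cannot use
    features <- cbind(features, .pad = 0)
  }
  if (cv) {
    grid <- alpha * 10^seq(-2, 2, length.out = 10)
    fit_cv <- glmnet::cv.glmnet(features, response,
      lambda = sort(grid, decreasing = TRUE),
      nfolds = 5, standardize = FALSE
    )
    alpha <- fit_cv$lambda.min
  }
  fit <- glmnet::glmnet(features, response,
    lambda = alpha, standardize = FALSE, intercept = TRUE
  )
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  beta <- beta[setdiff(names(beta), ".pad")]
  max_abs <- max(abs(beta))
  selected <- if (max_abs == 0) {
    rep(FALSE, length(beta))
  } else {
    abs(beta) >= threshold_frac * max_abs
  }
  tibble::tibble(
    compound = names(beta),
    lasso_coef = unname(beta),
    lasso_selected = selected
  )
}

#' Random-forest importances and selection flags against storage time
#'
#' An ensemble of `n_estimators` regression trees predicts storage day
#' from the compound concentrations; impurity-based (node purity)
#' importances are normalized to sum to 1. A compound is selected when its
#' importance reaches `threshold_frac` of the block maximum. The seed
#' makes the ensemble reproducible.
#'
#' @inheritParams lasso_metrics
#' @param n_estimators number of trees (default 100).
#' @param threshold_frac selection threshold as a fraction of the maximum
#'   importance.
#' @param seed integer seed (mandatory).
#' @return tibble with `compound`, `rfr_importance`, `rfr_selected`.
#' @export
rfr_metrics <- function(features, response, n_estimators = 100L,
                        threshold_frac = 0.10, seed) {
  check_block(features, response)
  if (n_estimators < 1) stop("`n_estimators` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = as.data.frame(features), y = response,
    ntree = as.integer(n_estimators), importance = FALSE
  )
  imp <- fit$importance[, "IncNodePurity"]
  imp <- pmax(imp, 0)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  selected <- if (max(imp) == 0) {
    rep(FALSE, length(imp))
  } else {
    imp >= threshold_frac * max(imp)
  }
  tibble::tibble(
    compound = colnames(features),
    rfr_importance = unname(imp),
    rfr_selected = unname(selected)
  )
}

#' Spearman rank correlation with storage time
#'
#' Monotone-trend screen: rho is the Pearson correlation of mid-ranks
#' (average ranks for ties); the p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' A zero-variance input is degenerate: rho is reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param feature compound concentration vector.
#' @param response storage day vector, same length, >= 3 pairs.
#' @return list with `rho`, `p`, `degenerate`.
#' @export
spearman_metrics <- function(feature, response) {
  ok <- is.finite(feature) & is.finite(response)
  feature <- feature[ok]
  response <- response[ok]
  n <- length(feature)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(feature) == 0 || stats::sd(response) == 0) {
    return(list(rho = 0, p = 1, degenerate = TRUE))
  }
  rho <- stats::cor(rank(feature), rank(response))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

check_block <- function(features, response) {
  if (!is.matrix(features)) stop("`features` must be a matrix", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features))) {
    stop("`features` contains non-finite entries", call. = FALSE)
  }
  if (length(response) != nrow(features)) {
    stop("`response` length must match rows of `features`", call. = FALSE)
  }
  if (nrow(features) <= 2) stop("need more than 2 samples", call. = FALSE)
  if (is.null(colnames(features))) {
    stop("`features` needs compound column names", call. = FALSE)
  }
  invisible(TRUE)
}

#' All three selection metrics per (oil type, compound class) block
#'
#' Runs [lasso_metrics()] and [rfr_metrics()] on each compound-class block
#' of a preprocessed feature matrix (models are fit per oil type and
#' class) and [spearman_metrics()] per compound, and returns one row per
#' compound.
#'
#' @param fm a preprocessed (z-scored, complete) `feature_matrix` of one
#'   oil type, from [preprocess_matrix()].
#' @param config a [pipeline_config()].
#' @return tibble with one row per compound: `oil_type`, `compound_class`,
#'   `compound`, `lasso_coef`, `lasso_selected`, `rfr_importance`,
#'   `rfr_selected`, `spearman_rho`, `spearman_p`, `spearman_degenerate`.
#' @export
selection_metrics <- function(fm, config = pipeline_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  oil <- unique(fm$sample_meta$oil_type)
  if (length(oil) != 1) stop("feature matrix must hold one oil type", call. = FALSE)
  response <- as.numeric(fm$sample_meta$day)

  blocks <- split(
    seq_len(ncol(fm$values)),
    metric_block(fm$compound_meta$compound_class)
  )
  per_block <- lapply(blocks, function(cols) {
    block <- fm$values[, cols, drop = FALSE]
    lasso <- lasso_metrics(block, response,
      alpha = config$lasso_alpha,
      threshold_frac = config$lasso_threshold_frac,
      cv = config$lasso_cv
    )
    rfr <- rfr_metrics(block, response,
      n_estimators = config$rfr_n_estimators,
      threshold_frac = config$rfr_threshold_frac,
      seed = config$seed
    )
    dplyr::inner_join(lasso, rfr, by = "compound")
  })
  metrics <- dplyr::bind_rows(per_block)

  spearman <- lapply(seq_len(ncol(fm$values)), function(j) {
    s <- spearman_metrics(fm$values[, j], response)
    tibble::tibble(
      compound = colnames(fm$values)[j],
      spearman_rho = s$rho, spearman_p = s$p, spearman_degenerate = s$degenerate
    )
  })
  metrics <- dplyr::inner_join(metrics, dplyr::bind_rows(spearman), by = "compound")

  out <- tibble::tibble(
    oil_type = oil,
    compound = fm$compound_meta$compound,
    compound_class = fm$compound_meta$compound_class
  )
  dplyr::inner_join(out, metrics, by = "compound")
}

# model-fit blocks: fatty acids / polyphenols / volatiles
metric_block <- function(compound_class) {
  ifelse(compound_class %in% POLYPHENOL_CLASSES, "polyphenol", compound_class)
}

#' Write the selection metrics table
#'
#' One CSV row per (oil type, class, compound) with coefficient,
#' importance, correlation and selection flags.
#'
#' @param metrics tibble from [selection_metrics()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}
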