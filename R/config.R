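#' Pipeline configuration
#'
#' Bundles every tunable of the scoring pipeline. Defaults follow common
#' practice for this analysis: LASSO regularization weight 0.01 with a
#' selection threshold at 20% of the maximum absolute coefficient, a
#' 100-tree random forest with a threshold at 10% of the maximum
#' importance, and composite weights of 0.4 (RFR), 0.4 (LASSO) and
#' 0.2 (Spearman correlation).
#'
#' @param lasso_alpha L1 regularization weight (objective
#'   `0.5 * MSE + alpha * sum(|beta|)`). Must be > 0.
#' @param lasso_threshold_frac fraction of the maximum absolute LASSO
#'   coefficient a compound must reach to be selected, in (0, 1).
#' @param rfr_n_estimators number of regression trees.
#' @param rfr_threshold_frac fraction of the maximum importance a compound
#'   must reach to be selected, in (0, 1).
#' @param weights named numeric triplet `c(rfr=, lasso=, corr=)`, summing
#'   to 1, used by the composite score.
#' @param seed integer seed; required by every stochastic step.
#' @param alpha_grubbs significance level of the Grubbs outlier screen.
#' @param significance_level level used by ANOVA/Tukey summaries.
#' @param gate_nonselected if `TRUE` (default) a metric contributes 0 to
#'   the composite score for compounds its significance threshold did not
#'   select.
#' @param normalization_group `"class"` (default) min-max normalizes
#'   metrics within each (oil type, compound class) block, matching the
#'   per-class model fits; `"oil"` pools all classes of an oil type.
#' @param zscore_scope `"oil"` (default) z-scores within oil type,
#'   `"global"` across the pooled dataset.
#' @param lasso_cv if `TRUE`, pick `lasso_alpha` by 5-fold cross-validation
#'   over 10 log-spaced values instead of the fixed default.
#' @param aggregate_bottles `"raw"` (default) keeps every bottle
#'   observation; `"mean"` averages analytical values per bottle first.
#'
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(lasso_alpha = 0.01,
                            lasso_threshold_frac = 0.20,
                            rfr_n_estimators = 100L,
                            rfr_threshold_frac = 0.10,
                            weights = c(rfr = 0.4, lasso = 0.4, corr = 0.2),
                            seed = 1L,
                            alpha_grubbs = 0.05,
                            significance_level = 0.05,
                            gate_nonselected = TRUE,
                            normalization_group = c("class", "oil"),
                            zscore_scope = c("oil", "global"),
                            lasso_cv = FALSE,
                            aggregate_bottles = c("raw", "mean")) {
  normalization_group <- match.arg(normalization_group)
  zscore_scope <- match.arg(zscore_scope)
  aggregate_bottles <- match.arg(aggregate_bottles)
  if (lasso_alpha <= 0) stop("`lasso_alpha` must be > 0", call. = FALSE)
  for (fr in c(lasso_threshold_frac, rfr_threshold_frac)) {
    if (!is.finite(fr) || fr <= 0 || fr >= 1) {
      stop("threshold fractions must lie in (0, 1)", call. = FALSE)
    }
  }
  if (rfr_n_estimators < 1) stop("`rfr_n_estimators` must be >= 1", call. = FALSE)
  weights <- validate_weights(weights)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(
      lasso_alpha = lasso_alpha,
      lasso_threshold_frac = lasso_threshold_frac,
      rfr_n_estimators = as.integer(rfr_n_estimators),
      rfr_threshold_frac = rfr_threshold_frac,
      weights = weights,
      seed = as.integer(seed),
      alpha_grubbs = alpha_grubbs,
      significance_level = significance_level,
      gate_nonselected = isTRUE(gate_nonselected),
      normalization_group = normalization_group,
      zscore_scope = zscore_scope,
      lasso_cv = isTRUE(lasso_cv),
      aggregate_bottles = aggregate_bottles
    ),
    class = "pipeline_config"
  )
}

validate_weights <- function(weights) {
  if (is.null(names(weights))) names(weights) <- c("rfr", "lasso", "corr")
  weights <- weights[c("rfr", "lasso", "corr")]
  if (anyNA(weights)) {
    stop("`weights` must name rfr, lasso and corr", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("`weights` must sum to 1", call. = FALSE)
  }
  weights
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors [pipeline_config()]: any subset of its arguments may
#' appear; missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$weights)) raw$weights <- unlist(raw$weights)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$weights <- as.list(out$weights)
  yaml::write_yaml(out, path)
  invisible(path)
}
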