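#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; the maximum maps to 1 and the minimum to 0.
#' A degenerate vector (all values equal) maps to all zeros with a
#' warning.
#'
#' @param values numeric vector with at least one finite value.
#' @return vector in [0, 1].
#' @export
minmax_normalize <- function(values) {
  if (length(values) == 0 || !any(is.finite(values))) {
    stop("need at least one finite value", call. = FALSE)
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("degenerate min-max normalization: all values equal, mapped to 0",
      call. = FALSE
    )
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Weighted composite biomarker score
#'
#' Combines the three min-max-normalized metrics with the configured
#' weights (default 0.4 random-forest importance, 0.4 absolute LASSO
#' coefficient, 0.2 absolute Spearman correlation). A compound maximal in
#' all three metrics scores exactly 1.
#'
#' @param norm_rfr,norm_lasso,norm_corr normalized metrics in [0, 1]
#'   (vectorized).
#' @param weights named triplet summing to 1 (see [pipeline_config()]).
#' @return weighted score(s) in [0, 1].
#' @export
composite_score <- function(norm_rfr, norm_lasso, norm_corr,
                            weights = c(rfr = 0.4, lasso = 0.4, corr = 0.2)) {
  weights <- validate_weights(weights)
  for (v in list(norm_rfr, norm_lasso, norm_corr)) {
    if (any(v < -1e-12 | v > 1 + 1e-12)) {
      stop("normalized metrics must lie in [0, 1]", call. = FALSE)
    }
  }
  weights[["rfr"]] * norm_rfr + weights[["lasso"]] * norm_lasso +
    weights[["corr"]] * norm_corr
}

#' Rank compounds of one oil type by composite biomarker score
#'
#' Raw metrics per compound are the absolute LASSO coefficient, the
#' random-forest importance and the absolute Spearman rho; by default a
#' metric whose significance threshold did not select the compound
#' contributes 0 (`gate_nonselected`). Each metric is min-max normalized
#' within its normalization group (per class block by default, matching
#' the per-class model fits) and combined with the configured weights.
#' Compounds are sorted by score descending with a deterministic
#' tie-break: class order as in [COMPOUND_CLASSES], then compound name.
#' The trend is `"up"` for rho > 0, `"down"` for rho < 0, `"flat"` when
#' degenerate.
#'
#' @param metrics tibble from [selection_metrics()] for one oil type.
#' @param config a [pipeline_config()].
#' @return a `biomarker_scores` tibble: `oil_type`, `compound`,
#'   `compound_class`, `norm_rfr`, `norm_lasso`, `norm_corr`,
#'   `weighted_score`, `trend`, `rank`.
#' @export
rank_biomarkers <- function(metrics, config = pipeline_config()) {
  if (nrow(metrics) == 0) stop("no metrics to rank", call. = FALSE)
  if (length(unique(metrics$oil_type)) != 1) {
    stop("metrics must cover exactly one oil type", call. = FALSE)
  }
  gate <- function(raw, selected) {
    if (config$gate_nonselected) ifelse(selected, raw, 0) else raw
  }
  raw_rfr <- gate(metrics$rfr_importance, metrics$rfr_selected)
  raw_lasso <- gate(abs(metrics$lasso_coef), metrics$lasso_selected)
  raw_corr <- abs(metrics$spearman_rho)

  group <- if (config$normalization_group == "class") {
    metric_block(metrics$compound_class)
  } else {
    rep("all", nrow(metrics))
  }
  norm_by_group <- function(raw) {
    out <- numeric(length(raw))
    for (g in unique(group)) {
      idx <- group == g
      out[idx] <- suppressWarnings(minmax_normalize(raw[idx]))
    }
    out
  }
  norm_rfr <- norm_by_group(raw_rfr)
  norm_lasso <- norm_by_group(raw_lasso)
  norm_corr <- norm_by_group(raw_corr)

  scores <- tibble::tibble(
    oil_type = metrics$oil_type,
    compound = metrics$compound,
    compound_class = metrics$compound_class,
    norm_rfr = norm_rfr,
    norm_lasso = norm_lasso,
    norm_corr = norm_corr,
    weighted_score = composite_score(norm_rfr, norm_lasso, norm_corr,
      weights = config$weights
    ),
    trend = ifelse(metrics$spearman_degenerate, "flat",
      ifelse(metrics$spearman_rho > 0, "up", "down")
    )
  )
  scores <- order_scores(scores)
  scores$rank <- seq_len(nrow(scores))
  class(scores) <- c("biomarker_scores", class(scores))
  scores
}

#' Top-k fingerprint report across oil types
#'
#' Assembles the ranked-fingerprint table: per oil type the `top_k`
#' highest-scoring compounds with substance type, substance, weighted
#' score (3 decimals) and trend arrow.
#'
#' @param scores a `biomarker_scores` tibble, or a list of them (one per
#'   oil type).
#' @param top_k rows to keep per oil type (>= 1).
#' @param markdown if `TRUE`, return a Markdown table string instead of a
#'   tibble.
#' @return a tibble (or Markdown string) mirroring the ranked-table
#'   layout.
#' @export
fingerprint_report <- function(scores, top_k = 6L, markdown = FALSE) {
  if (top_k < 1) stop("`top_k` must be >= 1", call. = FALSE)
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- dplyr::bind_rows(scores)
  }
  out <- scores |>
    dplyr::group_by(.data$oil_type) |>
    dplyr::slice_min(.data$rank, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      oil_type = .data$oil_type,
      substance_type = .data$compound_class,
      substance = .data$compound,
      weighted_score = sprintf("%.3f", .data$weighted_score),
      trend = trend_arrow(.data$trend)
    )
  if (!markdown) return(out)
  header <- paste(
    "| Oil Type | Substance Type | Substance | Weighted Score | Trend |",
    "|---|---|---|---|---|",
    sep = "\n"
  )
  rows <- sprintf(
    "| %s | %s | %s | %s | %s |",
    out$oil_type, out$substance_type, out$substance, out$weighted_score,
    out$trend
  )
  paste(c(header, rows), collapse = "\n")
}
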