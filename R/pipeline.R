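#' Run the full biomarker pipeline on a concentration dataset
#'
#' For each oil type present in `records`: pivot to a feature matrix,
#' preprocess (Grubbs screen, forward/backward imputation, CLR on fatty
#' acids, z-score), compute the three selection metrics per class block,
#' and rank compounds by weighted composite score. With
#' `config$aggregate_bottles = "mean"`, analytical replicates sharing a
#' (supplier, replicate, day, compound) cell are averaged before pivoting.
#'
#' @param records concentration records (long format).
#' @param config a [pipeline_config()].
#' @return list with `metrics` (one tibble over all oil types) and
#'   `scores` (named list of `biomarker_scores`, one per oil type).
#' @export
run_biomarker_pipeline <- function(records, config = pipeline_config()) {
  records <- validate_records(records, schedule = NULL)
  if (config$aggregate_bottles == "mean") {
    records <- records |>
      dplyr::group_by(
        .data$oil_type, .data$supplier_id, .data$replicate_id, .data$day,
        .data$compound, .data$compound_class, .data$unit
      ) |>
      dplyr::summarise(
        below_loq = all(.data$below_loq),
        value = if (all(is.na(.data$value))) NA_real_ else {
          mean(.data$value, na.rm = TRUE)
        },
        .groups = "drop"
      )
  }
  oils <- intersect(OIL_TYPES, unique(records$oil_type))

  global_stats <- NULL
  if (config$zscore_scope == "global") {
    pooled <- dplyr::bind_rows(lapply(oils, function(oil) {
      fm <- impute_matrix(grubbs_screen_matrix(
        pivot_to_matrix(records, oil),
        alpha = config$alpha_grubbs
      )$fm)
      fm <- clr_fatty_acids(fm)
      tibble::tibble(
        compound = rep(colnames(fm$values), each = nrow(fm$values)),
        value = as.vector(fm$values)
      )
    }))
    global_stats <- pooled |>
      dplyr::group_by(.data$compound) |>
      dplyr::summarise(
        mu = mean(.data$value), sigma = stats::sd(.data$value),
        .groups = "drop"
      )
  }

  per_oil <- lapply(oils, function(oil) {
    fm <- pivot_to_matrix(records, oil)
    if (config$zscore_scope == "global") {
      fm <- impute_matrix(grubbs_screen_matrix(fm, alpha = config$alpha_grubbs)$fm)
      fm <- clr_fatty_acids(fm)
      idx <- match(colnames(fm$values), global_stats$compound)
      sigma <- ifelse(global_stats$sigma[idx] > 0, global_stats$sigma[idx], 1)
      fm$values <- sweep(
        sweep(fm$values, 2, global_stats$mu[idx]), 2, sigma, "/"
      )
    } else {
      fm <- preprocess_matrix(fm, config)
    }
    metrics <- selection_metrics(fm, config)
    list(metrics = metrics, scores = rank_biomarkers(metrics, config))
  })
  names(per_oil) <- oils

  list(
    metrics = dplyr::bind_rows(lapply(per_oil, `[[`, "metrics")),
    scores = lapply(per_oil, `[[`, "scores")
  )
}

#' Simulate a dataset and write it, with its config, to a directory
#'
#' Convenience wrapper joining [default_oil_profiles()],
#' [generate_storage_dataset()] and [write_concentration_table()].
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param noise a [noise_model()].
#' @param profiles list of [oil_profile()]s.
#' @param schedule sampling days.
#' @return path of the written CSV, invisibly.
#' @export
simulate_to_dir <- function(out_dir, seed, noise = noise_model(),
                            profiles = default_oil_profiles(),
                            schedule = DEFAULT_SCHEDULE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- generate_storage_dataset(profiles,
    noise = noise, schedule = schedule, seed = seed
  )
  path <- file.path(out_dir, "concentrations.csv")
  write_concentration_table(records, path)
  invisible(path)
}

#' Score a dataset and write the output tables
#'
#' Runs [run_biomarker_pipeline()] and writes `metrics.csv` and
#' `ranked_biomarkers.csv` into `out_dir`.
#'
#' @param records concentration records or a path to a canonical CSV.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @return the pipeline result list, invisibly.
#' @export
score_to_dir <- function(records, out_dir, config = pipeline_config()) {
  if (is.character(records)) records <- read_concentration_table(records)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_biomarker_pipeline(records, config)
  write_metrics_table(res$metrics, file.path(out_dir, "metrics.csv"))
  write_ranked_table(
    dplyr::bind_rows(res$scores),
    file.path(out_dir, "ranked_biomarkers.csv")
  )
  invisible(res)
}
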