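#' Concentration records: the long-format data model
#'
#' One record is one measured concentration of one compound in one bottle
#' (oil type x supplier x replicate) at one sampling day. Below-LOQ
#' observations carry `below_loq = TRUE` and a missing `value`; they are
#' never encoded as a substituted number. Units are metadata: mg/g oil for
#' fatty acids, ug/g oil for polyphenol classes, ppm for volatiles. Mixing
#' units within a compound class is an error.
#'
#' @param records a data frame with columns `oil_type`, `supplier_id`,
#'   `replicate_id`, `day`, `compound`, `compound_class`, `value`, `unit`,
#'   `below_loq`.
#' @param schedule permitted sampling days; records outside it fail
#'   validation. `NULL` disables the check.
#' @return the validated records as a tibble, invisibly for the validator.
#' @export
validate_records <- function(records, schedule = DEFAULT_SCHEDULE) {
  required <- c(
    "oil_type", "supplier_id", "replicate_id", "day", "compound",
    "compound_class", "value", "unit", "below_loq"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- tibble::as_tibble(records)

  bad_oil <- !records$oil_type %in% OIL_TYPES
  if (any(bad_oil)) {
    stop("unknown oil_type at row(s) ", paste(which(bad_oil)[1:min(3, sum(bad_oil))],
      collapse = ", "
    ), call. = FALSE)
  }
  bad_class <- !records$compound_class %in% COMPOUND_CLASSES
  if (any(bad_class)) {
    stop("unknown compound_class '", records$compound_class[which(bad_class)[1]],
      "' at row ", which(bad_class)[1],
      call. = FALSE
    )
  }
  neg <- !is.na(records$value) & records$value < 0
  if (any(neg)) {
    stop("negative concentration at row ", which(neg)[1], call. = FALSE)
  }
  if (!is.null(schedule)) {
    bad_day <- !records$day %in% schedule
    if (any(bad_day)) {
      stop("day outside the sampling schedule at row ", which(bad_day)[1],
        call. = FALSE
      )
    }
  }
  quantified_censored <- records$below_loq & !is.na(records$value)
  if (any(quantified_censored)) {
    stop("below_loq = TRUE with a quantified value at row ",
      which(quantified_censored)[1],
      call. = FALSE
    )
  }
  units_per_class <- tapply(records$unit, records$compound_class,
    function(u) length(unique(u)),
    default = 0L
  )
  if (any(units_per_class > 1)) {
    stop("mixed units within compound_class '",
      names(units_per_class)[which(units_per_class > 1)[1]], "'",
      call. = FALSE
    )
  }
  invisible(records)
}

#' Read a long-format concentration table
#'
#' Reads the canonical CSV interchange format (UTF-8, header row). Empty
#' value cells and a configurable below-LOQ token map to
#' `below_loq = TRUE` with a missing value.
#'
#' @param path CSV file.
#' @param schema optional named character vector mapping the canonical
#'   column names to the file's column names, e.g.
#'   `c(supplier_id = "producer")`.
#' @param loq_token text marking a censored cell in the value column
#'   (besides an empty cell); default `"<LOQ"`.
#' @param delim field delimiter.
#' @param schedule passed to [validate_records()].
#' @return a tibble of validated concentration records.
#' @export
read_concentration_table <- function(path, schema = NULL, loq_token = "<LOQ",
                                     delim = ",", schedule = DEFAULT_SCHEDULE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      if (!schema[[canonical]] %in% names(raw)) {
        stop("schema column '", schema[[canonical]], "' not in file", call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  required <- c(
    "oil_type", "supplier_id", "replicate_id", "day", "compound",
    "compound_class", "value", "unit"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  value_chr <- trimws(ifelse(is.na(raw$value), "", raw$value))
  censored <- value_chr == "" | value_chr == loq_token
  if ("below_loq" %in% names(raw)) {
    censored <- censored | tolower(trimws(raw$below_loq)) %in% c("true", "1", "yes")
  }
  value <- suppressWarnings(as.numeric(value_chr))
  unparseable <- !censored & is.na(value)
  if (any(unparseable)) {
    stop("unparseable value '", value_chr[which(unparseable)[1]], "' at row ",
      which(unparseable)[1],
      call. = FALSE
    )
  }
  value[censored] <- NA_real_
  records <- tibble::tibble(
    oil_type = raw$oil_type,
    supplier_id = raw$supplier_id,
    replicate_id = raw$replicate_id,
    day = as.integer(raw$day),
    compound = raw$compound,
    compound_class = raw$compound_class,
    value = value,
    unit = raw$unit,
    below_loq = censored
  )
  validate_records(records, schedule = schedule)
  records
}

#' Write concentration records to the canonical CSV
#'
#' Below-LOQ records are written with an empty value cell and
#' `below_loq = TRUE`, so that a read round-trip reproduces the records
#' exactly.
#'
#' @param records validated concentration records.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(records, path) {
  validate_records(records, schedule = NULL)
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Pivot long records into a samples-by-compounds feature matrix
#'
#' Rows are bottles at sampling days, one per (supplier, replicate, day);
#' columns are compounds ordered by class (in the [COMPOUND_CLASSES]
#' order) then name, so the layout is deterministic. Missing combinations
#' and below-LOQ entries become `NA` (impute before modelling).
#'
#' @param records validated concentration records.
#' @param oil_type single oil type code to extract.
#' @return a `feature_matrix`: list with `values` (numeric matrix),
#'   `sample_meta` and `compound_meta` tibbles.
#' @export
pivot_to_matrix <- function(records, oil_type) {
  records <- validate_records(records, schedule = NULL)
  records <- records[records$oil_type == oil_type, ]
  if (nrow(records) == 0) {
    stop("no records for oil_type '", oil_type, "'", call. = FALSE)
  }
  key <- paste(records$supplier_id, records$replicate_id, records$day,
    records$compound,
    sep = "\r"
  )
  dup <- duplicated(key)
  if (any(dup)) {
    clash <- records[key %in% key[dup], ]
    vals <- tapply(clash$value, key[key %in% key[dup]], function(v) {
      length(unique(v[!is.na(v)]))
    })
    if (any(vals > 1)) {
      stop("conflicting duplicate (sample, compound) values in input", call. = FALSE)
    }
    records <- records[!dup, ]
  }

  compound_meta <- unique(records[, c("compound", "compound_class", "unit")])
  compound_meta <- compound_meta[order(
    match(compound_meta$compound_class, COMPOUND_CLASSES),
    compound_meta$compound
  ), ]
  sample_meta <- unique(records[, c("oil_type", "supplier_id", "replicate_id", "day")])
  sample_meta <- sample_meta[order(
    sample_meta$supplier_id, sample_meta$replicate_id, sample_meta$day
  ), ]

  values <- matrix(NA_real_,
    nrow = nrow(sample_meta), ncol = nrow(compound_meta),
    dimnames = list(NULL, compound_meta$compound)
  )
  row_key <- paste(sample_meta$supplier_id, sample_meta$replicate_id,
    sample_meta$day,
    sep = "\r"
  )
  rec_row <- match(
    paste(records$supplier_id, records$replicate_id, records$day, sep = "\r"),
    row_key
  )
  rec_col <- match(records$compound, compound_meta$compound)
  values[cbind(rec_row, rec_col)] <- records$value

  new_feature_matrix(values, sample_meta, compound_meta)
}

new_feature_matrix <- function(values, sample_meta, compound_meta) {
  stopifnot(
    nrow(values) == nrow(sample_meta),
    ncol(values) == nrow(compound_meta)
  )
  structure(
    list(
      values = values,
      sample_meta = tibble::as_tibble(sample_meta),
      compound_meta = tibble::as_tibble(compound_meta)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(
    "<feature_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
    " compounds (", sum(is.na(x$values)), " missing)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Write / read a ranked biomarker table
#'
#' The written CSV mirrors the ranked fingerprint layout: one row per
#' compound with `oil_type`, `substance_type`, `substance`,
#' `weighted_score` (3 decimals) and a `trend` arrow (up-arrow for
#' concentrations rising with storage time, down-arrow for falling,
#' right-arrow for a degenerate flat trend). Rows are ordered by score
#' descending with a deterministic tie-break (class order, then name).
#'
#' @param scores a `biomarker_scores` tibble from [rank_biomarkers()],
#'   or any tibble with the columns named above plus `trend` in
#'   `c("up","down","flat")`.
#' @param path output CSV.
#' @return `path` invisibly; `read_ranked_table()` returns the table.
#' @export
write_ranked_table <- function(scores, path) {
  if (nrow(scores) == 0) {
    warning("writing an empty ranked table (header only)", call. = FALSE)
    out <- tibble::tibble(
      oil_type = character(), substance_type = character(),
      substance = character(), weighted_score = character(),
      trend = character()
    )
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(path))
  }
  scores <- order_scores(scores)
  out <- tibble::tibble(
    oil_type = scores$oil_type,
    substance_type = scores$compound_class,
    substance = scores$compound,
    weighted_score = sprintf("%.3f", scores$weighted_score),
    trend = trend_arrow(scores$trend)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ranked_table
#' @export
read_ranked_table <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      weighted_score = readr::col_double(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
}

trend_arrow <- function(trend) {
  c(up = "↑", down = "↓", flat = "→")[trend]
}

order_scores <- function(scores) {
  scores[order(
    scores$oil_type,
    -scores$weighted_score,
    match(scores$compound_class, COMPOUND_CLASSES),
    scores$compound
  ), ]
}
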