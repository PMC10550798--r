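# Tabular interchange formats. CSV in, TSV out. Undetermined Cq is always
# represented as a missing value, never as a sentinel such as 40 or 0, because
# sentinels corrupt the medians and SDs used throughout the pipeline.
# Percentages are on the 0--100 scale everywhere.

fluor_cols <- c("sample_id", "card", "well", "target_id", "cycle", "rn")

#' Read a long-format fluorescence table
#'
#' Reads a CSV with one row per cycle (`sample_id, card, well, target_id,
#' cycle, rn`), groups rows into amplification curves and validates each
#' curve's cycle axis: no duplicated cycles, strictly increasing with no gaps.
#'
#' @param path Path to the CSV file.
#' @return A long curve tibble suitable for [subtract_baseline()] and
#'   [call_cq()].
#' @export
read_fluorescence_long <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(fluor_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("Fluorescence file is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  df <- df |> select(all_of(fluor_cols)) |>
    mutate(card = as.character(.data$card), cycle = as.integer(.data$cycle))
  if (any(!is.finite(df$rn))) abort("Non-finite fluorescence values in file.")
  dup <- df |>
    dplyr::count(.data$sample_id, .data$card, .data$well, .data$cycle) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("Duplicated (sample, well, cycle) rows, e.g. sample %s well %s cycle %d.",
                  dup$sample_id[1], dup$well[1], dup$cycle[1]))
  }
  bad <- df |>
    group_by(.data$sample_id, .data$card, .data$well) |>
    summarise(ok = all(diff(sort(.data$cycle)) == 1L), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad)) {
    abort(sprintf("Incomplete or non-contiguous cycles for sample %s well %s.",
                  bad$sample_id[1], bad$well[1]))
  }
  arrange(df, .data$sample_id, .data$card, .data$well, .data$cycle)
}

#' @rdname read_fluorescence_long
#' @param curves Long curve tibble to write.
#' @export
write_fluorescence_long <- function(curves, path) {
  check_curves(curves)
  readr::write_csv(curves[, fluor_cols], path, progress = FALSE)
  invisible(path)
}

#' Read a wide Cq matrix with sample metadata
#'
#' The matrix CSV has one row per target with columns `target_id`, optionally
#' `card` and `control`, then one column per sample; empty cells are
#' undetermined Cq and stay missing. The metadata CSV maps `sample_id` to
#' `group`.
#'
#' @param path Path to the wide Cq matrix CSV.
#' @param metadata_path Path to the sample metadata CSV (`sample_id,group`).
#' @return A long Cq tibble: `target_id`, `card`, `sample_id`, `group`, `cq`,
#'   `control`.
#' @export
read_cq_matrix <- function(path, metadata_path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"target_id" %in% names(wide)) {
    abort("Cq matrix must have a `target_id` column.")
  }
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta))) {
    abort("Metadata must have columns `sample_id` and `group`.")
  }
  if (!"card" %in% names(wide)) wide$card <- "A"
  if (!"control" %in% names(wide)) wide$control <- NA_character_
  sample_cols <- setdiff(names(wide), c("target_id", "card", "control"))
  if (!length(sample_cols)) abort("Cq matrix contains no sample columns.")
  orphans <- setdiff(sample_cols, meta$sample_id)
  if (length(orphans)) {
    abort(paste0("Sample(s) in matrix but absent from metadata: ",
                 paste(orphans, collapse = ", "), "."))
  }
  long <- wide |>
    tidyr::pivot_longer(all_of(sample_cols), names_to = "sample_id",
                        values_to = "cq") |>
    mutate(cq = as.numeric(.data$cq)) |>
    left_join(meta |> select("sample_id", "group"), by = "sample_id") |>
    select("target_id", "card", "sample_id", "group", "cq", "control")
  if (any(long$cq <= 0, na.rm = TRUE)) {
    abort("Cq values must be positive; found non-positive entries.")
  }
  long
}

#' @rdname read_cq_matrix
#' @param cq Long Cq tibble to write (wide on disk; missing stays blank).
#' @export
write_cq_matrix <- function(cq, path) {
  wide <- cq |>
    select("target_id", "card", "control", "sample_id", "cq") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cq") |>
    arrange(.data$card, .data$target_id)
  readr::write_csv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Serializes stability reports, expression results or any result tibble with
#' a fixed column order and deterministic row ordering: by rank column when
#' one exists (`final_rank`, else `rank`), ties and rankless tables by
#' identifier. Two runs on identical input produce byte-identical files.
#'
#' @param results A result tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  results <- as_tibble(results)
  rank_col <- intersect(c("final_rank", "rank"), names(results))[1]
  id_col <- intersect(c("target_id", "sample_id"), names(results))[1]
  ord <- list()
  if (!is.na(rank_col)) ord <- c(ord, list(results[[rank_col]]))
  if (!is.na(id_col)) ord <- c(ord, list(results[[id_col]]))
  if (length(ord)) results <- results[do.call(order, ord), , drop = FALSE]
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable post-analytical setting with the conventional
#' defaults: fixed threshold 0.2, QC gates amp_score > 1 and cq_conf > 0.8,
#' call rate >= 90%, median-Cq cutoff 32 (or `"adaptive"` to cut at the
#' median of per-target medians).
#'
#' @param threshold_method `"fixed"`, `"automatic"` or `"relative"`.
#' @param fixed_threshold Fluorescence threshold for the fixed method.
#' @param amp_score_min,cq_conf_min QC pass cutoffs.
#' @param call_rate_min Minimum call rate, percent (0--100).
#' @param median_cq_max Numeric cutoff or `"adaptive"`.
#' @param normalization `"reference"` (top-ranked stable target) or
#'   `"geomean"` (per-sample geometric-mean factor).
#' @param case,control Group labels used as case and reference group.
#' @param alpha Significance level for group-stability verdicts.
#' @param seed Integer seed recorded in run manifests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(threshold_method = c("fixed", "automatic", "relative"),
                            fixed_threshold = 0.2,
                            amp_score_min = 1.0,
                            cq_conf_min = 0.8,
                            call_rate_min = 90,
                            median_cq_max = 32,
                            normalization = c("reference", "geomean"),
                            case = "case",
                            control = "control",
                            alpha = 0.05,
                            seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  normalization <- match.arg(normalization)
  stopifnot_scalar_number(fixed_threshold, "fixed_threshold", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(amp_score_min, "amp_score_min", min = 0)
  stopifnot_scalar_number(cq_conf_min, "cq_conf_min", min = 0)
  stopifnot_scalar_number(call_rate_min, "call_rate_min", min = 0)
  if (!identical(median_cq_max, "adaptive")) {
    stopifnot_scalar_number(median_cq_max, "median_cq_max", min = 0, strict_min = TRUE)
  }
  structure(
    list(
      threshold_method = threshold_method,
      fixed_threshold = fixed_threshold,
      amp_score_min = amp_score_min,
      cq_conf_min = cq_conf_min,
      call_rate_min = call_rate_min,
      median_cq_max = median_cq_max,
      normalization = normalization,
      case = case,
      control = control,
      alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}
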