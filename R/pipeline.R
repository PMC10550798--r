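# End-to-end orchestration of the post-analytical flow, in the fixed stage
# order: Cq calling -> curve QC gating -> call-rate filter -> median-Cq
# filter -> reference stability / normalization -> relative expression. Every
# stage that drops targets or samples records what and why in the run
# manifest; identical config + inputs + seed produce byte-identical outputs.

#' Run the full post-analytical pipeline
#'
#' Executes the stages in the documented order, starting either from raw
#' amplification curves (full path: call, QC, filter, stability,
#' normalization, expression) or from an existing Cq table (the calling stage
#' is skipped). The three-method threshold comparison is a fan-out: run the
#' pipeline once per threshold method and feed the results to
#' [compare_thresholds()] / [cross_method_agreement()].
#'
#' @param config A [pipeline_config()].
#' @param curves Long curve tibble (full path), or `NULL`.
#' @param cq Long Cq tibble (matrix entry point), or `NULL`; exactly one of
#'   `curves`/`cq` must be supplied.
#' @param metadata Tibble `sample_id`, `group` (required with `curves`).
#' @param layout Optional card layout with control flags ([card_layout()]).
#' @param out_dir Optional output directory; when given, the Cq matrix,
#'   call-rate table, stability report, normalization factors, expression
#'   results and a JSON run manifest are written there deterministically.
#' @param input_paths Optional named character vector of input file paths;
#'   their MD5 digests are recorded in the manifest.
#' @return A list of class `pipeline_result`: `cq` (QC-annotated),
#'   `cq_filtered`, `call_rate_table`, `stability`, `normalization`,
#'   `expression`, `manifest`.
#' @export
run_pipeline <- function(config, curves = NULL, cq = NULL, metadata = NULL,
                         layout = NULL, out_dir = NULL, input_paths = NULL) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  if (is.null(curves) == is.null(cq)) {
    abort("Supply exactly one of `curves` (full path) or `cq` (matrix entry point).")
  }
  manifest <- list(
    tool = "cqpipe",
    version = as.character(packageVersion("cqpipe")),
    seed = config$seed,
    config = unclass(config),
    inputs = if (is.null(input_paths)) list() else
      as.list(unname(Map(function(p, n) list(name = n, path = p,
                                             md5 = unname(tools::md5sum(p))),
                         input_paths, names(input_paths)))),
    stages = list()
  )
  record <- function(name, ...) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- c(list(stage = name), list(...))
  }
  fail <- function(stage, err) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(err)),
          manifest = manifest)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  if (!is.null(curves)) {
    if (is.null(metadata)) abort("`metadata` is required with curve input.")
    scored <- run_stage("cq_calling", {
      calls <- suppressWarnings(call_cq(curves, method = config$threshold_method,
                                        threshold = config$fixed_threshold))
      suppressWarnings(score_curves(curves, calls,
                                    amp_score_min = config$amp_score_min,
                                    cq_conf_min = config$cq_conf_min))
    })
    record("cq_calling", method = config$threshold_method,
           n_curves = nrow(scored), n_called = sum(!is.na(scored$cq)))
    cq <- run_stage("cq_table", cq_table(scored, metadata, layout))
  }
  n_pass <- if ("qc_pass" %in% names(cq)) sum(cq$qc_pass, na.rm = TRUE) else NA_integer_
  record("curve_qc", n_cells = nrow(cq), n_qc_pass = n_pass,
         amp_score_min = config$amp_score_min, cq_conf_min = config$cq_conf_min)

  crt <- run_stage("call_rate_table", call_rate_table(cq))
  cq_cr <- run_stage("call_rate_filter", filter_call_rate(cq, config$call_rate_min))
  record("call_rate_filter", min_call_rate = config$call_rate_min,
         n_targets_in = dplyr::n_distinct(paste(cq$card, cq$target_id)),
         n_targets_out = dplyr::n_distinct(paste(cq_cr$card, cq_cr$target_id)),
         removed = removed_targets(cq_cr)$target_id)
  cq_f <- run_stage("median_cq_filter", filter_median_cq(cq_cr, config$median_cq_max))
  record("median_cq_filter", cutoff = config$median_cq_max,
         n_targets_out = dplyr::n_distinct(paste(cq_f$card, cq_f$target_id)),
         removed = setdiff(removed_targets(cq_f)$target_id,
                           removed_targets(cq_cr)$target_id))

  # stability on the 100%-call-rate candidates of each card
  complete <- call_rates(cq_f) |> filter(.data$call_rate == 100)
  stab <- NULL
  if (nrow(complete)) {
    cq_complete <- cq_f |> dplyr::semi_join(complete, by = c("target_id", "card"))
    enough <- cq_complete |>
      group_by(.data$card) |>
      summarise(n = dplyr::n_distinct(.data$target_id), .groups = "drop") |>
      filter(.data$n >= 3L)
    if (nrow(enough)) {
      stab <- run_stage("reference_stability",
                        rank_stability(cq_complete |>
                                         dplyr::semi_join(enough, by = "card")))
    }
  }
  record("reference_stability",
         n_candidates = if (is.null(stab)) 0L else nrow(stab),
         best = if (is.null(stab)) character() else
           stab$target_id[stab$final_rank == 1L])

  norm <- run_stage("normalization", {
    if (config$normalization == "geomean") {
      normalization_factor(cq_f, method = "geomean")
    } else {
      if (is.null(stab)) {
        abort("Reference normalization requires a stability ranking (>= 3 complete candidates per card).")
      }
      stab |>
        filter(.data$final_rank == 1L) |>
        dplyr::group_by(.data$card) |>
        dplyr::group_split() |>
        purrr::map(function(best) {
          normalization_factor(cq_f |> filter(.data$card == best$card[1]),
                               method = "reference",
                               reference = best$target_id[1])
        }) |>
        purrr::list_rbind()
    }
  })
  record("normalization", kind = norm$kind[1],
         n_samples = dplyr::n_distinct(norm$sample_id))

  expr <- run_stage("relative_expression", {
    cq_f |>
      dplyr::group_by(.data$card) |>
      dplyr::group_split() |>
      purrr::map(function(one) {
        relative_expression(one,
                            norm |> filter(.data$card == one$card[1]),
                            case = config$case, control = config$control,
                            method_label = config$threshold_method)
      }) |>
      purrr::list_rbind()
  })
  record("relative_expression", n_targets = nrow(expr),
         case = config$case, control = config$control)

  result <- structure(
    list(cq = cq, cq_filtered = cq_f, call_rate_table = crt,
         stability = stab, normalization = norm, expression = expr,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @rdname run_pipeline
#' @param result A `pipeline_result`.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cq_matrix(result$cq, file.path(out_dir, "cq_matrix.csv"))
  readr::write_tsv(result$call_rate_table, file.path(out_dir, "call_rate_table.tsv"),
                   progress = FALSE)
  if (!is.null(result$stability)) {
    write_report(result$stability, file.path(out_dir, "stability_report.tsv"))
  }
  write_report(result$normalization |> arrange(.data$card, .data$sample_id),
               file.path(out_dir, "normalization_factors.tsv"))
  write_report(result$expression, file.path(out_dir, "expression_results.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  method:   ", x$manifest$config$threshold_method, "\n", sep = "")
  cat("  targets:  ", dplyr::n_distinct(paste(x$cq$card, x$cq$target_id)),
      " in, ", dplyr::n_distinct(paste(x$cq_filtered$card, x$cq_filtered$target_id)),
      " after filters\n", sep = "")
  if (!is.null(x$stability)) {
    best <- x$stability |> filter(.data$final_rank == 1L)
    cat("  reference:", paste(sprintf("%s (card %s)", best$target_id, best$card),
                              collapse = ", "), "\n")
  }
  cat("  expression results for ", nrow(x$expression), " target(s)\n", sep = "")
  invisible(x)
}
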