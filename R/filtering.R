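# Reliability filtering of a QC-annotated Cq table, in the documented order:
# QC gating -> call-rate filter -> median-Cq filter. A cell counts as a
# reliable call only when a Cq is present AND the curve passed QC. The
# non-human negative control is excluded from call-rate accounting;
# endogenous control assays are retained and flagged.

reliable_calls <- function(cq) {
  ok <- !is.na(cq$cq)
  if ("qc_pass" %in% names(cq)) ok <- ok & !is.na(cq$qc_pass) & cq$qc_pass
  ok
}

drop_negative_controls <- function(cq) {
  if (!"control" %in% names(cq)) return(cq)
  filter(cq, is.na(.data$control) | .data$control != "negative")
}

#' Per-target call rates
#'
#' The call rate of a target is the percentage of samples with reliable
#' amplification for it: a Cq present and, when QC annotations exist, a
#' passing QC gate. The denominator is all samples loaded on that target's
#' card. Negative-control assays are excluded.
#'
#' @param cq Long Cq tibble (see [cq_table()] or [read_cq_matrix()]).
#' @return A tibble with one row per target: `target_id`, `card`, `control`,
#'   `n_samples`, `n_reliable`, `call_rate` (percent, 0--100).
#' @export
call_rates <- function(cq) {
  if (!nrow(cq) || dplyr::n_distinct(cq$sample_id) == 0L) {
    abort("Call rate is undefined with zero samples.")
  }
  df <- drop_negative_controls(cq)
  if (!"control" %in% names(df)) df$control <- NA_character_
  df$.reliable <- reliable_calls(df)
  df |>
    group_by(.data$target_id, .data$card, .data$control) |>
    summarise(
      n_samples = dplyr::n_distinct(.data$sample_id),
      n_reliable = sum(.reliable),
      .groups = "drop"
    ) |>
    mutate(call_rate = 100 * .data$n_reliable / .data$n_samples) |>
    arrange(.data$card, .data$target_id)
}

#' Filter targets by call rate
#'
#' Retains targets detected reliably in at least `min_rate` percent of
#' samples (default 90, the conventional cutoff). Negative-control assays are
#' always removed. Removed targets are recorded and recoverable with
#' [removed_targets()]; retained and removed targets partition the input.
#'
#' @param cq Long Cq tibble.
#' @param min_rate Minimum call rate in percent (0--100).
#' @return The filtered Cq tibble, with a `removed` attribute listing dropped
#'   targets and the reason.
#' @export
filter_call_rate <- function(cq, min_rate = 90) {
  stopifnot_scalar_number(min_rate, "min_rate", min = 0)
  rates <- call_rates(cq)
  keep <- rates |> filter(.data$call_rate >= min_rate)
  removed <- rates |>
    filter(.data$call_rate < min_rate) |>
    mutate(reason = sprintf("call rate %.1f%% < %.0f%%", .data$call_rate, min_rate)) |>
    select("target_id", "card", "reason")
  if ("control" %in% names(cq)) {
    neg <- cq |>
      filter(!is.na(.data$control), .data$control == "negative") |>
      distinct(.data$target_id, .data$card) |>
      mutate(reason = "negative control")
    removed <- bind_rows(neg, removed)
  }
  out <- cq |>
    drop_negative_controls() |>
    dplyr::semi_join(keep, by = c("target_id", "card"))
  attr(out, "removed") <- bind_rows(attr(cq, "removed"), removed)
  out
}

#' Filter targets by median Cq
#'
#' Drops barely expressed targets. In fixed mode a target is removed when the
#' median of its observed reliable Cq values exceeds `max_median` (default
#' 32, the conventional cutoff). In adaptive mode the cutoff is the median of
#' all per-target medians, which avoids discarding low-expressed targets of
#' potential biological relevance by an arbitrary fixed cycle. Apply after
#' the call-rate filter (the documented order).
#'
#' @param cq Long Cq tibble.
#' @param max_median Numeric cutoff in Cq cycles, or `"adaptive"`.
#' @return The filtered Cq tibble with the `removed` attribute extended.
#' @export
filter_median_cq <- function(cq, max_median = 32) {
  df <- drop_negative_controls(cq)
  df$.reliable <- reliable_calls(df)
  meds <- df |>
    filter(.data$.reliable) |>
    group_by(.data$target_id, .data$card) |>
    summarise(median_cq = median(.data$cq), .groups = "drop")
  cutoff <- if (identical(max_median, "adaptive")) {
    median(meds$median_cq)
  } else {
    stopifnot_scalar_number(max_median, "max_median", min = 0, strict_min = TRUE)
    max_median
  }
  removed <- meds |>
    filter(.data$median_cq > cutoff) |>
    mutate(reason = sprintf("median Cq %.2f > %.2f", .data$median_cq, cutoff)) |>
    select("target_id", "card", "reason")
  out <- cq |>
    drop_negative_controls() |>
    dplyr::anti_join(removed, by = c("target_id", "card"))
  attr(out, "removed") <- bind_rows(attr(cq, "removed"), removed)
  out
}

#' Targets removed by filtering
#'
#' @param cq A Cq tibble returned by [filter_call_rate()] or
#'   [filter_median_cq()].
#' @return A tibble `target_id`, `card`, `reason` (empty when nothing was
#'   removed).
#' @export
removed_targets <- function(cq) {
  attr(cq, "removed") %||% tibble(target_id = character(), card = character(),
                                  reason = character())
}

#' Cumulative call-rate table
#'
#' The classical call-rate accounting: for each category (100, 98, 96, 94,
#' 92, 90 percent) the cumulative number and percentage of targets whose call
#' rate is at least the category threshold. Percentages are computed against
#' the total number of QC-passing targets (targets with at least one reliable
#' call); negative controls are excluded.
#'
#' @param cq Long Cq tibble.
#' @param categories Call-rate category thresholds, percent.
#' @return A tibble `call_rate_category`, `n_targets`, `pct_targets`, with the
#'   QC-passing total in attribute `total`; counts are non-decreasing as the
#'   category threshold decreases.
#' @export
call_rate_table <- function(cq, categories = c(100, 98, 96, 94, 92, 90)) {
  if (!nrow(cq)) {
    out <- tibble(call_rate_category = categories, n_targets = 0L,
                  pct_targets = 0)
    attr(out, "total") <- 0L
    return(out)
  }
  rates <- call_rates(cq) |> filter(.data$n_reliable > 0L)
  total <- nrow(rates)
  out <- tibble(
    call_rate_category = categories,
    n_targets = vapply(categories, function(th) sum(rates$call_rate >= th),
                       integer(1))
  )
  out$pct_targets <- if (total > 0) 100 * out$n_targets / total else 0
  attr(out, "total") <- total
  out
}
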