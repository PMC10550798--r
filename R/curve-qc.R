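# Reliability scoring for amplification curves, replacing manual inspection.
# The scores honour the documented ranges and cutoffs used in instrument
# software (amplification score in [0, 2] with pass > 1; Cq confidence in
# [0, 1] with pass > 0.8, > 0.95 "very confident") but are open
# reimplementations: the vendor formulas are unpublished, and in downstream
# practice the scores act purely as pass/fail gates.

# Amplification score in [0, 2]. The quality signal is the product of the
# curve's nonlinear rise in noise units (high linear-region rise is what
# distinguishes strong amplification, and measuring it as the residual from a
# whole-curve straight line keeps baseline-extrapolation ramps from
# masquerading as signal) and the R^2 of a log-linear fit to the exponential
# region. The product is mapped through a logistic centred at 6, the
# geometric middle of the gap between the two classes on the separation
# benchmark (amplified curves at amplitude/noise >= 50 sit above ~8, flat or
# noise-only traces below ~4.5). Both inputs are ratios of corrected-signal
# magnitudes, so the score is invariant to positive scaling of the
# fluorescence axis.
amp_score_curve <- function(feat) {
  if (feat$range <= 0 || feat$rise <= 0) return(0)
  if (all(feat$corrected <= 0)) return(0)
  product <- feat$nonlin_snr * feat$exp_r2
  if (product <= 0) return(0)
  2 * plogis(3 * (log10(product) - log10(6)))
}

# Cq confidence in [0, 1]: the product of a saturating map of the local rise
# at the crossing (per cycle, relative to the baseline noise SD) and a
# root-compressed exponential-region log-linear R^2 (exponent 0.25,
# calibrated on the amplified/non-amplified separation benchmark). Returns 0
# when no Cq was called. Non-increasing in the noise level for fixed signal
# parameters.
cq_confidence_curve <- function(feat, cq) {
  if (is.na(cq)) return(0)
  n <- length(feat$corrected)
  i <- min(max(ceiling(cq), 2L), n)
  local_rise <- feat$corrected[i] - feat$corrected[i - 1L]
  if (local_rise <= 0) return(0)
  steep <- 1 - exp(-local_rise / feat$noise_sd)
  min(1, max(0, steep * max(0, feat$exp_r2)^0.25))
}

#' Amplification status from the QC scores
#'
#' Classifies each curve as `"AMP"` (both scores pass), `"NO_AMP"`
#' (amplification score < 0.5 and no threshold crossing) or `"INCONCLUSIVE"`
#' (anything in between; such curves are treated as failures by the QC gate,
#' never auto-promoted). Unlike instrument software, the status here is a
#' deliberate per-curve decision and does not depend on how many curves are in
#' the run.
#'
#' @param cq Numeric vector of called Cq values (`NA` = no crossing).
#' @param amp_score Numeric vector of amplification scores in `[0, 2]`.
#' @param cq_conf Numeric vector of Cq confidence values in `[0, 1]`.
#' @param amp_score_min,cq_conf_min Pass cutoffs (defaults 1.0 and 0.8).
#' @return Character vector: `"AMP"`, `"NO_AMP"` or `"INCONCLUSIVE"`.
#' @export
amp_status <- function(cq, amp_score, cq_conf,
                       amp_score_min = 1, cq_conf_min = 0.8) {
  dplyr::case_when(
    amp_score > amp_score_min & cq_conf > cq_conf_min ~ "AMP",
    amp_score < 0.5 & is.na(cq) ~ "NO_AMP",
    .default = "INCONCLUSIVE"
  )
}

#' Score amplification curves for reliability
#'
#' Computes, per curve, the amplification score (range `[0, 2]`, pass > 1),
#' the Cq confidence (range `[0, 1]`, pass > 0.8), the categorical
#' amplification status and the overall QC pass flag
#' (`amp_score > amp_score_min & cq_conf > cq_conf_min`). A curve passing QC
#' is one whose call can enter downstream call-rate and expression analysis.
#'
#' @param curves Long-format curve tibble (see [subtract_baseline()]).
#' @param calls Per-curve Cq calls from [call_cq()]; computed with
#'   `method`/`threshold` when omitted.
#' @param method,threshold Passed to [call_cq()] when `calls` is `NULL`.
#' @param amp_score_min,cq_conf_min QC pass cutoffs (defaults 1.0, 0.8).
#' @return The `calls` tibble with columns `amp_score`, `cq_conf`,
#'   `amp_status` and `qc_pass` appended.
#' @examples
#' cv <- simulate_curve(curve_params(noise_sd = 0.005), seed = 1)
#' score_curves(cv)
#' @export
score_curves <- function(curves, calls = NULL,
                         method = "fixed", threshold = 0.2,
                         amp_score_min = 1, cq_conf_min = 0.8) {
  check_curves(curves)
  if (is.null(calls)) {
    calls <- suppressWarnings(call_cq(curves, method = method, threshold = threshold))
  }
  pieces <- split_curves(curves)
  keys <- purrr::map(pieces, function(cv) cv[1, curve_keys]) |> purrr::list_rbind()
  feats <- purrr::map(pieces, function(cv) suppressWarnings(curve_features(cv$rn)))
  ord <- dplyr::left_join(
    keys |> mutate(.row = dplyr::row_number()),
    calls, by = curve_keys
  )
  if (anyNA(ord$method)) {
    abort("`calls` does not cover every curve in `curves`.")
  }
  scores <- purrr::map2(feats, ord$cq[order(ord$.row)], function(ft, cq) {
    a <- amp_score_curve(ft)
    tibble(amp_score = a, cq_conf = cq_confidence_curve(ft, cq))
  }) |> purrr::list_rbind()
  out <- ord |> arrange(.data$.row) |> select(-".row")
  out$amp_score <- scores$amp_score
  out$cq_conf <- scores$cq_conf
  out$amp_status <- amp_status(out$cq, out$amp_score, out$cq_conf,
                               amp_score_min, cq_conf_min)
  out$qc_pass <- out$amp_score > amp_score_min & out$cq_conf > cq_conf_min
  as_tibble(out)
}

#' Assemble a QC-annotated Cq table from scored calls
#'
#' Joins per-curve calls (typically from [score_curves()]) with sample
#' metadata and, optionally, a card layout carrying control-assay flags,
#' yielding the long-format Cq table consumed by the filtering, stability and
#' expression stages.
#'
#' @param calls Tibble of calls, one row per (target, sample); must contain
#'   `target_id`, `card`, `sample_id`, `cq`.
#' @param metadata Tibble with columns `sample_id`, `group`; every sample in
#'   `calls` must be present.
#' @param layout Optional tibble with `card`, `target_id`, `control` flags
#'   (see [card_layout()]).
#' @return A long Cq tibble: `target_id`, `card`, `sample_id`, `group`, `cq`,
#'   any QC columns present in `calls`, and `control`.
#' @export
cq_table <- function(calls, metadata, layout = NULL) {
  need <- c("target_id", "card", "sample_id", "cq")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols)) {
    abort(paste0("`calls` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("`metadata` must have columns `sample_id` and `group`.")
  }
  orphans <- setdiff(unique(calls$sample_id), metadata$sample_id)
  if (length(orphans)) {
    abort(paste0("Sample(s) missing from metadata: ",
                 paste(orphans, collapse = ", "), "."))
  }
  out <- calls |>
    left_join(metadata |> select("sample_id", "group"), by = "sample_id")
  if (!is.null(layout)) {
    out <- out |>
      left_join(layout |> select("card", "target_id", "control"),
                by = c("card", "target_id"))
  } else if (!"control" %in% names(out)) {
    out$control <- NA_character_
  }
  qc_cols <- intersect(c("method", "amp_score", "cq_conf", "amp_status",
                         "qc_pass"), names(out))
  out |>
    select("target_id", "card", "sample_id", "group", "cq",
           all_of(qc_cols), "control")
}
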