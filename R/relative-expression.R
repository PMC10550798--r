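# Relative quantification via the 2^-ddCq method with the field's reporting
# convention for down-regulation (negative inverse fold change), Wilcoxon
# rank-sum group tests, and the cross-threshold comparison statistics
# (Kruskal-Wallis with Dunn's post hoc; Pearson agreement of fold-change and
# p-value vectors between threshold methods).

#' Per-sample delta Cq
#'
#' \eqn{\Delta Cq_s = Cq_{target,s} - N_s} where \eqn{N_s} is the per-sample
#' normalization value (a reference target's Cq or the geometric-mean
#' factor). Samples with a missing target Cq are excluded, never imputed; a
#' missing normalization value for an observed sample is an error.
#'
#' @param cq Long Cq tibble.
#' @param normalization Output of [normalization_factor()] (columns
#'   `sample_id`, `value`), or a single reference target id found in `cq`.
#' @param target Optional target id; default all targets in `cq`.
#' @return A tibble `target_id`, `card`, `sample_id`, `group`, `delta_cq`.
#' @export
delta_cq <- function(cq, normalization, target = NULL) {
  norm <- if (is.character(normalization) && length(normalization) == 1L) {
    normalization_factor(cq, method = "reference", reference = normalization)
  } else {
    normalization
  }
  if (!all(c("sample_id", "value") %in% names(norm))) {
    abort("`normalization` must have columns `sample_id` and `value`.")
  }
  df <- drop_negative_controls(cq)
  if (!is.null(target)) df <- df |> filter(.data$target_id %in% target)
  df <- df |> filter(!is.na(.data$cq))
  missing_norm <- setdiff(unique(df$sample_id), norm$sample_id)
  if (length(missing_norm)) {
    abort(paste0("Normalization value missing for sample(s): ",
                 paste(missing_norm, collapse = ", "), "."))
  }
  df |>
    left_join(norm |> select("sample_id", "value"), by = "sample_id") |>
    mutate(delta_cq = .data$cq - .data$value) |>
    select("target_id", "card", "sample_id", "group", "delta_cq")
}

#' Fold change from a delta-delta Cq
#'
#' \eqn{RQ = 2^{-\Delta\Delta Cq}}; fold change is reported as \eqn{RQ} when
#' \eqn{RQ \ge 1} and as the negative inverse \eqn{-1/RQ} otherwise, so its
#' magnitude is always at least 1 and never falls in (−1, 1).
#'
#' @param ddcq Numeric vector of delta-delta Cq values.
#' @return Signed fold changes.
#' @examples
#' fold_change_from_ddcq(c(0, -1, 2)) # 1, 2, -4
#' @export
fold_change_from_ddcq <- function(ddcq) {
  rq <- 2^(-ddcq)
  ifelse(rq >= 1, rq, -1 / rq)
}

#' Delta-delta Cq and fold change for one target
#'
#' \eqn{\Delta\Delta Cq} = mean case \eqn{\Delta Cq} − mean reference-group
#' \eqn{\Delta Cq}; fold change per [fold_change_from_ddcq()].
#'
#' @param delta_case,delta_control Numeric vectors of per-sample delta Cq.
#' @return A one-row tibble `ddcq`, `rq`, `fold_change`.
#' @export
ddcq_fold_change <- function(delta_case, delta_control) {
  if (!length(delta_case) || !length(delta_control)) {
    abort("Both groups need at least one delta Cq value.")
  }
  ddcq <- mean(delta_case) - mean(delta_control)
  tibble(ddcq = ddcq, rq = 2^(-ddcq), fold_change = fold_change_from_ddcq(ddcq))
}

#' Two-sided Wilcoxon rank-sum group test
#'
#' Exact for small samples without ties, normal approximation with tie
#' correction otherwise (the behaviour of [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors for the two groups (each non-empty).
#' @return The two-sided p-value.
#' @export
group_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both groups must be non-empty.")
  p <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  if (is.nan(p)) p <- 1 # fully tied data carry no rank evidence
  p
}

#' Relative expression analysis (2^-ddCq)
#'
#' For every target: per-sample delta Cq against the chosen normalization,
#' group means (and medians) of delta Cq, delta-delta Cq of `case` versus the
#' `control` reference group, the signed fold change and the two-sided
#' Wilcoxon rank-sum p-value. Means drive the fold change; medians are
#' reported alongside for the nonparametric reader.
#'
#' @param cq Long Cq tibble (already filtered; call rate >= 90% by
#'   convention).
#' @param normalization See [delta_cq()].
#' @param case,control Group labels of the group of interest and the
#'   reference group.
#' @param method_label Label of the threshold method that produced the Cq
#'   input, carried into the result (default taken from a `method` column if
#'   present).
#' @return An `expression_result` tibble: one row per target with `n_case`,
#'   `n_control`, `mean_dcq_case`, `mean_dcq_control`, `median_dcq_case`,
#'   `median_dcq_control`, `ddcq`, `fold_change`, `p_value`, `method_label`.
#' @export
relative_expression <- function(cq, normalization, case, control,
                                method_label = NULL) {
  if (is.null(method_label)) {
    method_label <- if ("method" %in% names(cq)) cq$method[1] else NA_character_
  }
  dcq <- delta_cq(cq, normalization)
  gl <- unique(dcq$group)
  if (!case %in% gl) abort(sprintf("Case group `%s` not present.", case))
  if (!control %in% gl) abort(sprintf("Control group `%s` not present.", control))
  out <- dcq |>
    filter(.data$group %in% c(case, control)) |>
    dplyr::group_by(.data$target_id, .data$card) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      dc <- one$delta_cq[one$group == case]
      dk <- one$delta_cq[one$group == control]
      if (!length(dc) || !length(dk)) {
        abort(sprintf("Target %s has an empty group.", one$target_id[1]))
      }
      fc <- ddcq_fold_change(dc, dk)
      tibble(
        target_id = one$target_id[1], card = one$card[1],
        n_case = length(dc), n_control = length(dk),
        mean_dcq_case = mean(dc), mean_dcq_control = mean(dk),
        median_dcq_case = median(dc), median_dcq_control = median(dk),
        ddcq = fc$ddcq, fold_change = fc$fold_change,
        p_value = group_test(dc, dk),
        method_label = method_label
      )
    }) |>
    purrr::list_rbind() |>
    arrange(.data$card, .data$target_id)
  class(out) <- c("expression_result", class(out))
  out
}

#' @rdname relative_expression
#' @param x An `expression_result`.
#' @param ... Unused.
#' @method tidy expression_result
#' @export
tidy.expression_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "expression_result")
  out
}

#' @rdname relative_expression
#' @method glance expression_result
#' @export
glance.expression_result <- function(x, ...) {
  tibble(
    n_targets = nrow(x),
    n_up = sum(x$fold_change > 1),
    n_down = sum(x$fold_change < -1),
    min_p = min(x$p_value),
    method_label = x$method_label[1]
  )
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis test, with the
#' standard tie correction; two-sided p-values with multiplicity adjustment
#' (Holm by default).
#'
#' @param x Numeric response vector.
#' @param g Grouping vector, same length as `x`.
#' @param p_adjust Adjustment method for [stats::p.adjust()].
#' @return A tibble `group1`, `group2`, `z`, `p_value`, `p_adj`.
#' @export
dunn_posthoc <- function(x, g, p_adjust = "holm") {
  g <- as.character(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- unique(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- purrr::map(pairs, function(p) {
    i <- g == p[1]; j <- g == p[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sum(i) + 1 / sum(j)))
    z <- (mean(r[i]) - mean(r[j])) / se
    tibble(group1 = p[1], group2 = p[2], z = z,
           p_value = 2 * pnorm(-abs(z)))
  }) |> purrr::list_rbind()
  res$p_adj <- p.adjust(res$p_value, method = p_adjust)
  res
}

#' Compare Cq distributions across threshold methods
#'
#' For every target shared by the supplied Cq tables (one per threshold
#' method), a Kruskal-Wallis rank-sum test across the methods' Cq values,
#' followed by Dunn's post hoc pairwise comparisons with multiplicity
#' adjustment. Targets with Kruskal-Wallis p below `flag_p` (default 0.01,
#' the conventional reporting threshold) are flagged. Supply tables already
#' restricted to targets passing the quality filters under every method; the
#' function intersects targets and samples.
#'
#' @param cq_by_method Named list (method label -> long Cq tibble) of at least
#'   two matched Cq tables.
#' @param flag_p Flagging threshold on the Kruskal-Wallis p-value.
#' @param p_adjust Dunn adjustment method.
#' @return A `threshold_comparison` list: `tests` (per target: `kw_p`,
#'   `flagged`) and `posthoc` (per target and method pair: `z`, `p_value`,
#'   `p_adj`).
#' @export
compare_thresholds <- function(cq_by_method, flag_p = 0.01, p_adjust = "holm") {
  if (length(cq_by_method) < 2L) abort("At least two methods are required.")
  if (is.null(names(cq_by_method)) || any(!nzchar(names(cq_by_method)))) {
    abort("`cq_by_method` must be a named list.")
  }
  stacked <- purrr::imap(cq_by_method, function(d, nm) {
    d |> select("target_id", "card", "sample_id", "cq") |>
      mutate(method = nm)
  }) |> purrr::list_rbind()
  shared_targets <- stacked |>
    distinct(.data$target_id, .data$method) |>
    dplyr::count(.data$target_id) |>
    filter(.data$n == length(cq_by_method))
  shared_samples <- stacked |>
    distinct(.data$sample_id, .data$method) |>
    dplyr::count(.data$sample_id) |>
    filter(.data$n == length(cq_by_method))
  stacked <- stacked |>
    dplyr::semi_join(shared_targets, by = "target_id") |>
    dplyr::semi_join(shared_samples, by = "sample_id") |>
    filter(!is.na(.data$cq))
  pieces <- stacked |>
    dplyr::group_by(.data$target_id, .data$card) |>
    dplyr::group_split()
  tests <- purrr::map(pieces, function(one) {
    kw <- if (dplyr::n_distinct(one$cq) == 1L) {
      list(p.value = 1) # all values tied across methods: no evidence
    } else {
      suppressWarnings(kruskal.test(one$cq, factor(one$method)))
    }
    tibble(target_id = one$target_id[1], card = one$card[1],
           kw_p = kw$p.value)
  }) |> purrr::list_rbind() |>
    mutate(flagged = .data$kw_p < flag_p)
  posthoc <- purrr::map(pieces, function(one) {
    dunn_posthoc(one$cq, one$method, p_adjust = p_adjust) |>
      mutate(target_id = one$target_id[1], card = one$card[1]) |>
      select("target_id", "card", dplyr::everything())
  }) |> purrr::list_rbind()
  structure(list(tests = tests, posthoc = posthoc, flag_p = flag_p),
            class = "threshold_comparison")
}

#' @rdname compare_thresholds
#' @param x A `threshold_comparison`.
#' @param ... Unused.
#' @method tidy threshold_comparison
#' @export
tidy.threshold_comparison <- function(x, ...) x$tests

#' @export
print.threshold_comparison <- function(x, ...) {
  cat("<threshold_comparison> ", nrow(x$tests), " targets; ",
      sum(x$tests$flagged), " flagged at Kruskal-Wallis p < ", x$flag_p,
      "\n", sep = "")
  invisible(x)
}

#' Cross-method agreement of expression results
#'
#' Pearson correlation, between each pair of threshold methods, of the
#' fold-change vector and (separately) the p-value vector over the shared
#' targets. The matrices are symmetric with unit diagonal.
#'
#' @param results_by_method Named list (method label -> `expression_result`).
#' @return A `method_agreement` list with correlation matrices `fc` and `p`.
#' @export
cross_method_agreement <- function(results_by_method) {
  if (length(results_by_method) < 2L) abort("At least two methods are required.")
  nm <- names(results_by_method)
  shared <- purrr::reduce(purrr::map(results_by_method, function(r) {
    unique(paste(r$card, r$target_id))
  }), intersect)
  if (length(shared) < 3L) abort("At least 3 shared targets are required.")
  get_vec <- function(r, col) {
    key <- paste(r$card, r$target_id)
    r[[col]][match(shared, key)]
  }
  corr_mat <- function(col) {
    vecs <- purrr::map(results_by_method, get_vec, col = col)
    k <- length(vecs)
    m <- diag(1, k)
    dimnames(m) <- list(nm, nm)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        m[i, j] <- m[j, i] <- stats::cor(vecs[[i]], vecs[[j]], method = "pearson")
      }
    }
    m
  }
  structure(list(fc = corr_mat("fold_change"), p = corr_mat("p_value"),
                 n_targets = length(shared)),
            class = "method_agreement")
}

#' @rdname cross_method_agreement
#' @param x A `method_agreement`.
#' @param ... Unused.
#' @method tidy method_agreement
#' @export
tidy.method_agreement <- function(x, ...) {
  to_long <- function(m, what) {
    as_tibble(as.data.frame.table(m, responseName = "estimate")) |>
      rename(method1 = "Var1", method2 = "Var2") |>
      mutate(quantity = what,
             method1 = as.character(.data$method1),
             method2 = as.character(.data$method2))
  }
  bind_rows(to_long(x$fc, "fold_change"), to_long(x$p, "p_value"))
}

#' @export
print.method_agreement <- function(x, ...) {
  cat("<method_agreement> over", x$n_targets, "shared targets\n")
  cat("fold-change correlations:\n"); print(round(x$fc, 3))
  cat("p-value correlations:\n"); print(round(x$p, 3))
  invisible(x)
}
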