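# Reference (endogenous control) stability ranking. Four classical stability
# statistics are computed per candidate on Cq data -- BestKeeper (SD and CV of
# raw Cq), geNorm (average pairwise variation M), the comparative delta-Ct
# method (mean pairwise SD) and NormFinder (model-based intra-/intergroup
# variance decomposition) -- and combined into a comprehensive rank as the
# geometric mean of the four per-method ranks. Lower is more stable for every
# statistic. Cq is already a log2-scale quantity, so pairwise log-ratios are
# plain Cq differences and no re-exponentiation is performed. Cards are
# independent experiments; rank each card separately.

# Candidates must be expressed in all samples (call rate 100%): reshape to a
# complete targets x samples matrix or fail, naming the offenders.
cq_matrix_complete <- function(cq) {
  df <- drop_negative_controls(cq)
  df$.ok <- reliable_calls(df)
  bad <- df |>
    group_by(.data$target_id) |>
    summarise(complete = all(.data$.ok), .groups = "drop") |>
    filter(!.data$complete)
  if (nrow(bad)) {
    abort(paste0(
      "Stability input must be restricted to targets with 100% call rate; ",
      "offending target(s): ", paste(bad$target_id, collapse = ", "), "."
    ))
  }
  wide <- df |>
    select("target_id", "sample_id", "cq") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cq")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$target_id
  mat
}

sample_groups <- function(cq, mat) {
  g <- cq |> distinct(.data$sample_id, .data$group)
  setNames(g$group, g$sample_id)[colnames(mat)]
}

# SD across samples of the difference Cq_j - Cq_k, for every candidate pair.
pairwise_sd_matrix <- function(mat) {
  k <- nrow(mat)
  v <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(k - 1L)) {
    for (l in (j + 1L):k) {
      s <- sd(mat[j, ] - mat[l, ])
      v[j, l] <- s
      v[l, j] <- s
    }
  }
  v
}

#' BestKeeper stability statistics
#'
#' For each candidate, the sample standard deviation (n − 1 denominator) and
#' coefficient of variation (percent) of its raw Cq values across samples. A
#' smaller SD indicates more stable expression.
#'
#' @param cq Long Cq tibble restricted to candidates with 100% call rate.
#' @return A tibble `target_id`, `card`, `bestkeeper_sd`, `bestkeeper_cv`.
#' @examples
#' cq <- tibble::tibble(target_id = "t", card = "A",
#'                      sample_id = c("a", "b", "c"), group = "g",
#'                      cq = c(20, 22, 24))
#' bestkeeper_stats(cq) # SD 2, CV 9.09%
#' @export
bestkeeper_stats <- function(cq) {
  mat <- cq_matrix_complete(cq)
  if (ncol(mat) < 3L) abort("BestKeeper needs at least 3 samples.")
  cards <- cq |> distinct(.data$target_id, .data$card)
  sds <- unname(apply(mat, 1, sd))
  tibble(
    target_id = rownames(mat),
    bestkeeper_sd = sds,
    bestkeeper_cv = 100 * sds / unname(rowMeans(mat))
  ) |>
    left_join(cards, by = "target_id") |>
    select("target_id", "card", "bestkeeper_sd", "bestkeeper_cv")
}

#' geNorm expression-stability measure M
#'
#' For a candidate pair (j, k) the pairwise variation is the SD across
#' samples of the Cq difference; M of a candidate is the mean of its pairwise
#' variations with every other candidate. The lowest M is the most stable.
#' With `stepwise = TRUE` the classical iterative ranking is also returned:
#' the highest-M candidate is removed and M recomputed until two remain (the
#' final pair shares the top rank).
#'
#' @param cq Long Cq tibble restricted to candidates with 100% call rate.
#' @param stepwise Also compute the stepwise-exclusion ranking.
#' @return A tibble `target_id`, `card`, `genorm_m` (and `genorm_stepwise_rank`
#'   when requested), in input target order.
#' @export
genorm_m <- function(cq, stepwise = FALSE) {
  mat <- cq_matrix_complete(cq)
  if (nrow(mat) < 3L) abort("geNorm M needs at least 3 candidates.")
  v <- pairwise_sd_matrix(mat)
  m <- rowSums(v) / (nrow(mat) - 1L)
  out <- tibble(target_id = rownames(mat), genorm_m = unname(m))
  if (stepwise) {
    remaining <- rownames(mat)
    rank_out <- setNames(rep(NA_real_, length(remaining)), remaining)
    r <- length(remaining)
    while (length(remaining) > 2L) {
      vv <- pairwise_sd_matrix(mat[remaining, , drop = FALSE])
      mm <- rowSums(vv) / (length(remaining) - 1L)
      worst <- names(which.max(mm))
      rank_out[worst] <- r
      r <- r - 1L
      remaining <- setdiff(remaining, worst)
    }
    rank_out[remaining] <- 1.5 # final pair is indistinguishable
    out$genorm_stepwise_rank <- unname(rank_out[out$target_id])
  }
  cards <- cq |> distinct(.data$target_id, .data$card)
  out |> left_join(cards, by = "target_id") |>
    select("target_id", "card", dplyr::everything())
}

#' Comparative delta-Ct stability
#'
#' Compares the expression of every candidate pair within each sample: the
#' statistic of a candidate is the mean, over all partners, of the SD across
#' samples of the pairwise Cq difference (the same pairwise variations as
#' geNorm, without iterative exclusion).
#'
#' @inheritParams genorm_m
#' @return A tibble `target_id`, `card`, `deltact_mean_sd`.
#' @export
deltact_stability <- function(cq) {
  mat <- cq_matrix_complete(cq)
  if (nrow(mat) < 3L) abort("The comparative delta-Ct method needs at least 3 candidates.")
  v <- pairwise_sd_matrix(mat)
  cards <- cq |> distinct(.data$target_id, .data$card)
  tibble(
    target_id = rownames(mat),
    deltact_mean_sd = unname(rowSums(v) / (nrow(mat) - 1L))
  ) |>
    left_join(cards, by = "target_id") |>
    select("target_id", "card", "deltact_mean_sd")
}

#' NormFinder stability value
#'
#' Model-based variance decomposition on log-scale data (Cq is already
#' log2-scale). Each sample is centred by its mean over candidates; the
#' per-candidate, per-group intragroup variance is then estimated with the
#' bias correction that accounts for the shared sample centring, and the
#' intergroup component is the deviation of a candidate's group means from
#' its overall mean. The stability value averages, over groups,
#' |intergroup deviation| + sqrt(intragroup variance / group size); with a
#' single group it reduces to the intragroup-only variant
#' sqrt(intragroup variance). Lower is more stable.
#'
#' @param cq Long Cq tibble restricted to candidates with 100% call rate;
#'   column `group` supplies the group labels.
#' @param use_groups Use group labels when more than one group is present
#'   (default); `FALSE` forces the single-group variant.
#' @return A tibble `target_id`, `card`, `normfinder_value`.
#' @export
normfinder_stability <- function(cq, use_groups = TRUE) {
  mat <- cq_matrix_complete(cq)
  k <- nrow(mat)
  if (k < 2L) abort("NormFinder needs at least 2 candidates.")
  grp <- sample_groups(cq, mat)
  if (!use_groups || length(unique(grp)) < 2L) grp <- rep("all", ncol(mat))
  sizes <- table(grp)
  if (any(sizes < 2L)) {
    abort("Every group needs at least 2 samples for NormFinder.")
  }
  d <- sweep(mat, 2, colMeans(mat))

  intragroup_var <- function(dg) {
    u <- apply(dg, 1, var)
    if (k >= 3L) {
      s_hat <- sum(u) / (1 - 1 / k)
      pmax((u - s_hat / k^2) / (1 - 2 / k), 0)
    } else {
      u
    }
  }

  groups <- unique(grp)
  if (length(groups) == 1L) {
    value <- sqrt(intragroup_var(d))
  } else {
    m_ig <- sapply(groups, function(g) rowMeans(d[, grp == g, drop = FALSE]))
    v_ig <- sapply(groups, function(g) intragroup_var(d[, grp == g, drop = FALSE]))
    gamma <- m_ig - rowMeans(m_ig)
    # Re-centre the per-group deviations on a precision-weighted median of
    # the candidates. Mean centring alone lets group regulation of *other*
    # candidates leak into every candidate's deviation (the deviations sum to
    # zero across candidates by construction); anchoring the zero point to
    # the most precise (lowest intragroup variance) candidates removes that
    # contamination, and the median keeps a few genuinely regulated
    # candidates from dragging the anchor.
    w <- 1 / (rowMeans(v_ig) + 1e-6)
    for (g in seq_along(groups)) {
      gamma[, g] <- gamma[, g] - weighted_median(gamma[, g], w)
    }
    se <- sqrt(sweep(v_ig, 2, as.numeric(sizes[groups]), "/"))
    value <- rowMeans(abs(gamma) + se)
  }
  cards <- cq |> distinct(.data$target_id, .data$card)
  tibble(target_id = rownames(mat), normfinder_value = unname(value)) |>
    left_join(cards, by = "target_id") |>
    select("target_id", "card", "normfinder_value")
}

#' Comprehensive rank across stability methods
#'
#' Combines complete 1-based rankings from several stability methods into the
#' overall ranking: the score of a candidate is the geometric mean of its
#' per-method ranks, the final order is ascending by score with ties broken
#' lexicographically by target id. Ties within a method should be given
#' average ranks.
#'
#' @param ranks A tibble with a `target_id` column and one numeric rank column
#'   per method; every method must rank the same candidate set completely.
#' @return The input with `comprehensive_score` and `final_rank` appended,
#'   sorted by `final_rank`.
#' @examples
#' comprehensive_rank(tibble::tibble(target_id = c("a", "b"),
#'                                   m1 = c(1, 2), m2 = c(2, 1),
#'                                   m3 = c(1, 2), m4 = c(2, 1)))
#' @export
comprehensive_rank <- function(ranks) {
  if (!"target_id" %in% names(ranks)) abort("`ranks` needs a `target_id` column.")
  rank_cols <- setdiff(names(ranks), c("target_id", "card"))
  rm <- as.matrix(ranks[, rank_cols, drop = FALSE])
  if (!is.numeric(rm) || anyNA(rm)) {
    abort("Every method must supply a complete numeric ranking of the same candidates.")
  }
  if (any(rm < 1)) abort("Ranks must be 1-based.")
  score <- exp(rowMeans(log(rm)))
  out <- ranks
  out$comprehensive_score <- score
  ord <- order(score, out$target_id)
  out$final_rank <- integer(nrow(out))
  out$final_rank[ord] <- seq_len(nrow(out))
  arrange(out, .data$final_rank)
}

#' Rank candidate reference targets by expression stability
#'
#' Runs all four stability algorithms on the 100%-call-rate candidate set and
#' combines them: per-method statistics, per-method 1-based ranks (ties get
#' average ranks), the comprehensive score (geometric mean of the four ranks)
#' and the final rank (ascending score, ties by target id). Cards are ranked
#' separately and the results stacked.
#'
#' @param cq Long Cq tibble restricted to candidates with 100% call rate.
#' @param use_groups Group-aware NormFinder when group labels exist.
#' @param stepwise Also report the geNorm stepwise-exclusion rank (the raw-M
#'   rank remains the input to the comprehensive rank).
#' @return A `stability_report` tibble: one row per candidate with every
#'   statistic, every rank, `comprehensive_score` and `final_rank`.
#' @export
rank_stability <- function(cq, use_groups = TRUE, stepwise = FALSE) {
  per_card <- cq |>
    dplyr::group_by(.data$card) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      bk <- bestkeeper_stats(one)
      gn <- genorm_m(one, stepwise = stepwise)
      dc <- deltact_stability(one)
      nf <- normfinder_stability(one, use_groups = use_groups)
      tab <- bk |>
        left_join(gn, by = c("target_id", "card")) |>
        left_join(dc, by = c("target_id", "card")) |>
        left_join(nf, by = c("target_id", "card")) |>
        mutate(
          rank_bestkeeper = rank(.data$bestkeeper_sd),
          rank_genorm = rank(.data$genorm_m),
          rank_deltact = rank(.data$deltact_mean_sd),
          rank_normfinder = rank(.data$normfinder_value)
        )
      scored <- comprehensive_rank(
        tab |> select("target_id", "rank_bestkeeper", "rank_genorm",
                      "rank_deltact", "rank_normfinder")
      ) |> select("target_id", "comprehensive_score", "final_rank")
      left_join(tab, scored, by = "target_id") |>
        arrange(.data$final_rank)
    })
  out <- purrr::list_rbind(per_card)
  class(out) <- c("stability_report", class(out))
  out
}

#' @rdname rank_stability
#' @param x A `stability_report`.
#' @param ... Unused.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stability_report")
  out
}

#' @rdname rank_stability
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  x |>
    group_by(.data$card) |>
    summarise(
      n_candidates = n(),
      best_target = .data$target_id[which.min(.data$final_rank)],
      best_score = min(.data$comprehensive_score),
      .groups = "drop"
    )
}

#' Per-sample normalization factors
#'
#' Builds the normalization factor used by the relative-expression stage:
#' either the geometric mean, per sample and card, of the Cq values of all
#' 100%-call-rate targets on that card (global normalization), or the raw Cq
#' of a chosen reference target. The geometric mean is undefined when any
#' contributing Cq is zero or negative, and such input is an error.
#'
#' @param cq Long Cq tibble; for `method = "geomean"` it must be restricted to
#'   (or contain) targets with 100% call rate, which are selected
#'   automatically.
#' @param method `"geomean"` or `"reference"`.
#' @param reference Reference target id (required for `method = "reference"`).
#' @return A tibble `sample_id`, `card`, `group`, `value` (Cq cycles),
#'   `kind`, `n_targets`.
#' @export
normalization_factor <- function(cq, method = c("geomean", "reference"),
                                 reference = NULL) {
  method <- match.arg(method)
  df <- drop_negative_controls(cq)
  groups <- df |> distinct(.data$sample_id, .data$group)
  if (method == "reference") {
    if (is.null(reference)) abort("`reference` target id is required.")
    ref <- df |> filter(.data$target_id == reference)
    if (!nrow(ref)) abort(sprintf("Reference target `%s` not found.", reference))
    if (anyNA(ref$cq)) {
      abort(sprintf("Reference target `%s` has missing Cq values.", reference))
    }
    return(ref |>
             select("sample_id", "card", "group", value = "cq") |>
             mutate(kind = "reference_target", n_targets = 1L))
  }
  per_card <- df |>
    dplyr::group_by(.data$card) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      one$.ok <- reliable_calls(one)
      complete <- one |>
        group_by(.data$target_id) |>
        summarise(complete = all(.data$.ok), .groups = "drop") |>
        filter(.data$complete)
      if (!nrow(complete)) {
        abort("No targets with 100% call rate on card; geometric-mean factor undefined.")
      }
      sub <- one |> dplyr::semi_join(complete, by = "target_id")
      if (any(sub$cq <= 0, na.rm = TRUE)) {
        abort("Geometric mean cannot be calculated: Cq values contain zeros or negatives.")
      }
      sub |>
        group_by(.data$sample_id, .data$card, .data$group) |>
        summarise(value = geometric_mean(.data$cq),
                  n_targets = n(), .groups = "drop") |>
        mutate(kind = "geometric_mean")
    })
  purrr::list_rbind(per_card) |>
    select("sample_id", "card", "group", "value", "kind", "n_targets")
}

#' Group stability of a normalization factor
#'
#' A normalization factor should not differ between the study groups: a
#' two-sided Wilcoxon rank-sum test compares the per-sample factor values
#' between the two groups, per card, and the factor is flagged `"unstable"`
#' when p < `alpha`. With fewer than 3 samples in a group a warning is raised
#' and the exact test used.
#'
#' @param factor_tbl Output of [normalization_factor()] (needs `group`).
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A tibble per card: group sizes, `statistic` (rank-sum W),
#'   `p_value`, `verdict` (`"stable"`/`"unstable"`).
#' @export
factor_group_stability <- function(factor_tbl, alpha = 0.05) {
  factor_tbl |>
    dplyr::group_by(.data$card) |>
    dplyr::group_split() |>
    purrr::map(function(one) {
      gs <- unique(one$group)
      if (length(gs) != 2L) abort("Exactly two groups are required.")
      x <- one$value[one$group == gs[1]]
      y <- one$value[one$group == gs[2]]
      if (min(length(x), length(y)) < 3L) {
        warn("A group has fewer than 3 samples; exact rank-sum test used.")
      }
      ht <- suppressWarnings(wilcox.test(x, y, exact = NULL))
      pv <- ht$p.value
      if (is.nan(pv)) pv <- 1 # fully tied data carry no rank evidence
      tibble(
        card = one$card[1], group1 = gs[1], group2 = gs[2],
        n1 = length(x), n2 = length(y),
        statistic = unname(ht$statistic), p_value = pv,
        verdict = ifelse(pv < alpha, "unstable", "stable")
      )
    }) |>
    purrr::list_rbind()
}

#' Agreement between a reference target and the global factor
#'
#' Pearson correlation, across samples, of a reference target's raw Cq with
#' the per-sample geometric-mean factor. High correlation indicates the two
#' normalization strategies are interchangeable on the card.
#'
#' @param cq Long Cq tibble containing the reference target.
#' @param reference Reference target id.
#' @param factor_tbl Output of [normalization_factor()] for the same samples.
#' @return A tibble: `reference`, `n`, `estimate` (Pearson r), `p_value`.
#' @export
reference_factor_agreement <- function(cq, reference, factor_tbl) {
  ref <- cq |> filter(.data$target_id == reference, !is.na(.data$cq))
  joined <- inner_join(ref |> select("sample_id", "cq"),
                       factor_tbl |> select("sample_id", "value"),
                       by = "sample_id")
  if (nrow(joined) < 3L) abort("At least 3 samples are required for the correlation.")
  ht <- cor.test(joined$cq, joined$value, method = "pearson")
  tibble(reference = reference, n = nrow(joined),
         estimate = unname(ht$estimate), p_value = ht$p.value)
}
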