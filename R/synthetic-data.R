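#' Parameters of a simulated amplification curve
#'
#' A simulated well follows a four-parameter logistic riding on a linear
#' baseline: at cycle \eqn{c} the expected normalized reporter signal is
#' \deqn{Rn(c) = \beta_0 + \beta_1 c + \frac{A}{1 + e^{-(c - m)/b}}}
#' with i.i.d. Gaussian noise added per cycle. The four phases of a real
#' amplification plot (baseline, exponential, linear, plateau) are all
#' exhibited by this minimal model. `amplitude = 0` encodes a non-amplifying
#' well.
#'
#' The default steepness corresponds to perfect doubling per cycle: for
#' amplification efficiency \eqn{E} the logistic scale is
#' \eqn{b = 1/\ln(1+E)}, so \eqn{E = 1} gives \eqn{b \approx 1.44}.
#'
#' @param baseline_intercept Baseline fluorescence at cycle 0 (fluorescence
#'   units).
#' @param baseline_slope Linear baseline drift (fluorescence units per cycle).
#' @param amplitude Plateau rise above the baseline (fluorescence units,
#'   >= 0). Zero encodes a non-amplifying well.
#' @param midpoint_cycle Cycle of the logistic midpoint (inflection), > 0.
#' @param steepness Logistic scale parameter in cycles, > 0; smaller is
#'   steeper.
#' @param noise_sd Standard deviation of per-cycle Gaussian noise
#'   (fluorescence units, >= 0).
#' @param n_cycles Number of PCR cycles (integer >= 10, default 40).
#' @return A validated `curve_params` list.
#' @seealso [simulate_curve()], [analytic_crossing()]
#' @export
curve_params <- function(baseline_intercept = 0.05,
                         baseline_slope = 0.001,
                         amplitude = 1,
                         midpoint_cycle = 25,
                         steepness = 1.44,
                         noise_sd = 0.01,
                         n_cycles = 40L) {
  stopifnot_scalar_number(baseline_intercept, "baseline_intercept")
  stopifnot_scalar_number(baseline_slope, "baseline_slope")
  stopifnot_scalar_number(amplitude, "amplitude", min = 0)
  stopifnot_scalar_number(midpoint_cycle, "midpoint_cycle", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(steepness, "steepness", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(n_cycles, "n_cycles", min = 10)
  structure(
    list(
      baseline_intercept = baseline_intercept,
      baseline_slope = baseline_slope,
      amplitude = amplitude,
      midpoint_cycle = midpoint_cycle,
      steepness = steepness,
      noise_sd = noise_sd,
      n_cycles = as.integer(n_cycles)
    ),
    class = "curve_params"
  )
}

#' Simulate one amplification curve
#'
#' Draws the noisy logistic-plus-baseline trajectory defined by
#' [curve_params()]. Reproducible: the same `params` and `seed` always yield
#' an identical trace, and the caller's RNG state is left untouched.
#'
#' @param params A `curve_params` object.
#' @param seed Integer seed for the per-cycle noise.
#' @param sample_id,well,target_id,card Identifiers attached to the returned
#'   rows (defaults suit single-curve use).
#' @return A tibble with columns `sample_id`, `card`, `well`, `target_id`,
#'   `cycle`, `rn`; the generating parameters are kept in attribute
#'   `"params"` (ground truth is never discarded).
#' @examples
#' simulate_curve(curve_params(noise_sd = 0), seed = 1)
#' @export
simulate_curve <- function(params, seed,
                           sample_id = "s1", well = "w001",
                           target_id = "t1", card = "A") {
  if (!inherits(params, "curve_params")) params <- do.call(curve_params, params)
  cycles <- seq_len(params$n_cycles)
  mu <- params$baseline_intercept + params$baseline_slope * cycles +
    params$amplitude / (1 + exp(-(cycles - params$midpoint_cycle) / params$steepness))
  noise <- if (params$noise_sd > 0) {
    with_seed(seed, rnorm(length(cycles), 0, params$noise_sd))
  } else {
    numeric(length(cycles))
  }
  out <- tibble(
    sample_id = sample_id, card = card, well = well, target_id = target_id,
    cycle = cycles, rn = mu + noise
  )
  attr(out, "params") <- params
  out
}

#' Analytic threshold crossing of the noise-free curve model
#'
#' Inverts the noise-free, baseline-subtracted logistic
#' \eqn{A/(1+e^{-(c-m)/b})} at a fluorescence threshold: the crossing cycle is
#' \eqn{c = m + b \log(t/(A-t))} for \eqn{0 < t < A}. This closed form is the
#' ground-truth Cq used to validate every threshold algorithm.
#'
#' @param params A `curve_params` object (noise and baseline are ignored).
#' @param threshold Fluorescence threshold, > 0.
#' @return The fractional crossing cycle, or `NA_real_` when the threshold is
#'   never reached (`threshold >= amplitude`).
#' @examples
#' analytic_crossing(curve_params(amplitude = 1, midpoint_cycle = 25,
#'                                steepness = 1.5), 0.2)
#' @export
analytic_crossing <- function(params, threshold) {
  if (!inherits(params, "curve_params")) params <- do.call(curve_params, params)
  stopifnot_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE)
  if (threshold >= params$amplitude) return(NA_real_)
  params$midpoint_cycle +
    params$steepness * log(threshold / (params$amplitude - threshold))
}

#' Layout of one simulated 384-assay microfluidic card
#'
#' Reproduces the control complement of the real two-card assay set: per card,
#' four wells of "U6 snRNA-001973", one "RNU44-001094", one "RNU48-001006"
#' (endogenous controls) and one non-human negative control "ath-miR-159",
#' leaving 377 miRNA assay wells (so cards A + B carry 754 miRNAs).
#'
#' @param card `"A"` or `"B"`.
#' @param n_mirna Number of miRNA assays on the card (default 377).
#' @return A tibble with columns `card`, `well`, `target_id`, `control`
#'   (`NA`, `"endogenous"` or `"negative"`).
#' @export
card_layout <- function(card = c("A", "B"), n_mirna = 377L) {
  card <- match.arg(card)
  stopifnot_scalar_number(n_mirna, "n_mirna", min = 1)
  controls <- c(
    rep("U6 snRNA-001973", 4L), "RNU44-001094", "RNU48-001006", "ath-miR-159"
  )
  control_kind <- c(rep("endogenous", 6L), "negative")
  mirnas <- sprintf("miR-%s-%03d", card, seq_len(n_mirna))
  tibble(
    card = card,
    well = sprintf("w%03d", seq_len(n_mirna + length(controls))),
    target_id = c(controls, mirnas),
    control = c(control_kind, rep(NA_character_, n_mirna))
  )
}

#' Simulate a set of amplification curves with ground truth
#'
#' Generates one curve per sample x target on a card. Per-target logistic
#' midpoints encode abundance; a fraction of targets never amplify. The true
#' Cq of each curve is defined as the [analytic_crossing()] of its noise-free,
#' baseline-subtracted model at `truth_threshold`.
#'
#' @param n_samples,n_targets Counts of samples and targets.
#' @param seed Integer seed.
#' @param card Card label.
#' @param groups Optional named integer vector of group sizes summing to
#'   `n_samples` (e.g. `c(case = 2, control = 2)`); group labels are recorded
#'   in the truth table.
#' @param amplitude_range,midpoint_range,steepness_range Uniform sampling
#'   ranges for the curve parameters (steepness default spans amplification
#'   efficiency 0.8--1.1).
#' @param noise_sd Per-cycle Gaussian noise SD.
#' @param prop_nonamp Proportion of targets that never amplify (amplitude 0).
#' @param n_cycles PCR cycles per curve.
#' @param truth_threshold Threshold defining the ground-truth Cq.
#' @return A list of class `curve_sim` with elements `curves` (long tibble:
#'   `sample_id`, `card`, `well`, `target_id`, `cycle`, `rn`), `truth` (one
#'   row per curve with the generating parameters and `true_cq`) and
#'   `metadata` (`sample_id`, `group`).
#' @export
simulate_curve_dataset <- function(n_samples = 4L, n_targets = 8L, seed = 1L,
                                   card = "A", groups = NULL,
                                   amplitude_range = c(0.6, 2.5),
                                   midpoint_range = c(20, 30),
                                   steepness_range = c(1.35, 1.70),
                                   noise_sd = 0.01,
                                   prop_nonamp = 0.1,
                                   n_cycles = 40L,
                                   truth_threshold = 0.2) {
  stopifnot_scalar_number(n_samples, "n_samples", min = 1)
  stopifnot_scalar_number(n_targets, "n_targets", min = 1)
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  if (is.null(groups)) {
    metadata <- tibble(sample_id = sample_ids, group = "all")
  } else {
    if (sum(groups) != n_samples) abort("`groups` sizes must sum to `n_samples`.")
    metadata <- tibble(sample_id = sample_ids, group = rep(names(groups), groups))
  }
  targets <- sprintf("miR-%s-%03d", card, seq_len(n_targets))

  design <- with_seed(seed, {
    n_non <- round(prop_nonamp * n_targets)
    nonamp <- sample(targets, n_non)
    target_tbl <- tibble(
      target_id = targets,
      base_midpoint = runif(n_targets, midpoint_range[1], midpoint_range[2]),
      amplitude_t = runif(n_targets, amplitude_range[1], amplitude_range[2]),
      steepness = runif(n_targets, steepness_range[1], steepness_range[2]),
      nonamp = targets %in% nonamp
    )
    grid <- tidyr::expand_grid(sample_id = sample_ids, target_id = targets)
    grid$midpoint <- target_tbl$base_midpoint[match(grid$target_id, target_tbl$target_id)] +
      rnorm(nrow(grid), 0, 0.3)
    grid$curve_seed <- sample.int(.Machine$integer.max, nrow(grid))
    list(target_tbl = target_tbl, grid = grid)
  })

  tt <- design$target_tbl
  grid <- design$grid
  grid$well <- sprintf("w%03d", match(grid$target_id, targets))
  truth <- grid |>
    left_join(tt, by = "target_id") |>
    mutate(
      amplitude = ifelse(.data$nonamp, 0, .data$amplitude_t),
      card = card,
      baseline_intercept = 0.05,
      baseline_slope = 0.001,
      noise_sd = noise_sd,
      n_cycles = as.integer(n_cycles)
    ) |>
    select("sample_id", "card", "well", "target_id", "amplitude",
           midpoint_cycle = "midpoint", "steepness",
           "baseline_intercept", "baseline_slope", "noise_sd", "n_cycles",
           "curve_seed")
  truth$true_cq <- purrr::pmap_dbl(truth, function(amplitude, midpoint_cycle,
                                                   steepness, n_cycles, ...) {
    if (amplitude <= truth_threshold) return(NA_real_)
    p <- curve_params(amplitude = amplitude, midpoint_cycle = midpoint_cycle,
                      steepness = steepness, noise_sd = 0, n_cycles = n_cycles)
    analytic_crossing(p, truth_threshold)
  })

  curves <- purrr::pmap(truth, function(sample_id, card, well, target_id,
                                        amplitude, midpoint_cycle, steepness,
                                        baseline_intercept, baseline_slope,
                                        noise_sd, n_cycles, curve_seed, ...) {
    p <- curve_params(baseline_intercept, baseline_slope, amplitude,
                      midpoint_cycle, steepness, noise_sd, n_cycles)
    simulate_curve(p, seed = curve_seed, sample_id = sample_id, well = well,
                   target_id = target_id, card = card)
  }) |> purrr::list_rbind()

  structure(
    list(curves = curves, truth = truth, metadata = metadata,
         truth_threshold = truth_threshold, seed = seed),
    class = "curve_sim"
  )
}

#' Simulate a Cq data set with designated stable reference targets
#'
#' Generates a long-format Cq table under an additive model:
#' \deqn{Cq_{ts} = base_t + effect_{t,g(s)} + shift_s + \epsilon_{ts}}
#' where \eqn{shift_s} is a per-sample global abundance factor and
#' \eqn{\epsilon} is technical/biological noise with a per-target SD.
#' Designated stable targets have zero group effect and minimal noise;
#' missing entries are introduced completely at random. Defaults encode the
#' rank-recovery study design: one stable target (SD 0.05) among 20 targets
#' with SD >= 0.5, half of the unstable targets carrying a group shift,
#' 25 + 25 samples.
#'
#' @param n_targets Total number of targets (>= 2).
#' @param groups Named integer vector of group sizes; every group needs >= 2
#'   samples.
#' @param n_stable Number of designated stable targets.
#' @param stable_sd Technical SD of stable targets (Cq cycles).
#' @param target_sd_range Uniform range of per-target SD for unstable targets.
#' @param effect_range Uniform range of |group effect| (Cq cycles) for shifted
#'   targets; the sign is random. The first group is the reference (effect 0).
#' @param prop_shifted Proportion of unstable targets receiving a group
#'   effect.
#' @param base_cq_range Uniform range of per-target base Cq.
#' @param sample_shift_sd SD of the per-sample global shift.
#' @param missingness Probability that any cell is missing (MCAR, 0--1).
#' @param card Card label recorded on every target.
#' @param seed Integer seed.
#' @return A list of class `cq_sim` with elements `cq` (long tibble:
#'   `target_id`, `card`, `sample_id`, `group`, `cq`, `control`), `truth`
#'   (per-target tibble with `base_cq`, `sd`, `stable`, `effect_*` columns)
#'   and `metadata` (`sample_id`, `group`).
#' @export
simulate_cq_dataset <- function(n_targets = 20L,
                                groups = c(case = 25L, control = 25L),
                                n_stable = 1L,
                                stable_sd = 0.05,
                                target_sd_range = c(0.5, 1.5),
                                effect_range = c(0.5, 2),
                                prop_shifted = 0.5,
                                base_cq_range = c(20, 30),
                                sample_shift_sd = 0.5,
                                missingness = 0.05,
                                card = "A",
                                seed = 1L) {
  stopifnot_scalar_number(n_targets, "n_targets", min = 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named vector of group sizes.")
  }
  if (any(groups < 2)) {
    abort("Every group needs at least 2 samples; downstream tests are undefined otherwise.")
  }
  if (n_stable >= n_targets) abort("`n_stable` must be smaller than `n_targets`.")
  stopifnot_scalar_number(missingness, "missingness", min = 0)
  if (missingness >= 1) abort("`missingness` must be < 1.")

  n_samples <- sum(groups)
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  group_of <- rep(names(groups), groups)
  targets <- sprintf("miR-%s-%03d", card, seq_len(n_targets))

  sim <- with_seed(seed, {
    stable <- c(rep(TRUE, n_stable), rep(FALSE, n_targets - n_stable))
    sds <- ifelse(stable, stable_sd,
                  runif(n_targets, target_sd_range[1], target_sd_range[2]))
    base <- runif(n_targets, base_cq_range[1], base_cq_range[2])
    n_unstable <- n_targets - n_stable
    shifted <- stable == FALSE &
      seq_len(n_targets) %in% (n_stable + sample(n_unstable, round(prop_shifted * n_unstable)))
    # effect of each non-reference group, per target
    eff <- matrix(0, n_targets, length(groups),
                  dimnames = list(targets, names(groups)))
    for (g in names(groups)[-1]) {
      eff[shifted, g] <- sample(c(-1, 1), sum(shifted), replace = TRUE) *
        runif(sum(shifted), effect_range[1], effect_range[2])
    }
    shift_s <- rnorm(n_samples, 0, sample_shift_sd)
    noise <- matrix(rnorm(n_targets * n_samples), n_targets, n_samples) * sds
    cq <- base + eff[, group_of, drop = FALSE] +
      matrix(shift_s, n_targets, n_samples, byrow = TRUE) + noise
    miss <- matrix(runif(n_targets * n_samples) < missingness,
                   n_targets, n_samples)
    cq[miss] <- NA_real_
    list(cq = cq, stable = stable, sds = sds, base = base, eff = eff,
         shift_s = shift_s)
  })

  truth <- tibble(
    target_id = targets, card = card, base_cq = sim$base, sd = sim$sds,
    stable = sim$stable
  )
  eff_tbl <- as_tibble(sim$eff)
  names(eff_tbl) <- paste0("effect_", names(eff_tbl))
  truth <- dplyr::bind_cols(truth, eff_tbl)

  cq_long <- tibble(
    target_id = rep(targets, times = n_samples),
    card = card,
    sample_id = rep(sample_ids, each = n_targets),
    group = rep(group_of, each = n_targets),
    cq = as.vector(sim$cq),
    control = NA_character_
  )

  structure(
    list(
      cq = cq_long,
      truth = truth,
      metadata = tibble(sample_id = sample_ids, group = group_of),
      design = list(groups = groups, seed = seed, card = card,
                    missingness = missingness)
    ),
    class = "cq_sim"
  )
}

#' @export
print.cq_sim <- function(x, ...) {
  cat("<cq_sim> ", dplyr::n_distinct(x$cq$target_id), " targets x ",
      dplyr::n_distinct(x$cq$sample_id), " samples (",
      paste(sprintf("%s=%d", names(x$design$groups), x$design$groups),
            collapse = ", "),
      "); ", sum(x$truth$stable), " stable target(s)\n", sep = "")
  invisible(x)
}

#' @export
print.curve_sim <- function(x, ...) {
  cat("<curve_sim> ", nrow(x$truth), " curves (",
      dplyr::n_distinct(x$truth$sample_id), " samples x ",
      dplyr::n_distinct(x$truth$target_id), " targets), ",
      max(x$curves$cycle), " cycles\n", sep = "")
  invisible(x)
}

#' @rdname simulate_cq_dataset
#' @param x A `cq_sim` or `curve_sim` object.
#' @param ... Unused.
#' @method tidy cq_sim
#' @export
tidy.cq_sim <- function(x, ...) x$cq

#' @rdname simulate_curve_dataset
#' @param x A `curve_sim` object.
#' @param ... Unused.
#' @method tidy curve_sim
#' @export
tidy.curve_sim <- function(x, ...) x$curves
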