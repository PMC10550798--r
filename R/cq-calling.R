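# Cq determination under the three threshold algorithms compared in
# low-density-array practice: a manually fixed threshold (default 0.2), a
# per-target automatic threshold placed in the exponential region, and a
# per-curve relative (efficiency-based) threshold that is scale- and
# offset-invariant by construction. The automatic and relative methods are
# open analogues of proprietary instrument algorithms: they honour the same
# contracts (per-target shared threshold; threshold-free per-curve call) but
# make no claim of bit-compatibility with any vendor software.

# ---- per-curve engine -------------------------------------------------------

# Two-pass baseline estimation. Pass 1 fits a line to cycles 3..10 and locates
# the emergence of amplification as the first cycle whose (smoothed) corrected
# signal exceeds max(0.2% of the rise, 3x the pass-1 residual SD). Pass 2
# refits the line on cycles 3..(emergence - 6), clamped to [5, 15] so at least
# three cycles remain; when no emergence is detected the pass-1 window 3..10
# is kept. Keeping the window well clear of emergence bounds contamination of
# the fit by the exponential tail, which would otherwise bias Cq by up to
# ~0.1 cycles for early amplifiers. All decisions use signal ratios, so the
# corrected trace transforms exactly linearly under rn -> a*rn + b.
baseline_correct_curve <- function(rn) {
  n <- length(rn)
  if (n < 10L) abort("Curves must have at least 10 cycles for baseline correction.")
  cyc <- seq_len(n)
  w1 <- 3:10
  f1 <- line_fit(cyc[w1], rn[w1])
  corr1 <- rn - (f1$intercept + f1$slope * cyc)
  sm1 <- ma3(corr1)
  rise <- max(sm1)
  floor_level <- max(0.002 * rise, 3 * f1$resid_sd)
  emerge <- which(sm1 > floor_level)[1]
  fallback <- FALSE
  if (is.na(emerge) || rise <= 0) {
    wend <- 10L
    fallback <- TRUE
  } else {
    wend <- emerge - 6L
    if (wend < 5L) {
      wend <- 5L
      fallback <- TRUE
    }
    wend <- min(wend, 15L)
  }
  w <- 3:wend
  f2 <- line_fit(cyc[w], rn[w])
  corrected <- rn - (f2$intercept + f2$slope * cyc)
  # The noise estimate uses the larger of the two residual SDs: the final
  # window can shrink to three cycles (one residual degree of freedom), where
  # its own residual SD is an unusable noise estimate.
  list(
    corrected = corrected,
    window = c(3L, as.integer(wend)),
    noise_sd = max(f1$resid_sd, f2$resid_sd),
    fallback = fallback
  )
}

# Fractional threshold crossing of a baseline-corrected signal. The first
# upward crossing is located on the integer grid, then refined with a
# monotone cubic Hermite interpolant of log-signal through the neighbouring
# positive cycles; degrades to log-linear, then linear, interpolation when too
# few positive points surround the crossing.
crossing_cycle <- function(cycle, s, threshold) {
  n <- length(s)
  below <- s < threshold
  i <- which(!below & c(TRUE, below[-n]))[1]
  if (is.na(i) || i == 1L) return(NA_real_)
  idx <- max(1L, i - 3L):min(n, i + 2L)
  idx <- idx[s[idx] > 0]
  if (length(idx) >= 3L && s[i - 1L] > 0) {
    f <- splinefun(cycle[idx], log(s[idx]), method = "monoH.FC")
    root <- tryCatch(
      uniroot(function(x) f(x) - log(threshold),
              lower = cycle[i - 1L], upper = cycle[i], tol = 1e-9)$root,
      error = function(e) NA_real_
    )
    if (!is.na(root)) return(root)
  }
  if (s[i - 1L] > 0) {
    return(cycle[i - 1L] +
             (log(threshold) - log(s[i - 1L])) / (log(s[i]) - log(s[i - 1L])))
  }
  cycle[i - 1L] + (threshold - s[i - 1L]) / (s[i] - s[i - 1L])
}

# Exponential-phase midpoint: cycle index of the maximum smoothed first
# difference of the corrected signal (the logistic inflection for sigmoid
# curves, where the signal sits at ~half the plateau rise).
exp_midpoint <- function(s) {
  d <- ma3(diff(s))
  which.max(d) + 1L
}

# Characterise the log-linear (exponential) region of a corrected curve:
# the longest run of cycles with signal in (2.5*noise, 0.9*rise), and the R^2
# of a line fit to log-signal over that run. Returns r2 = 0 and an empty run
# when no such region exists.
exp_region_fit <- function(cycle, s, noise_sd, rise) {
  lo <- max(2.5 * noise_sd, 1e-4 * rise) # relative floor clears numerical dust
  ok <- s > lo & s < 0.9 * rise
  runs <- rle(ok)
  if (!any(runs$values & runs$lengths >= 3L)) {
    return(list(r2 = 0, n = 0L))
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values & runs$lengths >= 3L)
  best <- keep[which.max(runs$lengths[keep])]
  idx <- starts[best]:ends[best]
  fit <- line_fit(cycle[idx], log(s[idx]))
  list(r2 = max(0, fit$r2), n = length(idx))
}

# All per-curve features shared by the Cq callers and the QC scores.
curve_features <- function(rn) {
  bl <- baseline_correct_curve(rn)
  s <- bl$corrected
  cyc <- seq_along(rn)
  sm <- ma3(s)
  rng <- diff(range(s))
  rise <- max(sm)
  noise <- max(bl$noise_sd, 1e-9 * max(rng, .Machine$double.xmin))
  mid <- exp_midpoint(s)
  reg <- exp_region_fit(cyc, s, noise, rise)
  # Nonlinearity of the trace: largest smoothed residual from a straight line
  # fit to the whole curve, in noise units. A sigmoid leaves residuals of the
  # order of the plateau rise; pure noise -- including the spurious ramp a
  # baseline-slope error produces under extrapolation -- is globally linear
  # and leaves residuals of the order of the noise itself.
  gl <- line_fit(cyc, s)
  nonlin <- max(0, max(ma3(s - (gl$intercept + gl$slope * cyc)))) / noise
  list(
    corrected = s, smoothed = sm, window = bl$window, fallback = bl$fallback,
    noise_sd = noise, rise = rise, range = rng, mid_idx = mid,
    mid_signal = s[mid], exp_r2 = reg$r2, exp_n = reg$n, nonlin_snr = nonlin
  )
}

# Relative (efficiency-based) Cq: rescale the smoothed corrected signal to
# [0, 1]; form the per-cycle efficiency e(c) = z(c+1)/z(c) - 1 on the positive
# part; smooth; take the cycle past the efficiency peak where the smoothed
# efficiency falls to 50% of its maximum; read the rescaled fluorescence there
# and return the fractional cycle at which the curve crosses that level.
# Every step commutes with positive affine transforms of the raw signal.
relative_cq_curve <- function(feat) {
  z_raw <- feat$smoothed
  rng <- diff(range(z_raw))
  if (rng <= 0 || rng < 5 * feat$noise_sd) return(NA_real_)
  z <- (z_raw - min(z_raw)) / rng
  cyc <- seq_along(z)
  ok <- z >= 1e-3
  e <- rep(NA_real_, length(z))
  idx <- which(ok[-length(z)] & ok[-1])
  e[idx] <- z[idx + 1L] / z[idx] - 1
  def <- which(!is.na(e))
  if (length(def) < 4L) return(NA_real_)
  e_def <- ma3(e[def])
  pk <- which.max(e_def)
  if (e_def[pk] <= 0) return(NA_real_)
  ref <- 0.5 * e_def[pk]
  after <- pk:length(def)
  drop_at <- NA_real_
  for (j in after[-length(after)]) {
    if (e_def[j] >= ref && e_def[j + 1L] < ref) {
      c1 <- cyc[def[j]]; c2 <- cyc[def[j + 1L]]
      drop_at <- c1 + (e_def[j] - ref) / (e_def[j] - e_def[j + 1L]) * (c2 - c1)
      break
    }
  }
  if (is.na(drop_at)) return(NA_real_)
  # fluorescence level at the efficiency-drop cycle (linear interpolation)
  lo <- floor(drop_at); hi <- ceiling(drop_at)
  level <- if (lo == hi) z[lo] else z[lo] + (drop_at - lo) * (z[hi] - z[lo])
  if (level <= 0) return(NA_real_)
  crossing_cycle(cyc, z, level)
}

# ---- tidy surface -----------------------------------------------------------

curve_keys <- c("sample_id", "card", "well", "target_id")

check_curves <- function(curves) {
  missing_cols <- setdiff(c(curve_keys, "cycle", "rn"), names(curves))
  if (length(missing_cols)) {
    abort(paste0("`curves` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  invisible(curves)
}

split_curves <- function(curves) {
  curves |>
    arrange(.data$sample_id, .data$card, .data$well, .data$cycle) |>
    group_by(across(all_of(curve_keys))) |>
    dplyr::group_split()
}

warn_fallback <- function(n_fallback, n_total) {
  if (n_fallback > 0) {
    warn(sprintf(
      "Baseline window fell back to its minimal extent for %d of %d curve(s) (no clear pre-amplification phase).",
      n_fallback, n_total
    ))
  }
}

#' Subtract the baseline component from amplification curves
#'
#' Fits a straight line to the detected pre-amplification window of each curve
#' (two-pass detection: a provisional fit on cycles 3--10 locates the
#' emergence of amplification, then the line is refit on cycles 3 up to six
#' cycles before emergence, clamped to at least three cycles) and subtracts
#' it. Curves with no detectable pre-amplification phase fall back to the
#' fixed window 3--10 and a summarising warning is raised.
#'
#' @param curves Long-format tibble with columns `sample_id`, `card`, `well`,
#'   `target_id`, `cycle`, `rn` (one row per cycle).
#' @return The input tibble with additional columns `rn_corrected`,
#'   `bl_start`, `bl_end` (baseline window in cycles) and `bl_noise_sd`
#'   (residual SD of the baseline fit).
#' @export
subtract_baseline <- function(curves) {
  check_curves(curves)
  pieces <- split_curves(curves)
  n_fb <- 0L
  out <- purrr::map(pieces, function(cv) {
    bl <- baseline_correct_curve(cv$rn)
    if (bl$fallback) n_fb <<- n_fb + 1L
    cv$rn_corrected <- bl$corrected
    cv$bl_start <- bl$window[1]
    cv$bl_end <- bl$window[2]
    cv$bl_noise_sd <- bl$noise_sd
    cv
  }) |> purrr::list_rbind()
  warn_fallback(n_fb, length(pieces))
  out
}

#' Call quantification cycles (Cq) from amplification curves
#'
#' Determines one Cq per curve under the chosen threshold algorithm:
#'
#' * `"fixed"`: the fractional cycle at which the baseline-corrected signal
#'   first crosses a user-set fluorescence threshold (default 0.2), refined
#'   with a monotone interpolant of log-signal.
#' * `"automatic"`: one threshold per target, shared by all of that target's
#'   curves: 20% of the geometric-mean plateau rise over the target's
#'   amplified curves, the plateau rise being estimated as twice the
#'   corrected signal at the detected exponential-phase midpoint. This places
#'   the threshold in the exponential region (it coincides with the 0.2
#'   default for unit-rise curves).
#' * `"relative"`: a per-curve, threshold-free call from the rescaled
#'   reaction-efficiency model; invariant under positive affine transforms of
#'   the fluorescence scale, so no `threshold_used` is reported.
#'
#' @param curves Long-format curve tibble (see [subtract_baseline()]).
#' @param method One of `"fixed"`, `"automatic"`, `"relative"`.
#' @param threshold Fluorescence threshold for `method = "fixed"` (> 0).
#' @return A tibble with one row per curve: `sample_id`, `card`, `well`,
#'   `target_id`, `method`, `cq` (`NA` when the curve never crosses),
#'   `threshold_used` (`NA` for the relative method), `bl_start`, `bl_end`.
#' @examples
#' cv <- simulate_curve(curve_params(noise_sd = 0), seed = 1)
#' call_cq(cv, method = "fixed", threshold = 0.2)
#' @export
call_cq <- function(curves, method = c("fixed", "automatic", "relative"),
                    threshold = 0.2) {
  method <- match.arg(method)
  check_curves(curves)
  if (method == "fixed") {
    stopifnot_scalar_number(threshold, "threshold", min = 0, strict_min = TRUE)
  }
  pieces <- split_curves(curves)
  n_fb <- 0L
  feats <- purrr::map(pieces, function(cv) {
    ft <- curve_features(cv$rn)
    if (ft$fallback) n_fb <<- n_fb + 1L
    ft
  })
  keys <- purrr::map(pieces, function(cv) cv[1, curve_keys]) |> purrr::list_rbind()

  if (method == "fixed") {
    cqs <- purrr::map2_dbl(pieces, feats, function(cv, ft) {
      crossing_cycle(cv$cycle, ft$corrected, threshold)
    })
    thr_used <- rep(threshold, length(pieces))
  } else if (method == "relative") {
    cqs <- purrr::map_dbl(feats, relative_cq_curve)
    thr_used <- rep(NA_real_, length(pieces))
  } else {
    # automatic: per-target threshold shared across that target's curves
    amp_ok <- purrr::map_lgl(feats, function(ft) {
      ft$mid_signal > 5 * ft$noise_sd && ft$mid_signal > 0
    })
    plateau <- purrr::map_dbl(feats, function(ft) 2 * ft$mid_signal)
    tgt <- paste(keys$card, keys$target_id, sep = "\r")
    thr_used <- rep(NA_real_, length(pieces))
    for (t in unique(tgt)) {
      sel <- tgt == t
      good <- sel & amp_ok & plateau > 0
      if (any(good)) thr_used[sel] <- 0.2 * geometric_mean(plateau[good])
    }
    if (all(is.na(thr_used))) {
      warn("No curve with a detectable exponential phase; all automatic calls are NA.")
    }
    cqs <- purrr::pmap_dbl(list(pieces, feats, thr_used), function(cv, ft, th) {
      if (is.na(th)) return(NA_real_)
      crossing_cycle(cv$cycle, ft$corrected, th)
    })
  }
  warn_fallback(n_fb, length(pieces))

  out <- keys
  out$method <- method
  out$cq <- cqs
  out$threshold_used <- thr_used
  out$bl_start <- purrr::map_int(feats, function(ft) ft$window[1])
  out$bl_end <- purrr::map_int(feats, function(ft) ft$window[2])
  as_tibble(out)
}
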