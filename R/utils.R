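#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join distinct n bind_rows rename across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd median var lm coef predict quantile rnorm runif
#'   kruskal.test wilcox.test cor.test p.adjust pnorm plogis setNames
#'   splinefun uniroot complete.cases
#' @importFrom utils head tail packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. Keeps all randomness tied to explicit seed arguments.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Geometric mean of strictly positive values
#'
#' The geometric mean is undefined when any value is zero or negative, so such
#' input is rejected rather than silently dropped.
#'
#' @param x Numeric vector of strictly positive values; `NA` is not allowed.
#' @return A single number, `(prod(x))^(1/length(x))`, computed on the log
#'   scale for numerical stability.
#' @examples
#' geometric_mean(c(2, 8)) # 4
#' @export
geometric_mean <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    abort("`x` must be a non-empty numeric vector.")
  }
  if (anyNA(x)) abort("`x` contains missing values; the geometric mean is undefined.")
  if (any(x <= 0)) {
    abort("Geometric mean cannot be computed: `x` contains zero or negative values.")
  }
  exp(mean(log(x)))
}

# Centered 3-point moving average; endpoints keep their own value averaged
# with the single available neighbour.
ma3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1L)] <- (x[1:(n - 2L)] + x[2:(n - 1L)] + x[3:n]) / 3
  out[1L] <- (x[1L] + x[2L]) / 2
  out[n] <- (x[n - 1L] + x[n]) / 2
  out
}

# Fast simple linear regression returning intercept, slope, residual sd, r2.
line_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(list(intercept = my, slope = 0, resid_sd = 0, r2 = 0))
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sum(resid^2) / syy else 0
  resid_sd <- if (n > 2L) sqrt(sum(resid^2) / (n - 2L)) else 0
  list(intercept = intercept, slope = slope, resid_sd = resid_sd, r2 = r2)
}

# Lower weighted median: smallest x whose cumulative weight reaches half the
# total.
weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min)
  if (!ok) {
    cmp <- if (strict_min) ">" else ">="
    abort(sprintf("`%s` must be a single finite number %s %s.", name, cmp, format(min)))
  }
  invisible(x)
}
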