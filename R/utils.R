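#' @keywords internal
"_PACKAGE"

# Derive a reproducible 31-bit sub-seed from a master seed and a facet label.
# Each generator facet (effects, noise, foci, ...) gets its own stream so that
# adding cells to one facet never perturbs another.
derive_seed <- function(seed, facet) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(facet))
  h <- sum(utf8ToInt(facet) * seq_along(utf8ToInt(facet)))
  # double arithmetic stays exact here (< 2^53); result fits 31 bits
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (`n > 0`).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector with `estimate`, `lower`, `upper`
#'   (all proportions in `[0, 1]`).
#' @examples
#' wilson_ci(48, 400)
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# Two-sample t on raw vectors with the degenerate-variance conventions used
# throughout the package: zero pooled variance with equal means -> p = 1;
# zero pooled variance with unequal means -> smallest positive double,
# flagged degenerate.
two_sample_t <- function(a, b, var_equal = TRUE) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (!is.finite(se) || se == 0) {
    if (diff == 0) {
      return(list(statistic = 0, p = 1, df = df, diff = diff,
                  degenerate = FALSE))
    }
    return(list(statistic = sign(diff) * Inf, p = .Machine$double.xmin,
                df = df, diff = diff, degenerate = TRUE))
  }
  tstat <- diff / se
  list(statistic = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df,
       diff = diff, degenerate = FALSE)
}

# stop() with a consistent prefix for user input problems
fail <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    fail("%s is missing required column(s): %s", what,
         paste(missing, collapse = ", "))
  }
  invisible(df)
}
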