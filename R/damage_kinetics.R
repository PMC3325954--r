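# Comet-assay summaries and recovery kinetics. Percent tail DNA is the
# per-cell fraction of DNA signal in the comet tail; repair after an
# oxidative pulse is summarized per time point and, as an extension beyond
# per-timepoint testing, fitted with a single-exponential recovery model
# D(t) = D_inf + (D0 - D_inf) * exp(-k t).

#' Five-number tail-percent summary per group and time point
#'
#' Box-plot style summary: median, quartiles and 5th/95th percentiles,
#' computed with linear interpolation between order statistics (R quantile
#' type 7) — stated because box-plot percentiles differ across tools.
#'
#' @param records data.frame with `group`, `time_min`, `tail_percent`
#'   (a `treatment` column, if present, joins the grouping).
#' @param min_n Warn for cell groups smaller than this (default 50, the
#'   usual minimum number of scored comets per condition).
#' @return data.frame with `group`, (`treatment`,) `time_min`, `n`, `p5`,
#'   `q25`, `median`, `q75`, `p95`.
#' @export
tail_summary <- function(records, min_n = 50) {
  check_columns(records, c("group", "time_min", "tail_percent"), "records")
  keys <- c("group", intersect("treatment", names(records)), "time_min")
  splits <- split(records, records[keys], drop = TRUE)
  out <- lapply(splits, function(d) {
    if (nrow(d) < min_n) {
      warning(sprintf("cell group %s/%s has %d cells (< %d)",
                      d$group[1], d$time_min[1], nrow(d), min_n))
    }
    q <- stats::quantile(d$tail_percent, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         type = 7, names = FALSE)
    cbind(d[1, keys, drop = FALSE],
          data.frame(n = nrow(d), p5 = q[1], q25 = q[2], median = q[3],
                     q75 = q[4], p95 = q[5]))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$group, res$time_min), ]
  rownames(res) <- NULL
  res
}

#' Compare two tail-percent distributions
#'
#' Primary p-value from a two-sample t-test (pooled variance by default,
#' matching the convention that identical samples give p = 1); a Wilcoxon
#' rank-sum p-value is reported alongside as a distribution-free check.
#'
#' @param a,b Numeric vectors of percent tail DNA, or data.frames with a
#'   `tail_percent` column.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return List with `p_t`, `p_ranksum`, `mean_diff` (`mean(a) - mean(b)`),
#'   `t`, `df`.
#' @export
compare_tail_distributions <- function(a, b, var_equal = TRUE) {
  if (is.data.frame(a)) a <- a$tail_percent
  if (is.data.frame(b)) b <- b$tail_percent
  tt <- two_sample_t(a, b, var_equal = var_equal)
  pw <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(p_t = tt$p, p_ranksum = pw, mean_diff = tt$diff,
       t = tt$statistic, df = tt$df)
}

recovery_mean <- function(par, t) par[2] + (par[1] - par[2]) * exp(-par[3] * t)

#' Fit the exponential recovery model to a comet time-course
#'
#' Least-squares fit of per-timepoint mean tail percent to
#' `D(t) = D_inf + (D0 - D_inf) exp(-k t)` with box constraints
#' `0 <= D0, D_inf <= 100`, `k >= 0`. Initialization is deterministic:
#' `D0` from the earliest time point's mean, `D_inf` from the latest, and
#' `k = log(2) / t_half` with `t_half` the time point whose mean is nearest
#' the midpoint of the two. Flat series (initial `|D0 - D_inf|` below 1e-8
#' of the scale) are returned as the constant model with `k = 0`.
#'
#' @param records data.frame with `time_min` and `tail_percent` (treated
#'   cells only: filter out untreated records first), or a data.frame of
#'   per-timepoint means with columns `time_min`, `mean_tail`.
#' @return A `recovery_fit` list: `D0`, `D_inf`, `k`, `rss`, `se` (approximate
#'   standard errors from the Gauss-Newton curvature), `fitted` data.frame,
#'   `converged`, `n_timepoints`.
#' @export
fit_recovery_curve <- function(records) {
  if (all(c("time_min", "tail_percent") %in% names(records))) {
    means <- vapply(split(records$tail_percent, records$time_min), mean,
                    numeric(1))
    tt <- as.numeric(names(means))
  } else if (all(c("time_min", "mean_tail") %in% names(records))) {
    tt <- records$time_min; means <- records$mean_tail
  } else {
    fail("records need time_min plus tail_percent or mean_tail")
  }
  ord <- order(tt); tt <- tt[ord]; means <- as.numeric(means)[ord]
  if (length(tt) < 3) fail("need at least 3 distinct timepoints")

  d0_init <- means[1]
  dinf_init <- means[length(means)]
  mid <- (d0_init + dinf_init) / 2
  t_half <- tt[which.min(abs(means - mid))]
  k_init <- if (t_half > 0) log(2) / t_half else 0.01

  flat <- abs(d0_init - dinf_init) < 1e-8 * max(1, abs(d0_init))
  if (flat) {
    m <- mean(means)
    return(structure(list(D0 = m, D_inf = m, k = 0,
                          rss = sum((means - m)^2),
                          se = c(D0 = NA, D_inf = NA, k = NA),
                          fitted = data.frame(time_min = tt, mean_tail = means,
                                              fitted = m),
                          converged = TRUE, n_timepoints = length(tt)),
                     class = "recovery_fit"))
  }

  sse <- function(par) sum((means - recovery_mean(par, tt))^2)
  grad <- function(par) {
    ek <- exp(-par[3] * tt)
    r <- recovery_mean(par, tt) - means
    c(2 * sum(r * ek), 2 * sum(r * (1 - ek)),
      2 * sum(r * -(par[1] - par[2]) * tt * ek))
  }
  fit <- stats::optim(c(d0_init, dinf_init, max(k_init, 1e-4)), sse, grad,
                      method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(100, 100, 20),
                      control = list(factr = 10, maxit = 500))
  par <- fit$par
  # enforce D_inf <= D0 (can only be violated for rising series, which the
  # damage-recovery model does not describe)
  if (par[2] > par[1]) {
    m <- mean(means)
    par <- c(m, m, 0)
  }
  # approximate SEs from the Jacobian at the optimum
  ek <- exp(-par[3] * tt)
  J <- cbind(ek, 1 - ek, -(par[1] - par[2]) * tt * ek)
  rss <- sse(par)
  dof <- length(tt) - 3
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    jtj <- crossprod(J)
    if (abs(det(jtj)) > 1e-12) {
      se <- sqrt(diag(solve(jtj)) * rss / dof)
    }
  }
  structure(list(D0 = par[1], D_inf = par[2], k = par[3], rss = rss,
                 se = c(D0 = se[1], D_inf = se[2], k = se[3]),
                 fitted = data.frame(time_min = tt, mean_tail = means,
                                     fitted = recovery_mean(par, tt)),
                 converged = fit$convergence == 0,
                 n_timepoints = length(tt)), class = "recovery_fit")
}
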