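# DNA-content (ploidy) profiling from per-nucleus integrated stain
# intensities: histogram peak detection for the 2N and 4N modes, band-based
# classification including the >4N re-replication brackets, EdU and focus
# summaries, and the focus-distribution goodness-of-fit test.

PLOIDY_CLASSES <- c("sub2N", "2N", "S", "4N", "bracket1", "bracket2")
FOCI_BINS <- c("0", "1-5", "6-10", ">10")

#' Build a DNA-content profile from per-nucleus intensities
#'
#' Histograms the intensities over `[0, P99.9]`, smooths the counts with a
#' centred moving average, and takes the 2N mode as the highest smoothed
#' local maximum and the 4N mode as the highest local maximum within
#' `[1.8, 2.2]` times the 2N mode. Class boundaries are symmetric `band`
#' tolerance bands around the detected modes; the region above
#' `(1 + band) * mu_4N` is split into two equal-width brackets, with the
#' right edge at the larger of the observed maximum and `2 * mu_4N`.
#'
#' @param records data.frame with a `dna_intensity` column, or a numeric
#'   vector of intensities.
#' @param n_bins Histogram bins (default 100).
#' @param band Half-width of the 2N/4N class bands as a fraction of the mode
#'   (default 0.15).
#' @param smooth_window Moving-average window in bins (odd, default 5).
#' @return A `dna_profile` with peak positions, class boundaries, the
#'   bracket split point and the histogram.
#' @export
build_dna_profile <- function(records, n_bins = 100, band = 0.15,
                              smooth_window = 5) {
  x <- if (is.data.frame(records)) records$dna_intensity else as.numeric(records)
  if (any(x <= 0)) fail("DNA intensities must be positive")
  if (length(x) < 100) {
    warning("fewer than 100 nuclei; peak detection may be unstable")
  }
  hi <- stats::quantile(x, 0.999, names = FALSE)
  breaks <- seq(0, hi, length.out = n_bins + 1)
  xx <- x[x <= hi]
  counts <- tabulate(findInterval(xx, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  k <- (smooth_window - 1) / 2
  padded <- c(rep(0, k), counts, rep(0, k))
  smoothed <- vapply(seq_along(counts),
                     function(i) mean(padded[i:(i + 2 * k)]), numeric(1))
  is_peak <- vapply(seq_along(smoothed), function(i) {
    lo <- max(1, i - 1); up <- min(length(smoothed), i + 1)
    smoothed[i] > 0 && smoothed[i] >= smoothed[lo] && smoothed[i] >= smoothed[up]
  }, logical(1))
  peaks <- mids[is_peak]
  heights <- smoothed[is_peak]
  mu2 <- peaks[which.max(heights)]
  in_window <- peaks >= 1.8 * mu2 & peaks <= 2.2 * mu2
  if (!any(in_window)) {
    fail(paste0("4N peak not found: no smoothed mode in [1.8, 2.2] x mu_2N",
                " (mu_2N = %.4g; candidate modes: %s)"), mu2,
         paste(signif(peaks, 4), collapse = ", "))
  }
  mu4 <- peaks[in_window][which.max(heights[in_window])]
  gt4_start <- (1 + band) * mu4
  gt4_end <- max(max(x), 2 * mu4)
  structure(list(
    mu_2N = mu2, mu_4N = mu4, band = band,
    boundaries = c(sub2N_max = (1 - band) * mu2,
                   n2_max = (1 + band) * mu2,
                   s_max = (1 - band) * mu4,
                   n4_max = gt4_start),
    gt4N_start = gt4_start, gt4N_end = gt4_end,
    bracket_split = (gt4_start + gt4_end) / 2,
    histogram = list(breaks = breaks, counts = counts, smoothed = smoothed),
    n = length(x)), class = "dna_profile")
}

#' Classify nuclei into ploidy classes from a DNA-content profile
#'
#' Classes partition the intensity axis:
#' `sub2N < (1-band) mu_2N <= 2N <= (1+band) mu_2N < S < (1-band) mu_4N <=
#' 4N <= (1+band) mu_4N < bracket1 <= split < bracket2`. An intensity exactly
#' at the bracket split belongs to bracket1.
#'
#' @param profile A [build_dna_profile()] result for the same population.
#' @param records data.frame with `dna_intensity` (and any other columns,
#'   which are carried through).
#' @return `records` with a `class` factor column over the six classes.
#' @export
classify_nuclei <- function(profile, records) {
  stopifnot(inherits(profile, "dna_profile"))
  x <- records$dna_intensity
  if (any(x <= 0)) fail("DNA intensities must be positive")
  b <- profile$boundaries
  cls <- ifelse(x < b[["sub2N_max"]], "sub2N",
         ifelse(x <= b[["n2_max"]], "2N",
         ifelse(x < b[["s_max"]], "S",
         ifelse(x <= b[["n4_max"]], "4N",
         ifelse(x <= profile$bracket_split, "bracket1", "bracket2")))))
  records$class <- factor(cls, levels = PLOIDY_CLASSES)
  records
}

#' Percent of EdU-positive nuclei in the upper re-replication bracket
#'
#' EdU-positive nuclei with DNA content in bracket 2 (the upper half of the
#' >4N region) are replicating at super-4N content, the operational signature
#' of re-replication. Reported per group as a percentage of all EdU-positive
#' nuclei with a Wilson 95% confidence interval.
#'
#' @param classified Output of [classify_nuclei()]; needs `edu_positive` and
#'   `group` columns.
#' @return data.frame with `group`, `n_edu`, `n_bracket2`, `percent`,
#'   `ci_lower`, `ci_upper` (percent scale).
#' @export
edu_bracket_fraction <- function(classified) {
  check_columns(classified, c("class", "edu_positive", "group"), "records")
  out <- lapply(split(classified, classified$group), function(d) {
    pos <- d[d$edu_positive, , drop = FALSE]
    if (nrow(pos) == 0) fail("group '%s' has no EdU-positive nuclei",
                             d$group[1])
    x <- sum(pos$class == "bracket2")
    ci <- wilson_ci(x, nrow(pos))
    data.frame(group = d$group[1], n_edu = nrow(pos), n_bracket2 = x,
               percent = 100 * ci[["estimate"]],
               ci_lower = 100 * ci[["lower"]], ci_upper = 100 * ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ploidy class percentages per group
#'
#' @param classified Output of [classify_nuclei()] with a `group` column;
#'   if a `replicate` column is present, percentages are computed per
#'   replicate and reported as mean and s.d. across replicates.
#' @return data.frame with `group`, `class`, `percent` (summing to 100 per
#'   group) and, with replicates, `sd`.
#' @export
ploidy_fractions <- function(classified) {
  check_columns(classified, c("class", "group"), "records")
  per_tab <- function(d) {
    tab <- table(factor(d$class, levels = PLOIDY_CLASSES))
    100 * as.numeric(tab) / nrow(d)
  }
  out <- lapply(split(classified, classified$group), function(d) {
    if (nrow(d) == 0) fail("empty group")
    if ("replicate" %in% names(d) && length(unique(d$replicate)) > 1) {
      reps <- vapply(split(d, d$replicate), per_tab,
                     numeric(length(PLOIDY_CLASSES)))
      data.frame(group = d$group[1], class = PLOIDY_CLASSES,
                 percent = rowMeans(reps), sd = apply(reps, 1, stats::sd),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = d$group[1], class = PLOIDY_CLASSES,
                 percent = per_tab(d), stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bin per-nucleus focus counts into the standard four bins
#'
#' Bins are `0`, `1-5`, `6-10`, `>10` foci per nucleus (boundaries
#' inclusive: 5 falls in `1-5`, 10 in `6-10`).
#'
#' @param records data.frame with `foci_count` and `group` columns, or a
#'   bare numeric vector of counts.
#' @return A `foci_bins` data.frame: one row per group with the four bin
#'   counts and `total`.
#' @export
bin_foci <- function(records) {
  if (!is.data.frame(records)) {
    records <- data.frame(foci_count = records, group = "all",
                          stringsAsFactors = FALSE)
  }
  check_columns(records, c("foci_count", "group"), "records")
  if (any(records$foci_count < 0)) fail("negative focus counts")
  out <- lapply(split(records, records$group), function(d) {
    f <- d$foci_count
    counts <- c(sum(f == 0), sum(f >= 1 & f <= 5), sum(f >= 6 & f <= 10),
                sum(f > 10))
    df <- data.frame(group = d$group[1], t(counts), total = length(f),
                     stringsAsFactors = FALSE)
    names(df)[2:5] <- FOCI_BINS
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("foci_bins", "data.frame"))
}

foci_counts_vec <- function(x) {
  if (inherits(x, "foci_bins") || is.data.frame(x)) {
    if (nrow(x) != 1) fail("expected a single group of foci bins")
    as.numeric(x[1, FOCI_BINS])
  } else {
    if (length(x) != 4) fail("expected 4 bin counts")
    as.numeric(x)
  }
}

#' Goodness-of-fit test of a focus-count distribution against a reference
#'
#' The default (`method = "expected"`) treats the reference group's bin
#' proportions as a fixed expectation scaled to the observed total — a
#' chi-squared goodness-of-fit with 3 degrees of freedom. The
#' `"homogeneity"` variant tests the 2 x 4 contingency table instead.
#'
#' @param observed,reference Single-group [bin_foci()] rows or length-4
#'   count vectors over the bins `{0, 1-5, 6-10, >10}`.
#' @param method `"expected"` (reference proportions fixed, df = 3) or
#'   `"homogeneity"` (two-sample contingency test, df = 3).
#' @return List with `chi2`, `df`, `p`, `expected`, and `zero_expected`
#'   (TRUE when a reference bin is empty but observed there, in which case
#'   an exact/permutation alternative is recommended and empty cells are
#'   dropped from the statistic).
#' @export
foci_distribution_test <- function(observed, reference,
                                   method = c("expected", "homogeneity")) {
  method <- match.arg(method)
  o <- foci_counts_vec(observed)
  r <- foci_counts_vec(reference)
  if (sum(o) == 0 || sum(r) == 0) fail("observed and reference totals must be > 0")
  if (method == "homogeneity") {
    tab <- rbind(o, r)
    keep <- colSums(tab) > 0
    res <- suppressWarnings(stats::chisq.test(tab[, keep], correct = FALSE))
    return(list(chi2 = unname(res$statistic), df = unname(res$parameter),
                p = unname(res$p.value), expected = res$expected,
                zero_expected = FALSE))
  }
  e <- r / sum(r) * sum(o)
  zero <- e == 0 & o > 0
  use <- e > 0
  chi2 <- sum((o[use] - e[use])^2 / e[use])
  df <- 3L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = e, zero_expected = any(zero))
}
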