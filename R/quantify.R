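# Small quantifications: cumulative growth under a serial-passage (3T3)
# protocol, two-reference delta-Ct relative expression, and replicate
# proportion summaries with t-tests.

#' Relative cumulative cell number under a serial-passage protocol
#'
#' Each passage's fold increase is `counted / plated`; cumulative growth at
#' passage `p` is the running product of folds from the start passage, whose
#' plating defines the unit (relative cumulative number 1).
#'
#' @param records data.frame with `passage`, `plated`, `counted` and
#'   optionally `group` (groups are processed independently).
#' @return data.frame with `group`, `passage`, `fold`, `cumulative`.
#' @export
cumulative_growth <- function(records) {
  check_columns(records, c("passage", "plated", "counted"), "growth records")
  if (!"group" %in% names(records)) records$group <- "all"
  out <- lapply(split(records, records$group), function(d) {
    d <- d[order(d$passage), ]
    if (any(d$plated <= 0)) fail("zero or negative plating in group '%s'",
                                 d$group[1])
    if (any(diff(d$passage) != 1)) {
      fail("group '%s': passages must be contiguous (missing passage?)",
           d$group[1])
    }
    d$fold <- d$counted / d$plated
    d$cumulative <- cumprod(d$fold)
    d[, c("group", "passage", "fold", "cumulative")]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative expression by the delta-Ct method with multiple reference genes
#'
#' Per sample, `delta_Ct = Ct_target - mean(Ct_references)` (arithmetic mean
#' of reference Cts, i.e. the geometric mean of their linear expression) and
#' relative expression is `2^(-delta_Ct)`, rescaled so the control group's
#' mean is 1 for each gene. Adding a constant to every Ct of a sample leaves
#' the result unchanged.
#'
#' @param records data.frame with `sample`, `group`, `gene`, `ct`,
#'   `is_reference`.
#' @param control_group Group whose per-gene mean expression is set to 1.
#' @return List with `per_sample` (sample-level relative expression) and
#'   `summary` (`gene`, `group`, `mean`, `sd`, `n`).
#' @export
relative_expression_delta_ct <- function(records, control_group) {
  check_columns(records, c("sample", "group", "gene", "ct", "is_reference"),
                "qPCR records")
  if (!control_group %in% records$group) {
    fail("control group '%s' not present", control_group)
  }
  if (any(!is.finite(records$ct))) fail("non-finite Ct values")
  per <- lapply(split(records, records$sample), function(d) {
    refs <- d$ct[d$is_reference]
    if (length(refs) == 0) fail("sample '%s' has no reference genes",
                                d$sample[1])
    targets <- d[!d$is_reference, , drop = FALSE]
    data.frame(sample = targets$sample, group = targets$group,
               gene = targets$gene,
               expression = 2^(-(targets$ct - mean(refs))),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  # scale per gene so control-group mean is 1
  for (g in unique(per$gene)) {
    sel <- per$gene == g
    ctrl <- per$expression[sel & per$group == control_group]
    if (length(ctrl) == 0) fail("gene '%s' missing from control group", g)
    per$expression[sel] <- per$expression[sel] / mean(ctrl)
  }
  agg <- lapply(split(per, per[c("gene", "group")], drop = TRUE), function(d) {
    data.frame(gene = d$gene[1], group = d$group[1],
               mean = mean(d$expression),
               sd = if (nrow(d) > 1) stats::sd(d$expression) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  rownames(agg) <- NULL
  list(per_sample = per, summary = agg)
}

#' Replicate-culture proportion summary with a two-group t-test
#'
#' Converts per-replicate positive/total counts to percentages, summarizes
#' mean and s.d. per group, and (for exactly two groups, or a named pair)
#' tests the difference with a two-sided two-sample t-test on the replicate
#' percentages — matching error bars computed across replicate cultures, not
#' pooled counts.
#'
#' @param records data.frame with `group`, `replicate`, `positive`, `total`.
#' @param compare Optional length-2 character vector naming the groups to
#'   test (defaults to the only two groups present).
#' @return List with `summary` (`group`, `mean_percent`, `sd_percent`, `n`),
#'   `p_value`, `t`, and `compared`.
#' @export
proportion_summary <- function(records, compare = NULL) {
  check_columns(records, c("group", "replicate", "positive", "total"),
                "proportion records")
  if (any(records$total <= 0)) fail("replicate with total = 0")
  if (any(records$positive < 0 | records$positive > records$total)) {
    fail("positive counts must lie in [0, total]")
  }
  records$percent <- 100 * records$positive / records$total
  summ <- lapply(split(records, records$group), function(d) {
    data.frame(group = d$group[1], mean_percent = mean(d$percent),
               sd_percent = if (nrow(d) > 1) stats::sd(d$percent) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  groups <- unique(records$group)
  p_value <- NA_real_; tstat <- NA_real_; compared <- NULL
  if (is.null(compare) && length(groups) == 2) compare <- groups
  if (!is.null(compare)) {
    if (!all(compare %in% groups)) fail("compare names unknown group(s)")
    a <- records$percent[records$group == compare[1]]
    b <- records$percent[records$group == compare[2]]
    if (length(a) < 2 || length(b) < 2) {
      fail("need >= 2 replicate cultures per group for a test")
    }
    tt <- two_sample_t(a, b)
    p_value <- tt$p; tstat <- tt$statistic; compared <- compare
  }
  list(summary = summ, p_value = p_value, t = tstat, compared = compared)
}
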