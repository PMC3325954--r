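# Direction-partitioned overlap of two signatures and the 2x2 contingency
# chi-squared concordance test. The contingency is built only over the
# overlap (probes significant in both signatures); set-only counts are
# reported for Venn diagrams but excluded from the test.

#' Direction-partitioned overlap of two signatures
#'
#' @param a,b [select_significant()] results over a shared probe universe.
#' @return A `directional_overlap`: quadrant counts `uu`, `ud`, `du`, `dd`
#'   (direction in `a` x direction in `b` among co-significant probes),
#'   overlap total `n`, and `a_only`/`b_only` counts split by direction.
#' @export
directional_overlap <- function(a, b) {
  check_universe(list(a, b))
  m <- match(a$probe_id, b$probe_id)
  in_both <- !is.na(m)
  da <- a$direction[in_both]
  db <- b$direction[m[in_both]]
  quad <- c(uu = sum(da == 1 & db == 1), ud = sum(da == 1 & db == -1),
            du = sum(da == -1 & db == 1), dd = sum(da == -1 & db == -1))
  a_rest <- a$direction[!in_both]
  b_rest <- b$direction[is.na(match(b$probe_id, a$probe_id))]
  structure(list(quadrants = quad, n = sum(in_both),
                 a_only = c(up = sum(a_rest == 1), down = sum(a_rest == -1)),
                 b_only = c(up = sum(b_rest == 1), down = sum(b_rest == -1))),
            class = "directional_overlap")
}

#' Build a directional overlap from printed quadrant counts
#'
#' For published four-way tables where only the counts survive (e.g. a figure
#' legend's "176, 25, 50, 140").
#'
#' @param uu,ud,du,dd Quadrant counts: up/up, up/down, down/up, down/down.
#' @param a_only,b_only Optional `c(up, down)` counts outside the overlap.
#' @export
overlap_from_counts <- function(uu, ud, du, dd,
                                a_only = c(up = 0, down = 0),
                                b_only = c(up = 0, down = 0)) {
  quad <- c(uu = uu, ud = ud, du = du, dd = dd)
  if (any(quad < 0)) fail("quadrant counts must be non-negative")
  structure(list(quadrants = quad, n = sum(quad),
                 a_only = a_only, b_only = b_only),
            class = "directional_overlap")
}

#' Chi-squared test of directional concordance on a 2x2 overlap table
#'
#' Expected counts are the usual product of marginals over the overlap total;
#' the statistic is Pearson's chi-squared with 1 degree of freedom and no
#' continuity correction (switchable). Any zero marginal makes the table
#' degenerate: the statistic is undefined and flagged.
#'
#' @param ov A [directional_overlap()].
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A `concordance_result` list: `observed`, `expected`, `chi2`,
#'   `df = 1`, `p`, `degenerate`, `low_expected` (TRUE when any expected
#'   cell < 5, in which case the permutation p-value is recommended).
#' @export
concordance_chisq <- function(ov, correct = FALSE) {
  stopifnot(inherits(ov, "directional_overlap"))
  o <- ov$quadrants
  n <- ov$n
  if (n == 0) fail("empty overlap: no co-significant probes to test")
  row <- c(up = o[["uu"]] + o[["ud"]], down = o[["du"]] + o[["dd"]])
  col <- c(up = o[["uu"]] + o[["du"]], down = o[["ud"]] + o[["dd"]])
  if (any(row == 0) || any(col == 0)) {
    return(structure(list(observed = o, expected = rep(NA_real_, 4),
                          chi2 = NA_real_, df = 1L, p = NA_real_,
                          degenerate = TRUE, low_expected = NA),
                     class = "concordance_result"))
  }
  e <- c(uu = row[["up"]] * col[["up"]], ud = row[["up"]] * col[["down"]],
         du = row[["down"]] * col[["up"]], dd = row[["down"]] * col[["down"]]) / n
  dev <- abs(o - e)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi2 <- sum(dev^2 / e)
  structure(list(observed = o, expected = e, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 degenerate = FALSE, low_expected = any(e < 5)),
            class = "concordance_result")
}

#' Permutation null for the concordance chi-squared
#'
#' Reconstructs the paired direction labels of the overlap and permutes the
#' second signature's labels among overlap members, conditioning on both
#' marginal label counts. Serves as the independent oracle for the asymptotic
#' chi-squared p-value.
#'
#' @param ov A [directional_overlap()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed RNG seed.
#' @return List with `p_permutation` (add-one estimator
#'   `(1 + #\{chi2_perm >= chi2_obs\}) / (1 + n_perm)`), `chi2_obs`,
#'   `n_perm`, `seed`.
#' @export
permutation_null <- function(ov, n_perm = 10000, seed = 1L) {
  stopifnot(inherits(ov, "directional_overlap"))
  if (n_perm < 99) fail("n_perm must be at least 99")
  o <- ov$quadrants
  la <- rep(c(1L, 1L, -1L, -1L), o)   # uu, ud, du, dd
  lb <- rep(c(1L, -1L, 1L, -1L), o)
  base <- concordance_chisq(ov)
  if (base$degenerate) fail("degenerate marginals: permutation test undefined")
  chi2_obs <- base$chi2
  # margins are fixed under label permutation, so the statistic reduces to a
  # closed form in the up/up cell count
  n <- ov$n
  r_up <- sum(la == 1); c_up <- sum(lb == 1)
  ia <- which(la == 1)
  chi2_of_uu <- function(uu) {
    ud <- r_up - uu; du <- c_up - uu; dd <- n - r_up - c_up + uu
    n * (uu * dd - ud * du)^2 /
      (r_up * (n - r_up) * c_up * (n - c_up))
  }
  exceed <- with_seed(seed, {
    uu_perm <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      uu_perm[i] <- sum(sample(lb)[ia] == 1L)
    }
    sum(chi2_of_uu(uu_perm) >= chi2_obs - 1e-12)
  })
  list(p_permutation = (1 + exceed) / (1 + n_perm), chi2_obs = chi2_obs,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Three-way Venn region counts for significant sets
#'
#' @param a,b,c [select_significant()] results over a shared universe.
#' @return Named integer vector over the seven regions (`a_only`, `b_only`,
#'   `c_only`, `ab`, `ac`, `bc`, `abc`) plus each set's total and the union.
#' @export
triple_overlap_venn <- function(a, b, c) {
  check_universe(list(a, b, c))
  ids <- unique(c(a$probe_id, b$probe_id, c$probe_id))
  ina <- ids %in% a$probe_id
  inb <- ids %in% b$probe_id
  inc <- ids %in% c$probe_id
  counts <- c(
    a_only = sum(ina & !inb & !inc), b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc), ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc), bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc),
    total_a = sum(ina), total_b = sum(inb), total_c = sum(inc),
    union = length(ids))
  counts
}
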