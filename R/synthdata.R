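# Synthetic-data generators. Each generator consumes a "truth" object whose
# fields state the world being simulated (study design sizes, noise levels,
# planted effects) and returns seed-reproducible tables in the same layouts
# the analysis stages read from disk. Planted ground truth is always carried
# alongside the data so downstream recovery can be tested.

#' Describe a planted expression-array experiment
#'
#' The default design mirrors a triplicate three-condition fibroblast study
#' (an early-passage control, a late-passage culture and a knockout culture),
#' with two pairwise contrasts that share a fraction of their differential
#' probes. Among shared probes, `concordance` is the probability the planted
#' direction agrees between the two contrasts.
#'
#' @param n_probes Number of probe-sets.
#' @param conditions Character vector of condition labels.
#' @param contrasts List of length-2 character vectors `(first, second)`;
#'   planted log2 fold changes are `mean(first) - mean(second)`. Contrasts
#'   must form a forest over conditions (no cycles).
#' @param replicates Replicate cultures per condition (>= 2).
#' @param de_fraction Fraction of probes planted as differential per contrast.
#' @param shared_fraction Fraction of each contrast's planted probes shared
#'   with the other contrast (`rho`, requires exactly 2 contrasts when > 0).
#' @param concordance Probability a shared probe keeps its direction in the
#'   second contrast (`kappa`).
#' @param effect_range Range (log2 units) for planted effect magnitudes.
#' @param noise_sd Within-condition residual s.d. in log2 units. Free
#'   parameter of the simulated world; 0.25 is typical of normalized triplicate
#'   arrays, smaller values give a high-power regime.
#' @param seed Master seed; all facets derive sub-streams from it.
#' @return An `expression_truth` object.
#' @export
expression_truth <- function(n_probes = 10000,
                             conditions = c("null", "P3", "P5"),
                             contrasts = list(c("null", "P3"),
                                              c("null", "P5")),
                             replicates = 3,
                             de_fraction = 0.05,
                             shared_fraction = 0.5,
                             concordance = 0.8,
                             effect_range = c(0.5, 2.0),
                             noise_sd = 0.25,
                             seed = 1L) {
  if (n_probes < 1 || replicates < 2) {
    fail("n_probes must be positive and replicates >= 2")
  }
  if (de_fraction < 0 || de_fraction > 1) fail("de_fraction must be in [0,1]")
  if (shared_fraction < 0 || shared_fraction > 1) {
    fail("shared_fraction (rho) must be in [0,1]")
  }
  if (concordance < 0 || concordance > 1) {
    fail("concordance (kappa) must be in [0,1]")
  }
  if (shared_fraction > 0 && length(contrasts) != 2) {
    fail("shared_fraction > 0 requires exactly two contrasts")
  }
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% conditions)) {
      fail("each contrast must name two known conditions")
    }
  }
  structure(list(n_probes = as.integer(n_probes), conditions = conditions,
                 contrasts = contrasts, replicates = as.integer(replicates),
                 de_fraction = de_fraction, shared_fraction = shared_fraction,
                 concordance = concordance, effect_range = effect_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expression_truth")
}

#' Simulate a normalized log2 expression matrix with planted signatures
#'
#' Per-probe baselines are uniform on log2 8--10 units; planted contrasts add
#' condition offsets so that each member probe's true log2 fold change equals
#' its drawn effect magnitude times its direction, and every non-member
#' contrast sees a true fold change of exactly zero. Residual noise is
#' i.i.d. normal on the log2 scale.
#'
#' @param truth An [expression_truth()] object.
#' @return A list with `matrix` (probes x samples), `design` (data.frame with
#'   `sample_id`, `condition`, `replicate`) and `truth` (per-probe planted
#'   directions per contrast; 0 = not planted).
#' @export
simulate_expression <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  np <- truth$n_probes
  conds <- truth$conditions
  probe_ids <- sprintf("probe_%05d", seq_len(np))

  n_de <- round(truth$de_fraction * np)
  n_shared <- if (length(truth$contrasts) == 2) {
    round(truth$shared_fraction * n_de)
  } else 0L

  # membership: first n_shared probes shared, then contrast-specific blocks
  member <- matrix(FALSE, np, length(truth$contrasts))
  dir <- matrix(0L, np, length(truth$contrasts))
  mag <- matrix(0, np, length(truth$contrasts))
  if (n_de > 0) {
    idx_shared <- seq_len(n_shared)
    nxt <- n_shared
    with_seed(derive_seed(truth$seed, "directions"), {
      for (j in seq_along(truth$contrasts)) {
        own <- if (n_de > n_shared) nxt + seq_len(n_de - n_shared) else integer(0)
        nxt <- nxt + length(own)
        mem <- c(idx_shared, own)
        if (max(c(0L, mem)) > np) fail("de_fraction/shared_fraction exceed n_probes")
        member[mem, j] <- TRUE
        if (j == 1 || n_shared == 0) {
          dir[mem, j] <- sample(c(-1L, 1L), length(mem), replace = TRUE)
        } else {
          keep <- stats::runif(n_shared) < truth$concordance
          dir[idx_shared, j] <- ifelse(keep, dir[idx_shared, 1], -dir[idx_shared, 1])
          dir[own, j] <- sample(c(-1L, 1L), length(own), replace = TRUE)
        }
      }
    })
    with_seed(derive_seed(truth$seed, "effects"), {
      for (j in seq_along(truth$contrasts)) {
        mem <- which(member[, j])
        mag[mem, j] <- stats::runif(length(mem), truth$effect_range[1],
                                    truth$effect_range[2])
      }
    })
  }

  # Solve per-probe condition offsets so each contrast hits its target lfc
  # (dir * mag for members, 0 otherwise). Contrasts must form a forest.
  offsets <- matrix(0, np, length(conds), dimnames = list(NULL, conds))
  touched <- stats::setNames(rep(FALSE, length(conds)), conds)
  for (j in seq_along(truth$contrasts)) {
    a <- truth$contrasts[[j]][1]; b <- truth$contrasts[[j]][2]
    target <- dir[, j] * mag[, j]
    if (!touched[a] && !touched[b]) {
      offsets[, a] <- target
    } else if (touched[a] && !touched[b]) {
      offsets[, b] <- offsets[, a] - target
    } else if (!touched[a] && touched[b]) {
      offsets[, a] <- offsets[, b] + target
    } else {
      fail("contrasts form a cycle; planted offsets are over-determined")
    }
    touched[a] <- TRUE; touched[b] <- TRUE
  }

  design <- expand.grid(replicate = seq_len(truth$replicates),
                        condition = conds, stringsAsFactors = FALSE)
  design <- design[order(match(design$condition, conds), design$replicate), ]
  design$sample_id <- paste0(design$condition, "_r", design$replicate)
  design <- design[, c("sample_id", "condition", "replicate")]
  rownames(design) <- NULL

  base <- with_seed(derive_seed(truth$seed, "baseline"),
                    stats::runif(np, 6, 10))
  noise <- with_seed(derive_seed(truth$seed, "noise"),
                     matrix(stats::rnorm(np * nrow(design), 0, truth$noise_sd),
                            np, nrow(design)))
  mat <- base + offsets[, design$condition, drop = FALSE] + noise
  dimnames(mat) <- list(probe_ids, design$sample_id)

  truth_df <- data.frame(probe_id = probe_ids, stringsAsFactors = FALSE)
  for (j in seq_along(truth$contrasts)) {
    truth_df[[paste0("dir_", paste(truth$contrasts[[j]], collapse = "_vs_"))]] <-
      dir[, j]
    truth_df[[paste0("lfc_", paste(truth$contrasts[[j]], collapse = "_vs_"))]] <-
      dir[, j] * mag[, j]
  }
  truth_df$shared <- seq_len(np) <= n_shared

  list(matrix = mat, design = design, truth = truth_df)
}

#' Describe a planted per-nucleus DNA-content population
#'
#' Planted ploidy classes are a partition of intensity space: 2N and 4N are
#' truncated normals inside +/-`band` of their modes, S-phase is uniform on
#' the gap between the 2N and 4N bands, and the two re-replication brackets
#' are the equal-width halves of `(1 + band) * mu_4N` up to `mu_8N = 4 *
#' mu_2N`. This keeps the planted label recoverable from intensity alone.
#'
#' @param fractions Named proportions over
#'   `c("sub2N","2N","S","4N","bracket1","bracket2")`; must sum to 1.
#' @param mu_2N Modal integrated intensity of 2N nuclei (arbitrary units).
#' @param intensity_cv Coefficient of variation of the 2N/4N peaks.
#' @param edu_rates Named per-class probabilities of EdU positivity.
#' @param binucleate_rate Proportion of binucleate cells.
#' @param foci_model Either one probability vector over the focus bins
#'   `{0, 1-5, 6-10, >10}` or a named list of such vectors (one per group).
#' @param n_cells Cells per group.
#' @param band Half-width of the 2N/4N class bands as a fraction of the mode;
#'   matches the profile classifier's default.
#' @param seed Master seed.
#' @return A `ploidy_truth` object.
#' @export
ploidy_truth <- function(fractions = c(sub2N = 0, `2N` = 0.60, S = 0.15,
                                       `4N` = 0.15, bracket1 = 0.05,
                                       bracket2 = 0.05),
                         mu_2N = 100, intensity_cv = 0.08,
                         edu_rates = c(sub2N = 0, `2N` = 0.05, S = 0.95,
                                       `4N` = 0.10, bracket1 = 0.60,
                                       bracket2 = 0.60),
                         binucleate_rate = 0.05,
                         foci_model = c(0.55, 0.30, 0.10, 0.05),
                         n_cells = 5000, band = 0.15, seed = 1L) {
  classes <- c("sub2N", "2N", "S", "4N", "bracket1", "bracket2")
  fractions <- fractions[classes]
  if (anyNA(fractions)) fail("fractions must be named over: %s",
                             paste(classes, collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-9) fail("class fractions must sum to 1")
  if (mu_2N <= 0 || intensity_cv < 0) fail("mu_2N must be > 0, cv >= 0")
  if (!is.list(foci_model)) foci_model <- list(group1 = foci_model)
  for (g in names(foci_model)) {
    if (length(foci_model[[g]]) != 4 || abs(sum(foci_model[[g]]) - 1) > 1e-9) {
      fail("foci_model[[%s]] must be 4 probabilities summing to 1", g)
    }
  }
  structure(list(fractions = fractions, mu_2N = mu_2N,
                 intensity_cv = intensity_cv, edu_rates = edu_rates[classes],
                 binucleate_rate = binucleate_rate, foci_model = foci_model,
                 n_cells = as.integer(n_cells), band = band,
                 seed = as.integer(seed)),
            class = "ploidy_truth")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate per-nucleus measurement records
#'
#' @param truth A [ploidy_truth()] object.
#' @return data.frame with `cell_id`, `group`, `dna_intensity`, `area`,
#'   `edu_positive`, `foci_count`, `binucleate` and the planted `true_class`.
#' @export
simulate_nuclei <- function(truth) {
  stopifnot(inherits(truth, "ploidy_truth"))
  classes <- names(truth$fractions)
  mu2 <- truth$mu_2N; mu4 <- 2 * mu2; mu8 <- 4 * mu2
  b <- truth$band
  gt4_start <- (1 + b) * mu4
  split <- (gt4_start + mu8) / 2
  out <- list()
  for (g in names(truth$foci_model)) {
    n <- truth$n_cells
    cls <- with_seed(derive_seed(truth$seed, paste0("class_", g)),
                     sample(classes, n, replace = TRUE,
                            prob = truth$fractions))
    intensity <- numeric(n)
    with_seed(derive_seed(truth$seed, paste0("intensity_", g)), {
      for (k in classes) {
        idx <- which(cls == k)
        if (length(idx) == 0) next
        intensity[idx] <- switch(k,
          sub2N = stats::runif(length(idx), 0.4 * mu2, (1 - b) * mu2),
          `2N` = rtruncnorm1(length(idx), mu2, truth$intensity_cv * mu2,
                             (1 - b) * mu2, (1 + b) * mu2),
          S = stats::runif(length(idx), (1 + b) * mu2, (1 - b) * mu4),
          `4N` = rtruncnorm1(length(idx), mu4, truth$intensity_cv * mu4,
                             (1 - b) * mu4, (1 + b) * mu4),
          bracket1 = stats::runif(length(idx), gt4_start, split),
          bracket2 = stats::runif(length(idx), split, mu8))
      }
    })
    edu <- with_seed(derive_seed(truth$seed, paste0("edu_", g)),
                     stats::runif(n) < truth$edu_rates[cls])
    binuc <- with_seed(derive_seed(truth$seed, paste0("binuc_", g)),
                       stats::runif(n) < truth$binucleate_rate)
    foci <- with_seed(derive_seed(truth$seed, paste0("foci_", g)), {
      bin <- sample.int(4, n, replace = TRUE, prob = truth$foci_model[[g]])
      ifelse(bin == 1, 0L,
             ifelse(bin == 2, sample(1:5, n, replace = TRUE),
                    ifelse(bin == 3, sample(6:10, n, replace = TRUE),
                           sample(11:25, n, replace = TRUE))))
    })
    area <- with_seed(derive_seed(truth$seed, paste0("area_", g)),
                      50 * (intensity / mu2)^(2 / 3) *
                        exp(stats::rnorm(n, 0, 0.1)))
    out[[g]] <- data.frame(
      cell_id = paste0(g, "_cell_", seq_len(n)), group = g,
      dna_intensity = intensity, area = area,
      edu_positive = edu, foci_count = as.integer(foci),
      binucleate = binuc, true_class = cls, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Describe a comet-assay recovery time-course
#'
#' Mean percent tail DNA follows an exponential decay from `D0` (immediately
#' after the oxidative pulse) to the residual plateau `D_inf` at rate `k` per
#' minute. Per-cell dispersion is a symmetric scaled Beta(2,2) around the
#' mean, chosen because tail percent is bounded on 0--100; values are clipped
#' as a secondary guard.
#'
#' @param D0 Mean percent tail DNA at time 0 after damage.
#' @param D_inf Residual plateau (percent), `0 <= D_inf <= D0 <= 100`.
#' @param k Recovery rate per minute (`>= 0`).
#' @param baseline Undamaged mean percent tail DNA.
#' @param cell_noise Per-cell standard deviation in percent units.
#' @param timepoints Minutes post-treatment.
#' @param n_cells Cells scored per time point per treatment.
#' @param seed Master seed.
#' @export
comet_truth <- function(D0 = 60, D_inf = 10, k = 0.05, baseline = 2,
                        cell_noise = 8,
                        timepoints = c(0, 20, 40, 80, 160),
                        n_cells = 200, seed = 1L) {
  if (D_inf > D0) fail("D_inf must not exceed D0")
  if (D0 > 100 || D_inf < 0) fail("D0 and D_inf must lie in [0,100]")
  if (k < 0) fail("recovery rate k must be >= 0")
  structure(list(D0 = D0, D_inf = D_inf, k = k, baseline = baseline,
                 cell_noise = cell_noise, timepoints = timepoints,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "comet_truth")
}

# Beta(2,2) has sd = sqrt(0.05) of its support width; scale so the per-cell
# sd equals cell_noise before clipping.
rbeta_noise <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  span <- sd / sqrt(0.05)
  (stats::rbeta(n, 2, 2) - 0.5) * span
}

#' Simulate per-cell comet records over a recovery time-course
#'
#' @param truth A [comet_truth()] object.
#' @param group Group label stamped on every record.
#' @return data.frame with `cell_id`, `group`, `treatment`
#'   (`untreated`/`H2O2`), `time_min`, `tail_percent`.
#' @export
simulate_comet_timecourse <- function(truth, group = "WT") {
  stopifnot(inherits(truth, "comet_truth"))
  rows <- list()
  for (trt in c("H2O2", "untreated")) {
    for (t in truth$timepoints) {
      mu <- if (trt == "H2O2") {
        truth$D_inf + (truth$D0 - truth$D_inf) * exp(-truth$k * t)
      } else truth$baseline
      vals <- with_seed(derive_seed(truth$seed, paste0(trt, "_t", t)),
                        mu + rbeta_noise(truth$n_cells, truth$cell_noise))
      vals <- pmin(100, pmax(0, vals))
      rows[[paste(trt, t)]] <- data.frame(
        cell_id = sprintf("%s_%s_t%g_%d", group, trt, t,
                          seq_len(truth$n_cells)),
        group = group, treatment = trt, time_min = t, tail_percent = vals,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Simulate a serial-passage (3T3 protocol) growth series
#'
#' Each passage replates a fixed number of cells and counts the yield after
#' three days; `counted = plated * fold` exactly, so cumulative growth is the
#' running product of the folds.
#'
#' @param per_passage_folds Positive fold increases, one per passage.
#' @param plated Cells plated at each passage (study default 3e5).
#' @param start_passage First passage number (study default 2).
#' @param group Group label.
#' @return data.frame with `group`, `passage`, `plated`, `counted`.
#' @export
simulate_growth_series <- function(per_passage_folds, plated = 3e5,
                                   start_passage = 2, group = "WT") {
  if (any(per_passage_folds <= 0)) fail("folds must be positive")
  if (plated <= 0) fail("plated must be positive")
  data.frame(group = group,
             passage = start_passage + seq_along(per_passage_folds) - 1,
             plated = plated,
             counted = plated * per_passage_folds,
             stringsAsFactors = FALSE)
}

#' Simulate qPCR Ct tables with two reference genes
#'
#' Target Ct is `offset - log2(expression) + noise`; both reference genes sit
#' at the shared per-sample offset, so the delta-Ct transform cancels the
#' per-sample shift exactly.
#'
#' @param true_relative_expression Matrix or data.frame of positive relative
#'   expression values, genes in rows (rownames), groups in columns.
#' @param n_replicates Replicate samples per group.
#' @param ct_noise_sd Technical noise s.d. in cycles.
#' @param reference_genes Names of the two reference genes.
#' @param offset Baseline Ct for unit expression.
#' @param seed Master seed.
#' @return data.frame with `sample`, `group`, `gene`, `ct`, `is_reference`.
#' @export
simulate_qpcr <- function(true_relative_expression, n_replicates = 3,
                          ct_noise_sd = 0,
                          reference_genes = c("Rpl4", "Actb"),
                          offset = 20, seed = 1L) {
  expr <- as.matrix(true_relative_expression)
  if (any(expr <= 0)) fail("relative expression values must be positive")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    fail("expression matrix needs gene rownames and group colnames")
  }
  groups <- colnames(expr); genes <- rownames(expr)
  shift <- with_seed(derive_seed(seed, "sample_shift"),
                     stats::rnorm(length(groups) * n_replicates, 0, 0.5))
  rows <- list(); i <- 0L
  noise_seed <- derive_seed(seed, "ct_noise")
  with_seed(noise_seed, {
    for (gi in seq_along(groups)) {
      for (r in seq_len(n_replicates)) {
        i <- i + 1L
        sample_id <- paste0(groups[gi], "_r", r)
        ct_t <- offset + shift[i] - log2(expr[, gi]) +
          stats::rnorm(length(genes), 0, ct_noise_sd)
        ct_r <- offset + shift[i] +
          stats::rnorm(length(reference_genes), 0, ct_noise_sd)
        rows[[i]] <- data.frame(
          sample = sample_id, group = groups[gi],
          gene = c(genes, reference_genes), ct = c(ct_t, ct_r),
          is_reference = c(rep(FALSE, length(genes)),
                           rep(TRUE, length(reference_genes))),
          stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
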