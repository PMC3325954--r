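# Differential expression on normalized log2 matrices: per-contrast
# mean-difference fold changes with two-sample t p-values, and cutoff-based
# directional signature selection.

#' Construct a validated expression matrix container
#'
#' @param values Numeric matrix, probes x samples, probe IDs as rownames and
#'   sample IDs as colnames.
#' @param design data.frame with `sample_id`, `condition` (and optionally
#'   `replicate`) covering every column of `values`.
#' @return An `expression_matrix` object (list with `values`, `design`).
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    fail("values must be a numeric matrix")
  }
  if (anyNA(values)) fail("expression matrix contains missing values")
  if (is.null(rownames(values))) fail("values must carry probe IDs as rownames")
  if (anyDuplicated(rownames(values))) {
    fail("duplicate probe IDs: %s",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
               collapse = ", "))
  }
  check_columns(design, c("sample_id", "condition"), "design")
  missing <- setdiff(colnames(values), design$sample_id)
  if (length(missing) > 0) {
    fail("design is missing sample(s): %s", paste(missing, collapse = ", "))
  }
  extra <- setdiff(design$sample_id, colnames(values))
  if (length(extra) > 0) {
    fail("design names sample(s) absent from the matrix: %s",
         paste(extra, collapse = ", "))
  }
  design <- design[match(colnames(values), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(values = values, design = design),
            class = "expression_matrix")
}

#' Read an expression matrix (TSV) and its design table (CSV)
#'
#' The TSV's first column holds probe-set IDs; remaining columns are samples.
#' The design CSV must have `sample_id` and `condition` columns matching the
#' matrix header.
#'
#' @param path Path to the tab-delimited matrix.
#' @param design_path Path to the design CSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, design_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) fail("matrix file must have a probe column and samples")
  probe_ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) fail("non-numeric expression cells in %s", path)
  rownames(vals) <- probe_ids
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  expression_matrix(vals, design)
}

#' Write an expression matrix and design to disk
#'
#' @param em An [expression_matrix()] object or the list returned by
#'   [simulate_expression()].
#' @param matrix_path Output TSV path.
#' @param design_path Output CSV path.
#' @export
write_expression_matrix <- function(em, matrix_path, design_path) {
  vals <- if (inherits(em, "expression_matrix")) em$values else em$matrix
  design <- em$design
  df <- data.frame(probe_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(design, design_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix_path, design_path))
}

#' Per-probe differential expression for one pairwise contrast
#'
#' Log fold change is `mean(first) - mean(second)` on the log2 scale; the
#' p-value comes from a two-sample t-test per probe (equal-variance pooled t
#' by default, Welch behind `var_equal = FALSE`). Probes with zero pooled
#' variance get p = 1 when the means agree, and the smallest positive double
#' with a `degenerate` flag when they differ, so selection stays
#' deterministic on noiseless fixtures.
#'
#' @param em An [expression_matrix()] object.
#' @param first,second Condition labels; `first` is the numerator of the
#'   fold change.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return A `de_result`: data.frame with `probe_id`, `lfc`, `p`,
#'   `degenerate`; the contrast is kept in attributes.
#' @export
pairwise_de <- function(em, first, second, var_equal = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  cond <- em$design$condition
  for (lab in c(first, second)) {
    if (!(lab %in% cond)) fail("unknown condition '%s'", lab)
  }
  a <- em$values[, cond == first, drop = FALSE]
  b <- em$values[, cond == second, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) fail("each condition needs >= 2 replicates")
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  lfc <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(lfc))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(lfc / se), df)
  degenerate <- se == 0 & lfc != 0
  p[se == 0 & lfc == 0] <- 1
  p[degenerate] <- .Machine$double.xmin
  res <- data.frame(probe_id = rownames(em$values), lfc = lfc, p = p,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, contrast = c(first, second),
            class = c("de_result", "data.frame"))
}

#' Select a directional signature under fold-change and p-value cutoffs
#'
#' Membership requires `|lfc| >= lfc_cut` (inclusive) and `p < p_cut`
#' (strict); direction is `sign(lfc)`.
#'
#' @param de A [pairwise_de()] result.
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.5).
#' @param p_cut P-value cutoff (default 1e-4; 1e-3 is the conventional
#'   relaxation for cross-platform comparisons).
#' @return A `significant_set`: data.frame with `probe_id` and `direction`
#'   (+1/-1); the probe universe, contrast and cutoffs ride in attributes.
#' @export
select_significant <- function(de, lfc_cut = 0.5, p_cut = 1e-4) {
  stopifnot(inherits(de, "de_result") ||
              all(c("probe_id", "lfc", "p") %in% names(de)))
  if (lfc_cut <= 0 || p_cut <= 0) fail("cutoffs must be positive")
  keep <- abs(de$lfc) >= lfc_cut & de$p < p_cut
  res <- data.frame(probe_id = de$probe_id[keep],
                    direction = as.integer(sign(de$lfc[keep])),
                    stringsAsFactors = FALSE)
  structure(res, contrast = attr(de, "contrast"),
            cutoffs = c(lfc_cut = lfc_cut, p_cut = p_cut),
            universe = de$probe_id,
            class = c("significant_set", "data.frame"))
}

#' Build a significant set from explicit members
#'
#' Used to reconstruct published signatures (for example from a supplementary
#' probe-set table) without re-running the test.
#'
#' @param probe_id Character vector of member probe IDs.
#' @param direction Integer +1/-1 per member.
#' @param universe Optional full probe universe (defaults to the members).
#' @param contrast Optional contrast label pair.
#' @export
significant_set <- function(probe_id, direction, universe = probe_id,
                            contrast = c(NA, NA)) {
  if (length(probe_id) != length(direction)) {
    fail("probe_id and direction lengths differ")
  }
  if (!all(direction %in% c(-1L, 1L))) fail("direction must be +1 or -1")
  if (anyDuplicated(probe_id)) fail("duplicate probe IDs in signature")
  if (!all(probe_id %in% universe)) fail("members outside the probe universe")
  structure(data.frame(probe_id = probe_id,
                       direction = as.integer(direction),
                       stringsAsFactors = FALSE),
            contrast = contrast, universe = universe,
            class = c("significant_set", "data.frame"))
}

check_universe <- function(sets) {
  unis <- lapply(sets, attr, "universe")
  unis <- unis[!vapply(unis, is.null, logical(1))]
  if (length(unis) > 1) {
    for (u in unis[-1]) {
      if (!setequal(u, unis[[1]])) fail("signatures have mismatched probe universes")
    }
  }
  invisible(TRUE)
}

#' Union of significant sets with per-contrast directions
#'
#' @param sets List of [select_significant()] results sharing a universe.
#' @return data.frame with `probe_id` and one direction column per input set
#'   (0 where a probe was not selected); total union size as attribute `n`.
#' @export
union_significant <- function(sets) {
  stopifnot(length(sets) >= 1)
  check_universe(sets)
  ids <- sort(unique(unlist(lapply(sets, `[[`, "probe_id"))))
  out <- data.frame(probe_id = ids, stringsAsFactors = FALSE)
  nm <- names(sets)
  if (is.null(nm)) nm <- paste0("set", seq_along(sets))
  for (i in seq_along(sets)) {
    d <- integer(length(ids))
    m <- match(sets[[i]]$probe_id, ids)
    d[m] <- sets[[i]]$direction
    out[[paste0("dir_", nm[i])]] <- d
  }
  structure(out, n = length(ids), class = c("union_set", "data.frame"))
}

#' Collapse probe-level results to gene level
#'
#' Keeps, per gene, the probe with the largest absolute fold change; probes
#' absent from the annotation (unannotated) are dropped.
#'
#' @param de A [pairwise_de()] result.
#' @param annotation data.frame with `probe_id`, `gene` columns.
#' @return A `de_result` restricted to one probe per gene, with a `gene`
#'   column added.
#' @export
collapse_to_genes <- function(de, annotation) {
  check_columns(annotation, c("probe_id", "gene"), "annotation")
  m <- merge(de, annotation, by = "probe_id")
  m <- m[order(m$gene, -abs(m$lfc), m$probe_id), ]
  m <- m[!duplicated(m$gene), ]
  rownames(m) <- NULL
  structure(m, contrast = attr(de, "contrast"),
            class = c("de_result", "data.frame"))
}
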