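# Configuration-driven orchestration. A config (YAML or JSON) names the
# stages to run and their parameters; every report embeds the config hash,
# the master seed and the package version so reruns are byte-identical
# (timestamps are isolated to the run manifest).

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML or JSON file, or a list with the same
#'   structure. Recognized top-level fields: `seed`, `stages` (character
#'   vector among `simulate`, `de`, `concord`), `simulate` (arguments for
#'   [expression_truth()]), `de` (`contrasts`, `lfc_cut`, `p_cut`),
#'   `concord` (`a`, `b` contrast names, `n_perm`).
#' @return A `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "de", "concord"),
    simulate = list(),
    de = list(lfc_cut = 0.5, p_cut = 1e-4),
    concord = list(n_perm = 0L))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (config$de$lfc_cut <= 0 || config$de$p_cut <= 0) {
    fail("cutoffs must be positive")
  }
  structure(config, class = "pipeline_config")
}

config_hash <- function(config) {
  # order-stable structural hash; no external digest dependency
  ser <- serialize(config[sort(names(config))], NULL)
  sum(as.integer(ser) * (seq_along(ser) %% 997)) %% 2147483647
}

report_stamp <- function(config) {
  list(config_hash = config_hash(unclass(config)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("senecon")))
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the signature-concordance pipeline
#'
#' Executes the requested stages in dependency order: synthetic expression
#' simulation, per-contrast differential expression and signature selection,
#' and directional concordance testing. All outputs land under `out_dir`;
#' rerunning with the same config reproduces them byte-identically apart
#' from the timestamp in `manifest.json`.
#'
#' @param config A [pipeline_config()] (or path / list coercible to one).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- report_stamp(config)
  results <- list()

  if ("simulate" %in% config$stages) {
    truth_args <- config$simulate
    truth_args$seed <- config$seed
    truth <- do.call(expression_truth, truth_args)
    sim <- simulate_expression(truth)
    write_expression_matrix(sim, file.path(out_dir, "expression.tsv"),
                            file.path(out_dir, "design.csv"))
    utils::write.csv(sim$truth, file.path(out_dir, "expression_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    results$simulate <- sim
  }

  if ("de" %in% config$stages) {
    em <- if (!is.null(results$simulate)) {
      expression_matrix(results$simulate$matrix, results$simulate$design)
    } else {
      read_expression_matrix(config$de$matrix, config$de$design)
    }
    contrasts <- config$de$contrasts
    if (is.null(contrasts)) {
      contrasts <- lapply(config$simulate$contrasts %||%
                            list(c("null", "P3"), c("null", "P5")), identity)
    }
    sets <- list()
    counts <- list()
    for (ct in contrasts) {
      de <- pairwise_de(em, ct[1], ct[2])
      sig <- select_significant(de, config$de$lfc_cut, config$de$p_cut)
      key <- paste(ct, collapse = "_vs_")
      utils::write.csv(as.data.frame(de),
                       file.path(out_dir, paste0("de_", key, ".csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as.data.frame(sig),
                       file.path(out_dir, paste0("signature_", key, ".csv")),
                       row.names = FALSE, quote = FALSE)
      sets[[key]] <- sig
      counts[[key]] <- nrow(sig)
    }
    results$signatures <- sets
    write_report(c(stamp, list(cutoffs = config$de[c("lfc_cut", "p_cut")],
                               signature_sizes = counts,
                               union_size = attr(union_significant(sets), "n"))),
                 file.path(out_dir, "de_summary.json"))
  }

  if ("concord" %in% config$stages) {
    sets <- results$signatures
    if (is.null(sets) || length(sets) < 2) {
      fail("concord stage needs at least two signatures from the de stage")
    }
    ov <- directional_overlap(sets[[1]], sets[[2]])
    cc <- concordance_chisq(ov)
    rep <- c(stamp, list(
      a = names(sets)[1], b = names(sets)[2],
      quadrants = as.list(ov$quadrants), n_overlap = ov$n,
      a_only = as.list(ov$a_only), b_only = as.list(ov$b_only),
      expected = as.list(cc$expected), chi2 = cc$chi2, df = cc$df,
      p_asymptotic = cc$p, degenerate = cc$degenerate))
    if (config$concord$n_perm >= 99 && !cc$degenerate) {
      pn <- permutation_null(ov, n_perm = config$concord$n_perm,
                             seed = config$seed)
      rep$p_permutation <- pn$p_permutation
      rep$n_perm <- pn$n_perm
    }
    results$concordance <- rep
    write_report(rep, file.path(out_dir, "concordance.json"))
  }

  write_report(list(timestamp = format(Sys.time(), tz = "UTC"),
                    stages = config$stages, seed = config$seed,
                    config_hash = stamp$config_hash,
                    package_version = stamp$package_version),
               file.path(out_dir, "manifest.json"))
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) fail("unexpected CLI token '%s'", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1]
      i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Dispatches `senecon <subcommand> --flag value ...` invocations; see the
#' launcher script under `inst/cli/`. Subcommands: `simulate`, `de`,
#' `concord`, `venn`, `cyto`, `comet`, `growth`, `qpcr`, `proportions`,
#' `run`.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
senecon_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: senecon <simulate|de|concord|venn|cyto|comet|growth|qpcr|proportions|run> [--flags]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  out_dir <- opt$out %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  read_sig <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    significant_set(d$probe_id, d$direction)
  }
  res <- switch(cmd,
    run = ,
    simulate = {
      cfg <- pipeline_config(opt$config %||% list())
      cfg$seed <- seed
      if (cmd == "simulate") cfg$stages <- "simulate"
      run_pipeline(cfg, out_dir)
    },
    de = {
      em <- read_expression_matrix(opt$matrix, opt$design)
      ct <- strsplit(opt$contrast, ":")[[1]]
      de <- pairwise_de(em, ct[1], ct[2])
      sig <- select_significant(de, as.numeric(opt$lfc %||% 0.5),
                                as.numeric(opt$p %||% 1e-4))
      utils::write.csv(as.data.frame(de), file.path(out_dir, "de.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(as.data.frame(sig),
                       file.path(out_dir, "signature.csv"),
                       row.names = FALSE, quote = FALSE)
      cat(sprintf("%d probe-sets pass the cutoffs\n", nrow(sig)))
      sig
    },
    concord = {
      ov <- directional_overlap(read_sig(opt$a), read_sig(opt$b))
      cc <- concordance_chisq(ov)
      rep <- list(quadrants = as.list(ov$quadrants), n_overlap = ov$n,
                  expected = as.list(cc$expected), chi2 = cc$chi2,
                  df = cc$df, p_asymptotic = cc$p, seed = seed)
      if (!is.null(opt$perm)) {
        pn <- permutation_null(ov, as.integer(opt$perm), seed)
        rep$p_permutation <- pn$p_permutation
        rep$n_perm <- pn$n_perm
      }
      write_report(rep, file.path(out_dir, "concordance.json"))
      cat(sprintf("chi2 = %.4f, p = %.3g\n", cc$chi2, cc$p))
      rep
    },
    venn = {
      v <- triple_overlap_venn(read_sig(opt$a), read_sig(opt$b),
                               read_sig(opt$c))
      utils::write.csv(data.frame(region = names(v), count = as.integer(v)),
                       file.path(out_dir, "venn.csv"), row.names = FALSE,
                       quote = FALSE)
      v
    },
    cyto = {
      nuc <- utils::read.csv(opt$`in`, stringsAsFactors = FALSE)
      prof <- build_dna_profile(nuc)
      cls <- classify_nuclei(prof, nuc)
      utils::write.csv(cls, file.path(out_dir, "classified.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(ploidy_fractions(cls),
                       file.path(out_dir, "fractions.csv"),
                       row.names = FALSE, quote = FALSE)
      write_report(list(mu_2N = prof$mu_2N, mu_4N = prof$mu_4N,
                        boundaries = as.list(prof$boundaries),
                        gt4N_end = prof$gt4N_end,
                        bracket_split = prof$bracket_split),
                   file.path(out_dir, "profile.json"))
      prof
    },
    comet = {
      rec <- utils::read.csv(opt$`in`, stringsAsFactors = FALSE)
      summ <- tail_summary(rec)
      utils::write.csv(summ, file.path(out_dir, "tail_summary.csv"),
                       row.names = FALSE, quote = FALSE)
      treated <- rec[!("treatment" %in% names(rec)) | rec$treatment != "untreated", ]
      if (length(unique(treated$time_min)) >= 3) {
        fit <- fit_recovery_curve(treated)
        write_report(list(D0 = fit$D0, D_inf = fit$D_inf, k = fit$k,
                          rss = fit$rss, converged = fit$converged,
                          note = "exponential-recovery fit; extension beyond per-timepoint tests"),
                     file.path(out_dir, "recovery_fit.json"))
      }
      summ
    },
    growth = {
      g <- cumulative_growth(utils::read.csv(opt$`in`,
                                             stringsAsFactors = FALSE))
      utils::write.csv(g, file.path(out_dir, "growth.csv"),
                       row.names = FALSE, quote = FALSE)
      g
    },
    qpcr = {
      q <- relative_expression_delta_ct(
        utils::read.csv(opt$`in`, stringsAsFactors = FALSE),
        control_group = opt$control)
      utils::write.csv(q$summary, file.path(out_dir, "qpcr_summary.csv"),
                       row.names = FALSE, quote = FALSE)
      q
    },
    proportions = {
      p <- proportion_summary(utils::read.csv(opt$`in`,
                                              stringsAsFactors = FALSE))
      utils::write.csv(p$summary, file.path(out_dir, "proportions.csv"),
                       row.names = FALSE, quote = FALSE)
      write_report(list(p_value = p$p_value, t = p$t,
                        compared = p$compared),
                   file.path(out_dir, "proportions_test.json"))
      p
    },
    fail("unknown subcommand '%s'", cmd))
  invisible(res)
}
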