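test_that("expression matrix round-trips through TSV/CSV", {
  em <- tiny_matrix()
  mp <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".csv")
  write_expression_matrix(em, mp, dp)
  back <- read_expression_matrix(mp, dp)
  expect_equal(back$values, em$values)
  expect_equal(back$design$condition, em$design$condition)
})

test_that("matrix validation names the offending sample / probe", {
  em <- tiny_matrix()
  bad_design <- em$design[-2, ]
  expect_error(expression_matrix(em$values, bad_design), "null_r2")
  dup <- em$values
  rownames(dup) <- c("p1", "p1", "p3")
  expect_error(expression_matrix(dup, em$design), "duplicate.*p1")
})

test_that("identical groups give lfc 0 and p 1", {
  vals <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
                 dimnames = list("p1", paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       condition = rep(c("A", "B"), each = 3))
  de <- pairwise_de(expression_matrix(vals, design), "A", "B")
  expect_equal(de$lfc, 0)
  expect_equal(de$p, 1)
})

test_that("lfc is antisymmetric and p symmetric under contrast reversal", {
  set.seed(41)
  vals <- matrix(rnorm(60 * 6, 8, 1), 60,
                 dimnames = list(paste0("p", 1:60), paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       condition = rep(c("A", "B"), each = 3))
  em <- expression_matrix(vals, design)
  ab <- pairwise_de(em, "A", "B")
  ba <- pairwise_de(em, "B", "A")
  expect_equal(ab$lfc, -ba$lfc)
  expect_equal(ab$p, ba$p)
})

test_that("t statistic matches the closed-form pooled-variance oracle", {
  em <- tiny_matrix()  # p1: null {8.0,8.2,8.4} vs P3 {7.0,7.2,7.4}
  de <- pairwise_de(em, "null", "P3")
  expect_equal(de$lfc[de$probe_id == "p1"], 1.0)
  # hand-computed: both sample variances 0.04, pooled t = 1/sqrt(0.04*2/3)
  t_oracle <- 1 / sqrt(0.04 * 2 / 3)
  p_oracle <- 2 * pt(-t_oracle, df = 4)
  expect_equal(de$p[de$probe_id == "p1"], p_oracle, tolerance = 1e-12)
})

test_that("zero-variance probes follow the degenerate conventions", {
  vals <- matrix(c(rep(5, 6), rep(c(5, 6), each = 3)), 2, byrow = TRUE,
                 dimnames = list(c("same", "diff"), paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       condition = rep(c("A", "B"), each = 3))
  de <- pairwise_de(expression_matrix(vals, design), "A", "B")
  expect_equal(de$p[de$probe_id == "same"], 1)
  expect_false(de$degenerate[de$probe_id == "same"])
  expect_equal(de$p[de$probe_id == "diff"], .Machine$double.xmin)
  expect_true(de$degenerate[de$probe_id == "diff"])
})

test_that("selection boundary conventions: inclusive lfc, strict p", {
  de <- structure(data.frame(probe_id = c("a", "b", "c"),
                             lfc = c(0.5, 2.0, -0.49),
                             p = c(1e-5, 1e-4, 1e-9)),
                  contrast = c("X", "Y"),
                  class = c("de_result", "data.frame"))
  sel <- select_significant(de, lfc_cut = 0.5, p_cut = 1e-4)
  expect_equal(sel$probe_id, "a")        # b excluded: p == cutoff
  expect_equal(sel$direction, 1L)
  expect_error(select_significant(de, lfc_cut = 0), "positive")
})

test_that("relaxing either cutoff never shrinks the signature", {
  set.seed(13)
  vals <- matrix(rnorm(300 * 6, 8, 0.3), 300,
                 dimnames = list(paste0("p", 1:300), paste0("s", 1:6)))
  vals[1:40, 1:3] <- vals[1:40, 1:3] + rnorm(40, 0, 1)
  design <- data.frame(sample_id = paste0("s", 1:6),
                       condition = rep(c("A", "B"), each = 3))
  de <- pairwise_de(expression_matrix(vals, design), "A", "B")
  strict <- select_significant(de, 0.5, 1e-4)
  relaxed_p <- select_significant(de, 0.5, 1e-3)
  relaxed_l <- select_significant(de, 0.25, 1e-4)
  expect_true(all(strict$probe_id %in% relaxed_p$probe_id))
  expect_true(all(strict$probe_id %in% relaxed_l$probe_id))
})

test_that("type-I control: null selection rate is at most p_cut", {
  # under no planted signal, P(select) <= p_cut (the lfc filter only
  # removes more); pooled over probes with 3 MC s.e. slack
  tr <- expression_truth(n_probes = 20000, de_fraction = 0, noise_sd = 0.25,
                         seed = 17)
  sim <- simulate_expression(tr)
  em <- expression_matrix(sim$matrix, sim$design)
  de <- pairwise_de(em, "null", "P3")
  p_cut <- 0.01
  rate <- mean(de$p < p_cut & abs(de$lfc) >= 0)
  expect_lt(rate, p_cut + 3 * sqrt(p_cut * (1 - p_cut) / 20000))
})

test_that("planted-signal sensitivity matches the Monte-Carlo oracle", {
  # low-noise regime: pre-computed power of the df=4 pooled t at p<1e-4
  # with effects in [1,2] and sigma=0.05 is ~0.996
  tr <- expression_truth(n_probes = 4000, de_fraction = 0.1,
                         shared_fraction = 0, effect_range = c(1, 2),
                         noise_sd = 0.05, seed = 19)
  sim <- simulate_expression(tr)
  em <- expression_matrix(sim$matrix, sim$design)
  sel <- select_significant(pairwise_de(em, "null", "P3"))
  planted <- sim$truth[sim$truth$dir_null_vs_P3 != 0, ]
  hits <- merge(planted, as.data.frame(sel), by = "probe_id")
  expect_gte(nrow(hits) / nrow(planted), 0.9)
  expect_gte(mean(hits$direction == hits$dir_null_vs_P3), 0.99)

  # realistic-noise regime (sigma = 0.25): the same oracle pre-computes
  # sensitivity ~0.09 -- the plain triplicate t-test has essentially no
  # power at p < 1e-4. Assert the oracle value, not a wish.
  tr2 <- expression_truth(n_probes = 4000, de_fraction = 0.1,
                          shared_fraction = 0, effect_range = c(1, 2),
                          noise_sd = 0.25, seed = 23)
  sim2 <- simulate_expression(tr2)
  em2 <- expression_matrix(sim2$matrix, sim2$design)
  sel2 <- select_significant(pairwise_de(em2, "null", "P3"))
  planted2 <- sim2$truth[sim2$truth$dir_null_vs_P3 != 0, ]
  sens2 <- sum(sel2$probe_id %in% planted2$probe_id) / nrow(planted2)
  expect_gt(sens2, 0.04)
  expect_lt(sens2, 0.15)
})

test_that("union of signatures counts and directions are correct", {
  u <- paste0("p", 1:20)
  a <- significant_set(paste0("p", 1:3), c(1L, 1L, -1L), universe = u)
  b <- significant_set(paste0("p", 4:7), c(1L, -1L, 1L, -1L), universe = u)
  un <- union_significant(list(A = a, B = b))
  expect_equal(attr(un, "n"), 7)
  expect_equal(sum(un$dir_A != 0), 3)
  # idempotence
  same <- union_significant(list(A = a, B = a))
  expect_equal(attr(same, "n"), 3)
  # mismatched universes rejected
  c_set <- significant_set("q1", 1L, universe = "q1")
  expect_error(union_significant(list(a, c_set)), "universe")
})

test_that("gene collapse keeps the strongest probe and drops unannotated", {
  de <- structure(data.frame(probe_id = c("a", "b", "c", "d"),
                             lfc = c(0.2, -1.5, 1.0, 3),
                             p = c(0.5, 1e-5, 1e-3, 1e-8)),
                  class = c("de_result", "data.frame"))
  ann <- data.frame(probe_id = c("a", "b", "c"),
                    gene = c("G1", "G1", "G2"))
  g <- collapse_to_genes(de, ann)
  expect_equal(nrow(g), 2)
  expect_equal(g$probe_id[g$gene == "G1"], "b")
  expect_false("d" %in% g$probe_id)
})
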