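make_nuclei <- function(n = 5000, seed = 7, ...) {
  simulate_nuclei(ploidy_truth(n_cells = n, seed = seed, ...))
}

test_that("profile recovers planted peaks and fails gracefully without 4N", {
  nuc <- make_nuclei()
  prof <- build_dna_profile(nuc)
  expect_lt(abs(prof$mu_2N - 100) / 100, 0.05)
  expect_lt(abs(prof$mu_4N - 200) / 200, 0.05)
  expect_true(prof$mu_4N / prof$mu_2N >= 1.8 && prof$mu_4N / prof$mu_2N <= 2.2)

  pure <- simulate_nuclei(ploidy_truth(
    fractions = c(sub2N = 0, `2N` = 1, S = 0, `4N` = 0, bracket1 = 0,
                  bracket2 = 0),
    intensity_cv = 0.05, n_cells = 2000, seed = 3))
  expect_error(build_dna_profile(pure), "4N peak not found")
})

test_that("profile landmarks are scale-equivariant", {
  nuc <- make_nuclei(n = 3000)
  p1 <- build_dna_profile(nuc)
  scaled <- nuc
  scaled$dna_intensity <- nuc$dna_intensity * 7.5
  p2 <- build_dna_profile(scaled)
  expect_equal(p2$mu_2N / p1$mu_2N, 7.5, tolerance = 1e-9)
  expect_equal(p2$mu_4N / p1$mu_4N, 7.5, tolerance = 1e-9)
  expect_equal(p2$bracket_split / p1$bracket_split, 7.5, tolerance = 1e-9)
  # classification is invariant to the rescaling
  c1 <- classify_nuclei(p1, nuc)$class
  c2 <- classify_nuclei(p2, scaled)$class
  expect_equal(c1, c2)
})

test_that("classification is a partition with the stated boundaries", {
  nuc <- make_nuclei(n = 2000)
  prof <- build_dna_profile(nuc)
  cls <- classify_nuclei(prof, nuc)
  expect_false(anyNA(cls$class))
  expect_equal(nrow(cls), nrow(nuc))

  probe <- data.frame(dna_intensity = c(prof$bracket_split,
                                        prof$bracket_split + 1e-6,
                                        prof$boundaries[["n2_max"]],
                                        prof$gt4N_start))
  pc <- classify_nuclei(prof, probe)$class
  expect_equal(as.character(pc),
               c("bracket1", "bracket2", "2N", "4N"))
  expect_error(classify_nuclei(prof, data.frame(dna_intensity = -1)),
               "positive")
})

test_that("planted classes are recovered with few confusions", {
  nuc <- make_nuclei()
  cls <- classify_nuclei(build_dna_profile(nuc), nuc)
  off_diag <- mean(as.character(cls$class) != cls$true_class)
  expect_lte(off_diag, 0.10)
})

test_that("EdU bracket-2 fraction behaves at the edges and recovers truth", {
  # nobody above the >4N start -> 0%
  low <- simulate_nuclei(ploidy_truth(
    fractions = c(sub2N = 0, `2N` = 0.6, S = 0.2, `4N` = 0.2, bracket1 = 0,
                  bracket2 = 0), n_cells = 3000, seed = 5))
  cls <- classify_nuclei(build_dna_profile(low), low)
  eb <- edu_bracket_fraction(cls)
  expect_lt(eb$percent, 1)  # boundary jitter only

  # planted share recovered within its Wilson CI
  nuc <- make_nuclei(seed = 11)
  truth_share <- with(list(f = c(0.60, 0.15, 0.15, 0.05, 0.05),
                           r = c(0.05, 0.95, 0.10, 0.60, 0.60)),
                      f[5] * r[5] / sum(f * r))
  cls2 <- classify_nuclei(build_dna_profile(nuc), nuc)
  eb2 <- edu_bracket_fraction(cls2)
  expect_gte(100 * truth_share, eb2$ci_lower)
  expect_lte(100 * truth_share, eb2$ci_upper)

  none <- data.frame(class = factor("2N", levels = senecon:::PLOIDY_CLASSES),
                     edu_positive = FALSE, group = "g")
  expect_error(edu_bracket_fraction(none), "EdU")
})

test_that("ploidy fractions close to 100 and recover planted values", {
  nuc <- make_nuclei(seed = 13)
  cls <- classify_nuclei(build_dna_profile(nuc), nuc)
  fr <- ploidy_fractions(cls)
  expect_equal(sum(fr$percent), 100, tolerance = 1e-9)
  planted <- c(sub2N = 0, `2N` = 0.60, S = 0.15, `4N` = 0.15,
               bracket1 = 0.05, bracket2 = 0.05)
  se <- sqrt(planted * (1 - planted) / 5000)
  got <- fr$percent[match(names(planted), fr$class)] / 100
  nz <- planted > 0
  expect_true(all(abs(got[nz] - planted[nz]) <= 3 * se[nz] + 0.005))
  # planted-zero sub-2N only picks up boundary jitter from peak detection
  expect_lt(got[match("sub2N", names(planted))], 0.02)

  single <- data.frame(class = factor(rep("2N", 10),
                                      levels = senecon:::PLOIDY_CLASSES),
                       group = "g")
  fs <- ploidy_fractions(single)
  expect_equal(fs$percent[fs$class == "2N"], 100)

  # replicate-wise summaries carry an s.d.
  cls$replicate <- rep(1:2, length.out = nrow(cls))
  fr2 <- ploidy_fractions(cls)
  expect_true("sd" %in% names(fr2))
})

test_that("focus binning respects the bin edges", {
  b <- bin_foci(data.frame(foci_count = c(0, 1, 5, 6, 10, 11), group = "g"))
  expect_equal(as.numeric(b[1, c("0", "1-5", "6-10", ">10")]), c(1, 2, 2, 1))
  z <- bin_foci(data.frame(foci_count = rep(0, 7), group = "g"))
  expect_equal(as.numeric(z[1, c("0", "1-5", "6-10", ">10")]), c(7, 0, 0, 0))
  expect_error(bin_foci(data.frame(foci_count = -1, group = "g")), "negative")
})

test_that("focus distribution test matches its arithmetic oracle", {
  ident <- foci_distribution_test(c(40, 30, 20, 10), c(40, 30, 20, 10))
  expect_equal(ident$chi2, 0)
  expect_equal(ident$p, 1)

  r <- foci_distribution_test(c(10, 20, 30, 40), c(40, 30, 20, 10))
  expect_equal(r$chi2, 900 / 40 + 100 / 30 + 100 / 20 + 900 / 10,
               tolerance = 1e-12)
  expect_equal(r$df, 3L)

  # zero reference bin with observed mass is flagged
  fl <- foci_distribution_test(c(10, 5, 3, 2), c(20, 0, 5, 5))
  expect_true(fl$zero_expected)

  # homogeneity variant agrees with stats::chisq.test
  h <- foci_distribution_test(c(10, 20, 30, 40), c(40, 30, 20, 10),
                              method = "homogeneity")
  ref <- suppressWarnings(stats::chisq.test(
    rbind(c(10, 20, 30, 40), c(40, 30, 20, 10)), correct = FALSE))
  expect_equal(h$chi2, unname(ref$statistic), tolerance = 1e-9)
})

test_that("focus test holds its type-I error under the same distribution", {
  probs <- c(0.55, 0.30, 0.10, 0.05)
  set.seed(47)
  # the default method treats the reference distribution as a fixed
  # expectation, so the null draws only the observed sample
  ref <- probs * 1000
  rej <- mean(replicate(400, {
    o <- rmultinom(1, 300, probs)[, 1]
    foci_distribution_test(o, ref)$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.02)
})
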