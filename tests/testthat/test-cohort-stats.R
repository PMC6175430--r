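test_that("Bonferroni threshold is exactly alpha / m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 6), 0.05 / 6)
  expect_equal(sprintf("%.4f", bonferroni_threshold(0.05, 6)), "0.0083")
  expect_equal(floor(bonferroni_threshold(0.05, 3) * 1000) / 1000, 0.016)
  expect_error(bonferroni_threshold(0.05, 0), class = "nfstoich_domain_error")
})

test_that("two-group test picks the right branch and detects shifts", {
  x <- c(1, 2, 3, 4, 5)
  res <- two_group_test(x, x, gaussian = FALSE)
  expect_equal(res$test_name, "Mann-Whitney U")
  expect_gt(res$p_value, 0.9)
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30) + 10
  expect_lt(two_group_test(a, b)$p_value, 1e-3)
  expect_equal(two_group_test(a, b, gaussian = TRUE)$test_name, "Welch t")
  # clearly skewed data routed to the nonparametric branch
  set.seed(8)
  s <- exp(rnorm(50, sd = 2))
  expect_equal(two_group_test(s, s + 0.1)$test_name, "Mann-Whitney U")
  expect_error(two_group_test(1, c(1, 2)), class = "nfstoich_domain_error")
})

test_that("Mann-Whitney U equals brute-force discordant-pair counting", {
  expect_equal(unname(suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$statistic)), 0)
  expect_equal(brute_force_u(c(1, 2, 3), c(4, 5, 6)), 0)
  set.seed(99)
  for (k in 1:60) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:5, nx, replace = TRUE)  # small pool forces ties
    y <- sample(1:5, ny, replace = TRUE)
    w <- unname(suppressWarnings(stats::wilcox.test(x, y)$statistic))
    expect_equal(w, brute_force_u(x, y))
  }
})

test_that("one-way GLM F matches the textbook mean-square ratio", {
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(9, 10, 11))
  res <- multi_group_glm(unlist(groups),
                         rep(c("a", "b", "c"), lengths(groups)))
  omni <- res$omnibus[res$omnibus$test_name == "one-way GLM (ANOVA)", ]
  expect_equal(omni$statistic, brute_force_anova_f(groups))
  expect_equal(c(omni$df1, omni$df2), c(2, 6))
  # all groups identical -> F = 0
  flat <- multi_group_glm(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(flat$omnibus$statistic[1], 0)
})

test_that("post hoc stage is gated on omnibus significance", {
  set.seed(3)
  null_dat <- rnorm(30)
  res <- multi_group_glm(null_dat, rep(c("a", "b", "c"), each = 10))
  if (res$omnibus$p_value[1] >= 0.05) expect_equal(nrow(res$posthoc), 0)
  shifted <- c(rnorm(10), rnorm(10), rnorm(10) + 50)
  res2 <- multi_group_glm(shifted, rep(c("a", "b", "c"), each = 10))
  expect_gt(nrow(res2$posthoc), 0)
  expect_true(any(res2$posthoc$significant))
  expect_error(multi_group_glm(1:5, rep("a", 5)),
               class = "nfstoich_domain_error")
})

test_that("progression association flags the isoform that differs by category", {
  set.seed(12)
  n <- 60
  cats <- sample(c("slow", "intermediate", "fast"), n, replace = TRUE)
  # months chosen so that (48 - alsfrs)/months lands in the wanted category
  alsfrs <- sample(20:40, n, replace = TRUE)
  months <- (48 - alsfrs) / c(slow = 0.25, intermediate = 0.75, fast = 1.5)[cats]
  cohort <- tibble::tibble(subject_id = sprintf("A%02d", 1:n),
                           alsfrs_baseline = alsfrs,
                           months_onset_to_baseline = months)
  profiles <- tibble::tibble(
    subject_id = cohort$subject_id, group = "ALS",
    nfl = rnorm(n, 24, 2), nfm = rnorm(n, 3, 0.3) + 4 * (cats == "fast"),
    nfh = rnorm(n, 2, 0.2), calibrated = TRUE)
  res <- progression_association(profiles, cohort)
  expect_lt(res$p_value[res$isoform == "NfM"], 0.05)
  expect_gt(res$p_value[res$isoform == "NfL"], 0.05)
  expect_gt(res$p_value[res$isoform == "NfH"], 0.05)
  expect_equal(res$posthoc[[which(res$isoform == "NfM")]]$alpha_corrected[1],
               0.05 / 3)
})

test_that("category-independent counts rarely reach significance", {
  set.seed(31)
  hits <- c(NfL = 0, NfM = 0, NfH = 0)
  reps <- 40
  for (r in seq_len(reps)) {
    n <- 45
    alsfrs <- sample(20:40, n, replace = TRUE)
    months <- runif(n, 5, 60)
    cohort <- tibble::tibble(subject_id = sprintf("A%02d", 1:n),
                             alsfrs_baseline = alsfrs,
                             months_onset_to_baseline = months)
    profiles <- tibble::tibble(
      subject_id = cohort$subject_id, group = "ALS",
      nfl = rlnorm(n, log(24), 0.5), nfm = rlnorm(n, log(3), 0.5),
      nfh = rlnorm(n, log(2), 0.5), calibrated = TRUE)
    res <- progression_association(profiles, cohort)
    hits <- hits + (res$p_value[match(c("NfL", "NfM", "NfH"), res$isoform)] < 0.05)
  }
  # per-isoform rejection should stay near the nominal 5% level
  expect_true(all(hits / reps <= 0.15))
})

test_that("a single progression category is an error", {
  cohort <- tibble::tibble(subject_id = c("A1", "A2", "A3", "A4"),
                           alsfrs_baseline = c(40, 41, 42, 40),
                           months_onset_to_baseline = c(40, 40, 40, 40))
  profiles <- tibble::tibble(subject_id = cohort$subject_id, group = "ALS",
                             nfl = 1:4, nfm = 1:4, nfh = 1:4,
                             calibrated = TRUE)
  expect_error(progression_association(profiles, cohort),
               class = "nfstoich_domain_error")
})
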