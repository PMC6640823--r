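test_that("animal-level aggregation is the plain mean of the 9 measurements", {
  expect_equal(aggregate_animal(rep(2, 9)), 2)
  expect_equal(aggregate_animal(1:9), 5)
  set.seed(2)
  v <- rnorm(9)
  expect_equal(aggregate_animal(v), sum(v) / 9)
  expect_error(aggregate_animal(numeric(0)), "no measurement")
})

test_that("Welch's t-test matches stats::t.test and the summary variant", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1), 0, 1)
    y <- rnorm(sample(3:8, 1), 0.5, 2)
    mine <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  # identical groups
  z <- c(1, 2, 3)
  res <- welch_t(z, z)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # published-table summaries: heart-to-body-weight ratio at week 4
  s <- welch_t_summary(2.33, 0.12, 4, 3.89, 0.38, 3)
  expect_equal(abs(s$t), 6.86, tolerance = 0.005)
  expect_equal(s$df, 2.30, tolerance = 0.005)
  # near-complete separation
  sep <- welch_t(c(0, 0, 0, 0) + rnorm(4, 0, 1e-9),
                 c(1, 1, 1, 1) + rnorm(4, 0, 1e-9))
  expect_lt(sep$p, 1e-6)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch reduces to the pooled t-test for equal variances and sizes", {
  set.seed(12)
  x <- rnorm(6); y <- rnorm(6)
  # force exactly equal sample variances by standardizing
  x <- (x - mean(x)) / sd(x); y <- (y - mean(y)) / sd(y) + 0.8
  mine <- welch_t(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(pooled$statistic), tolerance = 1e-10)
  expect_equal(mine$df, unname(pooled$parameter), tolerance = 1e-10)
})

test_that("Holm-Sidak adjustment follows the step-down formula", {
  expect_equal(holm_sidak_adjust(0.03), 0.03)
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)), c(1 - 0.99^2, 0.04),
               tolerance = 1e-12)
  # ties: all equal p adjusted to 1 - (1-q)^m
  q <- 0.02
  expect_equal(holm_sidak_adjust(rep(q, 4)), rep(1 - (1 - q)^4, 4),
               tolerance = 1e-12)
  # permutation equivariance, monotonicity, never below raw
  set.seed(8)
  for (i in 1:20) {
    p <- runif(6)
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    perm <- sample(6)
    expect_equal(holm_sidak_adjust(p[perm]), adj[perm], tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's d uses the pooled SD and matches the published-table value", {
  x <- c(1, 2, 3, 4); y <- x + 2
  expect_equal(cohen_d(x, y), -2 / sd(x))
  expect_equal(cohen_d(x, x), 0)
  d <- cohen_d_summary(2.33, 0.12, 4, 3.89, 0.38, 3)
  expect_equal(abs(d), 6.05, tolerance = 0.005)
  expect_error(cohen_d(c(1, 1), c(1, 1)), "zero")
})

test_that("star notation maps adjusted p-values to the printed thresholds", {
  expect_equal(p_stars(c(0.04, 0.009, 0.0009, 0.00009, 0.2)),
               c("*", "**", "***", "****", "ns"))
})

test_that("group comparisons flip sign under group relabeling, p unchanged", {
  set.seed(31)
  animals <- expand.grid(week = c(1, 2), roi = "LVP",
                         parameter = "tau1_ch4", idx = 1:4,
                         group = c("AMC", "MI"), stringsAsFactors = FALSE)
  animals$animal_id <- paste0(animals$group, animals$idx)
  animals$value <- rnorm(nrow(animals),
                         mean = ifelse(animals$group == "MI", 0.35, 0.41),
                         sd = 0.05)
  res <- compare_groups(animals)
  swapped <- animals
  swapped$group <- ifelse(animals$group == "AMC", "MI", "AMC")
  res2 <- compare_groups(swapped)
  expect_equal(res2$t_stat, -res$t_stat, tolerance = 1e-10)
  expect_equal(res2$cohen_d, -res$cohen_d, tolerance = 1e-10)
  expect_equal(res2$p_raw, res$p_raw, tolerance = 1e-12)
  expect_equal(res2$p_adj, res$p_adj, tolerance = 1e-12)
  # adjusted p never below raw; stars consistent with p_adj
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_equal(res$stars, p_stars(res$p_adj))
})

test_that("comparisons with a missing group are skipped with a warning", {
  animals <- data.frame(
    animal_id = paste0("a", 1:4), group = c("AMC", "AMC", "AMC", "MI"),
    week = 1, roi = "RV", parameter = "tau_ch1",
    value = c(2.5, 2.6, 2.7, 3.1))
  expect_warning(res <- compare_groups(animals), "n >= 2")
  expect_equal(nrow(res), 0)
})
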