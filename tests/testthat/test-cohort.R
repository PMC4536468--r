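test_that("ratio distribution summary uses strict boundaries and the
           midpoint median", {
  s <- ratio_distribution_summary(c(0.8, 1.0, 1.2, 1.05))
  expect_equal(s$median, 1.025)
  expect_equal(s$frac_outside, 0.5)
  expect_equal(ratio_distribution_summary(c(1.15, 1.15))$frac_outside, 0)
  expect_equal(ratio_distribution_summary(c(1.15, 1.15))$frac_above_hi, 0)
  s1 <- ratio_distribution_summary(1.0)
  expect_equal(s1$median, 1.0)
  expect_equal(s1$frac_outside, 0)
  expect_error(ratio_distribution_summary(numeric(0)), "no finite")
})

test_that("metaphase and anaphase R selection follow the earliest-frames and
           last-frame-before-onset conventions", {
  sel <- metaphase_R_selection(c(1.10, 1.12, 1.14, 1.00))
  expect_equal(sel$metaphase_R, 1.12)
  expect_equal(metaphase_R_selection(c(1.0, 1.1))$metaphase_R, 1.05)
  r <- seq(1.00, 1.11, by = 0.01)
  sel10 <- metaphase_R_selection(r, anaphase_frame = 10L)
  expect_equal(sel10$anaphase_R, r[10])   # frame 9, the last before 10
  expect_true(is.na(metaphase_R_selection(r)$anaphase_R))
})

test_that("anaphase-aligned trajectories are deterministic and degenerate
           bands collapse for constant cells", {
  cells <- lapply(1:5, function(i) {
    list(time_s = seq(0, 300, by = 30), R = rep(1, 11),
         anaphase_time_s = 240)
  })
  tr <- anaphase_aligned_trajectories(cells, dt_s = 30, n_boot = 50,
                                      seed = 9)
  expect_true(all(tr$median_R == 1))
  expect_true(all(tr$ci_hi - tr$ci_lo == 0))
  expect_true(all(tr$ci_lo <= tr$median_R & tr$median_R <= tr$ci_hi))
  tr2 <- anaphase_aligned_trajectories(cells, dt_s = 30, n_boot = 50,
                                       seed = 9)
  expect_identical(tr, tr2)
  expect_error(anaphase_aligned_trajectories(list(list(
    time_s = 0, R = 1, anaphase_time_s = NA)), dt_s = 30), "no cell")
})

test_that("welch t and paired t match the textbook formulas", {
  x <- c(5.1, 4.9, 5.6, 4.7, 5.3, 5.0)
  y <- c(4.2, 4.8, 4.1, 4.4, 4.3, 4.6, 4.0)
  res <- compare_groups(x, y, "welch_t")
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                       (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_hand), df_hand),
               tolerance = 1e-12)
  # identical samples: statistic 0, p = 1
  z <- c(1, 2, 3, 4)
  res_id <- compare_groups(z, z, "welch_t")
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)

  # paired t on near-constant differences, n = 11
  set.seed(41)
  b <- stats::rnorm(11, 1.03, 0.05)
  a <- b - 0.08 + stats::rnorm(11, 0, 0.005)
  res_p <- compare_groups(b, a, "paired_t")
  d <- b - a
  t_hand <- mean(d) / (sd(d) / sqrt(11))
  expect_equal(res_p$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res_p$p_value, 2 * stats::pt(-abs(t_hand), 10),
               tolerance = 1e-12)
  expect_lt(res_p$p_value, 0.01)
})

test_that("Mann-Whitney U matches exhaustive permutation for small samples", {
  set.seed(42)
  for (rep in 1:5) {
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    x <- round(stats::rnorm(n1, 0, 1), 6)
    y <- round(stats::rnorm(n2, 0.5, 1), 6)
    res <- compare_groups(x, y, "mann_whitney_u")
    # oracle: enumerate all assignments of the pooled sample
    pool <- c(x, y)
    u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    u_all <- apply(combs, 2, function(idx) {
      sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
    expect_equal(res$statistic, u_obs)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  }
  # strong separation at n = 30: overwhelming evidence
  set.seed(43)
  a <- stats::rnorm(30)
  b <- stats::rnorm(30) + 10
  expect_lt(compare_groups(a, b, "mann_whitney_u")$p_value, 1e-6)
})

test_that("Levene test detects unequal variances and matches car", {
  set.seed(44)
  a <- stats::rnorm(40, 0, 1)
  b <- stats::rnorm(40, 0, 4)
  res <- compare_groups(a, b, "levene")
  ref <- car::leveneTest(c(a, b), factor(rep(1:2, each = 40)),
                         center = stats::median)
  expect_equal(res$p_value, ref[1, "Pr(>F)"])
  expect_lt(res$p_value, 0.01)
  expect_gt(compare_groups(a, a + 5, "levene")$p_value, 0.9)
})

test_that("exact binomial and Fisher tests match full enumeration", {
  res <- count_tests(8L, "exact_binomial", n = 8L)
  expect_identical(res$p_value, 2 / 256)
  # enumeration oracle over arbitrary (k, n)
  set.seed(45)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    k <- sample(0:n, 1)
    pk <- stats::dbinom(k, n, 0.5)
    p_oracle <- sum(stats::dbinom(0:n, n, 0.5)[
      stats::dbinom(0:n, n, 0.5) <= pk * (1 + 1e-7)])
    expect_equal(count_tests(k, "exact_binomial", n = n)$p_value, p_oracle,
                 tolerance = 1e-12)
  }

  expect_equal(count_tests(matrix(5, 2, 2), "fisher_exact")$p_value, 1.0)
  # hypergeometric enumeration oracle for a 2x2 table
  fisher_oracle <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    ks <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- stats::dhyper(ks, r1, n - r1, c1)
    p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tab_diag <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_equal(count_tests(tab_diag, "fisher_exact")$p_value,
               fisher_oracle(tab_diag), tolerance = 1e-12)
  expect_equal(fisher_oracle(tab_diag), 2 / choose(20, 10),
               tolerance = 1e-12)
  set.seed(46)
  for (rep in 1:10) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(count_tests(tab, "fisher_exact")$p_value,
                 fisher_oracle(tab), tolerance = 1e-9)
  }
})

test_that("cohort summary aggregates conditions and echoes provenance", {
  per_cell <- data.frame(
    cell_id = sprintf("c%02d", 1:6),
    config_label = rep(c("C22", "C21"), each = 3),
    metaphase_R = c(1.00, 1.02, 0.98, 1.10, 1.20, 1.16),
    anaphase_R = c(1.0, 1.01, 0.99, 1.02, 1.05, 1.0),
    rotating = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  s <- summarize_cohort(per_cell)
  expect_equal(s$conditions$C22$n_cells, 3L)
  expect_equal(s$conditions$C21$frac_above_hi, 2 / 3)
  expect_equal(s$conditions$C21$frac_rotating, 2 / 3)
  expect_equal(s$provenance$ratio_hi, 1.15)
})
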