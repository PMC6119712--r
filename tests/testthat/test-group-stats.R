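tab1 <- table1_fixture()

test_that("group descriptives use the population-SD convention", {
  tot <- describe_groups(tab1$ast_total, tab1$group)
  expect_equal(round(tot$mean[tot$group == "apraxic"], 1), 5.4)
  expect_equal(round(tot$sd[tot$group == "apraxic"], 1), 2.0)
  expect_equal(round(tot$mean[tot$group == "pseudo_apraxic"], 1), 9.8)
  expect_equal(round(tot$sd[tot$group == "pseudo_apraxic"], 1), 0.9)
  expect_equal(round(tot$mean[tot$group == "unaffected"], 1), 12.0)
  expect_equal(tot$sd[tot$group == "unaffected"], 0.0)
  dur <- describe_groups(tab1$disease_duration, tab1$group)
  expect_equal(round(dur$sd[dur$group == "apraxic"], 1), 367.9)
  expect_equal(round(dur$mean[dur$group == "apraxic"], 1), 284.6)
  cst <- describe_groups(rep(3, 5), rep("g", 5))
  expect_equal(cst$sd, 0.0)
  expect_error(describe_groups(1:3, factor(rep("a", 3), c("a", "b"))),
               "empty group")
})

test_that("tie-corrected Kruskal-Wallis reproduces the cohort statistics", {
  expect_equal(kruskal_wallis(tab1$education, tab1$group)$statistic,
               3.109, tolerance = 1e-3)
  expect_equal(kruskal_wallis(tab1$mmse, tab1$group)$statistic,
               1.417, tolerance = 1e-3)
  expect_equal(kruskal_wallis(tab1$disease_duration, tab1$group)$statistic,
               0.526, tolerance = 1e-3)
  deg <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))
  expect_true(isTRUE(deg$degenerate))
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
})

test_that("Pearson chi-square matches the printed sex table and the formula", {
  sex_tab <- rbind(c(7, 2), c(5, 1), c(3, 4))
  res <- pearson_chi_square(sex_tab)
  expect_equal(res$statistic, 3.086, tolerance = 1e-3)
  expect_equal(res$df, 2)
  # proportional rows: exact independence
  expect_equal(pearson_chi_square(rbind(c(2, 4), c(3, 6)))$statistic, 0)
  # random table vs cell-by-cell sum((O-E)^2/E)
  set.seed(1)
  o <- matrix(rpois(4, 8) + 1, 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(pearson_chi_square(o)$statistic, sum((o - e)^2 / e))
  expect_error(pearson_chi_square(rbind(c(0, 0), c(1, 2))), "marginal")
})

test_that("Mann-Whitney U uses exact enumeration for small samples", {
  res <- nonparametric_compare("mann_whitney", c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2 of the C(6,3) = 20 assignments
  # agrees with the exact distribution when there are no ties
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    res <- nonparametric_compare("mann_whitney", x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, unname(ref$statistic))
  }
})

test_that("Wilcoxon signed-rank handles zeros, ties, and small-sample exactness", {
  expect_error(nonparametric_compare("wilcoxon_signed_rank",
                                     c(1, 2, 3), c(1, 2, 3)),
               "zero")
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    res <- nonparametric_compare("wilcoxon_signed_rank", x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman statistic is maximal under perfectly consistent rankings", {
  m <- matrix(rep(c(1, 5, 9), each = 5), nrow = 5)
  res <- nonparametric_compare("friedman", m)
  expect_equal(res$statistic, 10)  # n (k - 1) with n = 5, k = 3
  expect_equal(res$df, 2)
  expect_error(nonparametric_compare("friedman", m[, 1, drop = FALSE]),
               "two conditions")
})

test_that("split-plot ANOVA yields the design dfs and matches aov when balanced", {
  set.seed(4)
  groups <- rep(c("apraxic", "pseudo_apraxic", "unaffected"), c(7, 6, 9))
  m <- matrix(rnorm(66), 22, 3,
              dimnames = list(NULL, c("tactile", "passive", "active")))
  res <- mixed_anova(m, groups)
  expect_equal(res$group$df, c(2, 19))
  expect_equal(res$condition$df, c(2, 38))
  expect_equal(res$interaction$df, c(4, 38))
  # all-equal measures: every F collapses to zero
  flat <- mixed_anova(matrix(5, 12, 3), rep(c("a", "b"), each = 6))
  expect_equal(flat$group$statistic, 0)
  expect_equal(flat$condition$statistic, 0)
  expect_equal(flat$interaction$statistic, 0)
  # balanced oracle: aov with an explicit Error(subject) stratum
  mb <- matrix(c(3, 5, 4, 8, 7, 9, 2, 6, 5, 9, 8, 11), 6, 2)
  gb <- rep(c("g1", "g2"), each = 3)
  res_b <- mixed_anova(mb, gb)
  df <- data.frame(y = as.vector(mb),
                   cond = factor(rep(1:2, each = 6)),
                   grp = factor(rep(gb, 2)),
                   subj = factor(rep(1:6, 2)))
  ref <- summary(aov(y ~ grp * cond + Error(subj), data = df))
  f_grp <- ref[["Error: subj"]][[1]]["grp", "F value"]
  f_cond <- ref[["Error: Within"]][[1]]["cond", "F value"]
  f_int <- ref[["Error: Within"]][[1]]["grp:cond", "F value"]
  expect_equal(res_b$group$statistic, f_grp, tolerance = 1e-10)
  expect_equal(res_b$condition$statistic, f_cond, tolerance = 1e-10)
  expect_equal(res_b$interaction$statistic, f_int, tolerance = 1e-10)
  expect_error(mixed_anova(m[, 1, drop = FALSE], groups), "2 conditions")
  expect_error(mixed_anova(m[1:8, ], rep(c("a", "b"), c(7, 1))),
               ">= 2 subjects")
})

test_that("post hoc comparisons behave at the degenerate boundaries", {
  m <- matrix(rep(1:3, each = 9), 9, 3)  # identical group means everywhere
  g <- rep(c("a", "b", "c"), 3)
  tk <- posthoc_interaction(m, g, "tukey")
  expect_true(all(tk$p_value > 0.999))
  pt <- posthoc_interaction(cbind(m[, 1], m[, 1]), g, "paired_t")
  expect_true(all(pt$statistic == 0))
  expect_true(all(pt$p_value == 1))
})

test_that("Bonferroni adjustment is uncapped by default", {
  expect_equal(bonferroni_adjust(0.013, 1), 0.013)
  expect_equal(bonferroni_adjust(0.5, 3), 1.5)
  expect_equal(round(bonferroni_adjust(0.8317, 3), 3), 2.495)
  expect_equal(bonferroni_adjust(0.5, 3, cap = TRUE), 1)
  expect_error(bonferroni_adjust(0.5, 0), "m must be")
})

test_that("Spearman correlation equals Pearson on mid-ranks", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x)$estimate, 1)
  expect_equal(spearman_correlation(x, rev(x))$estimate, -1)
  # ties: equals correlation of explicitly computed mid-ranks
  set.seed(6)
  xs <- sample(1:4, 12, replace = TRUE)
  ys <- sample(1:4, 12, replace = TRUE)
  midrank_by_count <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  expect_equal(spearman_correlation(xs, ys)$estimate,
               cor(midrank_by_count(xs), midrank_by_count(ys)))
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero rank variance")
})

test_that("rank tests conserve the total rank sum and link KW to MW", {
  set.seed(8)
  for (i in 1:20) {
    v <- sample(1:6, 15, replace = TRUE)
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (length(unique(g)) < 3) next
    expect_no_error(kruskal_wallis(v, g))
  }
  # k = 2 Kruskal-Wallis equals the squared normal-approximation MW z
  x <- c(1, 1, 2, 4, 5, 7, 7, 8, 9, 12, 13, 13, 15)
  y <- c(2, 3, 3, 6, 7, 10, 11, 11, 14, 16, 17)
  h <- kruskal_wallis(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
  u <- nonparametric_compare("mann_whitney", x, y)$statistic
  N <- length(x) + length(y)
  ties <- table(c(x, y))
  sig2 <- length(x) * length(y) / 12 *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (u - length(x) * length(y) / 2) / sqrt(sig2)
  expect_equal(h$statistic, z^2, tolerance = 1e-10)
})
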