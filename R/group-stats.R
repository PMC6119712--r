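# container for a named statistical test outcome
test_result <- function(test_name, statistic, df, p_value,
                        p_adjusted = NA_real_, effect_direction = NA_real_,
                        extra = NULL) {
  out <- list(test_name = test_name, statistic = unname(statistic),
              df = unname(df), p_value = unname(p_value),
              p_adjusted = unname(p_adjusted),
              effect_direction = effect_direction)
  out <- c(out, extra)
  class(out) <- "vmti_test"
  out
}

#' @export
print.vmti_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g",
              x$test_name, x$statistic,
              paste(signif(x$df, 5), collapse = ", "), x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p.adj = %.4g", x$p_adjusted))
  cat("\n")
  invisible(x)
}

# mid-ranks with the rank-sum conservation check every rank test relies on
midranks <- function(x) {
  r <- rank(x, ties.method = "average")
  stopifnot(isTRUE(all.equal(sum(r), length(x) * (length(x) + 1) / 2)))
  r
}

#' Group descriptives with the population-SD convention
#'
#' Mean and standard deviation per group, with the SD computed with
#' divisor n (population convention) to match the published table rows.
#' Rounding to one decimal is presentation-only, via the `digits`
#' argument of `print()`.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return data.frame with columns group, n, mean, sd.
#' @examples
#' tab <- table1_fixture()
#' describe_groups(tab$ast_total, tab$group)
#' @export
describe_groups <- function(values, groups) {
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (!is.factor(groups)) groups <- factor(groups)
  if (any(tabulate(groups, nlevels(groups)) == 0)) stop("empty group")
  agg <- lapply(split(values, groups), function(v) {
    c(n = length(v), mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
  })
  out <- data.frame(group = names(agg),
                    n = sapply(agg, `[[`, "n"),
                    mean = sapply(agg, `[[`, "mean"),
                    sd = sapply(agg, `[[`, "sd"))
  rownames(out) <- NULL
  out
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-sample location test on mid-ranks with the tie
#' correction \eqn{H / (1 - \sum (t^3 - t)/(N^3 - N))}; p-value from the
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (k >= 2 non-empty groups).
#' @return a `vmti_test` result.
#' @examples
#' tab <- table1_fixture()
#' kruskal_wallis(tab$education, tab$group)  # H = 3.109
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(tabulate(groups, nlevels(groups)) == 0)) stop("empty group")
  invisible(midranks(values))  # rank-sum conservation assertion
  if (length(unique(values)) == 1) {
    # all observations tied: the tie-correction denominator vanishes
    return(test_result("kruskal_wallis", statistic = 0,
                       df = nlevels(groups) - 1, p_value = 1,
                       extra = list(degenerate = TRUE)))
  }
  kt <- stats::kruskal.test(values, groups)
  test_result("kruskal_wallis", statistic = kt$statistic,
              df = kt$parameter, p_value = kt$p.value)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction on a contingency
#' table of counts; df = (r - 1)(c - 1).
#'
#' @param table matrix of non-negative integer counts, at least 2 x 2.
#' @return a `vmti_test` result.
#' @examples
#' pearson_chi_square(rbind(c(7, 2), c(5, 1), c(3, 4)))  # 3.086
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("pearson_chi_square", statistic = ct$statistic,
              df = ct$parameter, p_value = ct$p.value)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments;
# mid-rank U so ties are handled
mann_whitney_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  u_obs <- mw_u(x, y)
  idx <- combn(n, m)
  us <- apply(idx, 2, function(i) mw_u(pooled[i], pooled[-i]))
  # two-sided: fraction of assignments at least as extreme as observed
  # around the null mean mn/2
  dev <- abs(us - m * (n - m) / 2)
  mean(dev >= abs(u_obs - m * (n - m) / 2) - 1e-9)
}

mw_u <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Nonparametric two-sample / paired / repeated-measures comparisons
#'
#' Mann-Whitney U (independent samples), Wilcoxon signed-rank (paired,
#' zero differences dropped) and Friedman (subjects x conditions) tests
#' with mid-rank tie handling. For small samples (combined n <= 12 for
#' U; <= 12 nonzero pairs for Wilcoxon) the two-sided p-value is exact
#' by enumeration; larger samples use the tie-corrected normal (U,
#' Wilcoxon) or chi-square (Friedman) approximation.
#'
#' @param kind one of "mann_whitney", "wilcoxon_signed_rank", "friedman".
#' @param x first sample (mann_whitney, wilcoxon) or a subjects x
#'   conditions matrix (friedman).
#' @param y second sample / paired sample (ignored for friedman).
#' @param exact_max largest sample size for exact enumeration.
#' @return a `vmti_test` result.
#' @examples
#' nonparametric_compare("mann_whitney", c(1, 2, 3), c(4, 5, 6))
#' @export
nonparametric_compare <- function(kind = c("mann_whitney",
                                           "wilcoxon_signed_rank",
                                           "friedman"),
                                  x, y = NULL, exact_max = 12) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    if (is.null(y)) stop("mann_whitney needs two samples")
    invisible(midranks(c(x, y)))
    u <- mw_u(x, y)
    m <- length(x); n2 <- length(y); N <- m + n2
    if (N <= exact_max) {
      p <- mann_whitney_exact_p(x, y)
    } else {
      ties <- table(c(x, y))
      mu <- m * n2 / 2
      sig2 <- m * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      z <- (u - mu) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    return(test_result("mann_whitney", statistic = u, df = NA_real_,
                       p_value = min(p, 1),
                       effect_direction = sign(u - m * n2 / 2)))
  }
  if (kind == "wilcoxon_signed_rank") {
    if (is.null(y)) stop("wilcoxon needs paired samples")
    d <- x - y
    d <- d[d != 0]
    if (length(d) == 0) stop("all paired differences are zero")
    r <- midranks(abs(d))
    w <- sum(r[d > 0])
    n <- length(d)
    if (n <= exact_max) {
      signs <- expand.grid(rep(list(c(0, 1)), n))
      ws <- as.matrix(signs) %*% r
      dev <- abs(ws - n * (n + 1) / 4)
      p <- mean(dev >= abs(w - n * (n + 1) / 4) - 1e-9)
    } else {
      ties <- table(abs(d))
      mu <- n * (n + 1) / 4
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
      p <- 2 * stats::pnorm(-abs((w - mu) / sqrt(sig2)))
    }
    return(test_result("wilcoxon_signed_rank", statistic = w,
                       df = NA_real_, p_value = min(p, 1),
                       effect_direction = sign(w - n * (n + 1) / 4)))
  }
  # friedman
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("friedman needs at least two conditions")
  if (anyNA(x)) stop("friedman needs a complete subjects x conditions matrix")
  ft <- stats::friedman.test(x)
  test_result("friedman", statistic = ft$statistic, df = ft$parameter,
              p_value = ft$p.value)
}

#' Split-plot (mixed) ANOVA with Type III sums of squares
#'
#' Univariate mixed ANOVA for one between-subjects factor (group) and
#' one within-subjects factor (condition). The between stratum tests
#' group on the subject means against subjects-within-groups error; the
#' within stratum tests condition and the group x condition interaction
#' on subject-centred deviations with Type III drop-tests under sum
#' contrasts, against the subject x condition residual. For g groups, N
#' subjects and k conditions the error dfs are N - g (between) and
#' (N - g)(k - 1) (within), e.g. (2, 38) for condition and (4, 38) for
#' the interaction with 22 subjects in three groups and three
#' conditions. No sphericity correction is applied.
#'
#' @param measures numeric matrix, subjects x conditions (complete).
#' @param groups group label per subject (>= 2 groups, each with >= 2
#'   subjects).
#' @return list of `vmti_test` results: `group`, `condition`,
#'   `interaction`.
#' @examples
#' m <- matrix(rnorm(66), 22, 3)
#' mixed_anova(m, rep(c("a", "p", "u"), c(7, 6, 9)))
#' @export
mixed_anova <- function(measures, groups) {
  measures <- as.matrix(measures)
  if (anyNA(measures)) stop("missing cells in measures")
  groups <- factor(groups)
  n <- nrow(measures); k <- ncol(measures); g <- nlevels(groups)
  if (g < 2 || k < 2) stop("need >= 2 groups and >= 2 conditions")
  if (any(table(groups) < 2)) stop("each group needs >= 2 subjects")
  ## between stratum: subject means
  m_i <- rowMeans(measures)
  grand <- mean(m_i)
  gm <- tapply(m_i, groups, mean)
  ng <- tabulate(groups, g)
  ss_group <- k * sum(ng * (gm[levels(groups)] - grand)^2)
  ss_subj <- k * sum((m_i - gm[groups])^2)
  df_group <- g - 1; df_subj <- n - g
  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  ## within stratum: subject-centred deviations, Type III via sum contrasts
  d <- measures - m_i
  long <- data.frame(
    d = as.vector(d),
    cond = factor(rep(colnames(measures) %||% seq_len(k), each = n)),
    grp = rep(groups, k))
  mm_full <- stats::model.matrix(~ cond * grp, long,
                                 contrasts.arg = list(cond = "contr.sum",
                                                      grp = "contr.sum"))
  rss <- function(X) {
    fit <- stats::lm.fit(X, long$d)
    sum(fit$residuals^2)
  }
  asg <- attr(mm_full, "assign")  # 0 = intercept, 1 = cond, 2 = grp, 3 = int
  rss_full <- rss(mm_full)
  ss_cond <- rss(mm_full[, asg != 1, drop = FALSE]) - rss_full
  ss_int <- rss(mm_full[, asg != 3, drop = FALSE]) - rss_full
  df_cond <- k - 1
  df_int <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)
  ms_err <- rss_full / df_err
  safe_f <- function(ss, df) if (ms_err == 0 && ss == 0) 0 else (ss / df) / ms_err
  f_cond <- safe_f(ss_cond, df_cond)
  f_int <- safe_f(ss_int, df_int)
  if (ss_subj == 0 && ss_group == 0) f_group <- 0
  list(
    group = test_result("mixed_anova_group", f_group,
                        c(df_group, df_subj),
                        stats::pf(f_group, df_group, df_subj,
                                  lower.tail = FALSE)),
    condition = test_result("mixed_anova_condition", f_cond,
                            c(df_cond, df_err),
                            stats::pf(f_cond, df_cond, df_err,
                                      lower.tail = FALSE)),
    interaction = test_result("mixed_anova_interaction", f_int,
                              c(df_int, df_err),
                              stats::pf(f_int, df_int, df_err,
                                        lower.tail = FALSE))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Post hoc comparisons after a split-plot ANOVA
#'
#' `tukey`: Tukey-Kramer comparisons of group means within each
#' condition, using the pooled within-condition error term (one-way MSE
#' at that condition, df N - g). `paired_t`: within each group, paired
#' t-tests between the condition pairs with uncapped Bonferroni
#' adjustment over the pairs.
#'
#' @param measures subjects x conditions matrix.
#' @param groups group label per subject.
#' @param method "tukey" or "paired_t".
#' @return data.frame of comparisons with statistic, df, p, p_adjusted.
#' @export
posthoc_interaction <- function(measures, groups,
                                method = c("tukey", "paired_t")) {
  method <- match.arg(method)
  measures <- as.matrix(measures)
  groups <- factor(groups)
  conds <- colnames(measures) %||% paste0("cond", seq_len(ncol(measures)))
  colnames(measures) <- conds
  if (method == "tukey") {
    g <- nlevels(groups)
    rows <- list()
    for (cd in conds) {
      v <- measures[, cd]
      mse <- sum((v - tapply(v, groups, mean)[groups])^2) /
        (length(v) - g)
      dfe <- length(v) - g
      for (pair in combn(levels(groups), 2, simplify = FALSE)) {
        va <- v[groups == pair[1]]; vb <- v[groups == pair[2]]
        se <- sqrt(mse / 2 * (1 / length(va) + 1 / length(vb)))
        q <- if (se == 0) 0 else abs(mean(va) - mean(vb)) / se
        p <- stats::ptukey(q, g, dfe, lower.tail = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cd, group_a = pair[1], group_b = pair[2],
          statistic = q, df = dfe, p_value = p, p_adjusted = p)
      }
    }
    out <- do.call(rbind, rows)
  } else {
    pairs <- combn(conds, 2, simplify = FALSE)
    m <- length(pairs)
    rows <- list()
    for (gl in levels(groups)) {
      sub <- measures[groups == gl, , drop = FALSE]
      for (pair in pairs) {
        d <- sub[, pair[1]] - sub[, pair[2]]
        if (all(d == 0)) {
          tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
        } else {
          tt <- stats::t.test(sub[, pair[1]], sub[, pair[2]], paired = TRUE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          group = gl, cond_a = pair[1], cond_b = pair[2],
          statistic = unname(tt$statistic), df = unname(tt$parameter),
          p_value = tt$p.value,
          p_adjusted = bonferroni_adjust(tt$p.value, m))
      }
    }
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out
}

#' Bonferroni adjustment, uncapped by default
#'
#' Multiplies p-values by the number of comparisons. Following the
#' reporting convention of the source analyses, the product is not
#' capped at 1 unless `cap = TRUE` (an adjusted p of 2.495 is reported
#' as such).
#'
#' @param p p-value vector.
#' @param m number of comparisons (>= 1).
#' @param cap cap adjusted values at 1?
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(0.8317, 3)  # 2.495
#' @export
bonferroni_adjust <- function(p, m, cap = FALSE) {
  if (m < 1) stop("m must be >= 1")
  out <- p * m
  if (cap) out <- pmin(out, 1)
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (tie-safe); the two-sided
#' p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 df.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a `vmti_test` result with `estimate` holding rho.
#' @examples
#' tab <- table1_fixture()
#' spearman_correlation(tab$ast_total, tab$education)
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- midranks(x); ry <- midranks(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  test_result("spearman", statistic = rho, df = n - 2, p_value = p,
              effect_direction = sign(rho), extra = list(estimate = rho))
}
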