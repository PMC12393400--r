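test_that("significance stars follow the figure-legend thresholds", {
  expect_equal(significance_stars(c(0.03, 0.5, 9e-5, 0.004, 5e-4)),
               c("*", "NS", "****", "**", "***"))
  expect_equal(significance_stars(0.05), "NS")  # threshold is strict
  expect_error(significance_stars(1.2), "\\[0, 1\\]")
  expect_error(significance_stars(-0.1), "\\[0, 1\\]")
})

test_that("exact Mann-Whitney reproduces hand-enumerated cases", {
  out <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 0.1)  # 2 of the 20 assignments are as extreme
  expect_true(out$exact)
  same <- mann_whitney_exact(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_equal(same$p.value, 1)
})

test_that("exact Mann-Whitney agrees with enumeration for n1+n2 <= 12", {
  set.seed(55)
  sizes <- expand.grid(n1 = 2:6, n2 = 2:6)
  sizes <- sizes[sizes$n1 + sizes$n2 <= 12, ]
  for (k in seq_len(nrow(sizes))) {
    x <- sample(1:8, sizes$n1[k], replace = TRUE)  # ties likely
    y <- sample(1:8, sizes$n2[k], replace = TRUE)
    expect_equal(mann_whitney_exact(x, y)$p.value, oracle_mw_p(x, y),
                 info = paste("ties case", k))
    xc <- rnorm(sizes$n1[k])
    yc <- rnorm(sizes$n2[k])
    expect_equal(mann_whitney_exact(xc, yc)$p.value, oracle_mw_p(xc, yc),
                 info = paste("continuous case", k))
    # without ties, wilcox.test's exact p is an independent cross-check
    expect_equal(mann_whitney_exact(xc, yc)$p.value,
                 stats::wilcox.test(xc, yc, exact = TRUE)$p.value)
  }
})

test_that("large-sample Mann-Whitney tracks the normal approximation", {
  set.seed(9)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  out <- mann_whitney_exact(x, y)
  expect_false(out$exact)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(out$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("the normality gate routes by the all-pass Shapiro rule", {
  set.seed(204)
  gaussian <- data.frame(
    g = rep(c("a", "b", "c"), each = 30),
    y = rnorm(90)
  )
  gate <- normality_gate(gaussian, y, g)
  expect_equal(gate$route, "parametric")
  expect_equal(nrow(gate$shapiro), 3)
  heavy <- data.frame(g = rep(c("a", "b"), each = 50),
                      y = c(rnorm(50), rcauchy(50)))
  expect_equal(normality_gate(heavy, y, g)$route, "nonparametric")
})

test_that("the gate rejects undersized and degenerate groups by name", {
  small <- data.frame(g = c("a", "a", "a", "tiny", "tiny"), y = rnorm(5))
  expect_error(normality_gate(small, y, g), "tiny")
  flat <- data.frame(g = rep(c("a", "const"), each = 5),
                     y = c(rnorm(5), rep(1, 5)))
  expect_error(normality_gate(flat, y, g), "const")
})

test_that("two-group comparisons route to Student t or exact Mann-Whitney", {
  set.seed(31)
  d <- data.frame(g = rep(c("wt", "mut"), each = 12),
                  y = c(rnorm(12, 10, 2), rnorm(12, 14, 2)))
  par <- compare_groups(d, y, g, control = "wt", route = "parametric")
  expect_equal(par$method, "Student t")
  ref <- t.test(d$y[d$g == "mut"], d$y[d$g == "wt"], var.equal = TRUE)
  expect_equal(par$p.value, ref$p.value)
  nonpar <- compare_groups(d, y, g, control = "wt",
                           route = "nonparametric")
  expect_match(nonpar$method, "Mann-Whitney")
  small <- data.frame(g = rep(c("wt", "mut"), each = 5),
                      y = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  out <- compare_groups(small, y, g, route = "nonparametric")
  expect_match(out$method, "exact")
})

test_that("three-group parametric routing runs ANOVA with Dunnett", {
  set.seed(77)
  d <- data.frame(g = rep(c("wt", "m1", "m2"), each = 15),
                  y = c(rnorm(15, 10), rnorm(15, 10.2), rnorm(15, 14)))
  fit <- compare_groups(d, y, g, control = "wt", route = "parametric")
  expect_equal(fit$method, "one-way ANOVA + Dunnett")
  expect_equal(nrow(fit$posthoc), 2)
  expect_true(all(grepl("vs wt", fit$posthoc$comparison)))
  ref <- summary(stats::aov(y ~ g, data = d))[[1]]
  expect_equal(fit$p.value, ref$`Pr(>F)`[1])
  # the shifted group is flagged, the null group is not
  p_m2 <- fit$posthoc$p.value[grepl("m2", fit$posthoc$comparison)]
  p_m1 <- fit$posthoc$p.value[grepl("m1", fit$posthoc$comparison)]
  expect_lt(p_m2, 0.001)
  expect_gt(p_m1, 0.05)
})

test_that("three-group nonparametric routing runs Kruskal-Wallis + Dunn", {
  set.seed(78)
  d <- data.frame(g = rep(c("wt", "m1", "m2"), each = 15),
                  y = c(rcauchy(15), rcauchy(15), rcauchy(15) + 30))
  fit <- compare_groups(d, y, g, control = "wt")
  expect_equal(fit$route, "nonparametric")
  expect_equal(fit$method, "Kruskal-Wallis + Dunn (Holm)")
  ref <- stats::kruskal.test(d$y, factor(d$g))
  expect_equal(fit$p.value, ref$p.value)
  expect_equal(nrow(fit$posthoc), 2)
})

test_that("the unequal-variance route uses Welch tests", {
  set.seed(79)
  d <- data.frame(g = rep(c("wt", "m1", "m2"), each = 12),
                  y = c(rnorm(12, 10, 1), rnorm(12, 10, 6),
                        rnorm(12, 13, 6)))
  fit <- compare_groups(d, y, g, control = "wt",
                        route = "unequal_variance")
  ref <- stats::oneway.test(y ~ g, data = d, var.equal = FALSE)
  expect_equal(fit$p.value, ref$p.value)
  expect_equal(nrow(fit$posthoc), 2)
})

test_that("nonparametric p values are invariant to positive scaling and
           group relabeling permutes results identically", {
  set.seed(80)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 10),
                  y = rlnorm(30))
  f1 <- compare_groups(d, y, g, control = "a", route = "nonparametric")
  scaled <- dplyr::mutate(d, y = y * 7.3)
  f2 <- compare_groups(scaled, y, g, control = "a",
                       route = "nonparametric")
  expect_equal(f1$p.value, f2$p.value)
  expect_equal(f1$posthoc$p.value, f2$posthoc$p.value)
  shuffled <- d[sample(nrow(d)), ]
  f3 <- compare_groups(shuffled, y, g, control = "a",
                       route = "nonparametric")
  expect_equal(f1$p.value, f3$p.value)
  expect_equal(f1$posthoc[order(f1$posthoc$comparison), ],
               f3$posthoc[order(f3$posthoc$comparison), ])
})

test_that("comparison objects expose tidy, glance and autoplot", {
  set.seed(81)
  d <- data.frame(g = rep(c("wt", "mut"), each = 10),
                  y = c(rnorm(10, 5), rnorm(10, 9)))
  fit <- compare_groups(d, y, g, control = "wt")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("comparison", "estimate", "statistic", "p.value",
                     "stars"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$p.value, fit$p.value)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("comparisons validate their inputs", {
  d <- data.frame(g = rep("only", 5), y = rnorm(5))
  expect_error(compare_groups(d, y, g), "two groups")
  d2 <- data.frame(g = rep(c("a", "b"), each = 5), y = rnorm(10))
  expect_error(compare_groups(d2, y, g, control = "zz"), "control")
})
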