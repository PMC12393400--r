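#' Significance annotation for a p value
#'
#' The star convention used in the figures: `****` p < 0.0001, `***`
#' p < 0.001, `**` p < 0.01, `*` p < 0.05, `NS` otherwise.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Character vector of annotations.
#' @examples
#' significance_stars(c(0.03, 0.5, 9e-5))
#' @export
significance_stars <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  dplyr::case_when(
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "NS"
  )
}

#' Shapiro-Wilk normality gate
#'
#' Decides which test family a set of groups is routed to: every group is
#' tested with Shapiro-Wilk, and the routing is `"parametric"` only when
#' every group passes at `alpha` (the conservative all-pass reading);
#' otherwise `"nonparametric"`.
#'
#' @param data A data frame in long format.
#' @param value,group Columns holding the measurements and the group
#'   labels (tidy-eval).
#' @param alpha Gate level (default 0.05).
#' @return A list of class `normality_gate`: `route` and a `shapiro`
#'   tibble with per-group `n`, `W` and `p.value`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10), y = rnorm(20))
#' normality_gate(d, y, g)
#' @export
normality_gate <- function(data, value, group, alpha = 0.05) {
  df <- tibble::tibble(g = as.character(dplyr::pull(data, {{ group }})),
                       y = dplyr::pull(data, {{ value }}))
  if (any(!is.finite(df$y))) stop("values must be finite", call. = FALSE)
  split_y <- split(df$y, df$g)
  ns <- vapply(split_y, length, integer(1))
  if (any(ns < 3))
    stop("group(s) too small for normality testing (n < 3): ",
         paste(names(ns)[ns < 3], collapse = ", "), call. = FALSE)
  degenerate <- vapply(split_y, function(v) stats::sd(v) == 0, logical(1))
  if (any(degenerate))
    stop("group(s) with zero variance cannot be tested for normality: ",
         paste(names(degenerate)[degenerate], collapse = ", "),
         call. = FALSE)
  sw <- purrr::imap_dfr(split_y, function(v, nm) {
    fit <- stats::shapiro.test(v)
    tibble::tibble(group = nm, n = length(v),
                   W = unname(fit$statistic), p.value = fit$p.value)
  })
  structure(list(
    route = if (all(sw$p.value > alpha)) "parametric" else "nonparametric",
    shapiro = sw,
    alpha = alpha
  ), class = "normality_gate")
}

#' @export
print.normality_gate <- function(x, ...) {
  cat("<normality_gate> route:", x$route, "(alpha =", x$alpha, ")\n")
  print(x$shapiro)
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney test with mid-ranks for ties. For small samples
#' (`n1 + n2 <= exact_max`) the null distribution of U is obtained by full
#' enumeration of all group assignments, which remains exact under ties;
#' larger samples use the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined sample size enumerated exactly
#'   (default 12; `choose(12, 6) = 924` assignments).
#' @return A list with `statistic` (U for `x`), `p.value`, and `exact`
#'   (logical).
#' @examples
#' mann_whitney_exact(1:3, 4:6)  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, exact_max = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_from <- function(rank_sum) rank_sum - n1 * (n1 + 1) / 2
  u_obs <- u_from(sum(r[seq_len(n1)]))
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    idx <- utils::combn(N, n1)
    u_all <- u_from(colSums(matrix(r[idx], nrow = n1)))
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    list(statistic = u_obs, p.value = p, exact = TRUE)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    cc <- min(abs(u_obs - mu), 0.5)   # continuity correction
    z <- (abs(u_obs - mu) - cc) / sqrt(sigma2)
    list(statistic = u_obs, p.value = min(1, 2 * stats::pnorm(-z)),
         exact = FALSE)
  }
}

# Dunn's post-hoc z tests on mean ranks vs a control group, with tie
# correction and Holm adjustment across comparisons.
dunn_vs_control <- function(y, g, control, p_adjust = "holm") {
  r <- rank(y)
  N <- length(y)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- table(g)
  others <- setdiff(names(mean_ranks), control)
  z <- vapply(others, function(lvl) {
    (mean_ranks[[lvl]] - mean_ranks[[control]]) /
      sqrt((N * (N + 1) / 12 - tie_term) *
             (1 / ns[[lvl]] + 1 / ns[[control]]))
  }, numeric(1))
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  tibble::tibble(comparison = paste(others, "vs", control),
                 estimate = as.numeric(mean_ranks[others] -
                                         mean_ranks[[control]]),
                 statistic = as.numeric(z),
                 p.value = as.numeric(p))
}

#' Normality-gated group comparison
#'
#' Applies the routed comparison scheme used throughout the assays:
#' Shapiro-Wilk decides the family, then two groups are compared with
#' Student's t (parametric) or the exact Mann-Whitney test
#' (nonparametric), and three or more with one-way ANOVA plus Dunnett's
#' test against the control (parametric) or Kruskal-Wallis plus Dunn's
#' test with Holm adjustment (nonparametric). All tests are two-sided.
#' `route = "unequal_variance"` selects the heteroscedastic alternative
#' (Welch one-way ANOVA with pairwise Welch t tests vs control,
#' Holm-adjusted).
#'
#' @inheritParams normality_gate
#' @param control Label of the control group; required for post-hoc
#'   comparisons with three or more groups.
#' @param route `NULL` (decide via [normality_gate()]), or one of
#'   `"parametric"`, `"nonparametric"`, `"unequal_variance"` to override.
#' @param alpha Gate level passed to [normality_gate()].
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods, and [autoplot.group_comparison()].
#' @examples
#' d <- data.frame(g = rep(c("wt", "mut"), each = 10),
#'                 y = c(rnorm(10, 7), rnorm(10, 13)))
#' fit <- compare_groups(d, y, g, control = "wt")
#' glance(fit)
#' @export
compare_groups <- function(data, value, group, control = NULL,
                           route = NULL, alpha = 0.05) {
  df <- tibble::tibble(g = as.character(dplyr::pull(data, {{ group }})),
                       y = dplyr::pull(data, {{ value }}))
  levels_g <- unique(df$g)
  k <- length(levels_g)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (!is.null(control) && !control %in% levels_g)
    stop("control group '", control, "' not present", call. = FALSE)

  gate <- NULL
  if (is.null(route)) {
    gate <- normality_gate(df, .data$y, .data$g, alpha = alpha)
    route <- gate$route
  }
  route <- match.arg(route,
                     c("parametric", "nonparametric", "unequal_variance"))

  if (k == 2) {
    ref <- if (!is.null(control)) control else levels_g[1]
    other <- setdiff(levels_g, ref)
    x <- df$y[df$g == other]; yc <- df$y[df$g == ref]
    if (route == "parametric") {
      fit <- stats::t.test(x, yc, var.equal = TRUE)
      method <- "Student t"
      omnibus <- c(statistic = unname(fit$statistic), p = fit$p.value)
      post <- tibble::tibble(comparison = paste(other, "vs", ref),
                             estimate = mean(x) - mean(yc),
                             statistic = unname(fit$statistic),
                             p.value = fit$p.value)
    } else if (route == "unequal_variance") {
      fit <- stats::t.test(x, yc, var.equal = FALSE)
      method <- "Welch t"
      omnibus <- c(statistic = unname(fit$statistic), p = fit$p.value)
      post <- tibble::tibble(comparison = paste(other, "vs", ref),
                             estimate = mean(x) - mean(yc),
                             statistic = unname(fit$statistic),
                             p.value = fit$p.value)
    } else {
      fit <- mann_whitney_exact(x, yc)
      method <- if (fit$exact) "Mann-Whitney (exact)"
                else "Mann-Whitney (normal approx.)"
      omnibus <- c(statistic = fit$statistic, p = fit$p.value)
      post <- tibble::tibble(comparison = paste(other, "vs", ref),
                             estimate = stats::median(x) - stats::median(yc),
                             statistic = fit$statistic,
                             p.value = fit$p.value)
    }
  } else {
    if (route == "parametric") {
      dfa <- dplyr::mutate(df, g = stats::relevel(factor(.data$g),
                                                  ref = if (!is.null(control))
                                                    control else levels_g[1]))
      fit <- stats::aov(y ~ g, data = dfa)
      tab <- summary(fit)[[1]]
      method <- "one-way ANOVA + Dunnett"
      omnibus <- c(statistic = tab$`F value`[1], p = tab$`Pr(>F)`[1])
      post <- NULL
      if (!is.null(control)) {
        glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
        s <- summary(glht_fit)
        post <- tibble::tibble(
          comparison = sub(" - ", " vs ", names(s$test$coefficients)),
          estimate = as.numeric(s$test$coefficients),
          statistic = as.numeric(s$test$tstat),
          p.value = as.numeric(s$test$pvalues)
        )
      }
    } else if (route == "unequal_variance") {
      fit <- stats::oneway.test(y ~ g, data = df, var.equal = FALSE)
      method <- "Welch ANOVA + pairwise Welch t (Holm)"
      omnibus <- c(statistic = unname(fit$statistic), p = fit$p.value)
      post <- NULL
      if (!is.null(control)) {
        others <- setdiff(levels_g, control)
        yc <- df$y[df$g == control]
        post <- purrr::map_dfr(others, function(lvl) {
          tt <- stats::t.test(df$y[df$g == lvl], yc, var.equal = FALSE)
          tibble::tibble(comparison = paste(lvl, "vs", control),
                         estimate = mean(df$y[df$g == lvl]) - mean(yc),
                         statistic = unname(tt$statistic),
                         p.value = tt$p.value)
        })
        post$p.value <- stats::p.adjust(post$p.value, method = "holm")
      }
    } else {
      fit <- stats::kruskal.test(df$y, factor(df$g))
      method <- "Kruskal-Wallis + Dunn (Holm)"
      omnibus <- c(statistic = unname(fit$statistic), p = fit$p.value)
      post <- if (!is.null(control))
        dunn_vs_control(df$y, df$g, control) else NULL
    }
  }
  if (!is.null(post)) post$stars <- significance_stars(post$p.value)
  structure(list(
    route = route, method = method,
    statistic = unname(omnibus["statistic"]),
    p.value = unname(omnibus["p"]),
    posthoc = post, gate = gate, control = control,
    data = df, n_groups = k
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> route:", x$route, "|", x$method, "\n")
  cat(sprintf("  omnibus: statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p.value, significance_stars(x$p.value)))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return `tidy()` returns the post-hoc table (one row per comparison
#'   against the control, with Holm- or Dunnett-adjusted p values and
#'   star annotations); `glance()` returns a one-row omnibus summary.
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    return(tibble::tibble(comparison = character(), estimate = numeric(),
                          statistic = numeric(), p.value = numeric(),
                          stars = character()))
  }
  x$posthoc
}

#' @rdname tidy.group_comparison
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(route = x$route, method = x$method,
                 n_groups = x$n_groups, statistic = x$statistic,
                 p.value = x$p.value,
                 stars = significance_stars(x$p.value))
}

#' Plot a group comparison
#'
#' Renders the figure style used for the assays: one jittered point per
#' animal, overlaid with the group mean and a mean +/- SD bar.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  summ <- dplyr::summarise(dplyr::group_by(object$data, .data$g),
                           m = mean(.data$y), s = stats::sd(.data$y),
                           .groups = "drop")
  ggplot2::ggplot(object$data, ggplot2::aes(.data$g, .data$y)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(.data$g, .data$m, ymin = .data$m - .data$s,
                   ymax = .data$m + .data$s),
      inherit.aes = FALSE, shape = 95, size = 1, linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = "value",
                  subtitle = paste0(object$method, ": p = ",
                                    signif(object$p.value, 3), " (",
                                    significance_stars(object$p.value),
                                    ")")) +
    ggplot2::theme_classic()
}
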