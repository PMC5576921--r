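# --- Dunnett's T3 ----------------------------------------------------------

# CDF of the studentized maximum modulus with m variates and df nu:
# P(max_i |T_i| <= q) for independent t-variates.
psmm <- function(q, m, df) (2 * stats::pt(q, df) - 1)^m

qsmm <- function(p, m, df) {
  stats::uniroot(function(q) psmm(q, m, df) - p,
                 lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

#' Dunnett's T3 all-pairs comparison
#'
#' Pairwise comparisons after a significant ANOVA when group variances are
#' unequal: for each pair, a Welch-type t statistic with Satterthwaite
#' degrees of freedom, referred to the studentized maximum modulus (SMM)
#' distribution with as many variates as there are pairs. Designed for
#' small, unbalanced samples with heterogeneous variances.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 3 levels).
#' @param conf_level Confidence level for the adjusted intervals
#'   (default 0.95).
#' @return Tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `se`, `df`, `statistic`, `p_adj` (SMM-adjusted),
#'   `conf_low`, `conf_high`.
#' @export
dunnett_t3 <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 3) stop("Dunnett's T3 needs >= 3 groups", call. = FALSE)
  st <- vapply(lev, function(g) {
    x <- values[groups == g]
    c(n = length(x), m = mean(x), v = stats::var(x))
  }, numeric(3))
  if (any(st["n", ] < 2)) stop("every group needs n >= 2", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(i) {
    g1 <- pairs[1, i]
    g2 <- pairs[2, i]
    v1 <- st["v", g1] / st["n", g1]
    v2 <- st["v", g2] / st["n", g2]
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
      (v1^2 / (st["n", g1] - 1) + v2^2 / (st["n", g2] - 1))
    est <- st["m", g1] - st["m", g2]
    stat <- abs(est) / se
    crit <- qsmm(conf_level, m, df)
    tibble::tibble(
      group1 = g1, group2 = g2, estimate = est, se = se, df = df,
      statistic = stat,
      p_adj = 1 - psmm(stat, m, df),
      conf_low = est - crit * se, conf_high = est + crit * se
    )
  })
  dplyr::bind_rows(out)
}

# --- post-hoc selection ----------------------------------------------------

#' Choose and run the post-hoc test after ANOVA
#'
#' Variance homogeneity is assessed by Levene's test (median-centered) at
#' alpha = 0.05: equal variances lead to a Tukey HSD on the fitted ANOVA,
#' unequal variances to Dunnett's T3.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 3 levels).
#' @param alpha Homogeneity-gate level (default 0.05).
#' @return List with `method` (`"tukey_hsd"` or `"dunnett_t3"`),
#'   `levene_p`, and `pairwise` (tibble: `group1`, `group2`, `estimate`,
#'   `p_adj`, `conf_low`, `conf_high`).
#' @export
choose_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("post-hoc selection needs >= 3 groups",
                                call. = FALSE)
  lev_p <- car::leveneTest(values ~ groups, center = stats::median)[1, "Pr(>F)"]
  if (lev_p >= alpha) {
    fit <- stats::aov(values ~ groups)
    tk <- stats::TukeyHSD(fit)$groups
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- tibble::tibble(
      group1 = vapply(cmp, `[`, "", 1),
      group2 = vapply(cmp, `[`, "", 2),
      estimate = tk[, "diff"],
      p_adj = tk[, "p adj"],
      conf_low = tk[, "lwr"], conf_high = tk[, "upr"]
    )
    list(method = "tukey_hsd", levene_p = lev_p, pairwise = pairwise)
  } else {
    pw <- dunnett_t3(values, groups)
    list(method = "dunnett_t3", levene_p = lev_p,
         pairwise = pw[, c("group1", "group2", "estimate", "p_adj",
                           "conf_low", "conf_high")])
  }
}

# --- experiment-wise pooling -----------------------------------------------

#' Experiment-wise pooling with paired t-test
#'
#' Some measurements vary between independent experiments (batches) more
#' than within them; pooling unit-level datapoints across such experiments
#' would pseudo-replicate. The rule applied: within each group, one-way
#' ANOVA of value against experiment; if any group shows significant
#' (p < 0.05) experiment-to-experiment differences, values are averaged
#' within each (group, experiment) cell and the two groups are compared by
#' a two-tailed paired t-test, paired on experiment. Otherwise unit-level
#' analysis proceeds and the decision trail records that pooling did not
#' fire. Experiments present in only one group cannot be paired and are
#' dropped with a warning.
#'
#' @param data Data frame with the measurement table.
#' @param value,group,experiment Column names (strings).
#' @param alpha Heterogeneity-gate level (default 0.05).
#' @return List: `pooled` (logical), `heterogeneity_p` (per group),
#'   `pooled_table` (tibble of experiment means, when pooled), `test`
#'   (htest or `NULL`), `degenerate` (logical: zero-variance differences),
#'   `trail` (character).
#' @export
experimentwise_pool <- function(data, value = "value", group = "group",
                                experiment = "experiment_id", alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  e <- factor(data[[experiment]])
  if (nlevels(g) != 2) stop("pooling compares exactly 2 groups", call. = FALSE)
  shared <- Reduce(intersect, lapply(levels(g), function(gi) {
    unique(as.character(e[g == gi]))
  }))
  if (length(shared) < 3) {
    stop("need >= 3 experiments shared by both groups", call. = FALSE)
  }
  dropped <- setdiff(unique(as.character(e)), shared)
  if (length(dropped)) {
    warning("dropping unpaired experiment(s): ",
            paste(dropped, collapse = ", "))
    keep <- as.character(e) %in% shared
    v <- v[keep]; g <- droplevels(g[keep]); e <- droplevels(e[keep])
  }
  trail <- character()
  het_p <- vapply(levels(g), function(gi) {
    sel <- g == gi
    if (length(unique(e[sel])) < 2) return(1)
    stats::anova(stats::lm(v[sel] ~ factor(e[sel])))[1, "Pr(>F)"]
  }, numeric(1))
  fire <- any(het_p < alpha, na.rm = TRUE)
  trail <- c(trail, sprintf(
    "experiment heterogeneity ANOVA p = {%s}; pooling %s",
    paste(sprintf("%s: %.4g", levels(g), het_p), collapse = ", "),
    if (fire) "fires" else "does not fire"
  ))
  if (!fire) {
    return(list(pooled = FALSE, heterogeneity_p = het_p, pooled_table = NULL,
                test = NULL, degenerate = FALSE, trail = trail))
  }
  tb <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(v = v, g = g, e = e), .data$g, .data$e),
    mean_value = mean(.data$v), .groups = "drop"
  )
  wide <- split(tb, tb$g)
  m1 <- wide[[1]][order(wide[[1]]$e), ]
  m2 <- wide[[2]][order(wide[[2]]$e), ]
  d <- m1$mean_value - m2$mean_value
  degenerate <- stats::sd(d) < 1e-12
  if (degenerate) {
    trail <- c(trail, "paired differences have zero variance; t-test not defined")
    test <- NULL
  } else {
    test <- stats::t.test(m1$mean_value, m2$mean_value, paired = TRUE)
    trail <- c(trail, sprintf("paired t-test on %d experiment means: p = %.4g",
                              length(d), test$p.value))
  }
  list(pooled = TRUE, heterogeneity_p = het_p, pooled_table = tb,
       test = test, degenerate = degenerate, trail = trail)
}

# --- decision tree ---------------------------------------------------------

#' Run the group-comparison decision tree
#'
#' Implements the test-selection rules used throughout the study:
#' datapoints that are means of raw measurements are treated as normally
#' distributed and compared by a two-tailed Student's t-test (2 groups) or
#' one-way ANOVA with post-hoc selection via [choose_posthoc()] (3+
#' groups); data declared non-normal (counts, proportions, skewed
#' unit-level values) are compared by a two-tailed Mann-Whitney U test.
#' The distribution class is declared a priori through `dist_class`, not
#' decided by an automated normality test. When an experiment column is
#' supplied for a 2-group normal comparison, the experiment-wise pooling
#' rule ([experimentwise_pool()]) is checked first and, if it fires, the
#' comparison becomes a paired t-test on experiment means.
#'
#' Every branch taken is recorded in the `decision_trail`.
#'
#' @param data Data frame (one row per measurement unit).
#' @param value,group Column names (strings).
#' @param dist_class `"normal"` (means of raw measurements) or
#'   `"nonnormal"`.
#' @param experiment Optional experiment-id column name; enables the
#'   pooling check for 2-group normal comparisons.
#' @return Object of class `er_comparison`: list with `test`, `statistic`,
#'   `p_value`, `groups`, `pooling`, `posthoc` (tibble or `NULL`),
#'   `decision_trail`, `data`. Has [tidy()] and [glance()] methods.
#' @examples
#' df <- data.frame(value = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6),
#'                  group = rep(c("a", "b"), each = 5))
#' res <- compare_groups(df, dist_class = "normal")
#' res$p_value
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           dist_class = c("normal", "nonnormal"),
                           experiment = NULL) {
  dist_class <- match.arg(dist_class)
  v <- data[[value]]
  g <- factor(data[[group]])
  if (any(is.na(v)) || any(is.na(g))) stop("missing values or group labels",
                                           call. = FALSE)
  ns <- table(g)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(ns < 2)) {
    stop("insufficient data: group(s) with n < 2: ",
         paste(names(ns)[ns < 2], collapse = ", "), call. = FALSE)
  }
  trail <- sprintf("%d groups; distribution class '%s'",
                   nlevels(g), dist_class)
  posthoc <- NULL
  pooling <- "unit"
  if (nlevels(g) == 2) {
    if (dist_class == "normal") {
      if (!is.null(experiment)) {
        pool <- experimentwise_pool(data, value, group, experiment)
        trail <- c(trail, pool$trail)
        if (pool$pooled) {
          if (pool$degenerate) {
            stop("paired experiment means have zero-variance differences; ",
                 "paired t-test undefined", call. = FALSE)
          }
          ht <- pool$test
          return(new_er_comparison(
            test = "paired t-test (experiment means)",
            statistic = unname(ht$statistic), p_value = ht$p.value,
            groups = levels(g), pooling = "experiment",
            posthoc = NULL,
            trail = c(trail, "branch: experiment-wise pooled paired t-test"),
            data = data
          ))
        }
      }
      trail <- c(trail, "branch: two-tailed Student's t-test")
      ht <- stats::t.test(v ~ g, var.equal = TRUE)
      test <- "Student's t-test"
    } else {
      trail <- c(trail, "branch: two-tailed Mann-Whitney U test")
      ht <- suppressWarnings(stats::wilcox.test(v ~ g, correct = TRUE))
      test <- "Mann-Whitney U"
    }
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    trail <- c(trail, "branch: one-way ANOVA omnibus")
    fit <- stats::aov(v ~ g)
    an <- summary(fit)[[1]]
    stat <- an[1, "F value"]
    p <- an[1, "Pr(>F)"]
    ph <- choose_posthoc(v, g)
    trail <- c(trail, sprintf(
      "Levene (median-centered) p = %.4g => post-hoc: %s",
      ph$levene_p, ph$method
    ))
    posthoc <- ph$pairwise
    test <- sprintf("one-way ANOVA + %s", ph$method)
  }
  new_er_comparison(test = test, statistic = stat, p_value = p,
                    groups = levels(g), pooling = pooling, posthoc = posthoc,
                    trail = trail, data = data)
}

new_er_comparison <- function(test, statistic, p_value, groups, pooling,
                              posthoc, trail, data) {
  structure(
    list(test = test, statistic = statistic, p_value = p_value,
         groups = groups, pooling = pooling, posthoc = posthoc,
         decision_trail = trail, data = data),
    class = "er_comparison"
  )
}

#' @export
print.er_comparison <- function(x, ...) {
  cat(sprintf("<er_comparison> %s | groups: %s | p = %.4g\n",
              x$test, paste(x$groups, collapse = ", "), x$p_value))
  cat("decision trail:\n")
  for (s in x$decision_trail) cat("  - ", s, "\n", sep = "")
  if (!is.null(x$posthoc)) {
    cat("post-hoc pairwise comparisons:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x An `er_comparison`.
#' @param ... Unused.
#' @export
tidy.er_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) {
    dplyr::mutate(x$posthoc, test = x$test, .before = 1)
  } else {
    tibble::tibble(test = x$test, group1 = x$groups[1], group2 = x$groups[2],
                   statistic = x$statistic, p_value = x$p_value)
  }
}

#' @rdname compare_groups
#' @export
glance.er_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p_value = x$p_value, n_groups = length(x$groups),
                 pooling = x$pooling,
                 posthoc = !is.null(x$posthoc))
}

# --- two-way ANOVA ---------------------------------------------------------

#' Two-way ANOVA with type-II sums of squares
#'
#' Main effects and interaction for a two-factor design (e.g. genotype by
#' glial class for ER sheet profile length), using type-II sums of squares,
#' which are appropriate for the mildly unbalanced cell counts typical of
#' such data.
#'
#' @param data Data frame.
#' @param value Response column name.
#' @param factor1,factor2 Factor column names.
#' @return Tibble with `term` (`factor1`, `factor2`, `interaction`),
#'   `sumsq`, `df`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, value = "value", factor1 = "genotype",
                          factor2 = "class") {
  v <- data[[value]]
  f1 <- factor(data[[factor1]])
  f2 <- factor(data[[factor2]])
  if (nlevels(f1) < 2 || nlevels(f2) < 2) {
    stop("both factors need >= 2 levels", call. = FALSE)
  }
  cells <- table(f1, f2)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s = '%s', %s = '%s'",
                 factor1, rownames(cells)[bad[1]],
                 factor2, colnames(cells)[bad[2]]), call. = FALSE)
  }
  if (stats::var(v) < 1e-24) {
    stop("degenerate data: response has zero variance, F undefined",
         call. = FALSE)
  }
  fit <- stats::lm(v ~ f1 * f2)
  an <- car::Anova(fit, type = 2)
  tibble::tibble(
    term = c(factor1, factor2, "interaction"),
    sumsq = an[1:3, "Sum Sq"],
    df = an[1:3, "Df"],
    statistic = an[1:3, "F value"],
    p_value = an[1:3, "Pr(>F)"]
  )
}
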