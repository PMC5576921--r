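test_that("two-group branches match hand-computed references", {
  # identical groups: t statistic 0, p = 1
  df0 <- data.frame(value = rep(c(1, 2, 3), 2),
                    group = rep(c("a", "b"), each = 3))
  r0 <- compare_groups(df0, dist_class = "normal")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # fixed fixture against the pooled-variance t formula computed longhand
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  df <- data.frame(value = c(x, y), group = rep(c("a", "b"), each = 5))
  r <- compare_groups(df, dist_class = "normal")
  sp2 <- (4 * var(x) + 4 * var(y)) / 8
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_hand <- 2 * pt(abs(t_hand), df = 8, lower.tail = FALSE)
  expect_equal(abs(r$statistic), abs(t_hand), tolerance = 1e-10)
  expect_equal(r$p_value, p_hand, tolerance = 1e-6)
  expect_null(r$posthoc)
  expect_true(any(grepl("Student", r$decision_trail)))
  # insufficient data is refused
  expect_error(compare_groups(data.frame(value = c(1, 2, 3),
                                         group = c("a", "a", "b")),
                              dist_class = "normal"), "insufficient")
})

test_that("Mann-Whitney branch matches exhaustive permutation for small n", {
  set.seed(42)
  for (i in 1:8) {
    nx <- sample(4:8, 1); ny <- sample(4:8, 1)
    x <- round(runif(nx, 0, 100), 3)
    y <- round(runif(ny, 0, 100) + 10, 3)
    df <- data.frame(value = c(x, y),
                     group = rep(c("a", "b"), c(nx, ny)))
    r <- compare_groups(df, dist_class = "nonnormal")
    expect_equal(r$p_value, oracle_mw_perm_p(x, y), tolerance = 1e-10)
  }
})

test_that("three or more groups trigger the ANOVA + post-hoc branch", {
  set.seed(7)
  df <- data.frame(value = rnorm(45), group = rep(letters[1:3], each = 15))
  r <- compare_groups(df, dist_class = "normal")
  expect_false(is.null(r$posthoc))
  expect_equal(nrow(r$posthoc), 3) # all pairs of 3 groups
  # omnibus F matches a direct aov
  an <- summary(aov(value ~ factor(group), df))[[1]]
  expect_equal(r$statistic, an[1, "F value"], tolerance = 1e-10)
  expect_equal(r$p_value, an[1, "Pr(>F)"], tolerance = 1e-6)
  # decision trail pins down every branch taken
  expect_true(any(grepl("ANOVA omnibus", r$decision_trail)))
  expect_true(any(grepl("Levene", r$decision_trail)))
})

test_that("post-hoc selection follows the variance-homogeneity gate", {
  set.seed(10)
  eq <- data.frame(value = rnorm(60), group = rep(letters[1:3], each = 20))
  ph_eq <- choose_posthoc(eq$value, eq$group)
  expect_equal(ph_eq$method, "tukey_hsd")
  # grossly unequal variances select Dunnett's T3 in nearly all runs
  t3_hits <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    v <- c(rnorm(20, sd = 1), rnorm(20, sd = 1), rnorm(20, sd = 5))
    choose_posthoc(v, rep(letters[1:3], each = 20))$method == "dunnett_t3"
  }, logical(1))
  expect_gte(mean(t3_hits), 0.95)
  # Tukey p-values agree with stats::TukeyHSD directly
  tk <- TukeyHSD(aov(value ~ factor(group), eq))$`factor(group)`
  expect_equal(sort(ph_eq$pairwise$p_adj), sort(unname(tk[, "p adj"])),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Dunnett T3 uses valid SMM tail probabilities", {
  # Monte-Carlo check of the studentized-maximum-modulus distribution:
  # max |t| over m independent t-variates with df nu
  m <- 3; nu <- 12
  set.seed(99)
  mx <- replicate(40000, max(abs(rt(m, nu))))
  for (q in c(1.5, 2.5, 3.5)) {
    expect_equal(mean(mx <= q), (2 * pt(q, nu) - 1)^m, tolerance = 0.01)
  }
  # T3 on a fixed fixture: statistics equal the Welch t computed longhand
  v <- c(10.1, 11.3, 9.8, 10.9, 12.0,
         14.2, 15.1, 13.8, 16.0, 15.5,
         9.0, 19.5, 12.2, 17.8, 14.4)
  g <- rep(c("a", "b", "c"), each = 5)
  t3 <- dunnett_t3(v, g)
  x <- v[g == "a"]; y <- v[g == "b"]
  se <- sqrt(var(x) / 5 + var(y) / 5)
  t_ab <- abs(mean(x) - mean(y)) / se
  df_ab <- se^4 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  row <- t3[t3$group1 == "a" & t3$group2 == "b", ]
  expect_equal(row$statistic, t_ab, tolerance = 1e-10)
  expect_equal(row$df, df_ab, tolerance = 1e-10)
  expect_equal(row$p_adj, 1 - (2 * pt(t_ab, df_ab) - 1)^3,
               tolerance = 1e-12)
  expect_true(all(t3$p_adj >= 0 & t3$p_adj <= 1))
  # T3 adjusted p is never smaller than the unadjusted Welch p
  p_welch <- 2 * pt(t_ab, df_ab, lower.tail = FALSE)
  expect_gte(row$p_adj, p_welch - 1e-12)
})

test_that("experiment-wise pooling fires only on real batch structure", {
  mk <- function(batch_sd) {
    set.seed(55)
    g <- rep(c("wt", "mut"), each = 30)
    e <- rep(rep(paste0("exp", 1:3), each = 10), 2)
    batch <- rnorm(3, 0, batch_sd)[as.integer(factor(e))]
    data.frame(value = rnorm(60, ifelse(g == "mut", 1, 0), 0.5) + batch,
               group = g, experiment_id = e)
  }
  strong <- experimentwise_pool(mk(5))
  expect_true(strong$pooled)
  expect_false(is.null(strong$test))
  # the paired t on experiment means matches a hand-computed paired t
  tb <- strong$pooled_table
  m_wt <- tb$mean_value[tb$g == "wt"][order(tb$e[tb$g == "wt"])]
  m_mut <- tb$mean_value[tb$g == "mut"][order(tb$e[tb$g == "mut"])]
  d <- m_mut - m_wt
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(abs(unname(strong$test$statistic)), abs(t_hand),
               tolerance = 1e-10)
  none <- experimentwise_pool(mk(0))
  expect_false(none$pooled)
  expect_true(any(grepl("does not fire", none$trail)))
  # zero-variance paired differences are flagged, not reported as p = 0:
  # experiment means differ wildly within each group (pooling fires) but
  # the group difference is exactly 0.2 in every experiment
  base <- rep(c(0, 10, 20), each = 2) + c(-0.01, 0.01)
  df_deg <- data.frame(
    value = c(base, base + 0.2),
    group = rep(c("a", "b"), each = 6),
    experiment_id = rep(rep(paste0("e", 1:3), each = 2), 2)
  )
  res_deg <- experimentwise_pool(df_deg)
  expect_true(res_deg$pooled)
  expect_true(res_deg$degenerate)
  expect_null(res_deg$test)
  # unpaired experiments are dropped with a warning
  df_unp <- mk(5)
  df_unp <- rbind(df_unp,
                  data.frame(value = rnorm(5), group = "wt",
                             experiment_id = "exp9"))
  expect_warning(experimentwise_pool(df_unp), "unpaired")
})

test_that("two-way ANOVA reports type-II effects and rejects bad designs", {
  set.seed(12)
  df <- data.frame(
    value = rnorm(48),
    genotype = rep(c("wt", "mut"), each = 24),
    class = rep(rep(c("peri", "sub", "wrap"), each = 8), 2)
  )
  df$value <- df$value + ifelse(df$genotype == "mut", 2, 0)
  tw <- two_way_anova(df)
  expect_lt(tw$p_value[tw$term == "genotype"], 0.001)
  expect_gt(tw$p_value[tw$term == "class"], 0.05)
  # balanced design: type II equals the sequential ANOVA
  an <- anova(lm(value ~ factor(genotype) * factor(class), df))
  expect_equal(tw$p_value, an[1:3, "Pr(>F)"], tolerance = 1e-10)
  # contract failures
  expect_error(two_way_anova(df[df$class != "wrap" | df$genotype != "mut", ]),
               "empty design cell")
  df_const <- df; df_const$value <- 1
  expect_error(two_way_anova(df_const), "zero variance")
})

test_that("decision trail determines the analysis and tidies cleanly", {
  set.seed(20)
  df <- data.frame(value = rnorm(30), group = rep(c("a", "b"), each = 15))
  r1 <- compare_groups(df, dist_class = "normal")
  r2 <- compare_groups(df, dist_class = "normal")
  expect_identical(r1$decision_trail, r2$decision_trail)
  expect_identical(r1$p_value, r2$p_value)
  td <- tidy(r1)
  expect_equal(td$p_value, r1$p_value)
  gl <- glance(r1)
  expect_false(gl$posthoc)
  expect_equal(gl$n_groups, 2)
})
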