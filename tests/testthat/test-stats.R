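test_that("paired t matches the closed form on a constructed 25-mouse sample", {
  set.seed(8)
  a <- rnorm(25, 0.3, 0.1)
  b <- rnorm(25, 0.2, 0.1)
  d <- data.frame(va = a, vb = b)
  res <- paired_arm_comparisons(d, list(pos_vs_neg = c("va", "vb")))
  dd <- a - b
  t_hand <- mean(dd) / (sd(dd) / sqrt(25))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_identical(res$df, 24L)          # matches the reported t(24) df pattern
  # and stats::t.test as an independent route
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("Bonferroni adjustment and degenerate paired inputs behave", {
  set.seed(3)
  d <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10, 1))
  res <- paired_arm_comparisons(d, list(ab = c("a", "b"), ac = c("a", "c"),
                                        bc = c("b", "c")))
  expect_true(all(res$p_adj >= res$p))
  expect_equal(res$p_adj, pmin(1, res$p * 3), tolerance = 1e-12)
  # significance decisions invariant to contrast ordering
  res_rev <- paired_arm_comparisons(d, list(bc = c("b", "c"), ac = c("a", "c"),
                                            ab = c("a", "b")))
  expect_identical(res$significant[match(res_rev$contrast, res$contrast)],
                   res_rev$significant)
  # identical vectors: t = 0, p = 1
  d2 <- data.frame(a = 1:5 / 10, b = 1:5 / 10)
  r2 <- paired_arm_comparisons(d2, list(same = c("a", "b")))
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  expect_error(paired_arm_comparisons(data.frame(a = 1, b = 2),
                                      list(x = c("a", "b"))), "fewer than 2")
})

test_that("Kruskal-Wallis matches stats::kruskal.test and a permutation null", {
  # fully separated ranks, group sizes 13/4/3
  x <- c(1:13, 20 + 1:4, 40 + 1:3) / 10
  g <- rep(c("BAR", "TWIRL", "FLIP"), c(13, 4, 3))
  got <- stereotypy_form_test(x, g)
  ref <- kruskal.test(x, factor(g))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_identical(got$df, 2L)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)

  # ties handled identically
  set.seed(21)
  xt <- sample(round(runif(20, 0, 0.3), 1))
  gt <- sample(rep(c("A", "B", "C"), c(8, 7, 5)))
  got_t <- stereotypy_form_test(xt, gt)
  ref_t <- kruskal.test(xt, factor(gt))
  expect_equal(got_t$statistic, unname(ref_t$statistic), tolerance = 1e-12)

  # all values equal: statistic 0 by convention
  expect_equal(stereotypy_form_test(rep(0.1, 9), rep(c("A", "B", "C"), 3)
                                    )$statistic, 0)
  expect_error(stereotypy_form_test(1:5, rep("A", 5)), "two groups")

  # permutation null agrees with the chi-square p at n ~ 20
  set.seed(22)
  xp <- rnorm(20)
  gp <- rep(c("A", "B", "C"), c(9, 6, 5))
  obs <- stereotypy_form_test(xp, gp)$statistic
  perm <- replicate(1000, stereotypy_form_test(xp, sample(gp))$statistic)
  p_perm <- mean(perm >= obs - 1e-12)
  p_chisq <- stereotypy_form_test(xp, gp)$p
  expect_lt(abs(p_perm - p_chisq), 3 * sqrt(p_chisq * (1 - p_chisq) / 1000) + 0.02)
})

test_that("the mixed model reduces to OLS when group variances vanish", {
  d <- simulate_score_cohort(24, litter_sd = 0, cage_sd = 0,
                             stereotypy_effect = 0.5, seed = 31)
  f <- suppressWarnings(fit_mixed_model(d, model_spec("outcome")))
  # both grouping factors show no evidence of variance and are excluded
  expect_false(f$reml)
  expect_setequal(f$dropped, c("litter", "cage"))
  old <- options(contrasts = c("contr.sum", "contr.poly")); on.exit(options(old))
  d$sqrt_lvl <- sqrt(d$stereotypy_level)
  ols <- lm(outcome ~ factor(handling) + sqrt_lvl, data = d)
  expect_equal(f$table$estimate, unname(coef(ols)[-1]), tolerance = 1e-9)
  expect_equal(f$table$df2, rep(df.residual(ols), 2))
})

test_that("degenerate grouping factors are dropped with a warning", {
  d <- simulate_score_cohort(24, seed = 5)
  d$litter <- "L1"
  expect_warning(f <- fit_mixed_model(d, model_spec("outcome")),
                 "litter.*dropped")
  expect_true("litter" %in% f$dropped)
  d2 <- d; d2$cage <- d2$mouse_id  # one observation per cage level
  w <- capture_warnings(f2 <- fit_mixed_model(d2, model_spec("outcome")))
  expect_true(any(grepl("litter", w)) && any(grepl("cage", w)))
  expect_false(f2$reml)  # fell back to OLS
  # constant outcome warns rather than failing silently
  d3 <- d; d3$outcome <- 1
  w3 <- capture_warnings(fit_mixed_model(d3, model_spec("outcome")))
  expect_true(any(grepl("constant", w3)))
})

test_that("Satterthwaite df reproduces the paired-design closed form", {
  set.seed(5)
  nc <- 12
  cage <- rep(sprintf("C%02d", 1:nc), each = 2)
  treat <- rep(c("A", "B"), nc)
  y <- rnorm(nc, 0, 2)[rep(1:nc, each = 2)] + 0.5 * (treat == "B") +
    rnorm(2 * nc, 0, 1)
  d <- data.frame(cage = cage, handling = treat, outcome = y)
  f <- fit_mixed_model(d, model_spec("outcome", covariate = NULL,
                                     random = "cage"))
  dd <- y[treat == "B"] - y[treat == "A"]
  tt <- t.test(dd)
  # within-cage treatment with a cage random intercept is the paired t-test
  expect_equal(f$table$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(f$table$df2, nc - 1, tolerance = 1e-3)
  expect_identical(f$table$df_method, "satterthwaite")
})

test_that("the sqrt transform is applied exactly once", {
  expect_error(model_spec("y", covariate = "sqrt_stereotypy_level"),
               "already transformed")
  d <- simulate_score_cohort(24, seed = 9)
  f <- suppressWarnings(fit_mixed_model(d, model_spec("outcome")))
  expect_true("sqrt_stereotypy_level" %in% f$table$term)
})

test_that("type-I error for a null handling effect is near nominal (reduced run)", {
  # null world per the study's finding: litter and cage explain nothing
  n_rep <- 200
  rej <- vapply(seq_len(n_rep), function(i) {
    d <- simulate_score_cohort(24, handling_effect = 0,
                               litter_sd = 0, cage_sd = 0, seed = 40000 + i)
    f <- suppressWarnings(fit_mixed_model(d, model_spec("outcome")))
    f$table$p[f$table$term == "handling1"] < 0.05
  }, logical(1))
  # binomial 99% envelope around 0.05 at 200 replicates
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("a planted handling effect is recovered within its CI most of the time", {
  n_rep <- 60
  eff <- 1  # 1 residual SD
  hit <- vapply(seq_len(n_rep), function(i) {
    d <- simulate_score_cohort(24, handling_effect = eff, seed = 61000 + i)
    f <- suppressWarnings(fit_mixed_model(d, model_spec("outcome")))
    row <- f$table[f$table$term == "handling1", ]
    # contr.sum: handling1 is the CUPPED deviation from the grand mean,
    # so a TAIL effect of +eff makes the true coefficient -eff/2
    truth <- -eff / 2
    ci <- row$estimate + c(-1, 1) * qt(0.975, row$df2) * row$se
    ci[1] <= truth && truth <= ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
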