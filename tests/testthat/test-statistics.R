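test_that("the additive ANOVA has the balanced-design bookkeeping", {
  tab <- random_results_table(18, seed = 1)
  a <- fit_additive_anova(tab)
  expect_equal(a$df[a$term == "Residuals"], 48)
  expect_equal(a$df[a$term == "Individual"], 17)
  expect_equal(a$df[a$term == "Test"], 3)
  expect_equal(sum(a$df), 72 - 1)
  expect_equal(a$mean_sq, a$sum_sq / a$df)
  expect_true(all(a$sum_sq >= 0))
})

test_that("sequential SS match explicit design-matrix projections", {
  withr::with_seed(42, seeds <- sample.int(1e6, 50))
  for (s in seeds) {
    n_subj <- 5 + (s %% 2) # small tables, n <= 24
    tab <- random_results_table(n_subj, seed = s)
    a <- fit_additive_anova(tab)
    oracle <- oracle_sequential_ss(validate_results_table(tab))
    got <- a$sum_sq
    names(got) <- c("test", "order", "individual", "residuals")
    expect_equal(got, oracle, tolerance = 1e-9)
    # decomposition conserves the total (centered) sum of squares
    tot <- sum((tab$d_l2 - mean(tab$d_l2))^2)
    expect_equal(sum(a$sum_sq), tot, tolerance = 1e-9)
  }
})

test_that("degenerate tables are rejected with informative errors", {
  tab <- random_results_table(6, seed = 2)
  miss <- tab[-5, ]
  expect_error(fit_additive_anova(miss), "subject 2")
  # 2 subjects x 4 tests: residual df = 7 - 3 - 3 - 1 = 0
  expect_error(fit_additive_anova(random_results_table(2, seed = 3)),
               "saturated")
  # order confounded with test
  conf <- random_results_table(6, seed = 4)
  conf$order <- match(conf$test, c("A", "B", "C", "D"))
  expect_error(fit_additive_anova(conf), "confounded|rank")
})

test_that("null cohorts give uniform test-factor p-values", {
  p <- vapply(1:300, function(s) {
    a <- fit_additive_anova(simulate_null_results_table(18, seed = s))
    a$p_value[a$term == "Test"]
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("Duncan's test handles identical and well-separated groups", {
  tab <- random_results_table(10, seed = 9)
  # four identical group means (residual noise intact): all pairwise p = 1
  flat <- tab
  flat$d_l2 <- flat$d_l2 - stats::ave(flat$d_l2, flat$test) + 3
  a <- fit_additive_anova(flat)
  d <- duncan_mrt(flat, a)
  expect_true(all(d$p_matrix[lower.tri(d$p_matrix)] == 1))
  # widening a mean difference at fixed residual MS lowers the p-value
  sep <- function(delta) {
    t2 <- tab
    t2$d_l2 <- t2$d_l2 + ifelse(t2$test == "C", -delta, 0)
    a2 <- fit_additive_anova(t2)
    # hold the residual scale fixed by reusing the base ANOVA attributes
    duncan_mrt(t2, a, alpha = 0.05)$p_matrix["C", "A"]
  }
  ps <- vapply(c(0, 0.5, 1, 2), sep, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("with two groups Duncan reduces to the pooled t-test", {
  withr::with_seed(31, {
    tab <- do.call(rbind, lapply(1:10, function(s)
      data.frame(subject_id = s, test = c("A", "B"), order = sample(2),
                 d_l2 = rnorm(2, mean = c(3, 3.6), sd = 0.5))))
  })
  a <- fit_additive_anova(tab)
  d <- duncan_mrt(tab, a)
  mse <- attr(a, "mse"); dfres <- attr(a, "df_resid")
  means <- tapply(tab$d_l2, tab$test, mean)
  tstat <- abs(diff(means)) / sqrt(2 * mse / 10)
  p_t <- 2 * stats::pt(tstat, dfres, lower.tail = FALSE)
  expect_equal(unname(d$p_matrix["B", "A"]), unname(p_t),
               tolerance = 1e-6)
})

test_that("the numeric Duncan inversion matches its closed form", {
  # closed form: p = 1 - (1 - P)^(1/(r-1)) with P the studentized-range
  # exceedance probability of the observed standardized difference
  for (q_obs in c(0.5, 2, 3.5)) for (r in 2:4) {
    df <- 48
    p_num <- emgrehab:::duncan_pvalue(q_obs, r, df)
    P <- stats::ptukey(q_obs, r, df, lower.tail = FALSE)
    p_closed <- 1 - (1 - P)^(1 / (r - 1))
    expect_equal(p_num, p_closed, tolerance = 1e-6)
  }
})

test_that("the homoscedasticity check behaves under null and violation", {
  pass_null <- vapply(1:200, function(s) {
    tab <- simulate_null_results_table(18, seed = s)
    check_homoscedasticity(tab)$passed
  }, logical(1))
  expect_gt(mean(pass_null), 0.90) # ~ 1 - alpha
  # one group with 10x the spread fails in most seeds
  fail_het <- vapply(1:50, function(s) {
    tab <- simulate_null_results_table(18, seed = s)
    idx <- tab$test == "D"
    tab$d_l2[idx] <- mean(tab$d_l2[idx]) +
      10 * (tab$d_l2[idx] - mean(tab$d_l2[idx]))
    !check_homoscedasticity(tab)$passed
  }, logical(1))
  expect_gt(mean(fail_het), 0.8)
  # zero variance everywhere: degenerate, warned, not an error
  tab0 <- random_results_table(5, seed = 6)
  tab0$d_l2 <- 1
  expect_warning(h0 <- check_homoscedasticity(tab0), "degenerate")
  expect_true(is.na(h0$passed))
  # bartlett variant runs
  expect_type(check_homoscedasticity(
    simulate_null_results_table(10, seed = 3),
    method = "bartlett")$p_value, "double")
})
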