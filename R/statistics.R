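#' Validate a results table
#'
#' The inference stage consumes a long-format table with one row per
#' subject x test trial: `subject_id`, `test` (A-D), `order` (1-4),
#' `d_l2`. The design must be balanced (each subject exactly once per
#' test).
#'
#' @param table a `data.frame`.
#' @return The table, with `test`, `order` and `subject_id` as factors in
#'   columns `test`, `order`, `individual`.
#' @export
validate_results_table <- function(table) {
  need <- c("subject_id", "test", "order", "d_l2")
  if (!all(need %in% names(table)))
    abort_emg("results table must have columns ",
              paste(need, collapse = ", "))
  if (anyNA(table[need]))
    abort_emg("results table contains missing values")
  tab <- table(table$subject_id, table$test)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)[1, ]
    abort_emg("unbalanced design: subject ", rownames(tab)[bad[1]],
              " x test ", colnames(tab)[bad[2]], " appears ",
              tab[bad[1], bad[2]], " times (expected exactly once)")
  }
  out <- table
  out$test <- factor(out$test)
  out$order <- factor(out$order)
  out$individual <- factor(out$subject_id)
  out
}

#' Multifactorial additive ANOVA of L2 scores
#'
#' Fits the additive model `d_l2 ~ test + order + individual` (no
#' interactions) with sequential (Type I) sums of squares in that order;
#' the individual factor is included to block between-subject variability.
#' For the balanced subjects-by-tests design, test and individual are
#' orthogonal, so the sequential and marginal sums of squares coincide for
#' those factors. For the default 18 x 4 design the residual degrees of
#' freedom are 72 - 1 - 3 - 3 - 17 = 48.
#'
#' @param table a results table (see [validate_results_table()]).
#' @return An object of class `anova_table`: a `data.frame` with rows
#'   Test, Order, Individual, Residuals and columns `df`, `sum_sq`,
#'   `mean_sq`, `f_value`, `p_value`; attributes `mse`, `df_resid`,
#'   `group_n` and `data` (the validated table).
#' @export
fit_additive_anova <- function(table) {
  df <- validate_results_table(table)
  n <- nrow(df)
  df_resid <- n - 1 - (nlevels(df$test) - 1) - (nlevels(df$order) - 1) -
    (nlevels(df$individual) - 1)
  if (df_resid <= 0)
    abort_emg("fit_additive_anova: saturated model - no residual degrees ",
              "of freedom (", df_resid, "); enlarge the cohort")
  fit <- stats::aov(d_l2 ~ test + order + individual, data = df)
  s <- summary(fit)[[1]]
  full_df <- c(nlevels(df$test), nlevels(df$order),
               nlevels(df$individual)) - 1L
  if (any(is.na(stats::coef(fit))) || nrow(s) != 4 ||
      any(s[["Df"]][1:3] != full_df))
    abort_emg("fit_additive_anova: rank-deficient design - a factor is ",
              "confounded (e.g. order with test under a degenerate ",
              "randomization)")
  out <- data.frame(
    term = c("Test", "Order", "Individual", "Residuals"),
    df = s[["Df"]], sum_sq = s[["Sum Sq"]], mean_sq = s[["Mean Sq"]],
    f_value = s[["F value"]], p_value = s[["Pr(>F)"]],
    row.names = NULL)
  structure(out, class = c("anova_table", "data.frame"),
            mse = out$mean_sq[out$term == "Residuals"],
            df_resid = out$df[out$term == "Residuals"],
            group_n = as.vector(table(df$test))[1],
            data = df)
}

# Duncan least significant range at level alpha for a pair spanning r
# ranked means: the studentized range quantile at the rank-dependent
# protection level 1 - (1 - alpha)^(r - 1).
duncan_critical_q <- function(alpha, r, df_resid) {
  q <- suppressWarnings(stats::qtukey((1 - alpha)^(r - 1), r, df_resid))
  # qtukey can fail to converge in the extreme upper tail; the critical
  # range is then effectively unbounded
  if (is.nan(q)) Inf else q
}

#' Duncan's multiple range test over the four tests
#'
#' Post-hoc pairwise comparison based on the studentized range with
#' rank-dependent protection levels. Group means are sorted; a pair whose
#' means are separated by `r` ranks (span `r` means) is significant at
#' level `alpha` when its studentized difference exceeds the range
#' quantile at protection level `1 - (1 - alpha)^(r - 1)` with the ANOVA
#' residual degrees of freedom. The reported pairwise p-value is the
#' smallest `alpha` at which the pair separates, found numerically by
#' inverting that criterion.
#'
#' @param table a results table.
#' @param anova the matching [fit_additive_anova()] result (supplies the
#'   residual mean square and degrees of freedom).
#' @param alpha significance level (default 0.05).
#' @return An object of class `duncan_result`: `means` (named, sorted
#'   decreasing), `p_matrix` (lower-triangular, rows/cols in label order),
#'   `significant` (logical matrix at `alpha`), `alpha`, `mse`,
#'   `df_resid`.
#' @export
duncan_mrt <- function(table, anova, alpha = 0.05) {
  df <- validate_results_table(table)
  stopifnot(inherits(anova, "anova_table"))
  groups <- levels(df$test)
  k <- length(groups)
  if (k < 2) abort_emg("duncan_mrt: fewer than 2 groups")
  ns <- tapply(df$d_l2, df$test, length)
  if (length(unique(ns)) != 1)
    abort_emg("duncan_mrt: unequal group sizes")
  means <- tapply(df$d_l2, df$test, mean)
  mse <- attr(anova, "mse")
  df_resid <- attr(anova, "df_resid")
  se <- sqrt(mse / ns[1])
  rk <- rank(-means, ties.method = "first") # 1 = largest mean
  p_mat <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in 2:k) for (j in 1:(i - 1)) {
    r <- abs(rk[groups[i]] - rk[groups[j]]) + 1
    q_obs <- abs(means[groups[i]] - means[groups[j]]) / se
    p_mat[i, j] <- duncan_pvalue(q_obs, r, df_resid)
  }
  sig <- p_mat < alpha
  structure(list(means = sort(means, decreasing = TRUE),
                 p_matrix = p_mat, significant = sig, alpha = alpha,
                 mse = mse, df_resid = df_resid),
            class = "duncan_result")
}

# Smallest alpha at which a pair spanning r ranks separates, by bisection
# on the critical-range criterion.
duncan_pvalue <- function(q_obs, r, df_resid) {
  if (!is.finite(q_obs)) return(NA_real_)
  eps <- 1e-10
  f <- function(a) duncan_critical_q(a, r, df_resid) - q_obs
  if (f(1 - eps) > 0) return(1)   # never separates
  if (f(eps) < 0) return(0)       # separates at any level
  stats::uniroot(f, c(eps, 1 - eps), tol = 1e-10)$root
}

#' @export
print.duncan_result <- function(x, ...) {
  cat("Duncan's multiple range test (alpha =", x$alpha, ")\n")
  cat("Group means (sorted):\n")
  print(round(x$means, 4))
  cat("Pairwise p-values:\n")
  print(round(x$p_matrix, 4))
  invisible(x)
}

#' Homoscedasticity check across tests
#'
#' Levene's test (median-centered, via [car::leveneTest()]) of equal L2
#' variance across the four test groups; Bartlett's test available as an
#' alternative. Groups with identical values throughout (zero spread) make
#' the statistic degenerate; this is reported with a warning rather than
#' an error.
#'
#' @param table a results table.
#' @param alpha significance level (default 0.05).
#' @param method `"levene"` (default) or `"bartlett"`.
#' @return List `statistic`, `p_value`, `passed` (`p > alpha`), `method`,
#'   `alpha`.
#' @export
check_homoscedasticity <- function(table, alpha = 0.05,
                                   method = c("levene", "bartlett")) {
  method <- match.arg(method)
  df <- validate_results_table(table)
  if (any(tapply(df$d_l2, df$test, length) < 2))
    abort_emg("check_homoscedasticity: every group needs >= 2 observations")
  spreads <- tapply(df$d_l2, df$test, function(v) diff(range(v)))
  if (all(spreads == 0)) {
    warning("check_homoscedasticity: zero within-group variance in all ",
            "groups; test statistic is degenerate", call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, passed = NA,
                method = method, alpha = alpha))
  }
  if (method == "levene") {
    lt <- car::leveneTest(d_l2 ~ test, data = df, center = stats::median)
    stat <- lt[["F value"]][1]
    p <- lt[["Pr(>F)"]][1]
  } else {
    bt <- stats::bartlett.test(d_l2 ~ test, data = df)
    stat <- unname(bt$statistic)
    p <- bt$p.value
  }
  list(statistic = stat, p_value = p, passed = is.finite(p) && p > alpha,
       method = method, alpha = alpha)
}
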