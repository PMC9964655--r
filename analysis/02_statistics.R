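#!/usr/bin/env Rscript
# Inference stage over the simulated cohort: multifactorial additive ANOVA
# of the L2 distances on test, order and individual (individual included
# to block between-subject variability), Duncan's multiple range test for
# pairwise condition comparisons, and a Levene homoscedasticity check.
#
# Reads results/cohort_results.csv (from 01_simulate_and_score.R); writes
# results/anova.csv, results/duncan.csv and results/stats_summary.json,
# plus a d_L2-by-test boxplot under scratch/.

suppressPackageStartupMessages(library(emgrehab))

tab <- utils::read.csv("results/cohort_results.csv")

anova <- fit_additive_anova(tab)
duncan <- duncan_mrt(tab, anova, alpha = 0.05)
homo <- check_homoscedasticity(tab, alpha = 0.05)

dir.create("results", showWarnings = FALSE)
utils::write.csv(as.data.frame(anova), "results/anova.csv",
                 row.names = FALSE)
utils::write.csv(as.data.frame(duncan$p_matrix), "results/duncan.csv")
jsonlite::write_json(
  list(test_p = anova$p_value[anova$term == "Test"],
       order_p = anova$p_value[anova$term == "Order"],
       individual_p = anova$p_value[anova$term == "Individual"],
       residual_df = anova$df[anova$term == "Residuals"],
       duncan_p = as.list(duncan$p_matrix[lower.tri(duncan$p_matrix)]),
       levene = homo[c("statistic", "p_value", "passed")]),
  "results/stats_summary.json", auto_unbox = TRUE, digits = NA)

message("ANOVA of d_L2 ~ test + order + individual:")
print(as.data.frame(anova))
message("")
print(duncan)
message(sprintf("Levene homoscedasticity: F = %.3f, p = %.3f (%s)",
                homo$statistic, homo$p_value,
                if (isTRUE(homo$passed)) "pass" else "violated"))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("scratch", showWarnings = FALSE)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = test, y = d_l2)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Test condition", y = expression(d[L2]),
                  title = "L2 distance by feedback condition") +
    ggplot2::theme_minimal()
  ggplot2::ggsave("scratch/dl2_by_test.png", p, width = 5, height = 4)
  message("Wrote scratch/dl2_by_test.png")
}
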