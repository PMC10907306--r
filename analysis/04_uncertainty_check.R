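#!/usr/bin/env Rscript
# Cross-checks the first-order ("standard rules") error propagation against
# the Monte-Carlo oracle for the key operations, including both conventions
# for the shared-baseline term of the mixing ratio. Writes
# results/uncertainty_check.csv.

library(ewcdr)

a <- mq(3417, 279); b <- mq(2693, 196); cc <- mq(10899, 420)

rows <- list()
add <- function(label, analytic, mc) {
  rows[[length(rows) + 1]] <<- data.frame(
    case = label, analytic_sd = analytic, mc_sd = mc,
    rel_diff = (analytic - mc) / mc)
}

indep <- propagate_ratio_of_differences(a, b, cc)
mc_split <- monte_carlo("ratio_of_differences_split", list(a, b, b, cc),
                        n_draws = 1e6, seed = 11)
add("mixing ratio, independent-occurrence convention", indep$sd, mc_split$sd)

corr <- propagate_ratio_of_differences(a, b, cc, correlated_b = TRUE)
mc_shared <- monte_carlo("basalt_fraction", list(a, b, cc),
                         n_draws = 1e6, seed = 11)
add("mixing ratio, correlated (shared baseline)", corr$sd, mc_shared$sd)

p <- mq(indep$value, indep$sd)
an_mb <- propagate_through("basalt_mass", list(mq(1200), p))
mc_mb <- monte_carlo("basalt_mass", list(mq(1200), p), n_draws = 1e6, seed = 12)
add("basalt mass from p_basalt", an_mb$sd, mc_mb$sd)

an_cdr <- propagate_through("cdr_potential",
                            list(mq(0.32, 0.07), mq(0.12, 0.09),
                                 mq(31009, 1550), mq(70664, 3533), mq(200)))
mc_cdr <- monte_carlo("cdr_potential",
                      list(mq(0.32, 0.07), mq(0.12, 0.09),
                           mq(31009, 1550), mq(70664, 3533), mq(200)),
                      n_draws = 1e6, seed = 13)
add("cumulative CDR potential", an_cdr$sd, mc_cdr$sd)

tab <- do.call(rbind, rows)
print(tab, row.names = FALSE, digits = 4)
cat("\nNote: the independent-occurrence convention gives",
    round(indep$sd, 4), "for the mixing-ratio SD;",
    "the correlated treatment gives", round(corr$sd, 4), "\n")
cat("First-order SD of basalt mass:", round(an_mb$sd, 1),
    "t/ha (the per-sample spread of the mean is far tighter)\n")

dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/uncertainty_check.csv", row.names = FALSE)
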