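#!/usr/bin/env Rscript
# Stage 2: score the instruments and reproduce the group-comparison and
# correlation tables (Table-1/Table-2 shape) on the synthetic sample.

library(psychnet)

out <- "results"
data <- read_item_table(file.path(out, "synthetic_study.csv"),
                        list(gses_scale(), phq9_scale()))
scored <- score_sample(data)

cat(sprintf("classified by PHQ-9 >= 10: %d depressed / %d control\n",
            sum(scored$group == "depressed"),
            sum(scored$group == "control")))
print(table(scored$severity[scored$group == "depressed"]))

write.csv(scored, file.path(out, "scored_sample.csv"), row.names = FALSE)

tab1 <- group_comparison_table(scored)
write.csv(tab1, file.path(out, "table1_descriptives.csv"), row.names = FALSE)
print(tab1[, c("variable", "statistic", "df", "p", "cohen_d")])

ct <- correlation_table(
  scored[, c("age", "gender", "education", "phq9_total", "gses_total")])
write.csv(round(ct$r, 3), file.path(out, "table2_correlations.csv"))
cat(sprintf("r(PHQ-9 total, GSES total) = %.2f\n",
            ct$r["phq9_total", "gses_total"]))

alpha_g <- cronbach_alpha(data$values[, paste0("s", 1:10)])
alpha_p <- cronbach_alpha(data$values[, paste0("d", 1:9)])
cat(sprintf("Cronbach alpha: GSES %.2f, PHQ-9 %.2f\n", alpha_g, alpha_p))
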