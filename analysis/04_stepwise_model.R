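#!/usr/bin/env Rscript
# Forward stepwise logistic regression on the full ROI table: p-to-enter
# 0.05, p-to-remove 0.15, AIC guard against overfitting. Writes
# results/model.json and results/odds_ratios.csv.

library(fmritex)

ft <- utils::read.csv("results/feature_table.csv", stringsAsFactors = FALSE)
m <- suppressWarnings(stepwise_select(ft, p_enter = 0.05, p_remove = 0.15))
write_stepwise_model(m, "results/model.json")

cat("selected features (entry order):",
    paste(m$selected_features, collapse = ", "), "\n")
cat(sprintf("final AIC %.2f (intercept-only %.2f)\n",
            m$aic, m$aic_trace[1]))
or <- odds_ratios(m)
utils::write.csv(or, "results/odds_ratios.csv", row.names = FALSE)
print(or, row.names = FALSE, digits = 3)
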