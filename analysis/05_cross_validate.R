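#!/usr/bin/env Rscript
# Patient-grouped repeated holdout: 12 of 15 subjects train, 3 test,
# 100 random repeats; stepwise selection re-run inside every training
# fold so feature choice is never informed by test subjects. Writes
# results/evaluation.json and results/evaluation_repeats.csv.

library(fmritex)

seed <- 1L
ft <- utils::read.csv("results/feature_table.csv", stringsAsFactors = FALSE)
plans <- make_splits(unique(ft$subject_id), n_train = 12L, n_repeats = 100L,
                     seed = seed)
res <- suppressWarnings(run_cv(ft, plans))
write_eval_result(res, "results/evaluation.json",
                  "results/evaluation_repeats.csv")
print(res)
cat(sprintf("AUC defined in %d of %d repeats\n",
            res$aggregate$n_auc_defined, res$n_repeats))
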