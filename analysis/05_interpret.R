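#!/usr/bin/env Rscript
# Model interpretation: feature-group ablation (delta R2 under the shared
# fold plan) and permutation-sampling Shapley attribution on the fitted
# ensemble, for both fresh-weight targets.

library(pepperfw)

dir.create("results", showWarnings = FALSE)
records <- read_records("results/records.csv")
plan <- fold_plan_from_json("results/fold_plan.json")

cat("Feature-group ablation (ensemble, shared fold plan)...\n")
ablation <- ablation_table(records, plan = plan, seed = 21)
print(ablation, row.names = FALSE)
utils::write.csv(ablation, "results/ablation.csv", row.names = FALSE)

top <- function(tg) {
  a <- ablation[ablation$target == tg, ]
  a$group[which.max(a$delta_r2)]
}
cat(sprintf(
  "\nLargest delta-R2 group: %s for shoot FW, %s for fruit FW.\n",
  top("shoot_fw"), top("fruit_fw")
))

cat("\nShapley attribution on the final ensembles...\n")
set.seed(22)
bg_idx <- sample(nrow(records), 100)
ex_idx <- sample(nrow(records), 40)
X <- build_features(records)
attributions <- list()
for (target in c("shoot_fw", "fruit_fw")) {
  ens <- fit_ensemble(records, target, seed = 23)
  attributions[[target]] <- shapley_attribution(
    ens, X[ex_idx, , drop = FALSE], X[bg_idx, , drop = FALSE],
    n_permutations = 100, seed = 24
  )
  cat(sprintf("\nMean |attribution| ranking, %s (g):\n", target))
  print(round(shap_summary(attributions[[target]]), 1))
}

report <- importance_report(ablation, attributions)
jsonlite::write_json(
  list(
    ablation = report$ablation,
    shap_ranking = lapply(report$shap_ranking, as.list),
    beeswarm = report$beeswarm
  ),
  "results/importance_report.json", auto_unbox = TRUE, digits = NA
)
cat("\nWrote results/ablation.csv and results/importance_report.json\n")
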