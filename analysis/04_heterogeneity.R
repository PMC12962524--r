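#!/usr/bin/env Rscript
# Stage 4 — heterogeneity discovery. Jitters and standardizes the ITEs
# (mean 0, SD 0.1), clusters them with Ward.D2 over 2-10 clusters, picks k
# with Beale's index at alpha = 0.01, ranks candidate effect modifiers by
# between-cluster covariate z-score differences (threshold 0.25; sensitivity
# at 0.20 / 0.30), and summarizes per-cluster CATE / RR / NNT / E-value.

suppressPackageStartupMessages(library(gformulaHTE))
master_seed <- 1L
out <- "results"

schema <- read_schema_json(file.path(out, "schema.json"))
completed <- read_cohort_csv(file.path(out, "imputed.csv"), schema)
ite_tab <- utils::read.csv(file.path(out, "ite.csv"))
cf <- structure(list(p1 = ite_tab$p1, p0 = ite_tab$p0,
                     outcome_kind = "binary"),
                class = "counterfactual_predictions")
ite <- compute_ite(cf)

z <- jitter_standardize(ite, seed = stage_seed(master_seed, "jitter"))
sol <- ward_cluster(z)
beale <- beale_select_k(sol, alpha = 0.01)
labels <- cut_labels(sol, beale$k)
cat(sprintf("Beale's index selected k = %d%s\n", beale$k,
            if (beale$no_significant_structure)
              " (no significant structure; floor k = 2)" else ""))

imp <- covariate_importance(completed, labels, schema)
cat("\ntop candidate effect modifiers (importance > 0.25 starred):\n")
top <- head(imp[, c("variable", "importance")], 10)
top$selected <- ifelse(top$importance > 0.25, "*", "")
print(top, row.names = FALSE)
sens <- sensitivity_thresholds(imp)
cat(sprintf("\nselected: %d at 0.20, %d at 0.25, %d at 0.30 (nested)\n",
            length(sens[["0.20"]]), length(sens[["0.25"]]),
            length(sens[["0.30"]])))

cate <- cluster_cate(ite, cf, labels, n_boot = 500,
                     seed = stage_seed(master_seed, "cate"))
print(cate[, c("cluster", "n", "CATE", "cate_ci_low", "cate_ci_high",
               "RR", "NNT", "E_value")], row.names = FALSE)
profile <- cluster_profile(completed, labels, imp, cate)

utils::write.csv(data.frame(id = completed$id, label = labels),
                 file.path(out, "hte_labels.csv"), row.names = FALSE)
jsonlite::write_json(
  list(k = beale$k,
       no_significant_structure = beale$no_significant_structure,
       path = beale$beale_path),
  file.path(out, "beale.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
utils::write.csv(imp, file.path(out, "importance.csv"), row.names = FALSE)
utils::write.csv(cate, file.path(out, "cluster_cate.csv"),
                 row.names = FALSE)
utils::write.csv(profile, file.path(out, "cluster_profile.csv"),
                 row.names = FALSE)
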