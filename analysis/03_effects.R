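#!/usr/bin/env Rscript
# Stage 3 — G-formula average effects. Fits the cross-validated stacking
# ensemble (GLM, random forest, neural net, adaptive splines, gradient
# boosting) as the outcome model, predicts every person's risk under
# program and control, and summarizes ATE / RR / NNT / E-value with
# percentile-bootstrap intervals (weight-refit bootstrap at this desk
# scale). Also runs the propensity-overlap positivity diagnostic.

suppressPackageStartupMessages(library(gformulaHTE))
master_seed <- 1L
out <- "results"

schema <- read_schema_json(file.path(out, "schema.json"))
completed <- read_cohort_csv(file.path(out, "imputed.csv"), schema)

X <- build_design(completed, schema)
eff <- estimate_effects(X, completed$y_uncontrolled,
                        library = default_library(), V = 10,
                        n_boot = 200, fast_boot = TRUE,
                        seed = stage_seed(master_seed, "effects"))

cat("stacking weights:\n")
print(round(eff$model$weights, 3))
cat("\nATE:", format_effect(eff$ATE), "\n")
cat("RR: ", format_effect(eff$RR), "\n")
cat(sprintf("NNT: %.1f   E-value: %.2f\n", eff$NNT, eff$E_value))
cat(sprintf("ITE median %.2f (IQR %.2f)\n", median(eff$ite$ite),
            IQR(eff$ite$ite)))

ov <- propensity_overlap(X[, setdiff(colnames(X), "treatment")],
                         completed$treatment, V = 10,
                         seed = stage_seed(master_seed, "overlap"))
cat(sprintf("\npropensity overlap interval: [%.4f, %.4f]%s\n",
            ov$overlap_interval[1], ov$overlap_interval[2],
            if (ov$separation) " (separation warning)" else ""))

jsonlite::write_json(
  list(ATE = list(point = eff$ATE$point, ci_low = eff$ATE$ci_low,
                  ci_high = eff$ATE$ci_high),
       RR = list(point = eff$RR$point, ci_low = eff$RR$ci_low,
                 ci_high = eff$RR$ci_high),
       NNT = round(eff$NNT, 1), E_value = round(eff$E_value, 2),
       n_boot = 200, master_seed = master_seed),
  file.path(out, "effects.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
jsonlite::write_json(
  list(summary = as.data.frame(ov$summary),
       overlap_interval = ov$overlap_interval,
       separation = ov$separation),
  file.path(out, "overlap.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
utils::write.csv(
  data.frame(id = completed$id, p1 = eff$cf$p1, p0 = eff$cf$p0,
             ite = eff$ite$ite),
  file.path(out, "ite.csv"), row.names = FALSE)
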