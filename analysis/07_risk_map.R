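#!/usr/bin/env Rscript
# Stage 7 -- spatial disparity: per-district posterior mean/sd of the spatial
# effect, exceedance probabilities q_j = P(b_j > 0), elevated-district flags
# (q > 0.90), and district-averaged posterior predictive probabilities. Also
# reports how well the fitted field tracks the generator's true field.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

st <- load_study()
spec <- model_spec(random = "CAR")
bundle <- build_design(st$dataset, spec, st$graph)
fit <- fit_spatial_logit(bundle, st$graph, draws = SAMPLER$draws,
                         warmup = SAMPLER$warmup, seed = MASTER_SEED + 3L)
risk <- district_risk_map(fit, bundle)
write_risk_map(risk, file.path(RESULTS, "district_risk_map.csv"))

truth <- jsonlite::read_json(paste0(DATASET_CSV, ".truth.json"))
true_b <- unlist(truth$true_b)
cat(sprintf("elevated districts (q > 0.90): %d of %d\n",
            sum(risk$elevated), nrow(risk)))
cat(sprintf("correlation of posterior mean b with true field: %.2f\n",
            cor(risk$b_mean, true_b)))
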