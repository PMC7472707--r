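#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic survey the whole analysis runs on:
# 64 districts (8x8 shared-boundary lattice), 278 women per district
# (~17.8k records, the scale of the emulated national survey), stratified
# sampling weights, and the paper-calibrated ground truth (19.44% prevalence,
# Table-3-scale covariate effects, rise/decline-then-plateau age effects,
# sigma_b = 0.44, sigma_h = 0.25).
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

graph <- lattice_graph(8, 8)
dataset <- simulate_survey(graph, true_parameters(), n_per_district = 278,
                           weight_scheme = "stratified", seed = MASTER_SEED)
write_dataset(dataset, DATASET_CSV)
write_graph_edgelist(graph, GRAPH_CSV)

dt <- descriptive_table(dataset)
write.csv(dt$categorical, file.path(RESULTS, "table1_categorical.csv"),
          row.names = FALSE)
write.csv(dt$continuous, file.path(RESULTS, "table1_continuous.csv"),
          row.names = FALSE)

cat(sprintf("simulated %d records over %d districts; prevalence %.2f%% (target 19.44%%)\n",
            nrow(dataset$records), length(dataset$true_b), dt$prevalence_percent))
cat("wrote", DATASET_CSV, "and", GRAPH_CSV, "\n")
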