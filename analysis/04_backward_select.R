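#!/usr/bin/env Rscript
# Stage 4 -- backward covariate selection under the selected structure:
# repeatedly drop the covariate whose removal gives the lowest WAIC while the
# reduced model fits within 2 units of the current one. All five default
# covariates carry genuine effects, so the expectation is that nothing (or at
# most the weakest, residence) is dropped.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

st <- load_study()
ladder <- read.csv(file.path(RESULTS, "structure_ladder.csv"))
best <- ladder$label[which.min(ladder$waic)]
spec <- model_spec(random = best)
rep <- backward_select(st$dataset, st$graph, spec,
                       draws = 500, warmup = 300, seed = MASTER_SEED + 2L)
writeLines(rep$decision_trace)
write.csv(rep$candidates, file.path(RESULTS, "backward_selection.csv"),
          row.names = FALSE)
cat("retained covariates:", paste(rep$retained, collapse = ", "), "\n")
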