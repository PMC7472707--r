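#!/usr/bin/env Rscript
# Stage 3 -- choose the district random-effect structure by WAIC over the
# ladder NO / IID / CAR / CAR+IID (all with RW1 age effects). On data
# generated with a genuine spatial field the CAR-type structures should win
# by far more than the 2-unit similar-fit margin.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

st <- load_study()
rep <- structure_ladder(st$dataset, st$graph, model_spec(),
                        draws = SAMPLER$draws, warmup = SAMPLER$warmup,
                        seed = MASTER_SEED + 1L)
print(rep)
writeLines(rep$decision_trace)
write.csv(rep$candidates, file.path(RESULTS, "structure_ladder.csv"),
          row.names = FALSE)
cat("selected structure:", rep$best, "\n")
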