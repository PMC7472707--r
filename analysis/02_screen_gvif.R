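#!/usr/bin/env Rscript
# Stage 2 -- multicollinearity screen: GVIF^(1/2df) for every candidate
# covariate against the 1.58 rule-of-thumb cutoff. With the default design
# nothing should be flagged; a near-duplicate parity pair (children ever born
# vs children alive) is the classic flag case this screen exists for.
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_common.R"))

st <- load_study()
gv <- compute_gvif(st$dataset, c(names(default_references()),
                                 "age_survey", "age_cohab"))
print(gv)
write.csv(gv$table, file.path(RESULTS, "gvif.csv"), row.names = FALSE)
cat("flagged covariates:",
    if (length(gv$flagged)) paste(gv$flagged, collapse = ", ") else "none", "\n")
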