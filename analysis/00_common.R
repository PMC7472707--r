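# shared settings for the analysis scripts: one master seed, one output tree
library(spatlogit)

MASTER_SEED <- 20140601L          # survey-year flavoured, fixed once
RESULTS <- "results"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

DATASET_CSV <- file.path(RESULTS, "dataset.csv")
GRAPH_CSV <- file.path(RESULTS, "graph.csv")

SAMPLER <- list(draws = 900, warmup = 450, chains = 1)

load_study <- function() {
  list(dataset = read_dataset(DATASET_CSV),
       graph = read_graph_edgelist(GRAPH_CSV))
}
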