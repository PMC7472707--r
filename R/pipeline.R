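#' Run the full study workflow from a config
#'
#' Orchestrates the analysis end to end in the study's order: simulate (or
#' load) data and graph, GVIF multicollinearity screen, covariance-structure
#' ladder, backward covariate selection, final spatial fit, prior-sensitivity
#' sweep, and district risk summaries. Every stage writes its outputs under
#' `out_dir` and appends a row to `manifest.csv` (file, stage, seed, elapsed
#' seconds). A rerun with an existing manifest skips completed stages unless
#' `force = TRUE`. Any stage failure halts with an error naming the stage.
#'
#' @param config a named list (see Details) or the path of a YAML file.
#' @param out_dir output directory (created if absent); overrides
#'   `config$paths$out_dir`.
#' @param seed master integer seed; overrides `config$sampler$seed`. Each
#'   stage derives its own seed deterministically from it.
#' @param force rerun stages whose outputs already exist.
#'
#' @details Config keys (all optional, shown with defaults):
#' \preformatted{
#' paths:    dataset_csv: null   # simulate when null
#'           graph_csv:   null
#'           out_dir:     "results"
#' simulate: n_rows: 8, n_cols: 8, n_per_district: 300,
#'           weight_scheme: "stratified"
#' model:    (spec_to_list() block; default model_spec())
#' sampler:  draws: 500, warmup: 300, chains: 1, seed: 1
#' selection: run_ladder: true, run_backward: true, threshold: 2
#' sensitivity: families: ["gamma", "half_normal", "pc"]
#' summaries: exceedance_cutoff: 0.90
#' }
#' @return The manifest data.frame, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL,
                         force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  if (!is.null(out_dir)) cfg$paths$out_dir <- out_dir
  if (!is.null(seed)) cfg$sampler$seed <- as.integer(seed)
  validate_config(cfg)
  od <- cfg$paths$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(od, "manifest.csv")
  manifest <- if (file.exists(manifest_path) && !force)
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  else data.frame(file = character(0), stage = character(0),
                  seed = integer(0), elapsed = numeric(0))
  master <- cfg$sampler$seed

  done <- function(stage) !force && stage %in% manifest$stage
  record <- function(stage, files, t0, sd) {
    manifest <<- rbind(manifest, data.frame(file = files, stage = stage,
                                            seed = sd,
                                            elapsed = round(as.numeric(Sys.time()) - t0, 2)))
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
  }
  run_stage <- function(stage, fun) {
    if (done(stage)) {
      message("[pipeline] skipping completed stage: ", stage)
      return(invisible(NULL))
    }
    message("[pipeline] stage: ", stage)
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    record(stage, res$files, t0, res$seed)
    invisible(res)
  }

  spec <- spec_from_list(cfg$model)
  data_csv <- cfg$paths$dataset_csv %||% file.path(od, "dataset.csv")
  graph_csv <- cfg$paths$graph_csv %||% file.path(od, "graph.csv")

  # --- simulate (or reuse provided inputs)
  run_stage("simulate", function() {
    sd <- master
    if (is.null(cfg$paths$dataset_csv)) {
      graph <- lattice_graph(cfg$simulate$n_rows, cfg$simulate$n_cols)
      ds <- simulate_survey(graph, n_per_district = cfg$simulate$n_per_district,
                            weight_scheme = cfg$simulate$weight_scheme,
                            seed = sd)
      write_dataset(ds, data_csv)
      write_graph_edgelist(graph, graph_csv)
    }
    list(files = c(data_csv, graph_csv), seed = sd)
  })
  if (isTRUE(cfg$stages_only$simulate)) return(invisible(manifest))

  dataset <- read_dataset(data_csv)
  graph <- read_graph_edgelist(graph_csv)

  # --- GVIF screen
  run_stage("screen", function() {
    gv <- compute_gvif(dataset, c(names(spec$fixed), "age_survey", "age_cohab"))
    f <- file.path(od, "gvif.csv")
    utils::write.csv(gv$table, f, row.names = FALSE)
    list(files = f, seed = master)
  })

  # --- covariance-structure ladder
  if (isTRUE(cfg$selection$run_ladder)) run_stage("select_structure", function() {
    sd <- master + 1L
    rep <- structure_ladder(dataset, graph, spec,
                            draws = cfg$sampler$draws, warmup = cfg$sampler$warmup,
                            chains = cfg$sampler$chains, seed = sd)
    f <- file.path(od, "structure_ladder.csv")
    utils::write.csv(rep$candidates, f, row.names = FALSE)
    writeLines(rep$decision_trace, file.path(od, "structure_ladder_trace.txt"))
    spec$random <<- rep$best
    list(files = c(f, file.path(od, "structure_ladder_trace.txt")), seed = sd)
  })

  # --- backward covariate selection
  if (isTRUE(cfg$selection$run_backward)) run_stage("select_covariates", function() {
    sd <- master + 2L
    rep <- backward_select(dataset, graph, spec,
                           draws = cfg$sampler$draws, warmup = cfg$sampler$warmup,
                           chains = cfg$sampler$chains, seed = sd,
                           threshold = cfg$selection$threshold)
    f <- file.path(od, "backward_selection.csv")
    utils::write.csv(rep$candidates, f, row.names = FALSE)
    writeLines(rep$decision_trace, file.path(od, "backward_selection_trace.txt"))
    spec$fixed <<- rep$final_spec$fixed
    list(files = c(f, file.path(od, "backward_selection_trace.txt")), seed = sd)
  })

  # --- final fit
  fit_env <- new.env()
  run_stage("fit", function() {
    sd <- master + 3L
    bundle <- build_design(dataset, spec, graph)
    fit <- fit_spatial_logit(bundle, graph, draws = cfg$sampler$draws,
                             warmup = cfg$sampler$warmup,
                             chains = cfg$sampler$chains, seed = sd)
    assign("fit", fit, envir = fit_env)
    assign("bundle", bundle, envir = fit_env)
    stem <- file.path(od, "final_fit")
    write_fit(fit, stem)
    list(files = paste0(stem, c("_summary.csv", "_draws.csv", "_config.json")),
         seed = sd)
  })
  if (!exists("fit", envir = fit_env)) {
    bundle <- build_design(dataset, spec, graph)
    assign("bundle", bundle, envir = fit_env)
    assign("fit", fit_spatial_logit(bundle, graph, draws = cfg$sampler$draws,
                                    warmup = cfg$sampler$warmup,
                                    chains = cfg$sampler$chains,
                                    seed = master + 3L), envir = fit_env)
  }

  # --- prior sensitivity
  if (length(cfg$sensitivity$families)) run_stage("sensitivity", function() {
    sd <- master + 4L
    fams <- stats::setNames(vector("list", length(cfg$sensitivity$families)),
                            cfg$sensitivity$families)
    tab <- sensitivity_sweep(dataset, graph, spec, families = fams,
                             draws = cfg$sampler$draws, warmup = cfg$sampler$warmup,
                             chains = cfg$sampler$chains, seed = sd)
    f <- file.path(od, "sensitivity.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    list(files = f, seed = sd)
  })

  # --- summaries and risk map
  run_stage("summarize", function() {
    fit <- get("fit", envir = fit_env); bundle <- get("bundle", envir = fit_env)
    files <- file.path(od, "descriptive_table.csv")
    dt <- descriptive_table(dataset)
    utils::write.csv(dt$categorical, files, row.names = FALSE)
    if (fit$use_car) {
      risk <- district_risk_map(fit, bundle,
                                cutoff = cfg$summaries$exceedance_cutoff)
      rf <- file.path(od, "district_risk_map.csv")
      write_risk_map(risk, rf)
      files <- c(files, rf)
    }
    list(files = files, seed = master)
  })

  invisible(manifest)
}

pipeline_defaults <- function(cfg) {
  d <- list(
    paths = list(dataset_csv = NULL, graph_csv = NULL, out_dir = "results"),
    simulate = list(n_rows = 8, n_cols = 8, n_per_district = 300,
                    weight_scheme = "stratified"),
    model = spec_to_list(model_spec()),
    sampler = list(draws = 500, warmup = 300, chains = 1, seed = 1L),
    selection = list(run_ladder = TRUE, run_backward = TRUE, threshold = 2),
    sensitivity = list(families = c("gamma", "half_normal", "pc")),
    summaries = list(exceedance_cutoff = 0.90),
    stages_only = list(simulate = FALSE)
  )
  modifyList(d, cfg)
}

validate_config <- function(cfg) {
  s <- cfg$sampler
  if (!is.numeric(s$seed) || s$seed != as.integer(s$seed))
    stop("config error: sampler$seed must be an integer")
  if (s$draws < 2 || s$warmup < 0) stop("config error: bad sampler sizes")
  cut <- cfg$summaries$exceedance_cutoff
  if (!is.numeric(cut) || cut <= 0 || cut >= 1)
    stop("config error: exceedance cutoff must be in (0, 1)")
  if (!is.null(cfg$paths$dataset_csv) && !file.exists(cfg$paths$dataset_csv))
    stop("config error: dataset_csv does not exist")
  if (!is.null(cfg$paths$graph_csv) && !file.exists(cfg$paths$graph_csv))
    stop("config error: graph_csv does not exist")
  invisible(cfg)
}
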