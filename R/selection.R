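#' Widely applicable information criterion (WAIC)
#'
#' Computes WAIC from an S x n matrix of pointwise log predictive densities:
#' \deqn{lppd = \sum_i \log \frac{1}{S}\sum_s e^{ld_{si}}, \quad
#'       p_D = \sum_i \mathrm{var}_s(ld_{si}), \quad
#'       WAIC = -2 (lppd - p_D).}
#' The deviance-scale convention is used throughout: smaller is better and
#' two models within 2 units are regarded as fitting similarly. Per-record
#' log-mean-exp is computed stably.
#'
#' @param pointwise S x n matrix (S >= 2 draws, n observations) of log
#'   predictive densities, e.g. from [pointwise_log_density()].
#' @return A `waic_result`: list with `lppd`, `p_d`, `waic`, and `per_obs`
#'   (data.frame of per-observation lppd and p_d contributions).
#' @export
compute_waic <- function(pointwise) {
  if (!is.matrix(pointwise) || nrow(pointwise) < 2)
    stop("pointwise must be a matrix with at least 2 draws")
  if (any(!is.finite(pointwise))) stop("non-finite pointwise log-densities")
  S <- nrow(pointwise)
  mx <- apply(pointwise, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(pointwise, 2, mx))))
  pd_i <- apply(pointwise, 2, stats::var)
  structure(list(lppd = sum(lppd_i), p_d = sum(pd_i),
                 waic = -2 * (sum(lppd_i) - sum(pd_i)),
                 per_obs = data.frame(lppd = lppd_i, p_d = pd_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (p_d %.2f, lppd %.2f)\n", x$waic, x$p_d, x$lppd))
  invisible(x)
}

#' WAIC of one fitted model
#' @param fit a `spatlogit_fit`; @param bundle its `design_bundle`.
#' @keywords internal
fit_waic <- function(fit, bundle) compute_waic(pointwise_log_density(fit, bundle))

# shared machinery: fit one spec on a dataset and score it
fit_and_score <- function(dataset, graph, spec, draws, warmup, chains, seed) {
  bundle <- build_design(dataset, spec, graph)
  fit <- fit_spatial_logit(bundle, graph, draws = draws, warmup = warmup,
                           chains = chains, seed = seed)
  list(fit = fit, bundle = bundle, waic = fit_waic(fit, bundle))
}

#' Covariance-structure ladder
#'
#' Fits the four district random-effect structures (NO, IID, CAR, CAR_IID) at
#' identical sampler settings and seed, scores each by WAIC, and selects the
#' best with the 2-unit similar-fit rule: among models within 2 WAIC units of
#' the minimum, the one with the fewest effective parameters wins (parsimony
#' tie-break).
#'
#' @param dataset data.frame or `synthetic_dataset`.
#' @param graph an `adjacency_graph`.
#' @param base_spec `model_spec` whose `random` slot is swept; its covariates,
#'   smooth settings, and priors are shared by all four candidates.
#' @param draws,warmup,chains,seed shared sampler settings.
#' @return A `selection_report`: `candidates` (data.frame label/waic/p_d/
#'   lppd/converged), `best`, `decision_trace` (character), `fits` (named
#'   list of `spatlogit_fit`).
#' @export
structure_ladder <- function(dataset, graph, base_spec = model_spec(),
                             draws = 500, warmup = 300, chains = 1, seed = 1L) {
  labels <- c("NO", "IID", "CAR", "CAR_IID")
  rows <- list(); fits <- list(); trace <- character(0)
  for (lab in labels) {
    spec <- base_spec; spec$random <- lab
    res <- tryCatch(
      fit_and_score(dataset, graph, spec, draws, warmup, chains, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("structure ", lab, " failed: ", conditionMessage(res))
      rows[[lab]] <- data.frame(label = lab, waic = NA, p_d = NA, lppd = NA,
                                converged = FALSE)
      trace <- c(trace, paste0(lab, ": fit failed (", conditionMessage(res), ")"))
      next
    }
    rows[[lab]] <- data.frame(label = lab, waic = res$waic$waic,
                              p_d = res$waic$p_d, lppd = res$waic$lppd,
                              converged = TRUE)
    fits[[lab]] <- res$fit
  }
  candidates <- do.call(rbind, rows); rownames(candidates) <- NULL
  ok <- candidates[candidates$converged, , drop = FALSE]
  if (!nrow(ok)) stop("no candidate structure converged")
  best <- pick_best(ok, trace_env = environment())
  structure(list(candidates = candidates, best = best$label,
                 decision_trace = c(trace, best$trace), fits = fits),
            class = "selection_report")
}

# 2-unit rule: among candidates within 2 WAIC of the minimum, fewest p_d wins
pick_best <- function(ok, trace_env = NULL) {
  wmin <- min(ok$waic)
  near <- ok[ok$waic <= wmin + 2, , drop = FALSE]
  sel <- near[order(near$p_d), , drop = FALSE][1, ]
  trace <- c(
    sprintf("minimum WAIC %.2f (%s)", wmin, ok$label[which.min(ok$waic)]),
    sprintf("within 2 units: %s", paste(near$label, collapse = ", ")),
    sprintf("selected %s (fewest effective parameters among similar fits)", sel$label))
  list(label = sel$label, trace = trace)
}

#' @export
print.selection_report <- function(x, ...) {
  print(x$candidates)
  cat("best:", x$best, "\n")
  invisible(x)
}

#' Backward covariate selection by WAIC
#'
#' Starting from the full fixed-effect set, repeatedly refits the model with
#' each single covariate removed and accepts the removal yielding the lowest
#' WAIC whenever that reduced model fits similarly to or better than the
#' current one (its WAIC is below current + 2, the similar-fit rule: equal
#' predictive fit with fewer parameters is preferred). Stops when every
#' removal worsens WAIC by more than 2 units.
#'
#' @inheritParams structure_ladder
#' @param base_spec `model_spec` holding the full covariate set in `fixed`.
#' @param threshold the similar-fit margin in WAIC units (default 2).
#' @return A `selection_report` whose `best` is the comma-separated retained
#'   covariate set and whose `candidates` rows record each evaluated model.
#' @export
backward_select <- function(dataset, graph, base_spec = model_spec(),
                            draws = 500, warmup = 300, chains = 1, seed = 1L,
                            threshold = 2) {
  current <- base_spec
  cur <- fit_and_score(dataset, graph, current, draws, warmup, chains, seed)
  rows <- list(data.frame(label = paste(names(current$fixed), collapse = "+"),
                          waic = cur$waic$waic, p_d = cur$waic$p_d,
                          lppd = cur$waic$lppd, converged = TRUE))
  trace <- sprintf("start: {%s} WAIC %.2f",
                   paste(names(current$fixed), collapse = ", "), cur$waic$waic)
  repeat {
    if (length(current$fixed) <= 1) {
      trace <- c(trace, "single covariate left; stopping")
      break
    }
    cand <- lapply(names(current$fixed), function(drop_cov) {
      spec <- current
      spec$fixed <- spec$fixed[setdiff(names(spec$fixed), drop_cov)]
      res <- fit_and_score(dataset, graph, spec, draws, warmup, chains, seed)
      list(drop = drop_cov, spec = spec, waic = res$waic)
    })
    wvals <- vapply(cand, function(c) c$waic$waic, 1)
    k <- which.min(wvals)
    for (c in cand)
      rows[[length(rows) + 1]] <- data.frame(
        label = paste("-", c$drop), waic = c$waic$waic, p_d = c$waic$p_d,
        lppd = c$waic$lppd, converged = TRUE)
    if (wvals[k] < cur$waic$waic + threshold) {
      trace <- c(trace, sprintf(
        "drop %s: WAIC %.2f vs %.2f (within %.0f-unit similar-fit margin)",
        cand[[k]]$drop, wvals[k], cur$waic$waic, threshold))
      current <- cand[[k]]$spec
      cur <- fit_and_score(dataset, graph, current, draws, warmup, chains, seed)
    } else {
      trace <- c(trace, sprintf(
        "no removal within %.0f units of WAIC %.2f; stopping",
        threshold, cur$waic$waic))
      break
    }
  }
  candidates <- do.call(rbind, rows); rownames(candidates) <- NULL
  structure(list(candidates = candidates,
                 best = paste(names(current$fixed), collapse = "+"),
                 retained = names(current$fixed),
                 decision_trace = trace, final_spec = current),
            class = "selection_report")
}

#' Prior-sensitivity sweep over precision-prior families
#'
#' Refits one model under each precision-prior family and reports the
#' posterior mean and equal-tailed 95% interval of every variance-component
#' sd together with the model's WAIC; the analog of a prior-robustness table.
#'
#' @inheritParams structure_ladder
#' @param spec the `model_spec` to refit (its `priors` slot is swept).
#' @param families named list mapping family name to its parameter vector
#'   (NULL entries use the family defaults of [prior_spec()]).
#' @return A data.frame with one row per (family, sd component): columns
#'   family, component, mean, lower, upper, waic.
#' @export
sensitivity_sweep <- function(dataset, graph, spec = model_spec(),
                              families = list(gamma = NULL, half_normal = NULL,
                                              half_cauchy = NULL, half_t = NULL,
                                              uniform = NULL, pc = NULL),
                              draws = 500, warmup = 300, chains = 1, seed = 1L) {
  out <- list()
  for (fam in names(families)) {
    sp <- spec
    sp$priors <- prior_spec(fam, families[[fam]], beta_var = spec$priors$beta_var)
    res <- fit_and_score(dataset, graph, sp, draws, warmup, chains, seed)
    sm <- res$fit$summaries
    sds <- sm[grepl("^sigma_", sm$parameter), , drop = FALSE]
    out[[fam]] <- data.frame(family = fam, component = sds$parameter,
                             mean = sds$mean, lower = sds$lower,
                             upper = sds$upper, waic = res$waic$waic)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Linear versus RW1 age-effect comparison
#'
#' Fits the same model twice -- once with both age covariates entering
#' linearly, once with the smooth treatment of `spec` (RW1 by default) -- and
#' pairs the fixed-effect odds ratios, a forest-plot-ready misspecification
#' report.
#'
#' @inheritParams structure_ladder
#' @param spec the nonlinear-arm `model_spec`; the linear arm replaces every
#'   smooth treatment with `"linear"`.
#' @return A data.frame: covariate, or_linear, lower/upper_linear,
#'   or_nonlinear, lower/upper_nonlinear, interval_overlap (logical).
#' @export
linearity_comparison <- function(dataset, graph, spec = model_spec(),
                                 draws = 500, warmup = 300, chains = 1,
                                 seed = 1L) {
  lin <- spec
  lin$smooth[] <- "linear"
  arm <- function(sp) {
    res <- fit_and_score(dataset, graph, sp, draws, warmup, chains, seed)
    sm <- res$fit$summaries
    sm[grepl("\\.", sm$parameter) & !grepl("^(sigma|s_|b\\[|h\\[)", sm$parameter), ]
  }
  a <- arm(lin); b <- arm(spec)
  stopifnot(identical(a$parameter, b$parameter))
  data.frame(covariate = a$parameter,
             or_linear = exp(a$mean), lower_linear = exp(a$lower),
             upper_linear = exp(a$upper),
             or_nonlinear = exp(b$mean), lower_nonlinear = exp(b$lower),
             upper_nonlinear = exp(b$upper),
             interval_overlap = pmax(a$lower, b$lower) <= pmin(a$upper, b$upper),
             row.names = NULL)
}
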