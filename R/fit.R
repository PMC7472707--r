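#' Fit the survey-weighted Bayesian spatial logistic model
#'
#' Samples the joint posterior of the fixed effects, the RW smooth
#' coefficients, the district effects (ICAR `b`, IID `h`) and the variance
#' components under the weighted Bernoulli pseudo-likelihood
#' \deqn{\sum_{ij} w_{ij} [ y_{ij} \log p_{ij} + (1 - y_{ij}) \log(1 - p_{ij}) ]}
#' by Polya-Gamma Gibbs sampling. The ICAR field and the RW smooths are
#' centered every draw (hard sum-to-zero, level transferred to the intercept);
#' the IID field is unconstrained.
#'
#' @param bundle a `design_bundle` from [build_design()].
#' @param graph the `adjacency_graph` the bundle was built against (required
#'   when the model specification includes a CAR term).
#' @param draws posterior draws to keep per chain.
#' @param warmup burn-in iterations per chain.
#' @param chains number of independent chains.
#' @param seed master integer seed; chain c runs under seed + 1000 * (c - 1).
#' @return A `spatlogit_fit`: per-block draw matrices (chains stacked),
#'   `summaries` (data.frame: parameter, mean, sd, lower, upper, rhat, ess),
#'   knot metadata, and the call configuration.
#' @export
fit_spatial_logit <- function(bundle, graph = NULL, draws = 1000,
                              warmup = 500, chains = 1, seed = 1L) {
  spec <- bundle$spec
  use_car <- spec$random %in% c("CAR", "CAR_IID")
  use_iid <- spec$random %in% c("IID", "CAR_IID")
  if (use_car) {
    if (is.null(graph)) stop("CAR structure requires the adjacency graph")
    if (!is_connected(graph))
      stop("CAR structure on a disconnected graph is unsupported")
  }

  term_Q <- function(kn) {
    if (is.null(kn) || kn$degenerate) return(list(Q = matrix(0, 0, 0), idx = integer(0), rank = 0))
    K <- length(kn$knots)
    Q <- as.matrix(build_rw_precision(K, kn$order)$matrix)
    list(Q = Q, idx = kn$index - 1L, rank = K - kn$order)
  }
  t1 <- term_Q(bundle$knots1)
  t2 <- term_Q(bundle$knots2)
  # the sampler reads the district count off Qb's dimension
  J <- length(bundle$district_ids)
  Qb <- if (use_car) as.matrix(build_icar_precision(graph)$matrix)
        else if (use_iid) matrix(0, J, J)
        else matrix(0, 0, 0)

  pr <- spec$priors
  tau_family <- rep(pr$code, 4L)
  tau_p1 <- rep(pr$p1, 4L)
  tau_p2 <- rep(pr$p2, 4L)

  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + 1000L * (ch - 1L))
    chain_res[[ch]] <- pg_gibbs_cpp(
      y = bundle$y, w = bundle$w, Z = bundle$Z,
      k1 = t1$idx, Q1 = t1$Q, rnk1 = t1$rank,
      k2 = t2$idx, Q2 = t2$Q, rnk2 = t2$rank,
      dist = bundle$district_index - 1L,
      Qb = Qb,
      use_car = use_car, use_iid = use_iid,
      beta_var = pr$beta_var,
      tau_family = tau_family, tau_p1 = tau_p1, tau_p2 = tau_p2,
      n_iter = draws + warmup, n_burn = warmup)
  }

  stack <- function(name) do.call(rbind, lapply(chain_res, `[[`, name))
  beta <- stack("beta"); colnames(beta) <- colnames(bundle$Z)
  s1 <- stack("s1")
  if (ncol(s1)) colnames(s1) <- paste0("s_age_survey[", bundle$knots1$knots, "]")
  s2 <- stack("s2")
  if (ncol(s2)) colnames(s2) <- paste0("s_age_cohab[", bundle$knots2$knots, "]")
  b <- stack("b"); if (ncol(b)) colnames(b) <- paste0("b[", bundle$district_ids, "]")
  h <- stack("h"); if (ncol(h)) colnames(h) <- paste0("h[", bundle$district_ids, "]")
  sig <- stack("sigma")
  colnames(sig) <- c("sigma_s_age_survey", "sigma_s_age_cohab", "sigma_b", "sigma_h")
  sig <- sig[, colSums(is.na(sig)) == 0, drop = FALSE]

  all_draws <- cbind(beta, s1, s2, b, h, sig)
  summaries <- summarize_draws(all_draws, chains)

  structure(list(beta = beta, s1 = s1, s2 = s2, b = b, h = h, sigma = sig,
                 summaries = summaries, bundle_spec = spec,
                 knots1 = bundle$knots1, knots2 = bundle$knots2,
                 district_ids = bundle$district_ids,
                 use_car = use_car, use_iid = use_iid,
                 draws = draws, warmup = warmup, chains = chains, seed = seed),
            class = "spatlogit_fit")
}

#' @export
print.spatlogit_fit <- function(x, ...) {
  cat("spatlogit_fit:", x$bundle_spec$random, "structure,",
      nrow(x$beta), "draws (", x$chains, "chain(s) );",
      "max split-Rhat", sprintf("%.3f", max(x$summaries$rhat, na.rm = TRUE)), "\n")
  invisible(x)
}

# split-chain Rhat and a Geyer-style effective sample size, per column
summarize_draws <- function(draws, chains) {
  S <- nrow(draws)
  per <- S %/% chains
  rhat_one <- function(v) {
    # split each chain in half
    halves <- list()
    for (ch in seq_len(chains)) {
      seg <- v[((ch - 1) * per + 1):(ch * per)]
      m <- length(seg) %/% 2
      halves <- c(halves, list(seg[1:m], seg[(m + 1):(2 * m)]))
    }
    mns <- vapply(halves, mean, 1); vrs <- vapply(halves, stats::var, 1)
    m <- length(halves[[1]]); k <- length(halves)
    W <- mean(vrs); B <- m * stats::var(mns)
    if (W < 1e-300) return(NA_real_)
    sqrt(((m - 1) / m * W + B / m) / W)
  }
  ess_one <- function(v) {
    n <- length(v)
    if (stats::sd(v) < 1e-300) return(NA_real_)
    ac <- stats::acf(v, lag.max = min(200, n - 2), plot = FALSE)$acf[-1]
    # Geyer initial positive sequence on paired sums
    pos <- 0
    for (k in seq(1, length(ac) - 1, by = 2)) {
      s <- ac[k] + ac[k + 1]
      if (s <= 0) break
      pos <- pos + s
    }
    max(1, n / (1 + 2 * pos))
  }
  q <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lower = q[1, ], upper = q[2, ],
             rhat = apply(draws, 2, rhat_one),
             ess = apply(draws, 2, ess_one),
             row.names = NULL, stringsAsFactors = FALSE)
}

# per-draw linear predictor matrix (S x n) of a fit on a bundle
linear_predictor_draws <- function(fit, bundle) {
  if (!identical(colnames(fit$beta), colnames(bundle$Z)))
    stop("design does not match fit (fixed-effect columns differ)")
  eta <- fit$beta %*% t(bundle$Z)
  if (ncol(fit$s1)) {
    if (is.null(bundle$knots1)) stop("design does not match fit (missing smooth 1)")
    eta <- eta + fit$s1[, bundle$knots1$index, drop = FALSE]
  }
  if (ncol(fit$s2)) {
    if (is.null(bundle$knots2)) stop("design does not match fit (missing smooth 2)")
    eta <- eta + fit$s2[, bundle$knots2$index, drop = FALSE]
  }
  if (ncol(fit$b)) eta <- eta + fit$b[, bundle$district_index, drop = FALSE]
  if (ncol(fit$h)) eta <- eta + fit$h[, bundle$district_index, drop = FALSE]
  eta
}

#' Posterior predictive probabilities per record
#'
#' Inverse-logit of the per-draw linear predictor for every record of
#' `bundle`, with per-record posterior mean and sd.
#'
#' @param fit a `spatlogit_fit`.
#' @param bundle a `design_bundle` matching the fit's design.
#' @param keep_draws return the S x n draw matrix as well (memory permitting).
#' @return List with `mean`, `sd` (length-n vectors) and optionally `draws`.
#' @export
predict_probabilities <- function(fit, bundle, keep_draws = FALSE) {
  p <- stats::plogis(linear_predictor_draws(fit, bundle))
  out <- list(mean = colMeans(p), sd = apply(p, 2, stats::sd))
  if (keep_draws) out$draws <- p
  out
}

#' Weighted pointwise log predictive density matrix
#'
#' Entry (s, i) is \eqn{w_i \log \mathrm{Bernoulli}(y_i \mid p_i^{(s)})}: the
#' per-draw, per-record log-likelihood contribution under the same weighting
#' used in the pseudo-likelihood, the raw input of WAIC.
#'
#' @inheritParams predict_probabilities
#' @return An S x n matrix.
#' @export
pointwise_log_density <- function(fit, bundle) {
  eta <- linear_predictor_draws(fit, bundle)
  # log Bern(y | plogis(eta)) = y*eta - log(1 + exp(eta)), stable via plogis
  ll <- sweep(eta, 2, bundle$y, function(e, y) {
    stats::plogis(ifelse(y == 1, e, -e), log.p = TRUE)
  })
  sweep(ll, 2, bundle$w, `*`)
}

#' Export posterior summaries as CSV and draws as a columnar file
#'
#' Writes `summaries` keyed by parameter name to `<stem>_summary.csv` and the
#' stacked draw matrix to `<stem>_draws.csv`, plus a JSON sidecar with the
#' sampler configuration.
#' @param fit a `spatlogit_fit`.
#' @param stem output path stem.
#' @export
write_fit <- function(fit, stem) {
  utils::write.csv(fit$summaries, paste0(stem, "_summary.csv"), row.names = FALSE)
  dr <- cbind(fit$beta, fit$s1, fit$s2, fit$b, fit$h, fit$sigma)
  utils::write.csv(as.data.frame(dr), paste0(stem, "_draws.csv"), row.names = FALSE)
  jsonlite::write_json(list(random = fit$bundle_spec$random, draws = fit$draws,
                            warmup = fit$warmup, chains = fit$chains,
                            seed = fit$seed),
                       paste0(stem, "_config.json"), auto_unbox = TRUE)
  invisible(stem)
}
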