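#' True parameter sets for the synthetic survey generator
#'
#' Bundles the ground truth a synthetic dataset is generated from: fixed-effect
#' log-odds coefficients, two nonlinear age effects (as functions of age, in
#' years, returning log-odds contributions), the spatial (`sigma_b`) and
#' unstructured (`sigma_h`) district effect standard deviations, and the
#' intercept. Smooth functions are centered at generation time so that they
#' average to zero over the realized ages (identifiability with the intercept).
#'
#' The defaults emulate the study conditions of a national reproductive-health
#' survey: a ~19.4% outcome prevalence; covariate effects at the adjusted
#' odds-ratio scale of the fitted spatial model (urban 1.09, working 1.19,
#' wealth quintiles 1.08/1.18/1.19/1.26, separated/divorced/widowed
#' 0.50/0.37/0.41, parity 0.99/0.79/0.72/0.63); an age-at-survey effect rising
#' until age 25 then plateauing, an age-at-cohabitation effect declining until
#' age 22 then plateauing; sigma_b = 0.44 and sigma_h = 0.25 on the log-odds
#' scale.
#'
#' @param beta named vector of fixed-effect log-odds coefficients; names are
#'   `covariate.level`.
#' @param smooth_age_survey,smooth_age_cohab functions age -> log-odds.
#' @param sigma_b,sigma_h nonnegative sds of the district effects.
#' @param intercept scalar log-odds; `NULL` means calibrate numerically so
#'   that the population-average outcome probability over the generated
#'   records equals `target_prevalence`.
#' @param target_prevalence used only when `intercept` is `NULL`.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(beta = default_beta(),
                            smooth_age_survey = rise_plateau_effect(),
                            smooth_age_cohab = decline_plateau_effect(),
                            sigma_b = 0.44, sigma_h = 0.25,
                            intercept = NULL, target_prevalence = 0.1944) {
  if (sigma_b < 0 || sigma_h < 0) stop("sigma_b and sigma_h must be nonnegative")
  stopifnot(all(is.finite(beta)))
  structure(list(beta = beta, smooth_age_survey = smooth_age_survey,
                 smooth_age_cohab = smooth_age_cohab,
                 sigma_b = sigma_b, sigma_h = sigma_h,
                 intercept = intercept, target_prevalence = target_prevalence),
            class = "true_parameters")
}

#' @rdname true_parameters
#' @export
default_beta <- function() {
  c(residence.urban = log(1.09),
    occupation.working = log(1.19),
    wealth.poorer = log(1.08), wealth.middle = log(1.18),
    wealth.richer = log(1.19), wealth.richest = log(1.26),
    marital.separated = log(0.50), marital.divorced = log(0.37),
    marital.widowed = log(0.41),
    parity.one = log(0.99), parity.two = log(0.79),
    parity.three = log(0.72), parity.four_plus = log(0.63))
}

#' Nonlinear age-effect shapes
#'
#' `rise_plateau_effect()`: log odds rise linearly with age until the plateau
#' age, then stay flat (the age-at-survey pattern). `decline_plateau_effect()`:
#' log odds fall until the plateau age, then stay flat (age at first
#' cohabitation). Both are uncentered here; the generator centers them over
#' the realized ages.
#'
#' @param slope log-odds change per year before the plateau.
#' @param plateau age (years) after which the effect is flat.
#' @export
rise_plateau_effect <- function(slope = 0.2, plateau = 25) {
  force(slope); force(plateau)
  function(age) slope * (pmin(age, plateau) - plateau)
}

#' @rdname rise_plateau_effect
#' @export
decline_plateau_effect <- function(slope = 0.08, plateau = 22) {
  force(slope); force(plateau)
  function(age) -slope * (pmin(age, plateau) - plateau)
}

#' Default covariate mix of the synthetic survey
#'
#' Marginal category probabilities matching the descriptive profile of the
#' emulated survey: 65.4% rural, 31.5% working, near-uniform wealth quintiles,
#' 94.2% married, and a parity distribution peaking at two children.
#' @export
default_covariate_mix <- function() {
  norm1 <- function(x) x / sum(x)
  list(
    residence = norm1(c(rural = 0.654, urban = 0.346)),
    occupation = norm1(c(not_working = 0.685, working = 0.315)),
    wealth = norm1(c(poorest = 0.182, poorer = 0.188, middle = 0.203,
                     richer = 0.211, richest = 0.216)),
    marital = norm1(c(married = 0.942, separated = 0.013, divorced = 0.010,
                      widowed = 0.035)),
    parity = norm1(c(none = 0.100, one = 0.222, two = 0.264, three = 0.186,
                     four_plus = 0.227))
  )
}

#' Draw one ICAR (Besag) field over a connected graph
#'
#' Samples a zero-sum Gaussian field with density proportional to
#' \eqn{\exp(-b'Qb / (2\sigma_b^2))}, i.e. the intrinsic CAR distribution in
#' its conditional-variance parameterization (\eqn{\sigma_b^2 / m_j}
#' conditional variances), restricted to the sum-to-zero subspace. Sampling is
#' by eigendecomposition of the dense ICAR precision: independent normals on
#' the positive-eigenvalue eigenvectors scaled by \eqn{\sigma_b/\sqrt\lambda_k}.
#'
#' @param graph a connected `adjacency_graph`.
#' @param sigma_b nonnegative conditional sd.
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return Numeric vector of length `n units`, summing to zero.
#' @export
sample_icar_field <- function(graph, sigma_b, seed = NULL) {
  if (sigma_b < 0) stop("sigma_b must be nonnegative")
  if (!is_connected(graph))
    stop("ICAR sampling requires a connected graph (disconnected input rejected)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(graph$unit_ids)
  if (sigma_b == 0) return(stats::setNames(numeric(n), graph$unit_ids))
  Q <- as.matrix(build_icar_precision(graph)$matrix)
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > 1e-9 * max(eg$values)
  z <- stats::rnorm(sum(keep))
  x <- drop(eg$vectors[, keep, drop = FALSE] %*% (z / sqrt(eg$values[keep])))
  x <- x - mean(x)           # numerically exact zero sum
  stats::setNames(sigma_b * x, graph$unit_ids)
}

#' Simulate an areal survey dataset with known ground truth
#'
#' Generates individual survey records over the districts of `graph` from the
#' data-generating model
#' \deqn{logit(p_{ij}) = \alpha + Z_{ij}'\beta + s(t_{ij}) + \phi(t'_{ij}) + b_j + h_j}
#' with `b` an ICAR field (conditional sd `sigma_b`), `h` IID normal
#' (`sigma_h`), categorical covariates drawn from `covariate_mix`, age at
#' first cohabitation on a quarter-year grid in [10, 35], age at survey =
#' cohabitation age + duration, truncated to [15, 49], and smooths centered to
#' mean zero over the realized ages.
#'
#' Weights: `"uniform"` gives weight 1 to everyone; `"stratified"` draws a
#' synthetic selection probability varying by district and urban residence,
#' sets weights inversely proportional to it, clamps them to [0.3, 3] and
#' rescales to mean 1.
#'
#' @param graph a connected `adjacency_graph`.
#' @param truth a `true_parameters` object.
#' @param n_per_district records per district.
#' @param covariate_mix named list of per-covariate category probability
#'   vectors (each summing to 1); first category of each is the reference.
#' @param weight_scheme `"uniform"` or `"stratified"`.
#' @param seed integer seed; fixes every field of the output.
#' @return A `synthetic_dataset`: list with `records` (data.frame: outcome,
#'   covariates, age_survey, age_cohab, district, weight), `truth`, `true_b`,
#'   `true_h`, `intercept` (as calibrated), and `seed`.
#' @export
simulate_survey <- function(graph, truth = true_parameters(),
                            n_per_district = 300,
                            covariate_mix = default_covariate_mix(),
                            weight_scheme = c("stratified", "uniform"),
                            seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  if (!length(covariate_mix)) stop("covariate_mix must not be empty")
  for (cov in names(covariate_mix)) {
    pr <- covariate_mix[[cov]]
    if (abs(sum(pr) - 1) > 1e-8)
      stop("covariate_mix probabilities for '", cov, "' must sum to 1")
  }
  if (n_per_district < 1) stop("n_per_district must be >= 1")
  set.seed(seed)
  J <- length(graph$unit_ids)
  n <- J * n_per_district
  district <- rep(graph$unit_ids, each = n_per_district)
  dist_idx <- rep(seq_len(J), each = n_per_district)

  covs <- lapply(names(covariate_mix), function(cov) {
    pr <- covariate_mix[[cov]]
    factor(sample(names(pr), n, replace = TRUE, prob = pr), levels = names(pr))
  })
  names(covs) <- names(covariate_mix)

  age_cohab <- round(4 * pmin(pmax(10 + stats::rgamma(n, shape = 3.5, scale = 1.75),
                                   10), 35)) / 4
  age_survey <- pmin(pmax(age_cohab + stats::runif(n, 0, 30), 15), 49)

  b <- if (truth$sigma_b > 0) sample_icar_field(graph, truth$sigma_b)
       else stats::setNames(numeric(J), graph$unit_ids)
  h <- stats::setNames(stats::rnorm(J, 0, truth$sigma_h), graph$unit_ids)

  s_raw <- truth$smooth_age_survey(age_survey)
  phi_raw <- truth$smooth_age_cohab(age_cohab)
  s_c <- s_raw - mean(s_raw)
  phi_c <- phi_raw - mean(phi_raw)

  zb <- numeric(n)
  for (cov in names(covs)) {
    lv <- levels(covs[[cov]])
    nm <- paste(cov, lv, sep = ".")
    bet <- stats::setNames(c(0, truth$beta[nm[-1]]), lv)
    bet[is.na(bet)] <- 0
    zb <- zb + bet[as.character(covs[[cov]])]
  }

  rest <- zb + s_c + phi_c + b[dist_idx] + h[dist_idx]
  intercept <- if (is.null(truth$intercept)) {
    # exact calibration: population-average prevalence over the realized
    # records equals the target (accounts for the Jensen gap that a plain
    # logit-scale shift would leave)
    stats::uniroot(function(a) mean(stats::plogis(a + rest)) - truth$target_prevalence,
                   c(-20, 20), tol = 1e-10)$root
  } else truth$intercept
  eta <- intercept + rest
  y <- stats::rbinom(n, 1, stats::plogis(eta))

  w <- if (weight_scheme == "uniform") rep(1, n) else {
    u_d <- stats::runif(J, -0.8, 0.8)
    sel <- exp(u_d[dist_idx] +
                 0.3 * (if ("residence" %in% names(covs))
                          as.numeric(covs$residence == "urban") else 0) +
                 stats::rnorm(n, 0, 0.2))
    wr <- pmin(pmax(1 / sel, 0.3), 3)
    wr / mean(wr)
  }

  records <- data.frame(outcome = y, covs, age_survey = age_survey,
                        age_cohab = age_cohab, district = district, weight = w,
                        stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, true_b = b, true_h = h,
                 intercept = intercept, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$records), "records over",
      length(x$true_b), "districts; prevalence",
      sprintf("%.2f%%", 100 * mean(x$records$outcome)), "\n")
  invisible(x)
}

#' Write / read a synthetic dataset as CSV plus a JSON truth sidecar
#'
#' The CSV holds one row per individual (outcome, covariates, ages, district,
#' weight); the sidecar records the seed, the calibrated intercept, the fixed
#' effects, sigma_b / sigma_h, and the per-district true fields, so a fit can
#' be scored against the truth after a round trip. Smooth functions are not
#' serialized (only their realized, centered values enter the data).
#'
#' @param dataset a `synthetic_dataset`.
#' @param path CSV path; the sidecar is written next to it as `<path>.truth.json`.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(seed = dataset$seed, intercept = dataset$intercept,
                  beta = as.list(dataset$truth$beta),
                  sigma_b = dataset$truth$sigma_b, sigma_h = dataset$truth$sigma_h,
                  true_b = as.list(dataset$true_b), true_h = as.list(dataset$true_h))
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param factor_levels optional named list of level vectors used to restore
#'   factor level order (defaults to the generator's canonical levels).
#' @export
read_dataset <- function(path, factor_levels = lapply(default_covariate_mix(), names)) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cov in names(factor_levels)) {
    if (cov %in% names(rec))
      rec[[cov]] <- factor(rec[[cov]], levels = factor_levels[[cov]])
  }
  rec$district <- as.character(rec$district)
  rec
}
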