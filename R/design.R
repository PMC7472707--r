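#' Prior specification
#'
#' Priors for the fixed effects and the precision parameters of the GMRF
#' variance components. Fixed effects get vague Normal(0, `beta_var`) priors
#' (default variance 1e6). Each precision tau (one per smooth term, one for
#' the ICAR field, one for the IID field) gets one of:
#' \describe{
#'   \item{gamma(a1, a2)}{Gamma prior on tau itself; default a1 = 1,
#'     a2 = 1e-5 (an essentially flat exponential on the precision).}
#'   \item{half_normal(scale)}{on the sd sigma.}
#'   \item{half_cauchy(scale)}{on sigma.}
#'   \item{half_t(df, scale)}{on sigma.}
#'   \item{uniform(upper)}{flat on sigma over (0, upper).}
#'   \item{pc(u, alpha)}{penalized-complexity prior, i.e. an exponential on
#'     sigma with rate -log(alpha)/u; default u = 1, alpha = 0.01.}
#' }
#'
#' @param family one of `"gamma"`, `"half_normal"`, `"half_cauchy"`,
#'   `"half_t"`, `"uniform"`, `"pc"`.
#' @param params numeric vector of family parameters (see above).
#' @param beta_var prior variance of the fixed effects.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(family = "gamma", params = NULL, beta_var = 1e6) {
  fams <- c(gamma = 0L, half_normal = 1L, half_cauchy = 2L, half_t = 3L,
            uniform = 4L, pc = 5L)
  if (!family %in% names(fams)) stop("unknown precision-prior family: ", family)
  defaults <- list(gamma = c(1, 1e-5), half_normal = 1, half_cauchy = 1,
                   half_t = c(3, 1), uniform = 10, pc = c(1, 0.01))
  if (is.null(params)) params <- defaults[[family]]
  if (any(params <= 0 & !(family == "pc" & seq_along(params) == 2)))
    stop("prior parameters must be positive")
  # encode as (family code, p1, p2) for the sampler
  p1 <- params[1]
  p2 <- if (length(params) > 1) params[2] else 0
  structure(list(family = family, code = fams[[family]], p1 = p1, p2 = p2,
                 params = params, beta_var = beta_var),
            class = "prior_spec")
}

#' Model specification
#'
#' Declares the regression structure: which categorical covariates enter as
#' fixed effects (with their reference categories), how the two continuous age
#' covariates are treated (omitted, linear, RW1 or RW2 smooth), which
#' district-level random-effect structure is used, and the priors.
#'
#' Reference categories default to the study baselines (rural, not working,
#' poorest, married, no child) so coefficient signs are directly comparable
#' with the adjusted odds ratios of the source analysis.
#'
#' @param fixed named character vector: covariate name -> reference category.
#' @param smooth named character vector over continuous covariates
#'   (`age_survey`, `age_cohab`): each `"none"`, `"linear"`, `"rw1"` or `"rw2"`.
#' @param random one of `"NO"`, `"IID"`, `"CAR"`, `"CAR_IID"`.
#' @param priors a `prior_spec`.
#' @param bin_width,max_knots knot construction for smooth terms: ages are
#'   floor-binned to `bin_width`-year bins (default 1 year), the sorted unique
#'   bins are the knots, capped at `max_knots` (wider bins are used if needed).
#' @return A `model_spec` object.
#' @export
model_spec <- function(fixed = default_references(),
                       smooth = c(age_survey = "rw1", age_cohab = "rw1"),
                       random = c("CAR", "NO", "IID", "CAR_IID"),
                       priors = prior_spec(),
                       bin_width = 1, max_knots = 60) {
  random <- match.arg(random)
  bad <- setdiff(smooth, c("none", "linear", "rw1", "rw2"))
  if (length(bad)) stop("unknown smooth treatment: ", paste(bad, collapse = ", "))
  structure(list(fixed = fixed, smooth = smooth, random = random,
                 priors = priors, bin_width = bin_width, max_knots = max_knots),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
default_references <- function() {
  c(residence = "rural", occupation = "not_working", wealth = "poorest",
    marital = "married", parity = "none")
}

#' Serialize / restore a model spec as a JSON- or YAML-compatible list
#' @param spec a `model_spec`.
#' @export
spec_to_list <- function(spec) {
  list(fixed = as.list(spec$fixed), smooth = as.list(spec$smooth),
       random = spec$random,
       priors = list(family = spec$priors$family,
                     params = spec$priors$params,
                     beta_var = spec$priors$beta_var),
       bin_width = spec$bin_width, max_knots = spec$max_knots)
}

#' @rdname spec_to_list
#' @param x a list as produced by [spec_to_list()] (e.g. parsed from YAML).
#' @export
spec_from_list <- function(x) {
  model_spec(fixed = unlist(x$fixed),
             smooth = unlist(x$smooth),
             random = x$random,
             priors = prior_spec(x$priors$family %||% "gamma",
                                 unlist(x$priors$params),
                                 x$priors$beta_var %||% 1e6),
             bin_width = x$bin_width %||% 1,
             max_knots = x$max_knots %||% 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Knot assignment for random-walk smooth terms
#'
#' Floor-bins the values to a `bin_width` grid; the sorted unique bins are the
#' knots ("the ranked values" of the covariate after binning), and every
#' record maps to the knot of its bin. If more than `max_knots` distinct bins
#' arise, the bin width is doubled until the cap is met.
#'
#' @param values finite numeric vector.
#' @param bin_width positive bin width (same units as `values`).
#' @param max_knots cap on the number of knots.
#' @return List with `knots` (numeric, sorted bin left edges), `index`
#'   (1-based knot index per record), and `degenerate` (TRUE when a single
#'   knot remains, i.e. the smooth collapses into the intercept).
#' @export
assign_knots <- function(values, bin_width = 1, max_knots = 60) {
  if (!length(values)) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  if (bin_width <= 0) stop("bin_width must be positive")
  repeat {
    binned <- floor(values / bin_width) * bin_width
    knots <- sort(unique(binned))
    if (length(knots) <= max_knots) break
    bin_width <- 2 * bin_width
  }
  idx <- match(binned, knots)
  if (length(knots) == 1L)
    warning("constant covariate: smooth term degenerates to the intercept")
  list(knots = knots, index = idx, degenerate = length(knots) == 1L)
}

#' Build the design bundle for a model fit
#'
#' Turns a dataset (data.frame or `synthetic_dataset`) plus a `model_spec`
#' and an `adjacency_graph` into the concrete sampler inputs: outcome vector,
#' fixed-effect design matrix with an intercept and reference-cell dummy
#' coding (declared reference level dropped, deterministic column order),
#' per-record knot indices for each smooth term, per-record district indices,
#' and the weight vector. Records with missing values in any used column are
#' excluded listwise and counted.
#'
#' @param dataset data.frame with columns `outcome`, the fixed covariates,
#'   `age_survey`, `age_cohab`, `district`, and optionally `weight`; or a
#'   `synthetic_dataset`.
#' @param spec a `model_spec`.
#' @param graph an `adjacency_graph` covering all districts in the data.
#' @param normalize_weights rescale weights to mean 1 (default TRUE); with
#'   FALSE raw weights enter the pseudo-likelihood unchanged.
#' @return A `design_bundle`: list with `y`, `Z` (n x p, first column the
#'   intercept), `knots1`/`knots2` (as [assign_knots()] output or NULL),
#'   `district_index`, `district_ids`, `w`, `n_excluded`, `linear_age_cols`,
#'   and `spec`.
#' @export
build_design <- function(dataset, spec, graph, normalize_weights = TRUE) {
  df <- if (inherits(dataset, "synthetic_dataset")) dataset$records else dataset
  used <- c("outcome", names(spec$fixed),
            names(spec$smooth)[spec$smooth != "none"], "district")
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop("dataset lacks columns: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(df[, used, drop = FALSE])
  n_excluded <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (!n) stop("no complete records")

  # fixed effects: intercept + reference-cell dummies in declared order
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cov in names(spec$fixed)) {
    x <- df[[cov]]
    if (!is.factor(x)) x <- factor(x)
    ref <- spec$fixed[[cov]]
    if (!ref %in% levels(x))
      stop("reference category '", ref, "' absent from covariate '", cov, "'")
    x <- stats::relevel(x, ref = ref)
    unseen <- setdiff(unique(as.character(x)), levels(x))
    if (length(unseen)) stop("unseen category in '", cov, "'")
    lv <- levels(x)
    for (l in lv[-1]) {
      Z <- cbind(Z, as.numeric(x == l))
      colnames(Z)[ncol(Z)] <- paste(cov, l, sep = ".")
    }
  }
  # linear age terms are centered columns of Z
  linear_age_cols <- character(0)
  for (cov in names(spec$smooth)) {
    if (spec$smooth[[cov]] == "linear") {
      v <- df[[cov]]
      Z <- cbind(Z, v - mean(v))
      colnames(Z)[ncol(Z)] <- cov
      linear_age_cols <- c(linear_age_cols, cov)
    }
  }

  make_term <- function(cov) {
    if (!spec$smooth[[cov]] %in% c("rw1", "rw2")) return(NULL)
    kn <- assign_knots(df[[cov]], spec$bin_width, spec$max_knots)
    kn$order <- if (spec$smooth[[cov]] == "rw1") 1L else 2L
    kn$covariate <- cov
    kn
  }
  knots1 <- if ("age_survey" %in% names(spec$smooth)) make_term("age_survey")
  knots2 <- if ("age_cohab" %in% names(spec$smooth)) make_term("age_cohab")

  district_index <- match(as.character(df$district), graph$unit_ids)
  if (anyNA(district_index))
    stop("districts not in graph: ",
         paste(unique(df$district[is.na(district_index)]), collapse = ", "))

  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else rep(1, n)
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive and finite")
  if (normalize_weights) w <- w / mean(w)

  structure(list(y = as.numeric(df$outcome), Z = Z, knots1 = knots1,
                 knots2 = knots2, district_index = district_index,
                 district_ids = graph$unit_ids, w = w,
                 n_excluded = n_excluded, linear_age_cols = linear_age_cols,
                 spec = spec),
            class = "design_bundle")
}

#' @export
print.design_bundle <- function(x, ...) {
  cat("design_bundle:", length(x$y), "records,", ncol(x$Z), "fixed-effect columns",
      sprintf("(%d excluded for missingness)\n", x$n_excluded))
  invisible(x)
}
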