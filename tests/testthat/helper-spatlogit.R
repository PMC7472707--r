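# shared fixtures for the test suite; everything is generated in code

zero_smooth <- function(age) 0 * age

# truth with no nonlinear age effects and configurable district variances
flat_truth <- function(sigma_b = 0, sigma_h = 0, beta = default_beta(),
                       target_prevalence = 0.1944) {
  true_parameters(beta = beta, smooth_age_survey = zero_smooth,
                  smooth_age_cohab = zero_smooth,
                  sigma_b = sigma_b, sigma_h = sigma_h,
                  target_prevalence = target_prevalence)
}

# a small covariate mix with two binary covariates for fast fits
small_mix <- function() {
  list(residence = c(rural = 0.65, urban = 0.35),
       occupation = c(not_working = 0.6, working = 0.4))
}

small_spec <- function(random = "NO",
                       smooth = c(age_survey = "none", age_cohab = "none"), ...) {
  model_spec(fixed = c(residence = "rural", occupation = "not_working"),
             smooth = smooth, random = random, ...)
}

# path graph 1-2-3
path3 <- function() adjacency_graph(c("a", "b", "c"),
                                    rbind(c("a", "b"), c("b", "c")))

# a tiny fitted model (single district, 60 records) for interface tests
tiny_fit <- function(seed = 1) {
  g <- adjacency_graph(c("d1", "d2"), rbind(c("d1", "d2")))
  set.seed(seed)
  df <- data.frame(outcome = rbinom(60, 1, 0.4),
                   grp = factor(sample(c("a", "b"), 60, TRUE), c("a", "b")),
                   district = "d1")
  spec <- model_spec(fixed = c(grp = "a"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "NO")
  bundle <- build_design(df, spec, g)
  list(fit = fit_spatial_logit(bundle, g, draws = 50, warmup = 20, seed = seed),
       bundle = bundle, graph = g)
}

# dense-eigendecomposition oracle for null spaces
null_space <- function(Q, tol = 1e-8) {
  Q <- as.matrix(Q)
  eg <- eigen(Q, symmetric = TRUE)
  eg$vectors[, eg$values < tol * max(abs(eg$values), 1), drop = FALSE]
}
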