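test_that("Polya-Gamma draws match the closed-form mean", {
  # E[PG(b, z)] = b tanh(z/2) / (2 z); b = 1 exercises the exact Devroye
  # sampler, non-integer b the truncated-series path
  set.seed(42)
  for (case in list(c(1, 0), c(1, 1.5), c(1, 5), c(2, 1.5),
                    c(0.7, 1.5), c(2.4, 0), c(2.4, 3))) {
    b <- case[1]; z <- case[2]
    x <- spatlogit:::rpg_cpp(20000, b, z)
    m <- if (z == 0) b / 4 else b * tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(x) - m), 4 * sd(x) / sqrt(length(x)) + 0.002 * m)
    expect_true(all(x > 0))
  }
})

test_that("pointwise log density follows the weighted Bernoulli rule", {
  tf <- tiny_fit()
  ld <- pointwise_log_density(tf$fit, tf$bundle)
  expect_equal(dim(ld), c(50, 60))

  # loop oracle on a handful of records
  eta <- spatlogit:::linear_predictor_draws(tf$fit, tf$bundle)
  for (i in 1:5) for (s in c(1, 25, 50)) {
    p <- plogis(eta[s, i])
    manual <- tf$bundle$w[i] *
      (tf$bundle$y[i] * log(p) + (1 - tf$bundle$y[i]) * log(1 - p))
    expect_equal(ld[s, i], manual, tolerance = 1e-12)
  }

  # closed forms: y = 1, p = 0.5, w = 1 -> log 0.5; w = 2 doubles it
  fit0 <- tf$fit
  fit0$beta[] <- 0
  b1 <- tf$bundle; b1$y[] <- 1; b1$w[] <- 1
  expect_equal(unique(as.vector(pointwise_log_density(fit0, b1))), log(0.5))
  b2 <- b1; b2$w[] <- 2
  expect_equal(unique(as.vector(pointwise_log_density(fit0, b2))), 2 * log(0.5))
})

test_that("posterior predictions are probabilities with the right identities", {
  tf <- tiny_fit()
  pp <- predict_probabilities(tf$fit, tf$bundle)
  expect_true(all(pp$mean > 0 & pp$mean < 1))

  # all parameters zero -> p = 0.5 everywhere
  fit0 <- tf$fit; fit0$beta[] <- 0
  expect_equal(unique(predict_probabilities(fit0, tf$bundle)$mean), 0.5)

  # district average of per-record means equals the group-by mean exactly
  pd <- predict_probabilities(tf$fit, tf$bundle)
  agg <- tapply(pd$mean, tf$bundle$district_index, mean)
  expect_equal(unname(agg[["1"]]),
               mean(pd$mean[tf$bundle$district_index == 1]), tolerance = 1e-12)

  # monotonicity: shifting a positive-coefficient covariate up raises p
  fitp <- tf$fit
  fitp$beta[, 2] <- abs(fitp$beta[, 2])     # force positive mass on grp.b
  b_hi <- tf$bundle; b_hi$Z[, 2] <- 1
  b_lo <- tf$bundle; b_lo$Z[, 2] <- 0
  expect_true(all(predict_probabilities(fitp, b_hi)$mean >=
                  predict_probabilities(fitp, b_lo)$mean))
})

test_that("fits are reproducible and expose coherent summaries", {
  tf1 <- tiny_fit(seed = 7)
  tf2 <- tiny_fit(seed = 7)
  expect_identical(tf1$fit$beta, tf2$fit$beta)

  s <- tf1$fit$summaries
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
})

test_that("weight-one fits equal weightless fits", {
  g <- adjacency_graph(c("d1", "d2"), rbind(c("d1", "d2")))
  set.seed(9)
  df <- data.frame(outcome = rbinom(80, 1, 0.4),
                   grp = factor(sample(c("a", "b"), 80, TRUE)),
                   district = "d1")
  spec <- model_spec(fixed = c(grp = "a"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "NO")
  b_plain <- build_design(df, spec, g)
  df$weight <- 1
  b_w <- build_design(df, spec, g)
  f1 <- fit_spatial_logit(b_plain, g, draws = 60, warmup = 20, seed = 2)
  f2 <- fit_spatial_logit(b_w, g, draws = 60, warmup = 20, seed = 2)
  expect_identical(f1$beta, f2$beta)
})

test_that("posterior means match the ML oracle without random effects", {
  g <- adjacency_graph(c("d1", "d2"), rbind(c("d1", "d2")))
  set.seed(14)
  n <- 1500
  x <- rbinom(n, 1, 0.4)
  df <- data.frame(outcome = rbinom(n, 1, plogis(-1.4 + 0.5 * x)),
                   grp = factor(ifelse(x == 1, "b", "a"), c("a", "b")),
                   district = "d1")
  spec <- model_spec(fixed = c(grp = "a"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "NO")
  bundle <- build_design(df, spec, g)
  fit <- fit_spatial_logit(bundle, g, draws = 500, warmup = 250, seed = 3)
  ml <- coef(glm(outcome ~ grp, binomial, df))
  s <- fit$summaries
  expect_lt(abs(s$mean[1] - ml[1]), 3 * s$sd[1])
  expect_lt(abs(s$mean[2] - ml[2]), 3 * s$sd[2])
})

test_that("CAR draws are centered and variance draws positive", {
  g <- lattice_graph(3, 3)
  ds <- simulate_survey(g, flat_truth(sigma_b = 0.5), n_per_district = 60,
                        covariate_mix = small_mix(), seed = 6)
  bundle <- build_design(ds, small_spec("CAR_IID"), g)
  fit <- fit_spatial_logit(bundle, g, draws = 80, warmup = 40, seed = 4)
  expect_lt(max(abs(rowSums(fit$b))), 1e-8)
  expect_true(all(fit$sigma > 0))
  expect_equal(colnames(fit$sigma), c("sigma_b", "sigma_h"))
})

test_that("CAR on a disconnected graph is rejected", {
  g <- adjacency_graph(c("a", "b", "c", "d"), rbind(c("a", "b"), c("c", "d")))
  df <- data.frame(outcome = rbinom(40, 1, 0.5),
                   grp = factor(sample(c("x", "y"), 40, TRUE)),
                   district = sample(c("a", "b", "c", "d"), 40, TRUE))
  spec <- model_spec(fixed = c(grp = "x"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "CAR")
  bundle <- build_design(df, spec, g)
  expect_error(fit_spatial_logit(bundle, g, draws = 20, warmup = 10),
               "disconnected")
})

test_that("IID variance components agree with an independent GLMM oracle", {
  skip_if_not_installed("glmmTMB")
  g <- lattice_graph(8, 8)
  set.seed(31)
  J <- 64; npd <- 300
  h_true <- rnorm(J, 0, 0.4)
  dist <- rep(seq_len(J), each = npd)
  x <- rbinom(J * npd, 1, 0.4)
  rec <- data.frame(
    outcome = rbinom(J * npd, 1, plogis(-1.2 + 0.5 * x + h_true[dist])),
    grp = factor(ifelse(x == 1, "b", "a"), c("a", "b")),
    district = g$unit_ids[dist])
  spec <- model_spec(fixed = c(grp = "a"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "IID")
  bundle <- build_design(rec, spec, g)
  fit <- fit_spatial_logit(bundle, g, draws = 800, warmup = 400, seed = 2)
  s <- fit$summaries
  tm <- glmmTMB::glmmTMB(outcome ~ grp + (1 | district), family = binomial,
                         data = rec)
  sig_ml <- sqrt(glmmTMB::VarCorr(tm)$cond$district[1, 1])
  sig_row <- s[s$parameter == "sigma_h", ]
  expect_lt(abs(sig_row$mean - sig_ml), 3 * sig_row$sd)
  beta_ml <- glmmTMB::fixef(tm)$cond
  expect_lt(abs(s$mean[1] - beta_ml[1]), 3 * s$sd[1])
  expect_lt(abs(s$mean[2] - beta_ml[2]), 3 * s$sd[2])
})

test_that("spatially null data yield a near-zero spatial variance posterior", {
  g <- lattice_graph(8, 8)
  small <- 0
  for (r in 1:5) {
    ds <- simulate_survey(g, flat_truth(sigma_b = 0, sigma_h = 0),
                          n_per_district = 300, covariate_mix = small_mix(),
                          weight_scheme = "uniform", seed = 400 + r)
    bundle <- build_design(ds, small_spec("CAR"), g)
    fit <- fit_spatial_logit(bundle, g, draws = 500, warmup = 300,
                             seed = 500 + r)
    if (median(fit$sigma[, "sigma_b"]) < 0.1) small <- small + 1
  }
  expect_gte(small, 4)
})
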