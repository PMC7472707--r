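test_that("WAIC matches its closed forms", {
  # constant model p = 0.5, 10 observations, one repeated draw
  pw <- matrix(log(0.5), nrow = 2, ncol = 10)
  w <- compute_waic(pw)
  expect_equal(w$lppd, 10 * log(0.5))
  expect_equal(w$p_d, 0)
  expect_equal(w$waic, -20 * log(0.5))

  # duplicating every observation doubles all three
  set.seed(1)
  m <- matrix(rnorm(4 * 6, mean = -0.7), 4, 6)
  w1 <- compute_waic(m)
  w2 <- compute_waic(cbind(m, m))
  expect_equal(w2$lppd, 2 * w1$lppd)
  expect_equal(w2$p_d, 2 * w1$p_d)
  expect_equal(w2$waic, 2 * w1$waic)

  expect_error(compute_waic(matrix(c(1, NA), 2, 1)), "non-finite")
  expect_error(compute_waic(matrix(1, 1, 3)), "at least 2")
})

test_that("WAIC equals a literal two-loop oracle on random matrices", {
  waic_oracle <- function(m) {
    S <- nrow(m); n <- ncol(m)
    lppd <- 0; pd <- 0
    for (i in seq_len(n)) {
      acc <- 0
      for (s in seq_len(S)) acc <- acc + exp(m[s, i])
      lppd <- lppd + log(acc / S)
      mu <- mean(m[, i]); v <- 0
      for (s in seq_len(S)) v <- v + (m[s, i] - mu)^2
      pd <- pd + v / (S - 1)
    }
    -2 * (lppd - pd)
  }
  set.seed(2)
  for (rep in 1:100) {
    m <- matrix(rnorm(5 * 4, mean = -1, sd = 0.8), 4, 5)
    expect_equal(compute_waic(m)$waic, waic_oracle(m), tolerance = 1e-10)
  }
})

test_that("the structure ladder is deterministic and reports all four fits", {
  g <- lattice_graph(3, 3)
  ds <- simulate_survey(g, flat_truth(sigma_b = 0.6), n_per_district = 50,
                        covariate_mix = small_mix(), seed = 10)
  r1 <- structure_ladder(ds, g, small_spec(), draws = 60, warmup = 30, seed = 5)
  r2 <- structure_ladder(ds, g, small_spec(), draws = 60, warmup = 30, seed = 5)
  expect_equal(r1$candidates$label, c("NO", "IID", "CAR", "CAR_IID"))
  expect_true(all(r1$candidates$converged))
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$best, r2$best)
  # best is within 2 of the minimum by construction
  wmin <- min(r1$candidates$waic)
  expect_lte(r1$candidates$waic[r1$candidates$label == r1$best], wmin + 2)
})

test_that("ladder decisions are invariant to covariate order on clear data", {
  g <- lattice_graph(4, 4)
  ds <- simulate_survey(g, flat_truth(sigma_b = 0.8), n_per_district = 70,
                        covariate_mix = small_mix(), seed = 12)
  specA <- small_spec()
  specB <- specA
  specB$fixed <- rev(specB$fixed)
  rA <- structure_ladder(ds, g, specA, draws = 150, warmup = 80, seed = 6)
  rB <- structure_ladder(ds, g, specB, draws = 150, warmup = 80, seed = 6)
  # the substantive decision (a spatial structure is needed) must not depend
  # on column order; CAR vs CAR_IID is a genuine tie under sigma_h = 0 truth
  expect_true(rA$best %in% c("CAR", "CAR_IID"))
  expect_true(rB$best %in% c("CAR", "CAR_IID"))
  expect_equal(rA$candidates$waic, rB$candidates$waic, tolerance = 2e-3)
})

test_that("backward selection retains informative covariates, drops null ones", {
  g <- lattice_graph(3, 3)
  mix <- list(residence = c(rural = 0.6, urban = 0.4),
              occupation = c(not_working = 0.6, working = 0.4),
              noisecov = c(lo = 0.5, hi = 0.5))
  # strong true effects for two covariates, exactly zero for the third
  tr <- flat_truth(beta = c(residence.urban = 0.8, occupation.working = -0.8,
                            noisecov.hi = 0),
                   target_prevalence = 0.3)
  ds <- simulate_survey(g, tr, n_per_district = 700, covariate_mix = mix,
                        weight_scheme = "uniform", seed = 13)
  spec <- model_spec(fixed = c(residence = "rural", occupation = "not_working",
                               noisecov = "lo"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "NO")
  rep <- backward_select(ds, g, spec, draws = 250, warmup = 120, seed = 7)
  expect_true(all(c("residence", "occupation") %in% rep$retained))
  expect_false("noisecov" %in% rep$retained)

  # single strongly informative covariate is retained
  spec1 <- model_spec(fixed = c(residence = "rural"),
                      smooth = c(age_survey = "none", age_cohab = "none"),
                      random = "NO")
  rep1 <- backward_select(ds, g, spec1, draws = 200, warmup = 100, seed = 8)
  expect_identical(rep1$retained, "residence")
})

test_that("sensitivity sweeps cover every requested family deterministically", {
  g <- lattice_graph(3, 3)
  ds <- simulate_survey(g, flat_truth(sigma_b = 0.5), n_per_district = 40,
                        covariate_mix = small_mix(), seed = 15)
  fams <- list(gamma = NULL, half_normal = NULL, half_cauchy = NULL,
               half_t = NULL, uniform = NULL, pc = NULL)
  t1 <- sensitivity_sweep(ds, g, small_spec("CAR"), families = fams,
                          draws = 60, warmup = 30, seed = 9)
  expect_setequal(unique(t1$family), names(fams))
  expect_true(all(c("mean", "lower", "upper", "waic") %in% names(t1)))
  t2 <- sensitivity_sweep(ds, g, small_spec("CAR"), families = fams,
                          draws = 60, warmup = 30, seed = 9)
  expect_identical(t1, t2)
  expect_error(sensitivity_sweep(ds, g, small_spec("CAR"),
                                 families = list(bogus = NULL),
                                 draws = 60, warmup = 30),
               "unknown")
})

test_that("identical arms give identical linearity-comparison tables", {
  g <- lattice_graph(3, 3)
  ds <- simulate_survey(g, flat_truth(), n_per_district = 40,
                        covariate_mix = small_mix(), seed = 16)
  spec_lin <- small_spec("NO", smooth = c(age_survey = "linear",
                                          age_cohab = "linear"))
  tab <- linearity_comparison(ds, g, spec_lin, draws = 60, warmup = 30, seed = 4)
  expect_equal(tab$or_linear, tab$or_nonlinear)
  expect_true(all(tab$interval_overlap))
  expect_setequal(tab$covariate, c("residence.urban", "occupation.working"))
})
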