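test_that("descriptive tables reproduce toy worked examples", {
  df <- data.frame(outcome = c(1, 0, 0, 1),
                   residence = factor(rep("rural", 4), c("rural", "urban")),
                   district = "d1")
  dt <- descriptive_table(df)
  rural <- dt$categorical[dt$categorical$level == "rural", ]
  expect_equal(rural$row_pct_yes, 50.00)
  expect_equal(rural$column_pct, 100.00)
  expect_equal(dt$prevalence_percent, 50.00)
})

test_that("row percentages sum to 100 and continuous summaries are medians/IQRs", {
  ds <- simulate_survey(lattice_graph(3, 3), n_per_district = 80, seed = 17)
  dt <- descriptive_table(ds)
  sums <- dt$categorical$row_pct_yes + dt$categorical$row_pct_no
  expect_true(all(abs(sums - 100) <= 0.011))
  cont <- dt$continuous
  expect_setequal(cont$covariate, c("age_survey", "age_cohab"))
  r <- ds$records
  expect_equal(cont$median[cont$covariate == "age_survey"],
               round(median(r$age_survey), 2))
  expect_equal(cont$iqr_yes[cont$covariate == "age_cohab"],
               round(IQR(r$age_cohab[r$outcome == 1]), 2))
})

test_that("GVIF equals 1 for orthogonal designs and 1/(1-r^2) for correlated pairs", {
  # balanced factorial: two binary covariates, orthogonal by construction
  df <- expand.grid(a = c("l", "h"), b = c("l", "h"),
                    rep = 1:25, stringsAsFactors = TRUE)
  g0 <- compute_gvif(df, c("a", "b"))
  expect_equal(g0$table$gvif, c(1, 1), tolerance = 1e-12)
  expect_length(g0$flagged, 0)

  # exact sample correlation r = 0.8 via Gram-Schmidt
  set.seed(18)
  n <- 400
  x <- scale(rnorm(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  y <- 0.8 * x + sqrt(1 - 0.64) * e
  dfc <- data.frame(x = x, y = y)
  gv <- compute_gvif(dfc, c("x", "y"))
  expect_equal(round(gv$table$gvif, 2), c(2.78, 2.78))
  expect_equal(gv$table$adjusted, sqrt(gv$table$gvif))  # df = 1
})

test_that("GVIF agrees with the car package on a categorical design", {
  skip_if_not_installed("car")
  set.seed(19)
  n <- 600
  w <- factor(sample(c("p1", "p2", "p3", "p4"), n, TRUE))
  z <- rnorm(n) + 0.6 * (w == "p4")
  grp <- factor(ifelse(z + rnorm(n) > 0.3, "g1", "g2"))
  df <- data.frame(y = rnorm(n), w = w, z = z, grp = grp)
  ours <- compute_gvif(df, c("w", "z", "grp"))
  ref <- car::vif(lm(y ~ w + z + grp, df))
  expect_equal(ours$table$gvif, unname(ref[, "GVIF"]), tolerance = 1e-8)
  expect_equal(ours$table$df, unname(ref[, "Df"]))
})

test_that("GVIF is invariant to the choice of reference level", {
  set.seed(20)
  for (rep in 1:50) {
    n <- 120
    a <- factor(sample(c("u", "v", "w"), n, TRUE))
    bcov <- factor(sample(c("m", "f"), n, TRUE))
    x <- rnorm(n) + (a == "v")
    df <- data.frame(a = a, b = bcov, x = x)
    g1 <- compute_gvif(df, c("a", "b", "x"))
    df2 <- df
    df2$a <- relevel(df2$a, sample(levels(df2$a), 1))
    df2$b <- relevel(df2$b, sample(levels(df2$b), 1))
    g2 <- compute_gvif(df2, c("a", "b", "x"))
    expect_equal(g1$table$gvif, g2$table$gvif, tolerance = 1e-8)
  }
})

test_that("near-duplicate covariates are flagged and dropping one clears flags", {
  set.seed(21)
  n <- 2000
  born <- pmin(rpois(n, 2), 4)
  alive <- pmax(born - rbinom(n, 1, 0.02), 0)     # r ~ 0.99
  df <- data.frame(born = factor(born), alive = factor(alive),
                   x = rnorm(n))
  gv <- compute_gvif(df, c("born", "alive", "x"))
  expect_true(all(c("born", "alive") %in% gv$flagged))
  gv2 <- compute_gvif(df, c("born", "x"))
  expect_length(gv2$flagged, 0)
})

test_that("rank-deficient designs report infinite GVIF with the collinear set", {
  set.seed(22)
  df <- data.frame(x = rnorm(50))
  df$y <- 2 * df$x            # exact collinearity
  df$z <- rnorm(50)
  gv <- compute_gvif(df, c("x", "y", "z"))
  expect_true(is.infinite(gv$table$gvif[gv$table$covariate == "x"]))
  expect_true(all(c("x", "y") %in% gv$collinear_set) ||
              all(c("y") %in% gv$collinear_set))
})

test_that("exceedance probabilities follow the draw-counting definition", {
  tf <- tiny_fit()
  fit <- tf$fit
  # graft controlled spatial draws onto the fit
  fit$b <- cbind(rep(0.3, 4), c(-0.1, 0.2, 0.3, 0.4), c(-1, -2, 1, 2))
  colnames(fit$b) <- paste0("b[", c("dA", "dB", "dC"), "]")
  fit$district_ids <- c("dA", "dB", "dC")
  ex <- exceedance(fit)
  expect_equal(ex$q, c(1, 0.75, 0.5))
  expect_equal(ex$elevated, c(TRUE, FALSE, FALSE))   # strict > 0.90

  # sorting oracle: q = 1 - ecdf(0)
  set.seed(23)
  draws <- matrix(rnorm(500 * 3, mean = c(-0.2, 0, 0.4)), 500, 3, byrow = TRUE)
  fit$b <- draws
  oracle <- apply(draws, 2, function(v) 1 - sum(sort(v) <= 0) / length(v))
  expect_equal(exceedance(fit)$q, unname(oracle))
  # symmetric draws sit near 0.5
  expect_lt(abs(exceedance(fit)$q[2] - 0.5), 2 / sqrt(500) * 0.5 + 0.05)

  fitno <- tf$fit
  expect_error(exceedance(fitno), "CAR")
})

test_that("district risk maps agree with a group-by oracle", {
  g <- lattice_graph(3, 3)
  ds <- simulate_survey(g, flat_truth(sigma_b = 0.5), n_per_district = 50,
                        covariate_mix = small_mix(), seed = 24)
  bundle <- build_design(ds, small_spec("CAR"), g)
  fit <- fit_spatial_logit(bundle, g, draws = 100, warmup = 50, seed = 10)
  risk <- district_risk_map(fit, bundle)
  expect_equal(risk$district, g$unit_ids)
  pp <- predict_probabilities(fit, bundle)
  for (j in c(1, 5, 9)) {
    sel <- bundle$district_index == j
    expect_equal(risk$p_mean[j], mean(pp$mean[sel]), tolerance = 1e-12)
    expect_equal(risk$b_mean[j], mean(fit$b[, j]), tolerance = 1e-12)
  }
  expect_true(all(risk$p_mean > 0 & risk$p_mean < 1))
})

test_that("districts with no records keep b summaries but NA probabilities", {
  g <- lattice_graph(2, 2)
  set.seed(25)
  df <- data.frame(outcome = rbinom(90, 1, 0.3),
                   grp = factor(sample(c("x", "y"), 90, TRUE)),
                   district = sample(g$unit_ids[1:3], 90, TRUE))
  spec <- model_spec(fixed = c(grp = "x"),
                     smooth = c(age_survey = "none", age_cohab = "none"),
                     random = "CAR")
  bundle <- build_design(df, spec, g)
  fit <- fit_spatial_logit(bundle, g, draws = 60, warmup = 30, seed = 11)
  risk <- district_risk_map(fit, bundle)
  empty <- which(risk$n_records == 0)
  expect_length(empty, 1)
  expect_true(is.na(risk$p_mean[empty]))
  expect_false(is.na(risk$b_mean[empty]))
})

test_that("a designed hot-spot district attains the highest posterior mean effect", {
  # moderate background field with one district's true effect set to +0.8:
  # that district should top the posterior mean b ranking
  g <- lattice_graph(8, 8)
  J <- 64; npd <- 300; hot_j <- 28          # interior district
  hits <- 0
  for (r in 1:5) {
    b_true <- sample_icar_field(g, 0.2, seed = 600 + r)
    b_true[hot_j] <- 0.8
    set.seed(700 + r)
    dist <- rep(seq_len(J), each = npd)
    rec <- data.frame(
      outcome = rbinom(J * npd, 1, plogis(qlogis(0.2) + b_true[dist])),
      residence = factor(sample(c("rural", "urban"), J * npd, TRUE),
                         c("rural", "urban")),
      occupation = factor(sample(c("not_working", "working"), J * npd, TRUE),
                          c("not_working", "working")),
      district = g$unit_ids[dist])
    bundle <- build_design(rec, small_spec("CAR"), g)
    fit <- fit_spatial_logit(bundle, g, draws = 250, warmup = 150,
                             seed = 800 + r)
    if (which.max(colMeans(fit$b)) == hot_j) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
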