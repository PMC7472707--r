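#' Descriptive characteristics table
#'
#' Builds a frequency table in the layout of a survey characteristics table:
#' for each level of each categorical covariate, the total frequency, the
#' column percentage, and the outcome-stratified frequencies with row
#' percentages; for each continuous covariate, the median and IQR overall and
#' within each outcome stratum. Percentages are rounded to 2 decimals. Counts
#' are unweighted by default (set `weighted = TRUE` for weight-summed
#' frequencies).
#'
#' @param dataset data.frame (or `synthetic_dataset`) with an `outcome`
#'   column; all factor/character columns except `district` are tabulated,
#'   all numeric columns except `outcome` / `weight` summarized.
#' @param weighted use sampling weights in the tallies.
#' @return List with `prevalence_percent`, `n`, `categorical` (data.frame:
#'   covariate, level, n, column_pct, n_yes, row_pct_yes, n_no, row_pct_no)
#'   and `continuous` (covariate, median, iqr, median_yes, iqr_yes,
#'   median_no, iqr_no).
#' @export
descriptive_table <- function(dataset, weighted = FALSE) {
  df <- if (inherits(dataset, "synthetic_dataset")) dataset$records else dataset
  if (!"outcome" %in% names(df)) stop("dataset needs an 'outcome' column")
  wt <- if (weighted && "weight" %in% names(df)) df$weight else rep(1, nrow(df))
  y <- df$outcome
  n_tot <- sum(wt)
  cat_cols <- names(df)[vapply(df, function(x) is.factor(x) || is.character(x), TRUE)]
  cat_cols <- setdiff(cat_cols, "district")
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                      c("outcome", "weight"))

  cat_rows <- list()
  for (cov in cat_cols) {
    x <- df[[cov]]
    lvls <- if (is.factor(x)) levels(x) else sort(unique(x))
    for (l in lvls) {
      in_l <- x == l
      n_l <- sum(wt[in_l])
      n_yes <- sum(wt[in_l & y == 1]); n_no <- sum(wt[in_l & y == 0])
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        covariate = cov, level = l, n = n_l,
        column_pct = round(100 * n_l / n_tot, 2),
        n_yes = n_yes, row_pct_yes = round(100 * n_yes / n_l, 2),
        n_no = n_no, row_pct_no = round(100 * n_no / n_l, 2))
    }
  }
  num_rows <- lapply(num_cols, function(cov) {
    v <- df[[cov]]
    iqr2 <- function(z) round(stats::IQR(z), 2)
    data.frame(covariate = cov,
               median = round(stats::median(v), 2), iqr = iqr2(v),
               median_yes = round(stats::median(v[y == 1]), 2),
               iqr_yes = iqr2(v[y == 1]),
               median_no = round(stats::median(v[y == 0]), 2),
               iqr_no = iqr2(v[y == 0]))
  })
  list(prevalence_percent = round(100 * sum(wt[y == 1]) / n_tot, 2),
       n = n_tot,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
       continuous = if (length(num_rows)) do.call(rbind, num_rows) else NULL)
}

#' Generalized variance inflation factors
#'
#' Screens a covariate set for multicollinearity with the generalized VIF:
#' with R the correlation matrix of all non-intercept design columns, R11 the
#' block of one covariate's own dummy columns and R22 the block of all other
#' columns, \deqn{GVIF = det(R_{11}) det(R_{22}) / det(R).}
#' The comparable per-coefficient scale is \eqn{GVIF^{1/(2 df)}}, flagged
#' against a threshold of 1.58 (the square root of the rule-of-thumb VIF 2.5).
#' Computed on the unweighted design. A rank-deficient design yields infinite
#' GVIF for the covariates in the collinear set, which is identified.
#'
#' @param dataset data.frame or `synthetic_dataset`.
#' @param covariates character vector (at least 2) of column names;
#'   categorical columns contribute their dummy block, numeric columns one
#'   column each.
#' @param threshold adjusted-scale cutoff (default 1.58).
#' @return A `gvif_report`: data.frame rows (covariate, gvif, df, adjusted),
#'   `threshold`, `flagged`, and `collinear_set` (character, possibly empty).
#' @export
compute_gvif <- function(dataset, covariates, threshold = 1.58) {
  df <- if (inherits(dataset, "synthetic_dataset")) dataset$records else dataset
  if (length(covariates) < 2) stop("need at least 2 covariates")
  blocks <- list()
  for (cov in covariates) {
    x <- df[[cov]]
    if (is.null(x)) stop("no column '", cov, "'")
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      m <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(m) <- paste(cov, levels(x)[-1], sep = ".")
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, cov))
    }
    blocks[[cov]] <- m
  }
  X <- do.call(cbind, blocks)
  R <- stats::cor(X)
  dets <- function(M) det(as.matrix(M))
  detR <- dets(R)
  idx <- split(seq_len(ncol(X)),
               rep(names(blocks), vapply(blocks, ncol, 1L)))[names(blocks)]
  rank_ok <- qr(X)$rank == ncol(X) && detR > 1e-12
  rows <- lapply(names(blocks), function(cov) {
    own <- idx[[cov]]; oth <- setdiff(seq_len(ncol(X)), own)
    dfree <- length(own)
    g <- if (rank_ok) dets(R[own, own, drop = FALSE]) *
                      dets(R[oth, oth, drop = FALSE]) / detR else Inf
    data.frame(covariate = cov, gvif = g, df = dfree,
               adjusted = g^(1 / (2 * dfree)))
  })
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  collinear_set <- character(0)
  if (!rank_ok) {
    # identify the involved covariates via the dropped pivots of the QR
    qrX <- qr(X)
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    collinear_set <- unique(unlist(lapply(names(idx), function(cov)
      if (any(colnames(X)[idx[[cov]]] %in% dropped)) cov)))
    tab$gvif <- ifelse(tab$covariate %in% collinear_set, Inf, tab$gvif)
    tab$adjusted <- ifelse(tab$covariate %in% collinear_set, Inf, tab$adjusted)
  }
  structure(list(table = tab, threshold = threshold,
                 flagged = tab$covariate[tab$adjusted >= threshold],
                 collinear_set = collinear_set),
            class = "gvif_report")
}

#' @export
print.gvif_report <- function(x, ...) {
  print(transform(x$table, gvif = round(gvif, 2), adjusted = round(adjusted, 2)))
  if (length(x$flagged))
    cat("flagged (adjusted >=", x$threshold, "):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Exceedance probabilities of the spatial random effects
#'
#' For each district, the posterior probability that its residual relative
#' risk multiplier exceeds 1, \eqn{q_j = P(e^{b_j} > 1) = P(b_j > 0)},
#' estimated as the fraction of posterior draws with positive b. Districts
#' with q above the cutoff are flagged as having significantly elevated
#' residual risk.
#'
#' @param fit a `spatlogit_fit` containing CAR draws.
#' @param cutoff flag threshold (strict inequality; default 0.90).
#' @return A data.frame: district, q, elevated.
#' @export
exceedance <- function(fit, cutoff = 0.90) {
  if (!ncol(fit$b))
    stop("exceedance requires a CAR fit (no spatial random-effect draws)")
  q <- colMeans(fit$b > 0)
  data.frame(district = fit$district_ids, q = as.numeric(q),
             elevated = as.numeric(q) > cutoff, row.names = NULL)
}

#' District-level risk-map summary
#'
#' Per-district posterior mean and sd of the spatial effect b, exceedance
#' probability and elevated flag, and the mean and sd (over that district's
#' records) of the per-record posterior predictive probabilities of the
#' outcome. Districts with no records keep their b summaries but carry NA
#' probability fields.
#'
#' @param fit a CAR `spatlogit_fit`.
#' @param bundle the matching `design_bundle`.
#' @param cutoff exceedance flag cutoff.
#' @return A data.frame keyed by district: b_mean, b_sd, q, elevated,
#'   p_mean, p_sd, n_records.
#' @export
district_risk_map <- function(fit, bundle, cutoff = 0.90) {
  if (!ncol(fit$b)) stop("district_risk_map requires a CAR fit")
  ex <- exceedance(fit, cutoff)
  pp <- predict_probabilities(fit, bundle)
  J <- length(fit$district_ids)
  p_mean <- p_sd <- rep(NA_real_, J)
  nrec <- tabulate(bundle$district_index, nbins = J)
  for (j in which(nrec > 0)) {
    sel <- bundle$district_index == j
    p_mean[j] <- mean(pp$mean[sel])
    p_sd[j] <- if (sum(sel) > 1) stats::sd(pp$mean[sel]) else 0
  }
  data.frame(district = fit$district_ids,
             b_mean = colMeans(fit$b), b_sd = apply(fit$b, 2, stats::sd),
             q = ex$q, elevated = ex$elevated,
             p_mean = p_mean, p_sd = p_sd, n_records = nrec, row.names = NULL)
}

#' Write a district risk map as CSV
#' @param risk data.frame from [district_risk_map()]; @param path CSV path.
#' @export
write_risk_map <- function(risk, path) {
  utils::write.csv(risk, path, row.names = FALSE)
  invisible(path)
}
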