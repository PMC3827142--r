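# Statistical linkage stage: trend testing and detrending of the yearly
# series, arcsin transformation of diet fractions, backward covariate
# elimination on small-sample corrected AIC, and a final regression with
# autoregressive errors for the chick-size ~ larval-supply relationship.

#' Linear trend test of a yearly series
#'
#' OLS slope of the series on year with its two-sided p-value. A constant
#' series returns slope 0 with p = 1 by convention.
#'
#' @param y yearly values
#' @param year optional year vector (default 1..n)
#' @return list: slope, p_value, intercept
#' @export
trend_test <- function(y, year = seq_along(y)) {
  stopifnot(length(y) == length(year), length(y) >= 4)
  if (stats::sd(y) == 0) {
    return(list(slope = 0, p_value = 1, intercept = y[1]))
  }
  fit <- stats::lm(y ~ year)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["year", "Estimate"]),
       p_value = unname(sm["year", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]))
}

#' Detrend a yearly series
#'
#' Residuals from the OLS regression of the series on year; their mean is
#' exactly zero and detrending is idempotent.
#'
#' @inheritParams trend_test
#' @return residual series, same length as `y`
#' @export
detrend <- function(y, year = seq_along(y)) {
  stopifnot(length(y) >= 3)
  as.numeric(stats::residuals(stats::lm(y ~ year)))
}

#' Arcsin transform of a proportion
#'
#' The variance-stabilising `asin(sqrt(p))` by default; `sqrt = FALSE`
#' gives the plain `asin(p)` variant.
#'
#' @param p proportions in [0, 1]
#' @param sqrt take the square root first (default TRUE)
#' @return transformed values (radians; 0 maps to 0, 1 to pi/2)
#' @export
arcsin_fraction <- function(p, sqrt = TRUE) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  if (sqrt) asin(base::sqrt(p)) else asin(p)
}

# small-sample corrected AIC of an lm fit; k counts all estimated
# parameters (coefficients + error variance)
aicc_lm <- function(fit) {
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1
  if (n - k - 1 <= 0) {
    stop("too few observations for the AICc correction at ", k, " parameters")
  }
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Backward covariate elimination on AICc
#'
#' Starting from the full OLS model, repeatedly removes the covariate
#' whose removal most reduces the small-sample corrected AIC; stops when
#' no removal reduces it. Each accepted step is recorded (removed
#' covariate, remaining parameter count Np, AICc, adjusted R-squared, and
#' the removal p-value from the model before removal), mirroring a
#' GLMSELECT-style backstep ledger. The final model's coefficients are
#' reported with SE, t and p.
#'
#' @param table data.frame with the response and candidate columns (one
#'   row per year)
#' @param response response column name
#' @param candidates candidate covariate column names
#' @return list of class `selection_path`: `steps` (data.frame), `selected`
#'   (character), `final_fit` (lm), `coefficients` (data.frame)
#' @export
backward_aicc_select <- function(table, response, candidates) {
  stopifnot(all(c(response, candidates) %in% names(table)),
            !anyDuplicated(table$year))
  n <- nrow(table)
  if (n < length(candidates) + 3) {
    stop("need at least p + 3 rows for a p-covariate fit")
  }
  X <- as.matrix(table[, candidates, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("collinear candidates: ", paste(candidates[dropped], collapse = ", "))
  }
  form <- function(vars) {
    stats::as.formula(paste(response, "~",
                            if (length(vars)) paste(vars, collapse = " + ")
                            else "1"))
  }
  current <- candidates
  fit <- stats::lm(form(current), data = table)
  steps <- data.frame(step = 0L, removed = "(full model)",
                      np = length(stats::coef(fit)),
                      aicc = aicc_lm(fit),
                      adj_r2 = summary(fit)$adj.r.squared,
                      removal_p = NA_real_)
  step <- 0L
  repeat {
    if (length(current) == 0) break
    cand_aicc <- vapply(current, function(v) {
      aicc_lm(stats::lm(form(setdiff(current, v)), data = table))
    }, numeric(1))
    best <- names(which.min(cand_aicc))
    if (cand_aicc[best] >= steps$aicc[nrow(steps)]) break
    # p-value of the variable about to be removed, from the current model
    sm <- summary(fit)$coefficients
    removal_p <- if (best %in% rownames(sm)) sm[best, "Pr(>|t|)"] else NA_real_
    current <- setdiff(current, best)
    fit <- stats::lm(form(current), data = table)
    step <- step + 1L
    steps <- rbind(steps, data.frame(
      step = step, removed = best, np = length(stats::coef(fit)),
      aicc = unname(cand_aicc[best]),
      adj_r2 = summary(fit)$adj.r.squared,
      removal_p = unname(removal_p)
    ))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  structure(list(steps = steps, selected = current, final_fit = fit,
                 coefficients = coefs),
            class = "selection_path")
}

#' @export
print.selection_path <- function(x, ...) {
  cat("Backward AICc selection\n")
  print(x$steps, row.names = FALSE)
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Regression with autoregressive errors
#'
#' Fits `response = a + b*covariate + e`, `e` an AR(order) process, by
#' maximum likelihood (via [stats::arima()]). With order 0 this reduces
#' exactly to OLS. Explained variance is the squared correlation between
#' the one-step fitted values (observed minus innovation residuals) and
#' the observations, matching a predicted-vs-observed reading.
#'
#' @param response yearly response vector
#' @param covariate yearly covariate vector (same length)
#' @param order AR order (default 2)
#' @return list of class `ar_fit`: `beta`, `beta_se`, `intercept`,
#'   `ar_coef`, `sigma2`, `explained_variance`, `fitted`, `residuals`,
#'   `arch_lm_p` (heteroscedasticity screen, lags 1-2; reported, never
#'   gating), `n`, `order`
#' @export
ar_error_fit <- function(response, covariate, order = 2L) {
  stopifnot(length(response) == length(covariate))
  n <- length(response)
  if (n < order + 4) stop("need at least order + 4 observations")
  fit <- tryCatch(
    stats::arima(response, order = c(order, 0L, 0L),
                 xreg = matrix(covariate, ncol = 1,
                               dimnames = list(NULL, "covariate")),
                 include.mean = TRUE, method = "ML"),
    error = function(e) stop("AR fit did not converge: ",
                             conditionMessage(e))
  )
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  beta <- unname(co["covariate"])
  beta_se <- unname(se["covariate"])
  res <- as.numeric(stats::residuals(fit))
  fitted <- response - res
  ev <- if (stats::sd(fitted) > 0) stats::cor(fitted, response)^2 else 0
  # ARCH LM screen: regress squared residuals on lags 1-2
  arch_p <- NA_real_
  if (n >= 8) {
    r2 <- res^2
    d <- data.frame(y = r2[3:n], l1 = r2[2:(n - 1)], l2 = r2[1:(n - 2)])
    lmfit <- stats::lm(y ~ l1 + l2, data = d)
    r2s <- summary(lmfit)$r.squared
    stat <- length(d$y) * r2s
    arch_p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  }
  structure(list(beta = beta, beta_se = beta_se,
                 intercept = unname(co["intercept"]),
                 ar_coef = if (order > 0) unname(co[seq_len(order)])
                           else numeric(0),
                 sigma2 = fit$sigma2,
                 explained_variance = ev,
                 fitted = fitted, residuals = res,
                 arch_lm_p = arch_p, n = n, order = order),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d)-error regression (n = %d)\n", x$order, x$n))
  cat(sprintf("  beta = %.4g +/- %.4g (SE)\n", x$beta, x$beta_se))
  if (length(x$ar_coef)) {
    cat("  AR coefficients:", paste(sprintf("%.3f", x$ar_coef),
                                    collapse = ", "), "\n")
  }
  cat(sprintf("  explained variance = %.3f\n", x$explained_variance))
  invisible(x)
}

#' Squared Pearson correlation with p-value
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant)
#' @return list: r2, p_value, r
#' @export
pairwise_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pairwise_r2: zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r2 = unname(ct$estimate^2), p_value = ct$p.value,
       r = unname(ct$estimate))
}
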