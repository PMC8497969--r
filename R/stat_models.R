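# Inferential machinery: OLS and random-intercept fits wrapped in a common
# FitResult, pairwise timepoint contrasts, mean-centering, AIC/log-likelihood
# model comparison, and the three-step residualization procedure for
# disentangling collinear input predictors (a Frisch-Waugh-Lovell
# construction: the coefficient on resid(x1|x2) alongside x2 equals the
# coefficient on x1 in the joint model).

#' Fit an ordinary least-squares model
#'
#' Thin wrapper over [stats::lm()] returning the package's common fit
#' container. When a model mixes nested rows (one per word type) with
#' broadcast session-level covariates, name those covariates in
#' `unnested_terms`: their standard errors and p-values are artificially
#' deflated by the repeated rows, so they are suppressed (`NA`) and the fit
#' carries an `inflated_alpha` flag.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param unnested_terms character vector of coefficient names whose
#'   SE/t/p/CI must be suppressed in a nested-row model.
#' @return object of class `cds_fit`: list with `coefficients`, `se`, `t`,
#'   `p`, `ci` (95%), `residuals`, `fitted`, `logLik`, `k` (parameter count
#'   including the error variance), `AIC`, `n`, `sigma`,
#'   `inflated_alpha`, and the underlying `model`.
#' @export
fit_ols <- function(formula, data, unnested_terms = character(0)) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(formula, data = data)
  as_cds_fit(fit, unnested_terms = unnested_terms)
}

as_cds_fit <- function(fit, unnested_terms = character(0)) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  beta <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  tval <- co[, "t value"]
  pval <- co[, ncol(co)]
  df_res <- fit$df.residual
  tcrit <- stats::qt(0.975, df_res)
  ci <- cbind(lower = beta - tcrit * se, upper = beta + tcrit * se)
  if (length(unnested_terms) > 0) {
    bad <- setdiff(unnested_terms, names(beta))
    if (length(bad) > 0) {
      stop("unnested_terms not in the model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    hit <- names(beta) %in% unnested_terms
    se[hit] <- NA_real_; tval[hit] <- NA_real_; pval[hit] <- NA_real_
    ci[hit, ] <- NA_real_
  }
  ll <- stats::logLik(fit)
  structure(list(coefficients = beta, se = se, t = tval, p = pval, ci = ci,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 logLik = as.numeric(ll), k = attr(ll, "df"),
                 AIC = 2 * attr(ll, "df") - 2 * as.numeric(ll),
                 n = stats::nobs(fit), df_residual = df_res,
                 sigma = sm$sigma,
                 inflated_alpha = length(unnested_terms) > 0,
                 random_intercept_var = NA_real_,
                 model = fit),
            class = "cds_fit")
}

#' @export
print.cds_fit <- function(x, ...) {
  cat(sprintf("<cds_fit> n = %d, k = %d, logLik = %.3f, AIC = %.3f%s\n",
              x$n, x$k, x$logLik, x$AIC,
              if (isTRUE(x$inflated_alpha)) " [inflated-alpha: SE/p suppressed for unnested terms]" else ""))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Fit a linear model with a dyad random intercept
#'
#' REML fit of `response ~ fixed effects + (1 | group)` via
#' [lme4::lmer()], returned in the common fit container. Fixed-effect
#' p-values use a residual-df t approximation (`df = n - k_fixed`); they
#' are approximate by construction and flagged as such by this choice.
#'
#' @param formula fixed-effects formula (no random-effects term).
#' @param data data frame.
#' @param group name of the grouping-factor column (the dyad).
#' @return a `cds_fit` whose `random_intercept_var` holds the estimated
#'   between-group variance (`sigma` holds the residual SD).
#' @export
fit_random_intercept <- function(formula, data, group = "dyad_id") {
  if (length(unique(data[[group]])) < 2) {
    stop("need at least two groups for a random intercept", call. = FALSE)
  }
  full <- stats::update(formula,
                        paste(". ~ . + (1 |", group, ")"))
  fit <- lme4::lmer(full, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- beta / se
  n <- stats::nobs(fit)
  df_res <- n - length(beta)
  pval <- 2 * stats::pt(-abs(tval), df_res)
  tcrit <- stats::qt(0.975, df_res)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == group & vc$var1 == "(Intercept)" & is.na(vc$var2)]
  ll <- stats::logLik(fit)
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 ci = cbind(lower = beta - tcrit * se, upper = beta + tcrit * se),
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 logLik = as.numeric(ll), k = attr(ll, "df"),
                 AIC = 2 * attr(ll, "df") - 2 * as.numeric(ll),
                 n = n, df_residual = df_res,
                 sigma = stats::sigma(fit),
                 inflated_alpha = FALSE,
                 random_intercept_var = ri_var,
                 model = fit),
            class = "cds_fit")
}

#' Pairwise timepoint contrasts from a fitted model
#'
#' All pairwise differences between the levels of a categorical predictor
#' (typically timepoint), with t tests on the fit's residual df and Holm
#' adjustment of the p-values by default.
#'
#' @param fit a `cds_fit` whose model contains `factor_name` as a factor
#'   fixed effect.
#' @param factor_name name of the factor column.
#' @param adjust `"holm"` (default) or `"none"`.
#' @return data frame with one row per level pair: `level1`, `level2`,
#'   `estimate` (level2 minus level1), `se`, `t`, `p`, `p_adj`.
#' @export
timepoint_contrasts <- function(fit, factor_name = "timepoint",
                                adjust = c("holm", "none")) {
  adjust <- match.arg(adjust)
  beta <- fit$coefficients
  V <- as.matrix(stats::vcov(fit$model))
  xlev <- tryCatch(fit$model@frame[[factor_name]],
                   error = function(e) fit$model$model[[factor_name]])
  if (is.null(xlev)) stop("factor '", factor_name, "' not found in the fit",
                          call. = FALSE)
  levs <- levels(as.factor(xlev))
  coef_of <- function(lv) {
    nm <- paste0(factor_name, lv)
    v <- numeric(length(beta)); names(v) <- names(beta)
    if (nm %in% names(beta)) v[nm] <- 1
    v
  }
  pairs <- utils::combn(levs, 2)
  out <- data.frame(level1 = pairs[1, ], level2 = pairs[2, ],
                    estimate = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    L <- coef_of(pairs[2, k]) - coef_of(pairs[1, k])
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tv <- est / se
    out$estimate[k] <- est; out$se[k] <- se; out$t[k] <- tv
    out$p[k] <- 2 * stats::pt(-abs(tv), fit$df_residual)
  }
  out$p_adj <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out
}

#' Residualize one predictor on another
#'
#' Residuals of the OLS regression of `x` on `z` (plus intercept and any
#' covariates): the part of `x` not attributable to `z`. The result is
#' orthogonal to `z`, to each covariate, and to the constant.
#'
#' @param x numeric vector to residualize.
#' @param z numeric vector to residualize on.
#' @param covariates optional data frame or matrix of further columns to
#'   partial out.
#' @return numeric residual vector of the same length as `x`.
#' @export
residualize <- function(x, z, covariates = NULL) {
  if (length(x) != length(z)) stop("x and z differ in length", call. = FALSE)
  if (stats::sd(z) == 0) stop("z is constant; residualization undefined", call. = FALSE)
  df <- data.frame(.x = x, .z = z)
  rhs <- ".z"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    rhs <- paste(c(".z", names(covariates)), collapse = " + ")
  }
  stats::residuals(stats::lm(stats::as.formula(paste(".x ~", rhs)), data = df))
}

#' Disentangle two collinear predictors of an outcome
#'
#' The three-step residualization procedure: (1) regress each member of the
#' correlated pair on the other and keep the residuals; (2) fit the outcome
#' on the residuals plus the ambiguous (raw) other parameter and any
#' covariates, in both directions; (3) classify by which residual terms
#' reach significance at `alpha` — both directions significant = `both`,
#' only the x1 residual = `x1_direct` (the x1 effect is direct, the x2
#' effect is carried by x1), only the x2 residual = `x2_direct`, neither =
#' `neither`.
#'
#' @param data data frame holding all columns.
#' @param x1,x2 names of the correlated predictor columns.
#' @param y name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `cds_disentangle`: list with the two `cds_fit`s
#'   (`fit_resid_x1`, `fit_resid_x2`), the residual-term p-values
#'   (`p_resid_x1`, `p_resid_x2`), the observed `cor_x1_x2` and
#'   `classification`.
#' @export
disentangle <- function(data, x1, x2, y, covariates = character(0),
                        alpha = 0.05) {
  r <- stats::cor(data[[x1]], data[[x2]])
  if (abs(r) < 0.1) {
    warning(sprintf("|cor(%s, %s)| = %.3f < 0.1: predictors are barely collinear; residualization is unnecessary",
                    x1, x2, abs(r)), call. = FALSE)
  }
  covs <- if (length(covariates) > 0) data[, covariates, drop = FALSE] else NULL
  one_direction <- function(xa, xb) {
    # residuals of xa on xb, modeled next to raw xb
    d <- data.frame(.y = data[[y]],
                    resid_term = residualize(data[[xa]], data[[xb]]),
                    ambiguous = data[[xb]])
    rhs <- c("resid_term", "ambiguous", covariates)
    if (!is.null(covs)) d <- cbind(d, covs)
    fit_ols(stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "))), d)
  }
  f1 <- one_direction(x1, x2)
  f2 <- one_direction(x2, x1)
  p1 <- f1$p["resid_term"]
  p2 <- f2$p["resid_term"]
  s1 <- !is.na(p1) && p1 < alpha
  s2 <- !is.na(p2) && p2 < alpha
  classification <- if (s1 && s2) "both" else if (s1) "x1_direct"
    else if (s2) "x2_direct" else "neither"
  structure(list(x1 = x1, x2 = x2, y = y, alpha = alpha,
                 cor_x1_x2 = r,
                 fit_resid_x1 = f1, fit_resid_x2 = f2,
                 p_resid_x1 = unname(p1), p_resid_x2 = unname(p2),
                 classification = classification),
            class = "cds_disentangle")
}

#' @export
print.cds_disentangle <- function(x, ...) {
  cat(sprintf("<cds_disentangle> %s vs %s -> %s (r = %.2f)\n  p[resid(%s|%s)] = %.4g, p[resid(%s|%s)] = %.4g, alpha = %g\n",
              x$x1, x$x2, x$classification, x$cor_x1_x2,
              x$x1, x$x2, x$p_resid_x1, x$x2, x$x1, x$p_resid_x2, x$alpha))
  invisible(x)
}

#' Unnest a per-type statistic by a pooled median split
#'
#' Converts a nested per-word-type column (many observations per caregiver)
#' into one count per caregiver, so it can be compared directly with
#' unnested parameters such as the number of word types: with comparator
#' `"ge"` counts values at or above the pooled median (long words), with
#' `"lt"` counts values strictly below it (low-frequency words).
#'
#' @param per_caregiver_values named list of numeric vectors, one per
#'   caregiver (per-type word lengths or log frequencies).
#' @param comparator `"ge"` or `"lt"`.
#' @param pooled_median optional; computed with [pooled_type_median()] over
#'   the supplied caregivers when missing.
#' @return data frame with `caregiver`, `count` and the `pooled_median`
#'   attribute.
#' @export
unnest_by_median <- function(per_caregiver_values, comparator = c("ge", "lt"),
                             pooled_median = NULL) {
  comparator <- match.arg(comparator)
  if (is.null(pooled_median)) {
    pooled_median <- pooled_type_median(per_caregiver_values)
  }
  counter <- if (comparator == "ge") long_word_count else low_freq_count
  counts <- vapply(per_caregiver_values, counter, numeric(1),
                   pooled_median)
  out <- data.frame(caregiver = names(per_caregiver_values),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  attr(out, "pooled_median") <- pooled_median
  out
}

#' Compare fitted models by AIC and likelihood-ratio tests
#'
#' Ranks fits of the same response by AIC; for each pair nested by
#' parameter count, reports the likelihood-ratio statistic 2 * delta-logLik
#' with a chi-squared p-value. All fits must share the number of
#' observations.
#'
#' @param fits named list of `cds_fit` objects.
#' @return list with `ranking` (data frame `model`, `k`, `logLik`, `AIC`,
#'   `delta_AIC`, best first) and `lrt` (data frame of nested-pair tests).
#' @export
compare_models <- function(fits) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("models fit to differing numbers of observations", call. = FALSE)
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  tab <- data.frame(model = nm,
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  lrt <- NULL
  if (length(fits) > 1) {
    cmb <- utils::combn(length(fits), 2)
    rows <- list()
    for (j in seq_len(ncol(cmb))) {
      a <- fits[[cmb[1, j]]]; b <- fits[[cmb[2, j]]]
      if (a$k == b$k) next
      small <- if (a$k < b$k) a else b
      big <- if (a$k < b$k) b else a
      stat <- 2 * (big$logLik - small$logLik)
      df <- big$k - small$k
      rows[[length(rows) + 1L]] <-
        data.frame(smaller = nm[cmb[if (a$k < b$k) 1 else 2, j]],
                   larger = nm[cmb[if (a$k < b$k) 2 else 1, j]],
                   statistic = stat, df = df,
                   p = stats::pchisq(stat, df, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) lrt <- do.call(rbind, rows)
  }
  list(ranking = tab, lrt = lrt)
}

#' Mean-center columns of a data frame
#'
#' @param data data frame.
#' @param columns character vector of numeric column names to center; all
#'   numeric columns when missing.
#' @return the data frame with the named columns centered to mean zero.
#' @export
mean_center <- function(data, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (cn in columns) {
    data[[cn]] <- data[[cn]] - mean(data[[cn]], na.rm = TRUE)
  }
  data
}
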