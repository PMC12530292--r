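# Variable pruning and mixed-model fitting for the path analysis.

is_cv_name <- function(x) startsWith(x, "cv_") | startsWith(x, "cv-")

#' Remove highly correlated variables
#'
#' Greedy pruning of variable pairs with \code{|Pearson r| > r_max}
#' (strict). Pairs are processed from the highest \code{|r|} down; from each
#' pair the CV member is dropped in preference to the mean member
#' (\code{cv_} prefix convention); when both are the same kind the
#' alphabetically later name is dropped. Constant columns are removed first
#' with a warning (their correlation is undefined).
#'
#' @param data data.frame holding the variables.
#' @param vars variable names to consider (default: all numeric columns).
#' @param r_max threshold (default 0.70).
#' @return character vector of retained variable names.
#' @export
prune_correlated <- function(data, vars = NULL, r_max = 0.70) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  if (length(vars) < 2L) stop("need >= 2 variables", call. = FALSE)
  ok <- vapply(vars, function(v) {
    x <- data[[v]]
    stats::var(x, na.rm = TRUE) > 0
  }, logical(1))
  if (any(!ok)) {
    warning("removing constant column(s): ",
            paste(vars[!ok], collapse = ", "), call. = FALSE)
    vars <- vars[ok]
  }
  retained <- sort(vars)
  repeat {
    if (length(retained) < 2L) break
    cm <- abs(stats::cor(data[retained], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= r_max) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    a <- retained[min(idx)]; b <- retained[max(idx)]
    drop <- if (is_cv_name(a) && !is_cv_name(b)) a
            else if (is_cv_name(b) && !is_cv_name(a)) b
            else max(a, b) # alphabetically later
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Sequential variance-inflation-factor pruning
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} comes from the ordinary
#' least-squares regression of predictor j on the remaining predictors.
#' The largest VIF above \code{threshold} is dropped and VIFs recomputed
#' until all are at or below the threshold. On (numerically) tied maxima
#' the CV member is dropped in preference to a mean variable, then
#' alphabetically later names first.
#'
#' @param data data.frame holding the predictors.
#' @param predictors predictor names.
#' @param threshold VIF threshold (default 5).
#' @return character vector of retained predictor names, with the final
#'   VIFs attached as attribute \code{vif}.
#' @export
vif_prune <- function(data, predictors, threshold = 5) {
  if (length(predictors) < 2L) stop("need >= 2 predictors", call. = FALSE)
  keep <- sort(predictors)
  vif_of <- function(v, others) {
    fit <- stats::lm(stats::reformulate(others, response = v), data = data)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) < 2L) break
    vifs <- vapply(keep, function(v) vif_of(v, setdiff(keep, v)), numeric(1))
    mx <- max(vifs)
    if (mx <= threshold) break
    cand <- keep[vifs >= mx - 1e-8]
    if (any(is_cv_name(cand)) && !all(is_cv_name(cand))) {
      cand <- cand[is_cv_name(cand)]
    }
    keep <- setdiff(keep, max(cand))
  }
  vifs <- if (length(keep) >= 2L) {
    vapply(keep, function(v) vif_of(v, setdiff(keep, v)), numeric(1))
  } else stats::setNames(rep(1, length(keep)), keep)
  structure(keep, vif = vifs)
}

#' Fit a linear mixed model with crossed random intercepts
#'
#' REML fit of \code{response ~ predictors + (1|site) + (1|year)} (crossed,
#' not nested). Fixed-effect p-values use the large-sample normal
#' approximation on the t-ratios. Random factors with a single observed
#' level are dropped with a note in the record.
#'
#' @param response response variable name.
#' @param predictors character vector of fixed-predictor names (may be
#'   empty for an intercept-only model).
#' @param data model data.frame containing response, predictors and the
#'   random factors.
#' @param random random-intercept factor names (default
#'   \code{c("site", "year")}).
#' @return a \code{fit_record}: list with \code{response},
#'   \code{predictors}, \code{coefficients} (data.frame term, estimate, se,
#'   t, p), \code{varcomp} (named vector incl. \code{resid}),
#'   \code{singular}, \code{model} (the lme4 fit or lm fallback), \code{n},
#'   \code{data}.
#' @export
fit_lmm <- function(response, predictors, data,
                    random = c("site", "year")) {
  stop_if_missing_cols(data, c(response, predictors), "model data")
  for (p in predictors) {
    if (stats::var(data[[p]], na.rm = TRUE) == 0) {
      stop("constant predictor: ", p, call. = FALSE)
    }
  }
  usable <- random[vapply(random, function(r) {
    r %in% names(data) && length(unique(data[[r]])) > 1L
  }, logical(1))]
  fx <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (length(usable)) {
    fml <- stats::as.formula(paste(
      response, "~", fx, "+",
      paste(sprintf("(1 | %s)", usable), collapse = " + ")))
    fit <- lme4::lmer(fml, data = data, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    singular <- lme4::isSingular(fit, tol = 1e-5)
    co <- as.data.frame(summary(fit)$coefficients)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                               "resid", vc$grp))
    for (r in setdiff(random, usable)) varcomp[[r]] <- 0
  } else {
    fit <- stats::lm(stats::as.formula(paste(response, "~", fx)),
                     data = data)
    singular <- FALSE
    co <- as.data.frame(summary(fit)$coefficients)[, 1:3]
    varcomp <- c(resid = summary(fit)$sigma^2)
    for (r in random) varcomp[[r]] <- 0
  }
  coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                      se = co[, 2], t = co[, 3],
                      p = 2 * stats::pnorm(-abs(co[, 3])),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(response = response, predictors = predictors,
                 coefficients = coefs, varcomp = varcomp,
                 singular = singular, model = fit,
                 n = nrow(data), data = data),
            class = "fit_record")
}

#' @export
print.fit_record <- function(x, ...) {
  cat(sprintf("fit_record: %s ~ %s (n = %d%s)\n", x$response,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1", x$n, if (x$singular) ", singular fit" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Standardized fixed-effect estimates
#'
#' \eqn{\beta_{std} = \beta_{raw} \cdot SD(x) / SD(y)} with sample SDs taken
#' over the modelling data.
#'
#' @param fit a \code{fit_record}.
#' @param data data used for the SDs (default: the fit's data).
#' @return coefficient data.frame with an extra \code{std_estimate} column
#'   (NA for the intercept).
#' @export
standardized_estimates <- function(fit, data = fit$data) {
  sy <- stats::sd(data[[fit$response]])
  if (sy == 0) stop("zero-variance response", call. = FALSE)
  co <- fit$coefficients
  co$std_estimate <- NA_real_
  for (i in seq_len(nrow(co))) {
    term <- co$term[i]
    if (term %in% names(data)) {
      co$std_estimate[i] <- co$estimate[i] * stats::sd(data[[term]]) / sy
    }
  }
  co
}

#' Marginal and conditional R-squared of a mixed fit
#'
#' Variance-partition R²: marginal uses the fixed-effect variance over the
#' total (fixed + random intercept + residual) variance; conditional adds
#' the random-intercept variances to the numerator.
#'
#' @param fit a \code{fit_record}.
#' @return named numeric vector \code{c(marginal, conditional)}.
#' @export
r2_mixed <- function(fit) {
  co <- fit$coefficients
  terms <- co$term[co$term %in% names(fit$data)]
  var_f <- if (!length(terms)) 0 else {
    X <- as.matrix(fit$data[terms])
    b <- co$estimate[match(terms, co$term)]
    stats::var(as.numeric(X %*% b))
  }
  vr <- fit$varcomp
  resid <- vr[["resid"]]
  vrand <- sum(vr[setdiff(names(vr), "resid")])
  tot <- var_f + vrand + resid
  c(marginal = var_f / tot, conditional = (var_f + vrand) / tot)
}
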