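# Seasonal contrasts for the ecological-opportunity variables retained by
# the path models: mixed model with a seasonal fixed factor and site/year
# random intercepts, then Tukey-adjusted pairwise contrasts of estimated
# marginal means.

#' Seasonal mixed model for one campaign-level variable
#'
#' Fits \code{value ~ season + (1|site) + (1|year)}. Season comes from the
#' metadata, never from dates. Prey abundance variables should be ln+1
#' transformed (\code{\link{ln1p}}) before calling.
#'
#' @param data data.frame with columns \code{season}, \code{site},
#'   \code{year} and the variable.
#' @param variable variable (column) name.
#' @return list with the lme4 fit (\code{model}), \code{variable} and the
#'   season levels. A single observed season is an error.
#' @export
season_model <- function(data, variable) {
  stop_if_missing_cols(data, c(variable, "season", "site", "year"),
                       "seasonal data")
  data$season <- factor(data$season)
  if (nlevels(data$season) < 2L) {
    stop("need >= 2 seasons", call. = FALSE)
  }
  usable <- c("site", "year")[vapply(c("site", "year"), function(r)
    length(unique(data[[r]])) > 1L, logical(1))]
  fml <- stats::as.formula(paste(
    variable, "~ season",
    if (length(usable)) paste("+", paste(sprintf("(1 | %s)", usable),
                                         collapse = " + ")) else ""))
  fit <- if (length(usable)) {
    lme4::lmer(fml, data = data, REML = TRUE)
  } else {
    stats::lm(fml, data = data)
  }
  list(model = fit, variable = variable, seasons = levels(data$season),
       data = data)
}

#' Tukey-adjusted pairwise season contrasts
#'
#' All pairwise differences of estimated marginal means between seasons,
#' with a familywise multivariate-t (Tukey-style) adjustment;
#' \code{adjust = "bonferroni"} is the configurable fallback.
#'
#' @param fit output of \code{\link{season_model}}.
#' @param adjust p-value adjustment (default \code{"tukey"}).
#' @return data.frame \code{variable, season_a, season_b, estimate, p_adj,
#'   code} with significance codes *** (< 0.001), ** (< 0.01), * (< 0.05),
#'   ns.
#' @export
pairwise_seasons <- function(fit, adjust = c("tukey", "bonferroni")) {
  adjust <- match.arg(adjust)
  emm <- emmeans::emmeans(fit$model, "season", data = fit$data,
                          lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = adjust),
                 infer = c(FALSE, TRUE))
  labs <- strsplit(as.character(prs$contrast), " - ", fixed = TRUE)
  data.frame(
    variable = fit$variable,
    season_a = vapply(labs, `[`, "", 1L),
    season_b = vapply(labs, `[`, "", 2L),
    estimate = prs$estimate,
    p_adj = prs$p.value,
    code = significance_code(prs$p.value),
    stringsAsFactors = FALSE
  )
}

significance_code <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Display residuals for seasonal plots
#'
#' Residuals from \code{lm(y ~ site + year)}, the detrended values used to
#' visualise seasonal patterns net of spatial and annual effects.
#'
#' @inheritParams season_model
#' @return data.frame \code{season, residual}.
#' @export
seasonal_residuals <- function(data, variable) {
  fml <- stats::as.formula(paste(variable, "~ factor(site) + factor(year)"))
  data.frame(season = data$season,
             residual = stats::resid(stats::lm(fml, data = data)),
             stringsAsFactors = FALSE)
}
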