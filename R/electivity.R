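# Prey electivity via Monte-Carlo null models.
#
# For each campaign, every individual's total MNI is redistributed over the
# tested taxa by a multinomial draw with probabilities proportional to local
# prey availability; the per-taxon statistic (summed consumption by default)
# is aggregated over individuals. Observed consumption is classified against
# the 95% envelope of the simulated distribution: above the upper quantile
# is positive electivity, below the lower is negative, otherwise neutral
# (ties at the boundary count as inside the interval).

#' Null distribution of prey consumption
#'
#' @param diets MNI count matrix (individuals x taxa) for one campaign;
#'   every row must have a positive total.
#' @param availability per-taxon relative abundance, aligned with the diet
#'   columns (non-negative, at least one positive). Only relative magnitude
#'   matters. Taxa consumed but with zero availability receive a
#'   pseudo-availability of half the smallest nonzero value, with a warning.
#' @param n_sims number of simulations (default 1000).
#' @param seed integer seed.
#' @param statistic \code{"sum"} (total MNI across individuals, default) or
#'   \code{"mean"} (mean per individual).
#' @return \code{n_sims} x taxa matrix of simulated statistics; the
#'   (possibly adjusted) availability is attached as attribute
#'   \code{availability}.
#' @export
null_consumption <- function(diets, availability, n_sims = 1000, seed,
                             statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  diets <- unclass(diets)
  if (length(availability) != ncol(diets)) {
    stop("availability not aligned with diet taxa", call. = FALSE)
  }
  if (any(availability < 0) || all(availability == 0)) {
    stop("availability must be non-negative with a positive entry",
         call. = FALSE)
  }
  tot <- rowSums(diets)
  if (any(tot <= 0)) stop("individual(s) with zero total MNI", call. = FALSE)
  consumed <- colSums(diets) > 0
  zero_avail <- availability == 0 & consumed
  if (any(zero_avail)) {
    pseudo <- min(availability[availability > 0]) / 2
    warning(sprintf(
      "%d consumed taxa absent from surveys given pseudo-availability %.4g",
      sum(zero_avail), pseudo), call. = FALSE)
    availability[zero_avail] <- pseudo
  }
  prob <- availability / sum(availability)
  if (!missing(seed)) set.seed(seed)
  sims <- matrix(0, nrow = n_sims, ncol = ncol(diets),
                 dimnames = list(NULL, colnames(diets)))
  for (i in seq_along(tot)) {
    draw <- stats::rmultinom(n_sims, size = tot[i], prob = prob)
    sims <- sims + t(draw)
  }
  if (statistic == "mean") sims <- sims / length(tot)
  attr(sims, "availability") <- prob
  attr(sims, "statistic") <- statistic
  sims
}

#' Classify observed consumption against the null envelope
#'
#' @param observed per-taxon observed statistic, aligned with the null
#'   matrix columns.
#' @param null_matrix output of \code{\link{null_consumption}}.
#' @param alpha two-sided envelope level (default 0.05).
#' @return data.frame \code{taxon_id, observed, null_mean, null_lo,
#'   null_hi, classification} with classification in
#'   \{positive, neutral, negative\}.
#' @export
classify_electivity <- function(observed, null_matrix, alpha = 0.05) {
  if (length(observed) != ncol(null_matrix)) {
    stop("observed not aligned with null matrix", call. = FALSE)
  }
  lo <- apply(null_matrix, 2L, stats::quantile, probs = alpha / 2, type = 7)
  hi <- apply(null_matrix, 2L, stats::quantile, probs = 1 - alpha / 2,
              type = 7)
  cls <- ifelse(observed > hi, "positive",
                ifelse(observed < lo, "negative", "neutral"))
  degen <- apply(null_matrix, 2L, function(x) all(x == x[1]))
  if (any(degen & cls != "neutral")) {
    warning("degenerate null with deviating observation", call. = FALSE)
  }
  data.frame(taxon_id = colnames(null_matrix) %||%
               as.character(seq_along(observed)),
             observed = as.numeric(observed),
             null_mean = colMeans(null_matrix),
             null_lo = as.numeric(lo), null_hi = as.numeric(hi),
             classification = cls, stringsAsFactors = FALSE,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Electivity tests across campaigns
#'
#' Restricts the diet matrix to taxa passing the pooled occurrence filter,
#' derives per-campaign availability from the survey (mean per-taxon Surber
#' density, normalized), and runs the null-model classification per
#' campaign.
#'
#' @param matrix a \code{diet_matrix} covering all campaigns.
#' @param survey long survey data.frame (\code{campaign_id, point_id,
#'   taxon_id, count}).
#' @param min_occurrence pooled occurrence threshold (default 0.05).
#' @param n_sims simulations per campaign.
#' @param alpha envelope level.
#' @param seed root seed; one sub-seed per campaign.
#' @param statistic aggregation statistic, see
#'   \code{\link{null_consumption}}.
#' @return data.frame \code{campaign_id, taxon_id, observed, null_mean,
#'   null_lo, null_hi, classification}; campaigns without surveys are
#'   skipped with a warning. The per-taxon count of positive campaigns is
#'   attached as attribute \code{positive_counts}.
#' @export
run_electivity <- function(matrix, survey, min_occurrence = 0.05,
                           n_sims = 1000, alpha = 0.05, seed = 1,
                           statistic = "sum") {
  taxa <- occurrence_filter(matrix, min_occurrence)
  if (!length(taxa)) return(data.frame())
  m <- unclass(matrix)[, taxa, drop = FALSE]
  g <- attr(matrix, "campaign_id")
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  g <- g[keep]
  camps <- sort(unique(g))
  seeds <- split_seed(seed, length(camps))
  res <- vector("list", length(camps))
  for (k in seq_along(camps)) {
    cmp <- camps[k]
    sub <- survey[survey$campaign_id == cmp, , drop = FALSE]
    if (!nrow(sub)) {
      warning("campaign without surveys skipped: ", cmp, call. = FALSE)
      next
    }
    dens <- tapply(sub$count, as.character(sub$taxon_id), sum)
    n_pts <- length(unique(sub$point_id))
    avail <- vapply(taxa, function(tx) {
      if (tx %in% names(dens)) dens[[tx]] / n_pts else 0
    }, numeric(1))
    diets <- m[g == cmp, , drop = FALSE]
    if (!nrow(diets)) next
    sims <- null_consumption(diets, avail, n_sims = n_sims, seed = seeds[k],
                             statistic = statistic)
    obs <- if (identical(statistic, "mean")) colMeans(diets) else
      colSums(diets)
    cl <- classify_electivity(obs, sims, alpha = alpha)
    res[[k]] <- cbind(campaign_id = cmp, cl, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  pos <- tapply(out$classification == "positive", out$taxon_id, sum)
  attr(out, "positive_counts") <- pos
  out
}
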