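# Individual trophic traits.
#
# INW (individual niche width) is the Shannon diversity of an individual's
# diet proportions, in nats. BIC (between-individual component of the
# trophic niche) is the V index, 1 minus the proportional similarity between
# an individual's diet and its population's diet: 0 when identical to the
# population, 1 when fully divergent.

#' Shannon individual niche width
#'
#' \eqn{H = -\sum_{p_j > 0} p_j \ln p_j} (natural log).
#'
#' @param p proportion vector (non-negative, summing to 1). Inputs off by at
#'   most \code{1e-6} are renormalized with a warning; larger deviations are
#'   an error.
#' @return Shannon diversity in nats.
#' @export
shannon_inw <- function(p) {
  if (any(p < 0)) stop("negative proportions", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    stop(sprintf("proportions sum to %.6f, not 1", s), call. = FALSE)
  }
  if (s != 1) {
    warning("proportions renormalized to sum exactly to 1", call. = FALSE)
    p <- p / s
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Between-individual component of the trophic niche (V index)
#'
#' \eqn{V = 1 - \sum_j \min(p_{ij}, q_j)}, the complement of the
#' proportional similarity between an individual's diet proportions and the
#' population diet, equal to the total-variation distance
#' \eqn{0.5 \sum_j |p_{ij} - q_j|}.
#'
#' @param p_i individual diet proportions.
#' @param q population diet proportions over the same taxon set; if both
#'   vectors are named the names must match.
#' @return V in \[0, 1\].
#' @export
bic_v <- function(p_i, q) {
  if (length(p_i) != length(q)) {
    stop("p_i and q must be aligned on the same taxon set", call. = FALSE)
  }
  if (!is.null(names(p_i)) && !is.null(names(q)) &&
      !identical(names(p_i), names(q))) {
    stop("p_i and q have mismatched taxon names", call. = FALSE)
  }
  1 - sum(pmin(p_i, q))
}

#' Per-individual traits and per-campaign summaries
#'
#' Computes INW and BIC for every individual (BIC relative to its own
#' campaign's population diet) and campaign-level means and sample SDs.
#'
#' @param matrix a \code{diet_matrix} from \code{\link{compute_mni}}.
#' @param grouping campaign labels per row; defaults to the matrix
#'   attribute.
#' @param convention population-diet convention passed to
#'   \code{\link{pooled_diet}}.
#' @return list with \code{individuals} (data.frame \code{individual_id,
#'   campaign_id, inw, bic}) and \code{campaigns} (data.frame
#'   \code{campaign_id, n, bic_mean, bic_sd, inw_mean, inw_sd}). Campaigns
#'   with fewer than two individuals get \code{NA} BIC and a
#'   \code{flagged} mark.
#' @export
campaign_traits <- function(matrix, grouping = attr(matrix, "campaign_id"),
                            convention = c("sum", "average")) {
  convention <- match.arg(convention)
  g <- as.character(grouping)
  p <- unclass(matrix) / rowSums(matrix)
  q <- pooled_diet(matrix, g, convention)
  inw <- apply(p, 1L, shannon_inw)
  bic <- vapply(seq_len(nrow(p)),
                function(i) bic_v(p[i, ], q[g[i], ]), numeric(1))
  nsz <- table(g)
  small <- names(nsz)[nsz < 2L]
  if (length(small)) bic[g %in% small] <- NA_real_
  ind <- data.frame(individual_id = rownames(matrix), campaign_id = g,
                    inw = inw, bic = bic, stringsAsFactors = FALSE)
  camp <- do.call(rbind, lapply(sort(unique(g)), function(gr) {
    sub <- ind[ind$campaign_id == gr, ]
    data.frame(campaign_id = gr, n = nrow(sub),
               bic_mean = mean(sub$bic), bic_sd = stats::sd(sub$bic),
               inw_mean = mean(sub$inw), inw_sd = stats::sd(sub$inw),
               flagged = nrow(sub) < 2L, stringsAsFactors = FALSE)
  }))
  rownames(camp) <- NULL
  list(individuals = ind, campaigns = camp)
}

#' Population size-structure variability
#'
#' Fork length and weight are z-scored within the campaign (population SD,
#' the normalisation used by duality-diagram PCA) and the mean pairwise
#' Euclidean distance between individual points is returned. Because
#' Euclidean distance is rotation-invariant this equals the distance
#' computed on full-rank PCA scores of the two variables.
#'
#' @param lengths fork lengths (mm).
#' @param weights weights (g).
#' @return mean pairwise distance (dimensionless); 0 when a variable has
#'   zero variance in both dimensions; \code{NA} with a warning for fewer
#'   than two complete individuals.
#' @export
size_variability <- function(lengths, weights) {
  ok <- !is.na(lengths) & !is.na(weights)
  x <- lengths[ok]; y <- weights[ok]
  if (length(x) < 2L) {
    warning("size_variability undefined for < 2 individuals", call. = FALSE)
    return(NA_real_)
  }
  zs <- function(v) {
    n <- length(v)
    s <- stats::sd(v) * sqrt((n - 1) / n) # population SD, as in dudi-style PCA
    if (s == 0) rep(0, n) else (v - mean(v)) / s
  }
  d <- stats::dist(cbind(zs(x), zs(y)))
  mean(d)
}
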