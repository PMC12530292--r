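# Ecological-opportunity summaries per sampling campaign.
#
# The biotic dimension is summarised from Surber point samples (0.05 m^2):
# per-point prey richness, Shannon diversity and focal-taxon densities
# (with >= 5 mm size cohorts for the two main mayfly prey), campaign means
# and coefficients of variation, and mean pairwise Bray-Curtis dissimilarity
# between points. The abiotic dimension is six habitat measurements per
# point, summarised as campaign means and CVs. Sampling-effort differences
# are controlled by permutation standardisation to the minimum campaign
# size (subsample without replacement, average over iterations).

HABITAT_VARS <- c("SbV", "SbG", "vs3", "Dep", "Clg", "VgD")

#' Per-point community metrics
#'
#' @param counts named numeric vector of taxon counts for one Surber point.
#' @return list with \code{richness} (taxa with positive count),
#'   \code{diversity} (Shannon, natural log, 0 for an empty sample) and
#'   \code{density} (the raw counts per Surber unit).
#' @export
sample_metrics <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  pos <- counts[counts > 0]
  rich <- length(pos)
  div <- if (rich == 0L) 0 else {
    p <- pos / sum(pos)
    -sum(p * log(p))
  }
  list(richness = rich, diversity = div, density = counts)
}

#' Mean pairwise Bray-Curtis dissimilarity
#'
#' \eqn{BC(x, y) = \sum_t |x_t - y_t| / \sum_t (x_t + y_t)} averaged over
#' all unordered pairs of point samples. Pairs in which both samples are
#' empty are skipped with a warning (their dissimilarity is undefined).
#'
#' @param m point x taxon count matrix (>= 2 rows).
#' @param transform \code{"none"} (default) computes on raw counts;
#'   \code{"ln1p"} on log(x+1)-transformed counts.
#' @return mean Bray-Curtis dissimilarity in \[0, 1\].
#' @export
mean_bray_curtis <- function(m, transform = c("none", "ln1p")) {
  transform <- match.arg(transform)
  if (nrow(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (transform == "ln1p") m <- ln1p(m)
  d <- bray_curtis_pairs(m)
  vals <- d[upper.tri(d)]
  if (anyNA(vals)) {
    warning(sprintf("skipping %d empty-empty pair(s)", sum(is.na(vals))),
            call. = FALSE)
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

# Full pairwise Bray-Curtis matrix; NA where both samples are empty.
bray_curtis_pairs <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- sum(m[i, ] + m[j, ])
      d[i, j] <- d[j, i] <-
        if (tot == 0) NA_real_ else sum(abs(m[i, ] - m[j, ])) / tot
    }
  }
  d
}

#' Size-cohort densities for focal taxa
#'
#' Splits focal-taxon counts into total density and the density of large
#' individuals (body length >= \code{large_mm}, inclusive).
#'
#' @param survey long survey data.frame with columns \code{point_id},
#'   \code{taxon_id}, \code{count} and \code{length_mm} (per-row body-length
#'   class; may be \code{NA} for non-focal taxa).
#' @param focal character vector of focal taxa.
#' @param large_mm length threshold in mm (default 5).
#' @return data.frame \code{point_id} plus, per focal taxon \code{X},
#'   columns \code{X} (total) and \code{X5sup} (large cohort). Focal rows
#'   with missing length contribute to the total only, with a warning.
#' @export
cohort_split <- function(survey, focal = c("Baetis", "Heptageniidae"),
                         large_mm = 5) {
  stop_if_missing_cols(survey, c("point_id", "taxon_id", "count"), "survey")
  if (is.null(survey$length_mm)) survey$length_mm <- NA_real_
  pts <- sort(unique(as.character(survey$point_id)))
  out <- data.frame(point_id = pts, stringsAsFactors = FALSE)
  for (tx in focal) {
    sub <- survey[survey$taxon_id == tx, , drop = FALSE]
    if (any(is.na(sub$length_mm)) && nrow(sub)) {
      warning(sprintf("%s rows without length class counted in total only",
                      tx), call. = FALSE)
    }
    tot <- tapply(sub$count, factor(as.character(sub$point_id), levels = pts),
                  sum, default = 0)
    lg <- sub[!is.na(sub$length_mm) & sub$length_mm >= large_mm, ,
              drop = FALSE]
    big <- tapply(lg$count, factor(as.character(lg$point_id), levels = pts),
                  sum, default = 0)
    out[[tx]] <- as.numeric(tot)
    out[[paste0(tx, "5sup")]] <- as.numeric(big)
  }
  out
}

#' Permutation standardisation of a campaign estimator
#'
#' Controls for unequal sampling effort across campaigns: the estimator is
#' applied to \code{iters} uniform without-replacement subsamples of
#' \code{n_sub} points and the iteration mean is returned.
#'
#' @param points the campaign's point-level data (matrix or data.frame;
#'   rows are subsampled).
#' @param estimator function taking the subsampled rows and returning a
#'   scalar.
#' @param n_sub subsample size (default 45, the minimum campaign size).
#' @param iters number of iterations (default 1000).
#' @param seed integer seed; required for reproducibility.
#' @return mean estimator value over iterations. When the campaign has
#'   exactly \code{n_sub} points the plain estimator is returned.
#' @export
standardise_by_permutation <- function(points, estimator, n_sub = 45,
                                       iters = 1000, seed) {
  n <- nrow(points)
  if (n < n_sub) {
    stop(sprintf("campaign has %d points, fewer than n_sub = %d", n, n_sub),
         call. = FALSE)
  }
  if (n == n_sub) {
    return(estimator(points))
  }
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  vals <- vapply(seq_len(iters), function(i) {
    idx <- sample.int(n, n_sub)
    estimator(points[idx, , drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Campaign habitat summary
#'
#' @param points data.frame of per-point habitat measurements (columns
#'   \code{SbV, SbG, vs3, Dep, Clg, VgD} or any numeric subset).
#' @param vars habitat variable names (default the six standard ones).
#' @return named vector of means and \code{cv_}-prefixed CVs; missing
#'   values are dropped pairwise with a message of the complete count.
#' @export
habitat_summary <- function(points, vars = HABITAT_VARS) {
  vars <- intersect(vars, names(points))
  out <- numeric(0)
  for (v in vars) {
    x <- points[[v]]
    if (anyNA(x)) {
      message(sprintf("%s: %d of %d values complete", v, sum(!is.na(x)),
                      length(x)))
      x <- x[!is.na(x)]
    }
    out[[v]] <- mean(x)
    out[[paste0("cv_", v)]] <- cv(x)
  }
  out
}

#' Campaign-level ecological-opportunity table
#'
#' Builds the per-campaign estimator table: prey means (richness, Shannon
#' diversity, focal densities and >= 5 mm cohorts) with their CVs, mean
#' pairwise Bray-Curtis, and the six habitat means with CVs. Prey-community
#' estimators are permutation-standardised to \code{n_sub} points.
#'
#' @param survey long survey data.frame: \code{campaign_id, point_id,
#'   taxon_id, count, length_mm}.
#' @param habitat per-point habitat data.frame: \code{campaign_id, point_id}
#'   plus the six habitat columns.
#' @param focal focal taxa split into size cohorts.
#' @param extra_taxa additional taxa summarised as total density only
#'   (default \code{"Orthocladiinae"}).
#' @param n_sub,iters,seed permutation-standardisation controls; set
#'   \code{standardise = FALSE} to use all points of every campaign.
#' @param standardise logical.
#' @param bray_transform passed to \code{\link{mean_bray_curtis}}.
#' @return data.frame, one row per campaign: mean estimators, \code{cv_}
#'   CVs, \code{BrayCurtis}, habitat means and CVs, and \code{n_points}.
#' @export
opportunity_summary <- function(survey, habitat,
                                focal = c("Baetis", "Heptageniidae"),
                                extra_taxa = "Orthocladiinae",
                                n_sub = 45, iters = 1000, seed = 1,
                                standardise = TRUE,
                                bray_transform = "none") {
  stop_if_missing_cols(survey, c("campaign_id", "point_id", "taxon_id",
                                 "count"), "survey")
  stop_if_missing_cols(habitat, c("campaign_id", "point_id"), "habitat")
  camps <- sort(unique(as.character(survey$campaign_id)))
  seeds <- split_seed(seed, length(camps))
  rows <- vector("list", length(camps))
  for (k in seq_along(camps)) {
    cmp <- camps[k]
    sub <- survey[survey$campaign_id == cmp, , drop = FALSE]
    hsub <- habitat[habitat$campaign_id == cmp, , drop = FALSE]
    pv <- point_values(sub, focal, extra_taxa)
    bc <- bray_curtis_pairs(pv$counts)
    prey_cols <- setdiff(names(pv$values), "point_id")
    est_one <- function(rowsel) {
      vals <- pv$values[rowsel, , drop = FALSE]
      out <- numeric(0)
      for (v in prey_cols) {
        out[[v]] <- mean(vals[[v]])
        out[[paste0("cv_", v)]] <- suppressWarnings(cv(vals[[v]]))
      }
      sel <- which(rowsel)
      pair <- bc[sel, sel][upper.tri(matrix(0, length(sel), length(sel)))]
      out[["BrayCurtis"]] <- mean(pair, na.rm = TRUE)
      out
    }
    n <- nrow(pv$values)
    if (standardise && n > n_sub) {
      set.seed(seeds[k])
      acc <- NULL
      for (it in seq_len(iters)) {
        sel <- rep(FALSE, n)
        sel[sample.int(n, n_sub)] <- TRUE
        e <- est_one(sel)
        acc <- if (is.null(acc)) e else acc + e
      }
      prey_est <- acc / iters
    } else {
      if (standardise && n < n_sub) {
        stop(sprintf("campaign %s has %d points, fewer than n_sub = %d",
                     cmp, n, n_sub), call. = FALSE)
      }
      prey_est <- est_one(rep(TRUE, n))
    }
    if (bray_transform == "ln1p") {
      prey_est[["BrayCurtis"]] <-
        mean_bray_curtis(ln1p(pv$counts), transform = "none")
    }
    hab_est <- habitat_summary(hsub)
    rows[[k]] <- data.frame(campaign_id = cmp, n_points = n,
                            t(c(prey_est, hab_est)),
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Per-point derived values for one campaign: richness, diversity and
# focal/extra densities, plus the raw point x taxon count matrix.
point_values <- function(sub, focal, extra_taxa) {
  pts <- sort(unique(as.character(sub$point_id)))
  taxa <- sort(unique(as.character(sub$taxon_id)))
  counts <- matrix(0, nrow = length(pts), ncol = length(taxa),
                   dimnames = list(pts, taxa))
  agg <- tapply(sub$count,
                list(factor(as.character(sub$point_id), levels = pts),
                     factor(as.character(sub$taxon_id), levels = taxa)),
                sum, default = 0)
  counts[] <- agg
  rich <- rowSums(counts > 0)
  div <- apply(counts, 1L, function(x) sample_metrics(x)$diversity)
  vals <- data.frame(point_id = pts, Richness = as.numeric(rich),
                     Diversity = as.numeric(div), stringsAsFactors = FALSE)
  coh <- cohort_split(sub, focal = focal)
  vals <- merge(vals, coh, by = "point_id", sort = TRUE)
  for (tx in extra_taxa) {
    vals[[tx]] <- if (tx %in% colnames(counts)) counts[, tx] else 0
  }
  list(values = vals, counts = counts)
}
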