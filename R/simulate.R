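# Synthetic-study generators.
#
# simulate_study() produces a complete mechanistic study: habitat points,
# negative-binomial prey communities whose log-means depend on habitat,
# fish with local (patch-restricted) foraging, preference-weighted
# multinomial diets with tunable between-individual heterogeneity, and
# genotype-pool detections so that MNI counts saturate like real ASV data.
#
# simulate_path_study() is a linear-structural generator with exactly
# planted standardized path coefficients and site/year random intercepts,
# used to calibrate and validate the causal-path machinery.

#' Default generator configuration
#'
#' Defaults emulate the scale of the field study: ~24 campaigns over 8
#' sites x 2 years in three seasons, 45-90 Surber points and ~30 faecal
#' samples per campaign, eight prey taxa with genotype pools, preferences
#' concentrated on the two mayfly taxa, and habitat-driven log-linear prey
#' densities.
#'
#' @param seed mandatory integer seed.
#' @param ... overrides for any default field.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  taxa <- data.frame(
    taxon_id = c("Baetis", "Heptageniidae", "Orthocladiinae", "Gammarus",
                 "Hydropsyche", "Psychomyiidae", "Simuliidae",
                 "Chironomini"),
    omega = c(4, 3, 0.4, 1, 1, 0.8, 0.7, 0.5),  # preference weights
    pool = c(12L, 10L, 8L, 6L, 6L, 5L, 5L, 8L), # genotype pool sizes G_t
    base_log_density = c(1.6, 1.2, 2.2, 0.7, 0.9, 0.4, 0.8, 1.4),
    stringsAsFactors = FALSE
  )
  habitat <- data.frame(
    var = c("SbV", "SbG", "vs3", "Dep", "Clg", "VgD"),
    mean = c(4, 6, 40, 30, 2.5, 2.5),
    site_sd = c(0.8, 1.2, 12, 8, 0.6, 0.6),
    point_sd = c(1.0, 1.5, 15, 10, 0.8, 0.8),
    lo = c(1, 0, 0, 2, 1, 1),
    hi = c(10, 10, 200, 80, 5, 5),
    ordinal = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  # habitat -> prey log-linear coefficients (rows: habitat, cols: taxa),
  # on the z-scale of point habitat values
  coef <- matrix(0, nrow = nrow(habitat), ncol = nrow(taxa),
                 dimnames = list(habitat$var, taxa$taxon_id))
  coef["vs3", c("Baetis", "Heptageniidae", "Simuliidae")] <- c(0.4, 0.3, 0.5)
  coef["SbG", c("Heptageniidae", "Psychomyiidae")] <- c(0.35, 0.25)
  coef["Clg", c("Baetis", "Heptageniidae", "Orthocladiinae")] <-
    c(-0.3, -0.35, 0.3)
  coef["VgD", c("Baetis", "Gammarus", "Orthocladiinae")] <- c(0.25, 0.3, 0.2)
  coef["Dep", c("Hydropsyche", "Gammarus")] <- c(0.2, 0.15)
  cfg <- list(
    n_sites = 8L, n_years = 2L,
    seasons = c("spring", "summer", "autumn"),
    campaigns_per_site = 3L,
    points_choices = c(45L, 60L, 90L),
    fish_per_campaign = 30L,
    taxa = taxa,
    habitat = habitat,
    hab_prey_coef = coef,
    # seasonal log-density shifts for the focal mayfly taxa
    seasonal_prey = c(spring = 0.4, summer = 0.2, autumn = -0.8),
    # seasonal shifts of clogging (up in autumn) and vegetation (down)
    seasonal_clg = c(spring = -0.4, summer = 0, autumn = 0.8),
    seasonal_vgd = c(spring = 0.3, summer = 0.4, autumn = -0.8),
    p_large = c(spring = 0.45, summer = 0.35, autumn = 0.12),
    dispersion = 1.5,       # negative-binomial size
    heterogeneity = 1.5,    # SD of per-individual log-preference jitter
    patch_radius = 0.2,     # fraction of the reach a fish forages over
    items_rate = 20,        # mean prey items per faeces
    length_mean = 140, length_sd = 15, # fork length (mm)
    seed = as.integer(seed)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(override)] <- override
  if (any(cfg$taxa$omega < 0) || cfg$items_rate < 0 ||
      cfg$heterogeneity < 0) {
    stop("rates and weights must be non-negative", call. = FALSE)
  }
  if (!identical(dim(cfg$hab_prey_coef),
                 c(nrow(cfg$habitat), nrow(cfg$taxa)))) {
    stop("hab_prey_coef dimensions must match habitat and taxon lists",
         call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Simulate a complete synthetic study
#'
#' @param config a \code{\link{generator_config}}.
#' @return list of class \code{synthetic_study} with \code{detections}
#'   (validated-variant table), \code{fish} (biometry/metadata),
#'   \code{survey} (long point x taxon counts with length classes),
#'   \code{habitat} (per-point measurements), \code{campaigns} (schedule)
#'   and \code{ground_truth} (planted parameters).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  taxa <- config$taxa
  hab <- config$habitat
  focal <- c("Baetis", "Heptageniidae")

  # campaign schedule
  sched <- list()
  for (s in seq_len(config$n_sites)) {
    combos <- expand.grid(year = seq_len(config$n_years),
                          season = config$seasons,
                          stringsAsFactors = FALSE)
    pick <- combos[sample.int(nrow(combos),
                              min(config$campaigns_per_site, nrow(combos))), ]
    for (r in seq_len(nrow(pick))) {
      sched[[length(sched) + 1L]] <- data.frame(
        site = sprintf("site%02d", s),
        year = 2013L + pick$year[r],
        season = pick$season[r],
        n_points = config$points_choices[
          sample.int(length(config$points_choices), 1L)],
        stringsAsFactors = FALSE)
    }
  }
  campaigns <- do.call(rbind, sched)
  campaigns$campaign_id <- sprintf("%s_%d_%s", campaigns$site,
                                   campaigns$year, campaigns$season)

  site_eff <- matrix(stats::rnorm(config$n_sites * nrow(hab)),
                     nrow = config$n_sites,
                     dimnames = list(sprintf("site%02d",
                                             seq_len(config$n_sites)),
                                     hab$var))
  hab_rows <- list(); sur_rows <- list()
  fish_rows <- list(); det_rows <- list()

  for (k in seq_len(nrow(campaigns))) {
    cmp <- campaigns[k, ]
    npt <- cmp$n_points
    # point-level habitat
    H <- matrix(NA_real_, nrow = npt, ncol = nrow(hab),
                dimnames = list(NULL, hab$var))
    for (v in seq_len(nrow(hab))) {
      vn <- hab$var[v]
      shift <- if (vn == "Clg") config$seasonal_clg[[cmp$season]]
               else if (vn == "VgD") config$seasonal_vgd[[cmp$season]]
               else 0
      mu <- hab$mean[v] + hab$site_sd[v] * site_eff[cmp$site, vn] +
        shift * hab$site_sd[v]
      x <- stats::rnorm(npt, mu, hab$point_sd[v])
      x <- pmin(pmax(x, hab$lo[v]), hab$hi[v])
      if (hab$ordinal[v]) x <- round(x)
      H[, v] <- x
    }
    # point-level prey counts, log-linear in z-scored habitat
    Z <- sweep(sweep(H, 2L, hab$mean), 2L, hab$point_sd, "/")
    counts <- matrix(0L, nrow = npt, ncol = nrow(taxa),
                     dimnames = list(NULL, taxa$taxon_id))
    for (t in seq_len(nrow(taxa))) {
      tx <- taxa$taxon_id[t]
      eta <- taxa$base_log_density[t] +
        as.numeric(Z %*% config$hab_prey_coef[, tx]) +
        if (tx %in% focal) config$seasonal_prey[[cmp$season]] else 0
      counts[, t] <- stats::rnbinom(npt, mu = exp(eta),
                                    size = config$dispersion)
    }
    pts <- sprintf("%s_pt%03d", cmp$campaign_id, seq_len(npt))
    hab_rows[[k]] <- data.frame(campaign_id = cmp$campaign_id,
                                point_id = pts, H,
                                stringsAsFactors = FALSE)
    # long survey rows; focal taxa split into <5 mm and >=5 mm cohorts
    pl <- config$p_large[[cmp$season]]
    sr <- list()
    for (t in seq_len(nrow(taxa))) {
      tx <- taxa$taxon_id[t]
      if (tx %in% focal) {
        big <- stats::rbinom(npt, counts[, t], pl)
        sr[[length(sr) + 1L]] <- data.frame(
          campaign_id = cmp$campaign_id, point_id = pts, taxon_id = tx,
          count = counts[, t] - big, length_mm = 3,
          stringsAsFactors = FALSE)
        sr[[length(sr) + 1L]] <- data.frame(
          campaign_id = cmp$campaign_id, point_id = pts, taxon_id = tx,
          count = big, length_mm = 6, stringsAsFactors = FALSE)
      } else {
        sr[[length(sr) + 1L]] <- data.frame(
          campaign_id = cmp$campaign_id, point_id = pts, taxon_id = tx,
          count = counts[, t], length_mm = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    sur_rows[[k]] <- do.call(rbind, sr)

    # fish and diets
    nf <- config$fish_per_campaign
    lf <- stats::rnorm(nf, config$length_mean +
                         5 * site_eff[cmp$site, "Dep"], config$length_sd)
    wt <- 1e-5 * lf^3 * exp(stats::rnorm(nf, 0, 0.08))
    ids <- sprintf("%s_f%03d", cmp$campaign_id, seq_len(nf))
    fish_rows[[k]] <- data.frame(
      individual_id = ids, sample_id = paste0("S_", ids),
      campaign_id = cmp$campaign_id, site = cmp$site, year = cmp$year,
      season = cmp$season, fork_length = round(lf),
      weight = round(wt, 1), age_class = "adult",
      stringsAsFactors = FALSE)
    window <- max(1L, round(config$patch_radius * npt))
    for (f in seq_len(nf)) {
      start <- sample.int(npt - window + 1L, 1L)
      local <- colSums(counts[start:(start + window - 1L), , drop = FALSE])
      if (all(local == 0)) local <- colSums(counts)
      if (all(local == 0)) local <- rep(1, nrow(taxa))
      pref <- taxa$omega * local *
        exp(stats::rnorm(nrow(taxa), 0, config$heterogeneity))
      n_items <- max(1L, stats::rpois(1L, config$items_rate))
      items <- stats::rmultinom(1L, n_items, pref / sum(pref))[, 1L]
      for (t in which(items > 0L)) {
        genotypes <- unique(sample.int(taxa$pool[t], items[t],
                                       replace = TRUE))
        det_rows[[length(det_rows) + 1L]] <- data.frame(
          sample_id = paste0("S_", ids[f]), individual_id = ids[f],
          campaign_id = cmp$campaign_id,
          variant_id = sprintf("%s_g%02d", taxa$taxon_id[t], genotypes),
          taxon_id = taxa$taxon_id[t], stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    detections = do.call(rbind, det_rows),
    fish = do.call(rbind, fish_rows),
    survey = do.call(rbind, sur_rows),
    habitat = do.call(rbind, hab_rows),
    campaigns = campaigns,
    ground_truth = list(
      omega = stats::setNames(taxa$omega, taxa$taxon_id),
      genotype_pools = stats::setNames(taxa$pool, taxa$taxon_id),
      hab_prey_coef = config$hab_prey_coef,
      heterogeneity = config$heterogeneity,
      patch_radius = config$patch_radius,
      seasonal_prey = config$seasonal_prey,
      seed = config$seed
    ),
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d campaigns, %d fish, ",
                     "%d survey points, %d detections\n"),
              nrow(x$campaigns), nrow(x$fish), nrow(x$habitat),
              nrow(x$detections)))
  invisible(x)
}

#' Planted ground truth of a synthetic study
#'
#' @param study a \code{synthetic_study} or \code{path_study}.
#' @return the planted parameters; for a \code{path_study} this includes
#'   the implied standardized direct and indirect habitat effects.
#' @export
ground_truth <- function(study) {
  if (!is.null(study$ground_truth)) return(study$ground_truth)
  stop("not a synthetic study", call. = FALSE)
}

#' Simulate linear path-structured data
#'
#' Generates campaign-level habitat \code{Hab1} ~ N(0,1), a prey summary
#' \code{Prey1} with planted standardized habitat effect \code{hab_prey},
#' and an individual-level trait with planted standardized direct
#' (\code{direct}) and prey (\code{prey_trait}) effects, site and year
#' random intercepts, and unit total trait variance. The implied indirect
#' habitat effect is \code{hab_prey * prey_trait}.
#'
#' @param n_campaigns number of campaigns (default 40).
#' @param n_per_campaign individuals per campaign (default 30).
#' @param n_sites,n_years random-intercept structure (defaults 8 and 2).
#' @param direct standardized direct habitat -> trait effect (default 0.3;
#'   set 0 to generate under the mediation-only DAG).
#' @param hab_prey standardized habitat -> prey effect (default 0.5).
#' @param prey_trait standardized prey -> trait effect (default 0.4).
#' @param var_site,var_year random-intercept variances (defaults 0.05,
#'   0.02).
#' @param trait trait column name (default \code{"BIC"}).
#' @param seed integer seed.
#' @return list of class \code{path_study}: \code{data} (individual rows
#'   with campaign_id, site, year, Hab1, Prey1, trait), \code{dag} (the
#'   generating \code{path_dag}) and \code{ground_truth} with the planted
#'   standardized effects.
#' @export
simulate_path_study <- function(n_campaigns = 40L, n_per_campaign = 30L,
                                n_sites = 8L, n_years = 2L, direct = 0.3,
                                hab_prey = 0.5, prey_trait = 0.4,
                                var_site = 0.05, var_year = 0.02,
                                trait = "BIC", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  var_fixed <- direct^2 + prey_trait^2 + 2 * direct * prey_trait * hab_prey
  var_resid <- 1 - var_fixed - var_site - var_year
  if (var_resid <= 0) {
    stop("planted effects leave no residual variance", call. = FALSE)
  }
  site <- sprintf("site%02d", 1L + (seq_len(n_campaigns) - 1L) %% n_sites)
  year <- 2014L + (seq_len(n_campaigns) - 1L) %/% n_sites %% n_years
  H <- stats::rnorm(n_campaigns)
  P <- hab_prey * H + stats::rnorm(n_campaigns, 0, sqrt(1 - hab_prey^2))
  u_site <- stats::setNames(stats::rnorm(n_sites, 0, sqrt(var_site)),
                            sprintf("site%02d", seq_len(n_sites)))
  u_year <- stats::setNames(stats::rnorm(n_years, 0, sqrt(var_year)),
                            as.character(2014L + seq_len(n_years) - 1L))
  idx <- rep(seq_len(n_campaigns), each = n_per_campaign)
  tr <- direct * H[idx] + prey_trait * P[idx] +
    u_site[site[idx]] + u_year[as.character(year[idx])] +
    stats::rnorm(length(idx), 0, sqrt(var_resid))
  data <- data.frame(
    campaign_id = sprintf("c%03d", idx),
    site = site[idx], year = year[idx],
    Hab1 = H[idx], Prey1 = P[idx], stringsAsFactors = FALSE)
  data[[trait]] <- as.numeric(tr)
  edges <- data.frame(from = c("Hab1", "Prey1"), to = c("Prey1", trait),
                      stringsAsFactors = FALSE)
  if (direct != 0) {
    edges <- rbind(edges, data.frame(from = "Hab1", to = trait,
                                     stringsAsFactors = FALSE))
  }
  roles <- stats::setNames(c("habitat", "prey", "trait"),
                           c("Hab1", "Prey1", trait))
  structure(list(
    data = data,
    dag = path_dag(edges, roles = roles),
    ground_truth = list(direct = direct, hab_prey = hab_prey,
                        prey_trait = prey_trait,
                        indirect = hab_prey * prey_trait,
                        var_site = var_site, var_year = var_year,
                        var_resid = var_resid, seed = seed)
  ), class = "path_study")
}
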