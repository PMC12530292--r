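# End-to-end orchestration: input validation, stage execution, tabular and
# JSON outputs, and a reproducibility manifest.

#' Default run configuration
#'
#' Thresholds and convention switches for a pipeline run.
#'
#' @param seed integer seed recorded in all outputs.
#' @param ... overrides: \code{r_max} (0.70), \code{vif} (5), \code{alpha}
#'   (0.05), \code{occurrence} (0.05), \code{n_sub} (45), \code{iters}
#'   (1000), \code{n_sims} (1000), \code{diet_convention} ("sum" or
#'   "average"), \code{bray_transform} ("none" or "ln1p"),
#'   \code{electivity_statistic} ("sum" or "mean").
#' @return list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(r_max = 0.70, vif = 5, alpha = 0.05, occurrence = 0.05,
              n_sub = 45L, iters = 1000L, n_sims = 1000L,
              diet_convention = "sum", bray_transform = "none",
              electivity_statistic = "sum", seed = as.integer(seed))
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(override)] <- override
  stopifnot(cfg$r_max > 0, cfg$r_max <= 1, cfg$vif > 0,
            cfg$alpha > 0, cfg$alpha <= 1,
            cfg$occurrence > 0, cfg$occurrence <= 1,
            cfg$n_sub >= 1, cfg$iters >= 1, cfg$n_sims >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline input tables
#'
#' Checks column presence, referential integrity of campaign ids across
#' tables, and ordinal habitat ranges (clogging and vegetal development
#' classes 1-5, substrate size classes 0-10).
#'
#' @param detections,fish,survey,habitat input data.frames (any may be
#'   NULL to skip its checks).
#' @return data.frame \code{table, check, detail} of violations (zero rows
#'   when everything is valid).
#' @export
validate_inputs <- function(detections = NULL, fish = NULL, survey = NULL,
                            habitat = NULL) {
  v <- list()
  bad <- function(table, check, detail) {
    v[[length(v) + 1L]] <<- data.frame(table = table, check = check,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  }
  need <- function(df, cols, table) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) bad(table, "missing_columns",
                          paste(miss, collapse = ", "))
    !length(miss)
  }
  if (!is.null(detections)) {
    need(detections, c("sample_id", "individual_id", "campaign_id",
                       "variant_id", "taxon_id"), "detections")
  }
  if (!is.null(fish)) {
    need(fish, c("individual_id", "campaign_id", "fork_length", "weight"),
         "fish")
  }
  if (!is.null(survey)) {
    if (need(survey, c("campaign_id", "point_id", "taxon_id", "count"),
             "survey") && any(survey$count < 0, na.rm = TRUE)) {
      bad("survey", "negative_count", "counts must be >= 0")
    }
  }
  if (!is.null(habitat)) {
    need(habitat, c("campaign_id", "point_id"), "habitat")
    rng <- list(Clg = c(1, 5), VgD = c(1, 5), SbG = c(0, 10), SbV = c(0, 10))
    for (vn in names(rng)) {
      if (vn %in% names(habitat)) {
        x <- habitat[[vn]]
        out <- !is.na(x) & (x < rng[[vn]][1] | x > rng[[vn]][2])
        if (any(out)) {
          bad("habitat", "ordinal_range",
              sprintf("%s outside [%g, %g] in %d row(s)", vn,
                      rng[[vn]][1], rng[[vn]][2], sum(out)))
        }
      }
    }
  }
  ref <- function(child, childname, parent_ids) {
    if (is.null(child) || !"campaign_id" %in% names(child)) return()
    unknown <- setdiff(unique(child$campaign_id), parent_ids)
    if (length(unknown)) {
      bad(childname, "referential",
          paste("unknown campaign_id:", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(survey)) {
    ids <- unique(survey$campaign_id)
    ref(detections, "detections", ids)
    ref(fish, "fish", ids)
  }
  if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), check = character(),
               detail = character(), stringsAsFactors = FALSE)
}

#' Write a synthetic study to input TSVs
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if needed).
#' @return dir, invisibly. Writes \code{detections.tsv}, \code{fish.tsv},
#'   \code{survey.tsv}, \code{habitat.tsv} and \code{ground_truth.json}.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(study$detections, file.path(dir, "detections.tsv"))
  write_tsv_table(study$fish, file.path(dir, "fish.tsv"))
  write_tsv_table(study$survey, file.path(dir, "survey.tsv"))
  write_tsv_table(study$habitat, file.path(dir, "habitat.tsv"))
  gt <- study$ground_truth
  gt$hab_prey_coef <- as.data.frame(gt$hab_prey_coef)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes MNI diet quantification, trophic traits, ecological-opportunity
#' summaries, electivity null models, the BIC and INW path analyses
#' (separately) and seasonal contrasts, writing every intermediate table,
#' JSON model reports and a run manifest to \code{out_dir}.
#'
#' @param detections,fish,survey,habitat input tables (see
#'   \code{\link{validate_inputs}}); \code{fish} must carry \code{site},
#'   \code{year} and \code{season} columns for the modelling stages.
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory.
#' @return invisible list with the stage results: \code{mni},
#'   \code{traits}, \code{opportunity}, \code{electivity},
#'   \code{paths_bic}, \code{paths_inw}, \code{seasonal}.
#' @export
run_pipeline <- function(detections, fish, survey, habitat, config,
                         out_dir) {
  stopifnot(inherits(config, "run_config"))
  report <- validate_inputs(detections, fish, survey, habitat)
  if (nrow(report)) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s/%s] %s", report$table, report$check,
                       report$detail), collapse = "\n"), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf(...))
  # young-of-the-year filter
  if ("age_class" %in% names(fish)) {
    n0 <- nrow(fish)
    fish <- fish[fish$age_class != "yoy", , drop = FALSE]
    log_stage("fish: %d of %d retained after age filter", nrow(fish), n0)
    detections <- detections[detections$individual_id %in%
                               fish$individual_id, , drop = FALSE]
  }

  log_stage("stage mni: %d detections", nrow(detections))
  mni <- compute_mni(detections)
  write_tsv_table(data.frame(individual_id = rownames(mni),
                             campaign_id = attr(mni, "campaign_id"),
                             unclass(mni), check.names = FALSE),
                  file.path(out_dir, "diet_matrix.tsv"))
  write_tsv_table(diet_long(mni), file.path(out_dir, "diet_long.tsv"))

  log_stage("stage traits: %d individuals", nrow(mni))
  traits <- campaign_traits(mni, convention = config$diet_convention)
  sv <- do.call(rbind, lapply(split(fish, fish$campaign_id), function(f) {
    data.frame(campaign_id = f$campaign_id[1],
               size_variability = suppressWarnings(
                 size_variability(f$fork_length, f$weight)),
               stringsAsFactors = FALSE)
  }))
  rownames(sv) <- NULL
  traits$campaigns <- merge(traits$campaigns, sv, by = "campaign_id",
                            all.x = TRUE)
  write_tsv_table(traits$individuals, file.path(out_dir, "traits.tsv"))
  write_tsv_table(traits$campaigns,
                  file.path(out_dir, "traits_campaigns.tsv"))

  log_stage("stage opportunity: %d survey rows", nrow(survey))
  seeds <- split_seed(config$seed, 4L)
  opp <- opportunity_summary(survey, habitat, n_sub = config$n_sub,
                             iters = config$iters, seed = seeds[1],
                             bray_transform = config$bray_transform)
  write_tsv_table(opp, file.path(out_dir, "opportunity.tsv"))

  log_stage("stage electivity")
  elec <- run_electivity(mni, survey, min_occurrence = config$occurrence,
                         n_sims = config$n_sims, alpha = config$alpha,
                         seed = seeds[2],
                         statistic = config$electivity_statistic)
  write_tsv_table(elec, file.path(out_dir, "electivity.tsv"))

  log_stage("stage paths")
  model_data <- build_model_data(traits$individuals, traits$campaigns,
                                 opp, fish)
  paths <- list()
  for (trait in c("bic", "inw")) {
    res <- tryCatch(
      run_path_analysis(model_data, trait = trait, config = config),
      error = function(e) {
        warning(sprintf("path analysis for %s failed: %s", trait,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    paths[[trait]] <- res
    if (!is.null(res)) {
      jsonlite::write_json(path_model_report(res$model),
                           file.path(out_dir,
                                     sprintf("paths_%s.json", trait)),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      write_tsv_table(res$model$edges,
                      file.path(out_dir, sprintf("paths_%s_edges.tsv",
                                                 trait)))
    }
  }

  log_stage("stage seasonal")
  seasonal <- run_seasonal(model_data, paths, config)
  write_tsv_table(seasonal, file.path(out_dir, "seasonal.tsv"))

  manifest <- list(config = unclass(config), seed = config$seed,
                   n_detections = nrow(detections), n_fish = nrow(fish),
                   n_survey_rows = nrow(survey),
                   package_version = as.character(
                     utils::packageVersion("trophvar")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mni = mni, traits = traits, opportunity = opp,
                 electivity = elec, paths_bic = paths$bic,
                 paths_inw = paths$inw, seasonal = seasonal,
                 model_data = model_data))
}

# Individual-level modelling table: traits plus campaign-level opportunity
# and size-structure variables, with site/year/season metadata.
build_model_data <- function(ind_traits, camp_traits, opp, fish) {
  meta_cols <- intersect(c("individual_id", "campaign_id", "site", "year",
                           "season", "fork_length", "weight"), names(fish))
  d <- merge(ind_traits, fish[meta_cols],
             by = c("individual_id", "campaign_id"))
  d <- merge(d, camp_traits[c("campaign_id", "size_variability")],
             by = "campaign_id")
  merge(d, opp, by = "campaign_id")
}

# Variable pruning + initial diagram + four-step selection for one trait.
run_path_analysis <- function(model_data, trait = c("bic", "inw"), config) {
  trait <- match.arg(trait)
  tn <- toupper(trait)
  md <- model_data
  md[[tn]] <- md[[trait]]
  md <- md[!is.na(md[[tn]]), , drop = FALSE]
  prey_means <- intersect(c("Richness", "Diversity", "Baetis",
                            "Baetis5sup", "Heptageniidae",
                            "Heptageniidae5sup", "Orthocladiinae"),
                          names(md))
  for (v in setdiff(prey_means, c("Richness", "Diversity"))) {
    md[[v]] <- ln1p(md[[v]])
  }
  prey_vars <- c(prey_means, paste0("cv_", prey_means), "BrayCurtis")
  prey_vars <- intersect(prey_vars, names(md))
  hab_vars <- intersect(c(HABITAT_VARS, paste0("cv_", HABITAT_VARS)),
                        names(md))
  size_vars <- if (trait == "bic") "size_variability" else
    intersect(c("fork_length", "weight"), names(md))
  keep <- prune_correlated(md, c(prey_vars, hab_vars, size_vars),
                           r_max = config$r_max)
  keep <- vif_prune(md, keep, threshold = config$vif)
  prey_vars <- intersect(prey_vars, keep)
  hab_vars <- intersect(hab_vars, keep)
  size_vars <- intersect(size_vars, keep)
  if (!length(prey_vars) || !length(hab_vars)) {
    stop("no prey or habitat variables survive pruning", call. = FALSE)
  }
  edges <- rbind(
    expand.grid(from = hab_vars, to = prey_vars, stringsAsFactors = FALSE),
    data.frame(from = c(hab_vars, prey_vars, size_vars), to = tn,
               stringsAsFactors = FALSE))
  cor_links <- if (length(size_vars) && length(prey_vars)) {
    expand.grid(a = prey_vars, b = size_vars, stringsAsFactors = FALSE)
  } else NULL
  roles <- stats::setNames(
    c(rep("habitat", length(hab_vars)), rep("prey", length(prey_vars)),
      rep("size", length(size_vars)), "trait"),
    c(hab_vars, prey_vars, size_vars, tn))
  levels <- stats::setNames(ifelse(
    names(roles) %in% c(tn, "fork_length", "weight"),
    "individual", "campaign"), names(roles))
  dag <- path_dag(edges, roles = roles, cor_links = cor_links)
  model <- select_model(dag, md, alpha = config$alpha, levels = levels)
  list(model = model, data = md, retained = keep)
}

# Seasonal contrasts for the variables retained in either final path model.
run_seasonal <- function(model_data, paths, config) {
  vars <- unique(unlist(lapply(paths, function(p) {
    if (is.null(p)) character() else
      setdiff(p$model$dag$nodes,
              names(p$model$dag$roles)[p$model$dag$roles == "trait"])
  })))
  vars <- intersect(vars, names(model_data))
  vars <- vars[vapply(vars, function(v)
    stats::var(model_data[[v]], na.rm = TRUE) > 0, logical(1))]
  # only campaign-level (opportunity) variables are contrasted by season
  vars <- vars[vapply(vars, function(v) {
    all(tapply(model_data[[v]], model_data$campaign_id,
               function(x) length(unique(x)) == 1L))
  }, logical(1))]
  camp <- collapse_campaign(model_data, c(vars, "season"))
  out <- list()
  for (v in vars) {
    res <- tryCatch({
      fit <- season_model(camp, v)
      pairwise_seasons(fit)
    }, error = function(e) NULL)
    if (!is.null(res)) out[[v]] <- res
  }
  if (!length(out)) {
    return(data.frame(variable = character(), season_a = character(),
                      season_b = character(), estimate = numeric(),
                      p_adj = numeric(), code = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
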