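# Piecewise path-model fitting, the four-step selection procedure, and
# standardized direct / prey-mediated effect decomposition.
#
# The structural layer is a set of linear mixed models, one per endogenous
# variable, with crossed site and year random intercepts. Campaign-level
# variables (habitat and prey summaries, population size variability) are
# fitted on one row per campaign; individual-level variables (the trophic
# traits, individual biometry) on one row per individual, with
# campaign-level predictors repeated within campaigns.

default_levels <- function(dag) {
  stats::setNames(ifelse(dag$roles[dag$nodes] == "trait",
                         "individual", "campaign"), dag$nodes)
}

# One row per campaign for campaign-level regressions; campaign-level
# variables are constant within campaigns by construction.
collapse_campaign <- function(data, vars) {
  keep <- unique(c("campaign_id", "site", "year", vars))
  keep <- intersect(keep, names(data))
  data[!duplicated(data$campaign_id), keep, drop = FALSE]
}

node_data <- function(data, response, predictors, levels) {
  if (identical(levels[[response]], "individual")) {
    data
  } else {
    collapse_campaign(data, c(response, predictors))
  }
}

fit_node <- function(dag, node, data, levels, random) {
  parents <- sort(dag_parents(dag, node))
  fit_lmm(node, parents, node_data(data, node, parents, levels),
          random = random)
}

edge_pvalue <- function(fit, predictor) {
  co <- fit$coefficients
  co$p[match(predictor, co$term)]
}

# Campaign-mean residuals of a node (model residuals if endogenous,
# centered raw values otherwise), for correlated-error link tests.
node_residuals <- function(dag, node, data, levels, random) {
  parents <- dag_parents(dag, node)
  d <- node_data(data, node, parents, levels)
  r <- if (length(parents)) {
    fit <- fit_lmm(node, sort(parents), d, random = random)
    stats::resid(fit$model)
  } else {
    d[[node]] - mean(d[[node]])
  }
  tapply(r, as.character(d$campaign_id), mean)
}

test_cor_link <- function(dag, a, b, data, levels, random) {
  ra <- node_residuals(dag, a, data, levels, random)
  rb <- node_residuals(dag, b, data, levels, random)
  common <- intersect(names(ra), names(rb))
  ct <- stats::cor.test(ra[common], rb[common])
  list(r = unname(ct$estimate), p = ct$p.value)
}

claim_pvalue <- function(claim, dag, data, levels, random) {
  preds <- sort(unique(c(claim$predictor, claim$conditioning)))
  d <- node_data(data, claim$response, preds, levels)
  fit <- fit_lmm(claim$response, preds, d, random = random)
  edge_pvalue(fit, claim$predictor)
}

#' Fit a piecewise path model
#'
#' Fits every endogenous variable's mixed model, evaluates the union basis
#' set of d-separation claims, combines them with Fisher's C, and reports
#' standardized estimates, variance explained, and the direct / indirect
#' habitat effect decomposition.
#'
#' @param dag a \code{path_dag}.
#' @param data individual-level data.frame with columns \code{campaign_id},
#'   \code{site}, \code{year} plus every node; campaign-level variables
#'   repeated within campaigns.
#' @param levels named vector mapping nodes to \code{"individual"} or
#'   \code{"campaign"}; defaults to individual for trait nodes, campaign
#'   otherwise.
#' @param random random-intercept factors (default \code{c("site","year")}).
#' @param free_exogenous passed to \code{\link{basis_set}}.
#' @param alpha significance level recorded in the output.
#' @return object of class \code{path_model}: list with \code{dag},
#'   \code{edges} (from, to, estimate, se, p, std_estimate),
#'   \code{cor_links} (a, b, r, p), \code{fits}, \code{claims} (with
#'   p-values), \code{C}, \code{df}, \code{p_value}, \code{saturated},
#'   \code{r2} (response, marginal, conditional), \code{effects} (the
#'   decomposition), \code{alpha}.
#' @export
fit_path_model <- function(dag, data, levels = NULL,
                           random = c("site", "year"),
                           free_exogenous = TRUE, alpha = 0.05) {
  if (is.null(levels)) levels <- default_levels(dag)
  endo <- sort(unique(dag$edges$to))
  fits <- lapply(stats::setNames(endo, endo), fit_node, dag = dag,
                 data = data, levels = levels, random = random)
  edges <- dag$edges
  edges$estimate <- edges$se <- edges$p <- edges$std_estimate <- NA_real_
  for (i in seq_len(nrow(edges))) {
    fit <- fits[[edges$to[i]]]
    std <- standardized_estimates(fit)
    row <- match(edges$from[i], std$term)
    edges$estimate[i] <- std$estimate[row]
    edges$se[i] <- std$se[row]
    edges$p[i] <- std$p[row]
    edges$std_estimate[i] <- std$std_estimate[row]
  }
  cl <- dag$cor_links
  if (nrow(cl)) {
    cl$r <- cl$p <- NA_real_
    for (i in seq_len(nrow(cl))) {
      tst <- test_cor_link(dag, cl$a[i], cl$b[i], data, levels, random)
      cl$r[i] <- tst$r; cl$p[i] <- tst$p
    }
  }
  claims <- basis_set(dag, free_exogenous = free_exogenous)
  claim_df <- if (length(claims)) {
    data.frame(
      response = vapply(claims, `[[`, "", "response"),
      predictor = vapply(claims, `[[`, "", "predictor"),
      conditioning = vapply(claims, function(c)
        paste(c$conditioning, collapse = ","), ""),
      p = vapply(claims, claim_pvalue, numeric(1), dag = dag, data = data,
                 levels = levels, random = random),
      stringsAsFactors = FALSE)
  } else {
    data.frame(response = character(), predictor = character(),
               conditioning = character(), p = numeric())
  }
  fc <- fishers_c(claim_df$p)
  r2 <- do.call(rbind, lapply(endo, function(v) {
    r <- r2_mixed(fits[[v]])
    data.frame(response = v, marginal = r[["marginal"]],
               conditional = r[["conditional"]], stringsAsFactors = FALSE)
  }))
  model <- structure(list(dag = dag, edges = edges, cor_links = cl,
                          fits = fits, claims = claim_df, C = fc$C,
                          df = fc$df, p_value = fc$p_value,
                          saturated = fc$saturated, r2 = r2,
                          levels = levels, random = random,
                          free_exogenous = free_exogenous, alpha = alpha),
                     class = "path_model")
  model$effects <- effect_decomposition(model)
  model
}

#' @export
print.path_model <- function(x, ...) {
  cat("Piecewise path model\n")
  if (nrow(x$edges)) {
    cat("Paths:\n")
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -> %s  std = %+.3f  (p = %.4g)\n", x$edges$from[i],
                  x$edges$to[i], x$edges$std_estimate[i], x$edges$p[i]))
    }
  }
  if (x$saturated) {
    cat("Saturated model (no independence claims)\n")
  } else {
    cat(sprintf("Fisher's C = %.3f, df = %d, p = %.4g\n", x$C, x$df,
                x$p_value))
  }
  if (!is.null(x$r2) && nrow(x$r2)) {
    cat("R2 (marginal / conditional):\n")
    for (i in seq_len(nrow(x$r2))) {
      cat(sprintf("  %s: %.2f / %.2f\n", x$r2$response[i], x$r2$marginal[i],
                  x$r2$conditional[i]))
    }
  }
  invisible(x)
}

#' Four-step path selection
#'
#' Starting from the a-priori diagram (habitat -> prey, habitat -> trait,
#' prey -> trait, size -> trait, prey-size covariances), applies:
#' (i) removal of all non-significant covariate (correlated-error) links;
#' (ii) sequential removal of non-significant causal paths into the trait,
#' highest p first, refitting after every removal; (iii) removal of prey and
#' size variables left without a significant path to the trait; (iv)
#' sequential removal of non-significant habitat -> prey paths, highest p
#' first. Ties are broken alphabetically by path name for determinism.
#'
#' @inheritParams fit_path_model
#' @param alpha significance threshold (default 0.05).
#' @return the final fitted \code{path_model} (see
#'   \code{\link{fit_path_model}}); the selection trace is attached as
#'   attribute \code{removed} (data.frame step, item).
#' @export
select_model <- function(dag, data, alpha = 0.05, levels = NULL,
                         random = c("site", "year"),
                         free_exogenous = TRUE) {
  if (is.null(levels)) levels <- default_levels(dag)
  roles <- dag$roles
  trait <- names(roles)[roles == "trait"]
  if (length(trait) != 1L) stop("exactly one trait node required",
                                call. = FALSE)
  removed <- data.frame(step = character(), item = character(),
                        stringsAsFactors = FALSE)
  note <- function(step, item) {
    removed <<- rbind(removed, data.frame(step = step, item = item,
                                          stringsAsFactors = FALSE))
  }

  # (i) covariate links
  cl <- dag$cor_links
  if (nrow(cl)) {
    keep <- logical(nrow(cl))
    for (i in seq_len(nrow(cl))) {
      tst <- test_cor_link(dag, cl$a[i], cl$b[i], data, levels, random)
      keep[i] <- tst$p <= alpha
      if (!keep[i]) note("covariate", paste(cl$a[i], "~~", cl$b[i]))
    }
    dag$cor_links <- cl[keep, , drop = FALSE]
  }

  edge_name <- function(e, i) paste(e$from[i], "->", e$to[i])

  # (ii) causal paths into the trait, highest p first
  repeat {
    parents <- sort(dag_parents(dag, trait))
    if (!length(parents)) break
    fit <- fit_node(dag, trait, data, levels, random)
    ps <- vapply(parents, function(p) edge_pvalue(fit, p), numeric(1))
    if (max(ps) <= alpha) break
    worst <- sort(parents[ps >= max(ps) - 1e-12])
    drop <- worst[1L] # alphabetical order breaks ties
    dag$edges <- dag$edges[!(dag$edges$from == drop &
                               dag$edges$to == trait), , drop = FALSE]
    note("trait-path", paste(drop, "->", trait))
  }

  # (iii) prey / size variables without a path to the trait
  into_trait <- dag$edges$from[dag$edges$to == trait]
  orphan <- names(roles)[roles %in% c("prey", "size") &
                           !(names(roles) %in% into_trait) &
                           names(roles) %in% dag$nodes]
  for (v in sort(orphan)) {
    dag$edges <- dag$edges[dag$edges$from != v & dag$edges$to != v, ,
                           drop = FALSE]
    dag$cor_links <- dag$cor_links[dag$cor_links$a != v &
                                     dag$cor_links$b != v, , drop = FALSE]
    dag$nodes <- setdiff(dag$nodes, v)
    dag$roles <- dag$roles[names(dag$roles) != v]
    note("variable", v)
  }

  # (iv) habitat -> prey paths, highest p first
  repeat {
    prey <- sort(unique(dag$edges$to[dag$roles[dag$edges$to] == "prey"]))
    if (!length(prey)) break
    cand <- data.frame(from = character(), to = character(), p = numeric(),
                       stringsAsFactors = FALSE)
    for (pn in prey) {
      fit <- fit_node(dag, pn, data, levels, random)
      for (par in sort(dag_parents(dag, pn))) {
        cand <- rbind(cand, data.frame(from = par, to = pn,
                                       p = edge_pvalue(fit, par),
                                       stringsAsFactors = FALSE))
      }
    }
    if (!nrow(cand) || max(cand$p) <= alpha) break
    worst <- cand[cand$p >= max(cand$p) - 1e-12, , drop = FALSE]
    worst <- worst[order(worst$from, worst$to), , drop = FALSE]
    drop <- worst[1L, ] # alphabetical order breaks ties
    dag$edges <- dag$edges[!(dag$edges$from == drop$from &
                               dag$edges$to == drop$to), , drop = FALSE]
    note("prey-path", paste(drop$from, "->", drop$to))
  }

  model <- fit_path_model(dag, data, levels = levels, random = random,
                          free_exogenous = free_exogenous, alpha = alpha)
  attr(model, "removed") <- removed
  model
}

#' Direct, indirect and total habitat effects
#'
#' For each habitat variable H in the final model: the direct effect is the
#' standardized estimate of H -> trait (0 when the path is absent); the
#' indirect, prey-mediated effect is the sum over prey mediators P of
#' std(H -> P) * std(P -> trait); total = direct + indirect.
#'
#' @param model a fitted \code{path_model}.
#' @return data.frame \code{habitat, direct, indirect, total}.
#' @export
effect_decomposition <- function(model) {
  roles <- model$dag$roles
  trait <- names(roles)[roles == "trait"]
  habitat <- sort(names(roles)[roles == "habitat" &
                                 names(roles) %in% model$dag$nodes])
  e <- model$edges
  std_of <- function(from, to) {
    i <- which(e$from == from & e$to == to)
    if (length(i)) e$std_estimate[i] else 0
  }
  out <- do.call(rbind, lapply(habitat, function(h) {
    direct <- std_of(h, trait)
    prey <- e$to[e$from == h & roles[e$to] == "prey"]
    indirect <- sum(vapply(prey, function(p) std_of(h, p) * std_of(p, trait),
                           numeric(1)))
    data.frame(habitat = h, direct = direct, indirect = indirect,
               total = direct + indirect, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(habitat = character(), direct = numeric(),
                      indirect = numeric(), total = numeric())
  }
  out
}

#' Export a path model as a report list
#'
#' Machine-readable summary suitable for JSON serialisation.
#'
#' @param model a \code{path_model}.
#' @return list of plain vectors and data.frames.
#' @export
path_model_report <- function(model) {
  list(edges = model$edges, cor_links = model$cor_links,
       claims = model$claims,
       fishers_C = model$C, df = model$df, p_value = model$p_value,
       saturated = model$saturated, r2 = model$r2, effects = model$effects,
       alpha = model$alpha)
}
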