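# DAG plumbing for the piecewise path analysis: the causal graph, the union
# basis set of d-separation claims, and Fisher's C.

#' Construct a causal path diagram
#'
#' @param edges data.frame with columns \code{from}, \code{to} (directed
#'   causal paths).
#' @param roles named character vector assigning each node one of
#'   \code{"habitat"}, \code{"prey"}, \code{"size"}, \code{"trait"} (free
#'   labels are allowed for generic DAGs).
#' @param cor_links optional data.frame with columns \code{a}, \code{b}:
#'   correlated-error (undirected) links, e.g. prey-size covariances.
#' @return object of class \code{path_dag}.
#' @export
path_dag <- function(edges, roles = NULL, cor_links = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    stop_if_missing_cols(edges, c("from", "to"), "edges")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(cor_links)) {
    cor_links <- data.frame(a = character(), b = character(),
                            stringsAsFactors = FALSE)
  } else {
    cor_links <- as.data.frame(cor_links, stringsAsFactors = FALSE)
    stop_if_missing_cols(cor_links, c("a", "b"), "cor_links")
  }
  nodes <- unique(c(edges$from, edges$to, cor_links$a, cor_links$b,
                    names(roles)))
  if (is.null(roles)) roles <- stats::setNames(rep("node", length(nodes)),
                                               nodes)
  traits <- names(roles)[roles == "trait"]
  if (any(edges$from %in% traits)) {
    stop("trait nodes cannot have outgoing edges", call. = FALSE)
  }
  dag <- structure(list(nodes = nodes, edges = edges,
                        cor_links = cor_links, roles = roles),
                   class = "path_dag")
  if (is_cyclic(dag)) stop("graph is cyclic", call. = FALSE)
  dag
}

#' @export
print.path_dag <- function(x, ...) {
  cat(sprintf("path_dag: %d nodes, %d directed edges, %d correlated links\n",
              length(x$nodes), nrow(x$edges), nrow(x$cor_links)))
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to),
              collapse = "\n"), "\n")
  }
  if (nrow(x$cor_links)) {
    cat(paste(sprintf("  %s ~~ %s", x$cor_links$a, x$cor_links$b),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

dag_parents <- function(dag, node) dag$edges$from[dag$edges$to == node]

dag_ancestors <- function(dag, node) {
  anc <- character()
  frontier <- dag_parents(dag, node)
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, dag_parents,
                                             dag = dag))), anc)
  }
  anc
}

is_cyclic <- function(dag) {
  any(vapply(dag$nodes, function(v) v %in% dag_ancestors(dag, v),
             logical(1)))
}

# Longest-path depth from root nodes, for deterministic claim orientation.
dag_depth <- function(dag) {
  depth <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(dag$edges))) {
      f <- dag$edges$from[i]; t <- dag$edges$to[i]
      if (depth[[t]] < depth[[f]] + 1L) {
        depth[[t]] <- depth[[f]] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  depth
}

#' Union basis set of independence claims
#'
#' For every non-adjacent pair of nodes (directed edges in either direction
#' and correlated-error links both count as adjacency) one claim is emitted:
#' the pair is independent conditional on the union of both nodes' parents.
#' The causally downstream node is the claim's response; when neither node
#' is an ancestor of the other, the deeper node (longest path from the
#' roots), then the alphabetically later one, is the response. Pairs of
#' exogenous (parent-free) nodes are exempt by default: their covariances
#' are treated as free, consistent with handling habitat-variable
#' covariation outside the causal model.
#'
#' @param dag a \code{path_dag}.
#' @param free_exogenous exempt exogenous-exogenous pairs (default TRUE).
#' @return list of claims, each a list with \code{response},
#'   \code{predictor}, \code{conditioning} (character vector, possibly
#'   empty).
#' @export
basis_set <- function(dag, free_exogenous = TRUE) {
  if (is_cyclic(dag)) stop("graph is cyclic", call. = FALSE)
  nodes <- sort(dag$nodes)
  adj <- function(u, v) {
    any(dag$edges$from == u & dag$edges$to == v) ||
      any(dag$edges$from == v & dag$edges$to == u) ||
      any(dag$cor_links$a == u & dag$cor_links$b == v) ||
      any(dag$cor_links$a == v & dag$cor_links$b == u)
  }
  depth <- dag_depth(dag)
  claims <- list()
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      u <- nodes[i]; v <- nodes[j]
      if (adj(u, v)) next
      pu <- dag_parents(dag, u); pv <- dag_parents(dag, v)
      if (free_exogenous && !length(pu) && !length(pv)) next
      resp <- if (u %in% dag_ancestors(dag, v)) v
              else if (v %in% dag_ancestors(dag, u)) u
              else if (depth[[u]] != depth[[v]]) {
                if (depth[[u]] > depth[[v]]) u else v
              } else max(u, v)
      pred <- setdiff(c(u, v), resp)
      cond <- setdiff(sort(unique(c(pu, pv))), c(u, v))
      claims[[length(claims) + 1L]] <-
        list(response = resp, predictor = pred, conditioning = cond)
    }
  }
  claims
}

#' Fisher's C statistic
#'
#' Combines the p-values of the independence claims:
#' \eqn{C = -2 \sum_i \ln p_i}, chi-square distributed with \eqn{2k} degrees
#' of freedom under the causal model; a non-significant p (> 0.05) indicates
#' acceptable fit. An empty claim set yields the saturated model
#' (C = 0, df = 0, p = 1).
#'
#' @param p vector of claim p-values in (0, 1].
#' @return list \code{C}, \code{df}, \code{p_value}, \code{saturated}.
#' @export
fishers_c <- function(p) {
  if (!length(p)) {
    return(list(C = 0, df = 0L, p_value = 1, saturated = TRUE))
  }
  if (any(p <= 0)) stop("claim p-value of 0: upstream test failed",
                        call. = FALSE)
  if (any(p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df,
       p_value = stats::pchisq(C, df, lower.tail = FALSE),
       saturated = FALSE)
}
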