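# Diet quantification from validated metabarcoding detections.
#
# Prey abundance in a faecal sample is estimated by the Minimal Number of
# Individuals (MNI): the number of distinct sequence variants (ASVs or
# multi-marker contigs) assigned to a prey taxon in that sample. It is a
# conservative lower bound on the number of prey individuals consumed.

#' Build an individual diet matrix from metabarcoding detections
#'
#' Applies the Minimal Number of Individuals (MNI) rule: the cell for
#' individual \code{i} and taxon \code{t} is the number of distinct
#' \code{variant_id}s with \code{taxon_id == t} among the validated
#' detections of \code{i}'s faecal sample.
#'
#' @param detections data.frame with columns \code{sample_id},
#'   \code{individual_id}, \code{campaign_id}, \code{variant_id},
#'   \code{taxon_id}.
#' @param taxonomy optional character vector of known taxon ids; detections
#'   with a taxon outside this set raise an error.
#' @param deduplicate if \code{TRUE}, duplicated (sample_id, variant_id)
#'   rows are collapsed silently; if \code{FALSE} (default) they are an
#'   input error.
#' @return object of class \code{diet_matrix}: an integer matrix
#'   (individuals x taxa) with attributes \code{individual_id},
#'   \code{campaign_id} (aligned with rows). Samples with zero validated
#'   variants never appear (a warning reports how many input samples were
#'   empty, if any were present as all-NA rows).
#' @export
compute_mni <- function(detections, taxonomy = NULL, deduplicate = FALSE) {
  stop_if_missing_cols(detections,
    c("sample_id", "individual_id", "campaign_id", "variant_id", "taxon_id"),
    "detections")
  det <- detections
  if (!is.null(taxonomy)) {
    bad <- setdiff(unique(det$taxon_id), taxonomy)
    if (length(bad)) {
      stop("unknown taxon_id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  key <- paste(det$sample_id, det$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    if (!deduplicate) {
      stop("duplicate (sample_id, variant_id) rows; ",
           "set deduplicate = TRUE to collapse them", call. = FALSE)
    }
    det <- det[!duplicated(key), , drop = FALSE]
  }
  # one faecal sample per individual per campaign
  map <- unique(det[, c("sample_id", "individual_id", "campaign_id")])
  if (anyDuplicated(map$individual_id)) {
    dup <- map$individual_id[duplicated(map$individual_id)]
    stop("individual(s) with more than one sample: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  empty <- !nzchar(as.character(det$variant_id)) | is.na(det$variant_id)
  if (any(empty)) {
    warning(sprintf("dropping %d detection row(s) without a variant",
                    sum(empty)), call. = FALSE)
    det <- det[!empty, , drop = FALSE]
  }
  inds <- sort(unique(as.character(det$individual_id)))
  taxa <- sort(unique(as.character(det$taxon_id)))
  m <- matrix(0L, nrow = length(inds), ncol = length(taxa),
              dimnames = list(inds, taxa))
  tab <- table(factor(as.character(det$individual_id), levels = inds),
               factor(as.character(det$taxon_id), levels = taxa))
  m[] <- as.integer(tab)
  camp <- map$campaign_id[match(inds, map$individual_id)]
  structure(m,
            individual_id = inds,
            campaign_id = as.character(camp),
            class = c("diet_matrix", "matrix", "array"))
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat(sprintf("diet_matrix: %d individuals x %d prey taxa (MNI counts)\n",
              nrow(x), ncol(x)))
  cat(sprintf("campaigns: %s\n",
              paste(unique(attr(x, "campaign_id")), collapse = ", ")))
  invisible(x)
}

#' Per-individual diet proportions
#'
#' @param matrix a \code{diet_matrix} (or plain count matrix).
#' @return numeric matrix of row-normalized proportions
#'   \eqn{p_{ij} = MNI_{ij} / \sum_j MNI_{ij}}. Rows with zero total are
#'   excluded with a warning.
#' @export
diet_proportions <- function(matrix) {
  tot <- rowSums(matrix)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d individual(s) with zero-total diet",
                    sum(tot == 0)), call. = FALSE)
    keep <- tot > 0
    cid <- attr(matrix, "campaign_id")
    matrix <- matrix[keep, , drop = FALSE]
    if (!is.null(cid)) attr(matrix, "campaign_id") <- cid[keep]
    tot <- tot[keep]
  }
  p <- unclass(matrix) / tot
  attr(p, "campaign_id") <- attr(matrix, "campaign_id")
  attr(p, "individual_id") <- rownames(p)
  p
}

#' Population diet per group
#'
#' The population diet \eqn{q_j} against which each individual is compared.
#' Two conventions are exposed: \code{"sum"} (default) pools MNI counts over
#' the group's individuals and normalizes the column sums;
#' \code{"average"} averages the individuals' proportion vectors.
#'
#' @param matrix a \code{diet_matrix}.
#' @param grouping vector of group labels (typically campaign ids), one per
#'   row of \code{matrix}; defaults to the matrix's \code{campaign_id}
#'   attribute.
#' @param convention \code{"sum"} or \code{"average"}.
#' @return matrix (groups x taxa) of population diet proportions, rows
#'   summing to 1.
#' @export
pooled_diet <- function(matrix, grouping = attr(matrix, "campaign_id"),
                        convention = c("sum", "average")) {
  convention <- match.arg(convention)
  if (is.null(grouping) || length(grouping) != nrow(matrix)) {
    stop("grouping must assign each individual to exactly one group",
         call. = FALSE)
  }
  g <- as.character(grouping)
  groups <- sort(unique(g))
  m <- unclass(matrix)
  q <- matrix(NA_real_, nrow = length(groups), ncol = ncol(m),
              dimnames = list(groups, colnames(m)))
  for (gr in groups) {
    sub <- m[g == gr, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group: ", gr, call. = FALSE)
    if (convention == "sum") {
      cs <- colSums(sub)
      q[gr, ] <- cs / sum(cs)
    } else {
      p <- sub / rowSums(sub)
      q[gr, ] <- colMeans(p)
    }
  }
  q
}

#' Filter taxa by diet-sample occurrence
#'
#' Retains taxa detected (MNI > 0) in at least \code{min_occurrence} of all
#' samples, pooled across campaigns. The threshold is inclusive.
#'
#' @param matrix a \code{diet_matrix}.
#' @param min_occurrence fraction in (0, 1]; default 0.05.
#' @return character vector of retained taxon ids.
#' @export
occurrence_filter <- function(matrix, min_occurrence = 0.05) {
  stopifnot(min_occurrence > 0, min_occurrence <= 1)
  occ <- colMeans(unclass(matrix) > 0)
  colnames(matrix)[occ >= min_occurrence]
}

#' Long-format diet table
#'
#' @param matrix a \code{diet_matrix}.
#' @return data.frame \code{individual_id, campaign_id, taxon_id, mni,
#'   proportion} restricted to positive cells.
#' @export
diet_long <- function(matrix) {
  m <- unclass(matrix)
  p <- m / rowSums(m) # zero-total rows have no positive cell, never indexed
  idx <- which(m > 0, arr.ind = TRUE)
  data.frame(
    individual_id = rownames(matrix)[idx[, 1]],
    campaign_id = attr(matrix, "campaign_id")[idx[, 1]],
    taxon_id = colnames(matrix)[idx[, 2]],
    mni = m[idx],
    proportion = p[idx],
    stringsAsFactors = FALSE
  )
}
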