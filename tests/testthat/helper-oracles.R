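# Independent brute-force oracles, deliberately written differently from the
# package implementations.

oracle_shannon <- function(p) {
  h <- 0
  for (v in p) if (v > 0) h <- h - v * log(v)
  h
}

oracle_bic <- function(p, q) 0.5 * sum(abs(p - q))

oracle_bray <- function(x, y) {
  num <- 0; den <- 0
  for (t in seq_along(x)) {
    num <- num + abs(x[t] - y[t])
    den <- den + x[t] + y[t]
  }
  if (den == 0) NA_real_ else num / den
}

oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  100 * s / m
}

oracle_richness <- function(counts) sum(counts != 0)

# Recount MNI per (individual, taxon) by explicit looping over unique
# variants.
oracle_mni <- function(det) {
  out <- list()
  for (ind in unique(det$individual_id)) {
    sub <- det[det$individual_id == ind, ]
    for (tx in unique(sub$taxon_id)) {
      vs <- unique(sub$variant_id[sub$taxon_id == tx])
      out[[paste(ind, tx)]] <- data.frame(individual_id = ind,
                                          taxon_id = tx,
                                          mni = length(vs))
    }
  }
  do.call(rbind, out)
}

# Random detection table over n_ind individuals and a small taxon pool.
random_detections <- function(n_ind = 6, n_taxa = 4, max_var = 5) {
  taxa <- paste0("tax", seq_len(n_taxa))
  rows <- list()
  for (i in seq_len(n_ind)) {
    ind <- paste0("ind", i)
    k <- sample(1:8, 1)
    tx <- sample(taxa, k, replace = TRUE)
    vr <- paste0(tx, "_v", sample(max_var, k, replace = TRUE))
    rows[[i]] <- data.frame(sample_id = paste0("S", i), individual_id = ind,
                            campaign_id = paste0("c", 1 + i %% 2),
                            variant_id = vr, taxon_id = tx,
                            stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, rows)
  det[!duplicated(paste(det$sample_id, det$variant_id)), ]
}

# Two columns with an exact sample correlation r.
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- as.numeric(scale(rnorm(n)))
  e <- rnorm(n)
  e <- as.numeric(scale(residuals(lm(e ~ x))))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Small deterministic survey fixture in the long layout.
tiny_survey <- function(campaign = "c1", n_points = 6, seed = 1) {
  set.seed(seed)
  taxa <- c("Baetis", "Heptageniidae", "Orthocladiinae", "Gammarus")
  rows <- list()
  for (p in seq_len(n_points)) {
    for (tx in taxa) {
      cnt <- rpois(1, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        campaign_id = campaign, point_id = sprintf("%s_p%02d", campaign, p),
        taxon_id = tx, count = cnt,
        length_mm = if (tx %in% c("Baetis", "Heptageniidae"))
          sample(3:7, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
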