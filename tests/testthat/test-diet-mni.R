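det1 <- data.frame(
  sample_id = "S1", individual_id = "ind1", campaign_id = "c1",
  variant_id = c("v1", "v2", "v3"),
  taxon_id = c("Baetis", "Baetis", "Gammarus"),
  stringsAsFactors = FALSE
)

test_that("MNI counts distinct variants per taxon within a sample", {
  m <- compute_mni(det1)
  expect_identical(as.integer(m["ind1", "Baetis"]), 2L)
  expect_identical(as.integer(m["ind1", "Gammarus"]), 1L)

  one <- det1[1, ]
  expect_equal(sum(compute_mni(one)), 1)
})

test_that("MNI equals a brute-force recount on random detection tables", {
  set.seed(11)
  for (rep in 1:20) {
    det <- random_detections()
    m <- compute_mni(det)
    orc <- oracle_mni(det)
    for (k in seq_len(nrow(orc))) {
      expect_identical(as.integer(m[orc$individual_id[k], orc$taxon_id[k]]),
                       as.integer(orc$mni[k]))
    }
    expect_equal(sum(m), nrow(unique(det[c("sample_id", "variant_id")])))
  }
})

test_that("MNI is invariant to row order and variant relabeling", {
  set.seed(12)
  det <- random_detections()
  m1 <- compute_mni(det)
  m2 <- compute_mni(det[sample(nrow(det)), ])
  expect_equal(unclass(m1), unclass(m2))

  relab <- det
  relab$variant_id <- paste0("renamed_", relab$variant_id)
  expect_equal(unclass(compute_mni(relab)), unclass(m1))
})

test_that("merging two variants of one taxon drops that cell's MNI by 1", {
  det <- det1
  m_before <- compute_mni(det)
  det$variant_id[det$variant_id == "v2"] <- "v1" # collapse v1, v2
  m_after <- compute_mni(det, deduplicate = TRUE)
  expect_equal(as.integer(m_after["ind1", "Baetis"]),
               as.integer(m_before["ind1", "Baetis"]) - 1L)
})

test_that("input contract violations are rejected", {
  dup <- rbind(det1, det1[1, ])
  expect_error(compute_mni(dup), "duplicate")
  expect_silent(compute_mni(dup, deduplicate = TRUE))

  expect_error(compute_mni(det1, taxonomy = c("Baetis")), "unknown taxon")

  two_samples <- rbind(det1, transform(det1, sample_id = "S2"))
  expect_error(compute_mni(two_samples), "more than one sample")
})

test_that("diet proportions normalize rows and commute with permutation", {
  m <- compute_mni(det1)
  p <- diet_proportions(m)
  expect_equal(sort(as.numeric(p)), c(1 / 3, 2 / 3))

  set.seed(13)
  det <- random_detections()
  m <- compute_mni(det)
  p <- diet_proportions(m)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))

  perm <- sample(ncol(m))
  strip <- function(x) {
    attributes(x) <- attributes(x)[c("dim", "dimnames")]
    x
  }
  expect_equal(strip(p[, perm]), strip(diet_proportions(m[, perm])))
})

test_that("zero-total rows are excluded from proportions with a warning", {
  m <- matrix(c(2L, 1L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_warning(p <- diet_proportions(m), "zero-total")
  expect_identical(rownames(p), "a")
})

test_that("pooled diet follows the sum and average conventions", {
  m <- matrix(c(1L, 0L, 0L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(as.numeric(pooled_diet(m, c("g", "g"))), c(0.5, 0.5))
  # single-individual group equals that individual's proportions
  m2 <- matrix(c(3L, 1L), nrow = 1, dimnames = list("a", c("t1", "t2")))
  expect_equal(as.numeric(pooled_diet(m2, "g")), c(0.75, 0.25))
  # sum convention weights by totals, average does not
  m3 <- matrix(c(8L, 0L, 0L, 2L), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(as.numeric(pooled_diet(m3, c("g", "g"))), c(0.8, 0.2))
  expect_equal(as.numeric(pooled_diet(m3, c("g", "g"), "average")),
               c(0.5, 0.5))
  expect_error(pooled_diet(m3, c("g")), "exactly one group")
})

test_that("pooled diet matches column-sum normalization on random groups", {
  set.seed(14)
  for (rep in 1:10) {
    m <- matrix(rpois(24, 2), nrow = 6,
                dimnames = list(paste0("i", 1:6), paste0("t", 1:4)))
    m[rowSums(m) == 0, 1] <- 1L
    g <- sample(c("g1", "g2"), 6, replace = TRUE)
    if (length(unique(g)) < 2) g[1] <- setdiff(c("g1", "g2"), g)[1]
    q <- pooled_diet(m, g)
    for (gr in unique(g)) {
      cs <- colSums(m[g == gr, , drop = FALSE])
      expect_equal(as.numeric(q[gr, ]), unname(cs / sum(cs)))
    }
  }
})

test_that("occurrence filter threshold is inclusive and matches recount", {
  m <- matrix(0L, nrow = 100, ncol = 2,
              dimnames = list(paste0("i", 1:100), c("rare4", "rare5")))
  m[1:4, "rare4"] <- 1L
  m[1:5, "rare5"] <- 1L
  kept <- occurrence_filter(m, 0.05)
  expect_false("rare4" %in% kept)
  expect_true("rare5" %in% kept)

  set.seed(15)
  m <- matrix(rbinom(200, 1, 0.3), nrow = 20,
              dimnames = list(paste0("i", 1:20), paste0("t", 1:10)))
  thr <- 0.25
  kept <- occurrence_filter(m, thr)
  brute <- colnames(m)[apply(m, 2, function(x) sum(x > 0)) / 20 >= thr]
  expect_identical(kept, brute)
})
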