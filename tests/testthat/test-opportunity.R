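test_that("per-point metrics match closed forms", {
  m <- sample_metrics(c(3, 1, 0))
  expect_equal(m$richness, 2)
  expect_equal(m$diversity, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  empty <- sample_metrics(c(0, 0, 0))
  expect_equal(empty$richness, 0)
  expect_equal(empty$diversity, 0)
  expect_error(sample_metrics(c(-1, 2)), "negative")
})

test_that("coefficient of variation: closed form, invariance, guards", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-12)
  set.seed(31)
  x <- rgamma(20, 3)
  expect_equal(cv(x), cv(7.3 * x), tolerance = 1e-12)
  expect_equal(cv(x), oracle_cv(x), tolerance = 1e-12)
  expect_error(cv(3), "two values")
  expect_warning(v <- cv(c(-1, 1)), "undefined")
  expect_true(is.na(v))
})

test_that("Bray-Curtis mean: closed forms and vegan cross-check", {
  same <- rbind(c(2, 3), c(2, 3))
  expect_equal(mean_bray_curtis(same), 0)
  disjoint <- rbind(c(2, 0), c(0, 5))
  expect_equal(mean_bray_curtis(disjoint), 1)
  expect_equal(mean_bray_curtis(rbind(c(1, 1), c(0, 2))), 0.5)

  skip_if_not_installed("vegan")
  set.seed(32)
  for (rep in 1:5) {
    m <- matrix(rpois(30, 4) + 1, nrow = 5) # strictly positive, no empties
    ours <- mean_bray_curtis(m)
    ref <- mean(vegan::vegdist(m, method = "bray"))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("empty-empty pairs are skipped, not scored as zero", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 2))
  expect_warning(v <- mean_bray_curtis(m), "empty-empty")
  expect_equal(v, 1) # both informative pairs are fully disjoint from empty
})

test_that("cohort split separates totals and >= 5 mm densities", {
  sv <- data.frame(point_id = "p1", taxon_id = "Baetis", count = 1,
                   length_mm = c(4, 5, 6))
  cs <- cohort_split(sv)
  expect_equal(cs$Baetis, 3)
  expect_equal(cs$Baetis5sup, 2) # >= is inclusive
  expect_equal(cs$Heptageniidae, 0)
  expect_equal(cs$Heptageniidae5sup, 0)

  small <- data.frame(point_id = "p1", taxon_id = "Heptageniidae",
                      count = 2, length_mm = 3)
  expect_equal(cohort_split(small)$Heptageniidae5sup, 0)

  noclass <- data.frame(point_id = "p1", taxon_id = "Baetis", count = 4,
                        length_mm = NA_real_)
  expect_warning(cs2 <- cohort_split(noclass), "total only")
  expect_equal(cs2$Baetis, 4)
  expect_equal(cs2$Baetis5sup, 0)
})

test_that("cohort split matches a brute-force recount on random tables", {
  set.seed(33)
  for (rep in 1:5) {
    sv <- tiny_survey(seed = 330 + rep)
    cs <- cohort_split(sv)
    for (p in unique(sv$point_id)) {
      sub <- sv[sv$point_id == p & sv$taxon_id == "Baetis", ]
      expect_equal(cs$Baetis[cs$point_id == p], sum(sub$count))
      expect_equal(cs$Baetis5sup[cs$point_id == p],
                   sum(sub$count[sub$length_mm >= 5]))
    }
  }
})

test_that("permutation standardisation: identity, unbiasedness, rarefaction", {
  set.seed(34)
  pts <- data.frame(x = rgamma(45, 2))
  est <- function(d) mean(d$x)
  expect_equal(standardise_by_permutation(pts, est, n_sub = 45, iters = 3,
                                          seed = 1),
               mean(pts$x))

  # linear statistic: subsample mean is unbiased for the full mean
  pts90 <- data.frame(x = rgamma(90, 2))
  iters <- 400
  got <- standardise_by_permutation(pts90, est, n_sub = 45, iters = iters,
                                    seed = 2)
  se <- sd(pts90$x) / sqrt(45) / sqrt(iters)
  expect_lt(abs(got - mean(pts90$x)), 3 * se + 1e-9)

  # concave statistic (pooled richness) can only decrease under subsampling
  cnt <- matrix(rbinom(90 * 10, 1, 0.05), nrow = 90)
  colnames(cnt) <- paste0("t", 1:10)
  rich <- function(d) sum(colSums(d) > 0)
  std <- standardise_by_permutation(as.data.frame(cnt), rich, n_sub = 45,
                                    iters = 100, seed = 3)
  expect_lte(std, rich(as.data.frame(cnt)))

  expect_error(standardise_by_permutation(pts, est, n_sub = 99, iters = 2,
                                          seed = 1), "fewer than")
})

test_that("habitat summary produces means and CVs per variable", {
  uniform <- data.frame(SbV = rep(4, 6), Dep = rep(30, 6))
  hs <- habitat_summary(uniform)
  expect_equal(unname(hs[c("cv_SbV", "cv_Dep")]), c(0, 0))

  hs2 <- habitat_summary(data.frame(Dep = c(10, 30)))
  expect_equal(unname(hs2["Dep"]), 20)
  expect_equal(unname(hs2["cv_Dep"]), 70.71068, tolerance = 1e-5)
})

test_that("ln+1 transform: fixed points, monotonicity, domain", {
  expect_equal(ln1p(0), 0)
  expect_equal(ln1p(exp(1) - 1), 1)
  set.seed(35)
  x <- sort(rgamma(20, 2))
  expect_true(all(diff(ln1p(x)) >= 0))
  expect_error(ln1p(-0.5), "negative")
})

test_that("campaign estimators are invariant to point order", {
  sv <- tiny_survey(n_points = 8, seed = 36)
  hab <- data.frame(campaign_id = "c1",
                    point_id = unique(sv$point_id),
                    SbV = rpois(8, 4) + 1, Dep = rnorm(8, 30, 5))
  o1 <- opportunity_summary(sv, hab, standardise = FALSE)
  perm <- sample(nrow(sv))
  o2 <- opportunity_summary(sv[perm, ], hab[sample(8), ],
                            standardise = FALSE)
  expect_equal(o1, o2)
  expect_true(o1$BrayCurtis >= 0 && o1$BrayCurtis <= 1)
})
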