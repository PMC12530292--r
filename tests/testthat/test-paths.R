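test_that("correlation pruning drops one member per high-r pair", {
  set.seed(51)
  d <- data.frame(a = rnorm(50))
  d$a_copy <- d$a
  d$c <- rnorm(50)
  kept <- prune_correlated(d, c("a", "a_copy", "c"))
  expect_length(intersect(kept, c("a", "a_copy")), 1)
  expect_true("c" %in% kept)

  # r = 0.69 stays (threshold is strict)
  pr <- exact_cor_pair(60, 0.69, seed = 52)
  d2 <- data.frame(x = pr$x, y = pr$y)
  expect_setequal(prune_correlated(d2, c("x", "y")), c("x", "y"))

  # planted r = 0.9 with a CV member: the CV variable goes
  pr3 <- exact_cor_pair(60, 0.9, seed = 53)
  d3 <- data.frame(MeanBae = pr3$x, cv_Bae = pr3$y, other = rnorm(60))
  kept3 <- prune_correlated(d3, c("MeanBae", "cv_Bae", "other"))
  expect_true("MeanBae" %in% kept3)
  expect_false("cv_Bae" %in% kept3)

  d4 <- data.frame(a = rnorm(20), k = rep(1, 20), b = rnorm(20))
  expect_warning(kept4 <- prune_correlated(d4, c("a", "k", "b")),
                 "constant")
  expect_false("k" %in% kept4)
})

test_that("VIF pruning follows the closed-form thresholds", {
  set.seed(54)
  n <- 80
  ortho <- data.frame(x1 = rnorm(n))
  ortho$x2 <- as.numeric(scale(residuals(lm(rnorm(n) ~ ortho$x1))))
  ortho$x3 <- as.numeric(scale(residuals(lm(rnorm(n) ~ ortho$x1 + ortho$x2))))
  keep <- vif_prune(ortho, c("x1", "x2", "x3"))
  expect_setequal(as.character(keep), c("x1", "x2", "x3"))
  expect_true(all(abs(attr(keep, "vif") - 1) < 1e-8))

  pr9 <- exact_cor_pair(n, 0.9, seed = 55)
  d9 <- data.frame(x = pr9$x, y = pr9$y)
  k9 <- vif_prune(d9, c("x", "y"), threshold = 5)
  expect_length(k9, 1) # VIF = 5.263 > 5, one dropped
  k9b <- vif_prune(d9, c("x", "y"), threshold = 100)
  expect_equal(unname(attr(k9b, "vif")), rep(1 / (1 - 0.81), 2),
               tolerance = 1e-8)

  pr8 <- exact_cor_pair(n, 0.8, seed = 56)
  d8 <- data.frame(x = pr8$x, y = pr8$y)
  k8 <- vif_prune(d8, c("x", "y"), threshold = 5)
  expect_length(k8, 2) # VIF = 2.78 <= 5, both kept
  expect_equal(unname(attr(k8, "vif")), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-8)
})

test_that("VIF agrees with the car implementation", {
  skip_if_not_installed("car")
  set.seed(57)
  d <- data.frame(y = rnorm(60), x1 = rnorm(60), x2 = rnorm(60))
  d$x3 <- 0.6 * d$x1 + rnorm(60, 0, 0.5)
  keep <- vif_prune(d, c("x1", "x2", "x3"), threshold = 1e6)
  ref <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(unname(attr(keep, "vif")[names(ref)]), unname(ref),
               tolerance = 1e-8)
})

test_that("mixed fit collapses to OLS when random variance is absent", {
  set.seed(58)
  d <- data.frame(x = rnorm(120), site = rep(letters[1:6], each = 20),
                  year = rep(2014:2015, 60))
  d$y <- 2 * d$x + rnorm(120, 0, 0.5) # no site/year signal
  fit <- suppressMessages(fit_lmm("y", "x", d))
  ols <- coef(lm(y ~ x, data = d))
  # variance components need not shrink exactly to zero; near-OLS is enough
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 5e-3)
  expect_error(fit_lmm("y", "k", cbind(d, k = 1)), "constant predictor")
})

test_that("mixed fit recovers a known slope with site effects", {
  set.seed(59)
  cover <- 0
  for (rep in 1:20) {
    site <- rep(sprintf("s%02d", 1:10), each = 30)
    u <- rnorm(10, 0, 1)
    x <- rnorm(300)
    y <- 2 * x + u[as.integer(factor(site))] + rnorm(300, 0, 0.5)
    d <- data.frame(y = y, x = x, site = site, year = 2014L)
    fit <- suppressMessages(fit_lmm("y", "x", d))
    est <- fit$coefficients[fit$coefficients$term == "x", ]
    cover <- cover + (abs(est$estimate - 2) < 1.96 * est$se)
  }
  expect_gte(cover, 17) # ~95% nominal coverage
})

test_that("standardized estimates are scale-free and match a z-score refit", {
  set.seed(60)
  d <- data.frame(x = rnorm(100, 0, 3), site = "s1", year = 2014L)
  d$y <- 0.7 * d$x + rnorm(100)
  fit <- fit_lmm("y", "x", d)
  std <- standardized_estimates(fit)
  d10 <- transform(d, x = x * 10)
  std10 <- standardized_estimates(fit_lmm("y", "x", d10))
  expect_equal(std$std_estimate[std$term == "x"],
               std10$std_estimate[std10$term == "x"], tolerance = 1e-9)
  expect_equal(std10$estimate[std10$term == "x"],
               std$estimate[std$term == "x"] / 10, tolerance = 1e-9)

  dz <- data.frame(x = as.numeric(scale(d$x)), site = "s1", year = 2014L)
  dz$y <- as.numeric(scale(d$y))
  stdz <- standardized_estimates(fit_lmm("y", "x", dz))
  expect_equal(stdz$std_estimate[stdz$term == "x"],
               stdz$estimate[stdz$term == "x"], tolerance = 1e-9)
  # oracle: z-scored refit reproduces the standardized coefficient
  expect_equal(stdz$estimate[stdz$term == "x"],
               std$std_estimate[std$term == "x"], tolerance = 1e-9)
})

test_that("basis set enumerates the union claims of textbook DAGs", {
  chain <- path_dag(data.frame(from = c("X", "Y"), to = c("Y", "Z")))
  claims <- basis_set(chain)
  expect_length(claims, 1)
  expect_equal(claims[[1]]$response, "Z")
  expect_equal(claims[[1]]$predictor, "X")
  expect_equal(claims[[1]]$conditioning, "Y")

  complete <- path_dag(data.frame(from = c("X", "X", "Y"),
                                  to = c("Y", "Z", "Z")))
  expect_length(basis_set(complete), 0)
  expect_true(fishers_c(numeric(0))$saturated)

  expect_error(path_dag(data.frame(from = c("X", "Y"), to = c("Y", "X"))),
               "cyclic")
})

test_that("basis set matches a brute-force adjacency scan", {
  roles <- c(H1 = "habitat", H2 = "habitat", P = "prey", T1 = "trait")
  dag <- path_dag(data.frame(from = c("H1", "P", "H1"),
                             to = c("P", "T1", "T1")), roles = roles)
  claims <- basis_set(dag)
  # brute force: every non-adjacent pair not both-exogenous
  nodes <- sort(c("H1", "H2", "P", "T1"))
  edges <- rbind(c("H1", "P"), c("P", "T1"), c("H1", "T1"))
  want <- list()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    u <- nodes[i]; v <- nodes[j]
    adjacent <- any(apply(edges, 1, function(e) setequal(e, c(u, v))))
    exo <- c("H1", "H2")
    if (!adjacent && !(u %in% exo && v %in% exo)) {
      want[[length(want) + 1L]] <- sort(c(u, v))
    }
  }
  got <- lapply(claims, function(cl) sort(c(cl$response, cl$predictor)))
  expect_equal(got[order(sapply(got, paste, collapse = ""))],
               want[order(sapply(want, paste, collapse = ""))])
  # conditioning is the union of both nodes' parents
  hp <- Filter(function(cl) setequal(c(cl$response, cl$predictor),
                                     c("H2", "T1")), claims)[[1]]
  expect_setequal(hp$conditioning, c("H1", "P"))
})

test_that("Fisher's C matches its closed forms", {
  expect_equal(fishers_c(c(1, 1))$C, 0)
  expect_equal(fishers_c(c(1, 1))$p_value, 1)
  fc <- fishers_c(c(0.05, 0.05))
  expect_equal(fc$C, 11.983, tolerance = 1e-3)
  expect_equal(fc$df, 4)
  expect_equal(fc$p_value, 0.01748, tolerance = 1e-3)
  expect_error(fishers_c(c(0.5, 0)), "0")
})

test_that("variance-partition R2 behaves at its limits", {
  set.seed(61)
  d <- data.frame(x = rnorm(200), site = "s1", year = 2014L)
  d$y <- d$x + rnorm(200)
  fit <- fit_lmm("y", "x", d)
  r2 <- r2_mixed(fit)
  expect_equal(r2[["marginal"]], r2[["conditional"]])

  fit0 <- fit_lmm("y", character(0), d)
  expect_equal(r2_mixed(fit0)[["marginal"]], 0)
})

test_that("R2 recovers a planted variance budget", {
  set.seed(62)
  n_site <- 40
  site <- rep(sprintf("s%02d", 1:n_site), each = 50)
  u <- rnorm(n_site, 0, 1)
  x <- rnorm(2000)
  y <- x + u[as.integer(factor(site))] + rnorm(2000, 0, sqrt(2))
  d <- data.frame(y = y, x = x, site = site, year = 2014L)
  r2 <- r2_mixed(suppressMessages(fit_lmm("y", "x", d)))
  expect_equal(r2[["marginal"]], 0.25, tolerance = 0.05)
  expect_equal(r2[["conditional"]], 0.5, tolerance = 0.05)
})

test_that("selection keeps strong planted paths and is idempotent", {
  ps <- simulate_path_study(seed = 63)
  m <- suppressMessages(select_model(ps$dag, ps$data))
  expect_equal(nrow(m$edges), 3) # all planted paths survive
  expect_equal(nrow(attr(m, "removed")), 0)
  # idempotence: selecting again from the final DAG changes nothing
  m2 <- suppressMessages(select_model(m$dag, ps$data))
  expect_equal(m2$edges[c("from", "to")], m$edges[c("from", "to")])
  expect_equal(m2$edges$std_estimate, m$edges$std_estimate,
               tolerance = 1e-12)
})

test_that("pure-noise predictors are pruned from the trait model", {
  set.seed(64)
  removed <- 0
  for (rep in 1:10) {
    ps <- simulate_path_study(n_campaigns = 30L, n_per_campaign = 15L,
                              seed = 640 + rep)
    d <- ps$data
    camp <- unique(d$campaign_id)
    noise <- setNames(rnorm(length(camp)), camp)
    d$HabNoise <- noise[d$campaign_id]
    dag <- path_dag(rbind(ps$dag$edges,
                          data.frame(from = "HabNoise", to = "BIC")),
                    roles = c(ps$dag$roles, HabNoise = "habitat"))
    m <- suppressMessages(select_model(dag, d))
    rem <- attr(m, "removed")
    removed <- removed + any(rem$item == "HabNoise -> BIC")
  }
  expect_gte(removed, 8)
})

test_that("effect decomposition multiplies standardized path chains", {
  ps <- simulate_path_study(seed = 65)
  m <- suppressMessages(fit_path_model(ps$dag, ps$data))
  e <- m$edges
  std <- function(f, t) e$std_estimate[e$from == f & e$to == t]
  eff <- m$effects
  expect_equal(eff$direct[eff$habitat == "Hab1"], std("Hab1", "BIC"))
  expect_equal(eff$indirect[eff$habitat == "Hab1"],
               std("Hab1", "Prey1") * std("Prey1", "BIC"))
  expect_equal(eff$total, eff$direct + eff$indirect)
})

test_that("saturated three-node model reports C = 0", {
  ps <- simulate_path_study(seed = 66)
  m <- suppressMessages(fit_path_model(ps$dag, ps$data))
  expect_true(m$saturated)
  expect_equal(m$C, 0)
  expect_equal(m$df, 0)
})
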