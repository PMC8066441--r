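test_that("haversine distances match closed forms", {
  R <- 6371.0088
  frame <- validate_sample_frame(data.frame(
    sample_id = c("o", "e", "n", "anti"), group = "g",
    lat = c(0, 0, 1, 0), lon = c(0, 1, 0, 180)))
  d <- haversine_matrix(frame)
  expect_equal(d["o", "o"], 0)
  expect_lt(abs(d["o", "e"] - 2 * pi * R / 360), 0.01)
  expect_lt(abs(d["o", "n"] - 2 * pi * R / 360), 0.01)
  expect_lt(abs(d["o", "anti"] - pi * R), 1)
  frame$lat[2] <- NA
  expect_error(haversine_matrix(frame), "missing coordinates")
})

test_that("mantel matches the condensed-triangle oracle and is calibrated", {
  pe <- planted_euclidean(10, seed = 8)
  pe2 <- planted_euclidean(10, seed = 9)
  rownames(pe2$dm) <- colnames(pe2$dm) <- rownames(pe$dm)
  res <- mantel(pe$dm, pe2$dm, method = "spearman", n_perm = 199, seed = 1)
  v1 <- pe$dm[upper.tri(pe$dm)]; v2 <- pe2$dm[upper.tri(pe2$dm)]
  expect_equal(res$statistic, cor(v1, v2, method = "spearman"))
  # against vegan as an independent implementation
  vg <- vegan::mantel(as.dist(unclass(pe$dm)), as.dist(unclass(pe2$dm)),
                      method = "spearman", permutations = 99)
  expect_equal(res$statistic, unname(vg$statistic))
  # self-comparison: statistic 1, smallest attainable p
  self <- mantel(pe$dm, pe$dm, n_perm = 199, seed = 2)
  expect_equal(self$statistic, 1)
  expect_equal(self$p, 1 / 200)
  # type-I calibration over 20 independent pairs
  rejections <- 0L
  for (s in 1:20) {
    a <- planted_euclidean(12, seed = 100 + s)
    b <- planted_euclidean(12, seed = 200 + s)
    rownames(b$dm) <- colnames(b$dm) <- rownames(a$dm)
    if (mantel(a$dm, b$dm, n_perm = 99, seed = s)$p <= 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, 4L)
})

test_that("distance_decay detects monotone decay and counts pairs", {
  # similarity a strictly decreasing function of distance -> rho = -1
  n <- 8
  frame <- validate_sample_frame(data.frame(
    sample_id = sprintf("s%d", 1:n), group = "g", lat = 42,
    lon = 86 + 0.05 * (1:n)))
  geo <- haversine_matrix(frame)
  sim <- exp(-unclass(geo) / 10); diag(sim) <- 1
  comm <- dist_matrix(1 - sim, metric = "bray_curtis")
  dd <- distance_decay(geo, comm, n_perm = 199, seed = 3)
  expect_equal(dd$rho, -1)
  expect_equal(dd$n_pairs, n * (n - 1) / 2)
  expect_lt(dd$trend[["slope"]], 0)
  expect_lte(dd$p, 0.05)
})

test_that("pcnm truncation, orthogonality and transect wave structure", {
  n <- 20
  frame <- validate_sample_frame(data.frame(
    sample_id = sprintf("s%02d", 1:n), group = "g", lat = 42,
    lon = 86 + 0.02 * (1:n)))
  geo <- haversine_matrix(frame)
  sp <- pcnm(geo)
  # truncation = MST max edge; on a regular transect that is the step length
  step <- geo[1, 2]
  expect_equal(sp$truncation, step, tolerance = 1e-9)
  # brute-force MST oracle via vegan::spantree
  expect_equal(sp$truncation, max(vegan::spantree(as.dist(unclass(geo)))$dist))
  # eigenvectors centred and mutually orthogonal
  expect_true(all(abs(colMeans(sp$vectors)) < 1e-8))
  g <- crossprod(sp$vectors); diag(g) <- 0
  expect_true(all(abs(g) < 1e-6))
  # first eigenfunction: a half-wave with exactly one sign change
  signs <- sign(sp$vectors[, 1])
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1)
  # duplicate coordinates -> truncation would be 0
  frame2 <- frame; frame2$lon[2] <- frame2$lon[1]
  expect_error(pcnm(haversine_matrix(frame2)), "truncation")
})

test_that("forward_select has power on the generating gradient and honours contracts", {
  pool <- simulate_metacommunity(120, log_sd = 1.2, seed = 14)
  nic <- simulate_niche_samples(pool,
    simulation_scenario("niche", n_samples = 16, J = 3000,
                        niche_breadth = 0.3, seed = 15))
  sel <- forward_select(nic$table, data.frame(gradient = nic$frame$gradient),
                        n_perm = 199, seed = 5)
  expect_equal(sel$variable, "gradient")
  expect_lte(sel$p[1], 0.05)
  # determinism
  sel2 <- forward_select(nic$table, data.frame(gradient = nic$frame$gradient),
                         n_perm = 199, seed = 5)
  expect_identical(sel, sel2)
  # pure-noise candidates select rarely (~alpha); empty set is not an error
  picks <- 0L
  for (s in 1:20) {
    noise <- riverlake:::with_seed(300 + s,
      data.frame(x1 = rnorm(16), x2 = rnorm(16)))
    got <- forward_select(nic$table, noise, n_perm = 99, seed = s)
    if (nrow(got) > 0) picks <- picks + 1L
  }
  expect_lte(picks, 5L)
  # collinear candidate is skipped with a warning
  expect_warning(
    forward_select(nic$table, data.frame(g = nic$frame$gradient,
                                         g2 = 2 * nic$frame$gradient),
                   n_perm = 99, seed = 1),
    "collinear")
})

test_that("cca_analysis decomposes inertia and flags significance", {
  pool <- simulate_metacommunity(100, log_sd = 1.2, seed = 24)
  nic <- simulate_niche_samples(pool,
    simulation_scenario("niche", n_samples = 14, J = 3000,
                        niche_breadth = 0.3, seed = 25))
  res <- cca_analysis(nic$table, data.frame(gradient = nic$frame$gradient),
                      n_perm = 999, seed = 2)
  expect_lte(res$anova_p, 0.005)
  # constrained + unconstrained = total inertia
  expect_equal(res$cca$CCA$tot.chi + res$cca$CA$tot.chi, res$cca$tot.chi,
               tolerance = 1e-9)
  expect_equal(res$sole$inertia_pct, 100 * res$constrained_prop, tolerance = 1e-9)
  # constant predictor -> zero constrained inertia (vegan aliases it)
  res0 <- suppressMessages(cca_analysis(nic$table, data.frame(k = rep(1, 14))))
  expect_equal(res0$constrained_prop, 0)
  # genuinely rank-deficient predictors -> error
  expect_error(cca_analysis(nic$table,
                            data.frame(a = nic$frame$gradient,
                                       b = 2 * nic$frame$gradient)), "rank")
})

test_that("variation partitioning fractions behave and sum to one", {
  pool <- simulate_metacommunity(90, log_sd = 1.2, seed = 34)
  nic <- simulate_niche_samples(pool,
    simulation_scenario("niche", n_samples = 20, J = 2500,
                        niche_breadth = 0.3, seed = 35))
  geo <- haversine_matrix(nic$frame)
  sp <- pcnm(geo)
  spa <- sp$vectors[, 1:3]
  env <- nic$frame["gradient"]
  vp <- variation_partition(nic$table, env, spa)
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
  # env identical to spatial predictors: pure fractions collapse into shared
  vp_same <- variation_partition(nic$table, as.data.frame(spa), spa)
  expect_lt(abs(vp_same$a), 1e-9)
  expect_lt(abs(vp_same$c), 1e-9)
  # env orthogonal to space by construction: shared fraction near zero
  n <- 50
  set.seed(77)
  Y <- matrix(rpois(n * 40, 20), n,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("t%02d", 1:40)))
  x_spa <- rnorm(n)
  x_env <- residuals(lm(rnorm(n) ~ x_spa))   # orthogonalised
  vp_orth <- variation_partition(count_table(Y), data.frame(e = x_env),
                                 matrix(x_spa, dimnames = list(rownames(Y), "s1")))
  expect_lt(abs(vp_orth$b), 0.02)
  # order invariance of predictors
  env2 <- cbind(nic$frame["gradient"], noise = riverlake:::with_seed(1, rnorm(20)))
  expect_equal(unclass(variation_partition(nic$table, env2, spa))[c("a", "b", "c", "d")],
               unclass(variation_partition(nic$table, env2[, 2:1], spa))[c("a", "b", "c", "d")])
  expect_error(variation_partition(nic$table, NULL, NULL), "at least one")
})

test_that("niche data with a spatially structured gradient shows shared dominance", {
  pool <- simulate_metacommunity(100, log_sd = 1.2, seed = 44)
  nic <- simulate_niche_samples(pool,
    simulation_scenario("niche", n_samples = 20, J = 2500, niche_breadth = 0.3,
                        env_range_km = 120, seed = 45))
  sp <- pcnm(haversine_matrix(nic$frame))
  vp <- variation_partition(nic$table, nic$frame["gradient"], sp$vectors[, 1:2])
  expect_gt(vp$b, vp$a)
  expect_gt(vp$b, vp$c)
})
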