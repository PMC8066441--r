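test_that("filter_for_network applies strict thresholds", {
  # 4 samples; taxon A in exactly 2/4 samples, taxon B mean rel abund exactly 5e-4
  m <- matrix(c(10, 10, 0, 0,
                1, 1, 1, 1,
                500, 500, 500, 500), 4, 3,
              dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  tot <- rowSums(m)
  # scale B so its mean relative abundance is exactly 0.05%
  target <- 0.0005
  mB <- mean(m[, "B"] / tot)
  ct <- count_table(m)
  filt <- filter_for_network(ct, min_rel_abund = mean(m[, "A"] / tot) - 1e-9,
                             min_occurrence = 0.5)
  expect_false("A" %in% taxon_ids(filt))      # occurrence exactly 50% -> excluded
  filt2 <- filter_for_network(ct, min_rel_abund = mB, min_occurrence = 0.25)
  expect_false("B" %in% taxon_ids(filt2))     # mean rel abund exactly at cutoff
  # brute-force two-pass oracle on a random table
  ct2 <- toy_table(10, 40, seed = 55, lambda = 1)
  f <- filter_for_network(ct2, 0.01, 0.5)
  rel <- ct2$counts / rowSums(ct2$counts)
  keep <- colnames(ct2$counts)[colMeans(rel) > 0.01 & colMeans(ct2$counts > 0) > 0.5]
  expect_equal(taxon_ids(f), keep)
  expect_error(filter_for_network(ct2, 0.9, 0.99), "no taxa")
})

test_that("correlation_matrix equals the covariance/sd oracle and recovers blocks", {
  ct <- toy_table(12, 8, seed = 65, lambda = 10)
  r <- correlation_matrix(ct)
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  rel <- ct$counts / rowSums(ct$counts)
  i <- 2; j <- 5
  expect_equal(r[i, j], cov(rel[, i], rel[, j]) / (sd(rel[, i]) * sd(rel[, j])))
  sim <- simulate_block_correlated_taxa(40, list(list(size = 6, sign = 1,
                                                      strength = 0.85)),
                                        n_background = 20, seed = 6)
  rr <- correlation_matrix(sim$table)
  within <- rr[1:6, 1:6][upper.tri(rr[1:6, 1:6])]
  bg <- rr[7:26, 7:26][upper.tri(rr[7:26, 7:26])]
  expect_gt(median(within), median(abs(bg)))
  # zero-variance taxon dropped with warning
  m <- ct$counts; m[, 3] <- 7
  expect_warning(r2 <- correlation_matrix(count_table(m), log_transform = TRUE),
                 "zero-variance")
  expect_equal(ncol(r2), 7)
})

test_that("rmt_threshold scans candidates and respects planted structure", {
  sim <- simulate_block_correlated_taxa(30,
    list(list(size = 10, sign = 1, strength = 0.9),
         list(size = 10, sign = 1, strength = 0.9)),
    n_background = 80, seed = 16)
  corr <- correlation_matrix(sim$table)
  res <- rmt_threshold(corr, scan = seq(0.3, 0.8, by = 0.1))
  expect_true(res$threshold %in% seq(0.3, 0.8, by = 0.1) || res$fallback_used)
  expect_true(all(diff(res$diagnostics$n_edges) <= 0))  # monotone edge survival
  if (!res$fallback_used) {
    # blocks survive: threshold below the planted within-block correlation
    b1 <- corr[1:10, 1:10][upper.tri(corr[1:10, 1:10])]
    expect_lt(res$threshold, median(b1))
  }
  # single-candidate scan returns that candidate (or flags fallback)
  res1 <- rmt_threshold(corr, scan = 0.5, fallback = 0.5)
  expect_equal(res1$threshold, 0.5)
})

test_that("build_network thresholds edges with signs; error with no edges", {
  r <- matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  net <- build_network(r, 0.8)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_true(all(net$edges$sign == "positive"))
  # planted negative inter-block pairs are recovered as negative edges
  sim <- simulate_block_correlated_taxa(40,
    list(list(size = 5, sign = 1, strength = 0.9),
         list(size = 5, sign = -1, strength = 0.9)), seed = 26)
  corr <- correlation_matrix(sim$table)
  net2 <- build_network(corr, 0.5)
  neg <- net2$edges[net2$edges$sign == "negative", ]
  b1 <- sprintf("ASV_%04d", 1:5); b2 <- sprintf("ASV_%04d", 6:10)
  expect_gt(nrow(neg), 0)
  expect_true(all((neg$from %in% b1 & neg$to %in% b2) |
                  (neg$from %in% b2 & neg$to %in% b1)))
  noise <- diag(3); dimnames(noise) <- list(letters[1:3], letters[1:3])
  expect_error(build_network(noise, 0.99), "no edges")
})

test_that("network_metrics matches closed forms for K3 and P3", {
  k3 <- matrix(c(1, .9, .9, .9, 1, .9, .9, .9, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  m3 <- network_metrics(build_network(k3, 0.5))
  expect_equal(m3$avgCC, 1); expect_equal(m3$APL, 1); expect_equal(m3$ND, 1)
  expect_equal(m3$AD, 2); expect_equal(m3$GD, 1)
  # path a-b-c
  p3 <- matrix(c(1, .9, 0, .9, 1, .9, 0, .9, 1), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  mp <- network_metrics(build_network(p3, 0.5))
  expect_equal(mp$avgCC, 0); expect_equal(mp$APL, 4 / 3); expect_equal(mp$ND, 2)
  expect_equal(mp$AD, 4 / 3); expect_equal(mp$GD, 2 / 3)
  # AD/GD identities on a bigger random network
  sim <- simulate_block_correlated_taxa(30, list(list(size = 12, sign = 1,
                                                      strength = 0.8)),
                                        n_background = 30, seed = 36)
  net <- build_network(correlation_matrix(sim$table), 0.45)
  met <- network_metrics(net)
  g <- net$graph
  expect_equal(met$AD, mean(igraph::degree(g)), tolerance = 1e-12)
  expect_equal(met$GD, igraph::edge_density(g), tolerance = 1e-12)
  expect_equal(met$E_positive + met$E_negative, met$E)
  expect_equal(met$pct_positive + met$pct_negative, 100)
  expect_gte(met$modularity, 0)
})

test_that("printed lake topology panel is internally consistent", {
  # published worked example: N = 115, E = 2104 -> AD 36.59, GD 0.321
  expect_equal(round(2 * 2104 / 115, 2), 36.59)
  expect_equal(round(2 * 2104 / (115 * 114), 3), 0.321)
})

test_that("random ensemble sigma: formula, identity case, and G(N,E) degree", {
  expect_equal(small_world_sigma(0.3, 2.5, 0.3, 2.5), 1)
  sim <- simulate_block_correlated_taxa(30, list(list(size = 10, sign = 1,
                                                      strength = 0.85)),
                                        n_background = 20, seed = 46)
  met <- network_metrics(build_network(correlation_matrix(sim$table), 0.4))
  sw <- random_ensemble_sigma(met, n_random = 20, seed = 3)
  expect_equal(sw$sigma,
               (met$avgCC / sw$avgCC_r) / (met$APL / sw$APL_r))
  # every G(N, E) draw has average degree exactly 2E/N
  g <- riverlake:::with_seed(9, igraph::sample_gnm(met$N, met$E))
  expect_equal(mean(igraph::degree(g)), 2 * met$E / met$N)
  fake <- met; fake$E <- met$N * (met$N - 1)  # impossible edge count
  expect_error(random_ensemble_sigma(fake, n_random = 10, seed = 1), "exceeds")
})

test_that("node_roles computes zi/Pi with the canonical cutlines", {
  # two triangles joined by a bridge: construct correlation matrix directly
  ids <- letters[1:6]
  r <- diag(6); dimnames(r) <- list(ids, ids)
  link <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  for (k in seq_len(nrow(link))) r[link[k, 1], link[k, 2]] <-
      r[link[k, 2], link[k, 1]] <- 0.9
  net <- build_network(r, 0.5)
  membership <- stats::setNames(c(1, 1, 1, 2, 2, 2), ids)
  roles <- node_roles(net, membership)
  # all links of "a" inside its module -> Pi = 0
  expect_equal(roles$Pi[roles$node == "a"], 0)
  # "c" has 2 links in module 1 and 1 in module 2: Pi = 1 - (2/3)^2 - (1/3)^2
  expect_equal(roles$Pi[roles$node == "c"], 1 - (2 / 3)^2 - (1 / 3)^2)
  # node with links split equally across 2 modules: Pi = 0.5
  r2 <- diag(3); dimnames(r2) <- list(c("x", "y", "z"), c("x", "y", "z"))
  r2["x", "y"] <- r2["y", "x"] <- 0.9
  r2["x", "z"] <- r2["z", "x"] <- 0.9
  net2 <- build_network(r2, 0.5)
  roles2 <- node_roles(net2, c(x = 1, y = 1, z = 2))
  expect_equal(roles2$Pi[roles2$node == "x"], 0.5)
  # single-module network: everyone peripheral unless zi >= 2.5
  roles3 <- node_roles(net, stats::setNames(rep(1, 6), ids))
  expect_true(all(roles3$Pi == 0))
  expect_true(all(roles3$role[roles3$zi < 2.5] == "peripheral"))
})

test_that("export_network round-trips the edge set", {
  sim <- simulate_block_correlated_taxa(25, list(list(size = 8, sign = 1,
                                                      strength = 0.85)),
                                        n_background = 10, seed = 56)
  lin <- toy_lineages(taxon_ids(sim$table))
  net <- build_network(correlation_matrix(sim$table), 0.4, lineages = lin)
  met <- network_metrics(net)
  roles <- node_roles(net, met$membership)
  dir <- tempfile("net")
  paths <- export_network(net, met, roles, dir)
  expect_true(all(file.exists(paths)))
  g2 <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g2), met$E)
  edges <- read.delim(paths[["edges"]])
  nodes <- read.delim(paths[["nodes"]])
  expect_equal(nrow(edges), met$E)
  expect_equal(nrow(nodes), met$N)
  # edge sets identical as unordered pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  el <- igraph::as_edgelist(g2)
  expect_setequal(key(el[, 1], el[, 2]), key(net$edges$from, net$edges$to))
})
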