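#' Select abundant, frequent taxa for network construction
#'
#' Keeps taxa whose mean relative abundance is strictly above
#' `min_rel_abund` (default 0.05%) and whose occurrence is strictly above
#' `min_occurrence` of the samples (default 50%), mirroring the usual
#' abundant-and-frequent pre-filter for co-occurrence networks.
#'
#' @param x a `count_table`.
#' @param min_rel_abund mean relative-abundance threshold in (0, 1).
#' @param min_occurrence occupancy threshold in (0, 1).
#' @return a filtered `count_table`.
#' @export
filter_for_network <- function(x, min_rel_abund = 0.0005, min_occurrence = 0.5) {
  stopifnot(inherits(x, "count_table"),
            min_rel_abund > 0, min_rel_abund < 1,
            min_occurrence > 0, min_occurrence < 1)
  rel <- x$counts / rowSums(x$counts)
  keep <- colMeans(rel) > min_rel_abund & colMeans(x$counts > 0) > min_occurrence
  if (!any(keep))
    stopf("no taxa pass the network filter; relax min_rel_abund/min_occurrence")
  count_table(x$counts[, keep, drop = FALSE],
              lineages = if (is.null(x$lineages)) NULL else x$lineages[keep])
}

#' Pairwise taxon correlation matrix
#'
#' Pearson correlations of per-sample relative abundances (optionally
#' log(1 + x)-transformed counts). Zero-variance taxa are dropped with a
#' warning.
#'
#' @param x a `count_table` with >= 4 samples.
#' @param method currently `"pearson"`.
#' @param log_transform correlate log1p counts instead of relative abundances.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x, method = "pearson", log_transform = FALSE) {
  stopifnot(inherits(x, "count_table"))
  method <- match.arg(method, "pearson")
  if (n_samples(x) < 4L) stopf("need at least 4 samples")
  m <- if (log_transform) log1p(x$counts) else x$counts / rowSums(x$counts)
  v <- apply(m, 2L, stats::sd)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance taxa", sum(v == 0)))
    m <- m[, v > 0, drop = FALSE]
  }
  stats::cor(m, method = method)
}

#' Random-matrix-theory threshold for a correlation network
#'
#' Scans candidate thresholds; for each, entries below the threshold (in
#' absolute value) are zeroed and the eigenvalue nearest-neighbour spacing
#' distribution (NNSD) of the resulting matrix is tested against the
#' Poisson law \eqn{e^{-s}} by a chi-square on binned, unfolded spacings.
#' Random-matrix theory predicts Wigner-Dyson (GOE) spacings for a noisy
#' matrix and Poisson spacings once only modular signal remains; the chosen
#' threshold is the lowest candidate whose NNSD is consistent with Poisson
#' (chi-square p > `alpha`). Unfolding uses a smooth cubic fit to the
#' cumulative spectral function.
#'
#' @param corr symmetric correlation matrix.
#' @param scan numeric vector of candidate thresholds in (0, 1), scanned in
#'   increasing order.
#' @param alpha significance level of the chi-square test (default 0.05).
#' @param n_bins spacing histogram bins (default 20).
#' @param fallback threshold returned (with a warning) when no candidate
#'   satisfies the criterion.
#' @return list with `threshold`, `diagnostics` (data.frame per candidate:
#'   threshold, n_edges, chisq, p, poisson_ok), `fallback_used`.
#' @export
rmt_threshold <- function(corr, scan = seq(0.5, 0.9, by = 0.05), alpha = 0.05,
                          n_bins = 20, fallback = 0.8) {
  stopifnot(all(scan > 0), all(scan < 1))
  scan <- sort(scan)
  diag_rows <- list()
  chosen <- NA_real_
  for (th in scan) {
    m <- corr
    m[abs(m) < th] <- 0
    n_edges <- (sum(m != 0) - nrow(m)) / 2
    res <- nnsd_poisson_test(m, n_bins = n_bins)
    ok <- !is.na(res$p) && res$p > alpha
    diag_rows[[length(diag_rows) + 1L]] <-
      data.frame(threshold = th, n_edges = n_edges, chisq = res$chisq,
                 p = res$p, poisson_ok = ok)
    if (is.na(chosen) && ok) chosen <- th
  }
  diagnostics <- do.call(rbind, diag_rows)
  fallback_used <- is.na(chosen)
  if (fallback_used) {
    warning("no scanned threshold gave Poisson spacing statistics; ",
            sprintf("falling back to fixed threshold %.2f", fallback))
    chosen <- fallback
  }
  list(threshold = chosen, diagnostics = diagnostics, fallback_used = fallback_used)
}

# Chi-square test of the unfolded nearest-neighbour spacing distribution
# against Poisson exp(-s). Returns NA p when too few eigenvalues remain.
nnsd_poisson_test <- function(m, n_bins = 20) {
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  ev <- unique(round(ev, 10))          # degenerate eigenvalues carry no spacing info
  if (length(ev) < n_bins + 5L) return(list(chisq = NA_real_, p = NA_real_))
  # unfold via smooth cubic fit of the cumulative spectral function
  cum <- seq_along(ev)
  fit <- stats::lm(cum ~ stats::poly(ev, 3))
  unfolded <- stats::fitted(fit)
  s <- diff(unfolded)
  s <- s[s > 0]
  s <- s / mean(s)
  edges <- c(seq(0, 3, length.out = n_bins), Inf)
  obs <- as.numeric(table(cut(s, edges)))
  expd <- length(s) * diff(stats::pexp(edges))
  keep <- expd > 1e-12
  chisq <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  df <- sum(keep) - 1L
  list(chisq = chisq, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Build a signed co-occurrence network from a correlation matrix
#'
#' Edge (i, j) exists iff |r_ij| >= threshold; the sign of r is kept as an
#' edge attribute. Isolated nodes are dropped.
#'
#' @param corr symmetric correlation matrix.
#' @param threshold absolute-correlation cutoff in (0, 1).
#' @param lineages optional named lineage vector used to annotate nodes
#'   with a phylum.
#' @return list of class `corr_network`: `graph` (igraph, weight = r,
#'   sign attribute), `edges` (data.frame), `threshold`, `method`.
#' @export
build_network <- function(corr, threshold, lineages = NULL) {
  stopifnot(threshold > 0, threshold < 1 + 1e-12)
  adj <- corr
  diag(adj) <- 0
  adj[abs(adj) < threshold] <- 0
  ut <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) stopf("no edges at threshold %.2f", threshold)
  edges <- data.frame(from = rownames(adj)[ut[, 1L]],
                      to = colnames(adj)[ut[, 2L]],
                      r = adj[ut],
                      sign = ifelse(adj[ut] > 0, "positive", "negative"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::E(g)$weight <- abs(edges$r)
  igraph::E(g)$r <- edges$r
  igraph::E(g)$sign <- edges$sign
  if (!is.null(lineages)) {
    phyla <- vapply(igraph::V(g)$name, function(id) {
      lin <- lineages[[id]] %||% NA_character_
      if (is.na(lin)) return("unclassified")
      parts <- strsplit(lin, ";", fixed = TRUE)[[1L]]
      if (length(parts) >= 2L && nzchar(trimws(parts[2L]))) trimws(parts[2L]) else "unclassified"
    }, character(1))
    igraph::V(g)$phylum <- unname(phyla)
  }
  structure(list(graph = g, edges = edges, threshold = threshold,
                 method = "pearson"),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes, %d edges (|r| >= %.2f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Topology panel of a co-occurrence network
#'
#' Computes the standard descriptive panel: node and signed edge counts,
#' fast-greedy modularity, average local clustering coefficient (nodes with
#' degree < 2 contribute 0), average path length and diameter (on the
#' largest connected component; per-component values are also returned),
#' average degree AD = 2E/N and graph density GD = 2E/(N(N-1)).
#'
#' @param net a `corr_network`.
#' @return list of class `network_metrics` with fields `N`, `E`,
#'   `E_positive`, `E_negative`, `pct_positive`, `pct_negative`,
#'   `modularity`, `membership`, `avgCC`, `APL`, `ND`, `AD`, `GD`,
#'   `components`.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  g <- net$graph
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (E < 1L) stopf("network has no edges")
  Ep <- sum(igraph::E(g)$sign == "positive")
  En <- E - Ep
  # community detection needs a simple positive-weight graph
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero", weights = NA)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  gl <- igraph::induced_subgraph(g, which(comp$membership == big))
  per_comp <- lapply(seq_len(comp$no), function(k) {
    gk <- igraph::induced_subgraph(g, which(comp$membership == k))
    c(n = igraph::vcount(gk),
      apl = igraph::mean_distance(gk, weights = NA),
      nd = igraph::diameter(gk, weights = NA))
  })
  structure(list(N = N, E = E, E_positive = Ep, E_negative = En,
                 pct_positive = 100 * Ep / E, pct_negative = 100 * En / E,
                 modularity = igraph::modularity(comm),
                 membership = stats::setNames(igraph::membership(comm),
                                              igraph::V(g)$name),
                 avgCC = mean(cc),
                 APL = igraph::mean_distance(gl, weights = NA),
                 ND = igraph::diameter(gl, weights = NA),
                 AD = 2 * E / N,
                 GD = 2 * E / (N * (N - 1)),
                 components = per_comp),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network_metrics: N = %d, E = %d (%.1f%% +, %.1f%% -), ",
                     "modularity = %.3f\n  avgCC = %.3f, APL = %.3f, ND = %d, ",
                     "AD = %.2f, GD = %.3f\n"),
              x$N, x$E, x$pct_positive, x$pct_negative, x$modularity,
              x$avgCC, x$APL, x$ND, x$AD, x$GD))
  invisible(x)
}

#' Small-world coefficient from empirical and random-network values
#'
#' \eqn{\sigma = (avgCC / avgCC_r) / (APL / APL_r)}; values above 1 indicate
#' small-world structure (higher clustering than random at comparable path
#' length). A pure function so printed topology panels can be re-checked.
#'
#' @param avgCC,APL empirical average clustering coefficient and path length.
#' @param avgCC_r,APL_r random-ensemble means.
#' @return sigma.
#' @export
small_world_sigma <- function(avgCC, APL, avgCC_r, APL_r) {
  (avgCC / avgCC_r) / (APL / APL_r)
}

#' Random-graph ensemble and small-world coefficient
#'
#' Generates Erdos-Renyi G(N, E) graphs with the empirical node and edge
#' counts, averages their clustering, path length (largest component) and
#' fast-greedy modularity, and forms the small-world coefficient.
#'
#' @param metrics a `network_metrics` object.
#' @param n_random ensemble size (>= 10; default 100).
#' @param seed integer seed.
#' @return list of class `small_world`: ensemble means and sds, `sigma`,
#'   `n_random`.
#' @export
random_ensemble_sigma <- function(metrics, n_random = 100, seed = 1) {
  stopifnot(inherits(metrics, "network_metrics"), n_random >= 10)
  N <- metrics$N; E <- metrics$E
  if (E > N * (N - 1) / 2) stopf("E exceeds the maximum for %d nodes", N)
  stats_r <- with_seed(seed, {
    t(vapply(seq_len(n_random), function(k) {
      g <- igraph::sample_gnm(N, E)
      comp <- igraph::components(g)
      gl <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
      c(cc = mean(igraph::transitivity(g, type = "local", isolates = "zero")),
        apl = igraph::mean_distance(gl),
        mod = igraph::modularity(igraph::cluster_fast_greedy(g)))
    }, numeric(3)))
  })
  avgCC_r <- mean(stats_r[, "cc"]); APL_r <- mean(stats_r[, "apl"])
  structure(list(avgCC_r = avgCC_r, avgCC_r_sd = stats::sd(stats_r[, "cc"]),
                 APL_r = APL_r, APL_r_sd = stats::sd(stats_r[, "apl"]),
                 modularity_r = mean(stats_r[, "mod"]),
                 modularity_r_sd = stats::sd(stats_r[, "mod"]),
                 sigma = small_world_sigma(metrics$avgCC, metrics$APL, avgCC_r, APL_r),
                 n_random = n_random),
            class = "small_world")
}

#' @export
print.small_world <- function(x, ...) {
  cat(sprintf("small_world: sigma = %.2f (avgCC_r = %.3f, APL_r = %.3f, n = %d)\n",
              x$sigma, x$avgCC_r, x$APL_r, x$n_random))
  invisible(x)
}

#' Topological role of each node (zi / Pi)
#'
#' Within-module degree z-score \eqn{z_i = (k_{i,within} - \bar k_{m})
#' / sd(k_m)} (0 when the module sd is 0) and among-module connectivity
#' \eqn{P_i = 1 - \sum_s (k_{is} / k_i)^2}, with the conventional cutlines
#' zi >= 2.5 and Pi >= 0.62 classifying nodes as peripheral, connector,
#' module hub or network hub.
#'
#' @param net a `corr_network`.
#' @param membership named module membership (e.g. from [network_metrics()]).
#' @return data.frame with node, module, degree, zi, Pi, role.
#' @export
node_roles <- function(net, membership) {
  stopifnot(inherits(net, "corr_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  miss <- setdiff(nodes, names(membership))
  if (length(miss)) stopf("nodes without module assignment: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  k_within <- vapply(seq_along(nodes), function(i)
    sum(adj[i, mem == mem[i]]), numeric(1))
  zi <- numeric(length(nodes))
  for (mod in unique(mem)) {
    i <- which(mem == mod)
    s <- stats::sd(k_within[i])
    zi[i] <- if (is.na(s) || s == 0) 0 else (k_within[i] - mean(k_within[i])) / s
  }
  Pi <- vapply(seq_along(nodes), function(i) {
    if (k[i] == 0) return(0)
    k_is <- tapply(adj[i, ], mem, sum)
    1 - sum((k_is / k[i])^2)
  }, numeric(1))
  role <- ifelse(zi >= 2.5 & Pi >= 0.62, "network hub",
          ifelse(zi >= 2.5, "module hub",
          ifelse(Pi >= 0.62, "connector", "peripheral")))
  data.frame(node = nodes, module = as.integer(mem), degree = k,
             zi = zi, Pi = Pi, role = role, row.names = NULL)
}

#' Export a network for external visualisation
#'
#' Writes GraphML, a signed weighted edge list (TSV) and a node table (TSV)
#' with degree, module, zi, Pi and role.
#'
#' @param net a `corr_network`.
#' @param metrics a `network_metrics` (for module membership).
#' @param roles data.frame from [node_roles()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
export_network <- function(net, metrics, roles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(graphml = file.path(dir, "network.graphml"),
             edges = file.path(dir, "edges.tsv"),
             nodes = file.path(dir, "nodes.tsv"))
  igraph::write_graph(net$graph, paths[["graphml"]], format = "graphml")
  utils::write.table(net$edges, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- net$graph
  nodes <- data.frame(node = igraph::V(g)$name,
                      phylum = if (!is.null(igraph::V(g)$phylum))
                        igraph::V(g)$phylum else NA_character_)
  nodes <- merge(nodes, roles, by = "node", sort = FALSE)
  utils::write.table(nodes, paths[["nodes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
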