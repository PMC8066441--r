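#' Great-circle distance matrix between samples (km)
#'
#' Haversine distances on a sphere of radius 6371.0088 km from decimal
#' degree coordinates. No projection is applied: at catchment scale (~1
#' degree) curvature error is negligible.
#'
#' @param frame a `sample_frame` with `lat`/`lon`.
#' @return a [dist_matrix()] in km.
#' @export
haversine_matrix <- function(frame) {
  bad <- frame$sample_id[is.na(frame$lat) | is.na(frame$lon)]
  if (length(bad)) stopf("missing coordinates for: %s", paste(bad, collapse = ", "))
  R <- 6371.0088
  lat <- frame$lat * pi / 180
  lon <- frame$lon * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n, dimnames = list(frame$sample_id, frame$sample_id))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    a <- sin((lat[j] - lat[i]) / 2)^2 +
      cos(lat[i]) * cos(lat[j]) * sin((lon[j] - lon[i]) / 2)^2
    d[j, i] <- 2 * R * asin(pmin(1, sqrt(a)))
  }
  dist_matrix(d + t(d), metric = "haversine_km")
}

#' Mantel test between two distance matrices
#'
#' Correlates the condensed upper triangles and assesses significance by
#' jointly permuting rows and columns of the second matrix;
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + n_{perm})} (one-sided,
#' positive association).
#'
#' @param dm1,dm2 [dist_matrix()] objects with identical labels.
#' @param method `"spearman"` (default, the rank correlation used for
#'   distance-decay work) or `"pearson"`.
#' @param n_perm permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`, `method`.
#' @export
mantel <- function(dm1, dm2, method = c("spearman", "pearson"),
                   n_perm = 999, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(dm1, "dist_matrix"), inherits(dm2, "dist_matrix"),
            n_perm >= 99)
  if (!identical(rownames(dm1), rownames(dm2)))
    stopf("distance matrices must share identical labels")
  v1 <- dm_condensed(unclass(dm1))
  r_obs <- stats::cor(v1, dm_condensed(unclass(dm2)), method = method)
  m2 <- unclass(dm2)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      p <- sample.int(nrow(m2))
      stats::cor(v1, dm_condensed(m2[p, p]), method = method)
    }, numeric(1)) >= r_obs)
  })
  list(statistic = r_obs, p = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, method = method)
}

#' Distance decay of community similarity
#'
#' Spearman rank correlation between geographic distance and Bray-Curtis
#' similarity (1 - dissimilarity) over all unordered sample pairs, with a
#' Mantel permutation p-value (one-sided for negative association, i.e.
#' decay) and a least-squares linear trend of similarity on distance.
#'
#' @param geo geographic [dist_matrix()] (km).
#' @param comm community dissimilarity [dist_matrix()] (e.g. [bray_curtis()]).
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `rho`, `p`, `n_pairs`, `trend` (intercept, slope).
#' @export
distance_decay <- function(geo, comm, n_perm = 999, seed = 1) {
  stopifnot(inherits(geo, "dist_matrix"), inherits(comm, "dist_matrix"))
  if (!identical(rownames(geo), rownames(comm))) stopf("label mismatch")
  if (nrow(geo) < 5L) stopf("need at least 5 samples")
  d <- dm_condensed(unclass(geo))
  s <- 1 - dm_condensed(unclass(comm))
  rho <- stats::cor(d, s, method = "spearman")
  m <- unclass(comm)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      p <- sample.int(nrow(m))
      stats::cor(d, 1 - dm_condensed(m[p, p]), method = "spearman")
    }, numeric(1)) <= rho)   # one-sided: decay means rho more negative
  })
  fit <- stats::lm.fit(cbind(1, d), s)
  list(rho = rho, p = (1 + exceed) / (1 + n_perm),
       n_pairs = length(d),
       trend = c(intercept = fit$coefficients[[1L]], slope = fit$coefficients[[2L]]))
}

# Prim's algorithm: maximum edge weight of the minimum spanning tree.
mst_max_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[, 1L]
  maxe <- 0
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    maxe <- max(maxe, best[v])
    in_tree[v] <- TRUE
    best <- pmin(best, d[, v])
  }
  maxe
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Spatial eigenfunctions from a truncated geographic distance matrix: the
#' truncation distance t is the largest edge of the minimum spanning tree,
#' distances above t are replaced by 4t, and the principal coordinates of
#' the modified matrix with positive eigenvalues are retained as spatial
#' predictors. On a regular transect these eigenfunctions are sinusoids of
#' decreasing period.
#'
#' @param geo a geographic [dist_matrix()].
#' @return list of class `spatial_eigenfunctions`: `truncation` (t),
#'   `eigenvalues` (positive, decreasing), `vectors` (samples x functions,
#'   orthogonal, centred).
#' @export
pcnm <- function(geo) {
  stopifnot(inherits(geo, "dist_matrix"))
  n <- nrow(geo)
  if (n < 4L) stopf("PCNM needs at least 4 samples")
  d <- unclass(geo)
  if (any(d[upper.tri(d)] == 0))
    stopf("duplicate coordinates (zero distances) break the truncation")
  t <- mst_max_edge(d)
  dtr <- d
  dtr[dtr > t] <- 4 * t
  diag(dtr) <- 0
  B <- -0.5 * dtr^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% B %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > sqrt(.Machine$double.eps) * max(abs(e$values)))
  vec <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  dimnames(vec) <- list(rownames(d), paste0("PCNM", seq_along(pos)))
  structure(list(truncation = t, eigenvalues = e$values[pos], vectors = vec),
            class = "spatial_eigenfunctions")
}

## ---- redundancy-analysis machinery ----------------------------------------

#' Hellinger transformation of a count table
#'
#' Square root of per-sample relative abundances; the standard community
#' transform that makes Euclidean-based ordination (RDA) appropriate for
#' abundance data.
#'
#' @param x a `count_table` or matrix.
#' @return numeric matrix.
#' @export
hellinger <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  sqrt(m / rowSums(m))
}

# Multivariate RDA R^2 of response matrix Y on predictor matrix X
# (columns), both as given; intercept always included.
rda_r2 <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(X) || ncol(X) == 0L) return(0)
  q <- qr(cbind(1, as.matrix(X)))
  fitted <- qr.fitted(q, Yc)
  sum(fitted^2) / sum(Yc^2)
}

# Ezekiel adjustment; p = number of predictor columns actually used.
adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Forward selection of predictors for a community response
#'
#' Greedy forward selection on RDA R-squared with the double stopping rule:
#' at each step the candidate adding the most explained variation enters
#' only if (i) its permutation p-value (Freedman-Lane residual permutation
#' of the reduced model, partial-F statistic) is at most `alpha`, and (ii)
#' the cumulative adjusted R-squared does not exceed that of the global
#' model containing all candidates. Collinear candidates (no rank gain)
#' are skipped with a warning.
#'
#' @param response a `count_table` (Hellinger-transformed internally) or a
#'   numeric matrix already transformed.
#' @param candidates data.frame of named predictor columns.
#' @param alpha per-step significance level (default 0.05).
#' @param n_perm permutations per step (default 999).
#' @param seed integer seed.
#' @return data.frame of selected variables in entry order with columns
#'   variable, delta_r2, cum_r2, cum_adj_r2, p (zero rows if nothing
#'   passes), with attribute `global_adj_r2`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05, n_perm = 999, seed = 1) {
  Y <- if (inherits(response, "count_table")) hellinger(response) else as.matrix(response)
  X <- as.data.frame(candidates)
  if (ncol(X) < 1L) stopf("need at least one candidate")
  stopifnot(alpha > 0, alpha < 1)
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sst <- sum(Yc^2)
  Xm <- as.matrix(X)
  rank_all <- qr(cbind(1, Xm))$rank
  global_adj <- adj_r2(rda_r2(Y, Xm), n, rank_all - 1L)
  selected <- character(0)
  rows <- list()
  step_seed <- 0L
  repeat {
    remaining <- setdiff(names(X), selected)
    if (!length(remaining)) break
    Xs <- if (length(selected)) Xm[, selected, drop = FALSE] else NULL
    r2_red <- rda_r2(Y, Xs)
    best <- NULL
    for (v in remaining) {
      Xtry <- cbind(Xs, Xm[, v, drop = FALSE])
      if (qr(cbind(1, Xtry))$rank <= qr(cbind(1, Xs %||% matrix(0, n, 0)))$rank) {
        warning(sprintf("candidate '%s' is collinear with selected set; skipped", v))
        next
      }
      r2 <- rda_r2(Y, Xtry)
      if (is.null(best) || r2 > best$r2) best <- list(v = v, r2 = r2)
    }
    if (is.null(best)) break
    q_full <- length(selected) + 1L
    f_obs <- (best$r2 - r2_red) / ((1 - best$r2) / (n - q_full - 1L))
    # Freedman-Lane: permute residuals of the reduced model
    qred <- qr(cbind(1, Xs %||% matrix(0, n, 0)))
    fit_red <- qr.fitted(qred, Yc)
    res_red <- Yc - fit_red
    step_seed <- step_seed + 1L
    exceed <- with_seed(derive_seed(seed, paste0("fs", step_seed)), {
      sum(vapply(seq_len(n_perm), function(k) {
        Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
        r2p_red <- rda_r2(Yp, Xs)
        r2p <- rda_r2(Yp, cbind(Xs, Xm[, best$v, drop = FALSE]))
        (r2p - r2p_red) / ((1 - r2p) / (n - q_full - 1L))
      }, numeric(1)) >= f_obs)
    })
    p <- (1 + exceed) / (1 + n_perm)
    cum_adj <- adj_r2(best$r2, n, q_full)
    if (p > alpha || cum_adj > global_adj) break
    selected <- c(selected, best$v)
    rows[[length(rows) + 1L]] <- data.frame(variable = best$v,
                                            delta_r2 = best$r2 - r2_red,
                                            cum_r2 = best$r2,
                                            cum_adj_r2 = cum_adj, p = p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), delta_r2 = numeric(0),
               cum_r2 = numeric(0), cum_adj_r2 = numeric(0), p = numeric(0))
  attr(out, "global_adj_r2") <- global_adj
  out
}

#' Canonical correspondence analysis with permutation test
#'
#' Wraps \pkg{vegan}'s CCA on the (by default) log(1 + y) transformed count
#' table, reporting the constrained ordination, an overall permutation
#' ANOVA, and each variable's sole contribution (the percentage of total
#' inertia it explains when used as the only constraint).
#'
#' @param x a `count_table`.
#' @param predictors data.frame of predictor columns (samples in table order).
#' @param transform `"log1p"` (default) or `"none"`.
#' @param n_perm permutations for the ANOVA (default 999).
#' @param seed integer seed.
#' @return list with `cca` (the vegan object), `anova_p`, `constrained_prop`,
#'   `sole` (data.frame variable, inertia_pct).
#' @export
cca_analysis <- function(x, predictors, transform = c("log1p", "none"),
                         n_perm = 999, seed = 1) {
  transform <- match.arg(transform)
  stopifnot(inherits(x, "count_table"))
  predictors <- as.data.frame(predictors)
  if (nrow(x$counts) <= ncol(predictors) + 1L)
    stopf("need n_samples > n_predictors + 1")
  if (qr(as.matrix(predictors))$rank < ncol(predictors))
    stopf("rank-deficient predictors")
  Y <- if (transform == "log1p") log1p(x$counts) else x$counts
  keep <- colSums(Y) > 0
  Y <- Y[, keep, drop = FALSE]
  mod <- vegan::cca(Y ~ ., data = predictors)
  an <- with_seed(derive_seed(seed, "cca"),
                  stats::anova(mod, permutations = n_perm))
  tot <- mod$tot.chi
  sole <- vapply(names(predictors), function(v) {
    m1 <- vegan::cca(Y ~ ., data = predictors[, v, drop = FALSE])
    100 * m1$CCA$tot.chi / m1$tot.chi
  }, numeric(1))
  list(cca = mod,
       anova_p = an$`Pr(>F)`[1L],
       constrained_prop = mod$CCA$tot.chi / tot,
       sole = data.frame(variable = names(sole), inertia_pct = unname(sole)))
}

#' Partition community variation between environment and space
#'
#' Redundancy analysis of the Hellinger-transformed community on (i) the
#' selected environmental variables and (ii) the spatial predictors (PCNM
#' eigenfunctions plus the linear coordinate trend), with Ezekiel-adjusted
#' R-squared. Fractions: pure environment a = joint - space, pure space
#' c = joint - env, shared b = env + space - joint, unexplained d =
#' 1 - joint. Adjusted fractions can be slightly negative; they are
#' reported as-is (clamp only for display).
#'
#' @param x a `count_table`.
#' @param env data.frame of selected environmental columns.
#' @param spatial a `spatial_eigenfunctions` object (or matrix of spatial
#'   predictors).
#' @param trend optional two-column matrix/data.frame of linear coordinate
#'   trends (e.g. centred lon/lat), included with the spatial fraction.
#' @return list of class `variation_partition` with `a`, `b`, `c`, `d`,
#'   `explained`, and the underlying adjusted R-squared values.
#' @export
variation_partition <- function(x, env, spatial, trend = NULL) {
  stopifnot(inherits(x, "count_table"))
  Y <- hellinger(x)
  n <- nrow(Y)
  Xe <- if (is.null(env) || NCOL(env) == 0L) NULL else as.matrix(as.data.frame(env))
  Xs <- if (inherits(spatial, "spatial_eigenfunctions")) spatial$vectors
        else if (is.null(spatial)) NULL else as.matrix(spatial)
  if (!is.null(trend)) {
    tr <- scale(as.matrix(trend), center = TRUE, scale = FALSE)
    Xs <- cbind(Xs, tr)
  }
  if (is.null(Xe) && is.null(Xs)) stopf("at least one predictor set required")
  pe <- if (is.null(Xe)) 0L else qr(cbind(1, Xe))$rank - 1L
  ps <- if (is.null(Xs)) 0L else qr(cbind(1, Xs))$rank - 1L
  pj <- qr(cbind(1, Xe, Xs))$rank - 1L
  if (max(pe, ps, pj) >= n - 1L)
    stopf("too many predictors (p >= n - 1); reduce the predictor sets")
  r2e <- adj_r2(rda_r2(Y, Xe), n, pe)
  r2s <- adj_r2(rda_r2(Y, Xs), n, ps)
  r2j <- adj_r2(rda_r2(Y, cbind(Xe, Xs)), n, pj)
  structure(list(a = r2j - r2s, b = r2e + r2s - r2j, c = r2j - r2e,
                 d = 1 - r2j, explained = r2j,
                 adj_r2 = c(env = r2e, space = r2s, joint = r2j)),
            class = "variation_partition")
}

#' @export
print.variation_partition <- function(x, ...) {
  disp <- function(v) sprintf("%.1f%%", 100 * max(v, 0))
  cat(sprintf("variation partition: pure env %s | shared %s | pure space %s | unexplained %s\n",
              disp(x$a), disp(x$b), disp(x$c), disp(x$d)))
  invisible(x)
}
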