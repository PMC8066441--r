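#' Alpha diversity indices per sample
#'
#' Computes richness, Chao1, Shannon (natural log) and Simpson diversity for
#' every sample. Simpson is reported as Gini-Simpson \eqn{1 - \sum p_i^2}
#' (bounded in [0, 1]); the inverse form \eqn{1 / \sum p_i^2} is available
#' via `simpson = "inverse"`. Chao1 uses the classic estimator
#' \eqn{S + F_1^2 / (2 F_2)} with the \eqn{S + F_1 (F_1 - 1) / 2} fallback
#' when no doubletons exist; the bias-corrected form
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} is available via
#' `chao1 = "bias_corrected"`.
#'
#' @param x a `count_table`.
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @param chao1 `"classic"` (default) or `"bias_corrected"`.
#' @return data.frame with columns sample_id, richness, chao1, shannon, simpson.
#' @examples
#' ct <- count_table(matrix(c(5L, 5L, 5L, 5L), 1,
#'                   dimnames = list("s", paste0("t", 1:4))))
#' alpha_diversity(ct)  # richness 4, shannon log(4), simpson 0.75
#' @export
alpha_diversity <- function(x, simpson = c("gini", "inverse"),
                            chao1 = c("classic", "bias_corrected")) {
  stopifnot(inherits(x, "count_table"))
  simpson <- match.arg(simpson)
  chao1 <- match.arg(chao1)
  totals <- rowSums(x$counts)
  if (any(totals == 0))
    stopf("all-zero sample(s): %s", paste(rownames(x$counts)[totals == 0], collapse = ", "))
  out <- lapply(seq_len(nrow(x$counts)), function(i) {
    n <- x$counts[i, ]
    n <- n[n > 0]
    p <- n / sum(n)
    S <- length(n)
    F1 <- sum(n == 1)
    F2 <- sum(n == 2)
    ch <- switch(chao1,
      classic = if (F2 > 0) S + F1^2 / (2 * F2) else S + F1 * (F1 - 1) / 2,
      bias_corrected = S + F1 * (F1 - 1) / (2 * (F2 + 1)))
    si <- sum(p^2)
    data.frame(sample_id = rownames(x$counts)[i], richness = S, chao1 = ch,
               shannon = -sum(p * log(p)),
               simpson = if (simpson == "gini") 1 - si else 1 / si)
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis group comparison with Dunn post hoc letters
#'
#' Rank-based test for differences of a per-sample quantity (e.g. an alpha
#' index) among >= 2 groups, with tie-corrected H and chi-square p.
#' Pairwise contrasts use Dunn's z on mean ranks with Benjamini-Hochberg
#' adjustment, summarised as a compact letter display (groups sharing a
#' letter do not differ at `alpha`).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `H`, `df`, `p`, `pairwise` (data.frame of contrasts) and
#'   `letters` (named character vector per group).
#' @export
group_test_kw <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stopf("group(s) with fewer than 2 samples: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  n <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  H <- 12 / (n * (n + 1)) * sum(sizes * (Rbar - (n + 1) / 2)^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (C > 0) H / C else 0
  df <- nlevels(groups) - 1L
  p <- stats::pchisq(H, df, lower.tail = FALSE)

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  z <- p_raw <- numeric(ncol(pairs))
  sigma2 <- (n * (n + 1) / 12) * C
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(sigma2 * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- if (se == 0) 0 else (Rbar[[a]] - Rbar[[b]]) / se
    p_raw[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_raw, "BH")
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         z = z, p = p_raw, p_adj = p_adj)
  list(H = H, df = df, p = p,
       pairwise = pairwise,
       letters = cld_letters(lev, pairwise$group1, pairwise$group2,
                             pairwise$p_adj > alpha,
                             order(-unlist(Rbar))))
}

# Compact letter display by greedy insert-and-absorb. `ns` flags pairs that
# are NOT significantly different (may share a letter).
cld_letters <- function(levels, g1, g2, ns, preference = seq_along(levels)) {
  k <- length(levels)
  same <- matrix(TRUE, k, k, dimnames = list(levels, levels))
  for (i in seq_along(g1)) same[g1[i], g2[i]] <- same[g2[i], g1[i]] <- ns[i]
  groups <- list()
  for (idx in preference) {
    placed <- FALSE
    for (j in seq_along(groups)) {
      if (all(same[levels[idx], groups[[j]]])) {
        groups[[j]] <- c(groups[[j]], levels[idx]); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- levels[idx]
  }
  out <- stats::setNames(rep("", k), levels)
  for (j in seq_along(groups))
    out[groups[[j]]] <- paste0(out[groups[[j]]], letters[j])
  out
}

#' Spearman correlations of alpha indices with environmental variables
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param frame a `sample_frame` with environmental columns.
#' @return data.frame with index, variable, rho, p, stars (`**` p < 0.01,
#'   `***` p < 0.001, following the usual heatmap convention).
#' @export
env_correlations <- function(alpha, frame) {
  env <- env_columns(frame)
  env <- env[alpha$sample_id, , drop = FALSE]
  idx_cols <- c("richness", "chao1", "shannon", "simpson")
  res <- list()
  for (ic in idx_cols) {
    for (vc in names(env)) {
      v <- env[[vc]]
      ok <- stats::complete.cases(alpha[[ic]], v)
      if (sum(ok) < 5L) stopf("fewer than 5 paired observations for %s vs %s", ic, vc)
      if (stats::sd(v[ok]) == 0) {
        warning(sprintf("constant variable '%s': rho undefined", vc))
        res[[length(res) + 1L]] <- data.frame(index = ic, variable = vc,
                                              rho = NA_real_, p = NA_real_, stars = "")
        next
      }
      ct <- suppressWarnings(stats::cor.test(alpha[[ic]][ok], v[ok], method = "spearman"))
      res[[length(res) + 1L]] <- data.frame(index = ic, variable = vc,
                                            rho = unname(ct$estimate), p = ct$p.value,
                                            stars = ifelse(ct$p.value < 0.001, "***",
                                                    ifelse(ct$p.value < 0.01, "**", "")))
    }
  }
  do.call(rbind, res)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, in [0, 1].
#' Community similarity, where needed, is \eqn{1 - BC}. Bray-Curtis is
#' symmetric with zero self-distance but is not metric (no triangle
#' inequality); downstream ordination handles the resulting negative
#' eigenvalues explicitly.
#'
#' @param x a `count_table` (or plain sample-by-taxon matrix).
#' @return a [dist_matrix()].
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  totals <- rowSums(m)
  if (any(totals == 0))
    stopf("all-zero sample(s): %s", paste(rownames(m)[totals == 0], collapse = ", "))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    diffs <- abs(sweep(m[(i + 1L):n, , drop = FALSE], 2L, m[i, ]))
    sums <- sweep(m[(i + 1L):n, , drop = FALSE], 2L, m[i, ], `+`)
    d[(i + 1L):n, i] <- rowSums(diffs) / rowSums(sums)
  }
  dist_matrix(d + t(d), metric = "bray_curtis")
}

#' Principal coordinates analysis (classical MDS) of a distance matrix
#'
#' Gower double-centering of \eqn{-d^2/2} followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axis variance proportions are computed over the positive
#' eigenvalues only. Negative eigenvalues (expected for Bray-Curtis) are
#' reported, not corrected, unless `correction = "cailliez"`.
#'
#' @param dm a [dist_matrix()].
#' @param k number of axes to return (default all positive).
#' @param correction `"none"` or `"cailliez"` (adds the smallest constant to
#'   off-diagonal distances that removes negative eigenvalues).
#' @return list with `coordinates` (matrix), `eigenvalues` (all, decreasing),
#'   `proportion` (per returned axis), `negative` (number and total magnitude
#'   of negative eigenvalues), `correction`.
#' @export
pcoa <- function(dm, k = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  stopifnot(inherits(dm, "dist_matrix"))
  n <- nrow(dm)
  if (n < 3L) stopf("pcoa needs at least 3 samples")
  d <- unclass(dm)
  if (correction == "cailliez") {
    # eigen problem of Cailliez (1983): smallest c so that d + c is Euclidean
    d1 <- -0.5 * d^2; d2 <- -0.5 * d
    Jc <- diag(n) - matrix(1 / n, n, n)
    M <- rbind(cbind(matrix(0, n, n), 2 * Jc %*% d1 %*% Jc),
               cbind(-diag(n), -4 * Jc %*% d2 %*% Jc))
    cc <- max(Re(eigen(M, only.values = TRUE)$values))
    d <- d + cc
    diag(d) <- 0
  }
  B <- -0.5 * d^2
  Jm <- diag(n) - matrix(1 / n, n, n)
  B <- Jm %*% B %*% Jm
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k)
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_len(k)))
  list(coordinates = coords,
       eigenvalues = ev,
       proportion = ev[pos[seq_len(k)]] / sum(ev[pos]),
       negative = list(n = sum(ev < -sqrt(.Machine$double.eps) * max(abs(ev))),
                       magnitude = -sum(ev[ev < 0])),
       correction = correction)
}

#' One-factor PERMANOVA (adonis-style) on a distance matrix
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components and tests the pseudo-F statistic by permutation
#' of group labels. \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})}.
#'
#' @param dm a [dist_matrix()].
#' @param groups group labels in `dm` label order.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return list with `F`, `R2`, `df`, `p`, `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  stopifnot(inherits(dm, "dist_matrix"), n_perm >= 99)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("singleton group not allowed")
  n <- nrow(dm)
  d2 <- unclass(dm)^2
  f_stat <- function(g) {
    SST <- sum(d2[upper.tri(d2)]) / n
    SSW <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      SSW <- SSW + sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
    }
    SSA <- SST - SSW
    a <- nlevels(g)
    c(F = (SSA / (a - 1)) / (SSW / (n - a)), R2 = SSA / SST)
  }
  obs <- f_stat(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_stat(factor(sample(groups), levels = levels(groups)))[1L]
    }, numeric(1)) >= obs[1L])
  })
  list(F = unname(obs[1L]), R2 = unname(obs[2L]),
       df = c(nlevels(groups) - 1L, n - nlevels(groups)),
       p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
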