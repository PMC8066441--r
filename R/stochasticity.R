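#' Constraint-preserving null ensemble of count tables
#'
#' Randomises a count table while preserving, for every sample, its observed
#' richness and total reads. For each null sample the taxon identities are
#' drawn without replacement with probability proportional to the taxon's
#' regional occurrence frequency (fraction of samples it occupies), and the
#' sample's reads are then allocated to the chosen taxa by a multinomial
#' draw with probabilities proportional to regional relative abundance.
#' This is the abundance-based null expectation used by the stochasticity
#' ratio.
#'
#' @param x a `count_table`.
#' @param n_iter number of randomised tables (>= 100; default 1000).
#' @param seed integer seed.
#' @return list of class `null_ensemble`: `tables` (list of count matrices),
#'   `constraints` (descriptor string), `seed`.
#' @export
generate_null_ensemble <- function(x, n_iter = 1000, seed = 1) {
  stopifnot(inherits(x, "count_table"), n_iter >= 100)
  m <- x$counts
  occ <- colMeans(m > 0)
  relab <- colSums(m) / sum(m)
  present <- which(occ > 0)
  rich <- rowSums(m > 0)
  if (any(rich > length(present)))
    stopf("sample richness exceeds regional pool size")
  totals <- rowSums(m)
  tables <- with_seed(seed, {
    lapply(seq_len(n_iter), function(it) {
      null <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
      for (i in seq_len(nrow(m))) {
        if (rich[i] == 0L) next
        chosen <- present[sample.int(length(present), rich[i], replace = FALSE,
                                     prob = occ[present])]
        p <- relab[chosen]
        if (sum(p) == 0) p <- rep(1, length(chosen))
        # every chosen taxon must stay present: give each 1 read first
        extra <- totals[i] - rich[i]
        alloc <- if (extra > 0)
          stats::rmultinom(1L, extra, p / sum(p))[, 1L] else 0
        null[i, chosen] <- 1 + alloc
      }
      null
    })
  })
  structure(list(tables = tables,
                 constraints = paste("per-sample richness and totals fixed;",
                                     "taxa ~ occurrence frequency;",
                                     "reads ~ regional relative abundance"),
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d tables (%s)\n", length(x$tables), x$constraints))
  invisible(x)
}

# mean Bray-Curtis similarity matrix over an ensemble
ensemble_expected_similarity <- function(ensemble) {
  sims <- lapply(ensemble$tables, function(t) 1 - unclass(bray_curtis(t)))
  Reduce(`+`, sims) / length(sims)
}

#' Stochasticity ratio of community assembly per group
#'
#' For each within-group sample pair, compares the observed Bray-Curtis
#' similarity \eqn{C_{ij} = 1 - BC} with its null expectation
#' \eqn{\bar E_{ij}} (mean over a constraint-preserving ensemble) and forms
#' the ratio \eqn{ST_{ij} = \bar E_{ij} / C_{ij}} when \eqn{C_{ij} >
#' \bar E_{ij}}, else \eqn{C_{ij} / \bar E_{ij}} — i.e. min/max, bounded in
#' [0, 1]. The group stochasticity ratio is the mean of the pairwise values
#' (reported in percent, with sd). Values near 100% mean observed
#' similarity is indistinguishable from the null (stochastic assembly);
#' low values mean deterministic structuring. An alternative
#' dissimilarity-side normalisation \eqn{(1-\bar E)/(1-C)} (min/max) is
#' available via `side = "dissimilarity"`.
#'
#' @param x a `count_table` covering all samples.
#' @param groups group labels in sample order (each group >= 3 samples).
#' @param n_iter null ensemble size (default 1000).
#' @param seed integer seed.
#' @param side `"similarity"` (default) or `"dissimilarity"`.
#' @return list of class `stochasticity_result` keyed by group, each with
#'   `pairs` (data.frame i, j, C, E, ST), `sr_mean` and `sr_sd` (percent),
#'   plus `constraints` and `seed`.
#' @export
stochasticity_ratio <- function(x, groups, n_iter = 1000, seed = 1,
                                side = c("similarity", "dissimilarity")) {
  side <- match.arg(side)
  stopifnot(inherits(x, "count_table"))
  groups <- as.factor(groups)
  if (length(groups) != n_samples(x)) stopf("groups must match sample count")
  if (any(table(groups) < 3L)) stopf("each group needs >= 3 samples")
  out <- list()
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    sub <- count_table(x$counts[idx, , drop = FALSE])
    ens <- generate_null_ensemble(sub, n_iter = n_iter,
                                  seed = derive_seed(seed, paste0("null_", lev)))
    Cm <- 1 - unclass(bray_curtis(sub))
    Em <- ensemble_expected_similarity(ens)
    ut <- which(upper.tri(Cm), arr.ind = TRUE)
    C <- Cm[ut]; E <- Em[ut]
    if (side == "dissimilarity") { C <- 1 - C; E <- 1 - E }
    drop <- (C == 0 & E > 0) | (E == 0 & C > 0)
    if (any(drop))
      warning(sprintf("group %s: %d pair(s) with zero similarity excluded",
                      lev, sum(drop)))
    ST <- ifelse(C == E, 1, pmin(C, E) / pmax(C, E))
    ST[drop] <- NA_real_
    pairs <- data.frame(i = rownames(Cm)[ut[, 1L]], j = rownames(Cm)[ut[, 2L]],
                        C = C, E = E, ST = ST)
    out[[lev]] <- list(pairs = pairs,
                       sr_mean = 100 * mean(ST, na.rm = TRUE),
                       sr_sd = 100 * stats::sd(ST, na.rm = TRUE),
                       constraints = ens$constraints, seed = seed, side = side)
  }
  structure(out, class = "stochasticity_result")
}

#' @export
print.stochasticity_result <- function(x, ...) {
  for (lev in names(x))
    cat(sprintf("%s: SR = %.1f%% +/- %.1f%% (%d pairs)\n", lev,
                x[[lev]]$sr_mean, x[[lev]]$sr_sd, nrow(x[[lev]]$pairs)))
  invisible(x)
}

#' PERMANOVA of observed groups against a null ensemble
#'
#' Computes the pseudo-F of the observed Bray-Curtis matrix for the given
#' grouping, recomputes it on every null table of the ensemble, and reports
#' \eqn{p = (1 + \#\{F_{null} \ge F_{obs}\}) / (1 + n_{iter})}.
#'
#' @param x a `count_table`.
#' @param groups group labels in sample order.
#' @param ensemble a `null_ensemble` built on the same samples.
#' @return list with `F_obs`, `F_null` (vector), `p`.
#' @export
null_permanova <- function(x, groups, ensemble) {
  stopifnot(inherits(x, "count_table"), inherits(ensemble, "null_ensemble"))
  if (!identical(dim(ensemble$tables[[1L]]), dim(x$counts)) ||
      !identical(rownames(ensemble$tables[[1L]]), rownames(x$counts)))
    stopf("ensemble was not built on the same samples")
  groups <- as.factor(groups)
  fstat <- function(m) {
    d2 <- unclass(bray_curtis(m))^2
    n <- nrow(d2)
    SST <- sum(d2[upper.tri(d2)]) / n
    SSW <- 0
    for (lev in levels(groups)) {
      i <- which(groups == lev)
      SSW <- SSW + sum(d2[i, i][upper.tri(d2[i, i, drop = FALSE])]) / length(i)
    }
    ((SST - SSW) / (nlevels(groups) - 1)) / (SSW / (n - nlevels(groups)))
  }
  F_obs <- fstat(x$counts)
  F_null <- vapply(ensemble$tables, fstat, numeric(1))
  list(F_obs = F_obs, F_null = F_null,
       p = (1 + sum(F_null >= F_obs)) / (1 + length(F_null)))
}
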