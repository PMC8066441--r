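#' Rank-abundance representation of a community
#'
#' Pools a count table over samples (or accepts a plain abundance vector),
#' drops zero-count taxa and sorts descending. Ties keep stable input order.
#'
#' @param x a `count_table` or numeric vector of abundances.
#' @return list of class `rank_abundance` with `abundance` (descending
#'   integers >= 1), `S` and `N`.
#' @export
rank_abundance <- function(x) {
  n <- if (inherits(x, "count_table")) colSums(x$counts) else as.numeric(x)
  n <- n[n > 0]
  if (!length(n)) stopf("no taxa with positive abundance")
  n <- n[order(-n)]   # stable: ties keep input order
  structure(list(abundance = unname(n), S = length(n), N = sum(n)),
            class = "rank_abundance")
}

#' @export
print.rank_abundance <- function(x, ...) {
  cat(sprintf("rank_abundance: S = %d, N = %s, max = %s\n", x$S,
              format(x$N, big.mark = ","), format(x$abundance[1L], big.mark = ",")))
  invisible(x)
}

#' Normalised rank-abundance distributions (NRADs)
#'
#' Reduces every curve to a common species count by repeatedly subsampling
#' `target_S` species without replacement, re-sorting and renormalising to
#' relative abundance, then averages across replicates and samples with a
#' percentile 95% confidence band.
#'
#' @param rads list of `rank_abundance` objects.
#' @param target_S common species count, at most the minimum S.
#' @param reps subsampling replicates (>= 100 recommended).
#' @param seed integer seed.
#' @return data.frame with columns rank, mean, lower, upper (each rep's curve
#'   sums to 1).
#' @export
normalize_rads <- function(rads, target_S, reps = 1000, seed = 1) {
  stopifnot(length(rads) >= 1, reps >= 1)
  Ss <- vapply(rads, function(r) r$S, numeric(1))
  if (any(Ss < target_S))
    stopf("target_S = %d exceeds S of sample(s) %s", target_S,
          paste(which(Ss < target_S), collapse = ", "))
  curves <- with_seed(seed, {
    out <- matrix(NA_real_, length(rads) * reps, target_S)
    k <- 0L
    for (r in rads) {
      no_sub <- r$S == target_S
      for (rep in seq_len(reps)) {
        a <- if (no_sub) r$abundance else
          sort(sample(r$abundance, target_S, replace = FALSE), decreasing = TRUE)
        k <- k + 1L
        out[k, ] <- a / sum(a)
      }
    }
    out
  })
  data.frame(rank = seq_len(target_S),
             mean = colMeans(curves),
             lower = apply(curves, 2L, stats::quantile, 0.025),
             upper = apply(curves, 2L, stats::quantile, 0.975))
}

#' Octave (doubling abundance class) binning
#'
#' Octave `j` holds the species with abundance in `[2^j, 2^(j+1))`, so
#' abundance 1 falls in octave 0, abundances 2-3 in octave 1, and so on.
#'
#' @param ra a `rank_abundance`.
#' @return data.frame with columns octave, lower, upper, species.
#' @export
octave_bins <- function(ra) {
  stopifnot(inherits(ra, "rank_abundance"))
  j <- floor(log2(ra$abundance))
  tab <- table(factor(j, levels = 0:max(j)))
  data.frame(octave = as.integer(names(tab)),
             lower = 2^as.integer(names(tab)),
             upper = 2^(as.integer(names(tab)) + 1) - 1,
             species = as.integer(tab))
}

## ---- quadrature -----------------------------------------------------------

# Gauss-Legendre nodes/weights on [0, 1] by Golub-Welsch.
gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = (e$values[ord] + 1) / 2, weights = (2 * e$vectors[1, ord]^2) / 2)
}

# Gauss-Hermite nodes/weights for integrals against exp(-t^2).
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## ---- model expectations ---------------------------------------------------

# Broken-stick expected abundance per rank: E(n_i) = (N/S) * sum_{x=i}^S 1/x.
bs_expected <- function(S, N) (N / S) * rev(cumsum(1 / (S:1)))

# Geometric series expected abundance per rank given preemption k.
gs_expected <- function(S, N, k) N * k * (1 - k)^(seq_len(S) - 1) / (1 - (1 - k)^S)

# Zero-truncated Poisson-lognormal probabilities P(n) for integer n >= 1,
# by Gauss-Hermite quadrature over the lognormal mixing density.
.pln_gh <- gauss_hermite(40L)
pln_prob <- function(n, mu, sigma, truncated = TRUE) {
  lam <- exp(mu + sqrt(2) * sigma * .pln_gh$nodes)      # quadrature lambdas
  loglam <- mu + sqrt(2) * sigma * .pln_gh$nodes
  lw <- log(.pln_gh$weights) - 0.5 * log(pi)
  p <- vapply(n, function(nn) {
    s <- nn * loglam - lam - lgamma(nn + 1) + lw
    exp(logsumexp(s))
  }, numeric(1))
  if (truncated) {
    p0 <- exp(logsumexp(-lam + lw))
    p <- p / (1 - p0)
  }
  p
}

# Volkov neutral sampling formula: expected number of species with
# abundance n in a sample of J individuals, for biodiversity number theta
# and immigration rate m. gamma = m (J - 1) / (1 - m). Evaluated by
# Gauss-Legendre quadrature in log space.
.volkov_gl <- gauss_legendre01(160L)
volkov_phi <- function(n, J, theta, m) {
  if (m >= 1) m <- 1 - 1e-9
  gam <- m * (J - 1) / (1 - m)
  y <- .volkov_gl$nodes * gam
  lw <- log(.volkov_gl$weights * gam)
  base <- log(theta) + lgamma(gam) - lgamma(J + gam) - y * theta / gam +
    lw - lgamma(1 + y) - lgamma(gam - y)
  vapply(n, function(nn) {
    s <- lchoose(J, nn) + lgamma(nn + y) + lgamma(J - nn + gam - y) + base
    exp(logsumexp(s))
  }, numeric(1))
}

# Integer evaluation grid per octave: all integers for narrow octaves,
# log-spaced integers (trapezoid-summed) for wide ones.
octave_grid <- function(lower, upper, max_exact = 16L) {
  if (upper - lower + 1L <= max_exact) return(list(n = lower:upper, exact = TRUE))
  n <- unique(round(exp(seq(log(lower), log(upper), length.out = max_exact))))
  list(n = n, exact = FALSE)
}

# Sum f(n) over the integers of an octave, where fvals = f at grid$n.
octave_sum <- function(grid, fvals) {
  if (grid$exact) return(sum(fvals))
  n <- grid$n
  # trapezoid over integer index with unit spacing between consecutive ints
  widths <- diff(n)
  sum((fvals[-1] + fvals[-length(fvals)]) / 2 * widths) + fvals[1L]
}

## ---- fitting --------------------------------------------------------------

#' Fit a species-abundance distribution model
#'
#' Fits one of four SAD models and returns the maximised log-likelihood,
#' AIC, and predictions both per rank and per octave.
#'
#' \describe{
#'   \item{BS}{broken stick; expected rank abundance
#'     \eqn{(N/S) \sum_{x=i}^{S} 1/x}; no free parameters. Poisson
#'     likelihood around expected rank abundances.}
#'   \item{GS}{geometric series; \eqn{E(n_i) \propto k (1-k)^{i-1}} with the
#'     preemption fraction k estimated by Poisson maximum likelihood over
#'     ranks.}
#'   \item{Volkov}{the neutral-theory sampling formula for a local community
#'     of J individuals with immigration m from a metacommunity of
#'     biodiversity theta; expected species per abundance evaluated by
#'     Gauss-Legendre quadrature with log-gamma arithmetic; (theta, m)
#'     estimated by Poisson likelihood over octave species counts from a
#'     coarse grid start refined by Nelder-Mead on (log theta, logit m).}
#'   \item{PLN}{zero-truncated Poisson-lognormal; per-abundance
#'     probabilities by Gauss-Hermite quadrature over the lognormal mixing
#'     density; (mu, sigma_ln) estimated by Poisson likelihood over octave
#'     species counts (the veil-line convention: only n >= 1 observable).}
#' }
#'
#' BS and GS are rank-based fits; Volkov and PLN are octave-based fits,
#' since those models predict species-per-abundance rather than
#' per-rank values. AIC = 2 k - 2 logLik in all cases.
#'
#' @param ra a `rank_abundance` (S >= 5 for the parametric models).
#' @param model one of `"BS"`, `"GS"`, `"Volkov"`, `"PLN"`.
#' @return object of class `sad_fit`: list with `model`, `params`, `n_params`,
#'   `logLik`, `AIC`, `predicted_rank`, `predicted_octave`, `S`, `N`.
#' @export
fit_sad <- function(ra, model = c("BS", "GS", "Volkov", "PLN")) {
  model <- match.arg(model)
  stopifnot(inherits(ra, "rank_abundance"))
  if (model != "BS" && ra$S < 5L) stopf("S >= 5 required for %s fit", model)
  S <- ra$S; N <- ra$N
  oct <- octave_bins(ra)
  grids <- lapply(seq_len(nrow(oct)), function(i) octave_grid(oct$lower[i], oct$upper[i]))

  pois_ll <- function(obs, expd) {
    expd <- pmax(expd, 1e-12)
    sum(obs * log(expd) - expd - lgamma(obs + 1))
  }

  if (model == "BS") {
    pred <- bs_expected(S, N)
    ll <- pois_ll(ra$abundance, pred)
    fit <- list(params = list(), n_params = 0L, logLik = ll, predicted_rank = pred)
  } else if (model == "GS") {
    nll <- function(k) -pois_ll(ra$abundance, gs_expected(S, N, k))
    opt <- stats::optimize(nll, c(1e-8, 1 - 1e-8))
    pred <- gs_expected(S, N, opt$minimum)
    fit <- list(params = list(k = opt$minimum), n_params = 1L,
                logLik = -opt$objective, predicted_rank = pred)
  } else if (model == "PLN") {
    obj <- function(par) {
      mu <- par[1L]; sig <- exp(par[2L])
      expd <- vapply(grids, function(g)
        S * octave_sum(g, pln_prob(g$n, mu, sig)), numeric(1))
      -pois_ll(oct$species, expd)
    }
    # moment start from log abundances
    la <- log(ra$abundance)
    start <- c(mean(la), log(max(stats::sd(la), 0.3)))
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8))
    if (!is.finite(opt$value)) stopf("PLN fit did not converge")
    mu <- opt$par[1L]; sig <- exp(opt$par[2L])
    expd <- vapply(grids, function(g)
      S * octave_sum(g, pln_prob(g$n, mu, sig)), numeric(1))
    fit <- list(params = list(mu = mu, sigma_ln = sig), n_params = 2L,
                logLik = -opt$value,
                predicted_rank = sad_rank_prediction(function(n) pln_prob(n, mu, sig), S, N),
                predicted_octave = expd)
  } else { # Volkov
    J <- N
    obj <- function(par) {
      theta <- exp(par[1L]); m <- stats::plogis(par[2L])
      expd <- vapply(grids, function(g)
        octave_sum(g, volkov_phi(g$n, J, theta, m)), numeric(1))
      -pois_ll(oct$species, expd)
    }
    # coarse 5x5 grid start over (log theta, logit m)
    grid_t <- log(S / log(10) * c(0.2, 0.5, 1, 2, 5))
    grid_m <- stats::qlogis(c(0.02, 0.1, 0.3, 0.6, 0.9))
    cand <- as.matrix(expand.grid(grid_t, grid_m))
    vals <- apply(cand, 1L, obj)
    start <- cand[which.min(vals), ]
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-7))
    if (!is.finite(opt$value)) stopf("Volkov fit did not converge")
    theta <- exp(opt$par[1L]); m <- stats::plogis(opt$par[2L])
    expd <- vapply(grids, function(g)
      octave_sum(g, volkov_phi(g$n, J, theta, m)), numeric(1))
    fit <- list(params = list(theta = theta, m = m), n_params = 2L,
                logLik = -opt$value,
                predicted_rank = sad_rank_prediction(function(n) volkov_phi(n, J, theta, m), S, N),
                predicted_octave = expd)
  }
  if (is.null(fit$predicted_octave)) {
    pj <- floor(log2(pmax(fit$predicted_rank, 1)))
    fit$predicted_octave <- as.numeric(table(factor(pj, levels = oct$octave)))
  }
  structure(c(list(model = model, S = S, N = N, octaves = oct), fit,
              list(AIC = 2 * fit$n_params - 2 * fit$logLik)),
            class = "sad_fit")
}

# Expected abundance per (descending) rank from a species-abundance mass
# function f(n), via the quantile transform at plotting positions.
sad_rank_prediction <- function(f, S, N, n_max = NULL) {
  if (is.null(n_max)) n_max <- max(4L * ceiling(N / S), 2L^ceiling(log2(N)) )
  grid <- unique(round(c(1:64, exp(seq(log(65), log(n_max), length.out = 400)))))
  mass <- f(grid)
  mass[!is.finite(mass) | mass < 0] <- 0
  # piece together a CDF over the grid (trapezoid between grid points)
  w <- c(1, diff(grid))
  cum <- cumsum(mass * w)
  if (cum[length(cum)] <= 0) stopf("degenerate fitted abundance distribution")
  cdf <- cummax(cum / cum[length(cum)])
  q <- (S - seq_len(S) + 0.5) / S   # rank 1 = highest abundance
  idx <- findInterval(q, cdf) + 1L
  idx[idx > length(grid)] <- length(grid)
  grid[idx]
}

#' @export
print.sad_fit <- function(x, ...) {
  ps <- if (length(x$params))
    paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)), collapse = ", ")
  else "(no parameters)"
  cat(sprintf("sad_fit %s: %s; logLik = %.2f, AIC = %.2f\n", x$model, ps,
              x$logLik, x$AIC))
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit for a SAD model
#'
#' Compares the empirical CDF of observed species abundances with the model
#' CDF (parametric for Volkov/PLN; the CDF of predicted rank abundances for
#' BS/GS). The abundance axis is discrete, so the asymptotic one-sample
#' p-value is approximate (conservative); this is flagged in the result.
#'
#' @param ra a `rank_abundance`.
#' @param fit a `sad_fit` on the same data.
#' @return list with `D`, `p`, `approximate = TRUE`.
#' @export
ks_test_sad <- function(ra, fit) {
  stopifnot(inherits(ra, "rank_abundance"), inherits(fit, "sad_fit"))
  obs <- sort(ra$abundance)
  S <- ra$S
  grid <- sort(unique(c(obs, round(fit$predicted_rank))))
  emp <- vapply(grid, function(g) mean(obs <= g), numeric(1))
  mod <- if (fit$model %in% c("BS", "GS")) {
    pr <- sort(fit$predicted_rank)
    vapply(grid, function(g) mean(pr <= g), numeric(1))
  } else {
    n_max <- max(grid)
    f <- if (fit$model == "PLN")
      function(n) pln_prob(n, fit$params$mu, fit$params$sigma_ln)
    else
      function(n) volkov_phi(n, fit$N, fit$params$theta, fit$params$m)
    gg <- unique(round(c(1:64, exp(seq(log(65), log(n_max) + 0.01, length.out = 300)))))
    mass <- f(gg)
    w <- c(1, diff(gg))
    cum <- cumsum(mass * w)
    cdf_g <- cum / cum[length(cum)]
    cdf_fun <- stats::approxfun(gg, cdf_g, method = "linear", rule = 2)
    cdf_fun(grid)
  }
  D <- max(abs(emp - mod))
  list(D = D, p = ks_pvalue(sqrt(S) * D), approximate = TRUE)
}

# Asymptotic Kolmogorov distribution tail Q(t) = 2 sum (-1)^{k-1} exp(-2k^2 t^2)
ks_pvalue <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Rank SAD fits by AIC
#'
#' @param fits list of `sad_fit` objects on the same rank-abundance data.
#' @param ra optional `rank_abundance`; when given, a K-S test is run per fit
#'   and rejected models (p < 0.05) are flagged.
#' @return data.frame sorted by ascending AIC with columns model, n_params,
#'   logLik, AIC, dAIC and (when `ra` given) ks_D, ks_p, ks_rejected.
#' @export
compare_models <- function(fits, ra = NULL) {
  if (length(fits) < 2L) stopf("need at least 2 fits to compare")
  Ss <- vapply(fits, function(f) f$S, numeric(1))
  Ns <- vapply(fits, function(f) f$N, numeric(1))
  if (length(unique(Ss)) != 1L || length(unique(Ns)) != 1L)
    stopf("fits are not on the same data (S or N differ)")
  df <- data.frame(model = vapply(fits, function(f) f$model, character(1)),
                   n_params = vapply(fits, function(f) f$n_params, integer(1)),
                   logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                   AIC = vapply(fits, function(f) f$AIC, numeric(1)))
  if (!is.null(ra)) {
    ks <- lapply(fits, function(f) ks_test_sad(ra, f))
    df$ks_D <- vapply(ks, function(k) k$D, numeric(1))
    df$ks_p <- vapply(ks, function(k) k$p, numeric(1))
    df$ks_rejected <- df$ks_p < 0.05
  }
  df <- df[order(df$AIC), ]
  df$dAIC <- df$AIC - df$AIC[1L]
  rownames(df) <- NULL
  df
}
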