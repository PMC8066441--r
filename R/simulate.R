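#' Simulate a lognormal regional species pool
#'
#' Regional relative abundances are normalised `exp(Normal(log_mean, log_sd))`
#' draws, the standard lognormal species-abundance assumption for microbial
#' metacommunities.
#'
#' @param S number of taxa (>= 2).
#' @param log_mean mean of log abundance (only shifts the scale; the pool is
#'   normalised to a simplex).
#' @param log_sd standard deviation of log abundance (> 0).
#' @param seed integer seed.
#' @return list of class `metacommunity_pool` with `taxon_ids`, `abundance`
#'   (sums to 1), and `params`.
#' @export
simulate_metacommunity <- function(S, log_mean = 0, log_sd = 1.5, seed = 1) {
  stopifnot(S >= 2, log_sd > 0)
  ab <- with_seed(seed, exp(stats::rnorm(S, log_mean, log_sd)))
  ab <- ab / sum(ab)
  structure(list(taxon_ids = sprintf("ASV_%04d", seq_len(S)),
                 abundance = stats::setNames(ab, sprintf("ASV_%04d", seq_len(S))),
                 params = list(S = S, log_mean = log_mean, log_sd = log_sd, seed = seed)),
            class = "metacommunity_pool")
}

#' Describe a simulation scenario
#'
#' Bundles the knobs of the sample generators: assembly regime, number of
#' samples, local community size J (reads per sample; default 25000 so
#' simulated tables resemble a rarefied amplicon table), immigration rate m
#' (neutral), niche breadth in gradient standard-deviation units (niche),
#' the 1-D transect length in km, and the spatial autocorrelation range of
#' the environmental gradient in km.
#'
#' @param regime one of `"neutral"`, `"niche"`, `"mixed"`.
#' @param n_samples number of samples (>= 2).
#' @param J individuals (reads) per sample (>= 1).
#' @param m immigration rate in (0, 1]; 1 means samples are i.i.d.
#'   multinomial draws from the pool.
#' @param niche_breadth Gaussian niche breadth on the standardised gradient;
#'   small values give strong filtering, large values approach neutrality.
#' @param optima_spread taxon optima are drawn uniformly on `[-optima_spread,
#'   optima_spread]` on the standardised gradient.
#' @param transect_km length of the 1-D sampling transect.
#' @param env_range_km Gaussian smoothing range of the simulated gradient.
#' @param seed integer seed.
#' @return list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(regime = c("neutral", "niche", "mixed"),
                                n_samples = 26, J = 25000, m = 0.3,
                                niche_breadth = 0.5, optima_spread = 2,
                                transect_km = 300, env_range_km = 50, seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 2, J >= 1, m > 0, m <= 1, niche_breadth > 0,
            transect_km > 0, env_range_km > 0)
  structure(list(regime = regime, n_samples = n_samples, J = J, m = m,
                 niche_breadth = niche_breadth, optima_spread = optima_spread,
                 transect_km = transect_km, env_range_km = env_range_km,
                 seed = seed),
            class = "simulation_scenario")
}

# Equally spaced transect positions converted to decimal-degree coordinates
# near the latitude of an arid mid-latitude catchment.
transect_coords <- function(n, transect_km, lat0 = 42, lon0 = 86.7) {
  x_km <- seq(0, transect_km, length.out = n)
  list(x_km = x_km, lat = rep(lat0, n),
       lon = lon0 + x_km / (111.19493 * cos(lat0 * pi / 180)))
}

# Gaussian-kernel smoothed white noise along the transect, standardised.
smoothed_gradient <- function(x_km, range_km) {
  grid <- seq(min(x_km) - 3 * range_km, max(x_km) + 3 * range_km, by = range_km / 4)
  z <- stats::rnorm(length(grid))
  g <- vapply(x_km, function(x) {
    w <- exp(-(x - grid)^2 / (2 * range_km^2))
    sum(w * z) / sum(w)
  }, numeric(1))
  as.numeric(scale(g))
}

# Nuisance environmental variables (smoothed noise, independent of
# composition), named after common water-chemistry panels.
nuisance_env <- function(x_km, range_km) {
  vars <- c("WT", "pH", "EC", "DO", "TN", "TP", "TSS", "DOC")
  out <- vapply(vars, function(v) smoothed_gradient(x_km, range_km), numeric(length(x_km)))
  as.data.frame(out)
}

make_frame <- function(ids, coords, env, group = "sim") {
  validate_sample_frame(data.frame(sample_id = ids, group = group,
                                   lat = coords$lat, lon = coords$lon, env,
                                   check.names = FALSE))
}

#' Simulate neutral (dispersal-assembled) local communities
#'
#' Each local community is a multinomial draw of `J` individuals from a
#' Dirichlet-perturbed copy of the regional pool with concentration
#' \eqn{I = m (J - 1) / (1 - m)}, the stationary approximation of a
#' Hubbell-style local community receiving immigrants at rate `m`. With
#' `m = 1` samples are i.i.d. multinomial draws from the pool. Environmental
#' columns are generated but uncorrelated with composition.
#'
#' @param pool a `metacommunity_pool`.
#' @param scenario a `simulation_scenario` with `regime = "neutral"`.
#' @return list with `table` (a [count_table()]) and `frame` (a `sample_frame`).
#' @export
simulate_neutral_samples <- function(pool, scenario) {
  stopifnot(inherits(pool, "metacommunity_pool"),
            inherits(scenario, "simulation_scenario"))
  if (scenario$regime != "neutral") stopf("scenario regime must be 'neutral'")
  sc <- scenario
  p <- pool$abundance
  S <- length(p)
  coords <- transect_coords(sc$n_samples, sc$transect_km)
  with_seed(sc$seed, {
    counts <- matrix(0, sc$n_samples, S,
                     dimnames = list(sprintf("S%02d", seq_len(sc$n_samples)),
                                     pool$taxon_ids))
    for (i in seq_len(sc$n_samples)) {
      w <- if (sc$m >= 1 || sc$J == 1) p else {
        I <- sc$m * (sc$J - 1) / (1 - sc$m)
        g <- stats::rgamma(S, shape = I * p)
        if (sum(g) == 0) p else g / sum(g)
      }
      counts[i, ] <- stats::rmultinom(1L, sc$J, w)[, 1L]
    }
    env <- nuisance_env(coords$x_km, sc$env_range_km)
    list(table = count_table(counts),
         frame = make_frame(rownames(counts), coords, env))
  })
}

#' Simulate niche-filtered local communities along a spatial gradient
#'
#' A spatially autocorrelated environmental gradient (a salinity analogue,
#' written to the metadata as column `gradient`) filters the regional pool:
#' sampling weights are pool abundance times a Gaussian response
#' \eqn{\exp(-(g - o_k)^2 / (2 b^2))} with taxon optima \eqn{o_k} and common
#' breadth \eqn{b}. Narrow breadth produces strong composition turnover
#' along the gradient; as \eqn{b \to \infty} the samples become neutral
#' `m = 1` draws.
#'
#' @inheritParams simulate_neutral_samples
#' @param scenario a `simulation_scenario` with `regime = "niche"` (or
#'   `"mixed"`, which additionally applies the neutral Dirichlet drift).
#' @return list with `table`, `frame` (including the `gradient` column) and
#'   `optima` (the planted taxon optima).
#' @export
simulate_niche_samples <- function(pool, scenario) {
  stopifnot(inherits(pool, "metacommunity_pool"),
            inherits(scenario, "simulation_scenario"))
  if (!scenario$regime %in% c("niche", "mixed"))
    stopf("scenario regime must be 'niche' or 'mixed'")
  sc <- scenario
  p <- pool$abundance
  S <- length(p)
  coords <- transect_coords(sc$n_samples, sc$transect_km)
  with_seed(sc$seed, {
    g <- smoothed_gradient(coords$x_km, sc$env_range_km)
    optima <- stats::runif(S, -sc$optima_spread, sc$optima_spread)
    counts <- matrix(0, sc$n_samples, S,
                     dimnames = list(sprintf("S%02d", seq_len(sc$n_samples)),
                                     pool$taxon_ids))
    for (i in seq_len(sc$n_samples)) {
      w <- p * exp(-(g[i] - optima)^2 / (2 * sc$niche_breadth^2))
      if (sum(w) == 0) w <- p
      w <- w / sum(w)
      if (sc$regime == "mixed" && sc$m < 1) {
        I <- sc$m * (sc$J - 1) / (1 - sc$m)
        gam <- stats::rgamma(S, shape = I * w)
        if (sum(gam) > 0) w <- gam / sum(gam)
      }
      counts[i, ] <- stats::rmultinom(1L, sc$J, w)[, 1L]
    }
    env <- nuisance_env(coords$x_km, sc$env_range_km)
    env <- cbind(gradient = g, env)
    list(table = count_table(counts),
         frame = make_frame(rownames(counts), coords, env),
         optima = optima)
  })
}

#' Simulate taxa with planted co-abundance blocks
#'
#' Ground truth for the co-occurrence network stage. Taxa within a block of
#' `sign = +1` load on a shared latent Gaussian factor with loading
#' `sqrt(strength)`; a block with `sign = -1` loads negatively on the factor
#' of the nearest preceding positive block, so inter-block pairs
#' anti-correlate. Latent values are mapped to counts as Poisson draws with
#' a lognormal mean, which attenuates correlations only mildly at the
#' default abundance scale.
#'
#' @param n_samples number of samples.
#' @param blocks list of `list(size =, sign =, strength =)` with strength in
#'   (0, 1].
#' @param n_background independent-noise taxa appended after the blocks.
#' @param mean_log,sd_log lognormal abundance scale of the Poisson means.
#' @param seed integer seed.
#' @return list with `table` (a [count_table()]) and `membership` (block
#'   index per taxon, 0 = background).
#' @export
simulate_block_correlated_taxa <- function(n_samples, blocks, n_background = 0,
                                           mean_log = log(100), sd_log = 0.3,
                                           seed = 1) {
  stopifnot(n_samples >= 4)
  for (b in blocks)
    stopifnot(b$size >= 1, b$strength > 0, b$strength <= 1, b$sign %in% c(-1, 1))
  with_seed(seed, {
    cols <- list(); member <- integer(0); factor_pos <- NULL
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      if (b$sign > 0 || is.null(factor_pos))
        factor_pos <- stats::rnorm(n_samples)
      load <- b$sign * sqrt(b$strength)
      for (k in seq_len(b$size)) {
        z <- load * factor_pos + sqrt(1 - b$strength) * stats::rnorm(n_samples)
        cols[[length(cols) + 1L]] <- z
        member <- c(member, bi)
      }
    }
    for (k in seq_len(n_background)) {
      cols[[length(cols) + 1L]] <- stats::rnorm(n_samples)
      member <- c(member, 0L)
    }
    Z <- do.call(cbind, cols)
    lambda <- exp(mean_log + sd_log * Z)
    counts <- matrix(stats::rpois(length(lambda), lambda), nrow = n_samples,
                     dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                     sprintf("ASV_%04d", seq_len(ncol(Z)))))
    list(table = count_table(counts), membership = member)
  })
}

#' Write a simulated scenario to disk (table, metadata, provenance)
#'
#' @param sim result of a `simulate_*_samples()` call.
#' @param dir output directory (created if missing).
#' @param scenario the `simulation_scenario` used, recorded as provenance.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, scenario = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(sim$table, file.path(dir, "counts.tsv"))
  utils::write.table(sim$frame, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(scenario))
    writeLines(yaml::as.yaml(unclass(scenario)), file.path(dir, "provenance.yml"))
  invisible(dir)
}
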