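# Small fixtures built in code; all randomness goes through fixed seeds.

# deterministic small integer table
toy_table <- function(n_samples = 5, n_taxa = 8, seed = 42, lambda = 6) {
  m <- riverlake:::with_seed(seed,
    matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("t%02d", seq_len(n_taxa)))
  count_table(m)
}

toy_lineages <- function(ids) {
  phyla <- rep(c("Proteobacteria", "Verrucomicrobia", "Acidobacteria"),
               length.out = length(ids))
  stats::setNames(paste("Bacteria", phyla, sep = ";"), ids)
}

# metadata frame on a 1-D transect
toy_frame <- function(ids, group = "river", lat0 = 42, lon_step = 0.05, seed = 7) {
  env <- riverlake:::with_seed(seed,
    data.frame(TDS = runif(length(ids), 0.3, 1.6),
               WT = runif(length(ids), 5, 18),
               TSS = runif(length(ids), 1, 40)))
  validate_sample_frame(data.frame(
    sample_id = ids, group = group, lat = lat0,
    lon = 86.5 + lon_step * (seq_along(ids) - 1), env))
}

# Euclidean dist_matrix from planted 2-D coordinates
planted_euclidean <- function(n = 10, seed = 3) {
  xy <- riverlake:::with_seed(seed, matrix(rnorm(n * 2), n, 2))
  rownames(xy) <- sprintf("p%02d", seq_len(n))
  d <- as.matrix(stats::dist(xy))
  list(xy = xy, dm = dist_matrix(d, metric = "euclidean"))
}

# least-squares Procrustes error after centering + optimal rotation/scale
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(crossprod(B, A))
  R <- s$u %*% t(s$v)
  Bh <- B %*% R
  sc <- sum(diag(crossprod(A, Bh))) / sum(Bh^2)
  sqrt(sum((A - sc * Bh)^2))
}
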