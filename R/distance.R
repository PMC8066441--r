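#' Labelled symmetric distance matrices
#'
#' Thin validated container shared by community dissimilarities
#' (Bray-Curtis) and geographic distances. Stored as a full symmetric
#' matrix with a `metric` attribute.
#'
#' @param m symmetric numeric matrix with zero diagonal and dimnames.
#' @param metric name of the metric (free text, e.g. "bray_curtis", "haversine_km").
#' @return matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m, metric = "unknown") {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stopf("distance matrix must be square")
  if (is.null(rownames(m))) stopf("distance matrix must be labelled")
  if (max(abs(m - t(m))) > 1e-12) stopf("distance matrix not symmetric")
  if (any(diag(m) != 0)) stopf("distance matrix diagonal must be exactly 0")
  if (any(m < 0)) stopf("distances must be non-negative")
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix"), metric = metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d x %d\n", attr(x, "metric"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))), drop = FALSE])
  invisible(x)
}

# upper-triangle values in a fixed (column-major) order
dm_condensed <- function(m) m[upper.tri(m)]
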