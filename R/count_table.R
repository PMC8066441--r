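#' ASV count tables
#'
#' A `count_table` holds a sample-by-taxon matrix of non-negative integer
#' read counts, with samples as rows and taxa (ASVs) as columns, plus an
#' optional ranked lineage per taxon. It is the central container of the
#' package: every downstream stage (diversity, SAD fitting, null models,
#' ordination, networks) consumes one.
#'
#' @param counts numeric matrix of non-negative integers, samples in rows,
#'   taxa in columns; must carry row and column names.
#' @param lineages optional character vector of semicolon-delimited lineages
#'   (up to 7 ranks, kingdom to species), named by taxon id or given in
#'   column order.
#' @return an object of class `count_table` with elements `counts` and
#'   `lineages`.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' ct <- count_table(m)
#' n_samples(ct); n_taxa(ct)
#' @export
count_table <- function(counts, lineages = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count table must have sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate taxon ids: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stopf("count table needs at least 1 sample and 1 taxon")
  if (any(is.na(counts))) stopf("count table contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stopf("negative count at sample '%s', taxon '%s'",
          rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1L, ]
    stopf("non-integer count at sample '%s', taxon '%s'",
          rownames(counts)[bad[1L]], colnames(counts)[bad[2L]])
  }
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max when pooled
  if (!is.null(lineages)) {
    lineages <- as.character(lineages)
    if (is.null(names(lineages))) {
      if (length(lineages) != ncol(counts))
        stopf("unnamed lineages must have one entry per taxon")
      names(lineages) <- colnames(counts)
    }
    missing <- setdiff(colnames(counts), names(lineages))
    if (length(missing)) lineages[missing] <- NA_character_
    lineages <- lineages[colnames(counts)]
    depth <- lengths(strsplit(lineages[!is.na(lineages)], ";", fixed = TRUE))
    if (length(depth) && max(depth) > 7L)
      stopf("lineages may have at most 7 ranks")
  }
  structure(list(counts = counts, lineages = lineages), class = "count_table")
}

#' @rdname count_table
#' @param x a `count_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname count_table
#' @export
n_taxa <- function(x) ncol(x$counts)

#' @rdname count_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa, %s reads%s\n",
              n_samples(x), n_taxa(x), format(sum(x$counts), big.mark = ","),
              if (is.null(x$lineages)) "" else ", with lineages"))
  invisible(x)
}

#' Read a count table from TSV
#'
#' The file must be tab-separated with the first column holding row ids and
#' the header holding column ids. Orientation (whether rows are samples or
#' taxa) can be forced, or auto-detected from overlap of the file's ids with
#' a vector of known sample ids.
#'
#' @param path path to a TSV file.
#' @param orientation one of `"auto"`, `"samples_as_rows"`, `"taxa_as_rows"`.
#' @param sample_ids optional character vector of known sample ids used by
#'   auto-detection (e.g. from the metadata file).
#' @param lineages optional lineage vector passed to [count_table()].
#' @return a [count_table()].
#' @export
read_count_table <- function(path, orientation = c("auto", "samples_as_rows", "taxa_as_rows"),
                             sample_ids = NULL, lineages = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (orientation == "auto") {
    if (!is.null(sample_ids)) {
      row_hits <- length(intersect(rownames(m), sample_ids))
      col_hits <- length(intersect(colnames(m), sample_ids))
      orientation <- if (col_hits > row_hits) "taxa_as_rows" else "samples_as_rows"
    } else {
      # amplicon tables are usually written taxa-in-rows; but with nothing to
      # match against, prefer the wider axis as the taxon axis
      orientation <- if (ncol(m) >= nrow(m)) "taxa_as_rows" else "samples_as_rows"
      if (nrow(m) != ncol(m))
        message(sprintf("orientation auto-detected as %s (no sample ids supplied)", orientation))
    }
  }
  if (orientation == "taxa_as_rows") m <- t(m)
  count_table(m, lineages = lineages)
}

#' Read a BIOM-format (JSON, version 1.0) count table
#'
#' Convenience reader for the interchange format written by common amplicon
#' pipelines; requires the \pkg{biomformat} package. BIOM stores taxa in
#' rows and samples in columns.
#'
#' @param path path to a `.biom` JSON file.
#' @return a [count_table()].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stopf("reading BIOM files requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
  count_table(t(m))
}

#' Write a count table to TSV
#'
#' @param x a `count_table`.
#' @param path output path.
#' @param taxa_as_rows write taxa in rows (the common amplicon layout).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, taxa_as_rows = TRUE) {
  m <- if (taxa_as_rows) t(x$counts) else x$counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (taxa_as_rows) "taxon_id" else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table (taxon id + semicolon-delimited lineage)
#'
#' @param path TSV with two columns: taxon id, lineage.
#' @return named character vector of lineages.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}

#' Drop rare taxa by pooled total count
#'
#' Removes taxa whose summed count across all samples falls strictly below
#' `min_total`; this mirrors the usual discard of low-abundance unique
#' sequences (default 10 reads) before downstream analysis. Samples are kept
#' even if the filter empties them; emptied samples are reported via message.
#'
#' @param x a `count_table`.
#' @param min_total minimum pooled count for a taxon to be kept (default 10).
#' @return a filtered `count_table`.
#' @export
filter_min_abundance <- function(x, min_total = 10) {
  stopifnot(inherits(x, "count_table"), min_total >= 0)
  keep <- colSums(x$counts) >= min_total
  if (!any(keep)) stopf("no taxa pass min_total = %s", format(min_total))
  out <- count_table(x$counts[, keep, drop = FALSE],
                     lineages = if (is.null(x$lineages)) NULL else x$lineages[keep])
  emptied <- rownames(out$counts)[rowSums(out$counts) == 0]
  if (length(emptied))
    message("samples emptied by filtering (kept, flagged): ",
            paste(emptied, collapse = ", "))
  out
}

#' Rarefy each sample to a fixed depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric) within
#' each sample so that every sample total equals `depth` exactly. Used to
#' normalise unequal sequencing depth before diversity comparisons.
#'
#' @param x a `count_table`.
#' @param depth target reads per sample.
#' @param seed integer seed; identical inputs and seed give identical output.
#' @return a rarefied `count_table` (taxa axis unchanged; zero-total taxa kept).
#' @export
rarefy <- function(x, depth, seed) {
  stopifnot(inherits(x, "count_table"), depth >= 1)
  totals <- rowSums(x$counts)
  shallow <- rownames(x$counts)[totals < depth]
  if (length(shallow))
    stopf("samples shallower than depth %d: %s", depth,
          paste(shallow, collapse = ", "))
  S <- ncol(x$counts)
  out <- x$counts
  with_seed(seed, {
    for (i in seq_len(nrow(out))) {
      if (totals[i] == depth) next
      reads <- rep.int(seq_len(S), out[i, ])
      take <- sample(reads, depth, replace = FALSE)
      out[i, ] <- tabulate(take, nbins = S)
    }
  })
  count_table(out, lineages = x$lineages)
}

#' Rarefaction curves of richness versus sequencing effort
#'
#' For each sample and each fraction of its reads, repeatedly subsamples
#' without replacement and records observed richness. Fraction 1 reproduces
#' the observed richness exactly.
#'
#' @param x a `count_table`.
#' @param fractions proportions of reads in (0, 1].
#' @param reps subsamples per fraction (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns sample_id, fraction, depth, mean_richness, se.
#' @export
rarefaction_curves <- function(x, fractions = seq(0.1, 1, by = 0.1), reps = 10, seed = 1) {
  stopifnot(inherits(x, "count_table"), all(fractions > 0), all(fractions <= 1), reps >= 1)
  totals <- rowSums(x$counts)
  if (any(totals == 0))
    stopf("empty sample(s): %s", paste(names(totals)[totals == 0], collapse = ", "))
  S <- ncol(x$counts)
  res <- vector("list", nrow(x$counts) * length(fractions))
  k <- 0L
  with_seed(seed, {
    for (i in seq_len(nrow(x$counts))) {
      reads <- rep.int(seq_len(S), x$counts[i, ])
      for (f in sort(fractions)) {
        d <- max(1L, floor(f * totals[i]))
        rich <- if (d == totals[i]) {
          rep(sum(x$counts[i, ] > 0), reps)
        } else {
          vapply(seq_len(reps),
                 function(r) length(unique(sample(reads, d, replace = FALSE))),
                 numeric(1))
        }
        k <- k + 1L
        res[[k]] <- data.frame(sample_id = rownames(x$counts)[i], fraction = f,
                               depth = d, mean_richness = mean(rich),
                               se = stats::sd(rich) / sqrt(reps))
      }
    }
  })
  do.call(rbind, res)
}

.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Aggregate counts to a taxonomic rank as read fractions
#'
#' Sums counts over taxa sharing the same lineage entry at `rank` and
#' converts to per-sample read fractions; taxa with no assignment at that
#' rank are pooled under `"unclassified"`. A pooled (all samples summed) row
#' is appended.
#'
#' @param x a `count_table` with lineages.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return data.frame: rows = samples plus `"pooled"`, columns = groups at
#'   `rank`; each row sums to 1.
#' @export
aggregate_taxonomy <- function(x, rank = "phylum") {
  stopifnot(inherits(x, "count_table"))
  if (is.null(x$lineages)) stopf("count table has no lineages")
  ri <- match(tolower(rank), .RANKS)
  if (is.na(ri)) stopf("unknown rank '%s'", rank)
  parts <- strsplit(ifelse(is.na(x$lineages), "", x$lineages), ";", fixed = TRUE)
  if (all(lengths(parts) < ri))
    stopf("rank '%s' absent from all lineages", rank)
  grp <- vapply(parts, function(p) {
    v <- if (length(p) >= ri) trimws(p[ri]) else ""
    if (is.na(v) || v == "") "unclassified" else v
  }, character(1))
  m <- rbind(x$counts, pooled = colSums(x$counts))
  agg <- t(rowsum(t(m), grp))       # samples x groups
  frac <- agg / rowSums(agg)
  as.data.frame(frac, check.names = FALSE)
}

#' Partition samples into habitat groups
#'
#' Splits a count table by the metadata group label, after removing an
#' explicit exclusion list (e.g. outlier river-mouth samples). All group
#' tables keep the full taxon axis so they remain comparable.
#'
#' @param x a `count_table`.
#' @param frame a `sample_frame` (see [read_sample_frame()]) covering all samples.
#' @param exclusions sample ids to drop from every group.
#' @param group_map optional named character vector collapsing metadata
#'   labels into coarser groups, e.g. `c(tributary = "river", river = "river",
#'   lake = "lake")`.
#' @return named list of `count_table`s, one per group.
#' @export
split_habitats <- function(x, frame, exclusions = character(), group_map = NULL) {
  stopifnot(inherits(x, "count_table"))
  unknown <- setdiff(exclusions, sample_ids(x))
  if (length(unknown))
    stopf("unknown exclusion id(s): %s", paste(unknown, collapse = ", "))
  grp <- stats::setNames(as.character(frame$group), frame$sample_id)
  miss <- setdiff(sample_ids(x), names(grp))
  if (length(miss))
    stopf("samples missing from metadata: %s", paste(miss, collapse = ", "))
  grp <- grp[sample_ids(x)]
  if (!is.null(group_map)) {
    unmapped <- setdiff(unique(grp), names(group_map))
    if (length(unmapped))
      stopf("group_map does not cover label(s): %s", paste(unmapped, collapse = ", "))
    grp <- stats::setNames(unname(group_map[grp]), names(grp))
  }
  keep <- setdiff(sample_ids(x), exclusions)
  out <- lapply(split(keep, grp[keep]), function(ids)
    count_table(x$counts[ids, , drop = FALSE], lineages = x$lineages))
  out
}

#' Read a sample metadata table
#'
#' Expects TSV columns `sample_id`, `group`, `lat`, `lon`, then any number of
#' environmental variables (e.g. WT, pH, EC, TDS, DO, TN, TP, TSS, DOC,
#' Chl.a). Coordinates are decimal degrees.
#'
#' @param path TSV path.
#' @return a data.frame of class `sample_frame`.
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

#' @rdname read_sample_frame
#' @param df a data.frame with at least sample_id, group, lat, lon.
#' @export
validate_sample_frame <- function(df) {
  need <- c("sample_id", "group", "lat", "lon")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in metadata")
  ok_lat <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  ok_lon <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  if (!all(ok_lat)) stopf("latitude out of [-90, 90] for %s",
                          paste(df$sample_id[!ok_lat], collapse = ", "))
  if (!all(ok_lon)) stopf("longitude out of [-180, 180] for %s",
                          paste(df$sample_id[!ok_lon], collapse = ", "))
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Environmental variable columns of a sample frame
#' @param frame a `sample_frame`.
#' @return data.frame of the environmental columns, rownames = sample ids.
#' @export
env_columns <- function(frame) {
  env <- frame[, setdiff(names(frame), c("sample_id", "group", "lat", "lon")),
               drop = FALSE]
  rownames(env) <- frame$sample_id
  env
}
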