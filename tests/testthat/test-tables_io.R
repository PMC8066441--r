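test_that("count_table validates its invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  ct <- count_table(m)
  expect_s3_class(ct, "count_table")
  expect_equal(n_samples(ct), 2)
  expect_equal(n_taxa(ct), 3)

  m2 <- m; m2[1, 2] <- -2
  expect_error(count_table(m2), "negative count.*'a'.*'y'")
  m3 <- m; m3[2, 1] <- 1.5
  expect_error(count_table(m3), "non-integer")
  m4 <- m; rownames(m4) <- c("a", "a")
  expect_error(count_table(m4), "duplicate sample")
  expect_error(count_table(m, lineages = rep("k;p;c;o;f;g;s;x", 3)), "7 ranks")
})

test_that("read_count_table round-trips both orientations", {
  ct <- toy_table(4, 7, seed = 9)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_count_table(ct, f1, taxa_as_rows = TRUE)
  write_count_table(ct, f2, taxa_as_rows = FALSE)
  r1 <- read_count_table(f1, orientation = "taxa_as_rows")
  r2 <- read_count_table(f2, orientation = "samples_as_rows")
  expect_equal(r1$counts, ct$counts)
  expect_equal(r2$counts, ct$counts)
  # auto-detection via known sample ids
  r3 <- read_count_table(f1, sample_ids = sample_ids(ct))
  expect_equal(r3$counts, ct$counts)
  # a file with a negative cell fails validation
  writeLines(c("taxon_id\ts1\ts2", "t1\t3\t-2"), f1)
  expect_error(read_count_table(f1, orientation = "taxa_as_rows"), "negative")
})

test_that("read_biom_table matches the TSV reader on the same data", {
  skip_if_not_installed("biomformat")
  ct <- toy_table(3, 5, seed = 77)
  b <- biomformat::make_biom(t(ct$counts))   # biom stores taxa x samples
  f <- tempfile(fileext = ".biom")
  biomformat::write_biom(b, f)
  r <- read_biom_table(f)
  expect_equal(r$counts[sample_ids(ct), taxon_ids(ct)], ct$counts)
})

test_that("filter_min_abundance applies a strict pooled-count threshold", {
  m <- matrix(c(4, 5, 5, 5, 1, 2), 2, 3,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  ct <- count_table(m)             # taxa totals 9, 10, 3
  kept <- filter_min_abundance(ct, 10)
  expect_equal(taxon_ids(kept), "t2")
  expect_equal(filter_min_abundance(ct, 0)$counts, ct$counts)
  # brute-force scan on a random table
  ct2 <- toy_table(6, 20, seed = 2, lambda = 2)
  expect_equal(taxon_ids(filter_min_abundance(ct2, 12)),
               colnames(ct2$counts)[colSums(ct2$counts) >= 12])
})

test_that("rarefy fixes sample totals, preserves support, is seed-deterministic", {
  ct <- toy_table(4, 10, seed = 5, lambda = 20)
  r <- rarefy(ct, 100, seed = 1)
  expect_true(all(rowSums(r$counts) == 100))
  expect_true(all(r$counts[ct$counts == 0] == 0))
  expect_identical(r$counts, rarefy(ct, 100, seed = 1)$counts)
  expect_false(identical(r$counts, rarefy(ct, 100, seed = 2)$counts))
  # depth = total leaves a sample unchanged
  one <- count_table(matrix(c(5L, 5L), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(rarefy(one, 10, seed = 1)$counts, one$counts)
  # depth 1 leaves exactly one read
  r1 <- rarefy(ct, 1, seed = 3)
  expect_true(all(rowSums(r1$counts) == 1))
  expect_error(rarefy(ct, 10^6, seed = 1), "shallower")
})

test_that("rarefy matches the hypergeometric expectation", {
  counts <- c(40L, 25L, 20L, 10L, 5L)
  ct <- count_table(matrix(counts, 1, dimnames = list("s", paste0("t", 1:5))))
  N <- sum(counts); d <- N / 2
  reps <- 1000
  draws <- sapply(seq_len(reps), function(i) rarefy(ct, d, seed = i)$counts[1, ])
  m_obs <- rowMeans(draws)
  m_exp <- counts * d / N
  v_exp <- d * (counts / N) * (1 - counts / N) * (N - d) / (N - 1)
  expect_true(all(abs(m_obs - m_exp) <= 3 * sqrt(v_exp / reps)))
})

test_that("rarefaction_curves are monotone and hit observed richness at 1", {
  ct <- toy_table(3, 30, seed = 8, lambda = 3)
  rc <- rarefaction_curves(ct, fractions = c(0.25, 0.5, 1), reps = 20, seed = 1)
  obs_rich <- rowSums(ct$counts > 0)
  for (s in sample_ids(ct)) {
    cur <- rc[rc$sample_id == s, ]
    expect_true(all(diff(cur$mean_richness) >= 0))
    expect_equal(cur$mean_richness[cur$fraction == 1], unname(obs_rich[s]))
  }
  # single-taxon sample: richness 1 everywhere
  one <- count_table(matrix(50L, 1, dimnames = list("s", "t")))
  rc1 <- rarefaction_curves(one, c(0.2, 1), reps = 5, seed = 1)
  expect_true(all(rc1$mean_richness == 1))
})

test_that("rarefaction richness matches the hypergeometric absence oracle", {
  # uniform 100-taxon sample, fraction 0.5
  ct <- count_table(matrix(rep(10L, 100), 1,
                           dimnames = list("s", sprintf("t%03d", 1:100))))
  reps <- 200
  rc <- rarefaction_curves(ct, fractions = 0.5, reps = reps, seed = 4)
  N <- 1000; d <- 500; c_i <- 10
  p_absent <- prod((N - c_i - d + seq_len(c_i)) / (N - c_i + seq_len(c_i)))  # choose ratio
  expected <- 100 * (1 - p_absent)
  expect_lt(abs(rc$mean_richness - expected), 3 * rc$se + 1e-9)
})

test_that("aggregate_taxonomy sums to 1 and matches brute-force group-by", {
  ct <- toy_table(4, 9, seed = 3)
  ct <- count_table(ct$counts, lineages = toy_lineages(taxon_ids(ct)))
  agg <- aggregate_taxonomy(ct, "phylum")
  expect_true(all(abs(rowSums(agg) - 1) < 1e-9))
  # brute force for one sample and one phylum
  phyla <- sub("^Bacteria;", "", ct$lineages)
  manual <- sum(ct$counts[2, phyla == "Acidobacteria"]) / sum(ct$counts[2, ])
  expect_equal(agg["s02", "Acidobacteria"], manual)
  # permutation invariance to taxon order
  perm <- sample(taxon_ids(ct))
  ct_p <- count_table(ct$counts[, perm], lineages = ct$lineages[perm])
  agg_p <- aggregate_taxonomy(ct_p, "phylum")
  expect_equal(agg_p[, colnames(agg)], agg)
  # unclassified bucket and missing-rank error
  lin2 <- ct$lineages; lin2[1] <- NA
  ct2 <- count_table(ct$counts, lineages = lin2)
  expect_true("unclassified" %in% colnames(aggregate_taxonomy(ct2, "phylum")))
  expect_error(aggregate_taxonomy(ct, "genus"), "absent")
})

test_that("split_habitats reproduces the 15/11 partition and set algebra", {
  ids <- c(sprintf("A%02d", 1:8), sprintf("B%02d", 1:8), sprintf("C%02d", 1:12))
  m <- matrix(1L, 28, 4, dimnames = list(ids, paste0("t", 1:4)))
  frame <- validate_sample_frame(data.frame(
    sample_id = ids, group = rep(c("tributary", "river", "lake"), c(8, 8, 12)),
    lat = 42, lon = 86.5))
  parts <- split_habitats(count_table(m), frame, exclusions = c("A03", "C01"),
                          group_map = c(tributary = "river", river = "river",
                                        lake = "lake"))
  expect_equal(n_samples(parts$river), 15)
  expect_equal(n_samples(parts$lake), 11)
  expect_equal(taxon_ids(parts$river), taxon_ids(parts$lake))
  # union of groups = all minus exclusions; groups disjoint
  got <- unlist(lapply(parts, sample_ids), use.names = FALSE)
  expect_setequal(got, setdiff(ids, c("A03", "C01")))
  expect_equal(anyDuplicated(got), 0L)
  expect_error(split_habitats(count_table(m), frame, exclusions = "ZZZ"),
               "unknown exclusion")
})

test_that("sample_frame validation catches bad coordinates", {
  df <- data.frame(sample_id = c("a", "b"), group = "g", lat = c(42, 95), lon = 86)
  expect_error(validate_sample_frame(df), "latitude")
  df$lat <- c(42, 43); df$lon <- c(300, 86)
  expect_error(validate_sample_frame(df), "longitude")
})
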