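test_that("OTU table TSV round-trips, parses taxonomy, and rejects bad cells", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  vals <- matrix(c(5L, 0L, 3L, 2L, 7L, 1L), nrow = 3,
                 dimnames = list(c("OTU1", "OTU2", "OTU3"), c("S1", "S2")))
  tax <- c(OTU1 = "Bacteria;Firmicutes;Clostridia",
           OTU2 = "Bacteria;Bacteroidetes")
  write_otu_table(make_table(vals, taxonomy = tax), tmp)
  back <- read_otu_table(tmp)
  expect_identical(back$values, vals * 1.0)
  expect_equal(back$taxonomy[["OTU1"]], "Bacteria;Firmicutes;Clostridia")
  expect_equal(otu_phylum(back$taxonomy, rownames(vals)),
               c(OTU1 = "Firmicutes", OTU2 = "Bacteroidetes",
                 OTU3 = "unclassified"))

  writeLines(c("OTU_ID\tS1\tS2", "OTU1\t3\tx"), tmp)
  expect_error(read_otu_table(tmp), "non-numeric.*OTU1.*S2")
  writeLines(c("OTU_ID\tS1", "OTU1\t3", "OTU1\t4"), tmp)
  expect_error(read_otu_table(tmp), "duplicate OTU")
  writeLines(c("OTU_ID\tS1", "OTU1\t-3"), tmp)
  expect_error(read_otu_table(tmp), "negative")
})

test_that("constructor enforces the container invariants", {
  vals <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(make_table(vals), "otu_table")
  expect_error(otu_table(matrix(1:4, 2), units = "counts"), "names")
  bad <- vals; bad[1, 1] <- -1
  expect_error(make_table(bad), "non-negative")
  prop <- matrix(c(0.4, 0.6, 0.5, 0.6), 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(prop, units = "proportions"), "sum to 1")
})

test_that("rarefaction is exact-depth, seed-deterministic, hypergeometric", {
  vals <- matrix(c(30L, 20L, 50L, 10L, 25L, 15L), nrow = 3,
                 dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
  x <- make_table(vals)
  r1 <- rarefy(x, depth = 40, seed = 7)
  expect_true(all(colSums(r1$values) == 40))
  r2 <- rarefy(x, depth = 40, seed = 7)
  expect_identical(r1$values, r2$values)
  # exhaustive draw leaves the column unchanged
  full <- rarefy(make_table(vals[, 1, drop = FALSE]), depth = 100, seed = 1)
  expect_identical(full$values[, 1], vals[, 1] * 1.0)
  expect_equal(formals(rarefy)$depth, 39796)
  expect_error(rarefy(x, depth = 0), "positive")
  expect_error(rarefy(relative_abundance(x), depth = 10), "counts")
  # shallow samples dropped, not resampled
  expect_warning(r3 <- rarefy(x, depth = 60, seed = 1), "dropping 1 sample")
  expect_identical(colnames(r3$values), "S1")

  # counts (10, 10), depth 10: drawn first-OTU count is hypergeometric
  # (N = 20, K = 10, n = 10), mean 5, var n*K/N*(1-K/N)*(N-n)/(N-1)
  two <- make_table(matrix(c(10L, 10L), 2,
                           dimnames = list(c("A", "B"), "S")))
  set.seed(11)
  draws <- replicate(10000, rarefy(two, depth = 10)$values["A", 1])
  v <- 10 * 0.5 * 0.5 * (20 - 10) / (20 - 1)
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(v / 10000))
  expect_lt(abs(var(draws) - v), 0.15 * v)
})

test_that("prevalence filter applies the strict majority rule per group", {
  n21 <- 21; n22 <- 22
  vals <- rbind(
    kept    = c(rep(1L, 11), rep(0L, n21 - 11)),  # 11/21 > 0.5
    allzero = rep(0L, n21),
    allin   = rep(2L, n21))
  colnames(vals) <- paste0("g1_", seq_len(n21))
  x <- make_table(vals, groups = setNames(rep("G1", n21), colnames(vals)))
  f <- prevalence_filter(x, "G1")
  expect_setequal(rownames(f$values), c("kept", "allin"))

  vals2 <- rbind(boundary = c(rep(1L, 11), rep(0L, n22 - 11)),
                 allin = rep(1L, n22))
  colnames(vals2) <- paste0("g2_", seq_len(n22))
  y <- make_table(vals2, groups = setNames(rep("G2", n22), colnames(vals2)))
  expect_identical(rownames(prevalence_filter(y, "G2")$values), "allin")

  expect_error(prevalence_filter(x, "nope"), "unknown group")
  # min_fraction 0 keeps anything detected at least once; 1 keeps nothing
  expect_setequal(rownames(prevalence_filter(x, "G1", 0)$values),
                  c("kept", "allin"))
  expect_equal(nrow(prevalence_filter(x, "G1", 1)$values), 0)
})

test_that("relative abundance normalises columns exactly once", {
  vals <- matrix(c(2L, 2L, 1L, 3L), 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  rel <- relative_abundance(make_table(vals))
  expect_equal(rel$values[, "s1"], c(a = 0.5, b = 0.5))
  expect_equal(unname(colSums(rel$values)), c(1, 1))
  expect_equal(rel$units, "proportions")
  expect_error(relative_abundance(rel), "already proportions")
  single <- make_table(matrix(c(4L, 9L), 1,
                              dimnames = list("only", c("s1", "s2"))))
  expect_true(all(relative_abundance(single)$values == 1))
  zero <- make_table(matrix(c(1L, 0L), 1,
                            dimnames = list("a", c("s1", "s2"))))
  expect_error(relative_abundance(zero), "all-zero")
})
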