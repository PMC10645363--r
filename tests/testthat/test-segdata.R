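write_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

test_that("segmentation reader parses, fills defaults and sorts", {
  seg <- read_segments(write_bed(c("chr2\t100\t500\tarm2p\t3",
                                   "chr1\t0\t1000")))
  expect_equal(seg$chrom, c("chr1", "chr2"))
  expect_equal(seg$segment_id, c("chr1:0-1000", "arm2p"))
  expect_equal(seg$expected_cn, c(2L, 3L))
  expect_equal(seg$start, c(0, 100))
})

test_that("segmentation reader rejects malformed and overlapping input", {
  expect_error(read_segments(write_bed("chr3\t100\t100")), "line 1")
  expect_error(read_segments(write_bed("chr3\tabc\t200")), "line 1")
  expect_error(read_segments(write_bed(c("chr1\t0\t1000\ta",
                                         "chr1\t500\t2000\tb"))),
               "overlap")
  # same coordinates on different chromosomes are fine
  expect_silent(read_segments(write_bed(c("chr1\t0\t1000",
                                          "chr2\t0\t1000"))))
})

test_that("feature aggregation follows the midpoint rule and conserves mass", {
  seg <- read_segments(write_bed(c("chr1\t0\t1000\ts1",
                                   "chr1\t1000\t2000\ts2")))
  features <- list(
    counts = matrix(c(5, 0, 2,    # gene inside s1
                      1, 1, 1,    # gene spanning boundary, midpoint in s2
                      3, 3, 3,    # inside s2
                      9, 9, 9),   # outside every segment -> dropped
                    nrow = 4, byrow = TRUE),
    features = data.frame(feature_id = paste0("g", 1:4), name = paste0("g", 1:4),
                          chrom = "chr1",
                          start = c(200, 900, 1200, 5000),
                          end = c(300, 1300, 1400, 6000)),
    barcodes = c("A", "B", "C"))
  sc <- aggregate_to_segments(features, seg, "RNA")
  expect_equal(unname(sc$counts[, "s1"]), c(5, 0, 2))
  expect_equal(unname(sc$counts[, "s2"]), c(4, 4, 4))
  # mass conservation over assigned features
  expect_equal(rowSums(sc$counts),
               colSums(features$counts[1:3, ]), ignore_attr = TRUE)
  expect_equal(attr(sc, "features_per_segment"), c(s1 = 1L, s2 = 2L))
  expect_equal(attr(sc, "n_features_dropped"), 1L)
  # additivity: many features in one segment sum up
  many <- list(counts = matrix(1, 10, 2),
               features = data.frame(feature_id = paste0("g", 1:10),
                                     name = paste0("g", 1:10), chrom = "chr1",
                                     start = 1:10, end = 11:20),
               barcodes = c("A", "B"))
  sc2 <- aggregate_to_segments(many, seg, "RNA")
  expect_equal(unname(sc2$counts[, "s1"]), c(10, 10))
  # disjoint features error
  far <- many
  far$features$start <- far$features$start + 10000
  far$features$end <- far$features$end + 10000
  expect_error(aggregate_to_segments(far, seg), "do not overlap")
})

test_that("library factors are mean-normalised totals", {
  m <- rbind(c(60, 40), c(60, 40))
  expect_equal(compute_library_factors(m), c(1, 1))
  m2 <- rbind(c(30, 20), c(90, 60))
  expect_equal(compute_library_factors(m2), c(0.5, 1.5))
  m3 <- rbind(c(0, 0), c(50, 50))
  rownames(m3) <- c("cellA", "cellB")
  expect_error(compute_library_factors(m3), "cellA")
  # mean of factors is always 1
  set.seed(1)
  m4 <- matrix(rpois(200, 30) + 1, 20, 10)
  expect_equal(mean(compute_library_factors(m4)), 1)
})

test_that("segment filter removes high-zero segments in any modality", {
  set.seed(5)
  base <- matrix(rpois(100 * 3, 20) + 1, 100, 3)
  rna <- base; atac <- base
  rna[1:11, 2] <- 0   # 11% zeros in RNA segment 2 only
  rna_sc <- make_sc(rna, "RNA")
  atac_sc <- make_sc(atac, "ATAC")
  out <- filter_segments(rna_sc, atac_sc, max_zero_fraction = 0.10)
  expect_equal(attr(out, "removed_segments"), "seg2")
  expect_equal(out[[1]]$segment_ids, c("seg1", "seg3"))
  expect_equal(out[[2]]$segment_ids, c("seg1", "seg3"))  # synchronised
  # exactly 10% zeros is kept (removal requires exceeding the threshold)
  rna2 <- base; rna2[1:10, 2] <- 0
  out2 <- filter_segments(make_sc(rna2, "RNA"), max_zero_fraction = 0.10)
  expect_equal(length(attr(out2, "removed_segments")), 0)
  # vacuous threshold removes nothing
  out3 <- filter_segments(rna_sc, atac_sc, max_zero_fraction = 1)
  expect_equal(length(attr(out3, "removed_segments")), 0)
  # idempotence at a fixed threshold
  again <- filter_segments(out[[1]], out[[2]], max_zero_fraction = 0.10)
  expect_equal(again[[1]]$counts, out[[1]]$counts)
  # degenerate: everything removed
  sparse <- cbind(rep(c(0, 5), 5), rep(c(5, 0), 5))
  expect_error(filter_segments(make_sc(sparse, "RNA"),
                               max_zero_fraction = 0.01), "looser")
})

test_that("multiome pairing intersects and orders barcodes", {
  m <- matrix(rpois(12, 20) + 1, 4, 3)
  rna <- segmented_counts(m[1:3, ], c("A", "B", "C"), paste0("seg", 1:3), "RNA")
  atac <- segmented_counts(m[2:4, ], c("B", "C", "D"), paste0("seg", 1:3), "ATAC")
  paired <- pair_multiome(rna, atac)
  expect_equal(paired$rna$barcodes, c("B", "C"))
  expect_identical(paired$rna$barcodes, paired$atac$barcodes)
  expect_equal(attr(paired, "dropped"), c(rna = 1L, atac = 1L))
  expect_equal(paired$rna$counts["B", ], m[2, ], ignore_attr = TRUE)
  expect_equal(paired$atac$counts["B", ], m[2, ], ignore_attr = TRUE)
  atac2 <- segmented_counts(m[1:2, ], c("X", "Y"), paste0("seg", 1:3), "ATAC")
  expect_error(pair_multiome(rna, atac2), "flat model")
})

test_that("count tables round-trip through the delimited format", {
  sim <- strong_two_clone(seed = 9, n = 20, I = 4)
  dir <- tempfile()
  write_dataset(sim, dir)
  back <- read_segment_table(file.path(dir, "rna_counts.tsv"), "RNA")
  expect_equal(back$counts, sim$rna$counts)
  expect_equal(back$barcodes, sim$rna$barcodes)
  expect_equal(back$library_factors, sim$rna$library_factors)
})

test_that("MatrixMarket triplet reader matches the written sparse matrix", {
  dir <- tempfile(); dir.create(dir)
  m <- Matrix::Matrix(matrix(c(0, 3, 0, 1, 0, 0, 2, 5), 4, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  write.table(data.frame(id = paste0("g", 1:4), name = paste0("G", 1:4),
                         chrom = "chr1", start = c(0, 100, 200, 300),
                         end = c(50, 150, 250, 350)),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c("bcA", "bcB"), file.path(dir, "barcodes.tsv"))
  fm <- read_feature_matrix(dir)
  expect_equal(as.matrix(fm$counts), as.matrix(m), ignore_attr = TRUE)
  expect_equal(fm$barcodes, c("bcA", "bcB"))
  seg <- read_segments(write_bed("chr1\t0\t1000\tall"))
  sc <- aggregate_to_segments(fm, seg, "ATAC")
  expect_equal(unname(sc$counts[, 1]), unname(Matrix::colSums(m)))
})

test_that("segmented_counts validates counts and metadata", {
  expect_error(segmented_counts(matrix(-1, 2, 2), c("a", "b"), c("s1", "s2")),
               "non-negative")
  expect_error(segmented_counts(matrix(1.5, 2, 2), c("a", "b"), c("s1", "s2")),
               "integer")
  expect_error(segmented_counts(matrix(1, 2, 2), c("a", "a"), c("s1", "s2")),
               "unique")
  expect_error(segmented_counts(matrix(1, 2, 2), c("a", "b"), c("s1", "s2"),
                                library_factors = c(1, -1)), "positive")
})
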