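test_that("contact_matrix validates symmetry, sign and bins", {
  m <- matrix(c(0, 5, 5, 0), 2)
  bins <- data.frame(chrom = "chr1", start = c(0, 40000), end = c(40000, 80000))
  cm <- contact_matrix(m, bins)
  expect_identical(dim(cm), c(2L, 2L))
  expect_error(contact_matrix(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(contact_matrix(matrix(c(0, -1, -1, 0), 2)), "negative")
  expect_error(contact_matrix(m, bins[1, ]), "do not match")
  bad <- bins; bad$end[1] <- 0
  expect_error(contact_matrix(m, bad), "end > start")
})

test_that("triplet reader mirrors entries and rejects negative counts", {
  tdir <- withr::local_tempdir()
  trip <- file.path(tdir, "trip.tsv")
  writeLines("0\t1\t5", trip)
  cm <- read_contact_matrix(trip, "triplet", n_bins = 3)
  expect_equal(cm$counts[1, 2], 5)
  expect_equal(cm$counts[2, 1], 5)
  expect_equal(sum(cm$counts), 10)
  writeLines("2\t0\t-1", trip)
  expect_error(read_contact_matrix(trip, "triplet", n_bins = 3), "negative")
})

test_that("dense matrices with zero off-diagonals read back as zeros", {
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "dense.tsv")
  m <- diag(c(3, 4, 5))
  utils::write.table(m, p, sep = "\t", row.names = FALSE, col.names = FALSE)
  cm <- read_contact_matrix(p, "dense")
  expect_true(all(cm$counts[upper.tri(cm$counts)] == 0))
  expect_equal(diag(cm$counts), c(3, 4, 5))
})

test_that("read-write-read round trip preserves counts and bins", {
  d <- tiny_dataset(8, seed = 3)
  tdir <- withr::local_tempdir()
  for (fmt in c("dense", "triplet")) {
    mp <- file.path(tdir, paste0("m_", fmt, ".tsv"))
    bp <- file.path(tdir, paste0("b_", fmt, ".bed"))
    write_contact_matrix(d$cm, mp, fmt, bp)
    back <- read_contact_matrix(mp, fmt, bp)
    expect_equal(back$counts, d$cm$counts, info = fmt)
    expect_equal(back$bins, d$cm$bins, info = fmt)
  }
  fp <- file.path(tdir, "features.tsv")
  write_locus_features(d$lf, d$cm$bins, fp)
  back <- read_locus_features(fp)
  expect_equal(as.data.frame(back$features), as.data.frame(d$lf),
               tolerance = 1e-12)
})

test_that("filtering removes loci at or below the thresholds", {
  d <- tiny_dataset(8, seed = 4)
  lf <- as.data.frame(d$lf)
  # locus exactly at a threshold is removed; one clearing all is kept
  lf$frag_ends[2] <- 5                      # boundary: removed
  lf$gc[5] <- 0.30                          # boundary: removed
  lf$mappability[7] <- 0.80                 # boundary: removed
  lf$frag_ends[1] <- 6; lf$gc[1] <- 0.45; lf$mappability[1] <- 0.9  # kept
  res <- filter_loci(d$cm, locus_features(lf))
  expect_identical(res$kept, c(1L, 3L, 4L, 6L, 8L))
  expect_equal(nrow(res$cm$counts), 5)
  expect_equal(res$cm$counts, d$cm$counts[res$kept, res$kept])
})

test_that("filtering is idempotent and errors when too few loci remain", {
  d <- tiny_dataset(8, seed = 5)
  r1 <- filter_loci(d$cm, d$lf)
  r2 <- filter_loci(r1$cm, r1$lf)
  expect_equal(r1$cm$counts, r2$cm$counts)
  lf <- as.data.frame(d$lf)
  lf$gc[1:6] <- 0.3
  expect_error(filter_loci(d$cm, locus_features(lf)), "fewer than 3")
})

test_that("submatrix extraction respects interval and commutes with filtering", {
  d <- tiny_dataset(10, seed = 6)
  b <- d$cm$bins
  sub <- extract_submatrix(d$cm, d$lf, b$chrom[1], b$start[3], b$end[5])
  expect_identical(sub$kept, 3:5)
  expect_equal(sub$cm$counts, d$cm$counts[3:5, 3:5])
  all_ <- extract_submatrix(d$cm, d$lf, b$chrom[1], 0, max(b$end))
  expect_equal(all_$cm$counts, d$cm$counts)
  expect_error(extract_submatrix(d$cm, d$lf, "chrZ", 0, 1e6), "no bin")
  # commute: extract then filter == filter then extract (same interval)
  lf <- as.data.frame(d$lf); lf$gc[4] <- 0.1; lf <- locus_features(lf)
  a <- filter_loci(extract_submatrix(d$cm, lf, b$chrom[1], b$start[3],
                                     b$end[9])$cm,
                   locus_features(lf[3:9, ]))
  f <- filter_loci(d$cm, lf)
  bsub <- f$cm$bins
  keep2 <- which(bsub$start >= b$start[3] & bsub$end <= b$end[9])
  expect_equal(a$cm$counts, f$cm$counts[keep2, keep2])
})

test_that("domain reader enforces sorted non-overlapping intervals", {
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "dom.bed")
  writeLines(c("chr1\t0\t100\td1", "chr1\t100\t250\td2"), p)
  d <- read_domains(p)
  expect_equal(d$label, c("d1", "d2"))
  writeLines(c("chr1\t0\t150\td1", "chr1\t100\t250\td2"), p)
  expect_error(read_domains(p), "overlapping")
})
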