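make_layout <- function(sizes = c(chr1 = 100), res = 10, chunk = 5)
  genome_layout(sizes, resolution = res, chunk_size = chunk)

write_tmp <- function(lines) {
  p <- tempfile(fileext = ".bedGraph")
  writeLines(lines, p)
  p
}

test_that("bedGraph binning follows the coverage-mean contract", {
  lay <- make_layout()
  # empty file: every bin missing
  tr <- read_signal_track(write_tmp(character()), lay)
  expect_true(all(is.na(tr$chr1)))
  # constant coverage across two bins
  tr <- read_signal_track(write_tmp("chr1\t0\t20\t2.0"), lay)
  expect_identical(tr$chr1[1:2], c(2, 2))
  expect_true(all(is.na(tr$chr1[3:10])))
  # mean of two half-bin intervals: per-base expansion gives (5*1 + 5*3)/10
  tr <- read_signal_track(write_tmp(c("chr1\t0\t5\t1.0", "chr1\t5\t10\t3.0")),
                          lay)
  expect_equal(tr$chr1[1], 2.0)
})

test_that("binning matches a per-base expansion oracle and conserves mass", {
  lay <- genome_layout(c(chrZ = 200), resolution = 7, chunk_size = 5)
  for (seed in 1:10) {
    set.seed(seed)
    # random non-overlapping intervals tiling a prefix of the chromosome
    bounds <- sort(sample(0:200, sample(5:15, 1)))
    bounds <- unique(c(0, bounds, 200))
    v <- round(rnorm(length(bounds) - 1), 3)
    keep <- runif(length(v)) < 0.8
    iv <- data.frame(start = bounds[-length(bounds)][keep],
                     end = bounds[-1][keep], value = v[keep])
    if (!nrow(iv)) next
    p <- write_tmp(sprintf("chrZ\t%d\t%d\t%s", iv$start, iv$end, iv$value))
    tr <- read_signal_track(p, lay)
    # per-base expansion oracle
    base <- rep(NA_real_, 200)
    for (i in seq_len(nrow(iv)))
      base[(iv$start[i] + 1):iv$end[i]] <- iv$value[i]
    expected <- sapply(seq_len(lay$n_bins[["chrZ"]]), function(b) {
      xs <- base[((b - 1) * 7 + 1):min(b * 7, 200)]
      if (all(is.na(xs))) NA_real_ else mean(xs, na.rm = TRUE)
    })
    expect_equal(tr$chrZ, expected, tolerance = 1e-12)
    # conservation: sum(bin value * covered width) == sum of base values
    w <- sapply(seq_len(lay$n_bins[["chrZ"]]), function(b)
      sum(!is.na(base[((b - 1) * 7 + 1):min(b * 7, 200)])))
    expect_equal(sum(tr$chrZ * w, na.rm = TRUE), sum(base, na.rm = TRUE),
                 tolerance = 1e-9)
  }
})

test_that("malformed signal input is a hard, located error", {
  lay <- make_layout()
  expect_error(read_signal_track(write_tmp("chrX\t0\t10\t1.0"), lay),
               "unknown chromosome 'chrX'")
  expect_error(read_signal_track(write_tmp("chr1\t90\t110\t1.0"), lay),
               "invalid interval")
  expect_error(
    read_signal_track(write_tmp(c("chr1\t0\t20\t1.0", "chr1\t10\t30\t2.0")),
                      lay),
    "overlapping")
})

test_that("fixedStep wiggle input agrees with equivalent bedGraph", {
  lay <- make_layout(c(chr1 = 50), res = 5)
  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=5 span=5",
               "1.5", "2.5", "3.5"), wig)
  bg <- write_tmp(c("chr1\t0\t5\t1.5", "chr1\t5\t10\t2.5",
                    "chr1\t10\t15\t3.5"))
  expect_equal(read_signal_track(wig, lay)$chr1,
               read_signal_track(bg, lay)$chr1)
  # variableStep with span
  wig2 <- tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr1 span=5", "1\t1.5", "11\t3.5"), wig2)
  bg2 <- write_tmp(c("chr1\t0\t5\t1.5", "chr1\t10\t15\t3.5"))
  expect_equal(read_signal_track(wig2, lay)$chr1,
               read_signal_track(bg2, lay)$chr1)
})

test_that("chunking tiles chromosomes and concatenation is the identity", {
  lay <- genome_layout(c(a = 250, b = 70), resolution = 10, chunk_size = 10)
  set.seed(42)
  tr <- structure(list(a = rnorm(25), b = rnorm(7)), resolution = 10,
                  class = "binned_track")
  store <- build_obs_store(list(x = tr), lay)
  tab <- store$chunk_table
  expect_equal(tab$n_bins[tab$chrom == "a"], c(10L, 10L, 5L))
  expect_equal(tab$n_bins[tab$chrom == "b"], 7L)
  # no chunk spans a chromosome boundary
  expect_true(all(tab$end <= c(a = 250, b = 70)[tab$chrom]))
  # bit-identical round trip
  back <- unlist(lapply(which(tab$chrom == "a"),
                        function(i) store$chunks[[i]][, 1]))
  expect_identical(unname(back), tr$a)
})

test_that("validation split hits the requested fraction and is a partition", {
  lay <- genome_layout(c(g = 2000), resolution = 1, chunk_size = 2)
  tr <- structure(list(g = rep(0, 2000)), resolution = 1,
                  class = "binned_track")
  store <- build_obs_store(list(x = tr), lay)      # 1000 equal chunks
  sp <- split_validation(store, 0.015, seed = 11)
  expect_length(sp$validation, 15L)
  expect_identical(split_validation(store, 0.015, seed = 11)$validation,
                   sp$validation)
  for (seed in 1:100) {
    s <- split_validation(store, 0.13, seed = seed)
    expect_length(intersect(s$training, s$validation), 0L)
    expect_setequal(c(s$training, s$validation), store$chunk_table$id)
    # realized fraction within one chunk of the request
    expect_lt(abs(s$realized - 0.13), 2 / 1000 + 1e-12)
  }
  expect_error(split_validation(store, 0.9999, seed = 1), "no training")
})

test_that("BED round trips are lossless and byte-stable", {
  empty <- read_bed(write_bed(rand_annotation(1)[0, ], tempfile()))
  expect_equal(nrow(empty), 0L)
  p <- tempfile()
  write_bed(data.frame(chrom = "chr1", start = 0, end = 100, label = "3"),
            p)
  expect_identical(readLines(p), "chr1\t0\t100\t3")
  for (seed in 1:50) {
    a <- rand_annotation(seed)
    p1 <- tempfile(); p2 <- tempfile()
    write_bed(a, p1)
    b <- read_bed(p1)
    expect_equal(as.data.frame(b), as.data.frame(a))
    write_bed(b, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
  bad <- tempfile()
  writeLines("chr1\t50\t40\tx", bad)
  expect_error(read_bed(bad), "line 1")
  writeLines("chr1\t10", bad)
  expect_error(read_bed(bad), "line 1")
  overlapping <- data.frame(chrom = "chr1", start = c(0, 50),
                            end = c(60, 100), label = c("a", "b"))
  expect_error(write_bed(overlapping, tempfile()), "overlap")
})

test_that("observation store persists through its versioned container", {
  lay <- genome_layout(c(c1 = 40), resolution = 2, chunk_size = 8)
  set.seed(3)
  tr <- structure(list(c1 = rnorm(20)), resolution = 2,
                  class = "binned_track")
  store <- build_obs_store(list(sig = tr), lay)
  p <- tempfile()
  write_obs_store(store, p)
  back <- read_obs_store(p)
  expect_identical(back$chunks, store$chunks)
  expect_identical(back$chunk_table, store$chunk_table)
})
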