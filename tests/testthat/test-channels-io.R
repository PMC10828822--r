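test_that("channel layout enforces its structural invariants", {
  mz <- c(a = 126, b = 127, c = 128)
  expect_s3_class(channel_layout(names(mz), mz), "channel_layout")
  expect_error(channel_layout(c("a", "a"), mz), "duplicated")
  expect_error(channel_layout(names(mz), mz[1:2]), "every channel")
  expect_error(channel_layout(names(mz), mz,
                              impurity_matrix = matrix(0.6, 3, 3)),
               "sum to <= 1")
  expect_error(channel_layout(names(mz), mz, empty_channels = "a",
                              interference_only_channels = "a"),
               "cannot also be empty")
  expect_error(channel_layout(names(mz), mz, groups = list(
    g1 = list(channels = c("a", "b"), amount = 1),
    g2 = list(channels = c("b", "c"), amount = 2))),
    "at most one group")
})

test_that("the built-in two-proteome design reproduces its fold changes", {
  layout <- tmtpro16_twoproteome_layout()
  fc <- design_fold_changes(layout)
  expect_equal(sort(fc$fold_change), sort(c(1.5, 4 / 3, 2)))
  amounts <- vapply(layout$groups, `[[`, numeric(1), "amount")
  expect_identical(unname(sort(amounts)), c(0, 18, 27, 36))
  expect_equal(amounts[["100:9"]] / amounts[["100:6"]], 9 / 6)
  expect_setequal(layout$interference_only_channels,
                  c("128N", "129N", "130N"))
  expect_length(oil_denominator_channels(layout), 9)
})

test_that("PSM tables round-trip bit-identically and tolerate column order", {
  layout <- tiny_layout()
  set.seed(11)
  d <- make_psm_table(3, layout)
  d$reporter_ch1[2] <- NA  # empty reporter cell stays missing
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(d, path)
  r <- read_psm_table(path, layout)
  for (cc in names(d))
    expect_identical(r[[cc]], d[[cc]], label = paste("column", cc))
  expect_true(is.na(r$reporter_ch1[2]))

  # permuted column order yields identical records
  perm <- d[, sample(names(d))]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(perm, path2)
  r2 <- read_psm_table(path2, layout)
  for (cc in names(d))
    expect_identical(r2[[cc]], d[[cc]])
})

test_that("PSM reader reports missing columns and garbled cells", {
  layout <- tiny_layout()
  d <- make_psm_table(2, layout)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(d[, setdiff(names(d), "charge")], path)
  expect_error(read_psm_table(path, layout), "charge")

  d2 <- make_psm_table(2, layout)
  d2$reporter_ch2 <- c("12.5", "not-a-number")
  utils::write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- read_psm_table(path, layout)
  expect_equal(r$reporter_ch2, c(12.5, NA))
})

test_that("MS1 snapshot ingestion sorts, rejects bad noise, keeps empty scans", {
  df <- data.frame(
    raw_file = "r1",
    scan_number = c(2L, 2L, 2L, 1L, 1L, 3L),
    retention_time_min = c(5.5, 5.5, 5.5, 5.0, 5.0, 6.0),
    mz = c(503, 501, 502, 400, 401, NA),
    intensity = c(30, 10, 20, 5, 6, NA),
    noise = c(50, 50, -1, 40, 40, NA))
  expect_warning(runs <- as_ms1_runs(df), "non-positive noise")
  run <- runs$r1
  expect_identical(run$scan_numbers, c(1L, 2L, 3L))
  expect_equal(run$peaks[[2]]$mz, c(501, 503))  # bad-noise row dropped, sorted
  expect_identical(nrow(run$peaks[[3]]), 0L)    # empty scan retained

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ms1_snapshots(runs, path)
  back <- read_ms1_snapshots(path)$r1
  expect_equal(back$scan_numbers, run$scan_numbers)
  expect_equal(back$peaks[[2]], run$peaks[[2]])
  expect_identical(nrow(back$peaks[[3]]), 0L)
})

test_that("reporter inference takes the in-window maximum, boundaries closed", {
  layout <- tiny_layout(2)
  peaks <- data.frame(mz = c(126.0005, 126.0015, 127.1), intensity = c(5, 9, 3))
  got <- infer_reporter_intensities(peaks, layout)
  expect_equal(unname(got["ch1"]), 9)   # max of the two in-window peaks
  expect_true(is.na(got["ch2"]))        # nothing within 0.002 Th

  # exactly-representable boundary: |mz - reporter| == tol is included
  one <- channel_layout("x", c(x = 126))
  got2 <- infer_reporter_intensities(
    data.frame(mz = 126.25, intensity = 7), one, tol = 0.25)
  expect_equal(unname(got2["x"]), 7)

  expect_error(infer_reporter_intensities(peaks, tiny_layout(3), tol = 0.6),
               "overlap")
})

test_that("reporter inference equals the brute-force oracle on random spectra", {
  layout <- tiny_layout(6, tol_spacing = 0.5)
  set.seed(42)
  for (i in 1:300) {
    n <- sample(1:25, 1)
    peaks <- data.frame(mz = stats::runif(n, 125.8, 129.3),
                        intensity = stats::runif(n, 1, 1e4))
    expect_identical(infer_reporter_intensities(peaks, layout),
                     oracle_reporter_max(peaks, layout))
  }
})

test_that("impurity correction solves the leakage system", {
  expect_equal(correct_isotopic_impurities(c(3, 7), diag(2)), c(3, 7))
  M <- matrix(c(0.9, 0.1, 0, 1), 2, 2)  # 10% of channel 1 leaks into 2
  expect_equal(correct_isotopic_impurities(c(9, 1), M), c(10, 0))
  expect_equal(correct_isotopic_impurities(c(0, 0), M), c(0, 0))
  got <- correct_isotopic_impurities(c(9, NA), M)
  expect_equal(got[1], 10)
  expect_true(is.na(got[2]))
  expect_error(correct_isotopic_impurities(c(1, 1), matrix(1, 2, 2)),
               "singular")
})

test_that("impurity correction is a left inverse of applying the matrix", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(3:8, 1)
    M <- diag(k) * stats::runif(1, 0.8, 0.95)
    off <- matrix(stats::runif(k * k, 0, 0.05 / k), k, k)
    diag(off) <- 0
    M <- M + off
    x <- stats::runif(k, 0, 100)
    expect_equal(correct_isotopic_impurities(as.numeric(M %*% x), M), x,
                 tolerance = 1e-9)
  }
})
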