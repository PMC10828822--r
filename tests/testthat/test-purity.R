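# retention times in minutes; 2 s = 1/30 min
sec <- 1 / 60

test_that("retention-time weights are inverse to the scan distances", {
  psm <- make_psm(ms2_scan = 2, precursor_mz = 500, rt = 10)
  run <- make_run(list(scan = 1, rt = 10 - 2 * sec, mz = 500, int = 10),
                  list(scan = 3, rt = 10 + 3 * sec, mz = 500, int = 10))
  ex <- extract_isolation_window(psm, run)
  w <- vapply(ex$scans, `[[`, numeric(1), "w")
  expect_equal(w, c(0.6, 0.4))  # d = 2 s and 3 s
  expect_equal(sum(w), 1)
})

test_that("PPF and TIW follow the weighted precursor-share definition", {
  psm <- make_psm(ms2_scan = 2, precursor_mz = 500, rt = 10)
  run <- make_run(
    list(scan = 1, rt = 10 - 2 * sec, mz = c(500, 500.4), int = c(60, 40)),
    list(scan = 3, rt = 10 + 2 * sec, mz = c(500, 500.4), int = c(80, 20)))
  ex <- extract_isolation_window(psm, run)
  expect_equal(compute_ppf(ex), 0.7)   # equidistant scans, w = 0.5 each
  expect_equal(compute_tiw(ex), 100)

  # precursor-only window
  run2 <- make_run(list(scan = 1, rt = 9.9, mz = 500, int = 33),
                   list(scan = 3, rt = 10.1, mz = 500, int = 44))
  expect_equal(compute_ppf(extract_isolation_window(psm, run2)), 1)

  # single scan (no following), peaks 10 + 30
  run3 <- make_run(list(scan = 1, rt = 9.9, mz = c(500, 500.3), int = c(10, 30)))
  ex3 <- extract_isolation_window(psm, run3)
  expect_equal(ex3$scans[[1]]$w, 1)
  expect_equal(compute_tiw(ex3), 40)
})

test_that("an empty following window is skipped and the preceding scan carries weight 1", {
  psm <- make_psm(ms2_scan = 2, precursor_mz = 500, rt = 10)
  run <- make_run(
    list(scan = 1, rt = 9.95, mz = c(500, 500.2), int = c(70, 30)),
    list(scan = 3, rt = 10.05, mz = 600, int = 99))  # outside the window
  ex <- extract_isolation_window(psm, run)
  expect_length(ex$scans, 1)
  expect_equal(ex$scans[[1]]$w, 1)
  expect_equal(compute_ppf(ex), 0.7)
})

test_that("a missing precursor triggers second-last substitution, then imputation", {
  psm <- make_psm(ms2_scan = 6, precursor_mz = 500, rt = 10)
  # precursor absent from the preceding scan (5) but present in the
  # second-last (3): that scan substitutes, with its own retention time
  run <- make_run(
    list(scan = 3, rt = 9.90, mz = 500, int = 50),
    list(scan = 5, rt = 9.97, mz = 500.3, int = 10),
    list(scan = 7, rt = 10.03, mz = 500, int = 50))
  ex <- extract_isolation_window(psm, run)
  expect_identical(ex$flag, "second_last_substituted")
  expect_equal(ex$scans[[1]]$scan_number, 3)
  expect_equal(ex$scans[[1]]$d, 0.10, tolerance = 1e-9)

  # precursor absent everywhere: following scan skipped, precursor imputed
  # at the preceding-scan minimum intensity
  run2 <- make_run(
    list(scan = 5, rt = 9.97, mz = c(500.3, 499.8), int = c(1000, 4)),
    list(scan = 7, rt = 10.03, mz = 500.3, int = 900))
  ex2 <- extract_isolation_window(psm, run2)
  expect_length(ex2$scans, 1)
  expect_true(ex2$imputed)
  expect_equal(compute_ppf(ex2), 4 / (1000 + 4 + 4))  # imputed precursor near 0
  expect_lt(compute_ppf(ex2), 0.01)
})

test_that("a PSM without any preceding MS1 scan is flagged unquantifiable", {
  psm <- make_psm(ms2_scan = 2, precursor_mz = 500, rt = 10)
  run <- make_run(list(scan = 5, rt = 10.1, mz = 500, int = 10))
  ex <- extract_isolation_window(psm, run)
  expect_false(ex$ok)
  expect_identical(ex$flag, "no_preceding_ms1_scan")
  expect_true(is.na(compute_ppf(ex)))
  expect_true(is.na(compute_tiw(ex)))
})

test_that("isotope peaks are flagged at the charge-scaled spacing", {
  iso <- 1.00335484 / 2
  psm <- make_psm(ms2_scan = 2, precursor_mz = 500, rt = 10, charge = 2,
                  width = 2)
  run <- make_run(
    list(scan = 1, rt = 9.95, mz = c(500, 500 + iso, 500.3),
         int = c(60, 20, 20)),
    list(scan = 3, rt = 10.05, mz = c(500, 500 + iso, 500.3),
         int = c(60, 20, 20)))
  ex <- extract_isolation_window(psm, run)
  expect_equal(compute_ppf(ex), 0.8)  # isotope counts as precursor

  # a peak 1 full Th away is NOT an isotope of a 2+ precursor
  run2 <- make_run(
    list(scan = 1, rt = 9.95, mz = c(500, 501), int = c(60, 40)),
    list(scan = 3, rt = 10.05, mz = c(500, 501), int = c(60, 40)))
  expect_equal(compute_ppf(extract_isolation_window(psm, run2)), 0.6)
})

test_that("PPF matches an independent brute-force oracle on random windows", {
  set.seed(99)
  for (i in 1:500) {
    case <- random_window_case()
    run <- make_run(
      list(scan = 1, rt = case$prev$rt, mz = case$prev$mz, int = case$prev$int),
      list(scan = 10, rt = case$fol$rt, mz = case$fol$mz, int = case$fol$int))
    ex <- extract_isolation_window(case$psm, run)
    orc <- oracle_ppf(case$psm, case$prev, case$fol)
    expect_equal(compute_ppf(ex), orc$ppf, tolerance = 1e-12)
    expect_equal(compute_tiw(ex), orc$tiw, tolerance = 1e-12)
    expect_gte(compute_ppf(ex), 0)
    expect_lte(compute_ppf(ex), 1)
  }
})

test_that("PIC is TIC minus reporters, clamped at zero", {
  expect_equal(compute_pic(1000, c(50, 100, NA)), 850)
  expect_equal(compute_pic(1000, c(NA, NA)), 1000)
  expect_warning(p <- compute_pic(100, c(80, 80)), "clamped")
  expect_equal(p, 0)
})

test_that("OIL is the capped interference-to-signal average ratio", {
  mz <- seq(126, length.out = 6)
  names(mz) <- paste0("c", 1:6)
  layout <- channel_layout(names(mz), mz,
                           interference_only_channels = c("c1", "c2"))
  x <- c(c1 = 2, c2 = 2, c3 = 8, c4 = 8, c5 = 8, c6 = 8)
  expect_equal(as.numeric(compute_oil(x, layout)), 0.25)
  # interference exceeding the denominator average is capped at 1
  expect_equal(as.numeric(compute_oil(c(c1 = 20, c2 = 20, c3 = 8, c4 = 8,
                                        c5 = 8, c6 = 8), layout)), 1)
  expect_equal(as.numeric(compute_oil(c(c1 = 0, c2 = 0, c3 = 8, c4 = 8,
                                        c5 = 8, c6 = 8), layout)), 0)
  # missing values drop out of the averages
  expect_equal(as.numeric(compute_oil(c(c1 = 2, c2 = NA, c3 = 8, c4 = NA,
                                        c5 = 8, c6 = 8), layout)), 0.25)
  # zero denominator is undefined
  expect_true(is.na(compute_oil(c(c1 = 2, c2 = 2, c3 = 0, c4 = 0,
                                  c5 = 0, c6 = 0), layout)))
  # invariance to a common positive rescaling
  set.seed(3)
  for (i in 1:50) {
    v <- stats::runif(6, 0, 50)
    names(v) <- names(mz)
    expect_equal(compute_oil(v * stats::runif(1, 0.01, 100), layout),
                 compute_oil(v, layout))
  }
})
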