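# small synthetic metrics tables exercising the design assembly
make_metrics <- function(n = 200, classes = c("a", "b"), seed = 1) {
  set.seed(seed)
  layout <- tiny_layout(3)
  d <- data.frame(
    raw_file = "r1", psm_id = paste0("p", seq_len(n)),
    charge = sample(2:3, n, TRUE),
    ppf = stats::runif(n, 0.5, 1),
    tiw = stats::rlnorm(n, 10, 0.5),
    pic = stats::rlnorm(n, 10, 0.5),
    noise_estimate = stats::rlnorm(n, 2, 0.5),
    pep_class = sample(classes, n, TRUE))
  for (ch in layout$channel_names)
    d[[paste0("reporter_", ch)]] <- stats::rlnorm(n, 6, 0.3)
  list(metrics = d, layout = layout)
}

test_that("design assembly counts interaction columns and zeroes pure terms", {
  mm <- make_metrics(300)
  des <- build_design(mm$metrics, "general")
  # 2 classes + 2 charge categories + 1 noise column
  expect_identical(ncol(des$X), 5L)
  expect_setequal(unname(des$families),
                  c("precursor", "nonprecursor", "noise"))
  expect_identical(sum(des$families == "precursor"), 2L)

  mm$metrics$ppf <- 1
  des2 <- build_design(mm$metrics, "general")
  np <- des2$X[, des2$families == "nonprecursor", drop = FALSE]
  expect_true(all(np == 0))
})

test_that("the ground-truth design sums the interference-only channels", {
  mz <- c(a = 126, b = 127, c = 128, d = 129)
  layout <- channel_layout(names(mz), mz,
                           interference_only_channels = c("a", "b"))
  d <- data.frame(raw_file = "r1", charge = 2, ppf = 0.8, tiw = 100,
                  pic = 90, noise_estimate = 1,
                  reporter_a = 1, reporter_b = 2, reporter_c = 3,
                  reporter_d = 40, psm_id = "p1")
  d <- rbind(d, d)
  des <- build_design(d, "ground_truth", layout, min_charge_obs = 1)
  expect_equal(des$y, c(3, 3))  # 1 + 2
  expect_false(any(des$families == "precursor"))
  expect_error(build_design(d, "ground_truth", tiny_layout()),
               "interference-only")
})

test_that("noiseless generative data is recovered exactly", {
  mm <- make_metrics(400)
  des <- build_design(mm$metrics, "general")
  beta <- c(0.6, 1.2, 0.9, 0.7, 500)
  des$y <- as.numeric(des$X %*% beta)
  fit <- fit_robust(des)
  expect_equal(unname(fit$coef), beta, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$n_obs, 400L)
})

test_that("bisquare fitting shrugs off gross outliers where least squares fails", {
  set.seed(42)
  mm <- make_metrics(5000)
  des <- build_design(mm$metrics, "general")
  beta <- c(0.6, 1.2, 0.9, 0.7, 500)
  y <- as.numeric(des$X %*% beta)
  out <- sample(5000, 250)  # 5% gross outliers
  y[out] <- y[out] * 100
  des$y <- y
  fit <- fit_robust(des)
  expect_lt(max(abs(fit$coef / beta - 1)), 0.05)
  ls <- stats::lm.fit(des$X, y)$coefficients
  expect_gt(max(abs(ls / beta - 1)), 0.2)
  # outliers end with (near-)zero robust weight
  expect_lt(max(fit$robust_weights[out]), 0.01)
})

test_that("the plain robust fit matches a textbook bisquare oracle", {
  set.seed(7)
  X <- cbind(a = stats::rlnorm(50, 2, 0.5), b = stats::rlnorm(50, 1, 0.5))
  y <- as.numeric(X %*% c(2, 5)) * stats::rlnorm(50, 0, 0.2)
  des <- list(y = y, X = X, families = c(a = "precursor", b = "noise"),
              model = "general")
  fit <- fit_robust(des, variance_weight_rounds = 0)
  expect_equal(unname(fit$coef), oracle_irls(X, y), tolerance = 1e-6)
})

test_that("rank-deficient designs drop aliased columns with a warning", {
  set.seed(9)
  X <- cbind(a = stats::runif(100), b = stats::runif(100))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  des <- list(y = as.numeric(X[, 1:2] %*% c(1, 2)), X = X,
              families = c(a = "precursor", b = "nonprecursor", c = "noise"),
              model = "general")
  expect_warning(fit <- fit_robust(des), "aliased")
  expect_identical(fit$dropped, "c")
  expect_length(fit$coef, 2)
})

test_that("EIL is one minus the fitted precursor share, clamped", {
  X <- rbind(c(80, 15, 5), c(100, 0, 0), c(0, 50, 50), c(10, -20, 0))
  colnames(X) <- c("p", "np", "noise")
  fit <- structure(list(coef = c(p = 1, np = 1, noise = 1),
                        families = c(p = "precursor", np = "nonprecursor",
                                     noise = "noise"),
                        precursor_coef_names = "p"),
                   class = "interference_fit")
  des <- list(X = X)
  eil <- compute_eil(fit, des)
  expect_equal(eil[1], 0.2)          # precursor 80 of fitted 100
  expect_equal(eil[2], 0)            # no nonprecursor, no noise
  expect_equal(eil[3], 1)            # zero precursor term
  expect_true(is.na(eil[4]))         # non-positive fitted total
})

test_that("signal decomposition returns shares that sum to one", {
  mm <- make_metrics(400, seed = 3)
  des <- build_design(mm$metrics, "general")
  des$y <- as.numeric(des$X %*% c(0.6, 1.2, 0.9, 0.7, 500))
  fit <- fit_robust(des)
  dec <- decompose_signal(fit, des)
  expect_equal(sum(dec), 1, tolerance = 1e-9)
  expect_true(all(dec >= 0))

  # all-precursor data: zero the other columns
  des2 <- des
  des2$X[, des2$families != "precursor"] <- 0
  des2$y <- as.numeric(des2$X %*% c(0.6, 1.2, 0, 0, 0))
  fit2 <- suppressWarnings(fit_robust(des2))
  dec2 <- decompose_signal(fit2, des2)
  expect_equal(unname(dec2["precursor"]), 1, tolerance = 1e-9)
})

test_that("rescaling the response rescales coefficients and leaves EIL fixed", {
  mm <- make_metrics(500, seed = 11)
  des <- build_design(mm$metrics, "general")
  set.seed(2)
  des$y <- as.numeric(des$X %*% c(0.6, 1.2, 0.9, 0.7, 500)) *
    stats::rlnorm(500, 0, 0.1)
  f1 <- fit_robust(des)
  des_scaled <- des
  des_scaled$y <- des$y * 37
  f2 <- fit_robust(des_scaled)
  expect_equal(f2$coef, f1$coef * 37, tolerance = 1e-6)
  expect_equal(compute_eil(f2, des_scaled), compute_eil(f1, des),
               tolerance = 1e-8)
  # EIL stays inside the unit interval
  expect_true(all(compute_eil(f1, des) >= 0 & compute_eil(f1, des) <= 1,
                  na.rm = TRUE))
})

test_that("per-raw-file stratification fits each file separately", {
  mm1 <- make_metrics(300, seed = 21)
  mm2 <- make_metrics(300, seed = 22)
  m <- rbind(mm1$metrics, mm2$metrics)
  m$raw_file <- rep(c("f1", "f2"), each = 300)
  m$compensation_voltage <- NA_real_
  res <- fit_interference_model(m, "general")
  expect_setequal(names(res$fits), c("f1", "f2"))
  expect_length(res$eil, 600)

  # a compensation-voltage column splits fits further
  m$compensation_voltage <- rep(c(-50, -70), 300)
  res2 <- fit_interference_model(m, "general")
  expect_identical(length(res2$fits), 4L)
})
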