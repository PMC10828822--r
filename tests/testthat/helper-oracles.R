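# Independent brute-force oracles. These share no code with the package
# implementations: explicit loops, separate windowing, flagging and
# weighting logic.

# PPF / TIW from raw bordering-scan data; assumes the precursor peak is
# present in both scans (the random-window generators guarantee it)
oracle_ppf <- function(psm, prev, fol, precursor_tol = 0.0025,
                       isotope_tol = 0.00125) {
  pm <- psm$precursor_mz
  half <- psm$isolation_width / 2
  iso <- 1.00335484 / psm$charge
  d <- c(abs(prev$rt - psm$retention_time_min),
         abs(fol$rt - psm$retention_time_min))
  w <- c(1 - d[1] / (d[1] + d[2]), 1 - d[2] / (d[1] + d[2]))
  num <- 0; den <- 0
  scans <- list(prev, fol)
  for (i in 1:2) {
    s <- scans[[i]]
    for (p in seq_along(s$mz)) {
      if (s$mz[p] < pm - half) next
      if (s$mz[p] > pm + half) next
      wi <- w[i] * s$int[p]
      den <- den + wi
      flagged <- FALSE
      if (abs(s$mz[p] - pm) <= precursor_tol) flagged <- TRUE
      if (abs(s$mz[p] - (pm + iso)) <= isotope_tol) flagged <- TRUE
      if (abs(s$mz[p] - (pm - iso)) <= isotope_tol) flagged <- TRUE
      if (flagged) num <- num + wi
    }
  }
  list(ppf = num / den, tiw = den)
}

# bilinear interpolation with explicit cell search and corner arithmetic
oracle_bilinear <- function(grid, x, y) {
  xa <- grid$mz_axis; ya <- grid$rt_axis; v <- grid$values
  out <- numeric(length(x))
  for (q in seq_along(x)) {
    xi <- x[q]; yi <- y[q]
    if (xi < xa[1]) xi <- xa[1]
    if (xi > xa[length(xa)]) xi <- xa[length(xa)]
    if (yi < ya[1]) yi <- ya[1]
    if (yi > ya[length(ya)]) yi <- ya[length(ya)]
    i <- 1L
    while (i < length(xa) - 1L && xa[i + 1L] < xi) i <- i + 1L
    j <- 1L
    while (j < length(ya) - 1L && ya[j + 1L] < yi) j <- j + 1L
    tx <- (xi - xa[i]) / (xa[i + 1L] - xa[i])
    ty <- (yi - ya[j]) / (ya[j + 1L] - ya[j])
    top <- v[i, j] * (1 - tx) + v[i + 1L, j] * tx
    bot <- v[i, j + 1L] * (1 - tx) + v[i + 1L, j + 1L] * tx
    out[q] <- top * (1 - ty) + bot * ty
  }
  out
}

# maximum-in-window reporter inference by scanning every peak per channel
oracle_reporter_max <- function(peaks, layout, tol = 0.002) {
  out <- rep(NA_real_, length(layout$channel_names))
  names(out) <- layout$channel_names
  for (ch in layout$channel_names) {
    r <- layout$reporter_mz[[ch]]
    best <- NA_real_
    for (p in seq_along(peaks$mz)) {
      if (abs(peaks$mz[p] - r) <= tol) {
        if (is.na(best) || peaks$intensity[p] > best)
          best <- peaks$intensity[p]
      }
    }
    out[[ch]] <- best
  }
  out
}

# textbook bisquare IRLS: OLS start, MAD-about-zero scale, weighted LS
oracle_irls <- function(X, y, k = 4.685, maxit = 200, tol = 1e-12) {
  b <- solve(crossprod(X), crossprod(X, y))
  for (it in seq_len(maxit)) {
    r <- as.numeric(y - X %*% b)
    s <- stats::median(abs(r)) / 0.6745
    u <- r / s
    w <- ifelse(abs(u) < k, (1 - (u / k)^2)^2, 0)
    b_new <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    if (max(abs(b_new - b)) < tol * s) { b <- b_new; break }
    b <- b_new
  }
  as.numeric(b)
}

# random two-scan isolation windows with the precursor always present
random_window_case <- function() {
  pm <- stats::runif(1, 400, 1200)
  width <- sample(c(0.7, 1.4, 2), 1)
  charge <- sample(2:4, 1)
  rt <- stats::runif(1, 10, 100)
  mk_scan <- function(drt) {
    n_extra <- sample(0:6, 1)
    mz <- c(pm, stats::runif(n_extra, pm - width, pm + width))
    list(rt = rt + drt, mz = mz,
         int = stats::runif(length(mz), 1, 1000))
  }
  list(psm = data.frame(ms2_scan = 5L, precursor_mz = pm,
                        retention_time_min = rt, charge = charge,
                        isolation_width = width),
       prev = mk_scan(-stats::runif(1, 0.01, 0.08)),
       fol = mk_scan(stats::runif(1, 0.01, 0.08)))
}
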