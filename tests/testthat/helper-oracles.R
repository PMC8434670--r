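# Independent oracles, deliberately coded from first principles (loops, no
# shared helpers with the package) so they can cross-check the pipeline.

# brute-force centered moving average with symmetric edge truncation
oracle_ma <- function(y, window) {
  n <- length(y)
  hw <- (window - 1) / 2
  out <- numeric(n)
  for (i in 1:n) {
    h <- min(hw, i - 1, n - i)
    acc <- 0
    for (k in (i - h):(i + h)) acc <- acc + y[k]
    out[i] <- acc / (2 * h + 1)
  }
  out
}

# textbook pool-adjacent-violators for a non-increasing fit
oracle_pav_antitonic <- function(y) {
  n <- length(y)
  vals <- y
  wts <- rep(1, n)
  m <- 0
  for (i in 1:n) {
    m <- m + 1
    vals[m] <- y[i]
    wts[m] <- 1
    while (m > 1 && vals[m - 1] < vals[m]) {
      v <- (vals[m - 1] * wts[m - 1] + vals[m] * wts[m]) /
        (wts[m - 1] + wts[m])
      wts[m - 1] <- wts[m - 1] + wts[m]
      vals[m - 1] <- v
      m <- m - 1
    }
  }
  out <- numeric(0)
  for (k in 1:m) out <- c(out, rep(vals[k], wts[k]))
  out
}

# exhaustive enumeration of maximal increase runs and their cumulative gains
oracle_increase_runs <- function(v, threshold) {
  out <- NULL
  i <- 1
  n <- length(v)
  while (i < n) {
    if (v[i + 1] > v[i]) {
      j <- i
      while (j < n && v[j + 1] > v[j]) j <- j + 1
      if (v[j] - v[i] >= threshold) {
        out <- rbind(out, data.frame(start = i, end = j, gain = v[j] - v[i]))
      }
      i <- j
    } else {
      i <- i + 1
    }
  }
  out
}

# brute-force alert rule evaluation: scan every week, track runs explicitly
oracle_alerts <- function(dev, refill_week, refill_declared, tau, k) {
  n <- length(dev)
  hits <- abs(dev) > tau
  out <- NULL
  i <- 1
  while (i <= n) {
    if (hits[i]) {
      j <- i
      while (j < n && hits[j + 1]) j <- j + 1
      if (j - i + 1 >= k) {
        span <- (i:j) - 1          # weeks are 0-based
        undecl <- refill_week[is.na(refill_declared) &
                                refill_week %in% span]
        kind <- if (length(undecl)) "verify_refill_data" else
          "growth_deviation"
        wk <- if (length(undecl)) min(undecl) else min(span)
        out <- rbind(out, data.frame(kind = kind, week = wk))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

tmp_path <- function(...) file.path(withr::local_tempdir(.local_envir =
                                                           parent.frame()),
                                    ...)
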