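# Independent brute-force implementations of every GV metric, written as
# naive loops with no code shared with the package. Used as the oracle in
# equivalence tests on small series.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

# type-7 quantile: h = (n-1)p + 1, linear interpolation of sorted values
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_ranges <- function(x) {
  n_in <- n_lo <- n_hi <- 0
  for (v in x) {
    if (v < 70) n_lo <- n_lo + 1
    else if (v > 180) n_hi <- n_hi + 1
    else n_in <- n_in + 1
  }
  c(tir = 100 * n_in / length(x),
    tor_below_70 = 100 * n_lo / length(x),
    tor_above_180 = 100 * n_hi / length(x))
}

oracle_por <- function(x, k = 1) {
  m <- oracle_mean(x)
  s <- oracle_sd(x)
  if (s == 0) return(0)
  out <- 0
  for (v in x) if (v < m - k * s || v > m + k * s) out <- out + 1
  100 * out / length(x)
}

oracle_risk <- function(x) {
  lb <- hb <- 0
  for (v in x) {
    f <- 1.509 * (log(v)^1.084 - 5.381)
    r <- 10 * f^2
    if (f < 0) lb <- lb + r
    if (f > 0) hb <- hb + r
  }
  c(lbgi = lb / length(x), hbgi = hb / length(x))
}

oracle_j_index <- function(x) 0.001 * (oracle_mean(x) + oracle_sd(x))^2

oracle_gmi <- function(x) 3.31 + 0.02392 * oracle_mean(x)

oracle_roc_sd <- function(times_min, x, max_gap = 30) {
  rocs <- c()
  for (i in 2:length(x)) {
    dt <- times_min[i] - times_min[i - 1]
    if (dt > 0 && dt <= max_gap) rocs <- c(rocs, (x[i] - x[i - 1]) / dt)
  }
  if (length(rocs) < 2) return(NA_real_)
  oracle_sd(rocs)
}
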