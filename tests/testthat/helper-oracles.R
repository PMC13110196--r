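# Independent, deliberately naive oracle implementations used to verify
# the package's computations. These are written from the definitions and
# share no code with the implementation.

oracle_mean <- function(x) {
  x <- x[!is.na(x)]
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  x <- x[!is.na(x)]
  m <- oracle_mean(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (length(x) - 1))
}

oracle_range <- function(x) {
  x <- x[!is.na(x)]
  lo <- hi <- x[1]
  for (v in x) {
    if (v < lo) lo <- v
    if (v > hi) hi <- v
  }
  hi - lo
}

oracle_uvr <- function(x) {
  x <- x[!is.na(x)]
  distinct <- c()
  for (v in x) if (!any(distinct == v)) distinct <- c(distinct, v)
  length(distinct) / length(x)
}

# lag-1 Pearson autocorrelation over explicitly enumerated valid pairs
oracle_autocorr <- function(x) {
  a <- c()
  b <- c()
  for (t in seq_len(length(x) - 1)) {
    if (!is.na(x[t]) && !is.na(x[t + 1])) {
      a <- c(a, x[t])
      b <- c(b, x[t + 1])
    }
  }
  if (length(a) < 2) return(NA_real_)
  ma <- oracle_mean(a); mb <- oracle_mean(b)
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force LOF from the reachability-distance definition; complete
# matrices only, O(n^3)-ish loops on purpose
oracle_lof <- function(m, k) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  kdist <- numeric(n)
  nb <- vector("list", n)
  for (i in 1:n) {
    others <- sort(d[i, -i])
    kdist[i] <- others[k]
    nb[[i]] <- setdiff(which(d[i, ] <= kdist[i]), i)
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    tot <- 0
    for (o in nb[[i]]) tot <- tot + max(kdist[o], d[i, o], 1e-12)
    lrd[i] <- length(nb[[i]]) / tot
  }
  lof <- numeric(n)
  for (i in 1:n) {
    tot <- 0
    for (o in nb[[i]]) tot <- tot + lrd[o]
    lof[i] <- tot / length(nb[[i]]) / lrd[i]
  }
  lof
}

# direct Benjamini-Yekutieli step-up from the formula (no cummin tricks)
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    i <- ord[pos]
    best <- Inf
    for (pos2 in pos:m) {
      j <- ord[pos2]
      best <- min(best, p[j] * m * cm / pos2)
    }
    adj[i] <- min(1, best)
  }
  adj
}

# exact two-sample K-S p-value for observed statistic via enumeration of
# all assignments of the pooled sample (tiny n only, no ties)
oracle_ks_exact_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  d_stat <- function(xs, ys) {
    grid <- sort(unique(c(xs, ys)))
    max(abs(vapply(grid, function(g) mean(xs <= g) - mean(ys <= g),
                   numeric(1))))
  }
  d_obs <- d_stat(x, y)
  combos <- utils::combn(n + m, n)
  count <- 0
  for (ci in seq_len(ncol(combos))) {
    xi <- combos[, ci]
    if (d_stat(pooled[xi], pooled[-xi]) >= d_obs - 1e-12) count <- count + 1
  }
  count / ncol(combos)
}
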