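# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths: naive loops, explicit rank formulas,
# and series expansions.

MMHG_PER_PA_T <- 1 / 133.322

# naive double-loop time-domain HRV statistics on a plain numeric vector
bruteHrvTime <- function(rr, prr50 = 50) {
  n <- length(rr)
  m <- 0
  for (v in rr) m <- m + v
  m <- m / n
  ss <- 0
  for (v in rr) ss <- ss + (v - m)^2
  sdrr <- sqrt(ss / (n - 1))
  nd <- 0
  sumsq <- 0
  over <- 0
  for (i in seq_len(n - 1)) {
    d <- rr[i + 1] - rr[i]
    sumsq <- sumsq + d * d
    if (abs(d) > prr50) over <- over + 1
    nd <- nd + 1
  }
  list(sdrr = sdrr, cvrr = sdrr / m, rmssd = sqrt(sumsq / nd),
       prr50 = 100 * over / nd)
}

# mid-ranks computed by explicit counting (no rank())
bruteMidranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- 0
    equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) below <- below + 1
      if (j != i && x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- 1 + below + equal / 2
  }
  r
}

# Spearman correlation through the explicit Pearson-on-midranks formula
bruteSpearman <- function(x, y) {
  rx <- bruteMidranks(x)
  ry <- bruteMidranks(y)
  mx <- mean(rx)
  my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Dunn pairwise z and p values from first principles
bruteDunn <- function(values, groups, adjustM = NULL) {
  groups <- as.character(groups)
  lev <- unique(groups)
  r <- bruteMidranks(values)
  N <- length(values)
  tie <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie <- tie + (t^3 - t)
  }
  S2 <- N * (N + 1) / 12 - tie / (12 * (N - 1))
  pairs <- utils::combn(lev, 2)
  m <- if (is.null(adjustM)) ncol(pairs) else adjustM
  res <- data.frame(a = pairs[1, ], b = pairs[2, ], z = NA_real_,
                    p_unadj = NA_real_, p_adj = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    ra <- mean(r[groups == pairs[1, i]])
    rb <- mean(r[groups == pairs[2, i]])
    na <- sum(groups == pairs[1, i])
    nb <- sum(groups == pairs[2, i])
    z <- (ra - rb) / sqrt(S2 * (1 / na + 1 / nb))
    p <- 2 * (1 - stats::pnorm(abs(z)))
    res$z[i] <- z
    res$p_unadj[i] <- p
    res$p_adj[i] <- min(1, p * m)
  }
  res
}

# noncentral-F tail probability via the Poisson mixture of central Beta
# distributions: P(F > c) = 1 - sum_j pois(j; l/2) I_x(d1/2 + j, d2/2),
# x = c d1 / (c d1 + d2)
brutePowerNoncentralF <- function(N, f, alpha, k, terms = 400) {
  d1 <- k - 1
  d2 <- N - k
  if (d2 < 1) return(0)
  crit <- stats::qf(1 - alpha, d1, d2)
  lambda <- f^2 * N
  xx <- crit * d1 / (crit * d1 + d2)
  cdf <- 0
  for (j in 0:terms) {
    w <- exp(-lambda / 2 + j * log(lambda / 2) - lgamma(j + 1))
    cdf <- cdf + w * stats::pbeta(xx, d1 / 2 + j, d2 / 2)
  }
  1 - cdf
}

# masked-pixel metrics by explicit loop
bruteRoiMetrics <- function(image, mask) {
  px <- c()
  for (i in seq_len(nrow(image)))
    for (j in seq_len(ncol(image)))
      if (mask[i, j]) px <- c(px, image[i, j])
  px <- as.numeric(sort(px))
  n <- length(px)
  list(mean = sum(px) / n, id = sum(px), median = px[ceiling(n / 2)])
}

# small random cohort table in the package's long format
makeCohort <- function(values, groups, parameter = "p") {
  data.frame(subject_id = sprintf("s%02d", seq_along(values)),
             group = groups, parameter = parameter, value = values,
             stringsAsFactors = FALSE)
}
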