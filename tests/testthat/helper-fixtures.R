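# Fixtures are generated in code; no data files are shipped.

# small deterministic paired experiment: nTaxa taxa, one reactor,
# counts chosen so no cell is zero unless asked for
makeToyExperiment <- function(nTaxa = 4, days = c(10, 50), reactor = "R1",
                              zeroCell = NULL, depth = 1000) {
  set.seed(nTaxa * 1000 + depth)
  gid <- sprintf("%sR_d%02d", reactor, days)
  eid <- sprintf("%sE_d%02d", reactor, days)
  taxa <- paste0("g__T", seq_len(nTaxa))
  cnt <- matrix(sample(10:100, nTaxa * 2 * length(days), replace = TRUE),
                nTaxa, 2 * length(days),
                dimnames = list(taxa, c(gid, eid)))
  if (!is.null(zeroCell)) cnt[zeroCell$row, zeroCell$col] <- 0L
  storage.mode(cnt) <- "integer"
  md <- data.frame(sample_id = c(gid, eid), reactor = reactor,
                   compartment = rep(c("granular", "effluent"),
                                     each = length(days)),
                   day = rep(days, 2), stringsAsFactors = FALSE)
  WashoutExperiment(cnt, md)
}

# deterministic taxon specification for small simulator configs
makeTaxa <- function(n, affinity = NULL) {
  i <- seq_len(n) - 1L
  w <- exp(-0.15 * i)
  data.frame(label = paste0("g__S", seq_len(n)),
             initialFraction = w / sum(w),
             growthRate = 0,
             surfaceAffinity = if (is.null(affinity)) (i %% n) / max(1, n - 1)
                               else affinity,
             stringsAsFactors = FALSE)
}

# independent oracle: Bray-Curtis by an explicit double loop
bcOracle <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

# independent oracle: one-sample Wilcoxon two-sided p by full enumeration
# of all 2^n sign assignments of the observed ranks (n <= ~12)
wilcoxonEnumOracle <- function(x, mu = 0) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  pl <- mean(W <= V + 1e-9)
  pg <- mean(W >= V - 1e-9)
  list(statistic = V, p.value = min(1, 2 * min(pl, pg)))
}

# independent oracle: weighted isotonic regression by the minimax formula
# x*_i = max_{s<=i} min_{t>=i} weighted mean of y[s..t]  (O(n^3))
isotonicOracle <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    max(vapply(seq_len(i), function(s) {
      min(vapply(i:n, function(t)
        sum(y[s:t] * w[s:t]) / sum(w[s:t]), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}

# independent oracle: Pearson r and two-sided p from the definitional
# formulas (covariance over the product of sds; t CDF directly)
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}
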