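#' Weighted isotonic regression (pool-adjacent-violators)
#'
#' Least-squares fit of a non-decreasing sequence to \code{y} with optional
#' positive weights, by the pool-adjacent-violators algorithm. This is the
#' monotone-regression step of non-metric multidimensional scaling.
#'
#' @param y numeric vector.
#' @param w positive weights (default all 1).
#' @return numeric vector of fitted values, non-decreasing, same length.
#' @export
isotonicFit <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (!n) return(numeric())
  if (length(w) != n || any(w <= 0)) stop("weights must be positive, same length")
  # blocks kept as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = sz[seq_len(top)])
}

.lowerTriVec <- function(m) m[lower.tri(m)]

# stress-1 and monotone-fitted distances for a configuration
.nmdsStress <- function(d, delta) {
  ord <- order(delta, d)           # primary (weak) tie treatment
  dhat <- numeric(length(d))
  dhat[ord] <- isotonicFit(d[ord])
  stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
  list(stress = stress, dhat = dhat)
}

.guttman <- function(X, dhat, d, n) {
  ratio <- ifelse(d > 0, dhat / d, 0)
  B <- matrix(0, n, n)
  B[lower.tri(B)] <- -ratio
  B <- B + t(B)
  diag(B) <- -rowSums(B)
  (B %*% X) / n
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose Euclidean distances preserve
#' the rank order of the input dissimilarities, minimizing Kruskal stress-1
#' = sqrt(sum (d - dhat)^2 / sum d^2), where dhat is the monotone
#' (pool-adjacent-violators) regression of the configuration distances onto
#' the dissimilarity ranks (primary treatment of ties). Each run alternates
#' the isotonic fit with a Guttman transform, with step halving so the
#' stress trace is non-increasing; the first start is the classical-scaling
#' (metric MDS) configuration, the remaining starts are random, and the best
#' final stress wins.
#'
#' @param dm symmetric dissimilarity matrix with zero diagonal.
#' @param k number of dimensions (default 2; must satisfy nrow(dm) > k).
#' @param nRestarts number of starts including the classical one (20).
#' @param maxIter iteration cap per start (300).
#' @param tol convergence tolerance on the relative stress change (1e-7).
#' @param seed optional integer seed for the random starts.
#' @return an \linkS4class{OrdinationResult}; coordinates are centred.
#'   Degenerate input (all dissimilarities equal) is flagged, not fatal.
#' @export
nmdsOrdination <- function(dm, k = 2, nRestarts = 20, maxIter = 300,
                           tol = 1e-7, seed = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n <= k) stop("need more samples than dimensions")
  if (max(abs(dm - t(dm))) > 1e-12 || any(abs(diag(dm)) > 0))
    stop("dm must be symmetric with zero diagonal")
  if (!is.null(seed)) set.seed(seed)
  delta <- .lowerTriVec(dm)
  degenerate <- (max(delta) - min(delta)) < 1e-12
  runOne <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    d <- as.vector(stats::dist(X))
    st <- .nmdsStress(d, delta)
    trace <- st$stress
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      Xn <- .guttman(X, st$dhat, d, n)
      dn <- as.vector(stats::dist(Xn))
      stn <- .nmdsStress(dn, delta)
      tries <- 0L
      while (stn$stress > st$stress && tries < 8L) {
        Xn <- (X + Xn) / 2
        dn <- as.vector(stats::dist(Xn))
        stn <- .nmdsStress(dn, delta)
        tries <- tries + 1L
      }
      if (stn$stress > st$stress) break   # no improving step found
      improved <- st$stress - stn$stress
      X <- Xn; d <- dn; st <- stn
      trace <- c(trace, st$stress)
      if (st$stress == 0 ||
          improved / max(st$stress, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    }
    list(X = X, stress = st$stress, trace = trace, converged = converged)
  }
  Xc <- stats::cmdscale(dm, k = k)
  if (ncol(Xc) < k)
    Xc <- cbind(Xc, matrix(0, n, k - ncol(Xc)))
  classicalInit <- .nmdsStress(as.vector(stats::dist(Xc)), delta)$stress
  starts <- vector("list", nRestarts)
  starts[[1]] <- Xc
  for (i in seq_len(nRestarts - 1L))
    starts[[i + 1L]] <- matrix(stats::runif(n * k, -1, 1), n, k)
  runs <- lapply(starts, runOne)
  finals <- vapply(runs, `[[`, numeric(1), "stress")
  best <- which.min(finals)
  bestRun <- runs[[best]]
  pts <- scale(bestRun$X, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  new("OrdinationResult", points = pts, stress = bestRun$stress,
      trace = bestRun$trace, stressPerStart = finals,
      classicalInitStress = classicalInit,
      bestStart = as.integer(best), converged = bestRun$converged,
      degenerate = degenerate)
}
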