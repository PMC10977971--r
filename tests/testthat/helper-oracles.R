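# Independent oracles, deliberately naive implementations.

# literal nested-loop evaluation of the data log-likelihood:
# log prod_j sum_k (1/K) prod_i N(z_ij | mu_ik, 1)
bruteLogLik <- function(z, mu) {
  J <- ncol(z); K <- ncol(mu); I <- nrow(z)
  total <- 0
  for (j in seq_len(J)) {
    sj <- 0
    for (k in seq_len(K)) {
      lik <- 1 / K
      for (i in seq_len(I)) lik <- lik * dnorm(z[i, j], mu[i, k], 1)
      sj <- sj + lik
    }
    total <- total + log(sj)
  }
  total
}

# all valid sequences (multiset permutations of metric labels)
enumerateSequences <- function(counts) {
  res <- list()
  recur <- function(prefix, left) {
    if (all(left == 0)) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(left)) {
      if (left[i] > 0) {
        left2 <- left
        left2[i] <- left2[i] - 1L
        recur(c(prefix, i), left2)
      }
    }
  }
  recur(integer(0), as.integer(counts))
  res
}

# independent piecewise-linear stage-mean oracle: explicit per-segment
# slope arithmetic, no shared code with stageZscores / approx()
pwlStageOracle <- function(gridZ, labels) {
  I <- nrow(gridZ); N <- length(labels)
  mu <- matrix(NA_real_, I, N + 1)
  for (i in seq_len(I)) {
    ts <- c(0, which(labels == i), N + 1)
    zs <- gridZ[i, ]
    for (k in seq_len(N + 1)) {
      t <- k - 0.5
      seg <- max(which(ts <= t))
      slope <- (zs[seg + 1] - zs[seg]) / (ts[seg + 1] - ts[seg])
      mu[i, k] <- zs[seg] + slope * (t - ts[seg])
    }
  }
  mu
}

# sort-based tail-mean oracle for anchors
tailMeansOracle <- function(x, fraction) {
  s <- sort(x)
  nLow <- sum(x <= quantile(x, fraction, type = 7))
  nHigh <- sum(x >= quantile(x, 1 - fraction, type = 7))
  c(mean(s[seq_len(nLow)]), mean(rev(s)[seq_len(nHigh)]))
}

# exact likelihood weights over all valid sequences of a grid
exactSequenceWeights <- function(z, grid) {
  counts <- rep(ncol(ebmstager::gridZ(grid)) - 2L,
                nrow(ebmstager::gridZ(grid)))
  seqs <- enumerateSequences(counts)
  ll <- vapply(seqs, function(s)
    dataLogLikelihood(z, stageZscores(grid, eventSequence(s))), numeric(1))
  w <- exp(ll - max(ll))
  list(sequences = seqs, logLik = ll, weights = w / sum(w))
}

# small reproducible planted-problem builder: grid with anchors +/-2 and
# evenly spaced intermediate events, interleaved planted sequence
plantedProblem <- function(I = 2, nEvents = 3, anchors = c(-2, 2)) {
  z <- t(vapply(seq_len(I), function(i)
    seq(anchors[1], anchors[2], length.out = nEvents + 2), numeric(nEvents + 2)))
  rownames(z) <- paste0("metric_", seq_len(I))
  grid <- eventGrid(z)
  labels <- rep(seq_len(I), nEvents)   # round-robin interleaving
  list(grid = grid, sequence = eventSequence(labels,
                                             metricNames = rownames(z)))
}

# Kendall tau between two event sequences (by event positions)
sequenceTau <- function(s1, s2) {
  e1 <- sequenceEvents(s1); e2 <- sequenceEvents(s2)
  key1 <- paste(e1$metric, e1$event)
  key2 <- paste(e2$metric, e2$event)
  pos2 <- match(key1, key2)
  cor(e1$position, pos2, method = "kendall")
}

suppressPackageStartupMessages(library(SummarizedExperiment))
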