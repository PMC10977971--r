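#' Probability-weighted stage means and standard errors
#'
#' The stage value of a metric is the posterior-weighted mean
#' \eqn{\bar x(k) = \sum_j p_j(k) x_j / \sum_j p_j(k)} with the
#' subject-by-stage posterior as weights, and its standard error is
#' \eqn{SE(k) = \sigma \sqrt{\sum_j p_j(k)^2} / \sum_j p_j(k)} where
#' \eqn{\sigma} is the SD of the metric over the cohort. Under uniform
#' weights this reduces to the ordinary mean and \eqn{\sigma/\sqrt J}. A
#' stage with zero total weight is reported as missing.
#'
#' @param values per-subject metric values (raw scale).
#' @param posterior subjects x stages posterior matrix (rows sum to 1).
#' @param sigma metric SD used in the SE; default \code{sd(values)}.
#' @return data.frame with columns \code{stage}, \code{mean}, \code{se},
#'   \code{weight} (total posterior mass), and attribute \code{sigma}.
#' @export
weightedStageMean <- function(values, posterior, sigma = sd(values)) {
  posterior <- as.matrix(posterior)
  if (length(values) != nrow(posterior))
    stop("values must match the posterior's subjects")
  w <- colSums(posterior)
  m <- as.numeric(crossprod(posterior, values)) / w
  se <- sigma * sqrt(colSums(posterior^2)) / w
  zero <- w <= 0
  m[zero] <- NA_real_
  se[zero] <- NA_real_
  out <- data.frame(stage = seq_len(ncol(posterior)), mean = m, se = se,
                    weight = w)
  attr(out, "sigma") <- sigma
  out
}

#' Stage composition by a categorical label
#'
#' Applies the probability-weighted mean to the indicator vector of each
#' category (e.g. each CDR rating): the weighted fraction of each
#' category at each stage. Fractions over categories sum to one at every
#' stage.
#'
#' @param labels per-subject categorical labels.
#' @param posterior subjects x stages posterior matrix.
#' @return stages x categories matrix of fractions.
#' @export
stageProportions <- function(labels, posterior) {
  posterior <- as.matrix(posterior)
  if (length(labels) != nrow(posterior))
    stop("labels must match the posterior's subjects")
  labels <- as.factor(labels)
  if (nlevels(labels) == 0) stop("configuration error: empty label set")
  out <- vapply(levels(labels), function(lv)
    weightedStageMean(as.numeric(labels == lv), posterior)$mean,
    numeric(ncol(posterior)))
  rownames(out) <- paste0("stage_", seq_len(ncol(posterior)))
  out
}

#' Bootstrap comparison of two stage values
#'
#' Tests whether the probability-weighted mean of a metric differs
#' between stages k and k'. Subject values are resampled with
#' replacement while the posterior weights are held fixed (a conditional
#' bootstrap given the staging), and both weighted means are recomputed
#' per replicate. Because resampling breaks the pairing between values
#' and stage weights, the replicate differences \eqn{\delta x^\star =
#' \bar x^\star(k) - \bar x^\star(k')} form a null distribution of no
#' stage effect, centered at zero; the two-sided p-value is twice the
#' smaller tail of that null distribution beyond the observed
#' difference, with a +1 / (B + 1) continuity floor.
#'
#' @param values per-subject metric values.
#' @param posterior subjects x stages posterior matrix.
#' @param k,kPrime stage indices to compare.
#' @param B bootstrap replicates (default 50000; at least 1000).
#' @param seed integer seed; deterministic given it.
#' @return data.frame (one row) with \code{stage_k}, \code{stage_kprime},
#'   \code{delta} (observed difference), \code{p}, \code{B}.
#' @export
bootstrapStageDifference <- function(values, posterior, k, kPrime,
                                     B = 50000, seed = NULL) {
  posterior <- as.matrix(posterior)
  J <- nrow(posterior)
  if (length(values) != J) stop("values must match the posterior's subjects")
  if (B < 1000) stop("B must be at least 1000")
  if (k < 1 || kPrime < 1 || k > ncol(posterior) || kPrime > ncol(posterior))
    stop("invalid stage indices")
  wk <- posterior[, k] / sum(posterior[, k])
  wp <- posterior[, kPrime] / sum(posterior[, kPrime])
  delta <- sum(wk * values) - sum(wp * values)
  if (k == kPrime)
    return(data.frame(stage_k = k, stage_kprime = kPrime, delta = 0,
                      p = 1, B = B))
  if (sd(values) == 0) {
    warning("degenerate constant data; p = 1")
    return(data.frame(stage_k = k, stage_kprime = kPrime, delta = delta,
                      p = 1, B = B))
  }
  .withSeed(seed, {
    dw <- wk - wp
    # resample in blocks to bound memory at large B
    blocks <- split(seq_len(B), ceiling(seq_len(B) / 10000))
    nLe <- 0L
    nGe <- 0L
    for (ix in blocks) {
      Xstar <- matrix(values[sample.int(J, J * length(ix), replace = TRUE)],
                      J, length(ix))
      dstar <- as.numeric(crossprod(dw, Xstar))
      nLe <- nLe + sum(dstar <= delta)
      nGe <- nGe + sum(dstar >= delta)
    }
    p <- min(1, 2 * min((nLe + 1) / (B + 1), (nGe + 1) / (B + 1)))
    data.frame(stage_k = k, stage_kprime = kPrime, delta = delta,
               p = p, B = B)
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values) via \code{stats::p.adjust}, with
#' input validation.
#'
#' @param p numeric p-values in \code{[0, 1]}.
#' @return q-values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Compare all stage pairs of a metric with FDR control
#'
#' Runs [bootstrapStageDifference()] for every stage pair (the
#' multiple-comparison family for one metric) and adjusts the p-values by
#' Benjamini-Hochberg.
#'
#' @inheritParams bootstrapStageDifference
#' @return data.frame with one row per stage pair and columns
#'   \code{stage_k}, \code{stage_kprime}, \code{delta}, \code{p},
#'   \code{q}.
#' @export
compareAllStagePairs <- function(values, posterior, B = 50000, seed = NULL) {
  K <- ncol(as.matrix(posterior))
  pairs <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  res <- lapply(seq_len(nrow(pairs)), function(r)
    bootstrapStageDifference(values, posterior,
                             k = pairs[r, 2], kPrime = pairs[r, 1],
                             B = B,
                             seed = if (is.null(seed)) NULL
                                    else .childSeed(seed, r)))
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out[, c("stage_k", "stage_kprime", "delta", "p", "q")]
}
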