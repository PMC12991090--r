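# Internal helpers shared across modules.

# Integer-ish site key: chromosome index * offset + position. Positions in
# this package are 0-based; offset must exceed any chromosome length.
.site_key <- function(chrom, pos, chrom_levels) {
  idx <- match(chrom, chrom_levels)
  if (anyNA(idx)) stop("unknown chromosome in site key")
  as.numeric(idx) * 1e9 + as.numeric(pos)
}

# 19 evenly spaced percentiles 5%..95%.
.pct_probs <- seq(0.05, 0.95, by = 0.05)

# Fast type-7 (linear interpolation between closest ranks) percentiles of a
# pre-sorted vector, vectorized over probs.
.quantile_sorted <- function(x_sorted, probs = .pct_probs) {
  n <- length(x_sorted)
  if (n == 1L) return(rep(x_sorted, length(probs)))
  h <- (n - 1) * probs
  lo <- floor(h) + 1
  hi <- pmin(lo + 1, n)
  x_sorted[lo] + (h - (lo - 1)) * (x_sorted[hi] - x_sorted[lo])
}

#' Two-tailed exact binomial test
#'
#' Exact two-sided binomial p-value of observing `k` successes in `n` trials
#' under success probability `p`. The default "minlik" method sums the
#' probabilities of all outcomes no more likely than the observed one (the
#' convention of [stats::binom.test()]); "doubling" doubles the smaller tail
#' and caps at 1.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param p Null success probability.
#' @param method "minlik" (default) or "doubling".
#' @return The two-sided p-value.
#' @export
binom_two_tailed <- function(k, n, p, method = c("minlik", "doubling")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n, p >= 0, p <= 1)
  if (method == "minlik") {
    stats::binom.test(k, n, p)$p.value
  } else {
    lower <- stats::pbinom(k, n, p)
    upper <- stats::pbinom(k - 1, n, p, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midranks for ties: the probability that
#' a randomly chosen positive outscores a randomly chosen negative.
#'
#' @param labels Binary vector (1/TRUE = positive class).
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Derive a stream-specific 31-bit seed from a base seed.
.derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1000003) * 2011 + stream * 7919) %% 2147483647L
}
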