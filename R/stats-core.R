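# Inferential primitives shared by all analysis stages: mid-p hypergeometric
# tests, adaptive two-stage FDR, Bonferroni FWER cutoffs, empirical
# (Monte Carlo) mid-p values, and the Mann-Whitney U comparison.

#' Validate hypergeometric test parameters
#'
#' Checks the counting identities that any (N, K, n, k) quadruple drawn from
#' a finite sampling scheme must satisfy before a hypergeometric tail
#' probability is meaningful.
#'
#' @param N Population size (total trials), non-negative integer.
#' @param K Number of "success" items in the population.
#' @param n Number of draws.
#' @param k Observed number of successes among the draws.
#' @return Invisibly `TRUE`; otherwise an error naming the violated bound.
#' @keywords internal
check_hyper_params <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals)))
    stop("hypergeometric parameters must be non-negative integers")
  if (K > N) stop("successes K exceeds population N (K <= N violated)")
  if (n > N) stop("draws n exceed population N (n <= N violated)")
  if (k > n) stop("observed k exceeds draws n (k <= n violated)")
  if (k > K) stop("observed k exceeds successes K (k <= K violated)")
  if (k < max(0, n + K - N))
    stop("observed k below the hypergeometric support (k >= n + K - N violated)")
  invisible(TRUE)
}

#' Upper-tail mid-p hypergeometric test
#'
#' Computes `P(X > k) + 0.5 * P(X = k)` for `X ~ Hypergeometric(N, K, n)`.
#' The mid-p variant assigns half the probability mass of the observed
#' outcome to the tail, reducing the conservatism of exact discrete tests.
#' Evaluation is exact (log-space PMF/CDF, no normal approximation), so tail
#' values far below 1e-6 remain accurate.
#'
#' @inheritParams check_hyper_params
#' @return A single probability in (0, 1].
#' @examples
#' # chance of drawing one of 3 consensus motifs in a single draw from 60
#' midp_upper(N = 60, K = 3, n = 1, k = 1)
#' @seealso [midp_two_tailed()], [consensus_overlap_test()]
#' @export
midp_upper <- function(N, K, n, k) {
  check_hyper_params(N, K, n, k)
  stats::phyper(k, K, N - K, n, lower.tail = FALSE) +
    0.5 * stats::dhyper(k, K, N - K, n)
}

#' Lower-tail mid-p hypergeometric test
#'
#' `P(X < k) + 0.5 * P(X = k)`; the de-enrichment counterpart of
#' [midp_upper()].
#'
#' @inheritParams check_hyper_params
#' @return A single probability in (0, 1].
#' @export
midp_lower <- function(N, K, n, k) {
  check_hyper_params(N, K, n, k)
  stats::phyper(k - 1, K, N - K, n) + 0.5 * stats::dhyper(k, K, N - K, n)
}

#' Two-tailed mid-p hypergeometric test
#'
#' Doubles the smaller of the two one-sided mid-p values, capped at 1. This
#' is the usual two-sided convention for mid-p tests; for a point-mass
#' (degenerate) distribution both one-sided values are 0.5 and the result
#' is 1.
#'
#' @inheritParams check_hyper_params
#' @return A single probability in (0, 1].
#' @export
midp_two_tailed <- function(N, K, n, k) {
  min(1, 2 * min(midp_upper(N, K, n, k), midp_lower(N, K, n, k)))
}

#' Two-stage linear step-up FDR adjustment
#'
#' Adaptive false discovery rate control: stage 1 runs a linear (BH) step-up
#' at level `alpha / (1 + alpha)` and uses the number of rejections to
#' estimate the number of true null hypotheses `m0`; stage 2 sharpens the BH
#' adjustment by the factor `m0 / m`. Because `m0 <= m`, adjusted values can
#' be smaller than the raw p-values' plain BH adjustment (and, when `m0` is
#' small, smaller than the raw p-values themselves).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Target FDR level used in the stage-1 null estimate
#'   (default 0.05).
#' @return A numeric vector of adjusted q-values, in input order.
#' @examples
#' bky_fdr(c(0.001, 0.01, 0.2, 0.9))
#' @export
bky_fdr <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  m <- length(p)
  alpha1 <- alpha / (1 + alpha)
  bh <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha1)
  m0 <- m - r1
  pmin(1, bh * m0 / m)
}

#' Bonferroni family-wise error rate cutoff
#'
#' @param m Number of tests in the family (positive integer).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test p-value cutoff `alpha / m`.
#' @examples
#' bonferroni_cutoff(1770)  # FWER cutoff over all motif pairs
#' @export
bonferroni_cutoff <- function(m, alpha = 0.05) {
  if (length(m) != 1 || !is.finite(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / m
}

#' Mid-p value against an empirical discrete null
#'
#' Computes a mid-p value for an observed count against a discrete null
#' distribution given either as a vector of simulated counts or as a
#' named histogram of probabilities/frequencies. When the observed value
#' lies beyond the simulated support in the direction of the tested tail,
#' the tail estimate is zero and the achievable resolution bound
#' `1 / total` (total = number of simulations) is returned instead, with
#' `upper_bound = TRUE` marking the p-value as a maximum estimate.
#'
#' @param null Either an integer vector of simulated counts, or a named
#'   numeric vector mapping count values to probability mass (need not be
#'   normalised).
#' @param observed Observed count (non-negative integer).
#' @param sided `"upper"` for enrichment only, `"two"` for doubling the
#'   smaller one-sided mid-p (capped at 1).
#' @param n_total Total number of simulations behind `null`; defaults to
#'   `length(null)` for a raw vector and `sum(null)` for a histogram. Used
#'   only for the resolution bound.
#' @return A list with components `p` (probability) and `upper_bound`
#'   (logical flag).
#' @export
discrete_midp <- function(null, observed, sided = c("two", "upper"),
                          n_total = NULL) {
  sided <- match.arg(sided)
  if (length(observed) != 1 || !is.finite(observed) || observed < 0)
    stop("observed must be a single non-negative number")
  if (length(null) == 0) stop("empty null distribution")
  if (!is.null(names(null))) {
    vals <- as.numeric(names(null))
    mass <- as.numeric(null)
    if (is.null(n_total)) n_total <- sum(null)
  } else {
    vals <- as.numeric(null)
    mass <- rep(1, length(null))
    if (is.null(n_total)) n_total <- length(null)
  }
  mass <- mass / sum(mass)
  p_eq <- sum(mass[vals == observed])
  upper <- sum(mass[vals > observed]) + 0.5 * p_eq
  lower <- sum(mass[vals < observed]) + 0.5 * p_eq
  bound <- 1 / n_total
  out_of_support <- p_eq == 0 &&
    (observed > max(vals) || observed < min(vals))
  if (out_of_support) {
    # beyond the simulated support the tail mass is unresolved; report the
    # resolution limit as a maximum estimate
    return(list(p = bound, upper_bound = TRUE))
  }
  p <- switch(sided,
    upper = upper,
    two = min(1, 2 * min(upper, lower))
  )
  list(p = max(p, 0), upper_bound = FALSE)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U comparison of two groups. For combined sample
#' sizes up to 20 the full permutation distribution of U is enumerated
#' (midranks used under ties), giving an exact p-value
#' `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`; for larger samples a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list with `U` (the smaller of the two U statistics), `p`, the
#'   method used, and the two group medians.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (any(!is.finite(c(a, b)))) stop("inputs must be finite numeric")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u_obs <- min(u1, u2)
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 20) {
    # exact: enumerate every assignment of ranks to group a
    idx <- utils::combn(n1 + n2, n1)
    r1 <- colSums(matrix(r[idx], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u1 - mu))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1  # every pooled value tied: no evidence either way
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
    method <- "normal approximation (tie-corrected)"
  }
  list(U = u_obs, p = p, method = method,
       median_a = stats::median(a), median_b = stats::median(b))
}
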