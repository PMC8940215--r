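# Independent oracles used to check package computations. These are
# deliberately written from first principles (direct enumeration, manual
# step-up, dynamic-programming convolution) and never call the package
# functions they validate.

# hypergeometric PMF over the full support, via binomial coefficients
oracle_hyper_pmf <- function(N, K, n) {
  supp <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  names(pmf) <- supp
  pmf
}

oracle_midp <- function(N, K, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  pmf <- oracle_hyper_pmf(N, K, n)
  supp <- as.numeric(names(pmf))
  if (tail == "upper") sum(pmf[supp > k]) + 0.5 * sum(pmf[supp == k])
  else sum(pmf[supp < k]) + 0.5 * sum(pmf[supp == k])
}

# manual two-stage linear step-up adjusted values (no p.adjust)
oracle_bky <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  step_up_rejections <- function(level) {
    ok <- which(ps <= seq_len(m) * level / m)
    if (length(ok)) max(ok) else 0L
  }
  r1 <- step_up_rejections(alpha / (1 + alpha))
  m0 <- m - r1
  # BH adjustment by hand: running minimum from the largest p down
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q <- pmin(1, adj * m0 / m)
  out <- numeric(m)
  out[ord] <- q
  out
}

# exact Poisson-binomial PMF by convolution
oracle_poisbin_pmf <- function(probs) {
  pmf <- 1
  for (p in probs) pmf <- c(pmf * (1 - p), 0) + c(0, pmf * p)
  names(pmf) <- 0:(length(pmf) - 1)
  pmf
}

# closed-form no-hit complement for the without-replacement cleavage draw
oracle_pr_closed <- function(S, k, n) 1 - choose(n - k, S) / choose(n, S)

# strict Pareto frontier by pairwise dominance check
oracle_frontier <- function(points) {
  dominated <- vapply(seq_len(nrow(points)), function(i) {
    any(points$fold >= points$fold[i] &
          points$proportion >= points$proportion[i] &
          (points$fold > points$fold[i] |
             points$proportion > points$proportion[i]))
  }, TRUE)
  points[!dominated, , drop = FALSE]
}

# small event-table builder for hand-constructed fixtures
make_events <- function(replicate, accession, context, p1 = NA) {
  data.frame(replicate = replicate, accession = accession,
             p1 = as.integer(p1), context = context,
             stringsAsFactors = FALSE)
}
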