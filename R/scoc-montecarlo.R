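# Monte Carlo protein-cleavage null model for motif <-> annotation
# association.
#
# The unit of observation is a "protein-cleavage": an annotation-flagged
# substrate counted once per replicate if cleaved at least once at the
# motif (or either member of a motif pair). Under the null, each flagged
# substrate's S observed sites in a replicate behave like a
# without-replacement draw of S site slots from the replicate's n cleavage
# events, of which k carry the motif; the chance of hitting the motif at
# least once is then 1 - C(n-k, S)/C(n, S), evaluated in product form.

#' Probability a substrate is cleaved at a motif under the null
#'
#' `1 - prod_{i=0}^{S-1} (1 - k/(n - i))`, each factor clamped to \[0, 1\];
#' algebraically `1 - C(n-k, S)/C(n, S)`: the chance that a
#' without-replacement draw of the substrate's `S` sites from the
#' replicate's `n` site slots (of which `k` carry the motif) hits the
#' motif at least once.
#'
#' @param S Number of observed cleavage sites of the substrate in the
#'   replicate (1 <= S <= n).
#' @param k Motif-bearing cleavage events in the replicate.
#' @param n All cleavage events in the replicate.
#' @return A probability.
#' @examples
#' pr_cleaved_at_motif(S = 2, k = 1, n = 10)  # 0.2
#' @export
pr_cleaved_at_motif <- function(S, k, n) {
  if (any(c(S, k, n) != round(c(S, k, n))) || k < 0 || n < 0 || S < 1)
    stop("S, k, n must be integers with S >= 1, k >= 0, n >= 0")
  if (k > n) stop("k exceeds n")
  if (S > n) stop("S exceeds n (a substrate cannot carry more sites than the replicate)")
  fac <- 1 - k / (n - seq_len(S) + 1)
  fac <- pmin(pmax(fac, 0), 1)
  1 - prod(fac)
}

#' Per-replicate motif cleavage frequencies
#'
#' @param events Event data.frame.
#' @param target Motif or `"m1+m2"` pair label.
#' @return Data.frame with one row per replicate: `replicate`, `k`
#'   (matching events), `n` (all events).
#' @export
replicate_motif_frequency <- function(events, target) {
  validate_events(events)
  reps <- sort(unique(events$replicate))
  hit <- context_matches(events$context, target)
  data.frame(replicate = reps,
             k = vapply(reps, function(r)
               sum(hit[events$replicate == r]), 0L),
             n = vapply(reps, function(r)
               sum(events$replicate == r), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Observed protein-cleavages for a motif among flagged substrates
#'
#' Sum over replicates of the number of distinct flagged accessions with
#' at least one event matching the motif (either member, for pairs) in
#' that replicate.
#'
#' @param events Event data.frame.
#' @param flagged Character vector of annotation-flagged accessions.
#' @param target Motif or pair label; `NULL` counts cleavage at any site
#'   (the screen's denominator).
#' @return Integer count.
#' @export
observed_protein_cleavages <- function(events, flagged, target = NULL) {
  validate_events(events)
  sel <- events$accession %in% flagged
  if (!is.null(target)) sel <- sel & context_matches(events$context, target)
  ev <- events[sel, c("replicate", "accession")]
  nrow(unique(ev))
}

# Per-(replicate, flagged substrate) null cleavage probabilities.
flagged_null_probs <- function(events, flagged, target) {
  freq <- replicate_motif_frequency(events, target)
  sel <- events$accession %in% flagged
  sc <- events[sel, c("replicate", "accession")]
  if (nrow(sc) == 0) stop("no flagged substrates among the events")
  S <- stats::aggregate(list(S = rep(1L, nrow(sc))),
                        sc[c("replicate", "accession")], sum)
  i <- match(S$replicate, freq$replicate)
  vapply(seq_len(nrow(S)), function(j)
    pr_cleaved_at_motif(S$S[j], freq$k[i[j]], freq$n[i[j]]), 0)
}

#' Monte Carlo null simulation for one motif or pair
#'
#' Simulates the total protein-cleavage count under the null: in each
#' simulation every flagged substrate in every replicate where it was
#' cleaved contributes a Bernoulli draw with success probability
#' [pr_cleaved_at_motif()] computed from that replicate's motif frequency
#' and the substrate's observed site count. The observed count is compared
#' to the simulated distribution with an empirical mid-p value.
#'
#' @param events Event data.frame.
#' @param flagged Character vector of flagged accessions.
#' @param target Motif or pair label.
#' @param n_sims Number of simulations (default 1e5).
#' @param seed RNG seed (integer); results are reproducible given the seed.
#' @param sided `"two"` (default) or `"upper"`.
#' @return A `scoc_mc` object: list with `target`, `observed`,
#'   `expected_mean` (simulated), `analytic_mean` (sum of the Bernoulli
#'   probabilities), `fold`, `p_mid`, `p_is_upper_bound`, `null`
#'   (histogram of simulated counts), `n_sims`, `seed`, `sided`.
#' @export
simulate_null <- function(events, flagged, target, n_sims = 1e5,
                          seed = 1L, sided = c("two", "upper")) {
  sided <- match.arg(sided)
  if (n_sims < 1) stop("n_sims must be >= 1")
  probs <- flagged_null_probs(events, flagged, target)
  observed <- observed_protein_cleavages(events, flagged, target)
  set.seed(as.integer(seed))
  # sum of independent Bernoullis; identical probabilities grouped into
  # one binomial draw (exact, just fewer RNG calls)
  up <- unique(probs)
  C <- integer(n_sims)
  for (p in up)
    C <- C + stats::rbinom(n_sims, sum(probs == p), p)
  null_tab <- table(C)
  hist <- as.numeric(null_tab)
  names(hist) <- names(null_tab)
  mp <- discrete_midp(hist, observed, sided = sided, n_total = n_sims)
  em <- mean(C)
  structure(list(target = target,
                 observed = observed,
                 expected_mean = em,
                 analytic_mean = sum(probs),
                 fold = if (em > 0) observed / em else NA_real_,
                 p_mid = mp$p,
                 p_is_upper_bound = mp$upper_bound,
                 null = hist,
                 n_probs = length(probs),
                 n_sims = as.integer(n_sims),
                 seed = as.integer(seed),
                 sided = sided),
            class = "scoc_mc")
}

#' @export
print.scoc_mc <- function(x, ...) {
  cat("Monte Carlo protein-cleavage null for", x$target, "\n")
  cat("  observed:", x$observed,
      " expected (sim mean):", round(x$expected_mean, 3),
      " fold:", round(x$fold, 3), "\n")
  cat("  mid-p (", x$sided, "-sided): ", signif(x$p_mid, 4),
      if (x$p_is_upper_bound) " (maximum estimate: observed beyond simulated support)",
      "\n", sep = "")
  cat("  ", format(x$n_sims, big.mark = ","), " simulations, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Monte Carlo screen over motifs or motif pairs
#'
#' Runs [simulate_null()] for every target with a deterministic per-target
#' seed substream and adjusts the mid-p values across the screen with the
#' two-stage linear step-up FDR.
#'
#' @inheritParams simulate_null
#' @param targets Character vector of motif and/or pair labels.
#' @param alpha FDR level for the adjustment (default 0.05).
#' @return An `mc_screen` object: data.frame with one row per target
#'   (target, observed_C, expected_mean, fold, p_mid, p_is_upper_bound,
#'   q_fdr, n_sims, seed) and attributes `n_flagged`, `alpha`, `sided`.
#' @export
mc_screen <- function(events, flagged, targets, n_sims = 1e5, seed = 1L,
                      sided = c("two", "upper"), alpha = 0.05) {
  sided <- match.arg(sided)
  if (length(targets) == 0) stop("no targets to screen")
  seed <- as.integer(seed)
  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    # fixed offset per target: independent, reproducible substreams
    res[[i]] <- simulate_null(events, flagged, targets[i], n_sims = n_sims,
                              seed = (seed + i - 1L) %% .Machine$integer.max,
                              sided = sided)
  }
  out <- data.frame(target = targets,
                    observed_C = vapply(res, `[[`, 0L, "observed"),
                    expected_mean = vapply(res, `[[`, 0, "expected_mean"),
                    fold = vapply(res, `[[`, 0, "fold"),
                    p_mid = vapply(res, `[[`, 0, "p_mid"),
                    p_is_upper_bound = vapply(res, `[[`, TRUE,
                                              "p_is_upper_bound"),
                    n_sims = as.integer(n_sims),
                    seed = seed,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q_fdr <- bky_fdr(out$p_mid, alpha = alpha)
  out <- out[c("target", "observed_C", "expected_mean", "fold", "p_mid",
               "p_is_upper_bound", "q_fdr", "n_sims", "seed")]
  structure(out,
            class = c("mc_screen", "data.frame"),
            n_flagged = length(unique(
              events$accession[events$accession %in% flagged])),
            alpha = alpha, sided = sided)
}

#' @export
print.mc_screen <- function(x, n = 10, ...) {
  cat("Monte Carlo screen:", nrow(x), "target(s),",
      attr(x, "n_flagged"), "flagged substrate(s)\n")
  sig <- sum(x$q_fdr < attr(x, "alpha"))
  cat(sig, "target(s) at q <", attr(x, "alpha"), "\n\n")
  df <- as.data.frame(x)
  df <- df[order(df$p_mid), , drop = FALSE]
  df$expected_mean <- round(df$expected_mean, 2)
  df$fold <- round(df$fold, 2)
  df$p_mid <- signif(df$p_mid, 3)
  df$q_fdr <- signif(df$q_fdr, 3)
  print(utils::head(df[c("target", "observed_C", "expected_mean", "fold",
                         "p_mid", "q_fdr")], n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more targets\n")
  invisible(x)
}

#' Write an mc_screen table as TSV
#'
#' @param x An `mc_screen`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_mc_screen <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Analytic consensus-overlap meta-test
#'
#' Upper-tail mid-p hypergeometric test for the overlap between a set of
#' screen hits and a reference consensus set: e.g. the chance that at
#' least `observed_overlap` of `drawn` significant motifs belong to a
#' `consensus_size`-member consensus, drawing from `population` motifs.
#'
#' @param population Total number of motifs (or pairs) drawable.
#' @param consensus_size Number of consensus members in the population.
#' @param drawn Number of hits drawn.
#' @param observed_overlap Hits that are consensus members.
#' @return A probability (upper-tail mid-p).
#' @examples
#' consensus_overlap_test(60, 3, 11, 2)
#' @export
consensus_overlap_test <- function(population, consensus_size, drawn,
                                   observed_overlap) {
  midp_upper(N = population, K = consensus_size, n = drawn,
             k = observed_overlap)
}
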