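# Monte Carlo protein-cleavage null model and the analytic overlap tests.

test_that("null cleavage probability equals its closed form exhaustively", {
  for (n in c(1, 2, 5, 17, 50)) {
    for (k in 0:n) {
      for (S in seq_len(n)) {
        expect_equal(pr_cleaved_at_motif(S, k, n),
                     oracle_pr_closed(S, k, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("null cleavage probability has the hand-derived values", {
  expect_equal(pr_cleaved_at_motif(1, 0, 10), 0)
  expect_equal(pr_cleaved_at_motif(2, 1, 10), 0.2)     # 1 - 36/45
  expect_equal(pr_cleaved_at_motif(3, 2, 4), 1.0)       # third factor zero
  expect_error(pr_cleaved_at_motif(5, 1, 4), "S exceeds n")
})

test_that("null cleavage probability is monotone in S, k, and n", {
  for (rep in 1:50) {
    set.seed(rep)
    n <- sample(2:40, 1); k <- sample(0:n, 1); S <- sample(1:(n - 1), 1)
    p <- pr_cleaved_at_motif(S, k, n)
    expect_gte(pr_cleaved_at_motif(S + 1, k, n), p - 1e-12)
    if (k < n) expect_gte(pr_cleaved_at_motif(S, k + 1, n), p - 1e-12)
    if (S <= n - 1 && k <= n - 1)
      expect_lte(pr_cleaved_at_motif(S, k, n + 1), p + 1e-12)
  }
})

test_that("observed protein-cleavages use at-least-once-per-replicate counting", {
  # one flagged protein with a GD site in each of 3 replicates -> 3
  ev <- make_events(c("r1", "r2", "r3"), "PF", "IRGDSDGV", 6)
  expect_equal(observed_protein_cleavages(ev, "PF", "GD"), 3L)
  # five GD sites in one replicate still count once
  ev5 <- make_events(rep("r1", 5), "PF",
                     rep("IRGDSDGV", 5), c(6, 16, 26, 36, 46))
  expect_equal(observed_protein_cleavages(ev5, "PF", "GD"), 1L)
  # pair semantics: either member counts, protein counted once
  evp <- make_events(c("r1", "r1"), "PF", c("IRGDSDGV", "AARDSDGV"),
                     c(6, 16))
  expect_equal(observed_protein_cleavages(evp, "PF", "GD+RD"), 1L)
  expect_equal(observed_protein_cleavages(evp, "PF"), 1L)
  expect_equal(observed_protein_cleavages(evp, character(0), "GD"), 0L)
})

test_that("simulated null matches exact Poisson-binomial enumeration", {
  # 2 replicates, <= 3 flagged substrates, hand-checkable frequencies
  ev <- rbind(
    make_events("r1", c("PF1", "PF1", "PF2", "PB1", "PB2"),
                c("IRGDSDGV", "AAVDAAAA", "IRGDSDGV", "AAVDAAAA", "AAADAAAA"),
                c(6, 16, 6, 6, 6)),
    make_events("r2", c("PF1", "PB1", "PB2", "PB3"),
                c("IRGDSDGV", "IRGDSDGV", "AAADAAAA", "AAVDAAAA"),
                c(6, 6, 6, 6)))
  flagged <- c("PF1", "PF2")
  probs <- degradomics:::flagged_null_probs(ev, flagged, "GD")
  # r1: k=2, n=5; PF1 has S=2, PF2 S=1. r2: k=2, n=4; PF1 S=1.
  expect_equal(sort(probs),
               sort(c(1 - (3 / 5) * (2 / 4), 2 / 5, 2 / 4)),
               tolerance = 1e-12)
  obs <- observed_protein_cleavages(ev, flagged, "GD")
  expect_equal(obs, 3L)
  sim <- simulate_null(ev, flagged, "GD", n_sims = 2e5, seed = 42)
  # empirical mean within 4 Monte Carlo SE of the analytic expectation
  se_mean <- sqrt(sum(probs * (1 - probs)) / sim$n_sims)
  expect_lt(abs(sim$expected_mean - sum(probs)), 4 * se_mean)
  # simulated mid-p within 3 MC SE of the exact Poisson-binomial mid-p
  pmf <- oracle_poisbin_pmf(probs)
  supp <- as.numeric(names(pmf))
  upper <- sum(pmf[supp > obs]) + 0.5 * sum(pmf[supp == obs])
  lower <- sum(pmf[supp < obs]) + 0.5 * sum(pmf[supp == obs])
  exact_two <- min(1, 2 * min(upper, lower))
  se_p <- sqrt(exact_two * (1 - exact_two) / sim$n_sims)
  expect_lt(abs(sim$p_mid - exact_two), 3 * se_p + 1e-9)
})

test_that("identical seeds reproduce identical simulations", {
  x <- generate_degradome(synthetic_config(seed = 2, n_proteins = 60,
                                           events_per_replicate = 120))
  fl <- x$truth$flagged
  a <- simulate_null(x$events, fl, "GD", n_sims = 2000, seed = 99)
  b <- simulate_null(x$events, fl, "GD", n_sims = 2000, seed = 99)
  expect_identical(a, b)
  scr1 <- mc_screen(x$events, fl, c("GD", "RD"), n_sims = 1000, seed = 7)
  scr2 <- mc_screen(x$events, fl, c("GD", "RD"), n_sims = 1000, seed = 7)
  expect_identical(scr1, scr2)
})

test_that("a frequency-matched motif shows no flagged-substrate enrichment", {
  # flagged and unflagged substrates share the motif frequency by design
  x <- generate_degradome(synthetic_config(seed = 31, n_proteins = 200,
                                           events_per_replicate = 600))
  fl <- x$truth$flagged
  sim <- simulate_null(x$events, fl, "GD", n_sims = 2e4, seed = 5)
  expect_gt(sim$p_mid, 0.05)
  expect_lt(abs(sim$fold - 1), 0.5)
  expect_error(simulate_null(x$events, "NOTANACC", "GD"),
               "no flagged substrates")
})

test_that("screens attach per-family FDR and honour target cardinality", {
  x <- generate_degradome(synthetic_config(seed = 13, n_proteins = 60,
                                           events_per_replicate = 150))
  fl <- x$truth$flagged
  scr <- mc_screen(x$events, fl, c("GD+RD", "GD+IXXD", "RD+IXXD"),
                   n_sims = 500, seed = 3)
  expect_s3_class(scr, "mc_screen")
  expect_equal(nrow(scr), 3)
  expect_equal(scr$q_fdr, bky_fdr(scr$p_mid))
  expect_output(print(scr), "3 target")
  f <- tempfile(fileext = ".tsv")
  write_mc_screen(scr, f)
  expect_equal(nrow(read.delim(f)), 3)
})

test_that("the analytic overlap meta-tests reproduce the printed values", {
  expect_equal(consensus_overlap_test(60, 3, 1, 1), 0.025)
  expect_equal(signif(consensus_overlap_test(60, 3, 11, 2), 2), 0.044)
  # pair population: the 3 pairs formable from the 3 consensus motifs
  expect_equal(signif(consensus_overlap_test(1770, 3, 11, 1), 2), 9.3e-3)
})
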