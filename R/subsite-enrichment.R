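# Consensus-sequence analysis: replicate-weighted subsite counts and the
# 60-motif enrichment table.
#
# For each motif the test contrasts the motif's frequency among cleaved
# sites (k/n) with its frequency among all aspartates in the sequences of
# cleaved substrates (K/N). All four counts are replicate-weighted: a
# substrate cleaved in r replicates contributes its sequence counts r
# times, and every cleavage event counts once per replicate in which it
# was seen.

# Per-protein background profile: for each aspartate at position >= 5,
# which residue sits at each non-prime subsite. Returns list(N = scalar,
# K = 3 x 20 matrix rows P2/P3/P4, cols AA20).
protein_background <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  dpos <- which(chars == "D")
  dpos <- dpos[dpos >= 5]
  K <- matrix(0L, nrow = 3, ncol = 20,
              dimnames = list(c("P2", "P3", "P4"), AA20))
  for (off in 1:3) {
    res <- chars[dpos - off]
    tab <- table(factor(res, levels = AA20))
    K[off, ] <- as.integer(tab)
  }
  list(N = length(dpos), K = K)
}

#' Replicate-weighted subsite counts for one motif
#'
#' Computes the (k, n, K, N) quadruple: `k` = cleavage events matching the
#' motif (summed over replicates), `n` = all cleavage events, `K` = motif
#' occurrences before aspartates in the sequences of cleaved substrates
#' (each substrate weighted by the number of replicates in which it was
#' cleaved), `N` = aspartates in those sequences, weighted the same way.
#' Only aspartates at position >= 5 (full P4 window) enter the background,
#' so all 60 motif tests share one `N`. Residues outside the 20-letter
#' alphabet at a subsite match no motif but still count toward `N`.
#'
#' @param events Event data.frame (see [extract_cleavage_sites()]).
#' @param proteome Named character vector of sequences.
#' @param motif A single motif label, e.g. `"GD"`.
#' @return A list with integer components `k`, `n`, `K`, `N`.
#' @examples
#' prot <- c(P1 = "MAIRGDSDGVDK")
#' ev <- data.frame(replicate = "rep1", accession = "P1",
#'                  p1 = 6L, context = "IRGDSDGV")
#' count_subsite(ev, prot, "GD")
#' @export
count_subsite <- function(events, proteome, motif) {
  cs <- subsite_count_matrix(events, proteome)
  i <- match(motif, rownames(cs$k))
  if (is.na(i)) stop("unknown motif: ", motif)
  list(k = unname(cs$k[i, "k"]), n = cs$n, K = unname(cs$k[i, "K"]),
       N = cs$N)
}

# All 60 motifs at once: k/K per motif plus shared n/N.
subsite_count_matrix <- function(events, proteome) {
  validate_events(events)
  missing_acc <- setdiff(unique(events$accession), names(proteome))
  if (length(missing_acc))
    stop("accession(s) not in proteome: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  mot <- motifs()
  # k: one count per event per replicate; events already one row per
  # (replicate, accession, p1)
  k <- integer(length(mot)); names(k) <- mot
  k[seq_len(20)] <- as.integer(table(factor(substr(events$context, 3, 3),
                                            levels = AA20)))
  k[21:40] <- as.integer(table(factor(substr(events$context, 2, 2),
                                      levels = AA20)))
  k[41:60] <- as.integer(table(factor(substr(events$context, 1, 1),
                                      levels = AA20)))
  n <- nrow(events)
  # replicate weights: number of replicates in which each substrate is cleaved
  wt <- table(unique(events[c("replicate", "accession")])$accession)
  Kmat <- matrix(0, nrow = 3, ncol = 20,
                 dimnames = list(c("P2", "P3", "P4"), AA20))
  N <- 0
  for (acc in names(wt)) {
    bg <- protein_background(proteome[[acc]])
    w <- as.integer(wt[[acc]])
    Kmat <- Kmat + w * bg$K
    N <- N + w * bg$N
  }
  K <- c(Kmat["P2", ], Kmat["P3", ], Kmat["P4", ])
  out <- cbind(k = k, K = as.integer(K))
  rownames(out) <- mot
  list(k = out, n = n, N = as.integer(N))
}

#' Consensus-sequence enrichment table over the 60 subsite motifs
#'
#' For every single-residue motif at P2-P4, tests the replicate-weighted
#' observed cleavage frequency against the aspartate background with a
#' two-tailed mid-p hypergeometric test; adjusts across the 60 tests with
#' the two-stage linear step-up FDR and flags motifs passing the
#' Bonferroni family-wise cutoff.
#'
#' @param events Event data.frame.
#' @param proteome Named character vector of sequences.
#' @param alpha Significance level for the FDR stage-1 estimate and the
#'   Bonferroni cutoff (default 0.05).
#' @return A `consensus_table` object: a data.frame (one row per motif,
#'   sorted by p ascending) with columns motif, subsite, residue, k, n, K,
#'   N, fold, p_mid, q_fdr, bonferroni, and attributes `n_events`,
#'   `n_replicates`, `fwer_cutoff`.
#' @export
consensus_table <- function(events, proteome, alpha = 0.05) {
  if (nrow(events) == 0) stop("no cleavage events")
  cs <- subsite_count_matrix(events, proteome)
  mot <- rownames(cs$k)
  k <- cs$k[, "k"]; K <- cs$k[, "K"]; n <- cs$n; N <- cs$N
  p <- vapply(seq_along(mot), function(i)
    midp_two_tailed(N, K[i], n, k[i]), 0)
  fold <- ifelse(n > 0 & K > 0, (k / n) / (K / N), NA_real_)
  q <- bky_fdr(p, alpha = alpha)
  cutoff <- bonferroni_cutoff(length(mot), alpha)
  out <- data.frame(motif = mot,
                    subsite = motif_subsite(mot),
                    residue = motif_residue(mot),
                    k = as.integer(k), n = as.integer(n),
                    K = as.integer(K), N = as.integer(N),
                    fold = fold, p_mid = p, q_fdr = q,
                    bonferroni = p < cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_mid, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("consensus_table", "data.frame"),
            n_events = nrow(events),
            n_replicates = length(unique(events$replicate)),
            alpha = alpha,
            fwer_cutoff = cutoff)
}

#' @export
print.consensus_table <- function(x, n = 10, ...) {
  cat("Subsite consensus enrichment:", attr(x, "n_events"), "events,",
      attr(x, "n_replicates"), "replicate(s), 60 motifs\n")
  sig <- sum(x$q_fdr < attr(x, "alpha"))
  cat(sig, "motif(s) at q <", attr(x, "alpha"),
      "| Bonferroni cutoff", signif(attr(x, "fwer_cutoff"), 3), "\n\n")
  df <- as.data.frame(utils::head(x, n))
  df$fold <- round(df$fold, 2)
  df$p_mid <- signif(df$p_mid, 3)
  df$q_fdr <- signif(df$q_fdr, 3)
  print(df, ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more motifs\n")
  invisible(x)
}

#' @export
summary.consensus_table <- function(object, ...) {
  alpha <- attr(object, "alpha")
  enr <- object[object$q_fdr < alpha & object$fold > 1, "motif"]
  dep <- object[object$q_fdr < alpha & object$fold < 1, "motif"]
  structure(list(n_events = attr(object, "n_events"),
                 n_replicates = attr(object, "n_replicates"),
                 alpha = alpha,
                 enriched = enr, deenriched = dep,
                 consensus = consensus_string(enr)),
            class = "summary.consensus_table")
}

#' @export
print.summary.consensus_table <- function(x, ...) {
  cat("Events:", x$n_events, " Replicates:", x$n_replicates, "\n")
  cat("Enriched motifs (q <", x$alpha, "):",
      if (length(x$enriched)) paste(x$enriched, collapse = ", ")
      else "none", "\n")
  cat("De-enriched motifs:",
      if (length(x$deenriched)) paste(x$deenriched, collapse = ", ")
      else "none", "\n")
  cat("Consensus sequence:", x$consensus, "\n")
  invisible(x)
}

# Render enriched motifs as a P4..P1 consensus string, e.g. "IX(G/R)D"
consensus_string <- function(enriched) {
  if (length(enriched) == 0) return("XXXD (no enriched subsite)")
  res <- split(motif_residue(enriched), motif_subsite(enriched))
  slot <- function(ss) {
    r <- res[[ss]]
    if (is.null(r)) "X" else if (length(r) == 1) r
    else paste0("(", paste(sort(r), collapse = "/"), ")")
  }
  paste0(slot("P4"), slot("P3"), slot("P2"), "D")
}

#' Volcano-style plot of a consensus table
#'
#' @param x A `consensus_table`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.consensus_table <- function(x, ...) {
  alpha <- attr(x, "alpha")
  col <- ifelse(x$q_fdr < alpha, ifelse(x$fold > 1, "firebrick", "navy"),
                "grey60")
  graphics::plot(log2(x$fold), -log10(x$p_mid), pch = 19, col = col,
                 xlab = "log2 fold enrichment",
                 ylab = "-log10 mid-p", ...)
  graphics::abline(h = -log10(attr(x, "fwer_cutoff")), lty = 2)
  lab <- x$q_fdr < alpha
  if (any(lab))
    graphics::text(log2(x$fold[lab]), -log10(x$p_mid[lab]),
                   x$motif[lab], pos = 3, cex = 0.7)
  invisible(x)
}

#' Write a consensus table as TSV
#'
#' @param x A `consensus_table`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_consensus_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
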