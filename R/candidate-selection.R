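# Stepwise specificity/coverage selection of candidate consensus motif
# pairs: starting from the pair with the highest fold enrichment, a pair
# with lower fold is admitted only if it covers a strictly higher
# proportion of flagged protein-cleavages. The selected set is exactly
# the strict Pareto frontier of (fold, proportion) over the eligible,
# significant pairs.

#' Build pair points from a pair screen
#'
#' Converts an [mc_screen()] over motif pairs into the (fold, proportion)
#' points used for candidate selection, where `proportion` is the pair's
#' observed flagged protein-cleavages divided by the total observed
#' flagged protein-cleavages.
#'
#' @param screen An `mc_screen` over pair targets.
#' @param total_observed Total flagged protein-cleavages (from
#'   [observed_protein_cleavages()] with `target = NULL`).
#' @return Data.frame: pair, fold, proportion, p_mid, q_fdr, observed_C,
#'   eligible (all `TRUE` initially).
#' @export
pair_points <- function(screen, total_observed) {
  if (total_observed <= 0) stop("total observed protein-cleavages must be positive")
  data.frame(pair = screen$target,
             fold = screen$fold,
             proportion = screen$observed_C / total_observed,
             p_mid = screen$p_mid,
             q_fdr = screen$q_fdr,
             observed_C = screen$observed_C,
             eligible = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mark artifact-prone pairs ineligible
#'
#' Pairs combining a rarely-observed P4 motif (default IXXD, CXXD, GXXD)
#' with a partner seen in at most one flagged protein-cleavage tend to
#' have artificially inflated fold enrichment; such pairs are marked
#' ineligible before selection.
#'
#' @param points Pair-point data.frame from [pair_points()].
#' @param observed_counts Named integer vector: observed flagged
#'   protein-cleavages per single motif.
#' @param exclude P4 motif labels triggering the rule (set
#'   `character(0)` to disable).
#' @return `points` with the `eligible` column updated.
#' @export
eligibility_filter <- function(points, observed_counts,
                               exclude = c("IXXD", "CXXD", "GXXD")) {
  if (length(exclude) == 0) return(points)
  members <- strsplit(points$pair, "+", fixed = TRUE)
  cnt <- function(m) {
    v <- observed_counts[m]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  bad <- vapply(members, function(ms) {
    any(vapply(seq_along(ms), function(i) {
      other <- ms[-i]
      ms[i] %in% exclude && all(cnt(other) <= 1)
    }, TRUE))
  }, TRUE)
  points$eligible <- points$eligible & !bad
  points
}

#' Stepwise specificity/coverage candidate selection
#'
#' Restricts to eligible points passing the family-wise significance
#' cutoff, sorts by fold descending (ties: proportion descending, then
#' pair label), emits the first point, then each subsequent point whose
#' proportion strictly exceeds the last emitted one. The result is the
#' strict Pareto frontier of (fold, proportion) over the significant,
#' eligible points.
#'
#' @param points Pair-point data.frame (columns pair, fold, proportion,
#'   p_mid, eligible).
#' @param fwer_cutoff Per-test p cutoff, e.g.
#'   `bonferroni_cutoff(1770, 0.05)`.
#' @return A `candidate_set`: the selected rows, ranked, highest fold
#'   first.
#' @export
select_candidates <- function(points, fwer_cutoff) {
  if (!any(points$eligible)) stop("no eligible pair points")
  sel <- points[points$eligible & points$p_mid < fwer_cutoff &
                  is.finite(points$fold), , drop = FALSE]
  ord <- order(-sel$fold, -sel$proportion, sel$pair)
  sel <- sel[ord, , drop = FALSE]
  keep <- logical(nrow(sel))
  best_prop <- -Inf
  for (i in seq_len(nrow(sel))) {
    if (sel$proportion[i] > best_prop) {
      keep[i] <- TRUE
      best_prop <- sel$proportion[i]
    }
  }
  out <- sel[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out[c("rank", setdiff(names(out), "rank"))],
            class = c("candidate_set", "data.frame"),
            fwer_cutoff = fwer_cutoff,
            n_points = nrow(points))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate consensus motif pairs:", nrow(x), "selected from",
      attr(x, "n_points"), "pairs (FWER cutoff",
      signif(attr(x, "fwer_cutoff"), 3), ")\n\n")
  df <- as.data.frame(x)
  df$fold <- round(df$fold, 2)
  df$proportion <- round(df$proportion, 3)
  df$p_mid <- signif(df$p_mid, 3)
  print(df[c("rank", "pair", "fold", "proportion", "p_mid")], ...)
  invisible(x)
}

#' Specificity/coverage scatter of pair points
#'
#' Plots proportion of flagged protein-cleavages against fold enrichment
#' for all eligible points, starring the selected candidates.
#'
#' @param x A `candidate_set`.
#' @param points The full pair-point data.frame the candidates were
#'   selected from (optional; only the candidates are drawn if absent).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly `x`.
#' @export
plot.candidate_set <- function(x, points = NULL, ...) {
  bg <- if (is.null(points)) as.data.frame(x)
        else points[points$eligible, , drop = FALSE]
  graphics::plot(bg$fold, bg$proportion, pch = 19, col = "grey70",
                 xlab = "flagged-substrate fold enrichment",
                 ylab = "proportion of flagged protein-cleavages", ...)
  graphics::points(x$fold, x$proportion, pch = 8, col = "firebrick",
                   cex = 1.3)
  graphics::text(x$fold, x$proportion, x$pair, pos = 4, cex = 0.7)
  invisible(x)
}
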