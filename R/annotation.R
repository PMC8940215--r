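# Generic annotation-term enrichment against a user-supplied annotation
# map (accession -> category/term), replacing any web-service dependency,
# plus the per-protein site-count comparison between flagged and
# unflagged substrates.

#' Read an annotation map
#'
#' Expects columns `accession`, `category` (e.g. CC/BP/MF) and `term`.
#'
#' @param path Path to the delimited table (tab/comma sniffed, gzip ok).
#' @return Data.frame with those three character columns.
#' @export
read_annotations <- function(path) {
  df <- read_delim_sniff(path)
  need <- c("accession", "category", "term")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$accession <- as.character(df$accession)
  df$category <- as.character(df$category)
  df$term <- as.character(df$term)
  df[need]
}

#' Accessions carrying an annotation term
#'
#' @param annotations Annotation data.frame.
#' @param term Term string (matched case-insensitively).
#' @return Character vector of accessions.
#' @export
annotation_flags <- function(annotations, term) {
  unique(annotations$accession[tolower(annotations$term) == tolower(term)])
}

#' Annotation-term enrichment of a substrate foreground
#'
#' For each term annotated on the background, tests whether foreground
#' accessions carry the term more often than background accessions with an
#' upper-tail mid-p hypergeometric test (k = foreground accessions with
#' the term, n = foreground size, K = background accessions with the
#' term, N = background size). FDR adjustment is applied within each
#' annotation category separately.
#'
#' @param foreground Character vector of accessions (must be a subset of
#'   `background`).
#' @param background Character vector of accessions.
#' @param annotations Annotation data.frame.
#' @param alpha FDR level (default 0.05).
#' @return Data.frame: category, term, k, n, K, N, fold, p_mid, q_fdr,
#'   sorted by p within category.
#' @export
term_enrichment <- function(foreground, background, annotations,
                            alpha = 0.05) {
  foreground <- unique(foreground); background <- unique(background)
  if (length(foreground) == 0 || length(background) == 0)
    stop("foreground and background must be non-empty")
  if (!all(foreground %in% background))
    stop("foreground is not a subset of background")
  ann <- annotations[annotations$accession %in% background, , drop = FALSE]
  ann <- unique(ann)
  if (nrow(ann) == 0) stop("no annotations on the background")
  key <- paste(ann$category, ann$term, sep = "\r")
  terms <- unique(ann[c("category", "term")])
  n <- length(foreground); N <- length(background)
  k <- integer(nrow(terms)); K <- integer(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    accs <- ann$accession[ann$category == terms$category[i] &
                            ann$term == terms$term[i]]
    k[i] <- sum(foreground %in% accs)
    K[i] <- length(unique(accs))
  }
  p <- vapply(seq_len(nrow(terms)), function(i)
    midp_upper(N, K[i], n, k[i]), 0)
  fold <- ifelse(K > 0, (k / n) / (K / N), NA_real_)
  q <- rep(NA_real_, length(p))
  for (cat in unique(terms$category)) {
    sel <- terms$category == cat
    q[sel] <- bky_fdr(p[sel], alpha = alpha)
  }
  out <- data.frame(category = terms$category, term = terms$term,
                    k = k, n = n, K = K, N = N, fold = fold,
                    p_mid = p, q_fdr = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$category, out$p_mid, out$term), , drop = FALSE]
}

#' Substrates cleaved at any of the given motifs
#'
#' @param events Event data.frame.
#' @param motifs Character vector of motif labels (empty gives an empty
#'   set).
#' @return Character vector of accessions with at least one matching
#'   event in any replicate.
#' @export
motif_foreground <- function(events, motifs) {
  if (length(motifs) == 0) return(character(0))
  hit <- rep(FALSE, nrow(events))
  for (m in motifs) hit <- hit | context_matches(events$context, m)
  sort(unique(events$accession[hit]))
}

#' Cleavage sites per protein: flagged vs unflagged substrates
#'
#' Compares the number of cleavage sites per protein per replicate
#' between annotation-flagged and unflagged substrates with a two-sided
#' Mann-Whitney U test. The unit of observation is the (protein,
#' replicate) site count.
#'
#' @param events Event data.frame.
#' @param flagged Character vector of flagged accessions.
#' @return A list: `U`, `p`, `method`, `median_flagged`,
#'   `median_unflagged`, `n_flagged`, `n_unflagged`.
#' @export
sites_per_protein_comparison <- function(events, flagged) {
  validate_events(events)
  counts <- stats::aggregate(list(S = rep(1L, nrow(events))),
                             events[c("replicate", "accession")], sum)
  is_f <- counts$accession %in% flagged
  a <- counts$S[is_f]; b <- counts$S[!is_f]
  if (length(a) == 0 || length(b) == 0)
    stop("need both flagged and unflagged substrates among the events")
  mw <- mann_whitney(a, b)
  list(U = mw$U, p = mw$p, method = mw$method,
       median_flagged = mw$median_a, median_unflagged = mw$median_b,
       n_flagged = length(a), n_unflagged = length(b))
}
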