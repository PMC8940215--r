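# Synthetic degradome generator with known ground truth.
#
# Emulates the statistical structure the analysis assumes: a proteome of
# i.i.d. sequences, replicate-structured aspartate (P1 = D) cleavage
# events sampled without replacement within each replicate, configurable
# per-subsite motif preference weights, an annotation-flagged "SCoC-like"
# substrate subset with a motif-specific cleavage boost, and heavier
# per-protein site counts in the flagged subset.

#' Configuration for the synthetic degradome generator
#'
#' Defaults describe a three-replicate neo-N-terminomics experiment over
#' an 800-protein substrate pool with UniProt-like residue frequencies
#' (aspartate about 5.5%) and 1000 cleavage events per replicate, giving
#' roughly 1.2 observed sites per cleaved protein per replicate — the
#' site-per-substrate density typical of neo-N-terminal degradome
#' studies, where a few hundred substrates yield one to two sites each
#' per replicate. 10% of substrates are flagged, with a 3x per-protein
#' site-count inflation in the flagged subset (cytoskeletal substrates
#' typically carry several times more observed sites than others).
#' Motif preferences default to none (uniform cleavage over aspartates).
#'
#' @param seed Integer RNG seed; the whole generation is reproducible
#'   from it.
#' @param n_replicates Number of biological replicates.
#' @param n_proteins Substrate pool size.
#' @param protein_length `c(mean, spread)` of protein lengths (normal,
#'   clamped at 60 residues).
#' @param aa_frequencies Named 20-vector of residue frequencies summing
#'   to 1.
#' @param scoc_fraction Fraction of substrates flagged with the
#'   cytoskeletal annotation term.
#' @param subsite_weights Named vector, motif label -> multiplicative
#'   cleavage propensity applied to every site whose context matches
#'   (unlisted motifs weigh 1).
#' @param scoc_motif_boost Named vector, motif label -> extra multiplier
#'   applied only in flagged substrates.
#' @param events_per_replicate Cleavage events sampled per replicate
#'   (without replacement).
#' @param scoc_sites_multiplier Per-site weight multiplier in flagged
#'   substrates (inflates their per-protein site counts).
#' @param peptide_length Maximum emitted peptide length (tryptic-like
#'   truncation of the P1'-onward fragment).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_replicates = 3L,
                             n_proteins = 800L,
                             protein_length = c(450, 150),
                             aa_frequencies = uniprot_aa_frequencies(),
                             scoc_fraction = 0.1,
                             subsite_weights = NULL,
                             scoc_motif_boost = NULL,
                             events_per_replicate = 1000L,
                             scoc_sites_multiplier = 3,
                             peptide_length = 12L) {
  if (abs(sum(aa_frequencies) - 1) > 1e-9)
    stop("aa_frequencies must sum to 1")
  if (!setequal(names(aa_frequencies), AA20))
    stop("aa_frequencies must be named by the 20 standard residues")
  if (events_per_replicate < 1) stop("events_per_replicate must be >= 1")
  if (scoc_fraction <= 0 || scoc_fraction >= 1)
    stop("scoc_fraction must lie in (0, 1)")
  if (any(c(subsite_weights, scoc_motif_boost, scoc_sites_multiplier) <= 0))
    stop("weights and boosts must be positive")
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.numeric(protein_length),
                 aa_frequencies = aa_frequencies[AA20],
                 scoc_fraction = scoc_fraction,
                 subsite_weights = subsite_weights,
                 scoc_motif_boost = scoc_motif_boost,
                 events_per_replicate = as.integer(events_per_replicate),
                 scoc_sites_multiplier = scoc_sites_multiplier,
                 peptide_length = as.integer(peptide_length)),
            class = "synthetic_config")
}

#' UniProt-like amino-acid background frequencies
#'
#' @return Named numeric vector over the 20 standard residues, summing
#'   to 1.
#' @export
uniprot_aa_frequencies <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.65, T = 5.36, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

# multiplicative weight of one context under a named motif->weight map
context_weight <- function(context, weights) {
  if (is.null(weights) || length(weights) == 0)
    return(rep(1, length(context)))
  w <- rep(1, length(context))
  for (m in names(weights))
    w <- w * ifelse(context_matches(context, m), weights[[m]], 1)
  w
}

#' Generate a synthetic degradome
#'
#' Draws a proteome from the configured residue frequencies, flags a
#' subset of substrates, enumerates candidate sites (aspartates with a
#' full P4 window and at least one downstream residue), and samples
#' `events_per_replicate` sites per replicate without replacement with
#' probability proportional to the product of matching subsite weights,
#' the flagged-substrate motif boosts, and the flagged site-count
#' multiplier. Evidence rows emit the C-terminal (P1' onward) peptide
#' fragment with its start coordinate, exercising the D|X extraction
#' path; the pre-derived event table is also returned as a direct-site
#' shortcut.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_degradome` list: `proteome` (named character
#'   vector), `evidence` (data.frame), `annotations` (data.frame),
#'   `events` (event data.frame), `truth` (ground-truth manifest list).
#' @export
generate_degradome <- function(config = synthetic_config()) {
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- pmax(60L, as.integer(round(stats::rnorm(
    n, config$protein_length[1], config$protein_length[2]))))
  acc <- sprintf("SYN%04d", seq_len(n))
  proteome <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = config$aa_frequencies),
          collapse = ""), "")
  names(proteome) <- acc
  flagged <- sort(sample(acc, max(1L, round(config$scoc_fraction * n))))

  # candidate sites: D at 5 <= p1 <= len - 1
  site_acc <- character(0); site_p1 <- integer(0)
  for (i in seq_len(n)) {
    chars <- strsplit(proteome[[i]], "")[[1]]
    p <- which(chars == "D")
    p <- p[p >= 5 & p <= lens[i] - 1]
    site_acc <- c(site_acc, rep(acc[i], length(p)))
    site_p1 <- c(site_p1, p)
  }
  if (length(site_p1) < config$events_per_replicate)
    stop("only ", length(site_p1), " candidate sites for ",
         config$events_per_replicate,
         " events per replicate; use a larger proteome")
  ctx <- vapply(seq_along(site_p1), function(j)
    context_window(proteome[[site_acc[j]]], site_p1[j]), "")
  is_flag <- site_acc %in% flagged
  w <- context_weight(ctx, config$subsite_weights)
  wb <- context_weight(ctx, config$scoc_motif_boost)
  w <- w * ifelse(is_flag, wb * config$scoc_sites_multiplier, 1)

  reps <- sprintf("rep%d", seq_len(config$n_replicates))
  ev_rep <- character(0); ev_idx <- integer(0)
  for (r in reps) {
    idx <- sample(length(site_p1), config$events_per_replicate, prob = w)
    ev_rep <- c(ev_rep, rep(r, length(idx)))
    ev_idx <- c(ev_idx, idx)
  }
  events <- new_events(ev_rep, site_acc[ev_idx], site_p1[ev_idx],
                       ctx[ev_idx])
  events <- events[order(events$replicate, events$accession, events$p1), ,
                   drop = FALSE]
  rownames(events) <- NULL

  pep_start <- events$p1 + 1L
  pep_end <- pmin(pep_start + config$peptide_length - 1L,
                  nchar(proteome[events$accession]))
  evidence <- data.frame(
    replicate = events$replicate,
    peptide = substr(proteome[events$accession], pep_start, pep_end),
    accession = events$accession,
    start = pep_start,
    stringsAsFactors = FALSE, row.names = NULL)

  decoys <- sprintf("decoy term %d", 1:6)
  decoy_cat <- rep(c("CC", "BP", "MF"), 2)
  ann_acc <- flagged
  ann_cat <- rep("MF", length(flagged))
  ann_term <- rep("structural constituent of cytoskeleton", length(flagged))
  for (d in seq_along(decoys)) {
    members <- sample(acc, max(1L, round(0.15 * n)))
    ann_acc <- c(ann_acc, members)
    ann_cat <- c(ann_cat, rep(decoy_cat[d], length(members)))
    ann_term <- c(ann_term, rep(decoys[d], length(members)))
  }
  annotations <- data.frame(accession = ann_acc, category = ann_cat,
                            term = ann_term, stringsAsFactors = FALSE)

  truth <- list(config = unclass(config),
                flagged = flagged,
                n_candidate_sites = length(site_p1),
                scoc_term = "structural constituent of cytoskeleton")
  structure(list(proteome = proteome, evidence = evidence,
                 annotations = annotations, events = events,
                 truth = truth),
            class = "synthetic_degradome")
}

#' @export
print.synthetic_degradome <- function(x, ...) {
  cat("Synthetic degradome:", length(x$proteome), "proteins,",
      nrow(x$events), "events in",
      length(unique(x$events$replicate)), "replicate(s),",
      length(x$truth$flagged), "flagged substrate(s)\n")
  invisible(x)
}

#' Write a synthetic degradome to disk
#'
#' Writes the FASTA proteome, the evidence and annotation tables (TSV),
#' the derived site table, and the ground-truth manifest (JSON).
#'
#' @param x A `synthetic_degradome`.
#' @param dir Output directory (created if absent).
#' @return Invisibly the named vector of written paths.
#' @export
write_degradome <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteome.fasta"),
             evidence = file.path(dir, "evidence.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             sites = file.path(dir, "sites.tsv"),
             truth = file.path(dir, "truth.json"))
  writeLines(paste0(">", names(x$proteome), "\n", x$proteome),
             paths[["fasta"]])
  utils::write.table(x$evidence, paths[["evidence"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$annotations, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_site_table(x$events, paths[["sites"]])
  jsonlite::write_json(x$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Generate a compendium-style (wide) cleavage-site table
#'
#' Produces the wide site-table dialect (accession, p1, context, one 0/1
#' indicator column per replicate) from a synthetic degradome, mimicking
#' the shape of published cleavage-site compendia at reduced scale.
#'
#' @param config A [synthetic_config()]; a 32-replicate configuration
#'   mirrors the compendium layout.
#' @return A data.frame in the wide dialect (parses through
#'   [read_site_table()]).
#' @export
degrabase_like <- function(config = synthetic_config(n_replicates = 32L,
                                                     events_per_replicate = 150L)) {
  x <- generate_degradome(config)
  ev <- x$events
  reps <- sprintf("rep%d", seq_len(config$n_replicates))
  key <- paste(ev$accession, ev$p1, sep = "\r")
  sites <- !duplicated(key)
  out <- data.frame(accession = ev$accession[sites], p1 = ev$p1[sites],
                    context = ev$context[sites],
                    stringsAsFactors = FALSE, row.names = NULL)
  skey <- key[sites]
  for (r in reps)
    out[[r]] <- as.integer(skey %in% key[ev$replicate == r])
  out
}
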