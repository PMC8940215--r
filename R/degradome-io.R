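# Readers and derivation of cleavage events.
#
# Conventions: protein coordinates are 1-based; a cleavage site is indexed
# by the position of its P1 aspartate, with the scissile bond between P1
# and P1'. The stored context is the 8-character P4-P4' window (positions
# p1-3 .. p1+4), right-padded with "X" where it runs past the C terminus.
# Only sites with a full non-prime window (p1 >= 5) are kept, so all motif
# statistics share one background.

#' Read a proteome from FASTA
#'
#' Accessions are taken from the first whitespace-delimited header token;
#' UniProt-style `db|ACC|name` headers yield `ACC`. Sequences are
#' uppercased.
#'
#' @param path Path to a FASTA file (gzip transparently supported).
#' @return Named character vector of sequences, names = accessions.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path)
  acc <- sub("\\s.*$", "", names(aa))
  bar <- grepl("^[^|]+\\|[^|]+\\|", acc)
  acc[bar] <- vapply(strsplit(acc[bar], "|", fixed = TRUE), `[`, "", 2)
  if (anyDuplicated(acc))
    stop("duplicate accession in ", path, ": ", acc[duplicated(acc)][1])
  seqs <- toupper(as.character(aa))
  names(seqs) <- acc
  seqs
}

# delimiter-sniffing table reader (tab vs comma), gzip-transparent
read_delim_sniff <- function(path, ...) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 50)
  first <- first[!grepl("^#", first)]
  if (length(first) == 0) stop("empty table: ", path)
  sep <- if (sum(nchar(gsub("[^\t]", "", first[1]))) >=
             sum(nchar(gsub("[^,]", "", first[1])))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "\"", ...)
}

#' Read a replicate-structured peptide evidence table
#'
#' Expects columns `replicate`, `peptide`, `accession` and optionally
#' `start` (1-based position of the peptide's first residue). Tab or comma
#' delimiters are sniffed; gzip is transparent.
#'
#' @param path Path to the table.
#' @param replicate_col Name of the column holding replicate identifiers
#'   (renamed to `replicate` on read).
#' @return A data.frame with columns `replicate`, `peptide`, `accession`
#'   and, when present, `start`.
#' @export
read_evidence <- function(path, replicate_col = "replicate") {
  df <- read_delim_sniff(path)
  if (!replicate_col %in% names(df))
    stop("evidence table lacks replicate column '", replicate_col, "'")
  names(df)[names(df) == replicate_col] <- "replicate"
  need <- c("replicate", "peptide", "accession")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("evidence table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$peptide <- toupper(df$peptide)
  df$replicate <- as.character(df$replicate)
  df$accession <- as.character(df$accession)
  df[c(need, intersect("start", names(df)))]
}

# P4-P4' window around the P1 aspartate at position p1 (p1 >= 5 assumed)
context_window <- function(seq, p1) {
  len <- nchar(seq)
  right <- substr(seq, p1 - 3, pmin(p1 + 4, len))
  pad <- 8 - nchar(right)
  ifelse(pad > 0,
         paste0(right, strrep("X", pad)),
         right)
}

#' Assemble and validate a cleavage-event table
#'
#' @param replicate,accession,p1,context Parallel vectors; `p1` may be `NA`
#'   when events come from a context-only site table.
#' @return A `data.frame` with one row per event.
#' @keywords internal
new_events <- function(replicate, accession, p1, context) {
  ev <- data.frame(replicate = as.character(replicate),
                   accession = as.character(accession),
                   p1 = as.integer(p1),
                   context = as.character(context),
                   stringsAsFactors = FALSE)
  validate_events(ev)
  ev
}

#' Validate cleavage-event invariants
#'
#' Every event must carry an 8-character context with aspartate at the P1
#' slot, and any known P1 coordinate must leave a full P4 window
#' (`p1 >= 5`).
#'
#' @param events Event data.frame.
#' @return Invisibly `TRUE`, or an error.
#' @export
validate_events <- function(events) {
  need <- c("replicate", "accession", "p1", "context")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(events) == 0) return(invisible(TRUE))
  bad <- nchar(events$context) != 8
  if (any(bad)) stop("context not 8 characters in row ", which(bad)[1])
  bad <- substr(events$context, 4, 4) != "D"
  if (any(bad)) stop("context lacks P1 aspartate in row ", which(bad)[1])
  bad <- !is.na(events$p1) & events$p1 < 5
  if (any(bad)) stop("p1 < 5 (no full P4 window) in row ", which(bad)[1])
  invisible(TRUE)
}

#' Derive D|X cleavage events from peptide evidence
#'
#' A peptide whose immediately preceding residue in its protein is
#' aspartate witnesses a cleavage at `p1 = start - 1`. When `start` is
#' absent the peptide is located by exact substring search and every match
#' position yields a candidate event. Events without a full P4 window
#' (`p1 < 5`) are dropped, and events are deduplicated within
#' `(replicate, accession, p1)`.
#'
#' @param evidence Evidence data.frame as from [read_evidence()].
#' @param proteome Named character vector of sequences.
#' @return Event data.frame (replicate, accession, p1, context).
#' @examples
#' prot <- c(P1 = "MAIRGDSDGVDK")
#' ev <- data.frame(replicate = "rep1", peptide = "SDGVDK", accession = "P1")
#' extract_cleavage_sites(ev, prot)
#' @export
extract_cleavage_sites <- function(evidence, proteome) {
  missing_acc <- setdiff(unique(evidence$accession), names(proteome))
  if (length(missing_acc))
    stop("accession(s) not in proteome: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  rep_out <- character(0); acc_out <- character(0); p1_out <- integer(0)
  for (i in seq_len(nrow(evidence))) {
    acc <- evidence$accession[i]
    seq <- proteome[[acc]]
    pep <- evidence$peptide[i]
    if ("start" %in% names(evidence) && !is.na(evidence$start[i])) {
      st <- as.integer(evidence$start[i])
      if (substr(seq, st, st + nchar(pep) - 1) != pep)
        stop("peptide '", pep, "' not found at stated start ", st,
             " in ", acc)
      starts <- st
    } else {
      m <- gregexpr(pep, seq, fixed = TRUE)[[1]]
      starts <- m[m > 0]
    }
    for (st in starts) {
      p1 <- st - 1
      if (p1 < 5) next
      if (substr(seq, p1, p1) != "D") next
      rep_out <- c(rep_out, evidence$replicate[i])
      acc_out <- c(acc_out, acc)
      p1_out <- c(p1_out, p1)
    }
  }
  key <- paste(rep_out, acc_out, p1_out, sep = "\r")
  keep <- !duplicated(key)
  rep_out <- rep_out[keep]; acc_out <- acc_out[keep]; p1_out <- p1_out[keep]
  ctx <- character(length(p1_out))
  for (j in seq_along(p1_out))
    ctx[j] <- context_window(proteome[[acc_out[j]]], p1_out[j])
  ev <- new_events(rep_out, acc_out, p1_out, ctx)
  ev <- ev[order(ev$replicate, ev$accession, ev$p1), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Collapse family-duplicate cleavage events
#'
#' Within each replicate, events from *different* accessions sharing an
#' identical P4-P4' context are treated as one cleavage event, attributed
#' to the lexicographically smallest accession (a computable approximation
#' of "proteins in the same family"). Events from the same accession are
#' never merged, even with identical contexts. Discarded rows are recorded
#' in a `merge_log` attribute.
#'
#' @param events Event data.frame.
#' @param collapse Set `FALSE` to disable (events returned unchanged, empty
#'   log).
#' @return The collapsed event data.frame, with attribute `merge_log`.
#' @export
collapse_family_duplicates <- function(events, collapse = TRUE) {
  validate_events(events)
  if (!collapse || nrow(events) == 0) {
    attr(events, "merge_log") <- events[0, , drop = FALSE]
    return(events)
  }
  grp <- paste(events$replicate, events$context, sep = "\r")
  keep <- rep(TRUE, nrow(events))
  for (g in unique(grp[duplicated(grp)])) {
    rows <- which(grp == g)
    accs <- events$accession[rows]
    if (length(unique(accs)) > 1)
      keep[rows[accs != min(accs)]] <- FALSE
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  log <- events[!keep, , drop = FALSE]
  rownames(log) <- NULL
  attr(out, "merge_log") <- log
  out
}

#' Read a cleavage-site table
#'
#' Two dialects are accepted. Long format: columns `accession`, `context`,
#' `replicate` and optionally `p1` — one row per event. Wide
#' (compendium-style) format: columns `accession`, `context`, optionally
#' `p1`, plus one 0/1 indicator column per replicate; each row expands to
#' one event per replicate whose indicator is 1. Contexts must carry the
#' P1 aspartate at position 4.
#'
#' @param path Path to the delimited table (tab/comma sniffed, gzip ok).
#' @return Event data.frame.
#' @export
read_site_table <- function(path) {
  df <- read_delim_sniff(path)
  if (!all(c("accession", "context") %in% names(df)))
    stop("site table needs 'accession' and 'context' columns")
  bad <- substr(df$context, 4, 4) != "D"
  if (any(bad))
    stop("context lacks P1 aspartate in site-table row ", which(bad)[1])
  p1 <- if ("p1" %in% names(df)) df$p1 else rep(NA_integer_, nrow(df))
  if ("replicate" %in% names(df)) {
    return(new_events(df$replicate, df$accession, p1, df$context))
  }
  ind_cols <- setdiff(names(df), c("accession", "context", "p1"))
  if (length(ind_cols) == 0) stop("site table has no replicate columns")
  reps <- character(0); accs <- character(0)
  p1s <- integer(0); ctxs <- character(0)
  for (rc in ind_cols) {
    on <- which(df[[rc]] %in% c(1, "1", TRUE))
    reps <- c(reps, rep(rc, length(on)))
    accs <- c(accs, df$accession[on])
    p1s <- c(p1s, as.integer(p1[on]))
    ctxs <- c(ctxs, df$context[on])
  }
  new_events(reps, accs, p1s, ctxs)
}

#' Write a cleavage-site table (long format)
#'
#' @param events Event data.frame.
#' @param path Output path (TSV).
#' @return Invisibly `path`.
#' @export
write_site_table <- function(events, path) {
  validate_events(events)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste("# cleavage sites: 1-based coordinates,",
                   "cleavage between P1 and P1'"), con)
  utils::write.table(events[c("accession", "p1", "context", "replicate")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
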