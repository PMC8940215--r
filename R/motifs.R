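# Single-residue subsite motifs. A motif fixes one residue at P2, P3 or P4
# with P1 always aspartate: "GD" = G at P2, "KXD" = K at P3, "IXXD" = I at
# P4 (X = any residue). There are 3 x 20 = 60 motifs and C(60, 2) = 1770
# unordered pairs.

#' The 20 standard amino acids, alphabetical
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Enumerate the 60 single-residue subsite motifs
#'
#' Canonical order: subsite P2, then P3, then P4; residues alphabetical
#' within each subsite.
#'
#' @return Character vector of 60 motif labels (`"AD"`, ..., `"YXXD"`).
#' @examples
#' head(motifs())
#' @export
motifs <- function() {
  c(paste0(AA20, "D"), paste0(AA20, "XD"), paste0(AA20, "XXD"))
}

#' Enumerate the 1770 unordered motif pairs
#'
#' Pairs are labelled `"<motif1>+<motif2>"` with members in canonical
#' single-motif order.
#'
#' @return Character vector of 1770 pair labels.
#' @export
motif_pairs <- function() {
  m <- motifs()
  idx <- utils::combn(length(m), 2)
  paste(m[idx[1, ]], m[idx[2, ]], sep = "+")
}

#' Subsite of a motif label
#'
#' @param motif Character vector of motif labels.
#' @return `"P2"`, `"P3"` or `"P4"` per element.
#' @export
motif_subsite <- function(motif) {
  n <- nchar(motif)
  if (any(!n %in% 2:4)) stop("malformed motif label: ", motif[!n %in% 2:4][1])
  c("P2", "P3", "P4")[n - 1]
}

#' Residue constrained by a motif label
#'
#' @param motif Character vector of motif labels.
#' @return The single constrained residue per element.
#' @export
motif_residue <- function(motif) substr(motif, 1, 1)

# Position of each subsite within the 8-character P4-P4' context window
# (P4 P3 P2 P1 P1' P2' P3' P4').
subsite_context_index <- c(P2 = 3L, P3 = 2L, P4 = 1L)

#' Does a cleavage-site context match a motif or motif pair?
#'
#' A context matches a pair if it matches either member (at-least-once
#' semantics).
#'
#' @param context Character vector of 8-character P4-P4' windows.
#' @param target A single motif label or `"m1+m2"` pair label.
#' @return Logical vector along `context`.
#' @export
context_matches <- function(context, target) {
  members <- strsplit(target, "+", fixed = TRUE)[[1]]
  hit <- rep(FALSE, length(context))
  for (m in members) {
    i <- subsite_context_index[[motif_subsite(m)]]
    hit <- hit | substr(context, i, i) == motif_residue(m)
  }
  hit
}
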