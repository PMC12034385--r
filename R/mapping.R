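#' Map alignment columns to structure residues
#'
#' Globally aligns the ungapped reference sequence of the alignment against
#' the one-letter sequence extracted from the structure (Needleman-Wunsch,
#' BLOSUM62, gap open 10 / extend 0.5) and returns the monotone set of
#' matched (alignment column, structure residue) pairs. Columns where the
#' reference has a gap are never mapped. A percent identity below 30% over
#' aligned positions is treated as a likely mismatched alignment/structure
#' pair and raises an error.
#'
#' @param aln an [aa_alignment].
#' @param struct a [protein_structure].
#' @param min_identity minimum fraction identity over aligned positions
#'   (default 0.3).
#' @return An object of class `residue_mapping`: list with `pairs` (two-column
#'   matrix `alignment_column`, `structure_residue`, both 1-based),
#'   `unmapped_columns`, `unmapped_residues` and `identity`.
#' @export
map_alignment_to_structure <- function(aln, struct, min_identity = 0.3) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(struct, "protein_structure"))
  refrow <- strsplit(aln$seqs[aln$reference], "")[[1L]]
  ref_cols <- which(refrow != "-")
  if (length(ref_cols) == 0L)
    stop_input("reference row of the alignment is all gaps")
  refseq <- paste(refrow[ref_cols], collapse = "")
  sseq <- structure_sequence(struct)
  pa <- Biostrings::pairwiseAlignment(
    refseq, sseq, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  a1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  g1 <- a1 == "-"; g2 <- a2 == "-"
  both <- !g1 & !g2
  pairs <- cbind(ref_cols[cumsum(!g1)[both]], cumsum(!g2)[both])
  identity <- if (any(both)) mean(a1[both] == a2[both]) else 0
  if (identity < min_identity)
    stop_input(paste0("alignment reference and structure sequence share only ",
                      "%.1f%% identity; wrong structure/alignment pair?"),
               100 * identity)
  colnames(pairs) <- c("alignment_column", "structure_residue")
  structure(list(
    pairs = pairs,
    unmapped_columns = setdiff(seq_len(n_columns(aln)), pairs[, 1L]),
    unmapped_residues = setdiff(seq_len(nrow(struct$residues)), pairs[, 2L]),
    identity = identity), class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("Residue mapping: %d pairs (%.1f%% identity), %d unmapped columns, %d unmapped residues\n",
              nrow(x$pairs), 100 * x$identity,
              length(x$unmapped_columns), length(x$unmapped_residues)))
  invisible(x)
}

# identity mapping for synthetic data where column i is residue i
identity_mapping <- function(n) {
  structure(list(pairs = cbind(alignment_column = seq_len(n),
                               structure_residue = seq_len(n)),
                 unmapped_columns = integer(), unmapped_residues = integer(),
                 identity = 1), class = "residue_mapping")
}
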