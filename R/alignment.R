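#' Amino-acid alignment objects
#'
#' An `aa_alignment` holds an aligned set of protein sequences: equal-length
#' rows over the 20 standard residues plus `-` (gap) and `X` (unknown), with
#' one row designated as the reference used for structure mapping.
#'
#' @param ids character vector of sequence identifiers.
#' @param seqs character vector of aligned sequences (same length each).
#' @param reference index of the reference row (default 1).
#' @return An object of class `aa_alignment` with elements `ids`, `seqs`
#'   and `reference`.
#' @export
aa_alignment <- function(ids, seqs, reference = 1L) {
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop_input("ids and seqs must have the same length")
  if (length(seqs) < 1L) stop_input("alignment needs at least one sequence")
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop_input("alignment rows have unequal lengths (%s)",
               paste(sort(n), collapse = ", "))
  if (n < 1L) stop_input("alignment has zero columns")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX-]*$", seqs)
  if (!all(ok))
    stop_input("sequence '%s' contains characters other than amino acids, 'X' or '-'",
               ids[which(!ok)[1L]])
  reference <- as.integer(reference)
  if (reference < 1L || reference > length(seqs))
    stop_input("reference index out of range")
  structure(list(ids = as.character(ids), seqs = seqs, reference = reference),
            class = "aa_alignment")
}

#' Read a FASTA protein alignment
#'
#' Reads an aligned FASTA file, normalizing lowercase to uppercase and `.`
#' to `-`. All records must have equal length; characters outside the
#' amino-acid alphabet (plus gap and `X`) are an error naming the record.
#'
#' @param path path to an aligned FASTA file.
#' @param reference index of the reference row (default 1, the first record).
#' @return An [aa_alignment] object.
#' @export
read_fasta_alignment <- function(path, reference = 1L) {
  if (!file.exists(path)) stop_input("alignment file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input("cannot parse FASTA '%s': %s",
                                                 path, conditionMessage(e)))
  if (length(set) < 1L) stop_input("no FASTA records in %s", path)
  aa_alignment(names(set), as.character(set), reference = reference)
}

#' Write an alignment to FASTA
#' @param aln an [aa_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", aln$ids, "\n", aln$seqs), con)
  invisible(path)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns (reference: %s)\n",
              length(x$seqs), nchar(x$seqs[1L]), x$ids[x$reference]))
  invisible(x)
}

# integer-coded alignment matrix, n_seq x n_col; 1..20 per .AA_ORDER,
# 0 for gap/X (missing data)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  codes <- match(m, .AA_ORDER)
  codes[is.na(codes)] <- 0L
  matrix(as.integer(codes), nrow = length(aln$seqs),
         dimnames = list(aln$ids, NULL))
}

n_columns <- function(aln) nchar(aln$seqs[1L])

# empirical residue frequencies with a pseudocount, in .AA_ORDER order
empirical_frequencies <- function(aln) {
  m <- alignment_matrix(aln)
  cnt <- tabulate(m[m > 0L], nbins = 20L) + 1
  cnt / sum(cnt)
}
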