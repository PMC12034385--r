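# Residue-level view of a protein chain: one entry per standard amino-acid
# residue with a Calpha, plus a mass-weighted center of mass over heavy atoms.

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# standard atomic masses for elements seen in protein heavy atoms
.ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45,
                  BR = 79.904, I = 126.904)

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct a protein structure object
#'
#' Usually created by [read_pdb_structure()] or [simulate_structure()].
#'
#' @param residues data frame with columns `chain`, `resno`, `insert`,
#'   `resid` (three-letter) and `aa` (one-letter).
#' @param ca,com numeric matrices (n x 3) of Calpha and center-of-mass
#'   coordinates in Angstroms.
#' @param source origin of the model (file path or `"synthetic"`).
#' @param pdb optional `bio3d` pdb object retained for annotated output.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(residues, ca, com = ca, source = "synthetic",
                              pdb = NULL) {
  ca <- as.matrix(ca); com <- as.matrix(com)
  n <- nrow(residues)
  if (nrow(ca) != n || nrow(com) != n || ncol(ca) != 3L || ncol(com) != 3L)
    stop_input("coordinate matrices must be n x 3 and match the residue table")
  if (!all(is.finite(ca)) || !all(is.finite(com)))
    stop_compute("non-finite coordinates in structure model")
  structure(list(residues = residues, ca = unname(ca), com = unname(com),
                 source = source, pdb = pdb),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure: %d residues, chain %s (%s)\n",
              nrow(x$residues), x$residues$chain[1L] %||% "?", x$source))
  invisible(x)
}

#' Extract the one-letter sequence of a structure
#' @param x a `protein_structure`.
#' @return single string of one-letter residue codes, in file order.
#' @export
structure_sequence <- function(x) paste(x$residues$aa, collapse = "")

#' Read a protein chain from a PDB file
#'
#' Parses one chain of a PDB file into a residue-level model carrying both
#' Calpha coordinates and per-residue centers of mass. The center of mass is
#' the mass-weighted mean of the residue's heavy (non-hydrogen) atoms --
#' either all of them (default) or side-chain atoms only, which tracks
#' side-chain orientation more directly; residues whose selected atom set is
#' empty (glycine, in side-chain mode) fall back to the heavy atoms present.
#' Alternate locations keep the highest occupancy (ties: altloc `"A"`, then
#' first); HETATM records and waters are excluded; residues without a Calpha
#' are skipped with a warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` to take the first polymer chain.
#' @param com_atoms `"all"` (backbone + side chain, default) or
#'   `"sidechain"`.
#' @return A [protein_structure] object.
#' @export
read_pdb_structure <- function(path, chain = NULL,
                               com_atoms = c("all", "sidechain")) {
  com_atoms <- match.arg(com_atoms)
  if (!file.exists(path)) stop_input("structure file not found: %s", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e) stop_input("cannot parse PDB '%s': %s",
                                                 path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% names(.AA3TO1), , drop = FALSE]
  if (nrow(at) == 0L) stop_input("no parseable ATOM records in %s", path)
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains)
    stop_input("chain '%s' not found in %s (available: %s)", chain, path,
               paste(chains, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]

  # altloc: per (residue, atom name) keep highest occupancy, tie -> 'A'/first
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  if (any(at$alt != "")) {
    ord <- seq_len(nrow(at))
    key <- paste(at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    pref <- order(key, -occ, at$alt != "A", ord)
    keep <- pref[!duplicated(key[pref])]
    at <- at[sort(keep), , drop = FALSE]
  }

  rkey <- paste(at$resno, at$insert, sep = "|")
  groups <- split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey)))
  res <- list(); ca <- list(); com <- list(); skipped <- character()
  for (g in groups) {
    sub <- at[g, , drop = FALSE]
    ica <- which(sub$elety == "CA")
    if (length(ica) == 0L) {
      skipped <- c(skipped, paste0(sub$resid[1L], sub$resno[1L]))
      next
    }
    heavy <- sub[!(toupper(sub$elesy) %in% c("H", "D", "")), , drop = FALSE]
    if (nrow(heavy) == 0L) heavy <- sub
    sel <- if (com_atoms == "sidechain")
      heavy[!(heavy$elety %in% .BACKBONE_ATOMS), , drop = FALSE] else heavy
    if (nrow(sel) == 0L) sel <- heavy  # glycine fallback
    mass <- .ATOMIC_MASS[toupper(sel$elesy)]
    if (anyNA(mass)) {
      warning(sprintf("unknown element(s) %s in residue %s%s ignored for center of mass",
                      paste(unique(toupper(sel$elesy)[is.na(mass)]), collapse = ","),
                      sub$resid[1L], sub$resno[1L]))
      sel <- sel[!is.na(mass), , drop = FALSE]
      mass <- mass[!is.na(mass)]
      if (nrow(sel) == 0L) { sel <- sub[ica, , drop = FALSE]; mass <- 12.011 }
    }
    xyz <- as.matrix(sel[, c("x", "y", "z")])
    res[[length(res) + 1L]] <- data.frame(
      chain = chain, resno = sub$resno[1L], insert = sub$insert[1L],
      resid = sub$resid[1L], aa = unname(.AA3TO1[sub$resid[1L]]),
      stringsAsFactors = FALSE)
    ca[[length(ca) + 1L]] <- as.numeric(sub[ica[1L], c("x", "y", "z")])
    com[[length(com) + 1L]] <- colSums(xyz * mass) / sum(mass)
  }
  if (length(skipped))
    warning(sprintf("skipped %d residue(s) without a Calpha in chain %s: %s",
                    length(skipped), chain, paste(skipped, collapse = ", ")))
  if (length(res) == 0L)
    stop_input("chain %s of %s contains no residues with a Calpha", chain, path)
  protein_structure(do.call(rbind, res), do.call(rbind, ca),
                    do.call(rbind, com), source = path, pdb = pdb)
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Produces a copy of the structure's PDB records with the B-factor replaced
#' by a per-residue score (clamped to `[-99.99, 999.99]`, two decimals), for
#' coloring conserved patches in molecular viewers. Residues with `NA`
#' scores (e.g. unmapped ones) are written as 999.99.
#'
#' @param struct a [protein_structure].
#' @param scores numeric vector, one value per structure residue (`NA`
#'   allowed).
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_annotated_pdb <- function(struct, scores, path) {
  stopifnot(inherits(struct, "protein_structure"))
  n <- nrow(struct$residues)
  if (length(scores) != n)
    stop_input("need one score per structure residue (%d != %d)",
               length(scores), n)
  b <- pmin(pmax(round(as.numeric(scores), 2), -99.99), 999.99)
  b[is.na(b)] <- 999.99
  if (!is.null(struct$pdb)) {
    pdb <- struct$pdb
    key <- paste(struct$residues$chain, struct$residues$resno,
                 struct$residues$insert, sep = "|")
    ins <- pdb$atom$insert; ins[is.na(ins)] <- ""
    akey <- paste(pdb$atom$chain, pdb$atom$resno, ins, sep = "|")
    idx <- match(akey, key)
    pdb$atom$b <- ifelse(is.na(idx), 999.99, b[ifelse(is.na(idx), 1L, idx)])
    bio3d::write.pdb(pdb, file = path)
  } else {
    write_ca_pdb(struct, path, b = b)
  }
  invisible(path)
}

# minimal CA-only PDB writer for synthetic chains
write_ca_pdb <- function(struct, path, b = NULL) {
  r <- struct$residues
  b <- b %||% rep(0, nrow(r))
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), r$resid, r$chain, r$resno,
    struct$ca[, 1L], struct$ca[, 2L], struct$ca[, 3L], 1.00, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
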