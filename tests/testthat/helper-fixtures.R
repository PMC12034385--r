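# Fixtures built in code at test time (no binary files).

write_fasta_fixture <- function(lines, file = tempfile(fileext = ".fasta")) {
  writeLines(lines, file)
  file
}

# minimal PDB writer for hand-specified atoms
# atoms: data.frame(serial, name, resid, chain, resno, x, y, z, occ, b,
#                   elem, alt)
write_pdb_fixture <- function(atoms, file = tempfile(fileext = ".pdb"),
                              hetatm = NULL) {
  fmt <- function(a, rec) {
    if (is.na(a$alt)) a$alt <- " "
    if (is.na(a$occ)) a$occ <- 1
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, a$serial,
            ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
            a$alt, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$occ, a$b, a$elem)
  }
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    fmt(as.list(atoms[i, ]), "ATOM"), character(1))
  if (!is.null(hetatm)) {
    lines <- c(lines, vapply(seq_len(nrow(hetatm)), function(i)
      fmt(as.list(hetatm[i, ]), "HETATM"), character(1)))
  }
  writeLines(c(lines, "END"), file)
  file
}

atom_row <- function(serial, name, resid, resno, x, y, z, elem,
                     chain = "A", occ = 1, b = 0, alt = NA) {
  data.frame(serial = serial, name = name, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, occ = occ, b = b,
             elem = elem, alt = alt, stringsAsFactors = FALSE)
}

# small benchmark dataset reused by several files
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_benchmark(n_seq = 15, n_sites = 80,
                                   gamma_shape = 0.7, seed = 424)
    cache
  }
})
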