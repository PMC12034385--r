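#' Import a Rate4Site result file
#'
#' Parses the plain-text result format of Rate4Site: one row per alignment
#' position with columns `POS SEQ SCORE [QQ-INTERVAL STD MSA]`, `#` comment
#' lines ignored. Positions must be contiguous from 1. Scores follow the
#' usual convention that lower values indicate stronger conservation.
#'
#' @param path path to a Rate4Site result file.
#' @return A `site_rates` object with `provenance = "imported"`.
#' @export
read_rate4site <- function(path) {
  if (!file.exists(path)) stop_input("rate file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop_input("no data rows in Rate4Site file %s", path)
  pos <- integer(length(keep)); sc <- numeric(length(keep))
  res <- character(length(keep))
  for (k in seq_along(keep)) {
    f <- strsplit(trimws(lines[keep[k]]), "\\s+")[[1L]]
    if (length(f) < 3L)
      stop_input("line %d of %s: expected at least 3 fields", keep[k], path)
    p <- suppressWarnings(as.integer(f[1L]))
    s <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(p))
      stop_input("line %d of %s: non-integer position '%s'", keep[k], path, f[1L])
    if (is.na(s))
      stop_input("line %d of %s: non-numeric score '%s'", keep[k], path, f[3L])
    pos[k] <- p; sc[k] <- s; res[k] <- f[2L]
  }
  if (!identical(pos, seq_along(pos)))
    stop_input("positions in %s are not contiguous from 1", path)
  new_site_rates(sc, provenance = "imported", normalization = "raw",
                 residues = res)
}
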