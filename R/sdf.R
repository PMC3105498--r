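# MDL SD file (V2000) export. Coordinates are written as zeros (no 2D/3D
# layout in scope); formal charges go into M  CHG lines; per-molecule
# properties follow each molblock as "> <key>" data items.

#' Write molecules to an MDL SD file (V2000)
#'
#' @param molecules list of \code{Molecule} objects (at most 999 atoms each,
#'   the V2000 limit).
#' @param path output file path.
#' @param properties optional list (parallel to \code{molecules}) of named
#'   character/numeric vectors written as SD data items, e.g. activity
#'   scores.
#' @return the path, invisibly.
#' @export
writeSDF <- function(molecules, path, properties = NULL) {
  if (inherits(molecules, "Molecule")) molecules <- list(molecules)
  if (!is.null(properties))
    stopifnot(length(properties) == length(molecules))
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(molecules)) {
    mol <- molecules[[m]]
    a <- mol@atoms; b <- mol@bonds
    if (nrow(a) > 999L || nrow(b) > 999L)
      stop("molecule ", m, " exceeds the V2000 atom/bond limit of 999")
    nm <- if (!is.na(mol@name)) mol@name else paste0("mol", m)
    writeLines(c(nm, "  chemrdf          2D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    for (k in seq_len(nrow(a)))
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        0, 0, 0, a$element[k]), con)
    for (k in seq_len(nrow(b))) {
      code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)[[
        b$order[k]]]
      writeLines(sprintf("%3d%3d%3d  0", b$atom1[k], b$atom2[k], code), con)
    }
    charged <- which(a$charge != 0L)
    if (length(charged)) {
      # M  CHG lines carry up to 8 (atom, charge) pairs each
      for (start in seq(1L, length(charged), by = 8L)) {
        grp <- charged[start:min(start + 7L, length(charged))]
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    if (!is.null(properties) && length(properties[[m]])) {
      pr <- properties[[m]]
      for (key in names(pr))
        writeLines(c(paste0("> <", key, ">"), as.character(pr[[key]]), ""),
                   con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
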