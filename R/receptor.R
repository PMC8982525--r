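#' Read a receptor structure from a PDB file
#'
#' Parses ATOM and HETATM records (fixed-column PDB format) into a flat
#' atom table. Water molecules (residue HOH/WAT) are ordinary rows —
#' structure-based fingerprints in this package treat explicit waters as
#' contact-eligible receptor atoms.
#'
#' @param path PDB file path.
#' @return An object of class `ReceptorStructure`: a data.frame with
#'   columns `chain`, `resname`, `resnum`, `icode`, `atom`, `element`,
#'   `x`, `y`, `z` and a derived unique `key` (`RES_<num>_<atomname>`).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[sel]
  if (!length(lines)) stop("no ATOM/HETATM records in '", path, "'")
  atom <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resnum <- as.integer(substr(lines, 23, 26))
  icode <- trimws(substr(lines, 27, 27))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  element <- trimws(substr(lines, 77, 78))
  guess <- toupper(substr(gsub("[0-9]", "", atom), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  df <- data.frame(chain = chain, resname = resname, resnum = resnum,
                   icode = icode, atom = atom, element = element,
                   x = x, y = y, z = z, stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in '", path, "'")
  df$key <- receptor_atom_key(df$resname, df$resnum, df$atom, df$icode)
  if (anyDuplicated(paste(df$chain, df$resnum, df$atom, df$icode)))
    stop("duplicate (chain, residue number, atom name) in '", path, "'")
  class(df) <- c("ReceptorStructure", "data.frame")
  df
}

#' @param resname,resnum,atom,icode vectors naming receptor atoms.
#' @rdname read_pdb
#' @export
receptor_atom_key <- function(resname, resnum, atom, icode = "") {
  paste0(resname, "_", resnum, ifelse(nzchar(icode), icode, ""), "_", atom)
}

#' @param receptor a `ReceptorStructure` (for the writer).
#' @rdname read_pdb
#' @export
write_pdb <- function(receptor, path) {
  rec <- ifelse(receptor$resname %in% c("HOH", "WAT"), "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %-4s %-3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   rec, seq_len(nrow(receptor)),
                   substr(receptor$atom, 1, 4), receptor$resname,
                   receptor$chain, receptor$resnum,
                   ifelse(nzchar(receptor$icode), receptor$icode, " "),
                   receptor$x, receptor$y, receptor$z, receptor$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Receptor atoms inside a binding-site sphere
#'
#' The binding site is conventionally a sphere centred on the bound
#' crystallographic ligand; everything within `radius` of `center` is
#' returned.
#'
#' @param receptor a `ReceptorStructure`.
#' @param center length-3 numeric, Angstrom.
#' @param radius positive radius in Angstrom.
#' @return Character vector of receptor atom keys.
#' @export
binding_site_atoms <- function(receptor, center, radius) {
  stopifnot(radius > 0, length(center) == 3L)
  d2 <- (receptor$x - center[1])^2 + (receptor$y - center[2])^2 +
        (receptor$z - center[3])^2
  receptor$key[d2 <= radius^2]
}
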