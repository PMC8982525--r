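#' Read and write SDF (MDL V2000) structure files
#'
#' Multi-conformer molecules are represented as consecutive SDF records
#' sharing the same title line: they are merged into one
#' [molecule_record()] with one conformer per record. Data fields
#' (`> <name>` blocks) are collected into a per-record attribute list;
#' an `IC50_M` field, when present, populates the activity record.
#'
#' @param path file path.
#' @param merge_conformers merge consecutive same-title records into one
#'   multi-conformer molecule (default). Set `FALSE` for pose files where
#'   every record is a distinct entity.
#' @return `read_sdf()`: a named list of `MoleculeRecord`s.
#' @export
read_sdf <- function(path, merge_conformers = TRUE) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  while (i <= length(lines)) {
    # skip blank padding between records
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i + 3L > length(lines)) break
    title <- trimws(lines[i])
    counts <- lines[i + 3L]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    if (is.na(na) || is.na(nb))
      stop("malformed counts line at line ", i + 3L, " in ", path)
    at <- lines[(i + 4L):(i + 3L + na)]
    coords <- matrix(0, na, 3)
    element <- character(na); charge <- integer(na)
    for (k in seq_len(na)) {
      ln <- at[k]
      coords[k, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                  substr(ln, 21, 30)))
      element[k] <- trimws(substr(ln, 32, 34))
      cc <- suppressWarnings(as.integer(substr(ln, 37, 39)))
      charge[k] <- if (is.na(cc) || cc == 0L) 0L else 4L - cc
    }
    bonds <- data.frame(from = integer(), to = integer(),
                        order = integer(), aromatic = logical())
    if (nb > 0L) {
      bl <- lines[(i + 4L + na):(i + 3L + na + nb)]
      bonds <- data.frame(
        from = as.integer(substr(bl, 1, 3)),
        to = as.integer(substr(bl, 4, 6)),
        order = as.integer(substr(bl, 7, 9)),
        aromatic = as.integer(substr(bl, 7, 9)) == 4L)
      bonds$order[bonds$aromatic] <- 1L
    }
    j <- i + 4L + na + nb
    props <- list()
    while (j <= length(lines) && trimws(lines[j]) != "$$$$") {
      m <- regmatches(lines[j], regexec("^> *<([^>]+)>", lines[j]))[[1]]
      if (length(m)) {
        val <- character()
        j <- j + 1L
        while (j <= length(lines) && nzchar(trimws(lines[j])) &&
               trimws(lines[j]) != "$$$$") {
          val <- c(val, lines[j]); j <- j + 1L
        }
        props[[m[2]]] <- paste(val, collapse = "\n")
      } else j <- j + 1L
    }
    recs[[length(recs) + 1L]] <- list(title = title, element = element,
                                      charge = charge, coords = coords,
                                      bonds = bonds, props = props)
    i <- j + 1L
  }
  # merge consecutive records with identical titles into conformers
  out <- list()
  for (r in recs) {
    key <- r$title
    if (merge_conformers && length(out) && names(out)[length(out)] == key) {
      prev <- out[[length(out)]]
      prev$conformers[[length(prev$conformers) + 1L]] <- conformer(r$coords)
      out[[length(out)]] <- prev
    } else {
      atoms <- data.frame(element = r$element, charge = r$charge,
                          aromatic = rep(FALSE, length(r$element)))
      if (nrow(r$bonds)) {
        ar_atoms <- unique(c(r$bonds$from[r$bonds$aromatic],
                             r$bonds$to[r$bonds$aromatic]))
        atoms$aromatic[ar_atoms] <- TRUE
      }
      act <- NULL
      if (!is.null(r$props$IC50_M))
        act <- activity_record(as.numeric(r$props$IC50_M))
      mol <- molecule_record(key, atoms, r$bonds,
                             list(conformer(r$coords)), activity = act)
      attr(mol, "sdf_props") <- r$props
      out[[length(out) + 1L]] <- mol
      names(out)[length(out)] <- key
    }
  }
  out
}

#' @param mols list of `MoleculeRecord`s (for `write_sdf()`).
#' @rdname read_sdf
#' @return `write_sdf()`: the path, invisibly.
#' @export
write_sdf <- function(mols, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    props <- attr(mol, "sdf_props")
    cfs <- if (length(mol$conformers)) mol$conformers else
      stop("molecule '", mol$id, "' has no conformer to write")
    for (cf in cfs) {
      writeLines(c(mol$id, "  phoreqsar", ""), con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         n_atoms(mol), nrow(mol$bonds)), con)
      chg <- ifelse(mol$atoms$charge == 0L, 0L, 4L - mol$atoms$charge)
      for (k in seq_len(n_atoms(mol)))
        writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                           cf$coords[k, 1], cf$coords[k, 2], cf$coords[k, 3],
                           mol$atoms$element[k], chg[k]), con)
      b <- mol$bonds
      for (k in seq_len(nrow(b)))
        writeLines(sprintf("%3d%3d%3d  0", b$from[k], b$to[k],
                           if (b$aromatic[k]) 4L else b$order[k]), con)
      writeLines("M  END", con)
      if (!is.null(mol$activity))
        writeLines(c("> <IC50_M>", format(mol$activity$ic50, digits = 12), ""),
                   con)
      for (nm in setdiff(names(props), "IC50_M"))
        writeLines(c(paste0("> <", nm, ">"), props[[nm]], ""), con)
      writeLines("$$$$", con)
    }
  }
  invisible(path)
}
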