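#' Build a molecule from a SMILES string
#'
#' A compact SMILES reader covering the organic subset: elements
#' B/C/N/O/P/S/F/Cl/Br/I, aromatic `b c n o p s`, branches, ring closures
#' (digits and `%nn`), bond symbols `- = # :`, and bracket atoms with
#' explicit hydrogen counts and formal charges (e.g. `[NH3+]`, `[O-]`).
#' Stereochemistry and isotopes are not interpreted. Implicit hydrogens
#' are stored in an `hcount` atom column; use [add_hydrogens()] to make
#' them explicit graph atoms.
#'
#' Graph only: no coordinates are generated. Attach conformers explicitly
#' (tests and generators in this package build geometry in code).
#'
#' @param smiles SMILES string.
#' @param id compound identifier (defaults to the SMILES itself).
#' @return A [molecule_record()] without conformers.
#' @examples
#' benzene <- mol_from_smiles("c1ccccc1")
#' sum(benzene$atoms$aromatic)
#' @export
mol_from_smiles <- function(smiles, id = smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  elements <- character(); charges <- integer(); aroma <- logical()
  hfixed <- integer()                 # -1 = derive from valence
  bonds <- list()
  prev <- 0L; stack <- integer()
  pending <- 0L                       # 0 = default bond
  ring <- list()                      # closure digit -> c(atom, order)
  i <- 1L
  add_atom <- function(el, ar, chg, hf) {
    elements[[length(elements) + 1L]] <<- el
    aroma[[length(aroma) + 1L]] <<- ar
    charges[[length(charges) + 1L]] <<- chg
    hfixed[[length(hfixed) + 1L]] <<- hf
    length(elements)
  }
  add_bond <- function(a, b, ord) {
    ar <- FALSE
    if (ord == 0L) {                  # default: aromatic if both ends aromatic
      if (aroma[a] && aroma[b]) { ord <- 1L; ar <- TRUE } else ord <- 1L
    } else if (ord == 4L) { ord <- 1L; ar <- TRUE }
    bonds[[length(bonds) + 1L]] <<- c(a, b, ord, ar)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- match(ch, c("-", "=", "#", ":"))
      if (pending == 4L) pending <- 4L
      i <- i + 1L
    } else if (ch == "/" || ch == "\\") { i <- i + 1L }  # stereo bonds ignored
    else if (grepl("[0-9%]", ch)) {
      if (ch == "%") {
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (is.null(ring[[key]])) ring[[key]] <- c(prev, pending)
      else {
        op <- ring[[key]]
        ord <- max(op[2], pending)
        add_bond(op[1], prev, ord)
        ring[[key]] <- NULL
      }
      pending <- 0L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in SMILES: ", smiles)
      tok <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(tok, regexec(
        "^[0-9]*([A-Za-z][a-z]?)(@{0,2})(H([0-9]?))?([+-][0-9]*|\\+\\+|--)?$", tok))[[1]]
      if (!length(m)) stop("cannot parse bracket atom [", tok, "]")
      el <- m[2]
      ar <- el %in% c("b", "c", "n", "o", "p", "s")
      if (ar) el <- toupper(el)
      hf <- if (nzchar(m[4])) { if (nzchar(m[5])) as.integer(m[5]) else 1L } else 0L
      chg <- 0L
      if (nzchar(m[6])) {
        cs <- m[6]
        if (cs == "++") chg <- 2L else if (cs == "--") chg <- -2L
        else {
          sgn <- if (substr(cs, 1, 1) == "+") 1L else -1L
          mag <- if (nchar(cs) > 1L) as.integer(substr(cs, 2, nchar(cs))) else 1L
          chg <- sgn * mag
        }
      }
      a <- add_atom(el, ar, chg, hf)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- 0L; i <- j + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) { el <- two; i <- i + 2L; ar <- FALSE }
      else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        el <- ch; i <- i + 1L; ar <- FALSE
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        el <- toupper(ch); i <- i + 1L; ar <- TRUE
      } else stop("unexpected character '", ch, "' in SMILES: ", smiles)
      a <- add_atom(el, ar, 0L, -1L)
      if (prev > 0L) add_bond(prev, a, pending)
      prev <- a; pending <- 0L
    }
  }
  if (length(ring)) stop("unclosed ring bond in SMILES: ", smiles)
  bm <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(numeric(), 0, 4)
  bdf <- data.frame(from = as.integer(bm[, 1]), to = as.integer(bm[, 2]),
                    order = as.integer(bm[, 3]), aromatic = as.logical(bm[, 4]))
  atoms <- data.frame(element = unlist(elements), charge = unlist(charges),
                      aromatic = unlist(aroma), stringsAsFactors = FALSE)
  atoms$hcount <- .implicit_h(atoms, bdf, unlist(hfixed))
  molecule_record(id, atoms, bdf)
}

# standard valences for implicit-H derivation
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

.implicit_h <- function(atoms, bonds, hfixed) {
  n <- nrow(atoms)
  bsum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    o <- if (bonds$aromatic[i]) 1.5 else bonds$order[i]
    bsum[bonds$from[i]] <- bsum[bonds$from[i]] + o
    bsum[bonds$to[i]] <- bsum[bonds$to[i]] + o
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    if (hfixed[i] >= 0L) { out[i] <- hfixed[i]; next }
    v <- .default_valence[[atoms$element[i]]]
    if (is.null(v)) { out[i] <- 0L; next }
    v <- switch(atoms$element[i],
                N = , P = v + atoms$charge[i],
                O = , S = v + atoms$charge[i],
                C = , B = v - abs(atoms$charge[i]),
                v)
    out[i] <- max(0L, as.integer(v - ceiling(bsum[i])))
  }
  out
}

#' Make implicit hydrogens explicit graph atoms
#'
#' Appends one `H` atom and single bond per implicit hydrogen recorded in
#' the `hcount` column, zeroing that column. Conformers must be attached
#' after this call (coordinates are not invented).
#'
#' @param mol a `MoleculeRecord` without conformers.
#' @return The expanded molecule.
#' @export
add_hydrogens <- function(mol) {
  if (length(mol$conformers))
    stop("add hydrogens before attaching conformers")
  if (!"hcount" %in% names(mol$atoms)) return(mol)
  atoms <- mol$atoms; bonds <- mol$bonds
  for (i in seq_len(nrow(mol$atoms))) {
    k <- mol$atoms$hcount[i]
    if (k > 0L) {
      for (j in seq_len(k)) {
        atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                         aromatic = FALSE, hcount = 0L))
        bonds <- rbind(bonds, data.frame(from = i, to = nrow(atoms),
                                         order = 1L, aromatic = FALSE))
      }
      atoms$hcount[i] <- 0L
    }
  }
  molecule_record(mol$id, atoms, bonds, activity = mol$activity)
}
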