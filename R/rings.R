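# Smallest set of smallest rings (SSSR) on the heavy-atom graph.
#
# Candidate rings: for every edge, the shortest cycle through it (BFS with
# that edge removed). Candidates are sorted smallest-first (ties broken by
# canonical atom order) and greedily accepted while linearly independent
# over GF(2) in edge space, until E - V + C rings are collected.

.sssr <- function(mol) {
  hg <- .heavy_graph(mol)
  nv <- length(hg$heavy)
  b <- hg$bonds
  ne <- nrow(b)
  if (nv == 0L || ne == 0L) return(list())
  ncomp <- .n_components(nv, b)
  target <- ne - nv + ncomp
  if (target <= 0L) return(list())
  adj <- vector("list", nv)
  for (i in seq_len(ne)) {
    adj[[b$from[i]]] <- c(adj[[b$from[i]]], i)
    adj[[b$to[i]]] <- c(adj[[b$to[i]]], i)
  }
  other <- function(e, v) if (b$from[e] == v) b$to[e] else b$from[e]
  cand <- list()
  for (e in seq_len(ne)) {
    s <- b$from[e]; t <- b$to[e]
    # BFS s -> t avoiding edge e
    parent <- rep(NA_integer_, nv); pedge <- rep(NA_integer_, nv)
    seen <- logical(nv); seen[s] <- TRUE; queue <- s
    while (length(queue) && !seen[t]) {
      v <- queue[1L]; queue <- queue[-1L]
      for (ei in adj[[v]]) {
        if (ei == e) next
        w <- other(ei, v)
        if (!seen[w]) {
          seen[w] <- TRUE; parent[w] <- v; pedge[w] <- ei
          queue <- c(queue, w)
        }
      }
    }
    if (!seen[t]) next
    path <- t; v <- t
    while (v != s) { v <- parent[v]; path <- c(v, path) }
    cand[[length(cand) + 1L]] <- path   # cycle atom sequence (heavy indices)
  }
  if (!length(cand)) return(list())
  key <- vapply(cand, function(p) paste(sort(p), collapse = ","), "")
  cand <- cand[!duplicated(key)]
  sizes <- lengths(cand)
  ord <- order(sizes, vapply(cand, function(p) paste(sprintf("%06d", sort(p)),
                                                     collapse = ""), ""))
  cand <- cand[ord]
  ekey <- function(p) {
    pairs <- cbind(p, c(p[-1L], p[1L]))
    sort(apply(pairs, 1, function(r) paste(sort(r), collapse = "-")))
  }
  all_edges <- paste(pmin(b$from, b$to), pmax(b$from, b$to), sep = "-")
  # basis kept in reduced row-echelon form over GF(2): each row has a
  # unique pivot column that is zero in every other row
  basis <- matrix(integer(), nrow = 0, ncol = ne)
  pivots <- integer()
  chosen <- list()
  for (p in cand) {
    red <- as.integer(all_edges %in% ekey(p))
    for (r in seq_along(pivots))
      if (red[pivots[r]] == 1L) red <- (red + basis[r, ]) %% 2L
    if (any(red == 1L)) {
      piv <- which(red == 1L)[1L]
      if (nrow(basis))
        for (r in seq_len(nrow(basis)))
          if (basis[r, piv] == 1L) basis[r, ] <- (basis[r, ] + red) %% 2L
      basis <- rbind(basis, red)
      pivots <- c(pivots, piv)
      chosen[[length(chosen) + 1L]] <- hg$heavy[p]  # back to molecule indices
      if (length(chosen) == target) break
    }
  }
  chosen
}

.n_components <- function(nv, bonds) {
  comp <- seq_len(nv)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(nrow(bonds))) {
    a <- find(bonds$from[i]); b2 <- find(bonds$to[i])
    if (a != b2) comp[a] <- b2
  }
  length(unique(vapply(seq_len(nv), find, integer(1))))
}
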