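# Independent oracles.  These deliberately avoid the package's GF(2) and
# search code: cycles are enumerated from spanning-tree fundamental cycles
# with igraph, bases are found by matroid-greedy over the full cycle list,
# and MCES is solved by exhaustive edge-injection search.

# All elementary cycles of a molgraph, as sorted integer edge-index sets.
oracle_all_cycles <- function(mol) {
  ig <- as_ig(mol)
  m <- n_bonds(mol)
  if (m == 0) return(list())
  tree_e <- integer(0)
  # BFS spanning forest
  comp <- igraph::components(ig)$membership
  for (c0 in unique(comp)) {
    vs <- which(comp == c0)
    sub <- igraph::bfs(ig, root = vs[1], unreachable = FALSE, father = TRUE)
    f <- as.integer(sub$father)
    for (v in vs) {
      if (!is.na(f[v]) && f[v] > 0) {
        tree_e <- c(tree_e, igraph::get_edge_ids(ig, c(f[v], v)))
      }
    }
  }
  chords <- setdiff(seq_len(m), tree_e)
  nu <- length(chords)
  stopifnot(nu <= 14)
  tg <- igraph::subgraph_from_edges(ig, tree_e, delete.vertices = FALSE)
  fund <- lapply(chords, function(e) {
    uv <- igraph::ends(ig, e)
    p <- igraph::shortest_paths(tg, from = uv[1], to = uv[2],
                                output = "epath")$epath[[1]]
    # map tree-subgraph edges back to original ids by endpoints
    ends_p <- igraph::ends(tg, p)
    ids <- apply(ends_p, 1, function(r) igraph::get_edge_ids(ig, r))
    sort(c(as.integer(ids), e))
  })
  out <- list()
  for (mask in 1:(2^nu - 1)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(nu - 1))) != 0)
    cnt <- integer(m)
    for (i in sel) cnt[fund[[i]]] <- cnt[fund[[i]]] + 1L
    es <- which(cnt %% 2L == 1L)
    if (length(es) < 3) next
    sub <- igraph::subgraph_from_edges(ig, es, delete.vertices = TRUE)
    if (igraph::count_components(sub) == 1 &&
        all(igraph::degree(sub) == 2)) {
      out[[length(out) + 1L]] <- es
    }
  }
  unique(out)
}

# GF(2) independence bookkeeping on logical vectors (row-reduction).
oracle_gf2_add <- function(rows, v) {
  for (r in rows) {
    p <- which(r)[1]
    if (v[p]) v <- xor(v, r)
  }
  if (!any(v)) return(NULL)
  c(rows, list(v))
}

# Minimum cycle-basis weight via matroid greedy over all elementary cycles.
oracle_min_basis <- function(cycles, m) {
  lens <- vapply(cycles, length, 0L)
  ord <- order(lens, vapply(cycles, paste, "", collapse = ","))
  rows <- list()
  chosen <- integer(0)
  for (i in ord) {
    v <- rep(FALSE, m); v[cycles[[i]]] <- TRUE
    nr <- oracle_gf2_add(rows, v)
    if (!is.null(nr)) {
      rows <- nr
      chosen <- c(chosen, i)
    }
  }
  list(size = length(chosen), weight = sum(lens[chosen]))
}

# Exhaustive MCES: maximum number of edges of a label-consistent common
# edge subgraph with an injective vertex mapping.  Graphs are molgraphs.
oracle_mces_e12 <- function(a, b, vpi = function(x, y) x == y) {
  ea <- a$bonds; eb <- b$bonds
  na <- n_atoms(a); nb <- n_atoms(b)
  best <- 0L
  rec <- function(i, mapAB, mapBA, used_b, count) {
    if (count + (nrow(ea) - i + 1L) <= best) return()
    if (i > nrow(ea)) {
      if (count > best) best <<- count
      return()
    }
    # skip edge i
    rec(i + 1L, mapAB, mapBA, used_b, count)
    u <- ea$from[i]; v <- ea$to[i]
    for (j in seq_len(nrow(eb))) {
      if (used_b[j]) next
      s <- eb$from[j]; t <- eb$to[j]
      for (o in 1:2) {
        bs <- if (o == 1) c(s, t) else c(t, s)
        if (!vpi(a$atoms[u], b$atoms[bs[1]])) next
        if (!vpi(a$atoms[v], b$atoms[bs[2]])) next
        if (mapAB[u] != 0 && mapAB[u] != bs[1]) next
        if (mapAB[v] != 0 && mapAB[v] != bs[2]) next
        if (mapBA[bs[1]] != 0 && mapBA[bs[1]] != u) next
        if (mapBA[bs[2]] != 0 && mapBA[bs[2]] != v) next
        m1 <- mapAB; m2 <- mapBA; ub <- used_b
        m1[u] <- bs[1]; m1[v] <- bs[2]
        m2[bs[1]] <- u; m2[bs[2]] <- v
        ub[j] <- TRUE
        rec(i + 1L, m1, m2, ub, count + 1L)
      }
    }
  }
  rec(1L, integer(na), integer(nb), rep(FALSE, nrow(eb)), 0L)
  best
}

# Union-find connected components of a thresholded pair list.
oracle_components <- function(ids, pairs, alpha) {
  parent <- seq_along(ids)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- pairs[!is.na(pairs$sim) & pairs$sim >= alpha, , drop = FALSE]
  if (nrow(keep)) {
    for (r in seq_len(nrow(keep))) {
      i <- match(keep$id1[r], ids); j <- match(keep$id2[r], ids)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(ids), find, 0L)
  comp <- split(seq_along(ids), roots)
  comp <- comp[vapply(comp, length, 0L) >= 2]
  sizes <- sort(unname(vapply(comp, length, 0L)), decreasing = TRUE)
  dens <- vapply(comp, function(vs) {
    s <- length(vs)
    ne <- sum(match(keep$id1, ids) %in% vs & match(keep$id2, ids) %in% vs)
    ne / (s * (s - 1) / 2)
  }, 0)
  list(n = length(comp), sizes = sizes, densities = unname(dens))
}
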