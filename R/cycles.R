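#' GF(2) cycle-space algebra
#'
#' A cycle (or any edge set) is represented as a sorted integer vector of
#' edge indices over the edge universe of one graph; the binary vector of
#' the field formulation has a 1 exactly at those positions.  `cycle_xor()`
#' is the GF(2) sum: the symmetric difference of the two edge sets, which
#' for two elementary cycles is a union of edge-disjoint cycles.
#'
#' @param c1,c2 Integer vectors of edge indices.
#' @return `cycle_xor()`: sorted integer vector of edge indices.
#' @examples
#' cycle_xor(c(1L, 2L, 3L), c(3L, 4L))   # 1 2 4
#' cycle_xor(1:3, 1:3)                   # integer(0)
#' @export
cycle_xor <- function(c1, c2) {
  sort(c(setdiff(c1, c2), setdiff(c2, c1)))
}

#' Test whether an edge set is one elementary cycle
#'
#' True iff the edges form a connected subgraph in which every incident
#' vertex has degree exactly 2.  The empty set is not a cycle.
#'
#' @param edges Integer vector of edge indices into `g`.
#' @param g A [molgraph] providing the edge universe.
#' @return Logical scalar.
#' @export
is_elementary_cycle <- function(edges, g) {
  if (length(edges) < 3L) return(FALSE)
  ends <- c(g$bonds$from[edges], g$bonds$to[edges])
  deg <- table(ends)
  if (any(deg != 2L)) return(FALSE)
  verts <- as.integer(names(deg))
  adj <- lapply(seq_along(verts), function(i) integer())
  names(adj) <- verts
  for (e in edges) {
    u <- as.character(g$bonds$from[e]); v <- as.character(g$bonds$to[e])
    adj[[u]] <- c(adj[[u]], g$bonds$to[e])
    adj[[v]] <- c(adj[[v]], g$bonds$from[e])
  }
  seen <- rep(FALSE, length(verts))
  names(seen) <- verts
  queue <- verts[1L]
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[as.character(v)]]) {
      wi <- as.character(w)
      if (!seen[wi]) { seen[wi] <- TRUE; queue <- c(queue, w) }
    }
  }
  all(seen)
}

.cycle_key <- function(edges) paste(edges, collapse = ",")

## Reduce `vec` against a list of pivots; basis is a list of edge sets,
## pivots[i] = smallest edge index of basis[[i]] at insertion time.
.gf2_reduce <- function(vec, basis) {
  for (b in basis) {
    if (length(vec) == 0L) break
    if (b[1L] == vec[1L]) vec <- cycle_xor(vec, b)
  }
  vec
}

## Insert into a reduced GF(2) basis kept sorted by pivot; returns NULL if
## dependent, else the updated basis.
.gf2_insert <- function(vec, basis) {
  v <- vec
  repeat {
    if (length(v) == 0L) return(NULL)
    hit <- FALSE
    for (b in basis) {
      if (b[1L] == v[1L]) { v <- cycle_xor(v, b); hit <- TRUE; break }
    }
    if (!hit) break
  }
  c(basis, list(v))
}

## Deterministic BFS shortest-path tree inside one biconnected component.
## Returns parent edge index per vertex (0 = root / unreachable).
.bfs_tree <- function(v0, adj) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  parent_edge <- integer(n)
  dist[v0] <- 0L
  queue <- v0
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    if (is.null(nb) || nrow(nb) == 0L) next
    ord <- order(nb$to)     # smallest-vertex tie-break
    for (i in ord) {
      w <- nb$to[i]
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        parent_edge[w] <- nb$edge[i]
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, parent_edge = parent_edge)
}

.path_edges <- function(v, tree, bonds, v0) {
  out <- integer()
  while (v != v0) {
    e <- tree$parent_edge[v]
    out <- c(out, e)
    v <- if (bonds$from[e] == v) bonds$to[e] else bonds$from[e]
  }
  sort(out)
}

## Horton MCB of one 2-connected component given as an edge-index set.
.horton_component <- function(g, comp_edges) {
  bonds <- g$bonds
  verts <- sort(unique(c(bonds$from[comp_edges], bonds$to[comp_edges])))
  nu <- length(comp_edges) - length(verts) + 1L
  if (nu <= 0L) stop("component is not 2-connected")
  adj <- vector("list", n_atoms(g))
  for (e in comp_edges) {
    u <- bonds$from[e]; v <- bonds$to[e]
    adj[[u]] <- rbind(adj[[u]], data.frame(to = v, edge = e))
    adj[[v]] <- rbind(adj[[v]], data.frame(to = u, edge = e))
  }
  cand <- list(); seen <- character()
  for (v0 in verts) {
    tree <- .bfs_tree(v0, adj)
    paths <- vector("list", n_atoms(g))
    for (e in comp_edges) {
      x <- bonds$from[e]; y <- bonds$to[e]
      if (is.na(tree$dist[x]) || is.na(tree$dist[y])) next
      if (is.null(paths[[x]])) paths[[x]] <- .path_edges(x, tree, bonds, v0)
      if (is.null(paths[[y]])) paths[[y]] <- .path_edges(y, tree, bonds, v0)
      cyc <- cycle_xor(cycle_xor(paths[[x]], paths[[y]]), e)
      if (length(cyc) != tree$dist[x] + tree$dist[y] + 1L) next
      key <- .cycle_key(cyc)
      if (key %in% seen) next
      if (is_elementary_cycle(cyc, g)) {
        seen <- c(seen, key)
        cand[[length(cand) + 1L]] <- cyc
      }
    }
  }
  len <- vapply(cand, length, 0L)
  keys <- vapply(cand, .cycle_key, "")
  cand <- cand[order(len, keys)]
  basis <- list(); chosen <- list()
  for (cyc in cand) {
    nb <- .gf2_insert(cyc, basis)
    if (!is.null(nb)) {
      basis <- nb
      chosen[[length(chosen) + 1L]] <- cyc
      if (length(chosen) == nu) break
    }
  }
  if (length(chosen) != nu) {
    stop("Horton candidate set did not span the cycle space ",
         "(component not 2-connected?)")
  }
  chosen
}

.new_generator <- function(cycles, structural, decomp, j, basis_size, name) {
  cycles <- cycles[order(vapply(cycles, length, 0L),
                         vapply(cycles, .cycle_key, ""))]
  structure(list(cycles = cycles,
                 lengths = vapply(cycles, length, 0L),
                 weight = sum(vapply(cycles, length, 0L)),
                 j = j, basis_size = basis_size,
                 structural = structural, decomp = decomp, name = name),
            class = "cycle_generator")
}

#' Minimum cycle basis of a molecular graph
#'
#' Runs Horton's algorithm on each 2-connected component of the structural
#' graph: every candidate cycle `C(v, xy) = SP(v,x) + SP(v,y) + xy` is
#' enumerated, kept when elementary, and the candidates sorted by length are
#' reduced greedily over GF(2) to `m - n + 1` independent cycles per
#' component.  The basis weight (total length) is unique even when the basis
#' itself is not; canonicality is restored by [canonicalize_generator()].
#'
#' @param g A [molgraph] (the full molecule; its 2-core is taken internally).
#' @return A `cycle_generator` whose cycles are a minimum cycle basis, with
#'   edge indices referring to the structural graph stored in the object.
#' @export
minimum_cycle_basis <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  sg <- structural_graph(g)
  decomp <- biconnected_decomposition(sg)
  cycles <- list()
  for (comp in decomp$components) {
    cycles <- c(cycles, .horton_component(sg, comp))
  }
  .new_generator(cycles, sg, decomp, j = Inf,
                 basis_size = length(cycles), name = g$name)
}

#' Canonical closure of a cycle basis
#'
#' For each pair of generator cycles whose GF(2) sum is a single elementary
#' cycle `c` with `|c| = max(|c_i|, |c_j|)`, `c` is added.  With
#' `closure = "fixpoint"` (default) the pass is repeated, newly added cycles
#' included, until nothing changes, so the result does not depend on the
#' order in which pairs are visited; `"single-pass"` visits only pairs of
#' the original basis once.
#'
#' @param gen A `cycle_generator`, normally from [minimum_cycle_basis()].
#' @param closure `"fixpoint"` or `"single-pass"`.
#' @return A `cycle_generator` containing the canonical generator, sorted by
#'   (length, edge pattern).
#' @export
canonicalize_generator <- function(gen, closure = c("fixpoint", "single-pass")) {
  closure <- match.arg(closure)
  stopifnot(inherits(gen, "cycle_generator"))
  g <- gen$structural
  cycles <- gen$cycles
  keys <- vapply(cycles, .cycle_key, "")
  add_pairs <- function(cycles, keys, i_range, j_max) {
    added <- FALSE
    for (i in i_range) {
      for (jj in seq_len(min(j_max, i - 1L))) {
        ci <- cycles[[i]]; cj <- cycles[[jj]]
        cc <- cycle_xor(ci, cj)
        if (length(cc) != max(length(ci), length(cj))) next
        key <- .cycle_key(cc)
        if (key %in% keys) next
        if (is_elementary_cycle(cc, g)) {
          cycles[[length(cycles) + 1L]] <- cc
          keys <- c(keys, key)
          added <- TRUE
        }
      }
    }
    list(cycles = cycles, keys = keys, added = added)
  }
  if (closure == "single-pass") {
    n0 <- length(cycles)
    res <- add_pairs(cycles, keys, seq_len(n0), n0)
    cycles <- res$cycles
  } else {
    repeat {
      res <- add_pairs(cycles, keys, seq_along(cycles), length(cycles))
      cycles <- res$cycles; keys <- res$keys
      if (!res$added) break
    }
  }
  .new_generator(cycles, g, gen$decomp, j = gen$j,
                 basis_size = gen$basis_size, name = gen$name)
}

#' Restrict a generator to cycles of length at most j
#'
#' The j-hierarchical subset: a minimum cycle basis is hierarchical, so for
#' every `j` its cycles of length <= `j` generate all elementary cycles of
#' length <= `j`.
#'
#' @param gen A `cycle_generator`.
#' @param j Positive bound (>= 3) or `Inf` for no bound.
#' @return A `cycle_generator` with `j_bound` recorded.
#' @export
filter_generator <- function(gen, j = Inf) {
  stopifnot(inherits(gen, "cycle_generator"))
  if (is.finite(j) && j < 3) stop("j must be at least 3 (no shorter cycle exists)")
  keep <- gen$lengths <= j
  .new_generator(gen$cycles[keep], gen$structural, gen$decomp, j = j,
                 basis_size = gen$basis_size, name = gen$name)
}

#' Canonical hierarchical generator of a molecule
#'
#' End-to-end: 2-core, biconnected decomposition, Horton minimum cycle
#' basis per component, canonical closure, then the length-`j` restriction.
#' Two isomorphic molecular graphs yield the same generator regardless of
#' atom numbering.
#'
#' @param g A [molgraph].
#' @param j Cycle-length bound (default unbounded).
#' @param closure Closure policy, see [canonicalize_generator()].
#' @return A `cycle_generator`.
#' @examples
#' hexane_ring <- molgraph(rep("C", 6),
#'   data.frame(from = 1:6, to = c(2:6, 1), type = "single"), "cyclohexane")
#' canonical_generator(hexane_ring)
#' @export
canonical_generator <- function(g, j = Inf,
                                closure = c("fixpoint", "single-pass")) {
  closure <- match.arg(closure)
  mcb <- minimum_cycle_basis(g)
  gen <- canonicalize_generator(mcb, closure = closure)
  filter_generator(gen, j)
}

#' GF(2) span membership
#'
#' Tests whether cycle `c` (an edge set over the generator's structural
#' graph) is generated by the generator, i.e. is a GF(2) sum of some subset
#' of its cycles.
#'
#' @param gen A `cycle_generator`.
#' @param c Integer vector of edge indices.
#' @return Logical scalar.
#' @export
spans_cycle <- function(gen, c) {
  basis <- list()
  for (cyc in gen$cycles) {
    nb <- .gf2_insert(cyc, basis)
    if (!is.null(nb)) basis <- nb
  }
  v <- sort(unique(as.integer(c)))
  length(.gf2_reduce_full(v, basis)) == 0L
}

.gf2_reduce_full <- function(v, basis) {
  repeat {
    if (length(v) == 0L) return(v)
    hit <- FALSE
    for (b in basis) {
      if (b[1L] == v[1L]) { v <- cycle_xor(v, b); hit <- TRUE; break }
    }
    if (!hit) return(v)
  }
}

#' @export
print.cycle_generator <- function(x, ...) {
  jtxt <- if (is.finite(x$j)) paste0(", j = ", x$j) else ""
  cat("<cycle_generator> ", x$name, ": ", length(x$cycles),
      " cycle(s), weight ", x$weight, jtxt, "\n", sep = "")
  if (length(x$cycles)) {
    cat("  lengths:", paste(x$lengths, collapse = " "), "\n")
  }
  invisible(x)
}

## Vertex walk of an elementary cycle, canonically rotated/reflected to
## start at the smallest vertex and proceed towards its smaller neighbour.
.cycle_vertex_walk <- function(edges, g) {
  b <- g$bonds
  vs <- sort(unique(c(b$from[edges], b$to[edges])))
  nb <- lapply(vs, function(v) {
    inc <- edges[b$from[edges] == v | b$to[edges] == v]
    sort(ifelse(b$from[inc] == v, b$to[inc], b$from[inc]))
  })
  names(nb) <- vs
  start <- vs[1L]
  walk <- c(start, min(nb[[as.character(start)]]))
  while (length(walk) < length(vs)) {
    v <- walk[length(walk)]
    nxt <- setdiff(nb[[as.character(v)]], walk[length(walk) - 1L])
    walk <- c(walk, nxt[1L])
  }
  walk
}

#' Serialize a generator to JSON
#'
#' Cycles are written as canonical vertex walks (structural-graph indices)
#' with their lengths; output is deterministic across runs.
#'
#' @param gen A `cycle_generator`.
#' @return A JSON string.
#' @export
generator_to_json <- function(gen) {
  walks <- lapply(gen$cycles, .cycle_vertex_walk, g = gen$structural)
  jsonlite::toJSON(list(molecule = gen$name,
                        j = if (is.finite(gen$j)) gen$j else "unbounded",
                        weight = gen$weight,
                        cycles = lapply(seq_along(walks), function(i) {
                          list(length = gen$lengths[i], vertices = walks[[i]])
                        })),
                   auto_unbox = TRUE, digits = NA)
}
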