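#' Structural graph (2-core) of a molecular graph
#'
#' The structural graph is the maximum subgraph in which every vertex has
#' degree at least 2: vertices of degree < 2 are deleted iteratively until
#' none remain.  It keeps exactly the ring systems plus the isthmus chains
#' connecting them, and may be empty for an acyclic molecule.
#'
#' @param g A [molgraph].
#' @return A `molgraph` (possibly with zero bonds) with attributes
#'   `orig_vertex` and `orig_edge`: integer maps from the indices of the
#'   returned graph back to `g`.  For an acyclic input the result has a
#'   single placeholder-free empty mapping and zero atoms is signalled by
#'   `structural_is_empty()`.
#' @export
structural_graph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  keep <- rep(TRUE, n_atoms(g))
  deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = n_atoms(g))
  alive_edge <- rep(TRUE, n_bonds(g))
  repeat {
    drop <- which(keep & deg < 2L)
    if (length(drop) == 0L) break
    keep[drop] <- FALSE
    for (v in drop) {
      inc <- which(alive_edge & (g$bonds$from == v | g$bonds$to == v))
      if (length(inc)) {
        alive_edge[inc] <- FALSE
        other <- ifelse(g$bonds$from[inc] == v, g$bonds$to[inc],
                        g$bonds$from[inc])
        for (u in other) deg[u] <- deg[u] - 1L
      }
    }
    deg[drop] <- 0L
  }
  ov <- which(keep)
  oe <- which(alive_edge)
  remap <- match(seq_len(n_atoms(g)), ov)
  b <- g$bonds[oe, , drop = FALSE]
  if (length(ov) == 0L) {
    out <- structure(list(atoms = character(), bonds = data.frame(
      from = integer(), to = integer(), type = character()),
      name = g$name), class = "molgraph")
  } else {
    b$from <- remap[b$from]
    b$to <- remap[b$to]
    rownames(b) <- NULL
    out <- molgraph(g$atoms[ov], b, name = g$name)
  }
  attr(out, "orig_vertex") <- ov
  attr(out, "orig_edge") <- oe
  out
}

#' @rdname structural_graph
#' @export
structural_is_empty <- function(g) n_atoms(g) == 0L || n_bonds(g) == 0L

#' Biconnected decomposition
#'
#' Splits the edge set into 2-connected components and isthmus edges.  An
#' isthmus (bridge) is an edge lying on no cycle; equivalently its deletion
#' increases the number of connected components.  Biconnected components
#' containing a single edge are exactly the isthmuses.
#'
#' @param g A [molgraph], normally a structural graph.
#' @return An object of class `bicomp`: list with `components` (list of
#'   integer edge-index vectors, each a 2-connected component with >= 3
#'   edges), `isthmus_edges` (integer vector) and `component_of_edge`
#'   (integer vector over all edges; `0` marks an isthmus).
#' @export
biconnected_decomposition <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  m <- n_bonds(g)
  comp_of <- integer(m)
  comps <- list()
  isthmus <- integer()
  if (m > 0L) {
    bc <- igraph::biconnected_components(as_igraph(g))
    k <- 0L
    for (ce in bc$component_edges) {
      ids <- sort(as.integer(ce))
      if (length(ids) == 1L) {
        isthmus <- c(isthmus, ids)
      } else {
        k <- k + 1L
        comps[[k]] <- ids
        comp_of[ids] <- k
      }
    }
    isthmus <- sort(isthmus)
  }
  structure(list(components = comps, isthmus_edges = isthmus,
                 component_of_edge = comp_of),
            class = "bicomp")
}

#' @export
print.bicomp <- function(x, ...) {
  cat("<bicomp> ", length(x$components), " two-connected component(s), ",
      length(x$isthmus_edges), " isthmus edge(s)\n", sep = "")
  invisible(x)
}
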