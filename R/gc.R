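#' Graph of cycles
#'
#' The graph of cycles of a molecule has one vertex per cycle of the
#' canonical hierarchical generator, labelled by cycle length (`mu`).  Two
#' cycles sharing at least one atom (which covers fused rings and spiro
#' junctions alike) are joined by a type-1 edge (`nu = 1`) labelled by the
#' number of shared bonds
#' (`theta`, 0 when only an atom is shared, as in spiro junctions).  Two
#' cycles of different 2-connected components are joined by a type-2 edge
#' (`nu = 2`) when some path between them uses only bonds lying on no
#' generator cycle (an isthmus chain); `theta` is then the length of the
#' shortest such path.
#'
#' @param g A [molgraph] or a `cycle_generator`.
#' @param j Cycle-length bound passed to [canonical_generator()].
#' @param closure Closure policy for the canonical generator.
#' @param ... Passed to methods.
#' @return An object of class `graph_of_cycles`: list with `mu` (integer
#'   cycle lengths), `cycles` (edge-index sets over the structural graph),
#'   `edges` (data frame `from`, `to`, `nu`, `theta`), `name`, `j`.
#' @examples
#' ring <- molgraph(rep("C", 6),
#'   data.frame(from = 1:6, to = c(2:6, 1), type = "single"), "benzene")
#' graph_of_cycles(ring)
#' @export
graph_of_cycles <- function(g, ...) UseMethod("graph_of_cycles")

#' @rdname graph_of_cycles
#' @export
graph_of_cycles.molgraph <- function(g, j = Inf,
                                     closure = c("fixpoint", "single-pass"),
                                     ...) {
  gen <- canonical_generator(g, j = j, closure = match.arg(closure))
  graph_of_cycles(gen)
}

#' @rdname graph_of_cycles
#' @export
graph_of_cycles.cycle_generator <- function(g, ...) {
  gen <- g
  sg <- gen$structural
  decomp <- gen$decomp
  k <- length(gen$cycles)
  edges <- data.frame(from = integer(), to = integer(), nu = integer(),
                      theta = integer())
  if (k >= 2L) {
    comp_of_cycle <- vapply(gen$cycles, function(cy) {
      decomp$component_of_edge[cy[1L]]
    }, 0L)
    vsets <- lapply(gen$cycles, function(cy) {
      sort(unique(c(sg$bonds$from[cy], sg$bonds$to[cy])))
    })
    cyc_edges <- sort(unique(unlist(gen$cycles)))
    free_edges <- setdiff(seq_len(n_bonds(sg)), cyc_edges)
    free_adj <- .adjacency_list(sg, free_edges)
    for (i in seq_len(k - 1L)) {
      for (jj in (i + 1L):k) {
        shared_v <- intersect(vsets[[i]], vsets[[jj]])
        if (length(shared_v) >= 1L) {
          ## closed cycles: theta = 0 when only an atom is shared (spiro
          ## junctions count here even though a cut vertex separates the
          ## blocks: the cycles are not breakable by cutting a bond)
          theta <- length(intersect(gen$cycles[[i]], gen$cycles[[jj]]))
          edges <- rbind(edges, data.frame(from = i, to = jj, nu = 1L,
                                           theta = theta))
        } else if (comp_of_cycle[i] != comp_of_cycle[jj]) {
          d <- .restricted_distance(vsets[[i]], vsets[[jj]], free_adj,
                                    n_atoms(sg))
          if (!is.na(d)) {
            edges <- rbind(edges, data.frame(from = i, to = jj, nu = 2L,
                                             theta = d))
          }
        }
      }
    }
  }
  structure(list(mu = gen$lengths, cycles = gen$cycles, edges = edges,
                 name = gen$name, j = gen$j, structural = sg),
            class = "graph_of_cycles")
}

.adjacency_list <- function(g, edge_ids) {
  adj <- vector("list", n_atoms(g))
  for (e in edge_ids) {
    u <- g$bonds$from[e]; v <- g$bonds$to[e]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

## Multi-source BFS distance from vertex set A to vertex set B using only
## the adjacency restricted to non-cycle edges; NA when unreachable.
.restricted_distance <- function(a, b, adj, n) {
  dist <- rep(NA_integer_, n)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v %in% b && dist[v] > 0L) next
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        if (w %in% b) return(dist[w])
        queue <- c(queue, w)
      }
    }
  }
  if (length(intersect(a, b))) 0L else NA_integer_
}

#' Number of cycle vertices in a graph of cycles
#' @param gc A `graph_of_cycles`.
#' @return Integer.
#' @export
n_cycles <- function(gc) length(gc$mu)

#' @export
print.graph_of_cycles <- function(x, ...) {
  jtxt <- if (is.finite(x$j)) paste0(" (j = ", x$j, ")") else ""
  cat("<graph_of_cycles> ", x$name, jtxt, ": ", n_cycles(x),
      " cycle(s), ", nrow(x$edges), " edge(s)\n", sep = "")
  if (n_cycles(x)) cat("  mu:", paste(x$mu, collapse = " "), "\n")
  if (nrow(x$edges)) {
    lab <- sprintf("c%d-c%d nu=%d theta=%d", x$edges$from, x$edges$to,
                   x$edges$nu, x$edges$theta)
    cat("  edges:", paste(lab, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.graph_of_cycles <- function(object, ...) {
  print(object)
  if (nrow(object$edges)) {
    cat("  type-1 edges:", sum(object$edges$nu == 1L),
        " type-2 edges:", sum(object$edges$nu == 2L), "\n")
  }
  invisible(object)
}

#' Convert a graph of cycles to igraph
#'
#' Vertices carry `mu`, edges carry `nu` and `theta`.
#'
#' @param gc A `graph_of_cycles`.
#' @return An `igraph` graph.
#' @export
gc_as_igraph <- function(gc) {
  ig <- igraph::make_empty_graph(n = n_cycles(gc), directed = FALSE)
  igraph::V(ig)$mu <- as.integer(gc$mu)
  if (n_cycles(gc) > 0) {
    igraph::V(ig)$name <- paste0("c", seq_len(n_cycles(gc)))
  }
  if (nrow(gc$edges)) {
    ig <- igraph::add_edges(ig, rbind(gc$edges$from, gc$edges$to))
    igraph::E(ig)$nu <- gc$edges$nu
    igraph::E(ig)$theta <- gc$edges$theta
  }
  ig
}

#' Label-aware isomorphism of two graphs of cycles
#'
#' VF2 isomorphism with `mu` as vertex colour and `(nu, theta)` as edge
#' colour: the graphs are isomorphic only if cycle lengths, edge types and
#' edge labels all match.
#'
#' @param a,b `graph_of_cycles` objects.
#' @return Logical scalar.
#' @export
gc_isomorphic <- function(a, b) {
  stopifnot(inherits(a, "graph_of_cycles"), inherits(b, "graph_of_cycles"))
  if (n_cycles(a) != n_cycles(b)) return(FALSE)
  if (!identical(sort(a$mu), sort(b$mu))) return(FALSE)
  if (nrow(a$edges) != nrow(b$edges)) return(FALSE)
  if (n_cycles(a) == 0L) return(TRUE)
  vcol <- function(gc) match(gc$mu, sort(unique(c(a$mu, b$mu))))
  ecodes <- sort(unique(c(paste(a$edges$nu, a$edges$theta),
                          paste(b$edges$nu, b$edges$theta))))
  ecol <- function(gc) {
    if (nrow(gc$edges) == 0L) return(integer())
    match(paste(gc$edges$nu, gc$edges$theta), ecodes)
  }
  igraph::isomorphic(gc_as_igraph(a), gc_as_igraph(b), method = "vf2",
                     vertex.color1 = vcol(a), vertex.color2 = vcol(b),
                     edge.color1 = ecol(a), edge.color2 = ecol(b))
}

#' Serialize a graph of cycles
#'
#' `gc_to_json()` returns a JSON string; `write_gc_graphml()` and
#' `write_gc_dot()` write GraphML / DOT files with `mu`, `nu`, `theta`
#' attributes for visual inspection.
#'
#' @param gc A `graph_of_cycles`.
#' @param path Output file.
#' @return JSON string, or `path` invisibly for the writers.
#' @export
gc_to_json <- function(gc) {
  jsonlite::toJSON(list(molecule = gc$name,
                        j = if (is.finite(gc$j)) gc$j else "unbounded",
                        mu = as.integer(gc$mu), edges = gc$edges),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname gc_to_json
#' @export
write_gc_graphml <- function(gc, path) {
  igraph::write_graph(gc_as_igraph(gc), path, format = "graphml")
  invisible(path)
}

#' @rdname gc_to_json
#' @export
write_gc_dot <- function(gc, path) {
  igraph::write_graph(gc_as_igraph(gc), path, format = "dot")
  invisible(path)
}

#' Plot a graph of cycles
#'
#' Cycle vertices are labelled by length; type-1 edges are solid, type-2
#' edges dashed, both labelled by `theta`.
#'
#' @param x A `graph_of_cycles`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.graph_of_cycles <- function(x, ...) {
  ig <- gc_as_igraph(x)
  elty <- if (nrow(x$edges)) ifelse(x$edges$nu == 1L, 1, 2) else NULL
  igraph::plot.igraph(ig, vertex.label = x$mu,
                      edge.label = if (nrow(x$edges)) x$edges$theta else NULL,
                      edge.lty = elty, vertex.size = 24,
                      vertex.color = "lightsteelblue", ...)
  invisible(x)
}
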