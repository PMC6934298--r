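#' Vertex compatibility predicates
#'
#' `pi_molecular()` allows two atoms to correspond iff their element symbols
#' are equal.  `pi_cycles()` allows two cycles to correspond iff their
#' lengths differ by at most `tol * min(length_a, length_b)`; the default
#' tolerance 0.2 lets a 5-ring match a 6-ring but not a 6-ring an 8-ring.
#'
#' @param label_a,label_b Element symbols.
#' @return Logical scalar.
#' @examples
#' pi_molecular("C", "N")   # FALSE
#' pi_cycles(5, 6)          # TRUE:  |5-6| <= 0.2 * 5
#' pi_cycles(6, 8)          # FALSE: 2 > 0.2 * 6
#' @export
pi_molecular <- function(label_a, label_b) {
  as.character(label_a) == as.character(label_b)
}

#' @rdname pi_molecular
#' @param len_a,len_b Cycle lengths (positive).
#' @param tol Relative length tolerance.
#' @export
pi_cycles <- function(len_a, len_b, tol = 0.2) {
  if (any(c(len_a, len_b) <= 0)) stop("cycle lengths must be positive")
  abs(len_a - len_b) <= tol * pmin(len_a, len_b)
}

#' Compatibility rules for MCES
#'
#' Bundles the vertex predicate and the edge-label predicate used when two
#' graphs are compared.  In `"molecular"` mode vertices are atoms matched by
#' element and bond labels are ignored unless `match_bonds = TRUE`.  In
#' `"cycles"` mode vertices are cycles matched by [pi_cycles()] length
#' tolerance; matched edges must have equal type `nu`, and `theta` must be
#' equal (`theta_match = "strict"`, the default, required for similarity 1
#' on isomer pairs) or within 1 (`"relaxed"`).
#'
#' @param mode `"molecular"` or `"cycles"`.
#' @param tol Length tolerance for `pi_cycles`.
#' @param theta_match `"strict"` or `"relaxed"`.
#' @param match_bonds Require equal bond labels in molecular mode.
#' @return An object of class `compatibility_rule` with function fields
#'   `vertex_pi(la, lb)` and `edge_compat(ea, eb)`.
#' @export
compatibility_rule <- function(mode = c("molecular", "cycles"), tol = 0.2,
                               theta_match = c("strict", "relaxed"),
                               match_bonds = FALSE) {
  mode <- match.arg(mode)
  theta_match <- match.arg(theta_match)
  if (mode == "molecular") {
    vertex_pi <- function(la, lb) pi_molecular(la, lb)
    edge_compat <- if (match_bonds) {
      function(ea, eb) identical(ea$bond, eb$bond)
    } else {
      function(ea, eb) TRUE
    }
  } else {
    vertex_pi <- function(la, lb) pi_cycles(as.numeric(la), as.numeric(lb),
                                            tol = tol)
    edge_compat <- if (theta_match == "strict") {
      function(ea, eb) ea$nu == eb$nu && ea$theta == eb$theta
    } else {
      function(ea, eb) ea$nu == eb$nu && abs(ea$theta - eb$theta) <= 1
    }
  }
  structure(list(vertex_pi = vertex_pi, edge_compat = edge_compat,
                 mode = mode, tol = tol, theta_match = theta_match,
                 match_bonds = match_bonds),
            class = "compatibility_rule")
}

## ---- internal labelled-graph container -----------------------------------
## vlab: per-vertex label (element symbol or cycle length)
## edges: data.frame(from, to); elab: list of per-edge label objects
.lgraph <- function(vlab, edges, elab, name = "") {
  list(vlab = vlab, edges = edges, elab = elab, name = name,
       n = length(vlab), m = nrow(edges))
}

#' Internal labelled-graph view used by the MCES solver
#'
#' @param x A [molgraph] or `graph_of_cycles`.
#' @param core_only For molecular graphs: keep only the 2-connected part
#'   (leaves and isthmus chains removed before comparison).
#' @param ... Unused.
#' @return An opaque list understood by [mces()].
#' @export
as_lgraph <- function(x, ...) UseMethod("as_lgraph")

#' @rdname as_lgraph
#' @export
as_lgraph.molgraph <- function(x, core_only = FALSE, ...) {
  g <- if (core_only) biconnected_core(x) else x
  elab <- lapply(seq_len(n_bonds(g)), function(i) list(bond = g$bonds$type[i]))
  .lgraph(g$atoms, g$bonds[, c("from", "to")], elab, name = g$name)
}

#' @rdname as_lgraph
#' @export
as_lgraph.graph_of_cycles <- function(x, ...) {
  elab <- lapply(seq_len(nrow(x$edges)), function(i) {
    list(nu = x$edges$nu[i], theta = x$edges$theta[i])
  })
  .lgraph(as.numeric(x$mu), x$edges[, c("from", "to")], elab, name = x$name)
}

#' Two-connected core of a molecular graph
#'
#' The 2-core with isthmus edges (and the degree-0 vertices this leaves)
#' removed: exactly the union of the 2-connected components, the part of
#' the molecule compared by molecular-graph MCES.
#'
#' @param g A [molgraph].
#' @return A `molgraph`.
#' @export
biconnected_core <- function(g) {
  sg <- structural_graph(g)
  if (structural_is_empty(sg)) return(sg)
  decomp <- biconnected_decomposition(sg)
  keep_e <- sort(unlist(decomp$components))
  b <- sg$bonds[keep_e, , drop = FALSE]
  keep_v <- sort(unique(c(b$from, b$to)))
  remap <- match(seq_len(n_atoms(sg)), keep_v)
  b$from <- remap[b$from]; b$to <- remap[b$to]
  rownames(b) <- NULL
  out <- molgraph(sg$atoms[keep_v], b, name = sg$name)
  out
}

#' Line graph of a labelled graph
#'
#' Vertices of the result are the edges of the input (keeping the source
#' edge label and its endpoint labels); two line-graph vertices are adjacent
#' iff the underlying edges share an endpoint.
#'
#' @param x A [molgraph] or `graph_of_cycles`.
#' @return An `igraph` graph with vertex attributes `elabel` (serialized
#'   edge label) and `ends` (endpoint labels).
#' @export
line_graph <- function(x) {
  lg <- as_lgraph(x)
  ig <- igraph::make_empty_graph(n = lg$m, directed = FALSE)
  if (lg$m > 0) {
    igraph::V(ig)$elabel <- vapply(lg$elab, function(e) {
      paste(unlist(e), collapse = "/")
    }, "")
    igraph::V(ig)$ends <- paste(lg$vlab[lg$edges$from],
                                lg$vlab[lg$edges$to], sep = "-")
    if (lg$m > 1) {
      pairs <- utils::combn(lg$m, 2)
      sel <- apply(pairs, 2, function(p) {
        length(intersect(c(lg$edges$from[p[1]], lg$edges$to[p[1]]),
                         c(lg$edges$from[p[2]], lg$edges$to[p[2]]))) > 0
      })
      if (any(sel)) ig <- igraph::add_edges(ig, pairs[, sel, drop = FALSE])
    }
  }
  ig
}

#' Compatibility product of two labelled graphs
#'
#' The modular product of the two line graphs that the clique reduction of
#' MCES needs: vertices are pairs (edge of A, edge of B) with compatible
#' edge labels and pairable endpoints; two pairs are adjacent iff their A
#' edges share exactly as many endpoints as their B edges do, with any
#' shared endpoints compatible and the induced endpoint correspondence
#' orientation-consistent.
#'
#' @param a,b Labelled graphs from [as_lgraph()] (or objects convertible
#'   via it).
#' @param rule A [compatibility_rule()].
#' @return List with `pairs` (data frame `ea`, `eb`, `ok1`, `ok2`) and
#'   `adj` (logical adjacency matrix).
#' @export
compatibility_product <- function(a, b, rule) {
  if (!is.list(a) || is.null(a$vlab)) a <- as_lgraph(a)
  if (!is.list(b) || is.null(b$vlab)) b <- as_lgraph(b)
  vpi <- rule$vertex_pi
  pairs <- list()
  for (i in seq_len(a$m)) {
    a1 <- a$vlab[a$edges$from[i]]; a2 <- a$vlab[a$edges$to[i]]
    for (j in seq_len(b$m)) {
      if (!rule$edge_compat(a$elab[[i]], b$elab[[j]])) next
      b1 <- b$vlab[b$edges$from[j]]; b2 <- b$vlab[b$edges$to[j]]
      ok1 <- vpi(a1, b1) && vpi(a2, b2)
      ok2 <- vpi(a1, b2) && vpi(a2, b1)
      if (ok1 || ok2) {
        pairs[[length(pairs) + 1L]] <- c(i, j, ok1, ok2)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(list(pairs = data.frame(ea = integer(), eb = integer(),
                                   ok1 = logical(), ok2 = logical()),
                adj = matrix(FALSE, 0, 0), a = a, b = b))
  }
  pv <- do.call(rbind, pairs)
  pairs <- data.frame(ea = pv[, 1], eb = pv[, 2],
                      ok1 = as.logical(pv[, 3]), ok2 = as.logical(pv[, 4]))
  np <- nrow(pairs)
  adj <- matrix(FALSE, np, np)
  ea_ends <- cbind(a$edges$from[pairs$ea], a$edges$to[pairs$ea])
  eb_ends <- cbind(b$edges$from[pairs$eb], b$edges$to[pairs$eb])
  for (p in seq_len(np - 1L)) {
    for (q in (p + 1L):np) {
      if (pairs$ea[p] == pairs$ea[q] || pairs$eb[p] == pairs$eb[q]) next
      sa <- intersect(ea_ends[p, ], ea_ends[q, ])
      sb <- intersect(eb_ends[p, ], eb_ends[q, ])
      if (length(sa) != length(sb)) next
      if (length(sa) == 0L) {
        adj[p, q] <- adj[q, p] <- TRUE
      } else {
        u <- sa[1L]; w <- sb[1L]
        if (!vpi(a$vlab[u], b$vlab[w])) next
        xp <- setdiff(ea_ends[p, ], u); xq <- setdiff(ea_ends[q, ], u)
        sp <- setdiff(eb_ends[p, ], w); sq <- setdiff(eb_ends[q, ], w)
        if (vpi(a$vlab[xp], b$vlab[sp]) && vpi(a$vlab[xq], b$vlab[sq])) {
          adj[p, q] <- adj[q, p] <- TRUE
        }
      }
    }
  }
  list(pairs = pairs, adj = adj, a = a, b = b)
}

## ---- exact branch-and-bound maximum clique --------------------------------

## Greedy colouring upper bound; returns colours of `P` (ascending).
.colour_bound <- function(P, adj) {
  cols <- integer(length(P))
  for (i in seq_along(P)) {
    used <- cols[which(adj[P[seq_len(i - 1L)], P[i]])]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    cols[i] <- c0
  }
  cols
}

.bb_clique <- function(adj, time_limit, eval_clique) {
  n <- nrow(adj)
  state <- new.env(parent = emptyenv())
  state$best_e <- 0L
  state$best_v <- 0L
  state$best <- integer()
  state$timeout <- FALSE
  t0 <- proc.time()[["elapsed"]]
  expand <- function(C, P) {
    if (state$timeout) return()
    if (proc.time()[["elapsed"]] - t0 > time_limit) {
      state$timeout <- TRUE
      return()
    }
    if (length(P) == 0L) return()
    ord <- order(colSums(adj[P, P, drop = FALSE]))
    P <- P[ord]
    cols <- .colour_bound(P, adj)
    ord2 <- order(cols)          # ascending colours: cols[i] bounds the
    P <- P[ord2]                 # clique number of P[1..i]
    cols <- cols[ord2]
    for (i in rev(seq_along(P))) {
      if (length(C) + cols[i] < state$best_e) return()
      v <- P[i]
      C2 <- c(C, v)
      eval_clique(C2, state)
      P2 <- P[seq_len(i - 1L)][adj[v, P[seq_len(i - 1L)]]]
      if (length(P2)) expand(C2, P2)
      if (state$timeout) return()
    }
  }
  if (n > 0L) expand(integer(), seq_len(n))
  state
}

#' Exact maximum clique
#'
#' Branch-and-bound with a greedy-colouring bound.  When the time limit is
#' hit the best clique found so far is returned with status
#' `"timeout-best-found"`.
#'
#' @param g An `igraph` graph, or a logical/0-1 adjacency matrix.
#' @param time_limit Seconds.
#' @return List with `vertices` (integer clique) and `status`
#'   (`"optimal"` or `"timeout-best-found"`).
#' @examples
#' max_clique(igraph::make_full_graph(5))$vertices
#' @export
max_clique <- function(g, time_limit = 20) {
  stopifnot(time_limit > 0)
  adj <- if (igraph::is_igraph(g)) {
    as.matrix(igraph::as_adjacency_matrix(g)) > 0
  } else {
    as.matrix(g) > 0
  }
  diag(adj) <- FALSE
  st <- .bb_clique(adj, time_limit, function(C, state) {
    if (length(C) > state$best_e) {
      state$best_e <- length(C)
      state$best <- C
    }
  })
  if (nrow(adj) >= 1L && st$best_e == 0L) {
    st$best <- 1L
    st$best_e <- 1L
  }
  list(vertices = st$best,
       status = if (st$timeout) "timeout-best-found" else "optimal")
}

## Orientation-consistent vertex mapping for a clique of edge pairs.
## Returns NULL when no consistent injective mapping exists, else the
## mapping as a two-column matrix (va, vb).
.orient_clique <- function(members, prod) {
  pr <- prod$pairs[members, , drop = FALSE]
  k <- nrow(pr)
  a <- prod$a; b <- prod$b
  ends_a <- cbind(a$edges$from[pr$ea], a$edges$to[pr$ea])
  ends_b <- cbind(b$edges$from[pr$eb], b$edges$to[pr$eb])
  ## order members so that each (after the first of its block) shares an
  ## A endpoint with an earlier one: orientations become forced.
  ord <- integer(0); left <- seq_len(k)
  while (length(left)) {
    ord <- c(ord, left[1L]); left <- left[-1L]
    repeat {
      hit <- which(vapply(left, function(i) {
        any(ends_a[i, ] %in% ends_a[ord, ])
      }, TRUE))
      if (!length(hit)) break
      ord <- c(ord, left[hit[1L]]); left <- left[-hit[1L]]
    }
  }
  mapAB <- integer(a$n); mapBA <- integer(b$n)
  try_assign <- function(i, mapAB, mapBA) {
    if (i > k) return(list(mapAB = mapAB, mapBA = mapBA))
    id <- ord[i]
    for (o in 1:2) {
      if (o == 1L && !pr$ok1[id]) next
      if (o == 2L && !pr$ok2[id]) next
      av <- ends_a[id, ]
      bv <- if (o == 1L) ends_b[id, ] else ends_b[id, 2:1]
      ok <- TRUE
      for (t in 1:2) {
        u <- av[t]; w <- bv[t]
        if ((mapAB[u] != 0L && mapAB[u] != w) ||
            (mapBA[w] != 0L && mapBA[w] != u)) { ok <- FALSE; break }
      }
      if (!ok) next
      m1 <- mapAB; m2 <- mapBA
      m1[av] <- bv; m2[bv] <- av
      res <- try_assign(i + 1L, m1, m2)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- try_assign(1L, mapAB, mapBA)
  if (is.null(res)) return(NULL)
  va <- which(res$mapAB != 0L)
  cbind(va = va, vb = res$mapAB[va])
}

#' Similarity degree of a common subgraph
#'
#' `sim = (|V12| + |E12|)^2 / ((|V1| + |E1|) * (|V2| + |E2|))`, in `[0, 1]`,
#' equal to 1 exactly when both graphs are fully matched.
#'
#' @param v12,e12 Matched vertex and edge counts.
#' @param n1,m1,n2,m2 Vertex/edge counts of the two graphs.
#' @return Numeric scalar.
#' @export
similarity_degree <- function(v12, e12, n1, m1, n2, m2) {
  denom <- (n1 + m1) * (n2 + m2)
  if (denom == 0) return(0)
  (v12 + e12)^2 / denom
}

## Maximum compatible vertex matching (Kuhn augmenting paths) for the
## degenerate case where one side has no edges.
.max_vertex_matching <- function(a, b, vpi) {
  matchB <- integer(b$n)
  aug <- function(u, seen) {
    for (w in seq_len(b$n)) {
      if (!seen[w] && vpi(a$vlab[u], b$vlab[w])) {
        seen[w] <- TRUE
        if (matchB[w] == 0L) {
          matchB[w] <<- u
          return(TRUE)
        }
        old <- matchB[w]
        matchB[w] <<- u
        if (aug(old, seen)) return(TRUE)
        matchB[w] <<- old
      }
    }
    FALSE
  }
  for (u in seq_len(a$n)) aug(u, rep(FALSE, b$n))
  sum(matchB != 0L)
}

#' Maximum common edge subgraph of two labelled graphs
#'
#' Solves MCES exactly by searching for a maximum clique in the
#' compatibility product of the two line graphs; every clique considered is
#' converted back to an edge correspondence and accepted only when it
#' induces a consistent injective vertex mapping.  Among subgraphs with the
#' maximum number of edges the one with the larger vertex count (hence the
#' larger similarity degree) is reported.
#'
#' @param a,b [molgraph] or `graph_of_cycles` objects (or prebuilt lgraphs).
#' @param rule A [compatibility_rule()]; defaults to the mode matching the
#'   input class.
#' @param time_limit Seconds per comparison; on expiry the best common
#'   subgraph found so far is reported with status `"timeout-best-found"`.
#' @return An object of class `mces_result`: `edge_pairs` (data frame of
#'   matched edge indices), `vertex_map`, `v12`, `e12`, `similarity`,
#'   `status`, `elapsed`.
#' @export
mces <- function(a, b, rule = NULL, time_limit = 20) {
  stopifnot(time_limit > 0)
  t0 <- proc.time()[["elapsed"]]
  if (is.null(rule)) {
    mode <- if (inherits(a, "graph_of_cycles")) "cycles" else "molecular"
    rule <- compatibility_rule(mode)
  }
  la <- if (is.list(a) && !is.null(a$vlab)) a else as_lgraph(a)
  lb <- if (is.list(b) && !is.null(b$vlab)) b else as_lgraph(b)
  empty_result <- function(sim, v12 = 0L, e12 = 0L, status = "optimal",
                           vmap = NULL) {
    structure(list(edge_pairs = data.frame(edge_a = integer(),
                                           edge_b = integer()),
                   vertex_map = vmap, v12 = v12, e12 = e12,
                   similarity = sim, status = status,
                   elapsed = proc.time()[["elapsed"]] - t0,
                   a = la$name, b = lb$name),
              class = "mces_result")
  }
  if (la$n == 0L || lb$n == 0L) {
    warning("empty graph in MCES comparison; similarity set to 0")
    return(empty_result(0))
  }
  if (la$m == 0L || lb$m == 0L) {
    v12 <- .max_vertex_matching(la, lb, rule$vertex_pi)
    sim <- similarity_degree(v12, 0L, la$n, la$m, lb$n, lb$m)
    return(empty_result(sim, v12 = v12))
  }
  prod <- compatibility_product(la, lb, rule)
  if (nrow(prod$pairs) == 0L) return(empty_result(0))
  best <- new.env(parent = emptyenv())
  best$members <- integer(); best$map <- NULL
  st <- .bb_clique(prod$adj, time_limit, function(C, state) {
    if (length(C) < state$best_e) return()
    map <- .orient_clique(C, prod)
    if (is.null(map)) return()
    v12 <- nrow(map)
    if (length(C) > state$best_e ||
        (length(C) == state$best_e && v12 > state$best_v)) {
      state$best_e <- length(C)
      state$best_v <- v12
      state$best <- C
      best$members <- C
      best$map <- map
    }
  })
  if (st$best_e == 0L) {
    ## a single compatible edge pair always exists here
    map <- .orient_clique(1L, prod)
    st$best <- 1L; st$best_e <- 1L
    best$members <- 1L; best$map <- map
    st$best_v <- nrow(map)
  }
  pr <- prod$pairs[best$members, , drop = FALSE]
  sim <- similarity_degree(st$best_v, st$best_e, la$n, la$m, lb$n, lb$m)
  structure(list(edge_pairs = data.frame(edge_a = pr$ea, edge_b = pr$eb),
                 vertex_map = best$map,
                 v12 = st$best_v, e12 = st$best_e, similarity = sim,
                 status = if (st$timeout) "timeout-best-found" else "optimal",
                 elapsed = proc.time()[["elapsed"]] - t0,
                 a = la$name, b = lb$name),
            class = "mces_result")
}

#' @export
print.mces_result <- function(x, ...) {
  cat("<mces_result> ", x$a, " vs ", x$b, ": sim = ",
      format(x$similarity, digits = 4), " (|V12| = ", x$v12, ", |E12| = ",
      x$e12, ", ", x$status, ", ", format(x$elapsed, digits = 3), " s)\n",
      sep = "")
  invisible(x)
}

#' Graph-of-cycles similarity of two molecules
#'
#' Builds (or reuses) the canonical graphs of cycles of the two molecules
#' and returns the MCES similarity degree between them.  Identical graphs
#' of cycles short-circuit to similarity 1.
#'
#' @param a,b [molgraph] or `graph_of_cycles` objects.
#' @param j Cycle-length bound.
#' @param tol Cycle-length match tolerance.
#' @param theta_match `"strict"` or `"relaxed"`.
#' @param time_limit Seconds.
#' @param closure Closure policy for the canonical generator.
#' @return An `mces_result`.
#' @export
gc_similarity <- function(a, b, j = Inf, tol = 0.2,
                          theta_match = c("strict", "relaxed"),
                          time_limit = 20,
                          closure = c("fixpoint", "single-pass")) {
  theta_match <- match.arg(theta_match)
  closure <- match.arg(closure)
  gca <- if (inherits(a, "graph_of_cycles")) a else
    graph_of_cycles(a, j = j, closure = closure)
  gcb <- if (inherits(b, "graph_of_cycles")) b else
    graph_of_cycles(b, j = j, closure = closure)
  rule <- compatibility_rule("cycles", tol = tol, theta_match = theta_match)
  if (identical(gca[c("mu", "edges")], gcb[c("mu", "edges")]) &&
      n_cycles(gca) > 0L) {
    res <- structure(list(edge_pairs = data.frame(
      edge_a = seq_len(nrow(gca$edges)), edge_b = seq_len(nrow(gcb$edges))),
      vertex_map = cbind(va = seq_len(n_cycles(gca)),
                         vb = seq_len(n_cycles(gcb))),
      v12 = n_cycles(gca), e12 = nrow(gca$edges), similarity = 1,
      status = "optimal", elapsed = 0, a = gca$name, b = gcb$name),
      class = "mces_result")
    return(res)
  }
  mces(gca, gcb, rule = rule, time_limit = time_limit)
}

#' Molecular-graph similarity of two molecules
#'
#' MCES similarity on the molecular graphs themselves.  Following the
#' structural-comparison convention, leaves and isthmus chains are removed
#' first (`core_only = TRUE`) so that only the 2-connected part is compared.
#'
#' @param a,b [molgraph] objects.
#' @param core_only Compare only the union of 2-connected components.
#' @param match_bonds Require equal bond labels on matched bonds.
#' @param time_limit Seconds.
#' @return An `mces_result`.
#' @export
mg_similarity <- function(a, b, core_only = TRUE, match_bonds = FALSE,
                          time_limit = 20) {
  la <- as_lgraph(a, core_only = core_only)
  lb <- as_lgraph(b, core_only = core_only)
  rule <- compatibility_rule("molecular", match_bonds = match_bonds)
  mces(la, lb, rule = rule, time_limit = time_limit)
}

#' Tanimoto coefficient of two fragment sets
#'
#' `|F12| / (|F1| + |F2| - |F12|)` over fragment identifier sets (presence
#' only, multiplicity ignored).  Fragment/fingerprint generation is
#' delegated to an external toolkit; any vector of hashable identifiers
#' works.  Two empty sets give 0 by convention.
#'
#' @param f1,f2 Vectors of fragment identifiers.
#' @return Numeric in `[0, 1]`.
#' @examples
#' tanimoto(1:4, 3:8)   # 2 / 8
#' @export
tanimoto <- function(f1, f2) {
  f1 <- unique(f1); f2 <- unique(f2)
  inter <- length(intersect(f1, f2))
  denom <- length(f1) + length(f2) - inter
  if (denom == 0L) return(0)
  inter / denom
}

#' Atom-pair fragment sets from an SDF set
#'
#' Convenience wrapper generating fragment identifier sets with
#' \pkg{ChemmineR} atom-pair descriptors, for use with [tanimoto()].
#'
#' @param sdfset A `ChemmineR::SDFset`.
#' @return A list of integer fragment-identifier vectors.
#' @export
sdf_fragment_sets <- function(sdfset) {
  apset <- ChemmineR::sdf2ap(sdfset)
  lapply(ChemmineR::ap(apset), unique)
}
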