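#' Synthetic fused-ring molecule generator
#'
#' Builds reproducible molecule-like labelled graphs for testing: a first
#' ring, then further rings attached edge-fused (sharing one bond), spiro
#' (sharing one atom), bridged (sharing a two-bond path) or isthmus-linked
#' (joined by a chain of the given length), optionally decorated with leaf
#' atoms.  By construction every added ring raises the cyclomatic number by
#' exactly one, so the intended ring count equals the minimum-cycle-basis
#' size, which is recorded as ground truth.
#'
#' @param n_rings Number of rings.
#' @param ring_sizes Integer vector sampled from for each ring size
#'   (default 5:7, the common ring sizes of organic ring systems).
#' @param fusion_weights Named weights for modes `edge`, `spiro`, `bridge`,
#'   `isthmus`.
#' @param link_length Chain length for isthmus-linked attachments.
#' @param decoration Expected number of leaf atoms added per ring atom.
#' @param elements Element symbols sampled for vertices (carbon-biased).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param name Molecule name.
#' @return A [molgraph] with attribute `ground_truth`: list with
#'   `n_rings`, `ring_sizes`, `modes`.
#' @examples
#' m <- generate_molecule(3, ring_sizes = 6, seed = 1)
#' attr(m, "ground_truth")$n_rings
#' @export
generate_molecule <- function(n_rings, ring_sizes = 5:7,
                              fusion_weights = c(edge = 3, spiro = 1,
                                                 bridge = 1, isthmus = 1),
                              link_length = 2L, decoration = 0,
                              elements = c("C", "C", "C", "C", "N", "O"),
                              seed = 1L, name = NULL) {
  if (n_rings < 1L) stop("infeasible spec: need at least one ring")
  if (any(ring_sizes < 3L)) stop("infeasible spec: ring size below 3")
  rng <- .fixture_rng(seed)
  pick <- function(x) x[1L + rng() %% length(x)]
  if (is.null(name)) name <- paste0("fixture", seed)
  sizes <- integer(n_rings)
  modes <- character(n_rings)
  sizes[1L] <- pick(ring_sizes)
  modes[1L] <- "first"
  atoms <- character(0)
  bonds <- data.frame(from = integer(), to = integer(), type = character())
  new_atom <- function() {
    atoms[length(atoms) + 1L] <<- pick(elements)
    length(atoms)
  }
  bond_types <- c("single", "single", "double", "aromatic")
  add_bond <- function(u, v) {
    bonds[nrow(bonds) + 1L, ] <<- list(u, v, pick(bond_types))
  }
  ## first ring
  vs <- replicate(sizes[1L], new_atom())
  for (i in seq_along(vs)) add_bond(vs[i], vs[if (i == length(vs)) 1L else i + 1L])
  ring_atoms <- list(vs)
  mode_names <- names(fusion_weights)[fusion_weights > 0]
  wts <- fusion_weights[fusion_weights > 0]
  for (r in seq_len(n_rings)[-1L]) {
    s <- pick(ring_sizes)
    sizes[r] <- s
    draw <- rng() %% sum(wts)
    mode <- mode_names[min(which(cumsum(wts) > draw))]
    host <- ring_atoms[[1L + rng() %% length(ring_atoms)]]
    if (mode == "edge") {
      i0 <- 1L + rng() %% length(host)
      u <- host[i0]; v <- host[if (i0 == length(host)) 1L else i0 + 1L]
      path <- replicate(s - 2L, new_atom())
      chain <- c(u, path, v)
      for (i in seq_len(length(chain) - 1L)) add_bond(chain[i], chain[i + 1L])
      ring_atoms[[r]] <- chain
    } else if (mode == "bridge") {
      if (s < 4L) mode <- "spiro"    # a 3-ring cannot share a 2-bond path
    }
    if (mode == "bridge") {
      i0 <- 1L + rng() %% (length(host) - 2L)
      u <- host[i0]; mid <- host[i0 + 1L]; v <- host[i0 + 2L]
      path <- replicate(s - 3L, new_atom())
      chain <- c(u, path, v)
      for (i in seq_len(length(chain) - 1L)) add_bond(chain[i], chain[i + 1L])
      ring_atoms[[r]] <- c(chain, mid)
    } else if (mode == "spiro") {
      u <- host[1L + rng() %% length(host)]
      path <- replicate(s - 1L, new_atom())
      chain <- c(u, path, u)
      for (i in seq_len(length(chain) - 1L)) {
        if (chain[i] != chain[i + 1L] || TRUE) add_bond(chain[i], chain[i + 1L])
      }
      ring_atoms[[r]] <- c(u, path)
    } else if (mode == "isthmus") {
      u <- host[1L + rng() %% length(host)]
      link <- replicate(link_length - 1L, new_atom())
      anchor <- new_atom()
      chain <- c(u, link, anchor)
      for (i in seq_len(length(chain) - 1L)) add_bond(chain[i], chain[i + 1L])
      path <- replicate(s - 1L, new_atom())
      ring <- c(anchor, path)
      for (i in seq_along(ring)) {
        add_bond(ring[i], ring[if (i == length(ring)) 1L else i + 1L])
      }
      ring_atoms[[r]] <- ring
    }
    if (modes[r] == "" || is.na(modes[r])) modes[r] <- mode
    modes[r] <- mode
  }
  if (decoration > 0) {
    n_core <- length(atoms)
    for (v in seq_len(n_core)) {
      if ((rng() %% 1000L) < decoration * 1000L) {
        w <- new_atom()
        add_bond(v, w)
      }
    }
  }
  g <- molgraph(atoms, bonds, name = name)
  attr(g, "ground_truth") <- list(n_rings = n_rings, ring_sizes = sizes,
                                  modes = modes)
  g
}

## Small deterministic linear-congruential generator so fixtures do not
## disturb (or depend on) R's global RNG stream.
.fixture_rng <- function(seed) {
  state <- as.integer(seed %% 2147483647L)
  if (state <= 0L) state <- state + 2147483646L
  function() {
    state <<- as.integer((16807 * as.double(state)) %% 2147483647)
    state
  }
}

#' Random simple connected graph as a molecule-like fixture
#'
#' Uniform-ish random connected simple graph with `n` vertices and `m`
#' edges (a random spanning tree plus random chords), all atoms carbon and
#' all bonds single; used to exercise the cycle-space machinery on
#' topologies beyond fused-ring systems.
#'
#' @param n,m Vertex and edge counts (`m >= n - 1`).
#' @param seed Integer seed.
#' @return A [molgraph].
#' @export
random_graph_molecule <- function(n, m, seed = 1L) {
  stopifnot(n >= 2L, m >= n - 1L, m <= n * (n - 1L) / 2L)
  rng <- .fixture_rng(seed)
  edges <- matrix(0L, 0, 2)
  for (v in 2:n) {
    u <- 1L + rng() %% (v - 1L)
    edges <- rbind(edges, c(u, v))
  }
  have <- paste(edges[, 1], edges[, 2])
  all_pairs <- t(utils::combn(n, 2))
  free <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% have), ,
                    drop = FALSE]
  while (nrow(edges) < m && nrow(free) > 0L) {
    i <- 1L + rng() %% nrow(free)
    edges <- rbind(edges, free[i, ])
    free <- free[-i, , drop = FALSE]
  }
  molgraph(rep("C", n),
           data.frame(from = edges[, 1], to = edges[, 2], type = "single"),
           name = paste0("rgraph", seed))
}

#' Worked-example molecules
#'
#' Returns the transcribed example molecules shipped with the package:
#' `quinine` (quinoline fused bicycle joined by a two-bond chain to the
#' quinuclidine cage), `dopamine` (a single catechol ring with an acyclic
#' amine tail), `strychnine` (the heptacyclic alkaloid), plus
#' `vomicine_like`, a synthetic stand-in for vomicine built by
#' [vomicine_like()].
#'
#' @return Named list of [molgraph] objects.
#' @export
builtin_molecules <- function() {
  path <- system.file("extdata", "examples.sdf", package = "gcsim",
                      mustWork = TRUE)
  mols <- read_molecules(path)
  mols$vomicine_like <- vomicine_like(mols$strychnine)
  mols
}

#' Synthetic vomicine-like analogue of strychnine
#'
#' A stand-in for the strychnine congener vomicine, whose exact published
#' drawing is not shipped with the package.  It reproduces the features the
#' graph-of-cycles comparison needs: the strychnine ring skeleton is kept
#' intact and the tertiary amine region is re-bridged through an
#' N-methylated nitrogen, two atoms at graph distance 6 being joined by a
#' three-bond `C-C(H2)-N(CH3)-C` span.  The minimum cycle basis therefore
#' gains exactly one 9-membered ring through the nitrogen (canonical
#' closure adds a second 9-cycle), so that at cycle-length bound `j = 7`
#' the graph of cycles coincides with strychnine's while the unbounded
#' graphs of cycles differ — the behaviour described for the real pair.
#' Because it is a reconstruction, its molecular formula is not vomicine's.
#'
#' @param strychnine The strychnine [molgraph]; defaults to the shipped
#'   transcription.
#' @return A [molgraph] named `"vomicine_like"`.
#' @export
vomicine_like <- function(strychnine = NULL) {
  if (is.null(strychnine)) {
    path <- system.file("extdata", "examples.sdf", package = "gcsim",
                        mustWork = TRUE)
    strychnine <- read_molecules(path)$strychnine
  }
  g <- strychnine
  ## bridge endpoints: the lactam alpha-CH2 (atom 3) and the CH2 adjacent
  ## to the amine (atom 11) of the shipped strychnine numbering, at graph
  ## distance 6 in the 2-core.
  x <- 3L; y <- 11L
  stopifnot(g$atoms[x] == "C", g$atoms[y] == "C")
  a <- g$atoms
  b <- g$bonds
  c_new <- length(a) + 1L
  n_new <- length(a) + 2L
  me <- length(a) + 3L
  a <- c(a, "C", "N", "C")
  b <- rbind(b,
             data.frame(from = c(x, c_new, n_new, n_new),
                        to = c(c_new, n_new, y, me),
                        type = "single"))
  out <- molgraph(a, b, name = "vomicine_like")
  out
}
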