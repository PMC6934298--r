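#' Similarity graphs over a molecule set
#'
#' A similarity graph is the complete graph on a set of molecules with each
#' pair weighted by a similarity in `[0, 1]`.  Pairs whose computation
#' timed out may carry `NA` similarity together with a non-`"optimal"`
#' status; thresholding can either drop them or treat them as 0.
#'
#' @param pairs Data frame with columns `id1`, `id2`, `sim` and optionally
#'   `status` (default `"optimal"`).
#' @param ids Molecule identifiers; defaults to those appearing in `pairs`.
#' @param method Tag such as `"GC"`, `"MG"`, `"TC"`.
#' @return An object of class `similarity_graph`.
#' @export
similarity_graph <- function(pairs, ids = NULL, method = "GC") {
  stopifnot(all(c("id1", "id2", "sim") %in% names(pairs)))
  if (is.null(pairs$status)) pairs$status <- "optimal"
  pairs$id1 <- as.character(pairs$id1)
  pairs$id2 <- as.character(pairs$id2)
  if (any(pairs$id1 == pairs$id2)) stop("self-pairs are implicit (sim 1)")
  bad <- !is.na(pairs$sim) & (pairs$sim < 0 | pairs$sim > 1)
  if (any(bad)) stop("similarities must lie in [0, 1]")
  key <- paste(pmin(pairs$id1, pairs$id2), pmax(pairs$id1, pairs$id2))
  if (anyDuplicated(key)) stop("duplicate molecule pair")
  if (is.null(ids)) ids <- sort(unique(c(pairs$id1, pairs$id2)))
  structure(list(pairs = pairs, ids = as.character(ids), method = method),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  ok <- sum(!is.na(x$pairs$sim))
  cat("<similarity_graph> ", x$method, ": ", length(x$ids), " molecules, ",
      nrow(x$pairs), " pairs (", ok, " computed)\n", sep = "")
  invisible(x)
}

.pair_key <- function(id1, id2) paste(pmin(id1, id2), pmax(id1, id2))

#' Connected components at a similarity threshold
#'
#' Keeps the pairs with similarity at least `alpha` and returns the
#' connected components these edges induce, with their sizes and densities
#' (`edges / (s (s - 1) / 2)`).  Components listed have at least two
#' molecules.
#'
#' @param sg A [similarity_graph()].
#' @param alpha Threshold in `[0, 1]`.
#' @param timeouts `"remove"` (default) drops uncomputed pairs;
#'   `"zero"` counts them as similarity 0.
#' @return List with `components` (data frame `component`, `size`,
#'   `n_edges`, `density`), `n_components`, `membership` (named vector) and
#'   `alpha`.
#' @export
components_at_threshold <- function(sg, alpha,
                                    timeouts = c("remove", "zero")) {
  stopifnot(inherits(sg, "similarity_graph"), alpha >= 0, alpha <= 1)
  timeouts <- match.arg(timeouts)
  p <- sg$pairs
  if (timeouts == "zero") p$sim[is.na(p$sim)] <- 0
  p <- p[!is.na(p$sim) & p$sim >= alpha, , drop = FALSE]
  ig <- igraph::make_empty_graph(n = length(sg$ids), directed = FALSE)
  igraph::V(ig)$name <- sg$ids
  if (nrow(p)) {
    ig <- igraph::add_edges(ig, rbind(match(p$id1, sg$ids),
                                      match(p$id2, sg$ids)))
  }
  memb <- igraph::components(ig)$membership
  names(memb) <- sg$ids
  sizes <- table(memb)
  keep <- as.integer(names(sizes)[sizes >= 2L])
  comp <- data.frame(component = integer(), size = integer(),
                     n_edges = integer(), density = numeric())
  for (cid in keep) {
    vs <- which(memb == cid)
    s <- length(vs)
    ne <- sum(match(p$id1, sg$ids) %in% vs & match(p$id2, sg$ids) %in% vs)
    comp <- rbind(comp, data.frame(component = cid, size = s, n_edges = ne,
                                   density = ne / (s * (s - 1) / 2)))
  }
  comp <- comp[order(-comp$size), , drop = FALSE]
  rownames(comp) <- NULL
  list(components = comp, n_components = nrow(comp), membership = memb,
       alpha = alpha)
}

#' Threshold sweep summary
#'
#' Re-computes [components_at_threshold()] over a grid of thresholds and
#' tabulates component count, maximum component size and average density —
#' the shape of a similarity-network summary table.
#'
#' @param sg A [similarity_graph()].
#' @param alphas Thresholds, default `1.0, 0.9, ..., 0.0`.
#' @param timeouts Passed through.
#' @return Data frame with one row per threshold.
#' @export
threshold_sweep <- function(sg, alphas = seq(1, 0, by = -0.1),
                            timeouts = c("remove", "zero")) {
  timeouts <- match.arg(timeouts)
  out <- lapply(alphas, function(a) {
    res <- components_at_threshold(sg, a, timeouts = timeouts)
    data.frame(threshold = a,
               n_components = res$n_components,
               max_size = if (res$n_components) max(res$components$size) else 0L,
               avg_density = if (res$n_components) {
                 mean(res$components$density)
               } else NA_real_)
  })
  do.call(rbind, out)
}

#' Correlation of two similarity measures
#'
#' Pearson correlation over the pairs computed by both methods; pairs
#' missing in either (timeouts) are excluded and counted.
#'
#' @param sg1,sg2 [similarity_graph()] objects over the same molecules.
#' @return List with `r`, `n_pairs`, `n_excluded`.  `r` is `NA` with a
#'   warning when either measure has zero variance.
#' @export
similarity_correlation <- function(sg1, sg2) {
  k1 <- .pair_key(sg1$pairs$id1, sg1$pairs$id2)
  k2 <- .pair_key(sg2$pairs$id1, sg2$pairs$id2)
  common <- intersect(k1, k2)
  if (length(common) < 2L) stop("need at least 2 common pairs")
  s1 <- sg1$pairs$sim[match(common, k1)]
  s2 <- sg2$pairs$sim[match(common, k2)]
  ok <- !is.na(s1) & !is.na(s2)
  n_excluded <- sum(!ok)
  s1 <- s1[ok]; s2 <- s2[ok]
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, n_pairs = length(s1), n_excluded = n_excluded))
  }
  list(r = stats::cor(s1, s2), n_pairs = length(s1),
       n_excluded = n_excluded)
}

#' Confusion matrix of two similarity measures
#'
#' Two-dimensional histogram of pair similarities with bins
#' `[0, 0.1), ..., [0.9, 1.0)` and a separate closed bin for exactly 1.0.
#' Rows are `sg1`, columns `sg2`; only pairs computed by both are counted.
#'
#' @param sg1,sg2 [similarity_graph()] objects.
#' @return An 11 x 11 integer matrix with dimension names.
#' @export
similarity_confusion <- function(sg1, sg2) {
  k1 <- .pair_key(sg1$pairs$id1, sg1$pairs$id2)
  k2 <- .pair_key(sg2$pairs$id1, sg2$pairs$id2)
  common <- intersect(k1, k2)
  s1 <- sg1$pairs$sim[match(common, k1)]
  s2 <- sg2$pairs$sim[match(common, k2)]
  ok <- !is.na(s1) & !is.na(s2)
  s1 <- s1[ok]; s2 <- s2[ok]
  bin <- function(s) ifelse(s == 1, 11L, pmin(floor(s * 10), 10L) + 1L)
  labs <- c(sprintf("[.%d,.%d[", 0:9, 1:10), "=1.0")
  labs[10] <- "[.9,1.0["
  m <- matrix(0L, 11, 11, dimnames = list(labs, labs))
  if (length(s1)) {
    tab <- table(factor(bin(s1), levels = 1:11),
                 factor(bin(s2), levels = 1:11))
    m[] <- as.integer(tab)
  }
  m
}

#' All-pairs similarity matrix of a molecule set
#'
#' Computes every pairwise similarity with the chosen method.  For the
#' graph-of-cycles method the canonical generator and graph of cycles of
#' each molecule are pre-computed once and reused across pairs.
#'
#' @param mols Named list of [molgraph] objects (or, for `mode = "tc"`, a
#'   named list of fragment-identifier vectors).
#' @param mode `"gc"`, `"mg"` or `"tc"`.
#' @param j,tol,theta_match,closure Graph-of-cycles parameters.
#' @param time_limit Seconds per pair (MCES modes).
#' @param core_only,match_bonds Molecular-graph parameters.
#' @return A [similarity_graph()] whose `pairs` carry `sim`, `status` and
#'   `elapsed`; timed-out pairs keep their best-found similarity with
#'   status `"timeout-best-found"`.
#' @export
similarity_matrix <- function(mols, mode = c("gc", "mg", "tc"), j = Inf,
                              tol = 0.2, theta_match = "strict",
                              time_limit = 20, core_only = TRUE,
                              match_bonds = FALSE,
                              closure = "fixpoint") {
  mode <- match.arg(mode)
  ids <- names(mols)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("`mols` must be a uniquely named list")
  }
  n <- length(mols)
  if (mode == "gc") {
    pre <- lapply(mols, graph_of_cycles, j = j, closure = closure)
  }
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      res <- switch(mode,
        gc = gc_similarity(pre[[i]], pre[[k]], j = j, tol = tol,
                           theta_match = theta_match,
                           time_limit = time_limit),
        mg = mg_similarity(mols[[i]], mols[[k]], core_only = core_only,
                           match_bonds = match_bonds,
                           time_limit = time_limit),
        tc = list(similarity = tanimoto(mols[[i]], mols[[k]]),
                  status = "optimal", elapsed = 0))
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[k], sim = res$similarity,
        status = res$status, elapsed = res$elapsed)
    }
  }
  similarity_graph(do.call(rbind, rows), ids = ids, method = toupper(mode))
}
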