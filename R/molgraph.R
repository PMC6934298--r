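#' Labelled molecular graphs
#'
#' A `molgraph` is a hydrogen-suppressed, simple, undirected labelled graph:
#' atoms are vertices labelled by element symbol, covalent bonds are edges
#' labelled by bond type (`"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' The row order of `bonds` is the edge index set `e_1 .. e_m`; cycle vectors
#' are coordinates over exactly this indexing, so it is kept stable for a
#' given input record.
#'
#' @param atoms Character vector of element symbols, one per vertex.
#' @param bonds Data frame with integer columns `from`, `to` (1-based vertex
#'   indices) and character column `type`.
#' @param name Molecule identifier.
#' @return An object of class `molgraph` with components `atoms`, `bonds`
#'   and `name`.
#' @examples
#' tri <- molgraph(c("C", "C", "C"),
#'                 data.frame(from = c(1, 2, 3), to = c(2, 3, 1),
#'                            type = "single"), name = "cyclopropane")
#' n_bonds(tri)
#' @export
molgraph <- function(atoms, bonds, name = "molecule") {
  stopifnot(is.character(atoms))
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(), type = character())
  }
  bonds <- data.frame(from = as.integer(bonds$from), to = as.integer(bonds$to),
                      type = as.character(bonds$type))
  if (length(atoms) == 0L) stop("empty molecule: no atoms")
  if (nrow(bonds) > 0L) {
    if (any(bonds$from == bonds$to)) stop("self-loop bond in '", name, "'")
    if (any(bonds$from < 1L | bonds$to < 1L |
            bonds$from > length(atoms) | bonds$to > length(atoms))) {
      stop("bond endpoint out of range in '", name, "'")
    }
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key)) stop("parallel bonds in '", name, "'")
  }
  structure(list(atoms = atoms, bonds = bonds, name = name),
            class = "molgraph")
}

#' @rdname molgraph
#' @param g A `molgraph`.
#' @export
n_atoms <- function(g) length(g$atoms)

#' @rdname molgraph
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$name, ": ", n_atoms(x), " atoms, ", n_bonds(x),
      " bonds\n", sep = "")
  invisible(x)
}

#' @export
summary.molgraph <- function(object, ...) {
  cat("<molgraph> ", object$name, "\n", sep = "")
  cat("  atoms:", n_atoms(object), "-",
      paste(names(table(object$atoms)), table(object$atoms),
            sep = ":", collapse = " "), "\n")
  if (n_bonds(object)) {
    cat("  bonds:", n_bonds(object), "-",
        paste(names(table(object$bonds$type)), table(object$bonds$type),
              sep = ":", collapse = " "), "\n")
  }
  cat("  cyclomatic number:", cyclomatic_number(object), "\n")
  invisible(object)
}

#' Convert a molecular graph to an igraph object
#'
#' Vertex attribute `element` and edge attribute `bond` carry the labels;
#' edge order is preserved so igraph edge ids coincide with bond indices.
#'
#' @param g A `molgraph`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(g) {
  UseMethod("as_igraph")
}

#' @export
as_igraph.molgraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_atoms(g), directed = FALSE)
  if (n_bonds(g) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$from, g$bonds$to))
    igraph::E(ig)$bond <- g$bonds$type
  }
  igraph::V(ig)$element <- g$atoms
  igraph::V(ig)$name <- paste0(g$atoms, seq_len(n_atoms(g)))
  ig
}

#' Cyclomatic number of a molecular graph
#'
#' `m - n + p` where `p` is the number of connected components: the dimension
#' of the GF(2) cycle space, hence the size of any cycle basis.
#'
#' @param g A `molgraph`.
#' @return Integer.
#' @export
cyclomatic_number <- function(g) {
  p <- igraph::count_components(as_igraph(g))
  n_bonds(g) - n_atoms(g) + p
}

.bond_names <- c(`1` = "single", `2` = "double", `3` = "triple",
                 `4` = "aromatic")
.bond_codes <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

.molgraph_from_sdf <- function(sdf, name) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                      type = unname(.bond_names[as.character(bb[, 3])]))
  if (anyNA(bonds$type)) stop("unsupported bond order in record '", name, "'")
  g <- molgraph(elements, bonds, name = name)
  suppress_hydrogens(g)
}

#' Remove explicit hydrogen atoms
#'
#' Hydrogens never lie on a cycle of a simple molecular graph, so they are
#' dropped at parse time; remaining atoms and bonds are re-indexed in their
#' original order.
#'
#' @param g A `molgraph`.
#' @return A hydrogen-free `molgraph`.
#' @export
suppress_hydrogens <- function(g) {
  keep <- which(g$atoms != "H")
  if (length(keep) == n_atoms(g)) return(g)
  if (length(keep) == 0L) stop("molecule '", g$name, "' contains only hydrogen")
  remap <- match(seq_along(g$atoms), keep)
  b <- g$bonds
  b$from <- remap[b$from]
  b$to <- remap[b$to]
  b <- b[!is.na(b$from) & !is.na(b$to), , drop = FALSE]
  molgraph(g$atoms[keep], b, name = g$name)
}

#' Parse one molecule record
#'
#' @param text A character scalar: a SMILES string, or the full text of an
#'   MDL MOL V2000 block / single-record SDF.
#' @param format One of `"smiles"`, `"mol"`, `"sdf"`.
#' @param name Identifier for the molecule; for MOL/SDF input the record
#'   title line is used when `name` is `NULL`.
#' @return A hydrogen-suppressed [molgraph].
#' @details SMILES parsing is delegated to Open Babel through
#'   \pkg{ChemmineR}/\pkg{ChemmineOB}; MOL/SDF blocks are read natively by
#'   \pkg{ChemmineR}.  Aromatic bonds are kept as their own bond label and
#'   never kekulized: the cycle machinery is purely topological and ignores
#'   bond labels.
#' @examples
#' \dontrun{
#' parse_molecule("C1CCCCC1", "smiles", name = "cyclohexane")
#' }
#' @export
parse_molecule <- function(text, format = c("smiles", "mol", "sdf"),
                           name = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(text), length(text) >= 1L)
  if (format == "smiles") {
    smi <- trimws(text[1L])
    if (!nzchar(smi)) stop("empty SMILES record")
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop("SMILES parsing requires the ChemmineOB package")
    }
    sdfset <- tryCatch(ChemmineR::smiles2sdf(smi),
                       error = function(e) {
                         stop("SMILES parse failure for record '", smi, "': ",
                              conditionMessage(e))
                       })
    return(.molgraph_from_sdf(sdfset[[1]],
                              name = if (is.null(name)) smi else name))
  }
  txt <- if (length(text) > 1L) paste(text, collapse = "\n") else text
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  body <- sub("\\n?\\$\\$\\$\\$.*$", "", txt)
  writeLines(c(body, "$$$$"), tf)
  mols <- read_molecules(tf)
  if (length(mols) != 1L) stop("expected one MOL record, found ", length(mols))
  if (!is.null(name)) mols[[1]]$name <- name
  mols[[1]]
}

#' Read molecules from an SDF or SMILES file
#'
#' @param path Path to a multi-record SDF file, or a `.smi` file with one
#'   SMILES per line (optionally followed by whitespace and a name).
#' @return A named list of [molgraph] objects.
#' @export
read_molecules <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    mols <- lapply(lines, function(l) {
      parts <- strsplit(trimws(l), "[[:space:]]+")[[1]]
      parse_molecule(parts[1L], "smiles",
                     name = if (length(parts) > 1L) parts[2L] else parts[1L])
    })
  } else {
    sdfset <- ChemmineR::read.SDFset(path, skipErrors = FALSE)
    ids <- ChemmineR::sdfid(sdfset)
    mols <- lapply(seq_along(sdfset), function(i) {
      nm <- if (nzchar(trimws(ids[i]))) trimws(ids[i]) else paste0("mol", i)
      .molgraph_from_sdf(sdfset[[i]], name = nm)
    })
  }
  names(mols) <- vapply(mols, `[[`, "", "name")
  mols
}

#' Serialize a molecular graph
#'
#' `write_molgraph_graphml()` writes GraphML with `element` and `bond`
#' attributes; `molgraph_to_json()` returns a JSON string with the same
#' information.
#'
#' @param g A `molgraph`.
#' @param path Output file.
#' @return `write_molgraph_graphml()` returns `path` invisibly.
#' @export
write_molgraph_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_molgraph_graphml
#' @export
molgraph_to_json <- function(g) {
  jsonlite::toJSON(list(name = g$name, atoms = g$atoms, bonds = g$bonds),
                   auto_unbox = TRUE, digits = NA)
}

#' Read back a GraphML molecular graph
#'
#' @param path GraphML file written by [write_molgraph_graphml()].
#' @return A `molgraph`.
#' @export
read_molgraph_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(ig, names = FALSE)
  molgraph(igraph::V(ig)$element,
           data.frame(from = el[, 1], to = el[, 2],
                      type = igraph::E(ig)$bond),
           name = "graphml")
}

#' Apply a vertex permutation to a molecular graph
#'
#' Utility for canonicality checks: relabels vertex `i` as `perm[i]` and
#' re-sorts atoms accordingly; bond order is re-indexed in first-encounter
#' order of the permuted edge list.
#'
#' @param g A `molgraph`.
#' @param perm Integer permutation of `1:n_atoms(g)`.
#' @return A `molgraph` isomorphic to `g`.
#' @export
permute_molgraph <- function(g, perm) {
  stopifnot(length(perm) == n_atoms(g), !anyDuplicated(perm))
  inv <- order(perm)
  b <- g$bonds
  b$from <- perm[b$from]
  b$to <- perm[b$to]
  b <- b[order(pmin(b$from, b$to), pmax(b$from, b$to)), , drop = FALSE]
  rownames(b) <- NULL
  molgraph(g$atoms[inv], b, name = g$name)
}
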