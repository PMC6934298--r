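# Small graph constructors used across the suite.

ring_mol <- function(n, elements = "C", name = paste0("C", n, "-ring")) {
  molgraph(rep(elements, length.out = n),
           data.frame(from = 1:n, to = c(2:n, 1), type = "single"), name)
}

path_mol <- function(n, name = paste0("P", n)) {
  molgraph(rep("C", n),
           data.frame(from = 1:(n - 1), to = 2:n, type = "single"), name)
}

k4_mol <- function() {
  molgraph(rep("C", 4),
           data.frame(from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4),
                      type = "single"), "K4")
}

# Two hexagons sharing one edge (naphthalene skeleton).
naphthalene_mol <- function() {
  molgraph(rep("C", 10),
           data.frame(from = c(1, 2, 3, 4, 5, 6, 5, 7, 8, 9, 10),
                      to   = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 6),
                      type = "single"), "naphthalene")
}

# Theta graph: two degree-3 vertices joined by three paths of length 2;
# it has three 4-cycles and more than one minimum cycle basis.
theta_mol <- function() {
  molgraph(rep("C", 5),
           data.frame(from = c(1, 3, 1, 4, 1, 5), to = c(3, 2, 4, 2, 5, 2),
                      type = "single"), "theta")
}

# Two triangles sharing a single vertex (spiro-like cut vertex).
bowtie_mol <- function() {
  molgraph(rep("C", 5),
           data.frame(from = c(1, 2, 3, 3, 4, 5), to = c(2, 3, 1, 4, 5, 3),
                      type = "single"), "bowtie")
}

as_ig <- function(mol) {
  ig <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (n_bonds(mol)) ig <- igraph::add_edges(ig, rbind(mol$bonds$from, mol$bonds$to))
  ig
}
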