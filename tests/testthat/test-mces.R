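test_that("vertex compatibility predicates follow their definitions", {
  expect_true(pi_molecular("C", "C"))
  expect_false(pi_molecular("C", "N"))
  expect_true(pi_molecular("O", "O"))
  expect_true(pi_cycles(6, 6))
  expect_true(pi_cycles(5, 6))    # |5-6| = 1 <= 0.2 * 5
  expect_false(pi_cycles(6, 8))   # 2 > 0.2 * 6
  expect_false(pi_cycles(6, 8, tol = 0.2))
  expect_true(pi_cycles(6, 8, tol = 0.5))
  expect_error(pi_cycles(0, 6), "positive")
})

test_that("line graphs follow the textbook construction", {
  expect_equal(igraph::ecount(line_graph(ring_mol(3))), 3L)
  expect_true(igraph::isomorphic(line_graph(ring_mol(3)),
                                 igraph::make_ring(3)))
  expect_true(igraph::isomorphic(line_graph(path_mol(3)),
                                 igraph::make_full_graph(2)))
  star <- molgraph(rep("C", 4),
                   data.frame(from = 1, to = 2:4, type = "single"), "K1,3")
  expect_true(igraph::isomorphic(line_graph(star),
                                 igraph::make_full_graph(3)))
})

test_that("compatibility product encodes consistent correspondences", {
  tri <- ring_mol(3)
  rule <- compatibility_rule("molecular")
  pr <- compatibility_product(tri, tri, rule)
  expect_equal(igraph::clique_num(
    igraph::graph_from_adjacency_matrix(pr$adj, mode = "undirected")), 3L)

  e1 <- molgraph(c("C", "N"), data.frame(from = 1, to = 2, type = "single"))
  e2 <- molgraph(c("N", "C"), data.frame(from = 1, to = 2, type = "single"))
  pr2 <- compatibility_product(e1, e2, rule)
  expect_equal(nrow(pr2$pairs), 1L)
  expect_equal(sum(pr2$adj), 0L)

  # two 4-cycles each carrying one heteroatom: when the heteroatoms are
  # compatible a rotation aligns the rings (clique 4); when they are not,
  # only the two carbon-carbon edges can match (clique 2).  Cross-checked
  # against exhaustive clique enumeration on the product.
  a <- ring_mol(4); a$atoms[1] <- "N"
  b <- ring_mol(4); b$atoms[3] <- "N"
  b2 <- ring_mol(4); b2$atoms[3] <- "O"
  for (case in list(list(b, 4L), list(b2, 2L))) {
    pr3 <- compatibility_product(a, case[[1]], rule)
    cn <- igraph::clique_num(
      igraph::graph_from_adjacency_matrix(pr3$adj, mode = "undirected"))
    expect_equal(cn, case[[2]])
    expect_equal(mces(a, case[[1]], rule)$e12, oracle_mces_e12(a, case[[1]]))
  }
})

test_that("branch-and-bound maximum clique is exact", {
  expect_length(max_clique(igraph::make_full_graph(5))$vertices, 5L)
  expect_length(max_clique(igraph::make_ring(5))$vertices, 2L)
  set.seed(5)
  for (i in 1:10) {
    g <- igraph::sample_gnp(12, 0.5)
    res <- max_clique(g, time_limit = 30)
    expect_equal(res$status, "optimal")
    expect_length(res$vertices, igraph::clique_num(g))
    adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
    cl <- res$vertices
    if (length(cl) > 1) {
      for (p in seq_along(cl)[-1]) {
        expect_true(all(adj[cl[p], cl[-p]]))
      }
    }
  }
})

test_that("MCES equals the exhaustive common-subgraph oracle", {
  set.seed(9)
  elements <- c("C", "C", "C", "N", "O")
  for (i in 1:30) {
    na <- 4L + i %% 3L; nb <- 4L + (i + 1L) %% 3L
    a <- random_graph_molecule(na, min(na + 1L, na * (na - 1L) / 2L),
                               seed = 200 + i)
    b <- random_graph_molecule(nb, min(nb + 1L, nb * (nb - 1L) / 2L),
                               seed = 300 + i)
    a$atoms <- sample(elements, na, replace = TRUE)
    b$atoms <- sample(elements, nb, replace = TRUE)
    res <- mces(a, b, rule = compatibility_rule("molecular"),
                time_limit = 30)
    expect_equal(res$status, "optimal")
    expect_equal(res$e12, oracle_mces_e12(a, b))
    # symmetry and bounds
    res_ba <- mces(b, a, rule = compatibility_rule("molecular"),
                   time_limit = 30)
    expect_equal(res_ba$similarity, res$similarity, tolerance = 1e-12)
    expect_gte(res$similarity, 0)
    expect_lte(res$similarity, 1)
    expect_equal(nrow(res$edge_pairs), res$e12)
  }
})

test_that("similarity is exactly 1 on rule-isomorphic graphs only", {
  set.seed(31)
  for (i in 1:6) {
    m <- generate_molecule(2 + i %% 2, seed = 400 + i)
    p <- sample(n_atoms(m))
    mp <- permute_molgraph(m, p)
    expect_equal(mces(m, mp, compatibility_rule("molecular"))$similarity, 1)
  }
  tri <- ring_mol(3)
  sq <- ring_mol(4)
  expect_lt(mces(tri, sq, compatibility_rule("molecular"))$similarity, 1)
})

test_that("the similarity degree follows its closed form", {
  tri <- ring_mol(3)
  paw <- molgraph(rep("C", 4),
                  data.frame(from = c(1, 2, 3, 3), to = c(2, 3, 1, 4),
                             type = "single"), "triangle+pendant")
  r <- mces(tri, paw, compatibility_rule("molecular"))
  expect_equal(r$e12, 3L)
  expect_equal(r$v12, 3L)
  expect_equal(r$similarity, (3 + 3)^2 / ((3 + 3) * (4 + 4)))
  # against a triangle-containing graph with |V|+|E| = 9 (the diamond)
  diamond <- molgraph(rep("C", 4),
                      data.frame(from = c(1, 2, 3, 1, 2), to = c(2, 3, 1, 4, 4),
                                 type = "single"), "diamond")
  r2 <- mces(tri, diamond, compatibility_rule("molecular"))
  expect_equal(r2$similarity, 36 / 54, tolerance = 1e-12)
  expect_equal(similarity_degree(3, 3, 3, 3, 4, 5), 36 / 54)
})

test_that("degenerate inputs are handled as documented", {
  single <- graph_of_cycles(ring_mol(6))
  single5 <- graph_of_cycles(ring_mol(5))
  r <- gc_similarity(single, single5)
  expect_equal(r$similarity, 1)        # single vertices, pi admits (5,6)
  expect_equal(r$v12, 1L)
  acyclic <- graph_of_cycles(path_mol(4))
  expect_warning(r2 <- gc_similarity(acyclic, single), "empty")
  expect_equal(r2$similarity, 0)
})

test_that("raising the time limit never lowers the similarity", {
  a <- generate_molecule(4, seed = 61)
  b <- generate_molecule(4, seed = 62)
  lo <- mg_similarity(a, b, time_limit = 0.05)
  hi <- mg_similarity(a, b, time_limit = 30)
  expect_lte(lo$similarity, hi$similarity + 1e-12)
  expect_equal(hi$status, "optimal")
})

test_that("theta matching policy controls GC edge compatibility", {
  naph_gc <- graph_of_cycles(naphthalene_mol())
  # fused pair sharing two bonds: same mu, theta differs from naphthalene
  fused2 <- molgraph(rep("C", 9),
    data.frame(from = c(1, 2, 3, 4, 5, 6, 3, 7, 8, 9),
               to   = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 1),
               type = "single"), "fused-2-bond")
  g2 <- graph_of_cycles(fused2)
  strict <- gc_similarity(naph_gc, g2, theta_match = "strict")
  relaxed <- gc_similarity(naph_gc, g2, theta_match = "relaxed")
  expect_lt(strict$similarity, 1)
  expect_equal(relaxed$similarity, 1)
})

test_that("Tanimoto coefficient follows the set formula", {
  expect_equal(tanimoto(letters[1:5], letters[1:5]), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(1:4, c(3, 4, 7, 8, 9, 10)), 0.25)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  expect_equal(tanimoto(c(1, 1, 2), c(2, 2, 1)), 1)  # multiplicity ignored
})
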