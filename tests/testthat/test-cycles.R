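test_that("GF(2) cycle algebra behaves as a vector space over edge sets", {
  expect_equal(cycle_xor(1:3, 1:3), integer(0))
  naph <- naphthalene_mol()
  gen <- minimum_cycle_basis(naph)
  peri <- cycle_xor(gen$cycles[[1]], gen$cycles[[2]])
  expect_length(peri, 10L)
  expect_true(is_elementary_cycle(peri, gen$structural))
  # the perimeter is the unique 10-cycle of the fused bicyclic fixture
  all10 <- Filter(function(cy) length(cy) == 10, oracle_all_cycles(naph))
  expect_equal(list(peri), all10)

  two_tri <- molgraph(rep("C", 6),
    data.frame(from = c(1, 2, 3, 4, 5, 6), to = c(2, 3, 1, 5, 6, 4),
               type = "single"), "2xC3")
  expect_false(is_elementary_cycle(cycle_xor(1:3, 4:6), two_tri))
  expect_false(is_elementary_cycle(integer(0), two_tri))
  expect_true(is_elementary_cycle(1:6, ring_mol(6)))
})

test_that("Horton MCB matches hand-checked bases", {
  c6 <- minimum_cycle_basis(ring_mol(6))
  expect_equal(c6$lengths, 6L)
  expect_equal(c6$weight, 6L)

  naph <- minimum_cycle_basis(naphthalene_mol())
  expect_equal(naph$lengths, c(6L, 6L))
  expect_equal(naph$weight, 12L)   # never the 10-edge perimeter

  k4 <- minimum_cycle_basis(k4_mol())
  expect_equal(k4$lengths, c(3L, 3L, 3L))
  expect_equal(k4$weight, 9L)
})

test_that("MCB size and weight agree with the exhaustive oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- 4L + i %% 5L
    mmax <- min(12L, n * (n - 1L) / 2L)
    m <- (n - 1L) + 1L + i %% max(1L, (mmax - n + 1L))
    mol <- random_graph_molecule(n, min(m, mmax), seed = 100 + i)
    gen <- minimum_cycle_basis(mol)
    cyc <- oracle_all_cycles(structural_graph(mol))
    ref <- oracle_min_basis(cyc, n_bonds(gen$structural))
    expect_equal(length(gen$cycles), ref$size)
    expect_equal(gen$weight, ref$weight)
    expect_equal(ref$size, cyclomatic_number(structural_graph(mol)))
  }
})

test_that("canonical closure is independent of which MCB Horton found", {
  # the theta graph has three 4-cycles and three different minimum bases;
  # the canonical generator must contain all three cycles whichever basis
  # is the starting point
  th <- theta_mol()
  gen <- canonical_generator(th)
  expect_length(gen$cycles, 3L)
  all_c <- oracle_all_cycles(th)
  expect_setequal(vapply(gen$cycles, paste, "", collapse = ","),
                  vapply(all_c, paste, "", collapse = ","))
  # closing an explicitly different basis gives the same generator
  base <- minimum_cycle_basis(th)
  alt <- base
  alt$cycles[[1]] <- cycle_xor(base$cycles[[1]], base$cycles[[2]])
  closed <- canonicalize_generator(alt)
  expect_setequal(vapply(closed$cycles, paste, "", collapse = ","),
                  vapply(gen$cycles, paste, "", collapse = ","))
})

test_that("closure adds a cycle only when its length equals the pair max", {
  # naphthalene: hexagon xor hexagon is the 10-perimeter, 10 > 6, so the
  # canonical generator stays at two cycles
  gen <- canonical_generator(naphthalene_mol())
  expect_length(gen$cycles, 2L)
  # quinuclidine-like bicyclo[2.2.2]: two 6-cycles close to a third
  bic <- molgraph(rep("C", 8),
    data.frame(from = c(1, 2, 3, 1, 5, 6, 1, 7, 8),
               to   = c(2, 3, 4, 5, 6, 4, 7, 8, 4), type = "single"),
    "bicyclo222")
  expect_length(canonical_generator(bic)$cycles, 3L)
  expect_length(minimum_cycle_basis(bic)$cycles, 2L)
})

test_that("length filtering keeps the j-hierarchical subset", {
  v <- builtin_molecules()$vomicine_like
  gen <- canonical_generator(v)
  expect_true(any(gen$lengths == 9L))
  g7 <- filter_generator(gen, 7)
  expect_true(all(g7$lengths <= 7L))
  expect_equal(g7$j, 7)
  expect_error(filter_generator(gen, 2), "at least 3")
  expect_equal(filter_generator(gen, Inf)$lengths, gen$lengths)
})

test_that("a minimum cycle basis is hierarchical", {
  fixtures <- list(theta_mol(), k4_mol(), naphthalene_mol(),
                   generate_molecule(3, seed = 12),
                   generate_molecule(4, seed = 13),
                   structural_graph(builtin_molecules()$vomicine_like))
  for (mol in fixtures) {
    gen <- minimum_cycle_basis(mol)
    cycles <- oracle_all_cycles(structural_graph(mol))
    for (j in sort(unique(vapply(cycles, length, 0L)))) {
      sub <- filter_generator(gen, max(j, 3))
      for (cy in cycles) {
        if (length(cy) <= j) expect_true(spans_cycle(sub, cy))
      }
    }
  }
})

test_that("span membership distinguishes components", {
  two_rings <- generate_molecule(2, ring_sizes = 5,
                                 fusion_weights = c(isthmus = 1), seed = 9)
  gen <- canonical_generator(two_rings)
  expect_length(gen$cycles, 2L)
  expect_true(spans_cycle(gen, gen$cycles[[1]]))
  expect_false(spans_cycle(filter_generator(gen, Inf),
                           c(gen$cycles[[1]][1], gen$cycles[[2]][1],
                             gen$cycles[[2]][2])))
  one <- filter_generator(gen, Inf)
  one$cycles <- one$cycles[1]
  expect_false(spans_cycle(one, gen$cycles[[2]]))
})

test_that("canonical generator is invariant under vertex relabelling", {
  set.seed(3)
  for (i in 1:8) {
    mol <- generate_molecule(2 + i %% 4, seed = 40 + i, decoration = 0.2)
    gen0 <- canonical_generator(mol)
    sig0 <- sort(gen0$lengths)
    for (k in 1:10) {
      p <- sample(n_atoms(mol))
      genp <- canonical_generator(permute_molgraph(mol, p))
      expect_equal(sort(genp$lengths), sig0)
      expect_true(gc_isomorphic(graph_of_cycles(gen0),
                                graph_of_cycles(genp)))
    }
  }
})

test_that("generator JSON serialization is deterministic", {
  gen <- canonical_generator(builtin_molecules()$quinine)
  expect_identical(generator_to_json(gen), generator_to_json(gen))
  parsed <- jsonlite::fromJSON(generator_to_json(gen), simplifyVector = FALSE)
  expect_length(parsed$cycles, 5L)
  expect_equal(parsed$weight, 30L)
})
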