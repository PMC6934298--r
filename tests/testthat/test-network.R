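make_sg <- function(sim_fun, ids, method = "GC", status = NULL) {
  pairs <- t(utils::combn(ids, 2))
  df <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                   sim = apply(pairs, 1, function(p) sim_fun(p[1], p[2])))
  if (!is.null(status)) df$status <- status
  similarity_graph(df, ids = ids, method = method)
}

test_that("similarity graphs validate their inputs", {
  expect_error(similarity_graph(data.frame(id1 = "a", id2 = "a", sim = 1)),
               "self-pairs")
  expect_error(similarity_graph(data.frame(id1 = "a", id2 = "b", sim = 2)),
               "\\[0, 1\\]")
  expect_error(similarity_graph(
    data.frame(id1 = c("a", "b"), id2 = c("b", "a"), sim = 0.5)),
    "duplicate")
})

test_that("thresholded components match the union-find oracle", {
  set.seed(23)
  ids <- sprintf("m%02d", 1:12)
  sims <- stats::runif(utils::combn(12, 2) |> ncol())
  k <- 0
  sg <- make_sg(function(i, j) { k <<- k + 1; sims[k] }, ids)
  for (alpha in seq(0, 1, by = 0.1)) {
    res <- components_at_threshold(sg, alpha)
    ref <- oracle_components(ids, sg$pairs, alpha)
    expect_equal(res$n_components, ref$n)
    expect_equal(sort(res$components$size, decreasing = TRUE), ref$sizes)
    expect_equal(sort(res$components$density), sort(ref$densities))
  }
})

test_that("duplicate molecules collapse into one dense component at 1.0", {
  ids <- c("a", "b", "c", "d", "e")
  sg <- make_sg(function(i, j) {
    if (i %in% c("a", "b", "c") && j %in% c("a", "b", "c")) 1.0 else 0.2
  }, ids)
  res <- components_at_threshold(sg, 1.0)
  expect_equal(res$n_components, 1L)
  expect_equal(res$components$size, 3L)
  expect_equal(res$components$density, 1.0)
  res0 <- components_at_threshold(sg, 0.0)
  expect_equal(res0$n_components, 1L)
  expect_equal(res0$components$size, 5L)
  expect_equal(res0$components$density, 1.0)  # complete similarity graph
})

test_that("component count/maximum size are monotone across the sweep", {
  set.seed(77)
  ids <- sprintf("m%02d", 1:20)
  k <- 0
  sims <- stats::rbeta(190, 2, 3)
  sg <- make_sg(function(i, j) { k <<- k + 1; sims[k] }, ids)
  sweep <- threshold_sweep(sg, alphas = seq(1, 0, by = -0.1))
  expect_true(all(diff(sweep$n_components) <= 0 |
                  diff(sweep$max_size) >= 0))
  expect_true(all(diff(sweep$max_size) >= 0))
})

test_that("timeout pairs can be removed or zeroed", {
  ids <- c("a", "b", "c")
  df <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                   sim = c(0.9, NA, 0.9),
                   status = c("optimal", "timeout-best-found", "optimal"))
  sg <- similarity_graph(df, ids = ids)
  rem <- components_at_threshold(sg, 0.0, timeouts = "remove")
  expect_equal(rem$components$n_edges, 2L)
  zero <- components_at_threshold(sg, 0.0, timeouts = "zero")
  expect_equal(zero$components$n_edges, 3L)
  expect_equal(zero$components$density, 1.0)
})

test_that("correlation of similarity measures behaves like Pearson r", {
  set.seed(41)
  ids <- sprintf("m%d", 1:8)
  k <- 0; sims <- stats::runif(28)
  sg <- make_sg(function(i, j) { k <<- k + 1; sims[k] }, ids)
  self <- similarity_correlation(sg, sg)
  expect_equal(self$r, 1)
  inv <- sg; inv$pairs$sim <- 1 - inv$pairs$sim
  expect_equal(similarity_correlation(sg, inv)$r, -1)
  flat <- sg; flat$pairs$sim <- 0.5
  expect_warning(res <- similarity_correlation(sg, flat), "zero variance")
  expect_true(is.na(res$r))
  # hand computation on 6 pairs
  a <- sg; a$pairs <- a$pairs[1:6, ]
  b <- inv; b$pairs <- b$pairs[1:6, ]
  expect_equal(similarity_correlation(a, b)$r,
               stats::cor(a$pairs$sim, b$pairs$sim))
})

test_that("confusion matrices tally pairs into the printed binning", {
  ids <- sprintf("m%d", 1:6)
  k <- 0
  sims <- c(0.05, 0.15, 0.95, 1.0, 0.5, 0.5, 0.99, 1.0, 0.31, 0.0,
            0.45, 0.62, 0.78, 0.83, 0.91)
  sg <- make_sg(function(i, j) { k <<- k + 1; sims[k] }, ids)
  m <- similarity_confusion(sg, sg)
  expect_equal(sum(m), 15L)
  expect_equal(sum(diag(m)), 15L)         # identical measures: diagonal
  expect_equal(unname(m["=1.0", "=1.0"]), 2L)
  expect_equal(unname(m["[.9,1.0[", "[.9,1.0["]), 3L)  # 0.95, 0.99, 0.91
  empty <- similarity_confusion(
    similarity_graph(data.frame(id1 = "a", id2 = "b", sim = NA)),
    similarity_graph(data.frame(id1 = "a", id2 = "b", sim = NA)))
  expect_equal(sum(empty), 0L)
})

test_that("all-pairs matrices are reproducible and feed the network tools", {
  mols <- list(a = ring_mol(6), b = ring_mol(6), c = ring_mol(5),
               d = naphthalene_mol(), e = path_mol(4))
  suppressWarnings({
    sg1 <- similarity_matrix(mols, mode = "gc")
    sg2 <- similarity_matrix(mols, mode = "gc")
  })
  expect_equal(nrow(sg1$pairs), 10L)
  expect_identical(sg1$pairs[, c("id1", "id2", "sim", "status")],
                   sg2$pairs[, c("id1", "id2", "sim", "status")])
  expect_equal(sg1$pairs$sim[sg1$pairs$id1 == "a" & sg1$pairs$id2 == "b"], 1)
  res <- components_at_threshold(sg1, 1.0)
  expect_true(any(res$components$size >= 2))
  frag <- list(a = 1:4, b = 1:4, c = 5:8, d = c(1, 2, 9), e = 10)
  sgt <- similarity_matrix(frag, mode = "tc")
  expect_equal(sgt$pairs$sim[1], 1)
  expect_equal(sgt$method, "TC")
})
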