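test_that("direct counterparts mirror the interaction matrix", {
  im <- interaction_matrix(rbind(c(1L, 1L), c(0L, 1L)),
                           c("m1", "m2"), c("d1", "d2"))
  expect_equal(direct_counterparts("microbe", 1L, im), c(1L, 2L))
  expect_equal(direct_counterparts("drug", 1L, im), 1L)
  expect_length(direct_counterparts("microbe", 2L, im), 1L)

  withr::local_seed(21)
  im2 <- random_im(20L, 30L)
  for (i in sample(20L, 5L)) {
    oracle <- sort(Filter(function(j) im2$values[i, j] == 1L, 1:30))
    expect_equal(as.integer(direct_counterparts("microbe", i, im2)),
                 as.integer(oracle))
  }
  for (j in sample(30L, 5L)) {
    oracle <- sort(Filter(function(i) im2$values[i, j] == 1L, 1:20))
    expect_equal(as.integer(direct_counterparts("drug", j, im2)),
                 as.integer(oracle))
  }
})

test_that("local seeds are counterpart entities plus the anchor's own", {
  kg <- chain_kg(sprintf("e%d", 0:7))
  im <- interaction_matrix(rbind(c(1L, 1L), c(0L, 0L)),
                           c("m1", "m2"), c("d1", "d2"))
  al <- entity_alignment(c(3L, 4L), c(6L, 8L), kg)
  expect_equal(local_seed_entities("microbe", 1L, im, al), c(3L, 6L, 8L))
  # isolated microbe keeps only its own aligned entity
  expect_equal(local_seed_entities("microbe", 2L, im, al), 4L)
})

test_that("similar microbes and high-order drugs follow the two-hop walk", {
  im <- interaction_matrix(rbind(c(1L, 1L, 0L), c(0L, 1L, 0L),
                                 c(0L, 0L, 1L)),
                           c("m1", "m2", "m3"), c("d1", "d2", "d3"))
  expect_equal(similar_microbes(1L, im), 2L)
  expect_length(similar_microbes(3L, im), 1L - 1L)

  im2 <- interaction_matrix(rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)),
                            c("m1", "m2"), c("d1", "d2", "d3"))
  expect_equal(high_order_drugs(1L, im2), 3L)

  # isolated anchor gives empty sets all the way down
  im3 <- interaction_matrix(rbind(c(0L, 0L), c(1L, 1L)),
                            c("m1", "m2"), c("d1", "d2"))
  expect_length(similar_microbes(1L, im3), 0L)
  expect_length(high_order_drugs(1L, im3), 0L)
})

test_that("high-order sets equal brute-force bipartite walks on random data", {
  withr::local_seed(33)
  im <- random_im(30L, 40L, 0.1)
  A <- im$values
  for (m in sample(30L, 8L)) {
    msim <- sort(Filter(function(u) {
      u != m && any(A[m, ] == 1L & A[u, ] == 1L)
    }, 1:30))
    expect_equal(as.integer(similar_microbes(m, im)), as.integer(msim))
    dp <- sort(setdiff(
      Reduce(union, lapply(msim, function(u) which(A[u, ] == 1L)),
             integer(0)),
      which(A[m, ] == 1L)))
    expect_equal(as.integer(high_order_drugs(m, im)), as.integer(dp))
  }
})

test_that("non-local seeds compose alignment with the high-order walk", {
  kg <- chain_kg(sprintf("e%d", 0:9))
  im <- interaction_matrix(rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)),
                           c("m1", "m2"), c("d1", "d2", "d3"))
  al <- entity_alignment(c(1L, 2L), c(5L, 7L, 10L), kg)
  expect_equal(nonlocal_seed_entities("microbe", 1L, im, al), 10L)

  im0 <- interaction_matrix(rbind(c(0L, 0L, 0L), c(0L, 1L, 1L)),
                            c("m1", "m2"), c("d1", "d2", "d3"))
  expect_length(nonlocal_seed_entities("microbe", 1L, im0, al), 0L)
})

test_that("propagation walks directed chains and stops at sinks", {
  kg <- chain_kg(c("a", "b", "c"))
  res <- propagate(kg, seeds = 1L, n_layers = 2L)
  expect_equal(unname(res$triples[[1L]]), cbind(1L, 1L, 2L),
               ignore_attr = TRUE)
  expect_equal(unname(res$triples[[2L]]), cbind(2L, 1L, 3L),
               ignore_attr = TRUE)
  expect_equal(res$entities[[3L]], 3L)

  # a sink seed leaves every layer empty
  res2 <- propagate(kg, seeds = 3L, n_layers = 2L)
  expect_equal(nrow(res2$triples[[1L]]), 0L)
  expect_equal(nrow(res2$triples[[2L]]), 0L)
  expect_length(res2$entities[[2L]], 0L)
})

test_that("unbudgeted propagation equals the BFS frontier oracle", {
  withr::local_seed(7)
  for (rep in 1:100) {
    kg <- random_kg(50L, 5L, 200L)
    seeds <- sample.int(50L, sample(1:4, 1L))
    got <- propagate(kg, seeds, n_layers = 3L, budget = Inf)
    want <- bfs_frontier_oracle(kg, seeds, 3L)
    expect_identical(got$entities, want$entities)
    for (l in 1:3)
      expect_identical(sort_triples(got$triples[[l]]),
                       sort_triples(want$triples[[l]]))
  }
})

test_that("budgeted layers are subsets of the unbudgeted ones", {
  withr::local_seed(13)
  for (rep in 1:10) {
    kg <- random_kg(40L, 4L, 150L)
    seeds <- sample.int(40L, 2L)
    full <- propagate(kg, seeds, n_layers = 3L, budget = Inf)
    small <- propagate(kg, seeds, n_layers = 3L, budget = 5L, seed = rep)
    for (l in 1:3) {
      expect_lte(nrow(small$triples[[l]]), 5L)
      key <- function(tri) apply(tri, 1L, paste, collapse = ",")
      expect_true(all(key(small$triples[[l]]) %in%
                        key(full$triples[[l]])))
    }
  }
})

test_that("drug-side constructions mirror the microbe side on the transpose", {
  withr::local_seed(17)
  im <- random_im(15L, 25L, 0.15)
  imt <- interaction_matrix(t(im$values), im$drug_labels, im$microbe_labels)
  for (j in sample(25L, 6L)) {
    expect_equal(similar_drugs(j, im), similar_microbes(j, imt))
    expect_equal(high_order_microbes(j, im), high_order_drugs(j, imt))
    expect_equal(direct_counterparts("drug", j, im),
                 direct_counterparts("microbe", j, imt))
  }
})

test_that("build_all_graphs is complete, budgeted and deterministic", {
  withr::local_seed(3)
  kg <- random_kg(30L, 3L, 120L)
  im <- random_im(2L, 2L, 0.6)
  al <- entity_alignment(c(1L, 2L), c(3L, 4L), kg)
  g1 <- build_all_graphs(kg, im, al, n_layers = 2L, budget = 1L, seed = 5L)
  # one local+nonlocal record per anchor on each side
  expect_length(g1$microbe, 2L)
  expect_length(g1$drug, 2L)
  for (rec in c(g1$microbe, g1$drug))
    for (ctx in list(rec$local, rec$nonlocal))
      for (tri in ctx$triples) expect_lte(nrow(tri), 1L)
  g2 <- build_all_graphs(kg, im, al, n_layers = 2L, budget = 1L, seed = 5L)
  expect_identical(g1[c("microbe", "drug")], g2[c("microbe", "drug")])
})

test_that("graph dumps serialize every anchor and context", {
  withr::local_seed(91)
  kg <- random_kg(20L, 3L, 80L)
  im <- random_im(3L, 4L, 0.4)
  al <- entity_alignment(1:3, 4:7, kg)
  graphs <- build_all_graphs(kg, im, al, n_layers = 2L, budget = 4L,
                             seed = 2L)
  path <- withr::local_tempfile()
  write_graph_dump(graphs, kg, path)
  lines <- readLines(path)
  expect_length(lines, (3L + 4L) * 2L)
  rec <- jsonlite::fromJSON(lines[1L])
  expect_equal(rec$side, "microbe")
  expect_equal(rec$context, "local")
  expect_length(rec$layers, 3L)   # L + 1 entity sets
})
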