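test_that("realized interaction density matches the target", {
  # Monte-Carlo check over replicate seeds against the binomial standard
  # error of the pooled cell count.
  spec0 <- synthetic_spec(n_microbes = 100L, n_drugs = 200L,
                          interaction_density = 0.05)
  dens <- vapply(1:20, function(s) {
    spec <- synthetic_spec(n_microbes = 100L, n_drugs = 200L,
                           interaction_density = 0.05, seed = s)
    mean(generate_interactions(spec)$interactions$values)
  }, numeric(1))
  n_cells <- 20 * 100 * 200
  se <- sqrt(0.05 * 0.95 / n_cells)
  expect_lt(abs(mean(dens) - 0.05), 3 * se)
})

test_that("an extreme scale saturates the planted block", {
  # rank 1 with a huge slope: cells with positive latent score become 1,
  # the rest 0 (up to the density-matching bias threshold)
  spec <- synthetic_spec(n_microbes = 20L, n_drugs = 30L, latent_rank = 1L,
                         interaction_density = 0.3, scale = 1e6, seed = 2L)
  gi <- generate_interactions(spec)
  z <- gi$factors$U %*% t(gi$factors$V)
  thr <- -gi$factors$bias / spec$scale
  expect_true(all(gi$interactions$values[z > thr + 1e-9] == 1L))
  expect_true(all(gi$interactions$values[z < thr - 1e-9] == 0L))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- synthetic_spec(n_microbes = 30L, n_drugs = 40L,
                         n_attribute_entities = 50L)
  b1 <- make_benchmark(spec)
  b2 <- make_benchmark(spec)
  expect_identical(b1$interactions$values, b2$interactions$values)
  expect_identical(b1$kg$triples, b2$kg$triples)

  spec3 <- synthetic_spec(n_microbes = 30L, n_drugs = 40L,
                          n_attribute_entities = 50L, seed = 43L)
  b3 <- make_benchmark(spec3)
  expect_gt(sum(b1$interactions$values != b3$interactions$values), 0L)
})

test_that("noise-free attribute links go to the best-aligned directions", {
  spec <- synthetic_spec(n_microbes = 15L, n_drugs = 10L, latent_rank = 2L,
                         n_attribute_entities = 6L, kg_edges_per_node = 2L,
                         attribute_noise = 0, seed = 9L)
  gi <- generate_interactions(spec)
  dirs <- diag(2)[c(1, 2, 1, 2, 1, 2), ] * c(1, 1, -1, -1, 0.5, 0.5)
  gk <- generate_kg(spec, gi$factors, directions = dirs)
  fac <- rbind(gi$factors$U, gi$factors$V)
  n_nodes <- nrow(fac)
  # brute-force nearest-direction oracle per node
  for (i in seq_len(n_nodes)) {
    sc <- as.numeric(dirs %*% fac[i, ])
    best <- order(-sc, seq_along(sc))[1:2]
    out <- gk$kg$triples[gk$kg$triples[, 1L] == i, 3L] - n_nodes
    expect_setequal(out, best)
  }
})

test_that("full rewiring erases the factor-attribute association", {
  spec_fun <- function(noise) {
    synthetic_spec(n_microbes = 60L, n_drugs = 60L, latent_rank = 2L,
                   n_attribute_entities = 40L, kg_edges_per_node = 4L,
                   attribute_noise = noise, seed = 31L)
  }
  mean_alignment <- function(noise) {
    spec <- spec_fun(noise)
    gi <- generate_interactions(spec)
    gk <- generate_kg(spec, gi$factors)
    fac <- rbind(gi$factors$U, gi$factors$V)
    n_nodes <- nrow(fac)
    withr::with_seed(spec$seed + 1L, {
      dirs <- matrix(rnorm(40L * 2L), 40L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
    })
    out <- gk$kg$triples[gk$kg$triples[, 1L] <= n_nodes, , drop = FALSE]
    mean(rowSums(dirs[out[, 3L] - n_nodes, ] * fac[out[, 1L], ]))
  }
  # permuted control: random attribute choice has ~zero mean alignment
  a0 <- mean_alignment(0)
  a1 <- mean_alignment(1)
  expect_gt(a0, 0.5)             # strongly aligned links
  expect_lt(abs(a1), 0.15)       # indistinguishable from random rewiring
})

test_that("benchmarks satisfy the structural contracts", {
  spec <- synthetic_spec(n_microbes = 30L, n_drugs = 40L,
                         n_attribute_entities = 50L, seed = 4L)
  bench <- make_benchmark(spec)
  expect_equal(nrow(bench$positives), sum(bench$interactions$values))
  rep <- validate_dataset(bench$kg, bench$interactions, bench$alignment)
  expect_equal(rep$n_positives, nrow(bench$positives))
  expect_equal(rep$n_entities, 30L + 40L + 50L)
  # kg_data invariants hold on the generated graph
  expect_equal(build_head_index(bench$kg$triples, rep$n_entities),
               bench$kg$head_index)
  expect_false(any(duplicated(bench$kg$triples)))
})

test_that("degenerate specs are rejected", {
  expect_error(synthetic_spec(interaction_density = 1.5), "density")
  expect_error(synthetic_spec(attribute_noise = -0.1), "noise")
  spec <- synthetic_spec(latent_rank = 4L, n_attribute_entities = 2L)
  gi <- generate_interactions(spec)
  expect_error(generate_kg(spec, gi$factors), "latent_rank")
})

test_that("recovered signal degrades as attribute links are rewired", {
  # full-pipeline monotonicity of mean held-out AUC in the KG noise level,
  # at a small scale so three seeds per level stay affordable
  run <- function(noise, seed) {
    spec <- synthetic_spec(n_microbes = 50L, n_drugs = 80L,
                           interaction_density = 0.06,
                           n_attribute_entities = 120L,
                           attribute_noise = noise, seed = seed)
    bench <- make_benchmark(spec)
    cfg <- model_config(embed_dim = 32L, max_epochs = 15L,
                        layer_budget = 8L, batch_size = 256L, seed = seed,
                        transe = transe_config(epochs = 20L, seed = seed))
    cross_validate(bench$kg, bench$interactions, bench$alignment,
                   cfg)$mean_auc
  }
  means <- vapply(c(0, 0.5, 1), function(noise) {
    mean(vapply(c(42L, 43L, 44L), function(s) run(noise, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})
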