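test_that("qkv projections reduce to lookups under identity weights", {
  withr::local_seed(41)
  kg <- random_kg(10L, 3L, 30L)
  emb <- random_embeddings(kg, 4L)
  # single head, d_h = dim, key/value projection = identity
  w <- encoder_weights(4L, n_heads = 1L, seed = 1L)
  w$wk <- diag(4)
  w$wv <- diag(4)
  tri <- kg$triples[1:6, ]
  qkv <- build_qkv(tri, emb, w, 1L)
  expect_equal(qkv$k, emb$entity_vectors[tri[, 3L], ], ignore_attr = TRUE)
  expect_equal(qkv$v, emb$entity_vectors[tri[, 3L], ], ignore_attr = TRUE)

  one <- build_qkv(tri[1L, , drop = FALSE], emb, w, 1L)
  expect_equal(dim(one$q), c(1L, 4L))

  # scalar-loop oracle for the projections
  w2 <- encoder_weights(4L, n_heads = 2L, seed = 2L)
  qkv2 <- build_qkv(tri, emb, w2, 2L)
  cols <- 2L + 1:2
  for (i in 1:6) {
    hr <- c(emb$entity_vectors[tri[i, 1L], ],
            emb$relation_vectors[tri[i, 2L], ])
    for (c in seq_along(cols)) {
      expect_equal(qkv2$q[i, c], sum(hr * w2$wq[, cols[c]]))
      expect_equal(qkv2$k[i, c],
                   sum(emb$entity_vectors[tri[i, 3L], ] * w2$wk[, cols[c]]))
    }
  }
})

test_that("attention weights are row-stochastic softmax values", {
  # singleton key gets weight 1; identical keys give uniform weights
  expect_equal(attention_weights(matrix(rnorm(3), 1L), matrix(rnorm(3), 1L)),
               matrix(1), ignore_attr = TRUE)
  q <- matrix(rnorm(12), 4L, 3L)
  k <- matrix(rep(c(1, 2, 3), each = 5L), 5L, 3L)
  aw <- attention_weights(q, k)
  expect_equal(aw, matrix(1 / 5, 4L, 5L), ignore_attr = TRUE)

  # scalar softmax oracle with a max-shift, random rectangular case
  withr::local_seed(6)
  q2 <- matrix(rnorm(24), 4L, 6L)
  k2 <- matrix(rnorm(36), 6L, 6L)
  aw2 <- attention_weights(q2, k2)
  for (i in 1:4) {
    logits <- numeric(6)
    for (j in 1:6) logits[j] <- sum(q2[i, ] * k2[j, ]) / sqrt(6)
    ex <- exp(logits - max(logits))
    expect_equal(aw2[i, ], ex / sum(ex), tolerance = 1e-12)
  }
  expect_equal(rowSums(aw2), rep(1, 4L), tolerance = 1e-9)
})

test_that("attention weights survive large logit offsets", {
  withr::local_seed(60)
  q <- matrix(rnorm(20), 4L, 5L)
  k <- matrix(rnorm(25), 5L, 5L)
  base <- attention_weights(q, k)
  # offsetting every logit by +1e4 must not change the softmax
  qshift <- cbind(q, 1e4)
  kshift <- cbind(k, 1)
  shifted <- tcrossprod(qshift, kshift) / sqrt(5)  # logits + 1e4/sqrt(5)
  direct <- exp(shifted - apply(shifted, 1L, max))
  direct <- direct / rowSums(direct)
  expect_equal(base, direct, tolerance = 1e-6)
})

test_that("layer encoding matches a fully looped reference", {
  withr::local_seed(15)
  kg <- random_kg(12L, 4L, 80L)
  emb <- random_embeddings(kg, 8L)
  w <- encoder_weights(8L, n_heads = 2L, seed = 4L)
  for (n in c(1L, 3L, 17L, 64L)) {
    tri <- kg$triples[sample.int(nrow(kg$triples), n, replace = TRUE), ,
                      drop = FALSE]
    expect_equal(encode_layer(tri, emb, w),
                 encode_layer_oracle(tri, emb, w), tolerance = 1e-9)
  }
  # empty layer encodes to the zero vector
  expect_equal(encode_layer(matrix(integer(0), ncol = 3L), emb, w),
               numeric(8L))
  # mean-pool with one triple returns the tail embedding exactly
  tri1 <- kg$triples[1L, , drop = FALSE]
  expect_equal(encode_layer(tri1, emb, w, mode = "mean-pool"),
               emb$entity_vectors[tri1[1L, 3L], ], ignore_attr = TRUE)
})

test_that("layer encoding is permutation invariant", {
  withr::local_seed(25)
  kg <- random_kg(15L, 3L, 60L)
  emb <- random_embeddings(kg, 8L)
  w <- encoder_weights(8L, n_heads = 4L, seed = 9L)
  for (rep in 1:5) {
    tri <- kg$triples[sample.int(nrow(kg$triples), 10L), ]
    base <- encode_layer(tri, emb, w)
    perm <- encode_layer(tri[sample.int(10L), ], emb, w)
    expect_equal(base, perm, tolerance = 1e-9)
  }
})

test_that("uniform attention with identity values equals mean pooling", {
  withr::local_seed(35)
  kg <- random_kg(10L, 2L, 40L)
  emb <- random_embeddings(kg, 4L)
  w <- encoder_weights(4L, n_heads = 1L, seed = 11L)
  w$wv <- diag(4)
  w$wo <- diag(4)
  # identical tails force uniform attention weights; the attended value
  # then equals the unweighted tail mean
  tri <- cbind(sample.int(10L, 6L, replace = TRUE),
               sample.int(2L, 6L, replace = TRUE),
               7L)
  expect_equal(encode_layer(tri, emb, w),
               encode_layer(tri, emb, w, mode = "mean-pool"),
               tolerance = 1e-9)
})

test_that("anchor encoding stacks L + 1 layer vectors", {
  withr::local_seed(55)
  kg <- random_kg(20L, 3L, 100L)
  emb <- random_embeddings(kg, 8L)
  w <- encoder_weights(8L, n_heads = 2L, seed = 12L)
  prop <- propagate(kg, seeds = c(1L, 2L), n_layers = 3L, budget = 10L,
                    seed = 1L)
  le <- encode_anchor(prop$triples, prop$entities, emb, w)
  expect_equal(dim(le), c(4L, 8L))
  expect_equal(le[1L, ],
               colMeans(emb$entity_vectors[prop$entities[[1L]], ,
                                           drop = FALSE]))
  for (l in 1:3)
    expect_equal(le[l + 1L, ], encode_layer(prop$triples[[l]], emb, w))
})

test_that("the C++ batch encoder agrees with the R reference path", {
  withr::local_seed(70)
  spec <- synthetic_spec(n_microbes = 10L, n_drugs = 15L,
                         n_attribute_entities = 20L,
                         interaction_density = 0.15, seed = 8L)
  bench <- make_benchmark(spec)
  graphs <- build_all_graphs(bench$kg, bench$interactions, bench$alignment,
                             n_layers = 3L, budget = 6L, seed = 2L)
  pack <- mdalink:::pack_graphs(graphs)
  emb <- random_embeddings(bench$kg, 8L)
  w <- encoder_weights(8L, n_heads = 2L, seed = 14L)
  for (mode in c("attention", "mean-pool")) {
    enc <- mdalink:::cpp_encode_anchors(
      pack, emb$entity_vectors, emb$relation_vectors,
      w$wq, w$wk, w$wv, w$wo, w$n_heads, mode == "attention")
    for (a in c(1L, 4L, 11L, 25L)) {
      rec <- if (a <= 10L) graphs$microbe[[a]] else graphs$drug[[a - 10L]]
      want <- c(
        final_embedding(
          encode_anchor(rec$local$triples, rec$local$entities, emb, w,
                        mode),
          encode_anchor(rec$nonlocal$triples, rec$nonlocal$entities, emb, w,
                        mode)))
      expect_equal(as.numeric(enc[a, ]), want, tolerance = 1e-9)
    }
  }
})
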