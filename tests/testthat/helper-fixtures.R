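# Shared fixtures and independent oracles.  Oracles are deliberately naive
# (per-element loops, brute-force scans) and never share code with the
# implementation they check.

# --- tiny graphs -----------------------------------------------------------

chain_kg <- function(labels = c("a", "b", "c"), rel = "R") {
  n <- length(labels)
  tri <- cbind(seq_len(n - 1L), 1L, seq(2L, n))
  knowledge_graph(tri, labels, rel)
}

random_kg <- function(n_entities = 50L, n_relations = 5L, n_triples = 200L) {
  tri <- cbind(sample.int(n_entities, n_triples, replace = TRUE),
               sample.int(n_relations, n_triples, replace = TRUE),
               sample.int(n_entities, n_triples, replace = TRUE))
  knowledge_graph(tri, sprintf("e%d", seq_len(n_entities)),
                  sprintf("r%d", seq_len(n_relations)))
}

random_im <- function(n_m, n_d, density = 0.2) {
  interaction_matrix(matrix(rbinom(n_m * n_d, 1L, density), n_m, n_d),
                     sprintf("m%d", seq_len(n_m)),
                     sprintf("d%d", seq_len(n_d)))
}

random_embeddings <- function(kg, dim = 8L) {
  embedding_table(
    matrix(rnorm(length(kg$entity_labels) * dim), ncol = dim),
    matrix(rnorm(length(kg$relation_labels) * dim), ncol = dim))
}

# --- oracles ---------------------------------------------------------------

# Brute-force BFS frontier expansion: per layer, scan every triple.
bfs_frontier_oracle <- function(kg, seeds, n_layers) {
  ents <- vector("list", n_layers + 1L)
  trs <- vector("list", n_layers)
  ents[[1L]] <- sort(unique(as.integer(seeds)))
  for (l in seq_len(n_layers)) {
    keep <- kg$triples[, 1L] %in% ents[[l]]
    trs[[l]] <- kg$triples[keep, , drop = FALSE]
    ents[[l + 1L]] <- sort(unique(trs[[l]][, 3L]))
  }
  list(triples = trs, entities = ents)
}

sort_triples <- function(tri) {
  tri[order(tri[, 1L], tri[, 2L], tri[, 3L]), , drop = FALSE]
}

# Fully scalar multi-head attention reference for one layer.
encode_layer_oracle <- function(triples, emb, weights) {
  n <- nrow(triples)
  dh <- weights$head_dim
  o <- numeric(0)
  for (h in seq_len(weights$n_heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    q <- matrix(0, n, dh); k <- matrix(0, n, dh); v <- matrix(0, n, dh)
    for (i in seq_len(n)) {
      hr <- c(emb$entity_vectors[triples[i, 1L], ],
              emb$relation_vectors[triples[i, 2L], ])
      tl <- emb$entity_vectors[triples[i, 3L], ]
      for (c in seq_len(dh)) {
        q[i, c] <- sum(hr * weights$wq[, cols[c]])
        k[i, c] <- sum(tl * weights$wk[, cols[c]])
        v[i, c] <- sum(tl * weights$wv[, cols[c]])
      }
    }
    oh <- numeric(dh)
    for (i in seq_len(n)) {
      logits <- numeric(n)
      for (j in seq_len(n)) logits[j] <- sum(q[i, ] * k[j, ]) / sqrt(dh)
      ex <- exp(logits - max(logits))
      alpha <- ex / sum(ex)
      for (c in seq_len(dh))
        oh[c] <- oh[c] + sum(alpha * v[, c]) / n
    }
    o <- c(o, oh)
  }
  out <- numeric(weights$dim)
  for (d in seq_len(weights$dim)) out[d] <- sum(o * weights$wo[, d])
  out
}

# Direct (unstabilized) InfoNCE evaluation.
infonce_oracle <- function(anchor, positive, negatives, tau) {
  num <- exp(sum(anchor * positive) / tau)
  den <- num
  for (nn in negatives) den <- den + exp(sum(anchor * nn) / tau)
  -log(num / den)
}

# Tie-aware pair-counting AUC (ties count 1/2).
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# AUPR by brute-force sweep over all distinct score thresholds,
# right-constant precision steps.
aupr_sweep_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (th in ths) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# --- shared expensive runs -------------------------------------------------

# Desk-scale model configuration used by the signal-recovery and ablation
# checks: reduced dimension and epoch count, larger batches and a tighter
# layer budget for single-CPU throughput; everything else at package
# defaults (lr 0.1, patience 10, L = 3, 4 heads, tau 0.1, ssl weights 1e-5).
reduced_config <- function(seed, ablation = "full") {
  model_config(embed_dim = 32L, max_epochs = 30L, layer_budget = 8L,
               batch_size = 256L, seed = seed, ablation = ablation,
               transe = transe_config(epochs = 30L, seed = seed))
}

.bench_cache <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.bench_cache$bench))
    .bench_cache$bench <- make_benchmark(synthetic_spec())
  .bench_cache$bench
}

# Benchmark with the planted structure destroyed: the same number of
# positives is scattered uniformly at random, the KG is kept.
shuffled_benchmark <- function(seed) {
  bench <- default_benchmark()
  im <- bench$interactions
  n_pos <- sum(im$values)
  withr::with_seed(seed, {
    cells <- sample(length(im$values), n_pos)
  })
  v <- matrix(0L, nrow(im$values), ncol(im$values))
  v[cells] <- 1L
  im$values <- v
  dimnames(im$values) <- list(im$microbe_labels, im$drug_labels)
  bench$interactions <- im
  bench
}

# Memoised cross-validation on the default benchmark so that the recovery
# and ablation checks can share the full-model runs.
cached_cv <- function(seed, ablation = "full", shuffled = FALSE) {
  key <- paste(seed, ablation, shuffled, sep = "_")
  if (is.null(.bench_cache[[key]])) {
    bench <- if (shuffled) shuffled_benchmark(seed) else default_benchmark()
    .bench_cache[[key]] <- cross_validate(
      bench$kg, bench$interactions, bench$alignment,
      reduced_config(seed, ablation))
  }
  .bench_cache[[key]]
}
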