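# Multi-head scaled dot-product attention over a layer's triple set.
# Per triple i the query is a learned projection of [head || relation] and
# the key/value are projections of the tail; attention is computed with all
# triples of the layer as both queries and keys, and the query axis is
# mean-pooled per head before the output projection, giving one fixed-length
# vector per layer.  A mean-pooling mode (plain average of tail embeddings)
# implements the attention-free ablation.

#' Initialize multi-head encoder projection weights
#'
#' Per-head query projections map the concatenated head/relation embedding
#' (length `2*dim`) to `head_dim`; key and value projections map the tail
#' embedding (length `dim`) to `head_dim`; the output projection maps the
#' concatenated heads back to `dim`.  Weights are drawn from a seeded
#' uniform Glorot-style distribution and trained jointly with the main
#' objective.
#'
#' @param dim model embedding dimension (must be divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return object of class `encoder_weights` with matrices `wq`
#'   (`2*dim x dim`), `wk`, `wv` (`dim x dim`) and `wo` (`dim x dim`), where
#'   columns are grouped per head (`head_dim` columns each).
#' @export
encoder_weights <- function(dim, n_heads = 4L, seed = NULL) {
  if (dim %% n_heads != 0L)
    stop_mdalink("dim must be divisible by n_heads")
  head_dim <- dim %/% n_heads
  init <- function(nr, nc) {
    a <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -a, a), nr, nc)
  }
  run <- function() list(wq = init(2L * dim, dim), wk = init(dim, dim),
                         wv = init(dim, dim), wo = init(dim, dim))
  w <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(w, list(dim = dim, n_heads = as.integer(n_heads),
                      head_dim = as.integer(head_dim))),
            class = "encoder_weights")
}

head_cols <- function(weights, head) {
  (head - 1L) * weights$head_dim + seq_len(weights$head_dim)
}

#' Per-head query/key/value projections of a triple set
#'
#' @param triples integer triple matrix (rows are `(h, r, t)`).
#' @param emb an [embedding_table()].
#' @param weights an [encoder_weights()].
#' @param head head index in `1..n_heads`.
#' @return list of matrices `q`, `k`, `v`, each `nrow(triples) x head_dim`.
#' @export
build_qkv <- function(triples, emb, weights, head) {
  if (nrow(triples) == 0L) stop_mdalink("build_qkv needs a non-empty layer")
  cols <- head_cols(weights, head)
  hr <- cbind(emb$entity_vectors[triples[, 1L], , drop = FALSE],
              emb$relation_vectors[triples[, 2L], , drop = FALSE])
  tl <- emb$entity_vectors[triples[, 3L], , drop = FALSE]
  list(q = hr %*% weights$wq[, cols, drop = FALSE],
       k = tl %*% weights$wk[, cols, drop = FALSE],
       v = tl %*% weights$wv[, cols, drop = FALSE])
}

#' Scaled dot-product attention weights
#'
#' `alpha[i, j] = softmax_j(q_i . k_j / sqrt(d_h))`, computed with a
#' max-shift for numerical stability.  Every row sums to one.
#'
#' @param queries,keys matrices with `head_dim` columns.
#' @return row-stochastic weight matrix.
#' @export
attention_weights <- function(queries, keys) {
  dh <- ncol(queries)
  s <- tcrossprod(queries, keys) / sqrt(dh)
  s <- exp(s - apply(s, 1L, max))
  s / rowSums(s)
}

#' Encode one layer's triple set into a fixed-length vector
#'
#' In attention mode each head attends over the layer's triples, the
#' attended values are mean-pooled over the query axis, heads are
#' concatenated and projected by `wo`.  In mean-pool mode (the
#' attention-free ablation) the layer vector is the unweighted mean of the
#' tail embeddings.  An empty triple set encodes to the zero vector.
#'
#' @param triples integer triple matrix (may have zero rows).
#' @param emb an [embedding_table()].
#' @param weights an [encoder_weights()].
#' @param mode `"attention"` or `"mean-pool"`.
#' @return numeric vector of length `dim`.
#' @export
encode_layer <- function(triples, emb, weights,
                         mode = c("attention", "mean-pool")) {
  mode <- match.arg(mode)
  if (is.null(triples) || nrow(triples) == 0L)
    return(numeric(weights$dim))
  if (mode == "mean-pool") {
    return(colMeans(emb$entity_vectors[triples[, 3L], , drop = FALSE]))
  }
  o <- unlist(lapply(seq_len(weights$n_heads), function(h) {
    qkv <- build_qkv(triples, emb, weights, h)
    a <- attention_weights(qkv$q, qkv$k)
    colMeans(a %*% qkv$v)
  }))
  as.numeric(o %*% weights$wo)
}

#' Encode an anchor's layered triple sets into per-layer embeddings
#'
#' Layer 0 is the mean of the layer-0 entity set's embeddings (zero vector
#' if empty); layers `1..L` are [encode_layer()] applied to each triple set.
#'
#' @param layered_triples list of `L` triple matrices (layers 1..L).
#' @param layered_entities list of `L+1` entity-index vectors (layer 0
#'   first), as produced by [propagate()].
#' @param emb an [embedding_table()].
#' @param weights an [encoder_weights()].
#' @param mode `"attention"` or `"mean-pool"`.
#' @return matrix of `L+1` rows (one layer embedding per row, length `dim`).
#' @export
encode_anchor <- function(layered_triples, layered_entities, emb, weights,
                          mode = c("attention", "mean-pool")) {
  mode <- match.arg(mode)
  L <- length(layered_triples)
  out <- matrix(0, L + 1L, weights$dim)
  seeds <- layered_entities[[1L]]
  if (length(seeds) > 0L)
    out[1L, ] <- colMeans(emb$entity_vectors[seeds, , drop = FALSE])
  for (l in seq_len(L))
    out[l + 1L, ] <- encode_layer(layered_triples[[l]], emb, weights, mode)
  out
}
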