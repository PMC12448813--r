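# Translational knowledge-graph embedding (TransE): entities and relations
# live in the same d-dimensional space and plausible triples satisfy
# h + r ~ t.  Pre-training these embeddings initializes the trainable
# entity/relation tables of the association model.

#' TransE pre-training configuration
#'
#' @param dim embedding dimension.
#' @param margin hinge margin `gamma` (> 0).
#' @param norm_order scoring norm, 1 (L1) or 2 (L2).
#' @param learning_rate SGD learning rate.
#' @param epochs training epochs; 0 returns the seeded initialization.
#' @param negatives_per_positive corrupted triples per observed triple.
#' @param batch_size mini-batch size.
#' @param seed integer seed.
#' @return object of class `transe_config`.
#' @export
transe_config <- function(dim = 64L, margin = 1, norm_order = 2L,
                          learning_rate = 0.01, epochs = 100L,
                          negatives_per_positive = 1L, batch_size = 128L,
                          seed = 42L) {
  if (margin <= 0) stop_mdalink("margin must be positive")
  if (!norm_order %in% c(1L, 2L)) stop_mdalink("norm_order must be 1 or 2")
  if (dim < 1L) stop_mdalink("dim must be >= 1")
  structure(list(dim = as.integer(dim), margin = margin,
                 norm_order = as.integer(norm_order),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "transe_config")
}

#' Construct an embedding table
#' @param entity_vectors numeric matrix (entities x dim).
#' @param relation_vectors numeric matrix (relations x dim).
#' @return object of class `embedding_table`.
#' @export
embedding_table <- function(entity_vectors, relation_vectors) {
  if (ncol(entity_vectors) != ncol(relation_vectors))
    stop_mdalink("entity and relation dimensions differ")
  if (!all(is.finite(entity_vectors)) || !all(is.finite(relation_vectors)))
    stop_mdalink("embedding table contains non-finite values")
  structure(list(entity_vectors = entity_vectors,
                 relation_vectors = relation_vectors,
                 dim = ncol(entity_vectors)),
            class = "embedding_table")
}

#' Translational plausibility score of a triple
#'
#' `f(h, r, t) = ||h + r - t||` in the chosen norm; lower scores mean more
#' plausible triples.
#'
#' @param triple integer vector `(head, relation, tail)` (1-based).
#' @param emb an [embedding_table()].
#' @param norm_order 1 or 2.
#' @return non-negative scalar.
#' @export
transe_score <- function(triple, emb, norm_order = 2L) {
  d <- emb$entity_vectors[triple[1L], ] + emb$relation_vectors[triple[2L], ] -
    emb$entity_vectors[triple[3L], ]
  if (norm_order == 1L) sum(abs(d)) else sqrt(sum(d^2))
}

# Vectorized scores for a triple matrix.
transe_scores <- function(triples, emb, norm_order = 2L) {
  d <- emb$entity_vectors[triples[, 1L], , drop = FALSE] +
    emb$relation_vectors[triples[, 2L], , drop = FALSE] -
    emb$entity_vectors[triples[, 3L], , drop = FALSE]
  if (norm_order == 1L) rowSums(abs(d)) else sqrt(rowSums(d^2))
}

#' Corrupt a triple for negative sampling
#'
#' Replaces the head or the tail (fair coin) by an entity drawn uniformly
#' from all entities except the original, so the corrupted triple always
#' differs from the input.
#'
#' @param triple integer vector `(head, relation, tail)`.
#' @param entity_count number of entities (>= 2).
#' @return corrupted integer triple.
#' @export
corrupt_triple <- function(triple, entity_count) {
  if (entity_count < 2L)
    stop_mdalink("need at least 2 entities to corrupt a triple")
  slot <- if (runif(1) < 0.5) 1L else 3L
  orig <- triple[slot]
  # uniform over 1..entity_count excluding orig: draw from n-1 and shift
  repl <- sample.int(entity_count - 1L, 1L)
  if (repl >= orig) repl <- repl + 1L
  triple[slot] <- repl
  triple
}

# Vectorized corruption of a batch of triples.
corrupt_batch <- function(triples, entity_count) {
  n <- nrow(triples)
  slot <- ifelse(runif(n) < 0.5, 1L, 3L)
  orig <- triples[cbind(seq_len(n), slot)]
  repl <- sample.int(entity_count - 1L, n, replace = TRUE)
  repl <- repl + (repl >= orig)
  triples[cbind(seq_len(n), slot)] <- repl
  triples
}

#' Margin-based ranking loss over aligned positive/negative batches
#'
#' `sum(max(0, margin + f(pos) - f(neg)))`; zero exactly when every negative
#' scores worse than its positive by at least the margin.
#'
#' @param pos,neg integer triple matrices, aligned row by row.
#' @param emb an [embedding_table()].
#' @param config a [transe_config()].
#' @return non-negative scalar.
#' @export
transe_margin_loss <- function(pos, neg, emb, config) {
  stopifnot(nrow(pos) == nrow(neg))
  fp <- transe_scores(pos, emb, config$norm_order)
  fn <- transe_scores(neg, emb, config$norm_order)
  sum(pmax(0, config$margin + fp - fn))
}

#' Pre-train entity and relation embeddings on a knowledge graph
#'
#' Embeddings are initialized uniformly in `[-6/sqrt(d), 6/sqrt(d)]`,
#' relation vectors normalized once, and optimized by mini-batch SGD on the
#' margin ranking loss with uniform negative sampling; entity vectors are
#' renormalized to unit norm at the start of every epoch.  Deterministic
#' given `config$seed`.
#'
#' @param kg a non-empty [knowledge_graph()].
#' @param config a [transe_config()].
#' @return an [embedding_table()]; attribute `"loss_history"` holds the
#'   epoch-mean training loss and `"monitor_loss"` the end-of-epoch loss on
#'   a fixed corruption set (a deterministic convergence monitor).
#' @export
transe_pretrain <- function(kg, config = transe_config()) {
  n_tri <- nrow(kg$triples)
  if (n_tri == 0L) stop_mdalink("cannot pretrain on a graph with no triples")
  n_ent <- entity_count(kg)
  n_rel <- relation_count(kg)
  d <- config$dim
  p <- config$norm_order
  eps <- 1e-12
  withr::with_seed(config$seed, {
    bound <- 6 / sqrt(d)
    E <- matrix(runif(n_ent * d, -bound, bound), n_ent, d)
    R <- matrix(runif(n_rel * d, -bound, bound), n_rel, d)
    R <- R / pmax(sqrt(rowSums(R^2)), eps)
    history <- numeric(0)
    monitor <- numeric(0)
    # fixed corruption set: a deterministic monitor of training progress,
    # decoupled from the per-epoch resampling noise
    monitor_neg <- corrupt_batch(kg$triples, n_ent)
    if (config$epochs > 0L) {
      for (epoch in seq_len(config$epochs)) {
        E <- E / pmax(sqrt(rowSums(E^2)), eps)
        ord <- sample.int(n_tri)
        starts <- seq(1L, n_tri, by = config$batch_size)
        epoch_loss <- 0
        for (s in starts) {
          idx <- ord[s:min(s + config$batch_size - 1L, n_tri)]
          pos <- kg$triples[idx, , drop = FALSE]
          for (k in seq_len(config$negatives_per_positive)) {
            neg <- corrupt_batch(pos, n_ent)
            dp <- E[pos[, 1L], , drop = FALSE] + R[pos[, 2L], , drop = FALSE] -
              E[pos[, 3L], , drop = FALSE]
            dn <- E[neg[, 1L], , drop = FALSE] + R[neg[, 2L], , drop = FALSE] -
              E[neg[, 3L], , drop = FALSE]
            if (p == 1L) {
              fp <- rowSums(abs(dp)); fn <- rowSums(abs(dn))
              gp <- sign(dp); gn <- sign(dn)
            } else {
              fp <- sqrt(rowSums(dp^2)); fn <- sqrt(rowSums(dn^2))
              gp <- dp / pmax(fp, eps); gn <- dn / pmax(fn, eps)
            }
            act <- config$margin + fp - fn > 0
            epoch_loss <- epoch_loss + sum(pmax(0, config$margin + fp - fn))
            if (any(act)) {
              gp <- gp[act, , drop = FALSE]; gn <- gn[act, , drop = FALSE]
              pa <- pos[act, , drop = FALSE]; na <- neg[act, , drop = FALSE]
              lr <- config$learning_rate
              upd <- function(M, rows, G) {
                S <- rowsum(G, rows)
                u <- as.integer(rownames(S))
                M[u, ] <- M[u, ] - lr * S
                M
              }
              # d(loss)/dh+ = ghat+, /dt+ = -ghat+, /dh- = -ghat-, /dt- = ghat-
              E <- upd(E, pa[, 1L], gp)
              E <- upd(E, pa[, 3L], -gp)
              E <- upd(E, na[, 1L], -gn)
              E <- upd(E, na[, 3L], gn)
              R <- upd(R, pa[, 2L], gp - gn)
            }
          }
        }
        history <- c(history, epoch_loss / n_tri)
        fme <- embedding_table(E, R)
        monitor <- c(monitor,
                     transe_margin_loss(kg$triples, monitor_neg, fme,
                                        config) / n_tri)
      }
    }
  })
  out <- embedding_table(E, R)
  attr(out, "loss_history") <- history
  attr(out, "monitor_loss") <- monitor
  out
}

#' Save an embedding table as two label-keyed TSVs
#' @param emb an [embedding_table()].
#' @param kg the companion [knowledge_graph()] supplying labels.
#' @param entities_path,relations_path output paths.
#' @export
write_embeddings <- function(emb, kg, entities_path, relations_path) {
  we <- function(M, labels, path) {
    df <- data.frame(label = labels,
                     apply(M, 2L, function(x) sprintf("%.17g", x)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  we(emb$entity_vectors, kg$entity_labels, entities_path)
  we(emb$relation_vectors, kg$relation_labels, relations_path)
  invisible(NULL)
}

#' Load an embedding table written by [write_embeddings()]
#' @param kg the companion [knowledge_graph()]; rows are matched to its
#'   label order.
#' @param entities_path,relations_path input paths.
#' @return an [embedding_table()].
#' @export
read_embeddings <- function(kg, entities_path, relations_path) {
  re <- function(path, labels) {
    parts <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    lab <- vapply(parts, `[[`, character(1), 1L)
    M <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
    i <- match(labels, lab)
    if (anyNA(i)) stop_mdalink("embedding file is missing labels")
    M[i, , drop = FALSE]
  }
  embedding_table(re(entities_path, kg$entity_labels),
                  re(relations_path, kg$relation_labels))
}
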