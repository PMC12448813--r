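# Joint training of the association model: entity/relation embeddings
# (initialized by TransE) and the attention-encoder projections are
# optimized with Adam on the cross-entropy link objective plus the weighted
# intra-/inter-graph contrastive terms, with early stopping on validation
# AUC.  The numerical core (forward/backward through the layered attention
# encoder) lives in C++; see src/engine.cpp.

#' Model configuration
#'
#' Defaults mirror the published protocol where one is stated: Adam with
#' learning rate 0.1, batch size 64, at most 200 epochs, early-stopping
#' patience 10, seed 42, `L = 3` propagation layers, contrastive
#' temperature 0.1.  Embedding dimension (64), head count (4), per-layer
#' triple budget (64) and contrastive weights (1e-5) are tunable knobs with
#' no published value.
#'
#' @param embed_dim entity/relation embedding dimension.
#' @param n_layers propagation depth `L` (>= 1).
#' @param n_heads attention heads (must divide `embed_dim`).
#' @param layer_budget per-anchor per-layer triple budget.
#' @param learning_rate Adam learning rate.
#' @param batch_size training mini-batch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation-AUC
#'   improvement).
#' @param seed master seed; all sampling in a run derives from it.
#' @param ablation one of `"full"`, `"no_intra"`, `"no_inter"`, `"no_att"`.
#' @param validation_fraction fraction of training positives held out for
#'   early stopping (matched with an equal number of sampled negatives).
#' @param contrastive a [contrastive_config()].
#' @param transe a [transe_config()]; its `dim` is forced to `embed_dim`.
#' @return object of class `model_config`.
#' @export
model_config <- function(embed_dim = 64L, n_layers = 3L, n_heads = 4L,
                         layer_budget = 64L, learning_rate = 0.1,
                         batch_size = 64L, max_epochs = 200L, patience = 10L,
                         seed = 42L,
                         ablation = c("full", "no_intra", "no_inter",
                                      "no_att"),
                         validation_fraction = 0.1,
                         contrastive = contrastive_config(),
                         transe = transe_config()) {
  ablation <- match.arg(ablation)
  if (n_layers < 1L) stop_mdalink("n_layers must be >= 1")
  if (patience < 1L) stop_mdalink("patience must be >= 1")
  if (embed_dim %% n_heads != 0L)
    stop_mdalink("embed_dim must be divisible by n_heads")
  transe$dim <- as.integer(embed_dim)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 layer_budget = as.integer(layer_budget),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 ablation = ablation,
                 validation_fraction = validation_fraction,
                 contrastive = contrastive, transe = transe),
            class = "model_config")
}

sample_negative_pairs <- function(im, n) {
  zeros <- which(im$values == 0L)
  if (length(zeros) < n)
    stop_mdalink("not enough unknown pairs to sample ", n, " negatives")
  z <- sample(zeros, n)
  cbind(microbe = ((z - 1L) %% nrow(im$values)) + 1L,
        drug = ((z - 1L) %/% nrow(im$values)) + 1L)
}

#' Train the association model
#'
#' Builds the layered local/non-local graphs, pre-trains embeddings with
#' TransE (unless a table is supplied), then jointly optimizes embeddings
#' and encoder projections with Adam on
#' `L_pred + ssl_reg * L_intra + ssl_reg_inter * L_inter`, with per-epoch
#' 1:1 negative resampling and early stopping on validation AUC.
#' Deterministic given `config$seed`.
#'
#' @param kg a [knowledge_graph()].
#' @param im an [interaction_matrix()]; its positive entries are the
#'   training signal.
#' @param alignment an [entity_alignment()].
#' @param config a [model_config()].
#' @param pretrained optional [embedding_table()] to reuse (e.g. shared
#'   across folds); must match `embed_dim`.
#' @return object of class `mdalink_model`: best-epoch parameters, the
#'   packed graphs, the training history and the inputs needed for scoring.
#' @export
train_model <- function(kg, im, alignment, config = model_config(),
                        pretrained = NULL) {
  positives <- which(im$values == 1L, arr.ind = TRUE)
  if (nrow(positives) < 2L)
    stop_mdalink("training requires at least 2 positive interactions")
  L <- config$n_layers
  use_att <- config$ablation != "no_att"
  use_intra <- config$ablation != "no_intra" &&
    config$contrastive$intra_weight > 0
  use_inter <- config$ablation != "no_inter" &&
    config$contrastive$inter_weight > 0
  if (is.null(pretrained)) {
    tcfg <- config$transe
    tcfg$dim <- config$embed_dim
    pretrained <- transe_pretrain(kg, tcfg)
  }
  if (pretrained$dim != config$embed_dim)
    stop_mdalink("pretrained embedding dim ", pretrained$dim,
                 " != embed_dim ", config$embed_dim)
  withr::with_seed(config$seed, {
    graphs <- build_all_graphs(kg, im, alignment, L, config$layer_budget,
                               seed = sample.int(2^30, 1L))
    pack <- pack_graphs(graphs)
    weights <- encoder_weights(config$embed_dim, config$n_heads)
    n_pos <- nrow(positives)
    n_val <- min(max(1L, round(config$validation_fraction * n_pos)),
                 n_pos - 1L)
    vidx <- sample.int(n_pos, n_val)
    val_pos <- positives[vidx, , drop = FALSE]
    train_pos <- positives[-vidx, , drop = FALSE]
    val_neg <- sample_negative_pairs(im, n_val)
    n_train <- nrow(train_pos)
    epoch_pairs <- lapply(seq_len(config$max_epochs), function(e) {
      neg <- sample_negative_pairs(im, n_train)
      pairs <- rbind(cbind(train_pos, 1L), cbind(neg, 0L))
      pairs[sample.int(nrow(pairs)), , drop = FALSE]
    })
    n_anchor <- pack$n_anchor
    intra_neg <- if (L >= 2L) {
      matrix((2:L)[sample.int(L - 1L, config$max_epochs * 2L * n_anchor,
                              replace = TRUE)],
             config$max_epochs, 2L * n_anchor)
    } else {
      matrix(-1L, config$max_epochs, 2L * n_anchor)
    }
    res <- cpp_train_model(
      pack, pretrained$entity_vectors, pretrained$relation_vectors,
      weights$wq, weights$wk, weights$wv, weights$wo,
      epoch_pairs, intra_neg,
      val_pos[, 1L] - 1L, val_pos[, 2L] - 1L,
      val_neg[, 1L] - 1L, val_neg[, 2L] - 1L,
      list(n_heads = config$n_heads, lr = config$learning_rate,
           batch_size = config$batch_size, max_epochs = config$max_epochs,
           patience = config$patience,
           tau = config$contrastive$temperature,
           w_intra = config$contrastive$intra_weight,
           w_inter = config$contrastive$inter_weight,
           use_att = use_att, use_intra = use_intra,
           use_inter = use_inter))
  })
  weights$wq <- res$wq; weights$wk <- res$wk
  weights$wv <- res$wv; weights$wo <- res$wo
  structure(list(
    embeddings = embedding_table(res$entities, res$relations),
    weights = weights,
    config = config, kg = kg, im = im, alignment = alignment,
    pack = pack, use_attention = use_att,
    history = data.frame(epoch = seq_along(res$train_loss),
                         train_loss = res$train_loss,
                         val_auc = res$val_auc),
    best_epoch = res$best_epoch,
    val_auc = res$best_val_auc
  ), class = "mdalink_model")
}

#' @export
print.mdalink_model <- function(x, ...) {
  cat(sprintf(paste0("<mdalink_model> dim %d, L %d, ablation %s; ",
                     "best epoch %d (val AUC %.4f)\n"),
              x$config$embed_dim, x$config$n_layers, x$config$ablation,
              x$best_epoch, x$val_auc))
  invisible(x)
}

# Final (concatenated) node embeddings for every anchor, via the C++
# encoder: rows are microbes then drugs, length 2*(L+1)*dim each.
anchor_embeddings <- function(state) {
  cpp_encode_anchors(state$pack, state$embeddings$entity_vectors,
                     state$embeddings$relation_vectors,
                     state$weights$wq, state$weights$wk, state$weights$wv,
                     state$weights$wo, state$config$n_heads,
                     state$use_attention)
}

#' Score microbe-drug pairs with a trained model
#'
#' @param object an `mdalink_model`.
#' @param pairs two-column integer matrix (microbe index, drug index).
#' @param ... unused.
#' @return numeric vector of association scores in (0, 1).
#' @export
predict.mdalink_model <- function(object, pairs, ...) {
  emb <- anchor_embeddings(object)
  n_m <- nrow(object$im$values)
  em <- emb[pairs[, 1L], , drop = FALSE]
  ed <- emb[n_m + pairs[, 2L], , drop = FALSE]
  plogis(rowSums(em * ed))
}

#' Balanced k-fold cross-validation of the association model
#'
#' For every fold the test positives are zeroed out of the copy of the
#' interaction matrix used for graph construction and training (leakage
#' control), the model is trained on the remaining positives, and AUC/AUPR
#' are measured on the fold's balanced positive/negative test set.  TransE
#' pre-training is shared across folds (it depends only on the KG).
#'
#' @inheritParams train_model
#' @param k number of folds.
#' @return object of class `mdalink_cv` with per-fold and mean metrics.
#' @export
cross_validate <- function(kg, im, alignment, config = model_config(),
                           k = 5L) {
  folds <- make_folds(im, k, seed = config$seed)
  tcfg <- config$transe
  tcfg$dim <- config$embed_dim
  pre <- transe_pretrain(kg, tcfg)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    im_train <- im
    im_train$values[fold$test_positives] <- 0L
    # leakage guard: no test pair may be visible during graph construction
    stopifnot(all(im_train$values[fold$test_positives] == 0L),
              all(im_train$values[fold$test_negatives] == 0L))
    cfg <- config
    cfg$seed <- config$seed + fold$fold_id
    state <- train_model(kg, im_train, alignment, cfg, pretrained = pre)
    test_pairs <- rbind(fold$test_positives, fold$test_negatives)
    test_labels <- rep(c(1L, 0L), c(nrow(fold$test_positives),
                                    nrow(fold$test_negatives)))
    scores <- predict(state, test_pairs)
    per_fold[[f]] <- data.frame(
      fold = fold$fold_id,
      auc = compute_roc_auc(scores, test_labels),
      aupr = compute_aupr(scores, test_labels),
      best_epoch = state$best_epoch,
      epochs_run = nrow(state$history))
  }
  df <- do.call(rbind, per_fold)
  structure(list(per_fold = df, mean_auc = mean(df$auc),
                 mean_aupr = mean(df$aupr), config = config, k = k),
            class = "mdalink_cv")
}

#' @export
print.mdalink_cv <- function(x, ...) {
  cat(sprintf("<mdalink_cv> %d folds, ablation %s\n", x$k,
              x$config$ablation))
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean AUC %.4f, mean AUPR %.4f\n", x$mean_auc, x$mean_aupr))
  invisible(x)
}

#' Rank candidate partners for a query node
#'
#' Scores the query against every counterpart node, excludes known
#' positives, and returns the top `k` by descending score with ties broken
#' by counterpart index (stable).
#'
#' @param state a trained `mdalink_model`.
#' @param side `"microbe"` or `"drug"`: the side of the query node.
#' @param query query label (string) or 1-based index.
#' @param k number of candidates to return; if it exceeds the number of
#'   available candidates, all are returned with a message.
#' @return data.frame with columns `microbe`, `drug` (labels) and `score`,
#'   sorted by descending score.
#' @export
rank_candidates <- function(state, side = c("microbe", "drug"), query,
                            k = 20L) {
  side <- match.arg(side)
  im <- state$im
  labels <- if (side == "microbe") im$microbe_labels else im$drug_labels
  if (is.character(query)) {
    qi <- match(query, labels)
    if (is.na(qi)) stop_mdalink("unknown ", side, " label: ", query)
  } else {
    qi <- as.integer(query)
  }
  check_anchor(side, qi, im)
  known <- direct_counterparts(side, qi, im)
  n_cp <- if (side == "microbe") ncol(im$values) else nrow(im$values)
  cand <- setdiff(seq_len(n_cp), known)
  if (k > length(cand)) {
    message("only ", length(cand), " candidates available; returning all")
    k <- length(cand)
  }
  pairs <- if (side == "microbe") cbind(qi, cand) else cbind(cand, qi)
  scores <- predict(state, pairs)
  ord <- order(-scores, cand)[seq_len(k)]
  data.frame(
    microbe = if (side == "microbe") rep(labels[qi], k)
              else im$microbe_labels[cand[ord]],
    drug = if (side == "microbe") im$drug_labels[cand[ord]]
           else rep(labels[qi], k),
    score = scores[ord])
}

#' Run the ablation suite
#'
#' Cross-validates the full model and each single-component ablation
#' (`no_intra`, `no_inter`, `no_att`) under a shared base configuration.
#'
#' @inheritParams cross_validate
#' @param variants character vector of variants to run.
#' @return data.frame with one row per variant (mean AUC/AUPR).
#' @export
run_ablation <- function(kg, im, alignment, config = model_config(),
                         k = 5L,
                         variants = c("full", "no_intra", "no_inter",
                                      "no_att")) {
  rows <- lapply(variants, function(v) {
    cfg <- config
    cfg$ablation <- v
    cv <- cross_validate(kg, im, alignment, cfg, k)
    data.frame(variant = v, mean_auc = cv$mean_auc,
               mean_aupr = cv$mean_aupr)
  })
  do.call(rbind, rows)
}
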