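# Intra-graph and inter-graph InfoNCE contrastive losses over per-anchor
# layer embeddings.  Intra: within one graph context, layer 0 is the anchor,
# the adjacent layer 1 the positive, and randomly chosen non-adjacent layers
# (l >= 2) the negatives.  Inter: local layer k is the anchor, the matching
# non-local layer k the positive, and the remaining non-local layers the
# negatives.  Similarity is the raw dot product (cosine behind a flag).

#' Contrastive-loss configuration
#'
#' @param temperature softmax temperature `tau` (> 0); 0.1 follows standard
#'   contrastive-learning practice.
#' @param intra_weight weight of the intra-graph term in the combined
#'   self-supervised loss (`ssl_reg`).
#' @param inter_weight weight of the inter-graph term (`ssl_reg_inter`).
#' @param negatives_per_anchor negatives sampled per anchor/context in the
#'   intra-graph loss.
#' @param cosine use cosine similarity instead of the raw dot product.
#' @param seed seed for negative-layer sampling.
#' @return object of class `contrastive_config`.
#' @export
contrastive_config <- function(temperature = 0.1, intra_weight = 1e-5,
                               inter_weight = 1e-5,
                               negatives_per_anchor = 1L, cosine = FALSE,
                               seed = 42L) {
  if (temperature <= 0) stop_mdalink("temperature must be positive")
  if (intra_weight < 0 || inter_weight < 0)
    stop_mdalink("contrastive weights must be non-negative")
  structure(list(temperature = temperature, intra_weight = intra_weight,
                 inter_weight = inter_weight,
                 negatives_per_anchor = as.integer(negatives_per_anchor),
                 cosine = cosine, seed = as.integer(seed)),
            class = "contrastive_config")
}

sim_fun <- function(cosine) {
  if (cosine) {
    function(a, b) {
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
    }
  } else {
    function(a, b) sum(a * b)
  }
}

#' InfoNCE loss of one anchor/positive pair against a negative set
#'
#' `-log( exp(s(a,p)/tau) / (exp(s(a,p)/tau) + sum_n exp(s(a,n)/tau)) )`,
#' computed with log-sum-exp stabilization.  With zero negatives the loss is
#' exactly 0.
#'
#' @param anchor,positive numeric vectors of equal length.
#' @param negatives list of numeric vectors (possibly empty), or a matrix
#'   with one negative per row.
#' @param temperature softmax temperature.
#' @param cosine use cosine similarity.
#' @return non-negative scalar.
#' @export
infonce <- function(anchor, positive, negatives = list(), temperature = 0.1,
                    cosine = FALSE) {
  if (is.matrix(negatives))
    negatives <- lapply(seq_len(nrow(negatives)), function(i) negatives[i, ])
  s <- sim_fun(cosine)
  z <- c(s(anchor, positive),
         vapply(negatives, function(n) s(anchor, n), numeric(1))) /
    temperature
  m <- max(z)
  -(z[1L] - m - log(sum(exp(z - m))))
}

# Layer-row accessors for the (2*(L+1) x dim) per-anchor embedding stacks
# used across the training modules: rows 1..L+1 local, L+2..2L+2 non-local.
layer_row <- function(context, layer, L) {
  (if (context == "local") 0L else L + 1L) + layer + 1L
}

#' Intra-graph contrastive loss over all anchors
#'
#' For every anchor and each graph context independently, layer 0 is
#' contrasted with the adjacent layer 1 (positive) against up to
#' `negatives_per_anchor` uniformly sampled non-adjacent layers (l >= 2) of
#' the same context; the per-context terms are summed over microbes, drugs
#' and both contexts.  With `L < 2` no valid negatives exist: each term
#' contributes the zero-negative value (0) and a warning is issued.
#'
#' @param local,nonlocal lists over anchors of `(L+1) x dim` layer-embedding
#'   matrices (as returned by [encode_anchor()]), one list element per
#'   anchor (microbes and drugs together or separately; they are simply
#'   summed).
#' @param config a [contrastive_config()].
#' @param seed seed for the negative-layer draw; defaults to `config$seed`.
#' @return non-negative scalar.
#' @export
intra_loss <- function(local, nonlocal, config = contrastive_config(),
                       seed = config$seed) {
  L <- nrow(local[[1L]]) - 1L
  if (L < 2L) {
    warning("intra_loss: L < 2 leaves no non-adjacent negative layers; ",
            "the loss is identically zero")
    return(0)
  }
  nn <- min(config$negatives_per_anchor, L - 1L)
  withr::with_seed(seed, {
    total <- 0
    for (a in seq_along(local)) {
      for (ctx in list(local[[a]], nonlocal[[a]])) {
        negl <- (2:L)[sample.int(L - 1L, nn)]
        negs <- lapply(negl, function(l) ctx[l + 1L, ])
        total <- total +
          infonce(ctx[1L, ], ctx[2L, ], negs, config$temperature,
                  config$cosine)
      }
    }
  })
  total
}

#' Inter-graph contrastive loss over all anchors
#'
#' For every anchor node and every layer `k` in `0..L`, the local layer-`k`
#' vector is the anchor, the matching non-local layer-`k` vector the
#' positive, and the remaining non-local layers the negatives; terms are
#' summed over layers and anchors.  Deterministic (no sampling).
#'
#' @inheritParams intra_loss
#' @return non-negative scalar.
#' @export
inter_loss <- function(local, nonlocal, config = contrastive_config()) {
  L <- nrow(local[[1L]]) - 1L
  total <- 0
  for (a in seq_along(local)) {
    for (k in 0:L) {
      negs <- lapply(setdiff(0:L, k), function(j) nonlocal[[a]][j + 1L, ])
      total <- total + infonce(local[[a]][k + 1L, ], nonlocal[[a]][k + 1L, ],
                               negs, config$temperature, config$cosine)
    }
  }
  total
}

#' Weighted combination of the two contrastive terms
#'
#' `intra_weight * intra + inter_weight * inter`; the supervised objective
#' adds this to the cross-entropy loss.
#'
#' @param intra,inter scalar losses.
#' @param config a [contrastive_config()].
#' @return scalar.
#' @export
combined_ssl <- function(intra, inter, config = contrastive_config()) {
  config$intra_weight * intra + config$inter_weight * inter
}
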