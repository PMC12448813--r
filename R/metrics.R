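# Final scoring, the supervised cross-entropy objective, balanced fold
# construction and threshold-free evaluation metrics (ROC AUC, AUPR).

#' Concatenate local and non-local layer embeddings into a node embedding
#'
#' The final representation of a node is the concatenation of its `L+1`
#' local layer vectors followed by its `L+1` non-local layer vectors
#' (length `2*(L+1)*dim`).
#'
#' @param local,nonlocal `(L+1) x dim` matrices from [encode_anchor()].
#' @return numeric vector of length `2*(L+1)*dim`.
#' @export
final_embedding <- function(local, nonlocal) {
  if (!identical(dim(local), dim(nonlocal)))
    stop_mdalink("local and non-local layer embeddings have mismatched shape")
  c(as.vector(t(local)), as.vector(t(nonlocal)))
}

#' Association score of a microbe/drug embedding pair
#'
#' `sigmoid(e_m . e_d)`: strictly increasing in the dot product and strictly
#' inside (0, 1) for finite embeddings.
#'
#' @param e_m,e_d numeric vectors of equal length.
#' @return scalar in (0, 1).
#' @export
predict_score <- function(e_m, e_d) {
  if (length(e_m) != length(e_d))
    stop_mdalink("embedding lengths differ (", length(e_m), " vs ",
                 length(e_d), ")")
  plogis(sum(e_m * e_d))
}

#' Mean binary cross-entropy of predicted scores
#'
#' Scores are clipped into `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param predictions numeric vector of scores.
#' @param labels binary vector of the same length.
#' @return non-negative scalar.
#' @export
bce_loss <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  eps <- 1e-12
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Balanced k-fold splits of the known positives
#'
#' Positives are shuffled by `seed` and partitioned as evenly as possible;
#' each fold receives test negatives sampled uniformly from the zero entries
#' of the matrix (excluding all known positives), in equal number to its
#' test positives.  Deterministic given `seed`.
#'
#' @param im an [interaction_matrix()].
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` fold objects with fields `fold_id`,
#'   `train_positives`, `test_positives`, `test_negatives` (two-column
#'   integer matrices: microbe, drug).
#' @export
make_folds <- function(im, k = 5L, seed = 42L) {
  pos <- which(im$values == 1L, arr.ind = TRUE)
  dimnames(pos) <- list(NULL, c("microbe", "drug"))
  n_pos <- nrow(pos)
  if (n_pos < k) stop_mdalink("need at least ", k, " positives for ", k,
                              "-fold cross-validation")
  zeros <- which(im$values == 0L)
  withr::with_seed(seed, {
    ord <- sample.int(n_pos)
    fold_of <- rep(seq_len(k), length.out = n_pos)[order(ord)]
    # fold sizes differ by at most one; assignment is a seeded permutation
    folds <- lapply(seq_len(k), function(f) {
      test_idx <- which(fold_of == f)
      n_test <- length(test_idx)
      if (length(zeros) < n_test)
        stop_mdalink("not enough zero entries to balance fold ", f)
      negs <- sample(zeros, n_test)
      test_neg <- cbind(microbe = ((negs - 1L) %% nrow(im$values)) + 1L,
                        drug = ((negs - 1L) %/% nrow(im$values)) + 1L)
      list(fold_id = f,
           train_positives = pos[-test_idx, , drop = FALSE],
           test_positives = pos[test_idx, , drop = FALSE],
           test_negatives = test_neg)
    })
  })
  folds
}

# Tie-grouped cumulative confusion counts, shared by both curve metrics.
curve_counts <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop_mdalink("both classes must be present to compute a curve metric")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(rle(s)$lengths)       # index of last element of each tie run
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  list(tp = tp, fp = fp, n_pos = sum(labels), n_neg = sum(1 - labels))
}

#' Area under the ROC curve
#'
#' Threshold sweep over the distinct scores with trapezoidal handling of
#' ties; equal to the Mann-Whitney statistic normalized by
#' `n_pos * n_neg` (tied pairs count 1/2).
#'
#' @param scores numeric score vector.
#' @param labels binary labels (both classes must be present).
#' @return scalar in \[0, 1\].
#' @export
compute_roc_auc <- function(scores, labels) {
  cc <- curve_counts(scores, labels)
  tpr <- c(0, cc$tp / cc$n_pos)
  fpr <- c(0, cc$fp / cc$n_neg)
  sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation: precision is held constant to the right of each
#' recall step (no optimistic trapezoids); tied scores collapse into a
#' single operating point.
#'
#' @inheritParams compute_roc_auc
#' @return scalar in \[0, 1\].
#' @export
compute_aupr <- function(scores, labels) {
  cc <- curve_counts(scores, labels)
  recall <- cc$tp / cc$n_pos
  precision <- cc$tp / (cc$tp + cc$fp)
  sum(diff(c(0, recall)) * precision)
}

#' ROC curve coordinates
#'
#' Distinct-threshold sweep; one row per tie group plus the origin.
#'
#' @inheritParams compute_roc_auc
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  cc <- curve_counts(scores, labels)
  data.frame(fpr = c(0, cc$fp / cc$n_neg), tpr = c(0, cc$tp / cc$n_pos))
}

#' Precision-recall curve coordinates
#' @inheritParams compute_roc_auc
#' @return data.frame with columns `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  cc <- curve_counts(scores, labels)
  data.frame(recall = cc$tp / cc$n_pos,
             precision = cc$tp / (cc$tp + cc$fp))
}
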