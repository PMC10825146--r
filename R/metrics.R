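# Evaluation statistics: classification metrics, reconstruction/translation
# agreement, latent-space separation, and the GSEA-based rank distance.

#' Classification accuracy and F1
#'
#' One-vs-rest accounting: for each class, samples of that class are the
#' positives and everything else a negative. With more than two classes the
#' micro-averaged F1 is returned (summed TP over summed TP + (FP+FN)/2);
#' with two classes, the plain binary accuracy and F1 of the positive class.
#'
#' @param pred_labels,true_labels equal-length label vectors
#' @param positive for binary problems, which label is the positive class
#'   (default: the last level in sort order)
#' @return list with `accuracy`, `f1`, and the per-class `counts` table
#' @export
#' @examples
#' classification_metrics(c("a", "b", "b"), c("a", "b", "a"))
classification_metrics <- function(pred_labels, true_labels,
                                   positive = NULL) {
  if (length(pred_labels) == 0L) stop("empty input")
  if (length(pred_labels) != length(true_labels)) {
    stop("prediction and truth lengths differ")
  }
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  classes <- sort(unique(c(pred_labels, true_labels)))
  K <- length(classes)
  counts <- t(vapply(classes, function(cl) {
    tp <- sum(pred_labels == cl & true_labels == cl)
    fp <- sum(pred_labels == cl & true_labels != cl)
    fn <- sum(pred_labels != cl & true_labels == cl)
    tn <- sum(pred_labels != cl & true_labels != cl)
    c(TP = tp, FP = fp, FN = fn, TN = tn)
  }, numeric(4)))
  if (K > 2L) {
    accuracy <- (sum(counts[, "TP"]) + sum(counts[, "TN"])) / sum(counts)
    f1 <- sum(counts[, "TP"]) /
      (sum(counts[, "TP"]) + 0.5 * (sum(counts[, "FP"]) + sum(counts[, "FN"])))
  } else {
    pos <- positive %||% classes[K]
    tp <- sum(pred_labels == pos & true_labels == pos)
    fp <- sum(pred_labels == pos & true_labels != pos)
    fn <- sum(pred_labels != pos & true_labels == pos)
    tn <- sum(pred_labels != pos & true_labels != pos)
    accuracy <- (tp + tn) / length(pred_labels)
    f1 <- if (tp + 0.5 * (fp + fn) == 0) 0 else tp / (tp + 0.5 * (fp + fn))
  }
  list(accuracy = accuracy, f1 = f1, counts = counts)
}

#' Global Pearson correlation of flattened matrices
#' @param Y_hat,Y matrices of equal shape (predictions and ground truth)
#' @return a single correlation over all entries
#' @export
pearson_global <- function(Y_hat, Y) {
  stats::cor(as.numeric(as.matrix(Y_hat)), as.numeric(as.matrix(Y)))
}

#' Average per-sample Spearman correlation
#'
#' Rank-correlates each sample (row) separately and averages over samples;
#' ties receive average ranks.
#' @param Y_hat,Y matrices of equal shape
#' @return mean Spearman correlation across rows
#' @export
spearman_per_sample <- function(Y_hat, Y) {
  Y_hat <- as.matrix(Y_hat); Y <- as.matrix(Y)
  stopifnot(all(dim(Y_hat) == dim(Y)))
  mean(vapply(seq_len(nrow(Y)), function(i) {
    stats::cor(Y_hat[i, ], Y[i, ], method = "spearman")
  }, numeric(1)))
}

#' Sign accuracy of predicted regulation
#'
#' Fraction of genes whose direction of regulation agrees: positive in both,
#' negative in both, or a "true zero" -- absolute value at most `tol` in
#' both prediction and truth (a small tolerance rather than exact zero, for
#' numerical reasons).
#'
#' @param Y_hat,Y matrices (or vectors) of equal shape
#' @param tol zero tolerance, default 1e-6
#' @return fraction in [0, 1]
#' @export
sign_accuracy <- function(Y_hat, Y, tol = 1e-6) {
  yh <- as.numeric(as.matrix(Y_hat)); y <- as.numeric(as.matrix(Y))
  stopifnot(length(yh) == length(y))
  true_zero <- abs(yh) <= tol & abs(y) <= tol
  tp <- yh > tol & y > tol
  tn <- yh < -tol & y < -tol
  (sum(tp) + sum(tn) + sum(true_zero)) / length(y)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS`; applied to per-gene mean and variance statistics in
#' the count-mode evaluation.
#' @param stat_hat,stat_true numeric vectors (e.g. per-gene means)
#' @return scalar R^2 (1 for perfect prediction, 0 for predicting the grand
#'   mean)
#' @export
r2_per_gene <- function(stat_hat, stat_true) {
  rss <- sum((stat_hat - stat_true)^2)
  tss <- sum((stat_true - mean(stat_true))^2)
  1 - rss / tss
}

#' Cosine distance between two embeddings
#'
#' `1 - cosine similarity`, ranging from 0 (identical direction) to 2
#' (opposite direction).
#' @param z1,z2 nonzero numeric vectors of equal length
#' @return distance in [0, 2]
#' @export
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))  # orthogonal: 1
cosine_distance <- function(z1, z2) {
  n1 <- sqrt(sum(z1^2)); n2 <- sqrt(sum(z2^2))
  if (n1 == 0 || n2 == 0) stop("cosine distance undefined for zero vectors")
  1 - sum(z1 * z2) / (n1 * n2)
}

#' Cohen's d between two distributions
#'
#' Standardized mean difference with the pooled standard deviation
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2))`; antisymmetric under group
#' swap.
#' @param dist1,dist2 numeric samples of the two distributions
#' @return an `effect_size` list with `d`, group sizes, means and sds
#' @export
cohens_d <- function(dist1, dist2) {
  n1 <- length(dist1); n2 <- length(dist2)
  if (n1 + n2 <= 2L) stop("need more than two observations in total")
  s1 <- stats::sd(dist1); s2 <- stats::sd(dist2)
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (pooled == 0) stop("pooled standard deviation is zero")
  structure(list(d = (mean(dist1) - mean(dist2)) / pooled,
                 n1 = n1, n2 = n2, mean1 = mean(dist1), mean2 = mean(dist2),
                 s1 = s1, s2 = s2),
            class = "effect_size")
}

# unweighted Kolmogorov-Smirnov-style running-sum enrichment score of a gene
# set within a ranking: hit step 1/|S|, miss step 1/(N-|S|), signed by the
# maximum absolute deviation
running_es <- function(in_set) {
  nh <- sum(in_set)
  nm <- length(in_set) - nh
  steps <- ifelse(in_set, 1 / nh, -1 / nm)
  cs <- cumsum(steps)
  cs[which.max(abs(cs))]
}

es_of_in <- function(rank_src, rank_tgt, t) {
  ord_tgt <- order(rank_tgt, decreasing = TRUE)
  ord_src <- order(rank_src, decreasing = TRUE)
  up <- ord_src[seq_len(t)]
  dn <- ord_src[seq(length(rank_src) - t + 1L, length(rank_src))]
  es_up <- running_es(ord_tgt %in% up)
  es_dn <- running_es(ord_tgt %in% dn)
  (es_up - es_dn) / 2
}

#' GSEA-based distance between two ranked profiles
#'
#' For each threshold t, the top-t and bottom-t genes of profile A are scored
#' for enrichment at the corresponding extremes of profile B's ranking (and
#' vice versa) with an unweighted running-sum enrichment score; the distance
#' is `1 - (ES_AinB + ES_BinA)/2`, averaged over thresholds. 0 means the
#' most up- and downregulated genes coincide; 2 means the rankings are
#' reversed; unrelated rankings score about 1. The distance is symmetric and
#' invariant to strictly monotone transforms of either profile.
#'
#' @param rank_A,rank_B numeric score vectors over the same feature universe
#'   (e.g. z-scored expression); genes are ranked by decreasing score
#' @param thresholds integer vector of top/bottom set sizes; the default
#'   c(100, 250, 500) is scaled down proportionally (10/25/50% of the
#'   universe) when fewer than 1000 genes are supplied
#' @return distance in [0, 2]
#' @export
#' @examples
#' x <- rnorm(1000)
#' gsea_distance(x, x)    # 0
#' gsea_distance(x, -x)   # 2
gsea_distance <- function(rank_A, rank_B, thresholds = NULL) {
  stopifnot(length(rank_A) == length(rank_B))
  N <- length(rank_A)
  if (is.null(thresholds)) {
    thresholds <- if (N >= 1000L) c(100L, 250L, 500L) else
      unique(pmax(1L, round(N * c(0.1, 0.25, 0.5))))
  }
  if (any(thresholds > floor(N / 2))) {
    stop("thresholds must not exceed half the gene count")
  }
  if (any(thresholds < 1L)) stop("thresholds must be positive")
  d_t <- vapply(thresholds, function(t) {
    1 - (es_of_in(rank_A, rank_B, t) + es_of_in(rank_B, rank_A, t)) / 2
  }, numeric(1))
  mean(d_t)
}

#' Latent-space separation report
#'
#' Samples pairs of embeddings in four categories -- random pairs, pairs
#' from the same system, pairs from the same condition, and replicate pairs
#' (same condition and system) -- computes their cosine-distance
#' distributions, and quantifies each category's separation from random
#' pairs with Cohen's d. A negative d for same-condition pairs means they
#' sit closer together than random pairs.
#'
#' @param embeddings samples x latent matrix
#' @param metadata data.frame with `system` and `condition` columns
#' @param n_random number of random pairs to sample
#' @param seed RNG seed for pair sampling
#' @return list with `distances` (named list of distance vectors; a category
#'   with fewer than 2 pairs is NULL) and `effects` (data.frame of Cohen's d
#'   per category vs random)
#' @export
latent_separation_report <- function(embeddings, metadata, n_random = 1000,
                                     seed = 1) {
  Z <- as.matrix(embeddings)
  n <- nrow(Z)
  stopifnot(nrow(metadata) == n)
  set.seed(seed)
  cosd <- function(idx) {
    vapply(seq_len(nrow(idx)), function(k) {
      cosine_distance(Z[idx[k, 1L], ], Z[idx[k, 2L], ])
    }, numeric(1))
  }
  rand_idx <- cbind(sample.int(n, n_random, replace = TRUE),
                    sample.int(n, n_random, replace = TRUE))
  rand_idx <- rand_idx[rand_idx[, 1L] != rand_idx[, 2L], , drop = FALSE]
  all_pairs_where <- function(same) {
    out <- which(same & upper.tri(same), arr.ind = TRUE)
    if (nrow(out) > n_random) out[sample.int(nrow(out), n_random), ,
                                  drop = FALSE] else out
  }
  sys <- as.character(metadata$system)
  cond <- as.character(metadata$condition)
  cats <- list(
    random = rand_idx,
    same_system = all_pairs_where(outer(sys, sys, "==")),
    same_condition = all_pairs_where(outer(cond, cond, "==") &
                                       outer(sys, sys, "!=")),
    replicate = all_pairs_where(outer(cond, cond, "==") &
                                  outer(sys, sys, "==")))
  distances <- lapply(cats, function(idx) {
    if (nrow(idx) < 2L) NULL else cosd(idx)
  })
  effects <- do.call(rbind, lapply(setdiff(names(cats), "random"),
                                   function(nm) {
    if (is.null(distances[[nm]]) || is.null(distances$random)) {
      data.frame(category = nm, d = NA_real_, n = 0L)
    } else {
      data.frame(category = nm, d = cohens_d(distances[[nm]],
                                             distances$random)$d,
                 n = length(distances[[nm]]))
    }
  }))
  list(distances = distances, effects = effects)
}
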