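# Feature and latent-variable importance: integrated gradients, k-means
# latent selection, likelihood-ratio tests, and the serology
# feature-identification pipeline.

#' Integrated gradients
#'
#' Path-integral attribution with a zero baseline:
#' `IG_i(x) = x_i * integral_0^1 dF(a*x)/dx_i da`, approximated by a
#' trapezoid rule over `n_steps` path points (a left-Riemann rule is
#' available; the trapezoid's O(1/m^2) error is needed for tight
#' completeness). Scores satisfy completeness:
#' `sum_i IG_i(x) ~= F(x) - F(0)` per sample.
#'
#' @param F function mapping a samples x features matrix to a numeric vector
#'   (one output per sample) or matrix of outputs
#' @param x input matrix (a vector is treated as one sample)
#' @param target_index output column to attribute when `F` returns a matrix
#' @param n_steps number of path steps (default 50)
#' @param grad_F optional analytic gradient: `grad_F(X, target_index)`
#'   returning dF/dX of the same shape as X; central finite differences are
#'   used when absent
#' @param method `"trapezoid"` (default) or `"riemann_left"`
#' @param average also return the score vector averaged across samples
#' @return an `importance_result`: `scores` (samples x features),
#'   `average_scores` (when requested), `completeness_error` per sample,
#'   `baseline` (0), `n_steps`, `method`
#' @export
#' @examples
#' w <- c(2, -1)
#' f <- function(X) X %*% w
#' integrated_gradients(f, c(3, 4))$scores  # exactly w_i * x_i
integrated_gradients <- function(F, x, target_index = NULL, n_steps = 50,
                                 grad_F = NULL,
                                 method = c("trapezoid", "riemann_left"),
                                 average = FALSE) {
  method <- match.arg(method)
  if (n_steps < 1L) stop("n_steps must be at least 1")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  n <- nrow(x); d <- ncol(x)
  f_out <- function(X) {
    out <- F(X)
    out <- if (is.matrix(out)) {
      if (is.null(target_index)) {
        if (ncol(out) != 1L) stop("F returns a matrix; give target_index")
        out[, 1L]
      } else out[, target_index]
    } else as.numeric(out)
    out
  }
  g_fn <- if (!is.null(grad_F)) {
    function(X) grad_F(X, target_index)
  } else {
    function(X) {
      h <- 1e-4
      G <- matrix(0, nrow(X), d)
      for (i in seq_len(d)) {
        Xp <- X; Xp[, i] <- Xp[, i] + h
        Xm <- X; Xm[, i] <- Xm[, i] - h
        G[, i] <- (f_out(Xp) - f_out(Xm)) / (2 * h)
      }
      G
    }
  }
  if (method == "trapezoid") {
    alphas <- seq(0, 1, length.out = n_steps + 1L)
    wts <- c(1, rep(2, n_steps - 1L), 1) / (2 * n_steps)
  } else {
    alphas <- seq(0L, n_steps - 1L) / n_steps
    wts <- rep(1 / n_steps, n_steps)
  }
  G_acc <- matrix(0, n, d)
  for (k in seq_along(alphas)) G_acc <- G_acc + wts[k] * g_fn(alphas[k] * x)
  scores <- x * G_acc
  delta <- f_out(x) - f_out(matrix(0, n, d))
  res <- list(scores = scores,
              average_scores = if (average) colMeans(scores) else NULL,
              completeness_error = rowSums(scores) - delta,
              baseline = 0, n_steps = n_steps, method = method)
  class(res) <- "importance_result"
  res
}

#' Differentiable views of a trained model for attribution
#'
#' Returns a function/gradient pair suitable for [integrated_gradients()]:
#' `target = "latent"` exposes one latent coordinate of the system's encoder,
#' `target = "translation"` one output feature of the source-to-target
#' translation map, `target = "classifier"` one logit of a task classifier
#' evaluated on the global space. All views run in evaluation mode
#' (deterministic).
#'
#' @param model a `translator_model`
#' @param target which model output to expose
#' @param system input system
#' @param to target system for `"translation"`
#' @param classifier task-classifier name for `"classifier"`
#' @return list with elements `F` and `grad` (analytic, via the tape)
#' @export
ig_model_fn <- function(model, target = c("latent", "translation",
                                          "classifier"),
                        system, to = NULL, classifier = NULL) {
  target <- match.arg(target)
  forward <- function(Xn) {
    z <- encoder_forward(model, wrap_env$pn, Xn, system)
    switch(target,
           latent = z,
           translation = {
             if (model$config$variant == "v2" &&
                 model$config$compose_mode == "additive") {
               z <- nd_add_rowvec(z, nd_rows(wrap_env$pn[["cov_system"]],
                                             match(to, model$systems)))
             }
             out <- decoder_forward(model, wrap_env$pn, z, to)
             if (is.list(out) && !inherits(out, "lb_node")) out$mu else out
           },
           classifier = mlp_forward(wrap_env$pn,
                                    paste0("class_", classifier), z))
  }
  wrap_env <- new.env()
  list(
    F = function(X) {
      wrap_env$pn <- wrap_params(model$params)
      forward(nd(as.matrix(X)))$value
    },
    grad = function(X, j) {
      wrap_env$pn <- wrap_params(model$params)
      xn <- nd(as.matrix(X))
      out <- forward(xn)
      sel <- matrix(0, ncol(out$value), 1L)
      sel[j, 1L] <- 1
      root <- nd_mean_all(nd_matmul(out, nd(sel)))
      root <- nd_scale(root, nrow(out$value))  # sum over samples
      nd_backward(root)
      nd_grad(xn)
    })
}

#' Split latent variables into important and unimportant sets by k-means
#'
#' Clusters absolute importance scores into three clusters: an unimportant
#' cluster, an important cluster, and a small high-score outlier cluster.
#' The threshold is the midpoint between the highest score in the
#' unimportant cluster and the lowest score in the important (middle)
#' cluster; every variable above the threshold (important cluster plus
#' outliers) is selected. Deterministic under the fixed seed and restarts.
#'
#' @param abs_scores non-negative scores, one per latent variable (named
#'   vectors keep their names in the output)
#' @param restarts k-means restarts (default 10)
#' @param seed RNG seed
#' @return list with `important` (indices or names), `threshold`, and the
#'   cluster assignment
#' @export
kmeans_importance_split <- function(abs_scores, restarts = 10, seed = 1) {
  s <- abs_scores
  if (length(unique(s)) < 3L) {
    stop("no separation: need at least 3 distinct score values")
  }
  set.seed(seed)
  km <- stats::kmeans(matrix(s, ncol = 1L), centers = 3L, nstart = restarts)
  ord <- order(km$centers)  # low, mid, high(outlier)
  low <- which(km$cluster == ord[1L])
  mid <- which(km$cluster == ord[2L])
  threshold <- (max(s[low]) + min(s[mid])) / 2
  sel <- which(s > threshold)
  important <- if (!is.null(names(s))) names(s)[sel] else sel
  list(important = important, threshold = threshold,
       clusters = stats::setNames(match(km$cluster, ord), names(s)))
}

#' Likelihood-ratio test of a protection effect on each latent variable
#'
#' For every latent variable, fits the linear models
#' `z_i ~ protection + vaccination + species` (alternative) and
#' `z_i ~ vaccination + species` (null) and computes
#' `LRT = -2 ln(L(H0)/L(HA))`, its chi-square p value,
#' Benjamini-Hochberg-adjusted p, and the t value of the protection
#' coefficient.
#'
#' @param Z samples x latent embedding matrix
#' @param protection,vaccination,species per-sample covariates
#' @return data.frame with one row per latent variable: `latent`, `lrt`,
#'   `df`, `p`, `fdr`, `t`
#' @export
lrt_latent <- function(Z, protection, vaccination, species) {
  Z <- as.matrix(Z)
  df <- data.frame(protection = protection, vaccination = vaccination,
                   species = species)
  mm <- stats::model.matrix(~ protection + vaccination + species, df)[, -1L,
                                                                      drop = FALSE]
  # a constant covariate simply drops out (identical likelihoods, LRT = 0);
  # an error is raised only for genuinely collinear covariate *pairs*
  keep <- apply(mm, 2L, stats::var) > 0
  if (sum(keep) >= 2L) {
    cc <- stats::cor(mm[, keep, drop = FALSE])
    bad <- which(abs(cc) > 1 - 1e-12 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("collinear covariates: ", colnames(cc)[bad[1L, 1L]], " and ",
           colnames(cc)[bad[1L, 2L]])
    }
  }
  res <- lapply(seq_len(ncol(Z)), function(i) {
    d <- cbind(z = Z[, i], df)
    fitA <- stats::lm(z ~ protection + vaccination + species, data = d)
    fit0 <- stats::lm(z ~ vaccination + species, data = d)
    lrt <- as.numeric(2 * (stats::logLik(fitA) - stats::logLik(fit0)))
    dfree <- attr(stats::logLik(fitA), "df") - attr(stats::logLik(fit0), "df")
    co <- summary(fitA)$coefficients
    trow <- grep("^protection", rownames(co))
    tval <- if (length(trow)) co[trow[1L], "t value"] else NA_real_
    if (dfree < 1L) {  # protection dropped out: identical likelihoods
      data.frame(latent = i, lrt = 0, df = 0L, p = 1, t = tval)
    } else {
      data.frame(latent = i, lrt = max(lrt, 0), df = dfree,
                 p = stats::pchisq(max(lrt, 0), df = dfree,
                                   lower.tail = FALSE),
                 t = tval)
    }
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("latent", "lrt", "df", "p", "fdr", "t")]
}

#' Select protection-associated latent variables
#'
#' Intersects the FDR-significant latent variables of the likelihood-ratio
#' test with the integrated-gradient-important ones (average percentage
#' importance across folds at least `pct_threshold`, where the percentage
#' base is the fold's maximum absolute score), keeping only variables whose
#' protection-coefficient sign agrees with the sign of the mean gradient
#' score.
#'
#' @param lrt output of [lrt_latent()]
#' @param ig_scores latent x folds matrix (or vector) of signed
#'   integrated-gradient scores from the protection classifier
#' @param pct_threshold minimum average percentage importance (default 10)
#' @param alpha FDR level (default 0.05)
#' @return list with `selected` (latent indices), and the per-variable
#'   decision `table`
#' @export
select_protective_latents <- function(lrt, ig_scores, pct_threshold = 10,
                                      alpha = 0.05) {
  S <- if (is.matrix(ig_scores)) ig_scores else matrix(ig_scores, ncol = 1L)
  stopifnot(nrow(S) == nrow(lrt))
  pct <- apply(S, 2L, function(col) 100 * abs(col) / max(abs(col)))
  pct <- if (is.matrix(pct)) rowMeans(pct) else pct
  mean_score <- rowMeans(S)
  tab <- data.frame(latent = lrt$latent, fdr = lrt$fdr, t = lrt$t,
                    avg_pct = pct, mean_score = mean_score)
  tab$significant_lrt <- tab$fdr < alpha
  tab$important_ig <- tab$avg_pct >= pct_threshold
  tab$sign_agree <- sign(tab$t) == sign(tab$mean_score) & tab$mean_score != 0
  tab$selected <- tab$significant_lrt & tab$important_ig & tab$sign_agree
  list(selected = tab$latent[tab$selected], table = tab)
}

#' Score source-system features against protection-associated latents
#'
#' Integrated-gradient score of every input feature of the source system
#' for every selected latent variable, averaged across that system's
#' samples; percentage scores are relative to the maximum absolute score
#' and features at or above 20% are flagged. When a per-sample `protection`
#' label is supplied (same-species validation), a Wilcoxon rank-sum test
#' between protected and unprotected samples is attached per feature with
#' Bonferroni correction.
#'
#' On standardized (per-feature zero-mean) panels the plain sample average
#' of signed attributions cancels towards zero for every feature; the
#' `"class_contrast"` aggregation instead subtracts the mean attribution of
#' unprotected samples from that of protected samples, isolating each
#' feature's protection-linked contribution to the selected latents. It is
#' the default whenever protection labels are supplied.
#'
#' @param model a trained `translator_model`
#' @param data `omics_dataset` of the source system
#' @param important_latents latent indices from
#'   [select_protective_latents()]
#' @param source_system system name of `data`
#' @param protection optional binary per-sample labels
#' @param n_steps integrated-gradient path steps
#' @param aggregate how per-sample scores are averaged: `"mean"` over all
#'   samples, or `"class_contrast"` (difference of protected and
#'   unprotected class means; requires `protection`)
#' @return data.frame ordered by decreasing score magnitude: `feature`,
#'   per-latent aggregated scores, `score` (mean magnitude over latents),
#'   `pct`, `flag20`, and Wilcoxon columns when labels are given
#' @export
rank_cross_system_features <- function(model, data, important_latents,
                                       source_system, protection = NULL,
                                       n_steps = 50,
                                       aggregate = if (is.null(protection))
                                         "mean" else "class_contrast") {
  if (length(important_latents) == 0L) {
    stop("important_latents is empty")
  }
  aggregate <- match.arg(aggregate, c("mean", "class_contrast"))
  if (aggregate == "class_contrast" && is.null(protection)) {
    stop("class_contrast aggregation requires protection labels")
  }
  X <- data$matrix
  fn <- ig_model_fn(model, "latent", source_system)
  per_latent <- vapply(important_latents, function(j) {
    ig <- integrated_gradients(fn$F, X, target_index = j, n_steps = n_steps,
                               grad_F = fn$grad)
    if (aggregate == "class_contrast") {
      colMeans(ig$scores[protection == 1, , drop = FALSE]) -
        colMeans(ig$scores[protection == 0, , drop = FALSE])
    } else {
      colMeans(ig$scores)
    }
  }, numeric(ncol(X)))
  per_latent <- matrix(per_latent, ncol = length(important_latents),
                       dimnames = list(data$feature_ids,
                                       paste0("latent", important_latents)))
  score <- rowMeans(abs(per_latent)) * sign(rowMeans(per_latent))
  pct <- 100 * abs(score) / max(abs(score))
  out <- data.frame(feature = data$feature_ids, per_latent, score = score,
                    pct = pct, flag20 = pct >= 20, row.names = NULL)
  if (!is.null(protection)) {
    p_w <- vapply(seq_len(ncol(X)), function(i) {
      stats::wilcox.test(X[protection == 1, i], X[protection == 0, i],
                         exact = FALSE)$p.value
    }, numeric(1))
    out$p_wilcoxon <- p_w
    out$p_bonferroni <- stats::p.adjust(p_w, method = "bonferroni")
  }
  out[order(-abs(out$score)), ]
}

#' Filter cross-system feature pairs into a network edge list
#'
#' Applies, in order: (1) source-feature reconstruction correlation at least
#' `r_min` (inclusive); (2) across-fold importance standard deviation in the
#' bottom quartile of all input pairs; (3) importance magnitude greater than
#' `magnitude_min` (raw signed score scale); (4) importance magnitude in the
#' top quartile of the pairs passing (1)-(3). Output is a subset of the
#' input and deterministic.
#'
#' @param pair_scores data.frame with columns `source`, `target`,
#'   `importance`, `fold_sd`
#' @param recon_r named vector of reconstruction correlations per source
#'   feature
#' @param r_min criterion-1 threshold (default 0.75)
#' @param magnitude_min criterion-3 threshold (default 10)
#' @return the surviving rows of `pair_scores`
#' @export
build_feature_network <- function(pair_scores, recon_r, r_min = 0.75,
                                  magnitude_min = 10) {
  ps <- as.data.frame(pair_scores)
  if (nrow(ps) == 0L) return(ps)
  stopifnot(all(c("source", "target", "importance", "fold_sd") %in% names(ps)))
  q1 <- stats::quantile(ps$fold_sd, 0.25)
  keep <- recon_r[ps$source] >= r_min &
    ps$fold_sd <= q1 &
    abs(ps$importance) > magnitude_min
  keep[is.na(keep)] <- FALSE
  passed <- ps[keep, , drop = FALSE]
  if (nrow(passed) == 0L) return(passed)
  q3 <- stats::quantile(abs(passed$importance), 0.75)
  passed[abs(passed$importance) >= q3, , drop = FALSE]
}

#' Median percentile rank of feature scores per category
#'
#' Percentile ranks are computed over all features
#' (`100 * rank / n`, average ranks for ties) and the median is taken
#' within each category.
#'
#' @param scores numeric feature scores
#' @param categories category label per feature
#' @return data.frame with `category` and `median_percentile`
#' @export
percentile_rank_summary <- function(scores, categories) {
  if (anyNA(categories) || any(!nzchar(as.character(categories)))) {
    stop("unknown category label")
  }
  pr <- 100 * rank(scores, ties.method = "average") / length(scores)
  agg <- tapply(pr, as.character(categories), stats::median)
  data.frame(category = names(agg), median_percentile = as.numeric(agg),
             row.names = NULL)
}

#' Pre-ranked gene-set enrichment with a permutation null
#'
#' Running-sum enrichment score (the same unweighted kernel as the GSEA
#' rank distance) of each gene set in the ranking induced by the scores;
#' p values come from permuting gene labels.
#'
#' @param importance_scores named numeric vector of gene-level scores
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()])
#' @param n_perm number of label permutations
#' @param seed RNG seed
#' @return data.frame with `set`, `size` (overlap with the universe), `ES`,
#'   `p`; sets overlapping the universe in fewer than 2 genes are skipped
#'   with a warning
#' @export
preranked_enrichment <- function(importance_scores, gene_sets,
                                 n_perm = 1000, seed = 1) {
  if (length(gene_sets) == 0L) {
    return(data.frame(set = character(0), size = integer(0),
                      ES = numeric(0), p = numeric(0)))
  }
  stopifnot(!is.null(names(importance_scores)))
  set.seed(seed)
  universe <- names(importance_scores)
  ord <- order(importance_scores, decreasing = TRUE)
  genes_ranked <- universe[ord]
  n <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set_genes <- intersect(gene_sets[[nm]], universe)
    k <- length(set_genes)
    if (k < 2L) {
      warning("gene set '", nm, "' overlaps the universe in fewer than 2 ",
              "genes; skipped")
      return(NULL)
    }
    es <- running_es(genes_ranked %in% set_genes)
    es_null <- vapply(seq_len(n_perm), function(b) {
      running_es(seq_len(n) %in% sample.int(n, k))
    }, numeric(1))
    p <- (1 + sum(abs(es_null) >= abs(es))) / (n_perm + 1)
    data.frame(set = nm, size = k, ES = es, p = p)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Read gene sets from a GMT file
#' @param path GMT file: per line, set name, description, then gene ids,
#'   tab-separated
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  sets
}

#' Write a feature-network edge list
#' @param edges output of [build_feature_network()]
#' @param path output path (tab-delimited, importable by graph tools)
#' @return invisibly, the edge table
#' @export
write_edge_list <- function(edges, path) {
  data.table::fwrite(data.table::as.data.table(edges), path, sep = "\t")
  invisible(edges)
}
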