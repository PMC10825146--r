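# Every term of the training objective, as plain numeric functions. The
# training loop computes the same quantities through tape nodes (R/ad.R);
# the two routes are cross-checked in the tests.

#' Loss-term weights
#'
#' The multipliers of the weighted objective. All default to 1 and are fully
#' configurable; [default_train_weights()] gives the package's training
#' defaults (small L2/MI/prior weights chosen so that training converges on
#' the synthetic benchmark, see the vignette).
#'
#' @param recon,distance,MI,prior,cosine weights of the respective terms
#' @param enc,dec length-2 weights of the per-system encoder/decoder L2 terms
#' @param L2class,class per-classifier L2 and entropy weights
#' @param adverse,trained_effect v2 adversarial-entropy and covariate-L2
#'   weights
#' @return a `loss_weights` list
#' @export
loss_weights <- function(recon = 1, distance = 1, MI = 1, prior = 1,
                         cosine = 1, enc = c(1, 1), dec = c(1, 1),
                         L2class = 1, class = 1, adverse = 1,
                         trained_effect = 1) {
  w <- list(recon = recon, distance = distance, MI = MI, prior = prior,
            cosine = cosine, enc = enc, dec = dec, L2class = L2class,
            class = class, adverse = adverse,
            trained_effect = trained_effect)
  vals <- unlist(w)
  if (any(!is.finite(vals))) stop("loss weights must be finite")
  if (any(vals < 0)) stop("loss weights must be non-negative")
  class(w) <- "loss_weights"
  w
}

#' @rdname loss_weights
#' @export
default_train_weights <- function() {
  loss_weights(recon = 1, distance = 1, MI = 0.1, prior = 0.01, cosine = 1,
               enc = c(1e-4, 1e-4), dec = c(1e-4, 1e-4), L2class = 1e-4,
               class = 1, adverse = 0.1, trained_effect = 1e-4)
}

#' Prior discriminator loss (adversarial uniform-prior term)
#'
#' `L_prior = mean(log D(v) + log(1 - D(z)))` over the batch, natural log,
#' where `v` are embeddings sampled from the uniform [0,1] prior and `z` the
#' global embeddings. Scores must already lie strictly inside (0, 1) --
#' clamping is the caller's responsibility.
#'
#' @param discr2_scores_v discriminator outputs on prior samples
#' @param discr2_scores_z discriminator outputs on embeddings
#' @return scalar loss
#' @export
#' @examples
#' prior_loss(0.5, 0.5)  # 2 * log(0.5)
prior_loss <- function(discr2_scores_v, discr2_scores_z) {
  if (length(discr2_scores_v) != length(discr2_scores_z)) {
    stop("score vectors must have equal length")
  }
  if (any(discr2_scores_v <= 0 | discr2_scores_v >= 1) ||
      any(discr2_scores_z <= 0 | discr2_scores_z >= 1)) {
    stop("discriminator scores must lie strictly in (0, 1)")
  }
  mean(log(discr2_scores_v) + log(1 - discr2_scores_z))
}

#' Jensen-Shannon mutual-information loss
#'
#' From the pairwise score matrix of the MI estimator and the binary mask of
#' positives (same condition, different system; zero diagonal):
#' `E_p = mean over positives of [ln 2 - softplus(-D)]`,
#' `E_q = mean over off-diagonal negatives of [softplus(-D) + D - ln 2]`,
#' `L_MI = -(E_p - E_q)`.
#'
#' @param pair_scores square score matrix from the MI estimator
#' @param mask binary positive mask, symmetric with zero diagonal
#' @return list with `L_MI`, `E_p`, `E_q`
#' @export
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2)
#' mi_loss(matrix(0, 2, 2), m)  # all zero: softplus(0) = ln 2
mi_loss <- function(pair_scores, mask) {
  D <- as.matrix(pair_scores)
  m <- as.matrix(mask)
  stopifnot(nrow(D) == ncol(D), all(dim(D) == dim(m)))
  if (any(diag(m) != 0)) stop("mask must have a zero diagonal")
  q <- (1 - m) * (1 - diag(nrow(m)))
  if (sum(m) == 0 || sum(q) == 0) {
    stop("mask needs at least one positive and one negative off-diagonal ",
         "entry; skip the MI term for this batch")
  }
  sp <- stable_softplus(-D)
  E_p <- sum(m * (log(2) - sp)) / sum(m)
  E_q <- sum(q * (sp + D - log(2))) / sum(q)
  list(L_MI = -(E_p - E_q), E_p = E_p, E_q = E_q)
}

#' Latent alignment losses over positive pairs
#'
#' `L_distance` is the mean Euclidean distance and `L_cosine` the mean cosine
#' similarity between the embeddings of each positive pair. Note the cosine
#' term is *subtracted* in the total objective, i.e. cosine similarity is
#' maximized.
#'
#' @param Z embedding matrix (samples x latent)
#' @param pairs a `pair_index` or a two-column index matrix of positive pairs
#' @param squared use squared Euclidean distance instead
#' @return list with `L_distance`, `L_cosine`
#' @export
pair_alignment_losses <- function(Z, pairs, squared = FALSE) {
  pp <- if (inherits(pairs, "pair_index")) pairs$positive_pairs else
    as.matrix(pairs)
  if (nrow(pp) == 0L) stop("at least one positive pair is required")
  Z <- as.matrix(Z)
  A <- Z[pp[, 1L], , drop = FALSE]
  B <- Z[pp[, 2L], , drop = FALSE]
  d2 <- rowSums((A - B)^2)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("cosine similarity undefined for a zero-norm embedding")
  }
  list(L_distance = mean(if (squared) d2 else sqrt(d2)),
       L_cosine = mean(rowSums(A * B) / (na * nb)))
}

#' Reconstruction loss for z-scored profiles
#'
#' Sum of squared errors per sample, averaged across samples:
#' `(1/N) * sum_samples sum_features (x - xhat)^2`.
#'
#' @param X,X_hat observed and reconstructed matrices of equal shape
#' @return scalar loss
#' @export
recon_loss_mse <- function(X, X_hat) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("X and X_hat shapes differ")
  sum((X - X_hat)^2) / nrow(X)
}

#' Negative-binomial reconstruction loss for counts
#'
#' Summed per-gene negative log-likelihood under the NB(mu, theta)
#' parameterization with variance `mu + mu^2/theta`, averaged across
#' samples.
#'
#' @param counts non-negative integer matrix
#' @param mean,dispersion positive matrices (or scalars) of per-entry mu and
#'   inverse dispersion theta
#' @return scalar loss
#' @export
recon_loss_nb <- function(counts, mean, dispersion) {
  K <- as.matrix(counts)
  if (any(K < 0) || any(K != round(K))) {
    stop("counts must be non-negative integers")
  }
  M <- K * 0 + mean
  TH <- K * 0 + dispersion
  if (any(M <= 0) || any(TH <= 0)) stop("mean and dispersion must be positive")
  ll <- lgamma(K + TH) - lgamma(TH) - lgamma(K + 1) +
    TH * (log(TH) - log(TH + M)) + K * (log(M) - log(TH + M))
  -sum(ll) / nrow(K)
}

#' Classifier cross-entropy
#'
#' Mean cross-entropy (natural log) between predicted class probabilities
#' and true labels.
#'
#' @param probs samples x classes probability matrix
#' @param labels integer class indices (1-based) or factor
#' @return scalar loss
#' @export
#' @examples
#' classifier_entropy(matrix(c(0.5, 0.5), 1), 1)  # ln 2
classifier_entropy <- function(probs, labels) {
  P <- as.matrix(probs)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (length(labels) != nrow(P)) stop("one label per probability row required")
  if (any(labels < 1L | labels > ncol(P))) stop("label index out of range")
  -mean(log(P[cbind(seq_len(nrow(P)), labels)]))
}

#' Assemble the loss-term record
#'
#' Container for every term entering the objective; [total_loss()] combines
#' it under a given set of weights.
#'
#' @param L_recon,L_distance,L_cosine,L_MI,E_p,E_q,L_prior scalar terms
#' @param entropy numeric vector, one mean cross-entropy per classifier
#' @param entropy_adverse adversarial classifier cross-entropy (v2)
#' @param L2_encoder,L2_decoder length-2 per-system weight penalties
#' @param L2_classifier per-classifier weight penalties
#' @param L2_trained_effect covariate-vector penalty (v2)
#' @return a `loss_breakdown` list
#' @export
loss_breakdown <- function(L_recon = 0, L_distance = 0, L_cosine = 0,
                           L_MI = 0, E_p = 0, E_q = 0, L_prior = 0,
                           entropy = numeric(0), entropy_adverse = 0,
                           L2_encoder = c(0, 0), L2_decoder = c(0, 0),
                           L2_classifier = numeric(0),
                           L2_trained_effect = 0) {
  structure(list(L_recon = L_recon, L_distance = L_distance,
                 L_cosine = L_cosine, L_MI = L_MI, E_p = E_p, E_q = E_q,
                 L_prior = L_prior, entropy = entropy,
                 entropy_adverse = entropy_adverse,
                 L2_encoder = L2_encoder, L2_decoder = L2_decoder,
                 L2_classifier = L2_classifier,
                 L2_trained_effect = L2_trained_effect),
            class = "loss_breakdown")
}

#' Total training objective
#'
#' The weighted combination of all terms: reconstruction, pair alignment
#' (Euclidean added, cosine subtracted), mutual information, prior, the
#' per-system encoder/decoder L2 penalties, per-classifier entropy and L2
#' terms; the covariate variant (v2) subtracts the adversarial classifier
#' entropy and adds the covariate-vector L2 penalty. The competitive
#' classifier of v3 enters through the ordinary classifier entropy sum.
#'
#' @param parts a [loss_breakdown()]
#' @param w a [loss_weights()]
#' @param variant `"v1"`, `"v2"` or `"v3"`
#' @param prior_sign +1 applies the prior term literally; -1 flips it
#' @return scalar total loss
#' @export
total_loss <- function(parts, w = loss_weights(),
                       variant = c("v1", "v2", "v3"), prior_sign = 1) {
  variant <- match.arg(variant)
  wl <- unlist(w[c("recon", "distance", "MI", "prior", "cosine", "enc",
                   "dec", "L2class", "class", "adverse", "trained_effect")])
  if (any(wl < 0)) stop("loss weights must be non-negative")
  M <- length(parts$entropy)
  wclass <- rep_len(w$class, M)
  wl2class <- rep_len(w$L2class, max(M, length(parts$L2_classifier)))
  total <- w$recon * parts$L_recon +
    w$distance * parts$L_distance +
    w$MI * parts$L_MI +
    prior_sign * w$prior * parts$L_prior +
    sum(rep_len(w$enc, 2) * parts$L2_encoder) +
    sum(rep_len(w$dec, 2) * parts$L2_decoder) +
    sum(rep_len(wl2class, length(parts$L2_classifier)) * parts$L2_classifier) +
    sum(wclass * parts$entropy) -
    w$cosine * parts$L_cosine
  if (variant == "v2") {
    total <- total - w$adverse * parts$entropy_adverse +
      w$trained_effect * parts$L2_trained_effect
  }
  total
}
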