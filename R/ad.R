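# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a plain numeric matrix (scalars are 1x1). A node
# records its parents and one vector-Jacobian-product closure per parent;
# nd_backward() walks nodes in reverse construction order (construction order
# is a topological order by design) and accumulates gradients into the leaves.
# The engine only implements the operations the translator framework needs;
# each op's vjp is checked against central finite differences in the tests.

.nd_env <- new.env(parent = emptyenv())
.nd_env$counter <- 0L

nd_id <- function() {
  .nd_env$counter <- .nd_env$counter + 1L
  .nd_env$counter
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Create a tape node
#'
#' Leaf nodes (parameters or constants) have no parents. Internal use.
#'
#' @param value numeric matrix (scalars as 1x1 matrices)
#' @param parents list of parent nodes
#' @param vjps list of functions, one per parent, mapping the incoming
#'   gradient to that parent's gradient contribution
#' @return a node (environment) with fields `value`, `grad`, `id`
#' @keywords internal
nd <- function(value, parents = list(), vjps = list()) {
  e <- new.env(parent = emptyenv())
  e$value <- as_mat(value)
  e$parents <- parents
  e$vjps <- vjps
  e$grad <- NULL
  e$id <- nd_id()
  class(e) <- "lb_node"
  e
}

nd_value <- function(x) if (inherits(x, "lb_node")) x$value else as_mat(x)

#' Reverse sweep: accumulate gradients of a scalar node into all ancestors
#' @param root scalar node (1x1 value)
#' @keywords internal
nd_backward <- function(root) {
  stopifnot(inherits(root, "lb_node"), length(root$value) == 1L)
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  for (n in nodes) n$grad <- NULL
  root$grad <- matrix(1, 1, 1)
  for (n in nodes[ord]) {
    g <- n$grad
    if (is.null(g)) next
    if (length(n$parents)) {
      for (i in seq_along(n$parents)) {
        pg <- n$vjps[[i]](g)
        p <- n$parents[[i]]
        p$grad <- if (is.null(p$grad)) pg else p$grad + pg
      }
    }
  }
  invisible(root)
}

nd_grad <- function(x) {
  if (is.null(x$grad)) matrix(0, nrow(x$value), ncol(x$value)) else x$grad
}

# ---- core ops ---------------------------------------------------------------

nd_matmul <- function(a, b) {
  A <- a$value; B <- b$value
  nd(A %*% B, list(a, b), list(
    function(g) g %*% t(B),
    function(g) t(A) %*% g
  ))
}

nd_add <- function(a, b) {
  nd(a$value + b$value, list(a, b), list(function(g) g, function(g) g))
}

nd_sub <- function(a, b) {
  nd(a$value - b$value, list(a, b), list(function(g) g, function(g) -g))
}

nd_hadamard <- function(a, b) {
  A <- a$value; B <- b$value
  nd(A * B, list(a, b), list(function(g) g * B, function(g) g * A))
}

# add a 1 x d row vector (e.g. a bias) to every row of an n x d matrix
nd_add_rowvec <- function(a, b) {
  A <- a$value; bv <- b$value
  nd(sweep(A, 2L, as.numeric(bv), "+"), list(a, b), list(
    function(g) g,
    function(g) matrix(colSums(g), 1L)
  ))
}

# multiply every row of an n x d matrix elementwise by a 1 x d vector
# (the count-mode per-gene trainable input scaling)
nd_scale_rowvec <- function(a, w) {
  A <- a$value; wv <- as.numeric(w$value)
  nd(sweep(A, 2L, wv, "*"), list(a, w), list(
    function(g) sweep(g, 2L, wv, "*"),
    function(g) matrix(colSums(g * A), 1L)
  ))
}

nd_scale <- function(a, c) {
  nd(a$value * c, list(a), list(function(g) g * c))
}

nd_add_const <- function(a, c) {
  nd(a$value + c, list(a), list(function(g) g))
}

nd_rbind <- function(a, b) {
  na <- nrow(a$value)
  nd(rbind(a$value, b$value), list(a, b), list(
    function(g) g[seq_len(na), , drop = FALSE],
    function(g) g[-seq_len(na), , drop = FALSE]
  ))
}

nd_rows <- function(a, idx) {
  A <- a$value
  nd(A[idx, , drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    out
  }))
}

# ---- activations ------------------------------------------------------------

nd_relu <- function(a) {
  A <- a$value
  nd(pmax(A, 0), list(a), list(function(g) g * (A > 0)))
}

nd_leaky_relu <- function(a, slope = 0.01) {
  A <- a$value
  nd(ifelse(A > 0, A, slope * A), list(a),
     list(function(g) g * ifelse(A > 0, 1, slope)))
}

nd_elu <- function(a, alpha = 1) {
  A <- a$value
  val <- ifelse(A > 0, A, alpha * (exp(pmin(A, 0)) - 1))
  nd(val, list(a), list(function(g) g * ifelse(A > 0, 1, val + alpha)))
}

nd_sigmoid <- function(a) {
  s <- stable_sigmoid(a$value)
  nd(s, list(a), list(function(g) g * s * (1 - s)))
}

nd_tanh <- function(a) {
  t <- tanh(a$value)
  nd(t, list(a), list(function(g) g * (1 - t^2)))
}

nd_softplus <- function(a) {
  A <- a$value
  nd(stable_softplus(A), list(a), list(function(g) g * stable_sigmoid(A)))
}

#' Numerically stable softplus log(1 + exp(x))
#'
#' Branches at |x| > 30 so that neither exp() overflow nor catastrophic
#' cancellation occurs: for large x, softplus(x) = x + log1p(exp(-x)).
#'
#' @param x numeric vector or matrix
#' @return softplus evaluated elementwise
#' @export
#' @examples
#' stable_softplus(c(-1000, 0, 1000))
stable_softplus <- function(x) {
  out <- x
  hi <- x > 30
  lo <- !hi
  out[hi] <- x[hi] + log1p(exp(-x[hi]))
  out[lo] <- log1p(exp(x[lo]))
  out
}

stable_sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# ---- reductions and losses --------------------------------------------------

nd_sumsq <- function(a) {
  A <- a$value
  nd(sum(A^2), list(a), list(function(g) g[1] * 2 * A))
}

nd_abs_sum <- function(a) {
  A <- a$value
  nd(sum(abs(A)), list(a), list(function(g) g[1] * sign(A)))
}

nd_mean_all <- function(a) {
  A <- a$value
  nd(mean(A), list(a), list(function(g) matrix(g[1] / length(A), nrow(A), ncol(A))))
}

# mean over samples of the per-sample sum of squared reconstruction errors
nd_mse_recon <- function(x, xhat) {
  X <- nd_value(x); Xh <- xhat$value
  n <- nrow(X)
  nd(sum((X - Xh)^2) / n, list(xhat), list(function(g) g[1] * 2 * (Xh - X) / n))
}

# mean over samples of the summed per-gene negative binomial negative
# log-likelihood; counts are constant, mu and theta are tape nodes
nd_nb_nll <- function(counts, mu, theta) {
  K <- nd_value(counts); M <- mu$value; TH <- theta$value
  n <- nrow(K)
  ll <- lgamma(K + TH) - lgamma(TH) - lgamma(K + 1) +
    TH * (log(TH) - log(TH + M)) + K * (log(M) - log(TH + M))
  val <- -sum(ll) / n
  dmu <- -(K / M - (K + TH) / (TH + M)) / n
  dth <- -(digamma(K + TH) - digamma(TH) + log(TH) + 1 - log(TH + M) -
             TH / (TH + M) - K / (TH + M)) / n
  nd(val, list(mu, theta), list(
    function(g) g[1] * dmu,
    function(g) g[1] * dth
  ))
}

# mean Euclidean distance between paired rows of two embedding matrices
nd_pair_dist <- function(za, zb, eps = 1e-12) {
  A <- za$value; B <- zb$value
  P <- nrow(A)
  d2 <- rowSums((A - B)^2)
  dd <- sqrt(d2 + eps)
  nd(mean(dd), list(za, zb), list(
    function(g) g[1] * (A - B) / (P * dd),
    function(g) g[1] * (B - A) / (P * dd)
  ))
}

# mean cosine similarity between paired rows
nd_pair_cos <- function(za, zb) {
  A <- za$value; B <- zb$value
  P <- nrow(A)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("cosine similarity undefined for a zero-norm embedding")
  }
  cs <- rowSums(A * B) / (na * nb)
  nd(mean(cs), list(za, zb), list(
    function(g) g[1] * (B / (na * nb) - A * cs / na^2) / P,
    function(g) g[1] * (A / (na * nb) - B * cs / nb^2) / P
  ))
}

# Jensen-Shannon mutual-information loss from a pairwise score matrix and a
# binary positive mask (zero diagonal); negatives are the off-diagonal zeros.
nd_mi <- function(scores, mask) {
  D <- scores$value
  m <- nd_value(mask)
  n <- nrow(D)
  offdiag <- 1 - diag(n)
  q <- (1 - m) * offdiag
  sm <- sum(m); sq <- sum(q)
  if (sm == 0 || sq == 0) {
    stop("mask must contain at least one positive and one negative ",
         "off-diagonal pair; skip the MI term for this batch")
  }
  sp_neg <- stable_softplus(-D)
  ep <- sum(m * (log(2) - sp_neg)) / sm
  eq <- sum(q * (sp_neg + D - log(2))) / sq
  sig <- stable_sigmoid(D)  # d/dD softplus(-D) = -(1 - sig) = sig - 1
  node <- nd(-(ep - eq), list(scores), list(function(g) {
    dep <- m * (1 - sig) / sm
    deq <- q * sig / sq
    g[1] * (-(dep) + deq)
  }))
  attr(node, "E_p") <- ep
  attr(node, "E_q") <- eq
  node
}

# Eq-1 prior loss computed from discriminator *logits* for numerical safety:
# log sigmoid(t) = -softplus(-t), log(1 - sigmoid(t)) = -softplus(t)
nd_prior_from_logits <- function(logit_v, logit_z) {
  TV <- logit_v$value; TZ <- logit_z$value
  n <- nrow(TV)
  val <- mean(-stable_softplus(-TV)) + mean(-stable_softplus(TZ))
  nd(val, list(logit_v, logit_z), list(
    function(g) g[1] * (1 - stable_sigmoid(TV)) / length(TV),
    function(g) g[1] * (-stable_sigmoid(TZ)) / length(TZ)
  ))
}

# mean cross-entropy (natural log) from logits and integer class labels
nd_cross_entropy <- function(logits, labels) {
  L <- logits$value
  n <- nrow(L)
  stopifnot(length(labels) == n)
  if (any(labels < 1L | labels > ncol(L))) stop("label index out of range")
  mx <- apply(L, 1L, max)
  ex <- exp(L - mx)
  p <- ex / rowSums(ex)
  idx <- cbind(seq_len(n), labels)
  val <- -mean(log(pmax(p[idx], 1e-300)))
  nd(val, list(logits), list(function(g) {
    dp <- p
    dp[idx] <- dp[idx] - 1
    g[1] * dp / n
  }))
}

# batch normalization, training mode: per-column batch statistics (biased
# variance); running statistics updated as a side effect in `state`
nd_batchnorm_train <- function(a, gamma, beta, state, key,
                               momentum = 0.1, eps = 1e-5,
                               update_state = TRUE) {
  A <- a$value
  n <- nrow(A)
  if (n < 2L) stop("batch normalization requires a batch size of at least 2")
  mu <- colMeans(A)
  v <- colMeans(sweep(A, 2L, mu)^2)
  if (update_state) {
    rm_key <- paste0(key, ".mean"); rv_key <- paste0(key, ".var")
    if (is.null(state[[rm_key]])) {
      state[[rm_key]] <- mu
      state[[rv_key]] <- v * n / max(n - 1, 1)
    } else {
      state[[rm_key]] <- (1 - momentum) * state[[rm_key]] + momentum * mu
      state[[rv_key]] <- (1 - momentum) * state[[rv_key]] +
        momentum * v * n / max(n - 1, 1)
    }
  }
  sd_ <- sqrt(v + eps)
  xhat <- sweep(sweep(A, 2L, mu), 2L, sd_, "/")
  gm <- as.numeric(gamma$value); bt <- as.numeric(beta$value)
  val <- sweep(sweep(xhat, 2L, gm, "*"), 2L, bt, "+")
  nd(val, list(a, gamma, beta), list(
    function(g) {
      gxh <- g * rep(gm, each = n)
      cm1 <- colMeans(gxh)
      cm2 <- colMeans(gxh * xhat)
      sweep(gxh - rep(cm1, each = n) - xhat * rep(cm2, each = n),
            2L, sd_, "/")
    },
    function(g) matrix(colSums(g * xhat), 1L),
    function(g) matrix(colSums(g), 1L)
  ))
}

# batch normalization, evaluation mode: affine transform by running statistics
nd_batchnorm_eval <- function(a, gamma, beta, state, key, eps = 1e-5) {
  A <- a$value
  n <- nrow(A)
  rm_ <- state[[paste0(key, ".mean")]]
  rv_ <- state[[paste0(key, ".var")]]
  if (is.null(rm_)) {  # never trained: identity statistics
    rm_ <- rep(0, ncol(A)); rv_ <- rep(1, ncol(A))
  }
  sd_ <- sqrt(rv_ + eps)
  xhat <- sweep(sweep(A, 2L, rm_), 2L, sd_, "/")
  gm <- as.numeric(gamma$value); bt <- as.numeric(beta$value)
  val <- sweep(sweep(xhat, 2L, gm, "*"), 2L, bt, "+")
  nd(val, list(a, gamma, beta), list(
    function(g) sweep(g * rep(gm, each = n), 2L, sd_, "/"),
    function(g) matrix(colSums(g * xhat), 1L),
    function(g) matrix(colSums(g), 1L)
  ))
}

# inverted dropout (training only)
nd_dropout <- function(a, rate) {
  if (rate <= 0) return(a)
  A <- a$value
  mask <- matrix((stats::runif(length(A)) >= rate) / (1 - rate),
                 nrow(A), ncol(A))
  nd(A * mask, list(a), list(function(g) g * mask))
}

# weighted sum of scalar nodes (the Eq 6/7 combination)
nd_weighted_sum <- function(nodes, weights) {
  stopifnot(length(nodes) == length(weights))
  vals <- vapply(nodes, function(n) n$value[1], numeric(1))
  nd(sum(vals * weights), nodes,
     lapply(weights, function(w) function(g) matrix(g[1] * w, 1, 1)))
}

# ---- Adam optimizer ---------------------------------------------------------

#' Initialize Adam optimizer state for a named list of parameter matrices
#' @param params named list of numeric matrices
#' @return optimizer state (environment)
#' @keywords internal
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

#' One Adam update over a subset of parameters
#' @param st optimizer state from [adam_init()]
#' @param params named list of parameter matrices
#' @param grads named list of gradients (subset of params' names)
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @return updated params list
#' @keywords internal
adam_step <- function(st, params, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  params
}

# plain SGD alternative to the adaptive-moment default
sgd_step <- function(st, params, grads, lr, ...) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}
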