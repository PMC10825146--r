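# Reference translation methods: a shared-encoder autoencoder family
# (DeepCellState-style, "DCS"), principal-component projection
# (TransCompR-style), per-gene slope-one-penalized regression (FIT-style),
# and direct translation. All require a shared (homolog-matched) feature
# space between the two systems.

#' Shared-encoder autoencoder specification
#'
#' One common encoder and two system-specific decoders. The input first
#' passes a dropout layer (rate 0.5); hidden layers use leaky-ReLU; the
#' output layer uses tanh; the latent activations carry an L1 sparsity
#' penalty. The `original` variant adds a direct (skip) connection from the
#' input-dropout layer to the output layer; `mod1` removes the skip; `mod2`
#' additionally aligns same-condition latent embeddings *and* penalizes the
#' error of direct cross-system translation; `mod3` keeps only the latent
#' alignment term.
#'
#' @param variant one of `"original"`, `"mod1"`, `"mod2"`, `"mod3"`
#' @param enc_hidden,dec_hidden hidden layer sizes
#' @param latent_dim latent width
#' @param input_dropout dropout rate on the input (default 0.5)
#' @param l1_latent weight of the latent L1 penalty
#' @param align_weight weight of the same-condition latent distance term
#'   (mod2/mod3)
#' @param translate_weight weight of the direct-translation error (mod2)
#' @param epochs,lr,batch_size,seed training settings
#' @return a `dcs_spec` list
#' @export
dcs_spec <- function(variant = c("original", "mod1", "mod2", "mod3"),
                     enc_hidden = c(64), dec_hidden = c(64),
                     latent_dim = 16, input_dropout = 0.5,
                     l1_latent = 1e-4, align_weight = 1,
                     translate_weight = 1, epochs = 100, lr = 1e-3,
                     batch_size = 128, seed = 1) {
  variant <- match.arg(variant)
  structure(list(variant = variant, enc_hidden = enc_hidden,
                 dec_hidden = dec_hidden, latent_dim = latent_dim,
                 input_dropout = input_dropout, l1_latent = l1_latent,
                 align_weight = align_weight,
                 translate_weight = translate_weight, epochs = epochs,
                 lr = lr, batch_size = batch_size, seed = seed),
            class = "dcs_spec")
}

dcs_init <- function(d, spec) {
  p <- list()
  din <- d
  for (i in seq_along(spec$enc_hidden)) {
    p <- init_fc(p, paste0("enc.h", i), din, spec$enc_hidden[i])
    din <- spec$enc_hidden[i]
  }
  p <- init_fc(p, "enc.latent", din, spec$latent_dim)
  for (s in c("A", "B")) {
    din <- spec$latent_dim
    for (i in seq_along(spec$dec_hidden)) {
      p <- init_fc(p, paste0("dec_", s, ".h", i), din, spec$dec_hidden[i])
      din <- spec$dec_hidden[i]
    }
    p <- init_fc(p, paste0("dec_", s, ".out"), din, d, gain = 1)
    if (spec$variant == "original") {
      p <- init_fc(p, paste0("dec_", s, ".skip"), d, d, bias = FALSE,
                   gain = 1)
    }
  }
  p
}

dcs_encode_node <- function(pn, xn, spec, training) {
  h <- if (training) nd_dropout(xn, spec$input_dropout) else xn
  x_drop <- h
  for (i in seq_along(spec$enc_hidden)) {
    h <- nd_leaky_relu(nd_add_rowvec(nd_matmul(h, pn[[paste0("enc.h", i,
                                                             ".W")]]),
                                     pn[[paste0("enc.h", i, ".b")]]))
  }
  z <- nd_add_rowvec(nd_matmul(h, pn[["enc.latent.W"]]),
                     pn[["enc.latent.b"]])
  list(z = z, x_drop = x_drop)
}

dcs_decode_node <- function(pn, z, x_drop, spec, system) {
  pre <- z
  for (i in seq_along(spec$dec_hidden)) {
    key <- paste0("dec_", system, ".h", i)
    pre <- nd_leaky_relu(nd_add_rowvec(nd_matmul(pre, pn[[paste0(key, ".W")]]),
                                       pn[[paste0(key, ".b")]]))
  }
  out <- nd_add_rowvec(nd_matmul(pre, pn[[paste0("dec_", system, ".out.W")]]),
                       pn[[paste0("dec_", system, ".out.b")]])
  if (spec$variant == "original") {
    out <- nd_add(out, nd_matmul(x_drop,
                                 pn[[paste0("dec_", system, ".skip.W")]]))
  }
  nd_tanh(out)
}

#' Train a shared-encoder autoencoder baseline
#'
#' @param data_a,data_b `omics_dataset`s with identical feature spaces (the
#'   method depends on a 1-1 feature mapping)
#' @param pairs a `pair_index`; built from condition keys when NULL
#' @param spec a [dcs_spec()]
#' @return a `dcs_model`
#' @export
dcs_train <- function(data_a, data_b, pairs = NULL, spec = dcs_spec()) {
  if (!identical(data_a$feature_ids, data_b$feature_ids)) {
    stop("shared-encoder baseline requires a 1-1 feature mapping between ",
         "the systems")
  }
  set.seed(spec$seed)
  params <- dcs_init(ncol(data_a$matrix), spec)
  if (is.null(pairs)) pairs <- build_pair_index(list(data_a, data_b))
  na <- nrow(data_a$matrix)
  conds <- c(data_a$samples$condition, data_b$samples$condition)
  opt <- adam_init(params)
  align <- spec$variant %in% c("mod2", "mod3")
  for (epoch in seq_len(spec$epochs)) {
    for (batch in make_condition_batches(conds, spec$batch_size)) {
      ia <- batch[batch <= na]
      ib <- batch[batch > na] - na
      pn <- wrap_params(params)
      terms <- list(); wts <- numeric(0)
      push <- function(node, w) {
        terms[[length(terms) + 1L]] <<- node
        wts <<- c(wts, w)
      }
      za <- zb <- NULL
      if (length(ia)) {
        Xa <- data_a$matrix[ia, , drop = FALSE]
        ea <- dcs_encode_node(pn, nd(Xa), spec, training = TRUE)
        za <- ea$z
        push(nd_mse_recon(Xa, dcs_decode_node(pn, za, ea$x_drop, spec, "A")),
             1)
        push(nd_abs_sum(za), spec$l1_latent / max(length(ia), 1L))
      }
      if (length(ib)) {
        Xb <- data_b$matrix[ib, , drop = FALSE]
        eb <- dcs_encode_node(pn, nd(Xb), spec, training = TRUE)
        zb <- eb$z
        push(nd_mse_recon(Xb, dcs_decode_node(pn, zb, eb$x_drop, spec, "B")),
             1)
        push(nd_abs_sum(zb), spec$l1_latent / max(length(ib), 1L))
        if (align && length(ia)) {
          mask <- pair_mask(pairs, c(ia, ib + na))
          if (sum(mask) > 0) {
            ut <- which(upper.tri(mask) & mask == 1, arr.ind = TRUE)
            Z <- nd_rbind(za, zb)
            Zi <- nd_rows(Z, ut[, 1L]); Zj <- nd_rows(Z, ut[, 2L])
            push(nd_pair_dist(Zi, Zj), spec$align_weight)
            if (spec$variant == "mod2") {
              # direct-translation error on in-batch positive pairs
              src_a <- ut[, 1L]; tgt_b <- ut[, 2L] - length(ia)
              Xa_pair <- data_a$matrix[ia[src_a], , drop = FALSE]
              Xb_pair <- data_b$matrix[ib[tgt_b], , drop = FALSE]
              ea_p <- dcs_encode_node(pn, nd(Xa_pair), spec, training = TRUE)
              push(nd_mse_recon(Xb_pair,
                                dcs_decode_node(pn, ea_p$z, ea_p$x_drop,
                                                spec, "B")),
                   spec$translate_weight)
              eb_p <- dcs_encode_node(pn, nd(Xb_pair), spec, training = TRUE)
              push(nd_mse_recon(Xa_pair,
                                dcs_decode_node(pn, eb_p$z, eb_p$x_drop,
                                                spec, "A")),
                   spec$translate_weight)
            }
          }
        }
      }
      if (!length(terms)) next
      total <- nd_weighted_sum(terms, wts)
      nd_backward(total)
      params <- adam_step(opt, params, collect_grads(pn, names(params)),
                          spec$lr)
    }
  }
  structure(list(params = params, spec = spec,
                 feature_ids = data_a$feature_ids),
            class = "dcs_model")
}

#' Translate (or reconstruct) with a shared-encoder baseline
#' @param model a `dcs_model`
#' @param X input matrix in the shared feature space
#' @param target `"A"` or `"B"`: which decoder to use
#' @return predicted matrix
#' @export
dcs_translate <- function(model, X, target = c("A", "B")) {
  target <- match.arg(target)
  pn <- wrap_params(model$params)
  enc <- dcs_encode_node(pn, nd(as.matrix(X)), model$spec, training = FALSE)
  dcs_decode_node(pn, enc$z, enc$x_drop, model$spec, target)$value
}

#' Latent embeddings of a shared-encoder baseline (evaluation mode)
#' @param model a `dcs_model`
#' @param X input matrix
#' @return samples x latent matrix
#' @export
dcs_encode <- function(model, X) {
  pn <- wrap_params(model$params)
  dcs_encode_node(pn, nd(as.matrix(X)), model$spec, training = FALSE)$z$value
}

# ---- principal-component projection translator ------------------------------

#' Fit a principal-component projection translator
#'
#' Principal components are fitted on the *target* system's profiles; source
#' profiles (shared feature space) are projected into that component space,
#' and a multi-linear regression maps component scores of paired source
#' samples to the paired target profiles. `n_components = 0` reduces to
#' predicting the mean paired target profile.
#'
#' @param data_src,data_tgt `omics_dataset`s with identical feature spaces
#' @param pairs a `pair_index` over the combined data; built when NULL
#' @param n_components number of principal components retained
#' @return a `transcompr_model`
#' @export
transcompr_fit <- function(data_src, data_tgt, pairs = NULL,
                           n_components = 10) {
  if (!identical(data_src$feature_ids, data_tgt$feature_ids)) {
    stop("projection translator requires a shared feature space")
  }
  Xt <- data_tgt$matrix
  if (n_components > min(nrow(Xt), ncol(Xt))) {
    stop("n_components exceeds min(samples, features) of the target data")
  }
  pc <- stats::prcomp(Xt, center = TRUE, scale. = FALSE)
  if (is.null(pairs)) pairs <- build_pair_index(list(data_src, data_tgt))
  pp <- pairs$positive_pairs
  na <- nrow(data_src$matrix)
  src_i <- pp[, 1L]; tgt_j <- pp[, 2L] - na
  if (length(src_i) == 0L) stop("no paired conditions to fit on")
  project <- function(X) {
    Xc <- sweep(as.matrix(X), 2L, pc$center)
    if (n_components == 0L) {
      matrix(0, nrow(Xc), 0L)
    } else {
      Xc %*% pc$rotation[, seq_len(n_components), drop = FALSE]
    }
  }
  S <- project(data_src$matrix[src_i, , drop = FALSE])
  Y <- data_tgt$matrix[tgt_j, , drop = FALSE]
  fit <- stats::lm.fit(cbind(1, S), Y)
  structure(list(center = pc$center, rotation = pc$rotation,
                 n_components = n_components,
                 coef = fit$coefficients,
                 feature_ids = data_src$feature_ids),
            class = "transcompr_model")
}

#' @rdname transcompr_fit
#' @param model a `transcompr_model`
#' @param X source profiles to translate
#' @export
transcompr_translate <- function(model, X) {
  Xc <- sweep(as.matrix(X), 2L, model$center)
  S <- if (model$n_components == 0L) matrix(0, nrow(Xc), 0L) else
    Xc %*% model$rotation[, seq_len(model$n_components), drop = FALSE]
  out <- cbind(1, S) %*% model$coef
  colnames(out) <- model$feature_ids
  out
}

# ---- per-gene slope-one-penalized regression --------------------------------

#' Fit per-gene linear translation with a slope-one penalty
#'
#' For each homolog gene, fits `y = a x + b` over paired conditions,
#' minimizing the squared error plus `penalty * ((a - 1)^2 + b^2)`, which
#' shrinks towards the identity map (slope 1, intercept 0). `penalty = 0`
#' gives ordinary per-gene least squares; `penalty -> Inf` the identity.
#'
#' @param data_src,data_tgt `omics_dataset`s with identical feature spaces
#' @param pairs a `pair_index`; built when NULL
#' @param penalty non-negative ridge strength toward (1, 0)
#' @return a `fit_model` with per-gene `slope` and `intercept`
#' @export
fit_fit <- function(data_src, data_tgt, pairs = NULL, penalty = 1) {
  if (!identical(data_src$feature_ids, data_tgt$feature_ids)) {
    stop("per-gene regression requires a shared feature space")
  }
  if (is.null(pairs)) pairs <- build_pair_index(list(data_src, data_tgt))
  pp <- pairs$positive_pairs
  if (nrow(pp) == 0L) stop("no paired conditions available")
  na <- nrow(data_src$matrix)
  Xs <- data_src$matrix[pp[, 1L], , drop = FALSE]
  Yt <- data_tgt$matrix[pp[, 2L] - na, , drop = FALSE]
  n <- nrow(Xs)
  ab <- vapply(seq_len(ncol(Xs)), function(g) {
    x <- Xs[, g]; y <- Yt[, g]
    if (!is.finite(penalty)) return(c(1, 0))
    A <- matrix(c(sum(x^2) + penalty, sum(x),
                  sum(x), n + penalty), 2L, 2L)
    rhs <- c(sum(x * y) + penalty, sum(y))
    solve(A, rhs)
  }, numeric(2))
  structure(list(slope = ab[1L, ], intercept = ab[2L, ], penalty = penalty,
                 feature_ids = data_src$feature_ids),
            class = "fit_model")
}

#' @rdname fit_fit
#' @param model a `fit_model`
#' @param X source profiles to translate
#' @export
fit_translate <- function(model, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2L, model$slope, "*"), 2L, model$intercept, "+")
}

#' Direct translation baseline
#'
#' Predicts the target system's profile as the unmodified source profile;
#' defined only on a shared feature space.
#'
#' @param X source profiles
#' @param source_features,target_features feature-id vectors; must be
#'   identical
#' @return `X`, unchanged
#' @export
direct_translate <- function(X, source_features = colnames(X),
                             target_features = source_features) {
  if (!identical(as.character(source_features),
                 as.character(target_features))) {
    stop("direct translation requires identical feature spaces")
  }
  as.matrix(X)
}
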