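# Translator model: two system-specific autoencoders around a shared global
# latent space, a mutual-information estimator (Discr1), a prior
# discriminator (Discr2), task classifiers, and -- in the covariate variant
# (v2) -- trainable system/cell-type vectors plus an adversarial system
# classifier.

#' Model and training configuration
#'
#' `mode` presets carry the study-scale hyperparameters (latent dimension,
#' hidden sizes, batch size, epochs, learning rate) of the four full-size
#' study settings; `mode = "desk"` (the default) is the small
#' configuration used for the package's synthetic benchmark experiments.
#' Any field can be overridden explicitly.
#'
#' @param mode preset name: `"desk"`, `"l1000_978"`, `"l1000_10086"`,
#'   `"lung_fibrosis"`, `"serology"`
#' @param latent_dim global latent dimension
#' @param enc_hidden,dec_hidden integer vectors of hidden layer sizes
#' @param class_hidden hidden sizes of task classifiers
#' @param adverse_hidden hidden sizes of the adversarial classifier (v2)
#' @param discr_hidden hidden size of the two discriminators
#' @param batch_size total batch size across both systems
#' @param epochs training epochs
#' @param lr learning rate (adaptive-moment optimizer by default)
#' @param dropout dropout rate in encoder/decoder hidden layers
#' @param variant `"v1"` (basic), `"v2"` (covariate composition + adversary),
#'   `"v3"` (competitive classifier on the global space)
#' @param weights a [loss_weights()] object; `NULL` selects the package's
#'   training defaults (small L2/prior/MI weights, see the vignette)
#' @param data_mode `"zscore"`, `"count"`, or `"serology"` reconstruction mode
#' @param compose_mode `"additive"` covariate vectors or `"network"`
#'   intermediate networks (v2)
#' @param optimizer `"adam"` or `"sgd"`
#' @param pretrain_epochs adversary pretraining epochs (v2); default 10% of
#'   `epochs`
#' @param prior_sign +1 applies the Eq-1 prior term literally in the
#'   minimized objective (the framework then matches the prior); -1 flips it
#' @param seed integer RNG seed; training is deterministic given the seed
#' @return a `model_config` list
#' @export
model_config <- function(mode = c("desk", "l1000_978", "l1000_10086",
                                  "lung_fibrosis", "serology"),
                         latent_dim = NULL, enc_hidden = NULL,
                         dec_hidden = NULL, class_hidden = NULL,
                         adverse_hidden = NULL, discr_hidden = NULL,
                         batch_size = NULL, epochs = NULL, lr = 0.001,
                         dropout = 0.1, variant = c("v1", "v2", "v3"),
                         weights = NULL,
                         data_mode = c("zscore", "count", "serology"),
                         compose_mode = c("additive", "network"),
                         optimizer = c("adam", "sgd"),
                         pretrain_epochs = NULL, prior_sign = 1, seed = 1) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  data_mode <- match.arg(data_mode)
  compose_mode <- match.arg(compose_mode)
  optimizer <- match.arg(optimizer)
  preset <- switch(mode,
    desk = list(latent = 16L, enc = c(64L), dec = c(64L),
                cls = c(32L, 16L), adv = c(32L, 16L), batch = 128L,
                epochs = 150L),
    l1000_978 = list(latent = 292L, enc = c(640L, 384L), dec = c(384L, 640L),
                     cls = c(256L, 128L, 64L), adv = c(256L, 128L, 64L),
                     batch = 512L, epochs = 1000L),
    l1000_10086 = list(latent = 1024L, enc = c(4096L, 2048L, 1024L, 512L),
                       dec = c(512L, 1024L, 2048L, 4096L),
                       cls = c(512L, 256L, 128L), adv = c(512L, 256L, 128L),
                       batch = 512L, epochs = 1000L),
    lung_fibrosis = list(latent = 512L, enc = c(4096L, 2048L, 1024L, 512L),
                         dec = c(512L, 768L, 2048L, 4096L),
                         cls = c(256L, 128L, 64L, 32L),
                         adv = c(512L, 256L, 128L, 64L), batch = 1024L,
                         epochs = 200L),
    serology = list(latent = 32L, enc = c(64L), dec = c(64L),
                    cls = c(32L, 16L, 8L), adv = c(32L, 16L, 8L),
                    batch = 50L, epochs = 2000L))
  latent_dim <- latent_dim %||% preset$latent
  cfg <- list(
    mode = mode,
    latent_dim = latent_dim,
    enc_hidden = enc_hidden %||% preset$enc,
    dec_hidden = dec_hidden %||% preset$dec,
    class_hidden = class_hidden %||% preset$cls,
    adverse_hidden = adverse_hidden %||% preset$adv,
    discr_hidden = discr_hidden %||% latent_dim,
    batch_size = batch_size %||% preset$batch,
    epochs = epochs %||% preset$epochs,
    lr = lr, dropout = dropout, variant = variant,
    weights = weights %||% default_train_weights(),
    data_mode = data_mode, compose_mode = compose_mode,
    optimizer = optimizer,
    pretrain_epochs = pretrain_epochs %||%
      max(1L, round(0.1 * (epochs %||% preset$epochs))),
    prior_sign = prior_sign, seed = seed)
  class(cfg) <- "model_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# layer initializers ----------------------------------------------------------

init_fc <- function(params, prefix, d_in, d_out, bias = TRUE,
                    gain = sqrt(2)) {
  params[[paste0(prefix, ".W")]] <-
    matrix(stats::rnorm(d_in * d_out, sd = gain / sqrt(d_in)), d_in, d_out)
  if (bias) params[[paste0(prefix, ".b")]] <- matrix(0, 1L, d_out)
  params
}

init_bn <- function(params, prefix, d) {
  params[[paste0(prefix, ".gamma")]] <- matrix(1, 1L, d)
  params[[paste0(prefix, ".beta")]] <- matrix(0, 1L, d)
  params
}

# encoder/decoder stack: per hidden layer FC -> BN -> ELU -> dropout,
# final single FC with no trainable bias
init_codec <- function(params, prefix, d_in, hidden, d_out,
                       heads = "out") {
  d <- d_in
  for (i in seq_along(hidden)) {
    lp <- paste0(prefix, ".h", i)
    params <- init_fc(params, lp, d, hidden[i])
    params <- init_bn(params, lp, hidden[i])
    d <- hidden[i]
  }
  for (h in heads) {
    params <- init_fc(params, paste0(prefix, ".", h), d, d_out, bias = FALSE,
                      gain = 1)
  }
  params
}

init_mlp <- function(params, prefix, d_in, hidden, d_out) {
  d <- d_in
  for (i in seq_along(hidden)) {
    params <- init_fc(params, paste0(prefix, ".h", i), d, hidden[i])
    d <- hidden[i]
  }
  init_fc(params, paste0(prefix, ".out"), d, d_out, gain = 1)
}

#' Construct a translator model
#'
#' Builds all components for a pair of systems. The two systems' encoders and
#' decoders share no weights. In count mode the encoder additionally holds a
#' per-gene trainable input scaling vector and the decoder emits two heads
#' (mean and dispersion, both through softplus positivity links).
#'
#' @param d_a,d_b feature-space sizes of the two systems
#' @param config a [model_config()]
#' @param systems character names of the two systems
#' @param classifier_classes named list mapping task-classifier names to
#'   their class labels (e.g. `list(system = c("A","B"))`); v2 classifiers
#'   act on the composed space, v3's competitive classifier on the global
#'   space
#' @param celltypes optional cell-type labels for the v2 cell-type covariate
#' @return an object of class `translator_model`
#' @export
translator_init <- function(d_a, d_b, config = model_config(),
                            systems = c("A", "B"),
                            classifier_classes = NULL, celltypes = NULL) {
  stopifnot(length(systems) == 2L)
  set.seed(config$seed)
  L <- config$latent_dim
  p <- list()
  d_in <- stats::setNames(c(d_a, d_b), systems)
  for (s in systems) {
    ep <- paste0("enc_", s)
    if (config$data_mode == "count") {
      p[[paste0(ep, ".scale")]] <- matrix(1, 1L, d_in[[s]])
    }
    p <- init_codec(p, ep, d_in[[s]], config$enc_hidden, L)
    dp <- paste0("dec_", s)
    heads <- if (config$data_mode == "count") c("mu", "theta") else "out"
    p <- init_codec(p, dp, L, config$dec_hidden, d_in[[s]], heads = heads)
  }
  # Discr1: three FC + ReLU layers and one FC skip; score = product
  h <- config$discr_hidden
  p <- init_fc(p, "discr1.h1", L, h)
  p <- init_fc(p, "discr1.h2", h, h)
  p <- init_fc(p, "discr1.h3", h, h)
  p <- init_fc(p, "discr1.skip", L, h, gain = 1)
  # Discr2: three FC layers, scalar sigmoid output
  p <- init_fc(p, "discr2.h1", L, h)
  p <- init_fc(p, "discr2.h2", h, h)
  p <- init_fc(p, "discr2.out", h, 1L, gain = 1)
  if (!is.null(classifier_classes)) {
    for (nm in names(classifier_classes)) {
      p <- init_mlp(p, paste0("class_", nm), L, config$class_hidden,
                    length(classifier_classes[[nm]]))
    }
  }
  if (config$variant == "v2") {
    p <- init_mlp(p, "adverse", L, config$adverse_hidden, 2L)
    if (config$compose_mode == "additive") {
      p[["cov_system"]] <- matrix(0, 2L, L, dimnames = list(systems, NULL))
      if (!is.null(celltypes)) {
        p[["cov_celltype"]] <- matrix(0, length(celltypes), L,
                                      dimnames = list(celltypes, NULL))
      }
    } else {
      for (s in systems) {
        p <- init_mlp(p, paste0("covnet_", s), L, config$class_hidden, L)
      }
    }
  }
  state <- new.env(parent = emptyenv())
  structure(list(params = p, state = state, config = config,
                 systems = systems, d_in = d_in,
                 classifier_classes = classifier_classes,
                 celltypes = celltypes,
                 feature_ids = NULL, trace = NULL),
            class = "translator_model")
}

wrap_params <- function(params) lapply(params, nd)

# forward through an encoder/decoder stack (tape nodes in, tape node out)
codec_forward <- function(pn, prefix, x, n_hidden, training, state,
                          dropout, update_state, head = "out") {
  h <- x
  for (i in seq_len(n_hidden)) {
    lp <- paste0(prefix, ".h", i)
    h <- nd_matmul(h, pn[[paste0(lp, ".W")]])
    h <- nd_add_rowvec(h, pn[[paste0(lp, ".b")]])
    h <- if (training) {
      nd_batchnorm_train(h, pn[[paste0(lp, ".gamma")]],
                         pn[[paste0(lp, ".beta")]], state, lp,
                         update_state = update_state)
    } else {
      nd_batchnorm_eval(h, pn[[paste0(lp, ".gamma")]],
                        pn[[paste0(lp, ".beta")]], state, lp)
    }
    h <- nd_elu(h)
    if (training) h <- nd_dropout(h, dropout)
  }
  nd_matmul(h, pn[[paste0(prefix, ".", head, ".W")]])
}

mlp_forward <- function(pn, prefix, x) {
  h <- x
  i <- 1L
  while (!is.null(pn[[paste0(prefix, ".h", i, ".W")]])) {
    h <- nd_add_rowvec(nd_matmul(h, pn[[paste0(prefix, ".h", i, ".W")]]),
                       pn[[paste0(prefix, ".h", i, ".b")]])
    h <- nd_relu(h)
    i <- i + 1L
  }
  nd_add_rowvec(nd_matmul(h, pn[[paste0(prefix, ".out.W")]]),
                pn[[paste0(prefix, ".out.b")]])
}

encoder_forward <- function(model, pn, Xnode, system, training = FALSE,
                            update_state = FALSE) {
  prefix <- paste0("enc_", system)
  if (model$config$data_mode == "count") {
    Xnode <- nd_scale_rowvec(Xnode, pn[[paste0(prefix, ".scale")]])
  }
  codec_forward(pn, prefix, Xnode, length(model$config$enc_hidden),
                training, model$state, model$config$dropout, update_state)
}

decoder_forward <- function(model, pn, znode, system, training = FALSE,
                            update_state = FALSE) {
  prefix <- paste0("dec_", system)
  nh <- length(model$config$dec_hidden)
  if (model$config$data_mode == "count") {
    # shared hidden trunk evaluated twice head-by-head would double dropout
    # draws; build the trunk once by reusing codec internals per head with a
    # common hidden representation
    h <- znode
    for (i in seq_len(nh)) {
      lp <- paste0(prefix, ".h", i)
      h <- nd_add_rowvec(nd_matmul(h, pn[[paste0(lp, ".W")]]),
                         pn[[paste0(lp, ".b")]])
      h <- if (training) {
        nd_batchnorm_train(h, pn[[paste0(lp, ".gamma")]],
                           pn[[paste0(lp, ".beta")]], model$state, lp,
                           update_state = update_state)
      } else {
        nd_batchnorm_eval(h, pn[[paste0(lp, ".gamma")]],
                          pn[[paste0(lp, ".beta")]], model$state, lp)
      }
      h <- nd_elu(h)
      if (training) h <- nd_dropout(h, model$config$dropout)
    }
    mu <- nd_add_const(
      nd_softplus(nd_matmul(h, pn[[paste0(prefix, ".mu.W")]])), 1e-8)
    th <- nd_add_const(
      nd_softplus(nd_matmul(h, pn[[paste0(prefix, ".theta.W")]])), 1e-8)
    list(mu = mu, theta = th)
  } else {
    codec_forward(pn, prefix, znode, nh, training, model$state,
                  model$config$dropout, update_state)
  }
}

discr1_forward <- function(pn, znode) {
  h <- nd_relu(nd_add_rowvec(nd_matmul(znode, pn[["discr1.h1.W"]]),
                             pn[["discr1.h1.b"]]))
  h <- nd_relu(nd_add_rowvec(nd_matmul(h, pn[["discr1.h2.W"]]),
                             pn[["discr1.h2.b"]]))
  h <- nd_relu(nd_add_rowvec(nd_matmul(h, pn[["discr1.h3.W"]]),
                             pn[["discr1.h3.b"]]))
  skip <- nd_add_rowvec(nd_matmul(znode, pn[["discr1.skip.W"]]),
                        pn[["discr1.skip.b"]])
  f <- nd_add(h, skip)
  nd_matmul(f, nd(t(f$value), list(f), list(function(g) t(g))))  # F F^T
}

# score matrix via explicit transpose node (vjp above); wrapper for clarity
discr1_scores <- function(pn, znode) discr1_forward(pn, znode)

discr2_logits <- function(pn, znode) {
  h <- nd_relu(nd_add_rowvec(nd_matmul(znode, pn[["discr2.h1.W"]]),
                             pn[["discr2.h1.b"]]))
  h <- nd_relu(nd_add_rowvec(nd_matmul(h, pn[["discr2.h2.W"]]),
                             pn[["discr2.h2.b"]]))
  nd_add_rowvec(nd_matmul(h, pn[["discr2.out.W"]]), pn[["discr2.out.b"]])
}

check_system <- function(model, system) {
  if (!system %in% model$systems) {
    stop("unknown system '", system, "'; model systems are ",
         paste(model$systems, collapse = ", "))
  }
}

#' Encode profiles into the global latent space
#'
#' Evaluation-mode forward pass: dropout off, batch normalization using its
#' running statistics, hence deterministic.
#'
#' @param model a `translator_model`
#' @param X samples x features matrix in the system's feature space (raw
#'   counts in count mode; the log10(x+1) transform and the trainable gene
#'   scaling are applied internally)
#' @param system which system's encoder to use
#' @return samples x latent_dim matrix of global embeddings z_g
#' @export
encode <- function(model, X, system) {
  check_system(model, system)
  X <- as.matrix(X)
  if (ncol(X) != model$d_in[[system]]) {
    stop("X has ", ncol(X), " columns; system '", system, "' expects ",
         model$d_in[[system]])
  }
  if (model$config$data_mode == "count") X <- log_transform_counts(X)
  pn <- wrap_params(model$params)
  encoder_forward(model, pn, nd(X), system)$value
}

#' Compose system/cell-type effects onto global embeddings
#'
#' v2 only. In additive mode `z_c = z_g + v_system (+ v_celltype)`; in
#' network mode the covariate's intermediate network maps z_g to z_c.
#'
#' @param model a `translator_model` (variant v2)
#' @param z matrix of global embeddings
#' @param system system whose effect to add
#' @param celltype optional cell-type label (additive mode, when the model
#'   was built with cell-type covariates)
#' @return matrix of composed embeddings z_c, same dimension as `z`
#' @export
compose <- function(model, z, system, celltype = NULL) {
  if (model$config$variant != "v2") {
    stop("compose() requires a v2 model; variant is ", model$config$variant)
  }
  check_system(model, system)
  z <- as.matrix(z)
  if (model$config$compose_mode == "additive") {
    zc <- sweep(z, 2L, model$params[["cov_system"]][system, ], "+")
    if (!is.null(celltype)) {
      if (is.null(model$params[["cov_celltype"]])) {
        stop("model was built without cell-type covariates")
      }
      zc <- sweep(zc, 2L, model$params[["cov_celltype"]][celltype, ], "+")
    }
    zc
  } else {
    pn <- wrap_params(model$params)
    mlp_forward(pn, paste0("covnet_", system), nd(z))$value
  }
}

#' Decode latent embeddings into a system's feature space
#'
#' @param model a `translator_model`
#' @param z matrix of latent embeddings (global or composed)
#' @param system target system's decoder
#' @return in z-score/serology mode, the reconstruction matrix; in count
#'   mode a list with `mean`, `dispersion` and `variance`
#'   (`variance = mean + mean^2 / dispersion`)
#' @export
decode <- function(model, z, system) {
  check_system(model, system)
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("latent embeddings contain non-finite values")
  if (ncol(z) != model$config$latent_dim) {
    stop("z must have latent_dim = ", model$config$latent_dim, " columns")
  }
  pn <- wrap_params(model$params)
  out <- decoder_forward(model, pn, nd(z), system)
  if (model$config$data_mode == "count") {
    mu <- out$mu$value; th <- out$theta$value
    list(mean = mu, dispersion = th, variance = mu + mu^2 / th)
  } else {
    out$value
  }
}

#' Translate profiles from one system to the other
#'
#' Encodes with the source system's encoder and decodes with the target's
#' decoder; v2 models first add the target system's covariate effect in the
#' composed space.
#'
#' @param model a `translator_model`
#' @param X samples x features matrix in the source feature space
#' @param source,target system names; equal source and target is routed to
#'   plain reconstruction with a warning
#' @param celltype optional cell-type covariate label (v2 additive mode)
#' @return predicted profiles in the target system's feature space
#' @export
translate <- function(model, X, source, target, celltype = NULL) {
  check_system(model, source)
  check_system(model, target)
  if (identical(source, target)) {
    warning("source equals target; returning the reconstruction")
  }
  z <- encode(model, X, source)
  if (model$config$variant == "v2") {
    z <- compose(model, z, target, celltype = celltype)
  }
  decode(model, z, target)
}

#' Per-component trainable parameter counts
#'
#' @param model a `translator_model`
#' @return named integer vector: number of scalar parameters per component
#'   prefix (e.g. `enc_A`, `dec_B`, `discr1`)
#' @export
param_count <- function(model) {
  comp <- sub("\\..*$", "", names(model$params))
  vapply(split(vapply(model$params, length, integer(1)), comp), sum,
         integer(1))
}

param_names_matching <- function(model, prefixes) {
  nm <- names(model$params)
  nm[Reduce(`|`, lapply(prefixes, function(p) startsWith(nm, p)))]
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the weights, batch-norm running statistics,
#' configuration and feature-id lists. The loader checks feature ids against
#' the data it is asked to handle via [encode()]'s dimension checks.
#'
#' @param model a `translator_model`
#' @param path file path
#' @return `load_checkpoint` returns the restored model
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(params = model$params, state = as.list(model$state),
              config = model$config, systems = model$systems,
              d_in = model$d_in, classifier_classes = model$classifier_classes,
              celltypes = model$celltypes, feature_ids = model$feature_ids,
              trace = model$trace)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) state[[nm]] <- obj$state[[nm]]
  structure(list(params = obj$params, state = state, config = obj$config,
                 systems = obj$systems, d_in = obj$d_in,
                 classifier_classes = obj$classifier_classes,
                 celltypes = obj$celltypes, feature_ids = obj$feature_ids,
                 trace = obj$trace),
            class = "translator_model")
}
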