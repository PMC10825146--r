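# Training orchestration for the three framework variants, fold
# construction, and latent-space probing.

prep_training_inputs <- function(data_a, data_b, pairs, model) {
  Xa <- data_a$matrix
  Xb <- data_b$matrix
  list(
    Xa = Xa, Xb = Xb,
    Ea = if (model$config$data_mode == "count") log_transform_counts(Xa) else Xa,
    Eb = if (model$config$data_mode == "count") log_transform_counts(Xb) else Xb,
    na = nrow(Xa), nb = nrow(Xb),
    meta = rbind(
      data.frame(system = data_a$samples$system,
                 condition = data_a$samples$condition,
                 stringsAsFactors = FALSE),
      data.frame(system = data_b$samples$system,
                 condition = data_b$samples$condition,
                 stringsAsFactors = FALSE)),
    pairs = pairs)
}

# batches are built by sampling *conditions*, so both members of a paired
# condition always co-occur and the positive mask is never empty by
# construction when pairs exist
make_condition_batches <- function(conditions, batch_size) {
  conds <- sample(unique(conditions))
  batches <- list()
  cur <- integer(0)
  for (k in conds) {
    cur <- c(cur, which(conditions == k))
    if (length(cur) >= batch_size) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur) >= 4L) {
    batches[[length(batches) + 1L]] <- cur
  } else if (length(cur) && length(batches)) {
    batches[[length(batches)]] <- c(batches[[length(batches)]], cur)
  } else if (length(cur)) {
    batches[[1L]] <- cur
  }
  batches
}

classifier_label_table <- function(model, data_a, data_b, targets) {
  if (is.null(targets)) return(NULL)
  out <- list()
  for (nm in names(targets)) {
    col <- targets[[nm]]
    vals <- c(as.character(data_a$samples[[col]]),
              as.character(data_b$samples[[col]]))
    lev <- model$classifier_classes[[nm]]
    lab <- match(vals, lev)
    if (anyNA(lab)) stop("labels in column '", col,
                         "' outside the classifier's class set")
    out[[nm]] <- lab
  }
  out
}

# forward pass + every loss node for one batch; returns nodes and numerics
batch_forward <- function(model, pn, inp, batch, labels, training = TRUE,
                          update_state = TRUE, include_recon = TRUE,
                          include_classifiers = TRUE) {
  cfg <- model$config
  sysA <- model$systems[1L]; sysB <- model$systems[2L]
  ia <- batch[batch <= inp$na]
  ib <- batch[batch > inp$na] - inp$na
  if (length(ia) < 2L) ia <- integer(0)
  if (length(ib) < 2L) ib <- integer(0)
  order_idx <- c(ia, ib + inp$na)
  if (length(order_idx) < 2L) return(NULL)

  za <- zb <- NULL
  if (length(ia)) {
    za <- encoder_forward(model, pn, nd(inp$Ea[ia, , drop = FALSE]), sysA,
                          training, update_state)
  }
  if (length(ib)) {
    zb <- encoder_forward(model, pn, nd(inp$Eb[ib, , drop = FALSE]), sysB,
                          training, update_state)
  }
  Z <- if (is.null(za)) zb else if (is.null(zb)) za else nd_rbind(za, zb)

  terms <- list()   # name -> list(node, weight)
  nums <- list()

  add_term <- function(name, node, weight) {
    terms[[name]] <<- list(node = node, weight = weight)
    nums[[name]] <<- node$value[1]
  }

  # composed embeddings (v2)
  zca <- za; zcb <- zb
  if (cfg$variant == "v2" && cfg$compose_mode == "additive") {
    cov <- pn[["cov_system"]]
    if (!is.null(za)) zca <- nd_add_rowvec(za, nd_rows(cov, 1L))
    if (!is.null(zb)) zcb <- nd_add_rowvec(zb, nd_rows(cov, 2L))
  } else if (cfg$variant == "v2" && cfg$compose_mode == "network") {
    if (!is.null(za)) zca <- mlp_forward(pn, paste0("covnet_", sysA), za)
    if (!is.null(zb)) zcb <- mlp_forward(pn, paste0("covnet_", sysB), zb)
  }

  # reconstruction
  if (include_recon) {
    n_tot <- length(ia) + length(ib)
    rec_nodes <- list(); rec_w <- numeric(0)
    mk_rec <- function(zdec, Xtgt, sys) {
      out <- decoder_forward(model, pn, zdec, sys, training, update_state)
      if (cfg$data_mode == "count") {
        nd_nb_nll(Xtgt, out$mu, out$theta)
      } else {
        nd_mse_recon(Xtgt, out)
      }
    }
    if (length(ia)) {
      rec_nodes <- c(rec_nodes, list(mk_rec(zca, inp$Xa[ia, , drop = FALSE],
                                            sysA)))
      rec_w <- c(rec_w, length(ia) / n_tot)
    }
    if (length(ib)) {
      rec_nodes <- c(rec_nodes, list(mk_rec(zcb, inp$Xb[ib, , drop = FALSE],
                                            sysB)))
      rec_w <- c(rec_w, length(ib) / n_tot)
    }
    add_term("L_recon", nd_weighted_sum(rec_nodes, rec_w), cfg$weights$recon)
  }

  # alignment + MI over in-batch positives
  mask <- pair_mask(inp$pairs, order_idx)
  if (sum(mask) > 0) {
    ut <- which(upper.tri(mask) & mask == 1, arr.ind = TRUE)
    Zi <- nd_rows(Z, ut[, 1L]); Zj <- nd_rows(Z, ut[, 2L])
    add_term("L_distance", nd_pair_dist(Zi, Zj), cfg$weights$distance)
    add_term("L_cosine", nd_pair_cos(Zi, Zj), -cfg$weights$cosine)
    if (sum((1 - mask) * (1 - diag(nrow(mask)))) > 0) {
      D <- discr1_scores(pn, Z)
      mi <- nd_mi(D, mask)
      add_term("L_MI", mi, cfg$weights$MI)
      nums$E_p <- attr(mi, "E_p"); nums$E_q <- attr(mi, "E_q")
    }
  }

  # adversarial uniform prior on the global space
  nz <- nrow(Z$value)
  v <- matrix(stats::runif(nz * cfg$latent_dim), nz, cfg$latent_dim)
  lp <- nd_prior_from_logits(discr2_logits(pn, nd(v)), discr2_logits(pn, Z))
  add_term("L_prior", lp, cfg$prior_sign * cfg$weights$prior)

  # task classifiers (v3: global space; v2: composed space)
  if (include_classifiers && !is.null(labels)) {
    Zc <- if (cfg$variant == "v2") {
      if (is.null(zca)) zcb else if (is.null(zcb)) zca else nd_rbind(zca, zcb)
    } else Z
    M <- length(labels)
    for (mi_ in seq_along(labels)) {
      nm <- names(labels)[mi_]
      logits <- mlp_forward(pn, paste0("class_", nm), Zc)
      ce <- nd_cross_entropy(logits, labels[[nm]][order_idx])
      add_term(paste0("entropy.", nm), ce, rep_len(cfg$weights$class, M)[mi_])
    }
  }

  # adversarial system classifier on the global space (v2), parameters frozen
  # in the framework step: the encoders are pushed to *increase* its entropy
  if (cfg$variant == "v2") {
    adv_logits <- mlp_forward(pn, "adverse", Z)
    sys_lab <- c(rep(1L, length(ia)), rep(2L, length(ib)))
    adv_ce <- nd_cross_entropy(adv_logits, sys_lab)
    add_term("entropy_adverse", adv_ce, -cfg$weights$adverse)
  }

  # L2 penalties on weights and biases
  l2_of <- function(prefixes) {
    nms <- param_names_matching(model, prefixes)
    nms <- nms[grepl("\\.(W|b)$", nms)]
    nodes <- lapply(nms, function(nm) nd_sumsq(pn[[nm]]))
    nd_weighted_sum(nodes, rep(1, length(nodes)))
  }
  add_term("L2_enc_a", l2_of(paste0("enc_", sysA)), cfg$weights$enc[1L])
  add_term("L2_enc_b", l2_of(paste0("enc_", sysB)), cfg$weights$enc[2L])
  if (include_recon) {
    add_term("L2_dec_a", l2_of(paste0("dec_", sysA)), cfg$weights$dec[1L])
    add_term("L2_dec_b", l2_of(paste0("dec_", sysB)), cfg$weights$dec[2L])
  }
  if (include_classifiers && !is.null(labels)) {
    for (nm in names(labels)) {
      add_term(paste0("L2_class.", nm), l2_of(paste0("class_", nm)),
               cfg$weights$L2class)
    }
  }
  if (cfg$variant == "v2" && cfg$compose_mode == "additive") {
    covs <- c("cov_system", if (!is.null(pn[["cov_celltype"]])) "cov_celltype")
    add_term("L2_trained_effect",
             nd_weighted_sum(lapply(covs, function(nm) nd_sumsq(pn[[nm]])),
                             rep(1, length(covs))),
             cfg$weights$trained_effect)
  }

  total <- nd_weighted_sum(lapply(terms, `[[`, "node"),
                           vapply(terms, `[[`, numeric(1), "weight"))
  list(total = total, terms = terms, nums = nums, Z = Z,
       order_idx = order_idx, ia = ia, ib = ib, pn = pn)
}

collect_grads <- function(pn, names_wanted) {
  g <- lapply(pn[names_wanted], nd_grad)
  names(g) <- names_wanted
  g
}

framework_param_names <- function(model, include_decoders = TRUE,
                                  include_classifiers = TRUE) {
  nm <- names(model$params)
  keep <- !startsWith(nm, "discr2.") & !startsWith(nm, "adverse.")
  if (!include_decoders) keep <- keep & !startsWith(nm, "dec_")
  if (!include_classifiers) keep <- keep & !startsWith(nm, "class_")
  nm[keep]
}

# one adversarial-classifier update on frozen global embeddings
adverse_step <- function(model, opt, Zval, sys_lab) {
  pn <- wrap_params(model$params)
  ce <- nd_cross_entropy(mlp_forward(pn, "adverse", nd(Zval)), sys_lab)
  nd_backward(ce)
  nms <- grep("^adverse\\.", names(model$params), value = TRUE)
  model$params <- adam_step(opt, model$params, collect_grads(pn, nms),
                            model$config$lr)
  model
}

# one ascent step of the prior discriminator on L_prior
discr2_step <- function(model, opt, Zval) {
  cfg <- model$config
  pn <- wrap_params(model$params)
  v <- matrix(stats::runif(length(Zval)), nrow(Zval), ncol(Zval))
  lp <- nd_prior_from_logits(discr2_logits(pn, nd(v)),
                             discr2_logits(pn, nd(Zval)))
  neg <- nd_scale(lp, -1)
  nd_backward(neg)
  nms <- grep("^discr2\\.", names(model$params), value = TRUE)
  model$params <- adam_step(opt, model$params, collect_grads(pn, nms),
                            cfg$lr)
  model
}

#' Train the translator framework
#'
#' All framework components are trained simultaneously by mini-batch
#' gradient descent; batches are drawn condition-wise so that both members
#' of a paired condition co-occur and the in-batch positive mask is well
#' defined. The prior discriminator takes an alternating ascent step on the
#' Eq-1 prior term each batch; in the covariate variant (v2) the adversarial
#' system classifier is likewise updated on its own step (and pre-trained
#' first, see [pretrain_adverse()]), and its parameters are frozen during
#' the framework step.
#'
#' @param data_a,data_b `omics_dataset`s, one per system
#' @param pairs a `pair_index`; computed from the condition keys when NULL
#' @param config a [model_config()]
#' @param classifier_targets named list mapping classifier names to metadata
#'   columns (default: a `system` classifier for v2/v3, none for v1)
#' @param verbose print the per-epoch total loss
#' @return a trained `translator_model`; element `trace` holds the per-epoch
#'   loss breakdown (one column per term)
#' @export
train_translator <- function(data_a, data_b, pairs = NULL,
                             config = model_config(),
                             classifier_targets = NULL, verbose = FALSE) {
  if (config$batch_size < 2L) {
    stop("batch size must be at least 2 (batch normalization)")
  }
  set.seed(config$seed)
  if (is.null(pairs)) pairs <- build_pair_index(list(data_a, data_b))
  w_align <- config$weights$distance + config$weights$cosine +
    config$weights$MI
  if (w_align > 0 && nrow(pairs$positive_pairs) == 0L) {
    stop("alignment weights are positive but the training split contains ",
         "no positive pair")
  }
  if (is.null(classifier_targets) && config$variant %in% c("v2", "v3")) {
    classifier_targets <- list(system = "system")
  }
  classes <- NULL
  if (!is.null(classifier_targets)) {
    classes <- lapply(classifier_targets, function(col) {
      sort(unique(c(as.character(data_a$samples[[col]]),
                    as.character(data_b$samples[[col]]))))
    })
  }
  model <- translator_init(ncol(data_a$matrix), ncol(data_b$matrix), config,
                           systems = c(unique(data_a$samples$system)[1L],
                                       unique(data_b$samples$system)[1L]),
                           classifier_classes = classes)
  model$feature_ids <- list(data_a$feature_ids, data_b$feature_ids)
  inp <- prep_training_inputs(data_a, data_b, pairs, model)
  labels <- classifier_label_table(model, data_a, data_b, classifier_targets)

  if (config$variant == "v2" && config$pretrain_epochs > 0L) {
    model <- pretrain_adverse(model, data_a, data_b, pairs,
                              epochs = config$pretrain_epochs)
  }

  step_fn <- if (config$optimizer == "adam") adam_step else sgd_step
  opt <- adam_init(model$params)
  opt_d2 <- adam_init(model$params)
  opt_adv <- adam_init(model$params)
  fw_names <- framework_param_names(model)
  trace <- list()

  for (epoch in seq_len(config$epochs)) {
    batches <- make_condition_batches(inp$meta$condition, config$batch_size)
    ep_rows <- list()
    for (batch in batches) {
      pn <- wrap_params(model$params)
      fw <- batch_forward(model, pn, inp, batch, labels,
                          training = TRUE, update_state = TRUE)
      if (is.null(fw)) next
      Zval <- fw$Z$value
      if (config$variant == "v2") {
        sys_lab <- c(rep(1L, length(fw$ia)), rep(2L, length(fw$ib)))
        model <- adverse_step(model, opt_adv, Zval, sys_lab)
      }
      model <- discr2_step(model, opt_d2, Zval)
      nd_backward(fw$total)
      model$params <- step_fn(opt, model$params,
                              collect_grads(pn, fw_names), config$lr)
      ep_rows[[length(ep_rows) + 1L]] <-
        c(total = fw$total$value[1], unlist(fw$nums))
    }
    tr <- colMeans(do.call(rbind, lapply(ep_rows, function(r) {
      all_nm <- unique(unlist(lapply(ep_rows, names)))
      r[setdiff(all_nm, names(r))] <- NA_real_
      r[all_nm]
    })), na.rm = TRUE)
    trace[[epoch]] <- c(epoch = epoch, tr)
    if (verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %d  total %.4f", epoch, tr[["total"]]))
    }
  }
  model$trace <- as.data.frame(do.call(rbind, trace))
  model
}

#' Pre-train the adversarial system classifier
#'
#' Before joint training, the v2 adversary is trained together with the
#' encoders and the two discriminators -- no decoders, no task classifiers --
#' so that it can already distinguish the systems in the global space. With
#' `epochs = 0` the model is returned unchanged.
#'
#' @param model a v2 `translator_model`
#' @param data_a,data_b training datasets
#' @param pairs a `pair_index` over the combined data
#' @param epochs number of pretraining epochs
#' @return the model with updated encoder/discriminator/adversary weights;
#'   decoder and task-classifier parameters are untouched
#' @export
pretrain_adverse <- function(model, data_a, data_b, pairs = NULL,
                             epochs = model$config$pretrain_epochs) {
  if (model$config$variant != "v2") {
    stop("pretrain_adverse() applies to v2 models only")
  }
  if (epochs <= 0L) return(model)
  if (is.null(pairs)) pairs <- build_pair_index(list(data_a, data_b))
  inp <- prep_training_inputs(data_a, data_b, pairs, model)
  opt <- adam_init(model$params)
  opt_d2 <- adam_init(model$params)
  opt_adv <- adam_init(model$params)
  enc_names <- framework_param_names(model, include_decoders = FALSE,
                                     include_classifiers = FALSE)
  for (epoch in seq_len(epochs)) {
    batches <- make_condition_batches(inp$meta$condition,
                                      model$config$batch_size)
    for (batch in batches) {
      pn <- wrap_params(model$params)
      fw <- batch_forward(model, pn, inp, batch, labels = NULL,
                          training = TRUE, update_state = TRUE,
                          include_recon = FALSE,
                          include_classifiers = FALSE)
      if (is.null(fw)) next
      sys_lab <- c(rep(1L, length(fw$ia)), rep(2L, length(fw$ib)))
      model <- adverse_step(model, opt_adv, fw$Z$value, sys_lab)
      model <- discr2_step(model, opt_d2, fw$Z$value)
      nd_backward(fw$total)
      model$params <- adam_step(opt, model$params,
                                collect_grads(pn, enc_names),
                                model$config$lr)
    }
  }
  model
}

#' Adversary accuracy on given data
#'
#' Convenience check that the (pre)trained adversarial classifier separates
#' the systems in the global space.
#' @param model a v2 `translator_model`
#' @param data_a,data_b datasets for the two systems
#' @return fraction of samples whose system the adversary predicts correctly
#' @export
adverse_accuracy <- function(model, data_a, data_b) {
  Z <- rbind(encode(model, data_a$matrix, model$systems[1L]),
             encode(model, data_b$matrix, model$systems[2L]))
  pn <- wrap_params(model$params)
  logits <- mlp_forward(pn, "adverse", nd(Z))$value
  pred <- max.col(logits, ties.method = "first")
  truth <- c(rep(1L, nrow(data_a$matrix)), rep(2L, nrow(data_b$matrix)))
  mean(pred == truth)
}

#' Condition-level cross-validation folds
#'
#' Assigns *conditions* (not samples) to k folds, so a paired condition is
#' hidden from training in both systems simultaneously. Fold sizes differ by
#' at most one condition.
#'
#' @param data_a,data_b `omics_dataset`s
#' @param pairs unused placeholder for API symmetry (pairing is implied by
#'   the shared condition keys)
#' @param k number of folds
#' @param seed RNG seed for the condition shuffle
#' @return a `fold_plan` list: `fold_a`/`fold_b` give each sample's fold,
#'   `condition_folds` the underlying condition assignment
#' @export
make_folds <- function(data_a, data_b, pairs = NULL, k = 10, seed = 1) {
  conds <- unique(c(data_a$samples$condition, data_b$samples$condition))
  if (k > length(conds)) {
    stop("k = ", k, " exceeds the number of conditions (", length(conds), ")")
  }
  set.seed(seed)
  shuffled <- sample(conds)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(conds)), shuffled)
  structure(list(
    fold_a = unname(fold_of[data_a$samples$condition]),
    fold_b = unname(fold_of[data_b$samples$condition]),
    condition_folds = fold_of, k = k),
    class = "fold_plan")
}

#' Probe how much system identity survives in each latent space
#'
#' Trains probe classifiers (multinomial logistic regression on frozen
#' embeddings) to predict a metadata label from the global and, for v2
#' models, the composed space, and reports held-out accuracy and F1. A
#' well-shaped global space "forgets" the system of origin, so the composed
#' space should be the easier probe target.
#'
#' @param model a trained `translator_model`
#' @param data_a,data_b datasets for the two systems
#' @param label metadata column to probe (default `"system"`)
#' @param train_frac fraction of samples used to fit each probe
#' @param seed RNG seed for the split
#' @return data.frame with one row per latent space: `space`, `accuracy`, `f1`
#' @export
evaluate_globality <- function(model, data_a, data_b, label = "system",
                               train_frac = 0.7, seed = 1) {
  zg <- rbind(encode(model, data_a$matrix, model$systems[1L]),
              encode(model, data_b$matrix, model$systems[2L]))
  y <- factor(c(as.character(data_a$samples[[label]]),
                as.character(data_b$samples[[label]])))
  zc <- if (model$config$variant == "v2") {
    rbind(compose(model, encode(model, data_a$matrix, model$systems[1L]),
                  model$systems[1L]),
          compose(model, encode(model, data_b$matrix, model$systems[2L]),
                  model$systems[2L]))
  } else zg
  set.seed(seed)
  n <- length(y)
  tr <- sample.int(n, max(2L, round(train_frac * n)))
  te <- setdiff(seq_len(n), tr)
  probe <- function(Z) {
    df <- data.frame(y = y, Z)
    fit <- nnet::multinom(y ~ ., data = df[tr, , drop = FALSE],
                          trace = FALSE, maxit = 200)
    pred <- stats::predict(fit, newdata = df[te, , drop = FALSE])
    cm <- classification_metrics(as.character(pred), as.character(y[te]))
    c(accuracy = cm$accuracy, f1 = cm$f1)
  }
  res <- rbind(global = probe(zg), composed = probe(zc))
  data.frame(space = rownames(res), accuracy = res[, "accuracy"],
             f1 = res[, "f1"], row.names = NULL)
}

#' Write the per-epoch loss table
#' @param model trained model with a `trace` element
#' @param path output path (tab-delimited)
#' @return invisibly, the trace data.frame
#' @export
write_trace <- function(model, path) {
  data.table::fwrite(data.table::as.data.table(model$trace), path, sep = "\t")
  invisible(model$trace)
}
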