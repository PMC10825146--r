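# Shared fixtures: tiny datasets and small trained models (cached so that
# several test files can reuse one training run).

.fixture_cache <- new.env(parent = emptyenv())

# numerical gradient of a scalar-valued function of one matrix
num_grad <- function(f, X, h = 1e-5) {
  G <- X * 0
  for (i in seq_along(X)) {
    Xp <- X; Xp[i] <- Xp[i] + h
    Xm <- X; Xm[i] <- Xm[i] - h
    G[i] <- (f(Xp) - f(Xm)) / (2 * h)
  }
  G
}

# two systems over a *shared* feature space, one sample per condition,
# target = diagonal rescaling of the source (exact per-gene linear relation)
toy_shared_pair <- function(n = 40, p = 8, seed = 1, rank = NULL) {
  set.seed(seed)
  Xa <- if (is.null(rank)) matrix(stats::rnorm(n * p), n, p) else
    matrix(stats::rnorm(n * rank), n, rank) %*%
      matrix(stats::rnorm(rank * p), rank, p)
  cvec <- seq(0.5, 1.5, length.out = p)
  Xb <- Xa %*% diag(cvec)
  feats <- paste0("g", seq_len(p))
  colnames(Xa) <- colnames(Xb) <- feats
  ma <- data.frame(sample_id = paste0("a", seq_len(n)), system = "A",
                   condition = paste0("c", seq_len(n)))
  mb <- data.frame(sample_id = paste0("b", seq_len(n)), system = "B",
                   condition = paste0("c", seq_len(n)))
  list(da = omics_dataset(Xa, ma), db = omics_dataset(Xb, mb), cvec = cvec)
}

tiny_sim <- function(seed = 3, n_conditions = 40) {
  generate_paired_bulk(synth_config(n_conditions = n_conditions,
                                    n_features_a = 20, n_features_b = 25,
                                    latent_dim_true = 5, seed = seed))
}

tiny_config <- function(epochs = 30, batch_size = 64, ...) {
  model_config(latent_dim = 8, enc_hidden = 16, dec_hidden = 16,
               class_hidden = 8, adverse_hidden = 8, discr_hidden = 8,
               epochs = epochs, batch_size = batch_size, ...)
}

get_tiny_v1 <- function() {
  if (is.null(.fixture_cache$v1)) {
    sim <- tiny_sim(seed = 3)
    .fixture_cache$v1_sim <- sim
    .fixture_cache$v1 <- train_translator(sim$data_a, sim$data_b,
                                          config = tiny_config(seed = 3))
  }
  list(model = .fixture_cache$v1, sim = .fixture_cache$v1_sim)
}

get_tiny_v2 <- function() {
  if (is.null(.fixture_cache$v2)) {
    sim <- tiny_sim(seed = 4)
    .fixture_cache$v2_sim <- sim
    .fixture_cache$v2 <- train_translator(
      sim$data_a, sim$data_b,
      config = tiny_config(variant = "v2", seed = 4, epochs = 40))
  }
  list(model = .fixture_cache$v2, sim = .fixture_cache$v2_sim)
}

# exhaustive oracle: best contiguous 3-partition of sorted scores by
# within-cluster sum of squares, then the midpoint threshold rule
kmeans_split_oracle <- function(s) {
  o <- order(s)
  ss <- s[o]
  n <- length(ss)
  best <- NULL; best_ss <- Inf
  wss <- function(v) sum((v - mean(v))^2)
  for (c1 in 1:(n - 2)) for (c2 in (c1 + 1):(n - 1)) {
    tot <- wss(ss[1:c1]) + wss(ss[(c1 + 1):c2]) + wss(ss[(c2 + 1):n])
    if (tot < best_ss) { best_ss <- tot; best <- c(c1, c2) }
  }
  thr <- unname((ss[best[1]] + ss[best[1] + 1]) / 2)
  list(threshold = thr, important = which(s > thr))
}
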