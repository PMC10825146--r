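# Two-system synthetic data with a shared condition effect observed through
# system-specific feature maps. The generator provides the structure the
# framework assumes -- paired conditions across disjoint feature spaces --
# so every downstream module is testable without external downloads.

#' Synthetic-data configuration
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' experiments: 300 conditions of which half are paired across systems,
#' disjoint feature spaces of 50 and 80 features, a 10-dimensional true
#' condition effect, a unit-scale additive system effect and moderate
#' (sd 0.5) measurement noise on z-score-like profiles.
#'
#' @param n_conditions number of distinct conditions
#' @param paired_fraction fraction of conditions observed in both systems
#' @param n_features_a,n_features_b feature-space sizes of the two systems
#' @param latent_dim_true dimension of the true condition effect u_c
#' @param system_effect_scale sd of the additive per-feature system offset
#' @param noise_sd sd of the additive Gaussian measurement noise
#' @param nonlinearity `"none"` or `"tanh"` applied to u_c before the linear map
#' @param mode `"zscore"`, `"count"` or `"serology"`
#' @param nb_dispersion negative-binomial inverse dispersion theta (count mode)
#' @param protection_effect shift added to protection-linked features
#'   (serology mode)
#' @param n_samples samples per species in serology mode
#' @param seed integer seed; the generator is a pure function of this config
#' @return a `synth_config` list
#' @export
synth_config <- function(n_conditions = 300, paired_fraction = 0.5,
                         n_features_a = 50, n_features_b = 80,
                         latent_dim_true = 10, system_effect_scale = 1,
                         noise_sd = 0.5, nonlinearity = c("none", "tanh"),
                         mode = c("zscore", "count", "serology"),
                         nb_dispersion = 4, protection_effect = 1,
                         n_samples = 100, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  mode <- match.arg(mode)
  if (paired_fraction < 0 || paired_fraction > 1) {
    stop("paired_fraction must lie in [0, 1]")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(list(n_conditions = n_conditions,
                 paired_fraction = paired_fraction,
                 n_features_a = n_features_a, n_features_b = n_features_b,
                 latent_dim_true = latent_dim_true,
                 system_effect_scale = system_effect_scale,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 mode = mode, nb_dispersion = nb_dispersion,
                 protection_effect = protection_effect,
                 n_samples = n_samples, seed = seed),
            class = "synth_config")
}

apply_nonlin <- function(u, kind) if (kind == "tanh") tanh(u) else u

#' Generate paired two-system bulk profiles
#'
#' Each condition c has a true latent vector u_c ~ N(0, I). System s observes
#' `x = W_s g(u_c) + b_s + eps` with `eps ~ N(0, noise_sd^2)`; `W_s` entries
#' are N(0, 1/sqrt(latent_dim_true)) so profiles have O(1) scale, and `b_s`
#' is the additive system effect. A `paired_fraction` of the conditions
#' appears in both systems; the remainder is split evenly between them.
#'
#' @param cfg a [synth_config()]
#' @return list with `data_a`, `data_b` (`omics_dataset`s) and
#'   `ground_truth` (`U`, `W_a`, `W_b`, `b_a`, `b_b`, condition keys, and the
#'   shared-key set)
#' @export
#' @examples
#' sim <- generate_paired_bulk(synth_config(n_conditions = 10, seed = 7))
#' dim(sim$data_a$matrix)
generate_paired_bulk <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  nc <- cfg$n_conditions
  L <- cfg$latent_dim_true
  keys <- sprintf("cond%03d", seq_len(nc))
  n_shared <- round(cfg$paired_fraction * nc)
  shared <- keys[seq_len(n_shared)]
  rest <- setdiff(keys, shared)
  only_a <- rest[seq_len(ceiling(length(rest) / 2))]
  only_b <- setdiff(rest, only_a)

  U <- matrix(stats::rnorm(nc * L), nc, L, dimnames = list(keys, NULL))
  W_a <- matrix(stats::rnorm(cfg$n_features_a * L, sd = 1 / sqrt(L)),
                L, cfg$n_features_a)
  W_b <- matrix(stats::rnorm(cfg$n_features_b * L, sd = 1 / sqrt(L)),
                L, cfg$n_features_b)
  b_a <- stats::rnorm(cfg$n_features_a, sd = cfg$system_effect_scale)
  b_b <- stats::rnorm(cfg$n_features_b, sd = cfg$system_effect_scale)

  make_system <- function(ks, W, b, sys, prefix, nf) {
    G <- apply_nonlin(U[ks, , drop = FALSE], cfg$nonlinearity)
    X <- G %*% W
    X <- sweep(X, 2L, b, "+")
    X <- X + matrix(stats::rnorm(length(X), sd = cfg$noise_sd),
                    nrow(X), ncol(X))
    colnames(X) <- paste0(prefix, seq_len(nf))
    meta <- data.frame(sample_id = paste0(sys, "_", ks), system = sys,
                       perturbagen = ks, dose = "d1", time = "t1",
                       stringsAsFactors = FALSE)
    omics_dataset(X, meta, mode = "zscore")
  }
  keys_a <- c(shared, only_a)
  keys_b <- c(shared, only_b)
  data_a <- make_system(keys_a, W_a, b_a, "A", "ga", cfg$n_features_a)
  data_b <- make_system(keys_b, W_b, b_b, "B", "gb", cfg$n_features_b)
  list(data_a = data_a, data_b = data_b,
       ground_truth = list(U = U, W_a = W_a, W_b = W_b, b_a = b_a, b_b = b_b,
                           keys_a = keys_a, keys_b = keys_b,
                           shared = shared,
                           nonlinearity = cfg$nonlinearity))
}

#' Generate a single-system negative-binomial count dataset
#'
#' Per-gene means come from the bulk construction, exponentiated to the
#' positive scale; entries are drawn from a negative binomial with mean mu
#' and inverse dispersion `theta = nb_dispersion`, i.e. variance
#' `mu + mu^2/theta`. Cell-type labels are attached in round-robin order.
#'
#' @param cfg a [synth_config()] with `mode = "count"`
#' @param n_celltypes number of cell-type labels to attach
#' @return an `omics_dataset` in count mode with `mu` (the true mean matrix)
#'   attached as attribute `"mu"`
#' @export
generate_counts <- function(cfg = synth_config(mode = "count"),
                            n_celltypes = 2) {
  if (cfg$mode != "count") stop("generate_counts requires mode = 'count'")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(cfg$seed)
  nc <- cfg$n_conditions
  L <- cfg$latent_dim_true
  U <- matrix(stats::rnorm(nc * L), nc, L)
  W <- matrix(stats::rnorm(cfg$n_features_a * L, sd = 1 / sqrt(L)),
              L, cfg$n_features_a)
  logmu <- apply_nonlin(U, cfg$nonlinearity) %*% W
  mu <- exp(logmu)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = cfg$nb_dispersion),
                   nrow(mu), ncol(mu))
  colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  meta <- data.frame(sample_id = sprintf("cell%03d", seq_len(nc)),
                     system = "A",
                     condition = sprintf("cond%03d", seq_len(nc)),
                     celltype = paste0("ct",
                                       rep_len(seq_len(n_celltypes), nc)),
                     stringsAsFactors = FALSE)
  out <- omics_dataset(counts, meta, mode = "count")
  attr(out, "mu") <- mu
  out
}

#' Generate a two-species serology-style dataset
#'
#' Two species with disjoint feature panels; a per-sample binary protection
#' label (balanced exactly) shifts a known subset of features in each species
#' by `protection_effect` through a protection-linked latent factor.
#' Vaccination labels are assigned independently.
#'
#' @param cfg a [synth_config()] with `mode = "serology"`
#' @param important_fraction fraction of each panel linked to protection
#' @return list with `data_human`, `data_nhp` (protection keyed datasets) and
#'   `ground_truth` listing the planted protection-linked features per species
#' @export
generate_serology <- function(cfg = synth_config(mode = "serology"),
                              important_fraction = 0.2) {
  if (cfg$mode != "serology") stop("generate_serology requires mode = 'serology'")
  set.seed(cfg$seed)
  make_species <- function(nf, n, species, prefix) {
    n_prot <- floor(n / 2)
    protection <- c(rep(1L, n_prot), rep(0L, n - n_prot))
    protection <- protection[sample.int(n)]
    vaccination <- stats::rbinom(n, 1L, 0.5)
    n_imp <- max(1L, round(important_fraction * nf))
    imp <- sample.int(nf, n_imp)
    X <- matrix(stats::rnorm(n * nf), n, nf)
    # protection-linked latent factor loads only on the planted features
    X[, imp] <- X[, imp] + outer(protection, rep(cfg$protection_effect, n_imp))
    colnames(X) <- paste0(prefix, seq_len(nf))
    meta <- data.frame(sample_id = paste0(species, seq_len(n)),
                       system = species,
                       protection = protection, vaccination = vaccination,
                       stringsAsFactors = FALSE)
    ds <- omics_dataset(X, meta, mode = "serology")
    list(ds = ds, important = colnames(X)[sort(imp)])
  }
  h <- make_species(cfg$n_features_a, cfg$n_samples, "human", "hu_")
  p <- make_species(cfg$n_features_b, cfg$n_samples, "nhp", "np_")
  list(data_human = h$ds, data_nhp = p$ds,
       ground_truth = list(important_human = h$important,
                           important_nhp = p$important))
}
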