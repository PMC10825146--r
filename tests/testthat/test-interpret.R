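test_that("integrated gradients are exact for linear maps", {
  w <- c(2, -1, 0.5)
  f <- function(X) X %*% w
  x <- c(3, 4, 5)
  ig <- integrated_gradients(f, x)
  expect_equal(as.numeric(ig$scores), w * x, tolerance = 1e-8)
  expect_error(integrated_gradients(f, x, n_steps = 0), "n_steps")
})

test_that("completeness holds within 1e-3 at 200 steps on a smooth network", {
  set.seed(3)
  W1 <- matrix(rnorm(5 * 7, sd = 0.5), 5, 7)
  W2 <- matrix(rnorm(7), 7, 1)
  f <- function(X) tanh(X %*% W1) %*% W2
  x <- matrix(rnorm(3 * 5), 3, 5)
  ig <- integrated_gradients(f, x, n_steps = 200)
  expect_lt(max(abs(ig$completeness_error)), 1e-3)
})

test_that("the path integral converges as steps double", {
  set.seed(4)
  W1 <- matrix(rnorm(4 * 6, sd = 0.7), 4, 6)
  W2 <- matrix(rnorm(6), 6, 1)
  f <- function(X) tanh(X %*% W1) %*% W2
  x <- matrix(rnorm(2 * 4), 2, 4)
  s <- lapply(c(25, 50, 100), function(m) {
    integrated_gradients(f, x, n_steps = m)$scores
  })
  change1 <- max(abs(s[[2]] - s[[1]]))  # 25 -> 50
  change2 <- max(abs(s[[3]] - s[[2]]))  # 50 -> 100
  expect_lt(change2, change1)
})

test_that("analytic model gradients agree with finite differences", {
  fx <- get_tiny_v1()
  fn <- ig_model_fn(fx$model, "latent", "A")
  X <- fx$sim$data_a$matrix[1:3, , drop = FALSE]
  ig_a <- integrated_gradients(fn$F, X, target_index = 2, n_steps = 20,
                               grad_F = fn$grad)
  ig_n <- integrated_gradients(fn$F, X, target_index = 2, n_steps = 20)
  expect_equal(ig_a$scores, ig_n$scores, tolerance = 1e-4)
})


test_that("k-means latent selection matches the exhaustive partition oracle", {
  s <- c(rep(0.01, 10), rep(0.5, 5), 5.0)
  names(s) <- paste0("z", seq_along(s))
  oracle <- kmeans_split_oracle(s)
  got <- kmeans_importance_split(s)
  expect_equal(got$threshold, (0.01 + 0.5) / 2)
  expect_equal(got$threshold, oracle$threshold)
  expect_setequal(got$important, names(s)[oracle$important])
  expect_length(got$important, 6)

  # two separated bands plus one extreme outlier: outlier is important
  s2 <- c(rnorm(8, 0.05, 0.005), rnorm(4, 1, 0.02), 50)
  names(s2) <- paste0("v", seq_along(s2))
  got2 <- kmeans_importance_split(s2)
  oracle2 <- kmeans_split_oracle(s2)
  expect_setequal(got2$important, names(s2)[oracle2$important])
  expect_true("v13" %in% got2$important)

  # permutation invariance of the selected set
  set.seed(9)
  perm <- sample(length(s))
  got3 <- kmeans_importance_split(s[perm])
  expect_setequal(got3$important, got$important)

  expect_error(kmeans_importance_split(rep(1, 5)), "no separation")
})

test_that("the latent LRT matches an independent implementation and its edge cases", {
  set.seed(11)
  n <- 60
  prot <- rbinom(n, 1, 0.5)
  vac <- rbinom(n, 1, 0.5)
  sp <- sample(rep(c("h", "m"), n / 2))
  z <- 0.8 * prot + rnorm(n)
  mine <- lrt_latent(matrix(z), prot, vac, sp)
  fA <- lm(z ~ prot + vac + sp)
  f0 <- lm(z ~ vac + sp)
  ref <- lmtest::lrtest(f0, fA)
  expect_equal(mine$lrt, ref$Chisq[2], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>Chisq)`[2], tolerance = 1e-10)

  # constant protection: identical likelihoods
  r0 <- lrt_latent(matrix(rnorm(20)), rep(1, 20), rbinom(20, 1, 0.5),
                   rep(c("h", "m"), 10))
  expect_equal(r0$lrt, 0)
  expect_equal(r0$p, 1)

  # collinear covariates are refused by name
  expect_error(lrt_latent(matrix(rnorm(20)), rbinom(20, 1, 0.5),
                          rep(c(0, 1), 10), rep(c("h", "m"), 10)),
               "collinear")

  # strong effect at n = 100 is found
  set.seed(12)
  prot2 <- rbinom(100, 1, 0.5)
  z2 <- prot2 + rnorm(100)
  r2 <- lrt_latent(matrix(z2), prot2, rbinom(100, 1, 0.5),
                   sample(rep(c("h", "m"), 50)))
  expect_lt(r2$fdr, 0.05)
})

test_that("type-I error of the LRT stays within binomial bounds of nominal alpha", {
  set.seed(13)
  rej <- replicate(200, {
    n <- 100
    lrt_latent(matrix(rnorm(n)), rbinom(n, 1, 0.5), rbinom(n, 1, 0.5),
               sample(rep(c("h", "m"), n / 2)))$p < 0.05
  })
  # 200 replicates: 0.05 +/- 3 * sqrt(.05*.95/200)
  expect_gt(mean(rej), 0.05 - 3 * 0.0154)
  expect_lt(mean(rej), 0.05 + 3 * 0.0154)
})

test_that("protective-latent selection applies all three rules", {
  lrt <- data.frame(latent = 1:5,
                    fdr = c(0.01, 0.2, 0.01, 0.04, 0.001),
                    t = c(2.5, 3.0, -2.2, 2.0, 2.8))
  ig <- cbind(c(0.9, 0.8, -0.7, 0.05, -0.6),
              c(1.0, 0.9, -0.8, 0.04, -0.5))
  sel <- select_protective_latents(lrt, ig, pct_threshold = 10)
  # rule enumeration: 1 passes all; 2 fails FDR; 3 passes (negative sign
  # agrees); 4 fails the percentage cut; 5 fails sign agreement
  expect_setequal(sel$selected, c(1, 3))
  # disjoint significant sets: empty result
  lrt2 <- data.frame(latent = 1:2, fdr = c(0.01, 0.5), t = c(1, 1))
  sel2 <- select_protective_latents(lrt2, c(0.01, 1), pct_threshold = 50)
  expect_length(sel2$selected, 0)
})

test_that("feature-network filters apply the four criteria in order", {
  set.seed(14)
  ps <- data.frame(
    source = rep(paste0("n", 1:4), each = 3),
    target = rep(paste0("h", 1:3), 4),
    importance = c(20, 30, 2, 60, 40, 25, 12, 5, 50, 1, 3, 2),
    fold_sd = c(0.1, 0.2, 0.1, 0.1, 5, 5, 0.15, 0.1, 0.05, 9, 9, 9))
  recon_r <- c(n1 = 0.9, n2 = 0.75, n3 = 0.5, n4 = 0.95)
  got <- build_feature_network(ps, recon_r)
  # independent enumeration of the four filters
  q1 <- quantile(ps$fold_sd, 0.25)
  pass123 <- recon_r[ps$source] >= 0.75 & ps$fold_sd <= q1 &
    abs(ps$importance) > 10
  q3 <- quantile(abs(ps$importance[pass123]), 0.75)
  expected <- ps[pass123 & abs(ps$importance) >= q3, ]
  expect_equal(got$importance, expected$importance)
  expect_true(all(paste(got$source, got$target) %in%
                    paste(ps$source, ps$target)))  # subset of input
  # boundary: the source with recon_r exactly 0.75 survives criterion 1
  # and, carrying the largest magnitude, ends up in the network
  expect_true(any(recon_r[got$source] == 0.75))
  # empty input stays empty
  expect_identical(nrow(build_feature_network(ps[0, ], recon_r)), 0L)
})

test_that("percentile-rank summaries order categories by score", {
  sc <- c(1, 2, 3, 10, 20, 30)
  cat1 <- rep(c("low", "high"), each = 3)
  out <- percentile_rank_summary(sc, cat1)
  expect_identical(out$category[which.max(out$median_percentile)], "high")
  # worked table: percentile rank = 100 * rank / n
  pr <- 100 * rank(sc) / 6
  expect_equal(out$median_percentile[out$category == "low"],
               median(pr[1:3]))
  one <- percentile_rank_summary(sc, rep("all", 6))
  expect_equal(one$median_percentile, median(pr))
  expect_error(percentile_rank_summary(sc, c(cat1[-1], NA)), "category")
})

test_that("pre-ranked enrichment flags a top-loaded set and stays null for random sets", {
  set.seed(15)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- paste0("g", 1:200)
  sets <- list(top = paste0("g", 1:15))
  res <- preranked_enrichment(scores, sets, n_perm = 200)
  expect_gt(res$ES, 0.8)
  expect_lt(res$p, 0.05)
  # random sets: p roughly uniform
  rnd <- lapply(1:30, function(i) sample(names(scores), 15))
  names(rnd) <- paste0("r", 1:30)
  pr <- preranked_enrichment(scores, rnd, n_perm = 100, seed = 16)$p
  expect_gt(mean(pr), 0.25)
  expect_lt(mean(pr), 0.85)
  # degenerate sets
  expect_identical(nrow(preranked_enrichment(scores, list())), 0L)
  expect_warning(preranked_enrichment(scores, list(tiny = "g1")), "skipped")
})

test_that("an all-zero input feature receives a zero attribution", {
  fx <- get_tiny_v1()
  da <- fx$sim$data_a
  da$matrix[, 3] <- 0
  rk <- rank_cross_system_features(fx$model, da, c(1, 2), "A")
  expect_equal(rk$score[rk$feature == da$feature_ids[3]], 0,
               tolerance = 1e-12)
  expect_error(rank_cross_system_features(fx$model, da, integer(0), "A"),
               "empty")
})

test_that("the serology pipeline recovers the planted protective features", {
  for (s in 1:2) {
    ser <- generate_serology(synth_config(mode = "serology", seed = s,
                                          protection_effect = 1.5))
    dh <- ser$data_human; dn <- ser$data_nhp
    dh$matrix <- preprocess_serology(dh$matrix, mode = "human")
    dn$matrix <- preprocess_serology(dn$matrix, mode = "human")
    cfg <- model_config("serology", latent_dim = 16, epochs = 250,
                        variant = "v2", seed = s, batch_size = 50)
    m <- train_translator(dh, dn,
                          pairs = build_pair_index(list(dh, dn),
                                                   by = "protection"),
                          config = cfg,
                          classifier_targets = list(protection = "protection"))
    Z <- rbind(encode(m, dh$matrix, "human"), encode(m, dn$matrix, "nhp"))
    prot <- c(dh$samples$protection, dn$samples$protection)
    lr <- lrt_latent(Z, prot,
                     c(dh$samples$vaccination, dn$samples$vaccination),
                     c(dh$samples$system, dn$samples$system))
    imp <- lr$latent[lr$fdr < 0.05]
    if (!length(imp)) imp <- lr$latent[order(lr$p)][1:3]
    rk <- rank_cross_system_features(m, dh, imp, "human",
                                     protection = dh$samples$protection)
    planted <- ser$ground_truth$important_human
    k <- length(planted)
    recall <- mean(planted %in% rk$feature[1:k])
    expect_gte(recall, 0.7)
    # the univariate Wilcoxon validation flags the planted features
    sig <- rk$feature[rk$p_bonferroni < 0.05]
    expect_gt(mean(sig %in% planted), 0.9)
  }
})

test_that("GMT gene sets round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"),
                              setB = c("g2", "g4")))
  unlink(path)
})
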