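test_that("prior loss matches its closed forms and rejects invalid scores", {
  expect_equal(prior_loss(0.5, 0.5), 2 * log(0.5), tolerance = 1e-12)
  expect_equal(prior_loss(0.9, 0.2), log(0.9) + log(0.8), tolerance = 1e-12)
  # perfect discriminator limit: approaches 0 from below
  delta <- 1e-8
  v <- prior_loss(1 - delta, delta)
  expect_lt(v, 0)
  expect_gt(v, -1e-7)
  expect_error(prior_loss(1, 0.5), "strictly")
  expect_error(prior_loss(0.5, 0), "strictly")
  expect_error(prior_loss(c(0.5, 0.5), 0.5), "equal length")
})

test_that("MI loss matches softplus identities, limits, and a toy oracle", {
  mask2 <- matrix(0, 3, 3); mask2[1, 2] <- mask2[2, 1] <- 1
  z <- mi_loss(matrix(0, 3, 3), mask2)
  expect_equal(z$E_p, 0, tolerance = 1e-12)  # softplus(0) = ln 2
  expect_equal(z$E_q, 0, tolerance = 1e-12)
  expect_equal(z$L_MI, 0, tolerance = 1e-12)

  # perfect discriminator: +inf on positives, -inf on negatives
  D <- matrix(-60, 3, 3); D[1, 2] <- D[2, 1] <- 60
  mask3 <- matrix(0, 3, 3); mask3[1, 2] <- mask3[2, 1] <- 1
  lim <- mi_loss(D, mask3)
  expect_equal(lim$E_p, log(2), tolerance = 1e-8)
  expect_equal(lim$E_q, -log(2), tolerance = 1e-8)
  expect_equal(lim$L_MI, -2 * log(2), tolerance = 1e-8)

  # 3x3 toy, elementwise oracle computed independently
  set.seed(1)
  D <- matrix(rnorm(9), 3, 3)
  sp <- function(x) log(1 + exp(x))
  ep <- eq <- 0; np <- nq <- 0
  for (i in 1:3) for (j in 1:3) {
    if (mask3[i, j] == 1) { ep <- ep + log(2) - sp(-D[i, j]); np <- np + 1 }
    if (i != j && mask3[i, j] == 0) {
      eq <- eq + sp(-D[i, j]) + D[i, j] - log(2); nq <- nq + 1
    }
  }
  res <- mi_loss(D, mask3)
  expect_equal(res$E_p, ep / np, tolerance = 1e-12)
  expect_equal(res$E_q, eq / nq, tolerance = 1e-12)
  expect_equal(res$L_MI, -(ep / np - eq / nq), tolerance = 1e-12)
})

test_that("MI loss is invariant to sample relabeling and errors on degenerate masks", {
  set.seed(2)
  D <- matrix(rnorm(25), 5, 5)
  mask <- matrix(0, 5, 5)
  mask[1, 3] <- mask[3, 1] <- mask[2, 5] <- mask[5, 2] <- 1
  perm <- sample(5)
  a <- mi_loss(D, mask)
  b <- mi_loss(D[perm, perm], mask[perm, perm])
  expect_equal(a$L_MI, b$L_MI, tolerance = 1e-12)
  expect_error(mi_loss(matrix(0, 2, 2), matrix(0, 2, 2)), "skip")
  all_pos <- matrix(1, 2, 2) - diag(2)
  expect_error(mi_loss(matrix(0, 2, 2), all_pos), "skip")
})

test_that("pair alignment losses match hand geometry", {
  Z <- rbind(c(1, 0), c(1, 0))
  r <- pair_alignment_losses(Z, cbind(1, 2))
  expect_equal(r$L_distance, 0, tolerance = 1e-6)
  expect_equal(r$L_cosine, 1, tolerance = 1e-12)

  Z <- rbind(c(1, 0), c(0, 1))
  r <- pair_alignment_losses(Z, cbind(1, 2))
  expect_equal(r$L_distance, sqrt(2), tolerance = 1e-6)
  expect_equal(r$L_cosine, 0, tolerance = 1e-12)

  Z <- rbind(c(1, 0), c(0, 2))
  r <- pair_alignment_losses(Z, cbind(1, 2))
  expect_equal(r$L_distance, sqrt(5), tolerance = 1e-6)
  expect_equal(r$L_cosine, 0, tolerance = 1e-12)

  expect_error(pair_alignment_losses(rbind(c(0, 0), c(1, 0)), cbind(1, 2)),
               "zero-norm")
  expect_error(pair_alignment_losses(Z, matrix(integer(0), 0, 2)),
               "positive pair")
})

test_that("MSE reconstruction loss averages per-sample squared error sums", {
  X <- matrix(rnorm(6), 2, 3)
  expect_equal(recon_loss_mse(X, X), 0)
  expect_equal(recon_loss_mse(matrix(c(0, 0), 1), matrix(c(1, -1), 1)), 2)
  set.seed(3)
  A <- matrix(rnorm(6), 2, 3); B <- matrix(rnorm(6), 2, 3)
  oracle <- (sum((A[1, ] - B[1, ])^2) + sum((A[2, ] - B[2, ])^2)) / 2
  expect_equal(recon_loss_mse(A, B), oracle, tolerance = 1e-12)
  expect_error(recon_loss_mse(A, B[, 1:2]), "differ")
  expect_gte(recon_loss_mse(A, B), 0)
})

test_that("NB reconstruction loss defines a normalized pmf and the Poisson limit", {
  mu <- 2.5; th <- 1.7
  pmf <- vapply(0:300, function(k) exp(-recon_loss_nb(matrix(k), mu, th)),
                numeric(1))
  expect_gte(sum(pmf), 1 - 1e-6)
  expect_lte(sum(pmf), 1 + 1e-6)

  # theta -> infinity: Poisson negative log-likelihood
  nb <- recon_loss_nb(matrix(1), 2, 1e8)
  expect_equal(nb, -dpois(1, 2, log = TRUE), tolerance = 1e-3)

  # single observation: NLL minimized in mu at mu = k
  k <- 5
  grid <- seq(3, 7, by = 0.01)
  nll <- vapply(grid, function(m) recon_loss_nb(matrix(k), m, 2), numeric(1))
  expect_equal(grid[which.min(nll)], k, tolerance = 0.011)

  expect_error(recon_loss_nb(matrix(1.5), 2, 2), "integer")
  expect_error(recon_loss_nb(matrix(1), -1, 2), "positive")
})

test_that("classifier entropy matches cross-entropy arithmetic", {
  expect_equal(classifier_entropy(matrix(c(1, 0), 1), 1), 0)
  expect_equal(classifier_entropy(matrix(c(0.5, 0.5), 1), 1), log(2),
               tolerance = 1e-12)
  p <- rbind(c(0.8, 0.2), c(0.7, 0.3))
  expect_equal(classifier_entropy(p, c(1, 2)),
               -(log(0.8) + log(0.3)) / 2, tolerance = 1e-12)
  expect_error(classifier_entropy(p, c(1, 3)), "out of range")
})

test_that("total loss combines terms exactly per variant", {
  parts1 <- loss_breakdown(L_recon = 1, L_distance = 1, L_cosine = 1,
                           L_MI = 1, L_prior = 1, entropy = 1,
                           L2_encoder = c(1, 1), L2_decoder = c(1, 1),
                           L2_classifier = 1)
  # substitution: 1+1+1+1 + 2 + 2 + 1 + 1 - 1 = 9
  expect_equal(total_loss(parts1, loss_weights(), "v1"), 9)

  w0 <- loss_weights(recon = 1, distance = 0, MI = 0, prior = 0, cosine = 0,
                     enc = c(0, 0), dec = c(0, 0), L2class = 0, class = 0)
  expect_equal(total_loss(parts1, w0, "v1"), parts1$L_recon)

  # linearity in every weight: doubling one lambda adds exactly its term
  set.seed(4)
  parts <- loss_breakdown(L_recon = runif(1), L_distance = runif(1),
                          L_cosine = runif(1), L_MI = runif(1),
                          L_prior = runif(1), entropy = runif(1),
                          entropy_adverse = runif(1),
                          L2_encoder = runif(2), L2_decoder = runif(2),
                          L2_classifier = runif(1),
                          L2_trained_effect = runif(1))
  base <- total_loss(parts, loss_weights(), "v1")
  w2 <- loss_weights(MI = 2)
  expect_equal(total_loss(parts, w2, "v1") - base, parts$L_MI,
               tolerance = 1e-12)
  w3 <- loss_weights(cosine = 2)
  expect_equal(total_loss(parts, w3, "v1") - base, -parts$L_cosine,
               tolerance = 1e-12)

  # v2 - v1 = -lambda_adverse * entropy_adverse + lambda_te * L2_te
  d <- total_loss(parts, loss_weights(), "v2") -
    total_loss(parts, loss_weights(), "v1")
  expect_equal(d, -parts$entropy_adverse + parts$L2_trained_effect,
               tolerance = 1e-12)

  expect_error(loss_weights(recon = -1), "non-negative")
})

test_that("tape-node losses agree with the public numeric functions", {
  nd <- latentbridge:::nd
  set.seed(5)
  D <- matrix(rnorm(16), 4, 4)
  mask <- matrix(0, 4, 4); mask[1, 2] <- mask[2, 1] <- 1
  node <- latentbridge:::nd_mi(nd(D), mask)
  ref <- mi_loss(D, mask)
  expect_equal(node$value[1], ref$L_MI, tolerance = 1e-12)
  expect_equal(attr(node, "E_p"), ref$E_p, tolerance = 1e-12)

  X <- matrix(rnorm(12), 3, 4); Xh <- matrix(rnorm(12), 3, 4)
  expect_equal(latentbridge:::nd_mse_recon(X, nd(Xh))$value[1],
               recon_loss_mse(X, Xh), tolerance = 1e-12)

  K <- matrix(rpois(12, 3), 3, 4)
  MU <- matrix(runif(12, 1, 4), 3, 4); TH <- matrix(runif(12, 1, 4), 3, 4)
  expect_equal(latentbridge:::nd_nb_nll(K, nd(MU), nd(TH))$value[1],
               recon_loss_nb(K, MU, TH), tolerance = 1e-10)

  tv <- rnorm(5); tz <- rnorm(5)
  expect_equal(
    latentbridge:::nd_prior_from_logits(nd(matrix(tv)), nd(matrix(tz)))$value[1],
    prior_loss(plogis(tv), plogis(tz)), tolerance = 1e-10)

  Z1 <- matrix(rnorm(9), 3, 3); Z2 <- matrix(rnorm(9), 3, 3)
  pa <- pair_alignment_losses(rbind(Z1, Z2), cbind(1:3, 4:6))
  expect_equal(latentbridge:::nd_pair_dist(nd(Z1), nd(Z2))$value[1],
               pa$L_distance, tolerance = 1e-6)
  expect_equal(latentbridge:::nd_pair_cos(nd(Z1), nd(Z2))$value[1],
               pa$L_cosine, tolerance = 1e-12)

  logits <- matrix(rnorm(8), 4, 2)
  pr <- exp(logits) / rowSums(exp(logits))
  lab <- c(1L, 2L, 1L, 2L)
  expect_equal(latentbridge:::nd_cross_entropy(nd(logits), lab)$value[1],
               classifier_entropy(pr, lab), tolerance = 1e-12)
})
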