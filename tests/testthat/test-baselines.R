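test_that("shared-encoder variants require a 1-1 feature mapping", {
  toy <- toy_shared_pair(n = 10, p = 4, seed = 1)
  db2 <- toy$db
  db2$matrix <- db2$matrix[, 1:3]
  db2$feature_ids <- db2$feature_ids[1:3]
  expect_error(dcs_train(toy$da, db2, spec = dcs_spec(epochs = 1)), "1-1")
})

test_that("the original skip connection keeps output input-dependent; mod1 does not", {
  toy <- toy_shared_pair(n = 20, p = 6, seed = 2)
  toy$da$matrix <- tanh(toy$da$matrix)
  toy$db$matrix <- tanh(toy$db$matrix)
  sp0 <- dcs_spec("original", epochs = 2, latent_dim = 4, enc_hidden = 8,
                  dec_hidden = 8, seed = 2)
  m0 <- dcs_train(toy$da, toy$db, spec = sp0)
  m0$params[["dec_B.out.W"]][] <- 0
  m0$params[["dec_B.out.b"]][] <- 0
  for (i in seq_along(sp0$dec_hidden)) {
    m0$params[[paste0("dec_B.h", i, ".W")]][] <- 0
    m0$params[[paste0("dec_B.h", i, ".b")]][] <- 0
  }
  out1 <- dcs_translate(m0, toy$da$matrix[1:3, ], "B")
  out2 <- dcs_translate(m0, toy$da$matrix[4:6, ], "B")
  expect_gt(max(abs(out1)), 0)            # skip path still feeds the output
  expect_false(isTRUE(all.equal(out1, out2)))

  m1 <- dcs_train(toy$da, toy$db,
                  spec = dcs_spec("mod1", epochs = 2, latent_dim = 4,
                                  enc_hidden = 8, dec_hidden = 8, seed = 2))
  m1$params[["dec_B.out.W"]][] <- 0
  m1$params[["dec_B.out.b"]][] <- 0
  expect_equal(max(abs(dcs_translate(m1, toy$da$matrix[1:3, ], "B"))), 0)
})

test_that("the alignment term of mod2 tightens same-condition latent pairs", {
  res <- vapply(1:3, function(s) {
    toy <- toy_shared_pair(n = 40, p = 10, seed = s, rank = 4)
    toy$da$matrix <- tanh(toy$da$matrix)
    toy$db$matrix <- tanh(toy$db$matrix)
    dist_of <- function(v) {
      m <- dcs_train(toy$da, toy$db,
                     spec = dcs_spec(v, epochs = 60, latent_dim = 8,
                                     enc_hidden = 16, dec_hidden = 16,
                                     seed = s))
      za <- dcs_encode(m, toy$da$matrix)
      zb <- dcs_encode(m, toy$db$matrix)
      mean(sqrt(rowSums((za - zb)^2)))
    }
    dist_of("mod2") < dist_of("mod1")
  }, logical(1))
  expect_true(all(res))
})

test_that("projection translation is exact on rank-r data and at full rank
           coincides with per-gene least squares on diagonal-map data", {
  toy <- toy_shared_pair(n = 40, p = 8, seed = 3)
  # full rank: both reduce to (the same) least squares on y = c_g * x data
  f0 <- fit_fit(toy$da, toy$db, penalty = 0)
  tc <- transcompr_fit(toy$da, toy$db, n_components = 8)
  expect_lt(max(abs(fit_translate(f0, toy$da$matrix) -
                      transcompr_translate(tc, toy$da$matrix))), 1e-6)
  expect_equal(f0$slope, toy$cvec, tolerance = 1e-8)

  # exact rank-3 data reconstructed exactly with 3 components
  toy3 <- toy_shared_pair(n = 40, p = 8, seed = 4, rank = 3)
  src <- toy3$da
  tgt <- omics_dataset(toy3$da$matrix, toy3$db$samples)
  tc3 <- transcompr_fit(src, tgt, n_components = 3)
  expect_lt(max(abs(transcompr_translate(tc3, src$matrix) - src$matrix)),
            1e-8)

  # zero components predict the mean paired target profile
  tc0 <- transcompr_fit(toy$da, toy$db, n_components = 0)
  pred <- transcompr_translate(tc0, toy$da$matrix[1:3, ])
  expect_lt(max(abs(sweep(pred, 2, colMeans(toy$db$matrix)))), 1e-10)

  expect_error(transcompr_fit(toy$da, toy$db, n_components = 100),
               "exceeds")
})

test_that("slope-one-penalized regression solves its normal equations", {
  # one gene, pairs {(1,2), (2,4)}, penalty 1: closed form (5/3, 1/3)
  da <- omics_dataset(matrix(c(1, 2), 2, 1, dimnames = list(NULL, "g")),
                      data.frame(sample_id = c("a1", "a2"), system = "A",
                                 condition = c("c1", "c2")))
  db <- omics_dataset(matrix(c(2, 4), 2, 1, dimnames = list(NULL, "g")),
                      data.frame(sample_id = c("b1", "b2"), system = "B",
                                 condition = c("c1", "c2")))
  f1 <- fit_fit(da, db, penalty = 1)
  expect_equal(f1$slope, 5 / 3, tolerance = 1e-12)
  expect_equal(f1$intercept, 1 / 3, tolerance = 1e-12)

  # penalty 0: ordinary least squares per gene
  toy <- toy_shared_pair(n = 30, p = 5, seed = 5)
  toy$db$matrix <- toy$db$matrix + matrix(rnorm(150, sd = 0.1), 30, 5)
  f0 <- fit_fit(toy$da, toy$db, penalty = 0)
  for (g in 1:5) {
    ols <- coef(lm(toy$db$matrix[, g] ~ toy$da$matrix[, g]))
    expect_equal(f0$intercept[g], unname(ols[1]), tolerance = 1e-8)
    expect_equal(f0$slope[g], unname(ols[2]), tolerance = 1e-8)
  }

  # infinite penalty: the identity map
  fInf <- fit_fit(toy$da, toy$db, penalty = Inf)
  expect_equal(fInf$slope, rep(1, 5))
  expect_equal(fInf$intercept, rep(0, 5))
  expect_lt(max(abs(fit_translate(fInf, toy$da$matrix) - toy$da$matrix)), 1e-12)

  # no paired conditions
  db2 <- toy$db
  db2$samples$condition <- paste0("other", seq_len(30))
  expect_error(fit_fit(toy$da, db2), "paired")
})

test_that("direct translation is the identity on shared features only", {
  X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("g", 1:4)))
  expect_identical(direct_translate(X), X)
  expect_error(direct_translate(X, paste0("g", 1:4), paste0("h", 1:4)),
               "identical feature spaces")
})
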