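# Small configuration keeps the unit tests quick; the full-size regime is
# exercised by the acceptance suite.
small_mcfg <- function(seed = 1L) {
  mvae_moe_config(tga_dim = 721L, ftir_dim = 3476L, latent_dim = 8L,
                  encoder_hidden = 64L, n_experts = 3L, expert_hidden = 32L,
                  gating_hidden = 16L, seed = seed)
}

test_that("encoders emit finite latent posteriors deterministically", {
  model <- build_mvae_moe(small_mcfg())
  x <- seq(0.45, 1, length.out = 721)
  g <- encode_modality(x, "TGA", model)
  expect_length(g$mu, 8L)
  expect_length(g$logvar, 8L)
  expect_true(all(is.finite(c(g$mu, g$logvar))))
  expect_identical(encode_modality(x, "TGA", model), g)
  xf <- runif(3476, 0, 2)
  gf <- encode_modality(xf, "FTIR", model)
  expect_true(all(is.finite(c(gf$mu, gf$logvar))))
  expect_error(encode_modality(x[1:700], "TGA", model), "shape error")
})

test_that("product-of-experts fusion matches closed-form Gaussian products", {
  std <- gaussian_latent(0, 0)  # N(0, 1)
  two <- fuse_experts(list(std, std))
  expect_equal(two$mu, 0)
  expect_equal(exp(two$logvar), 1 / 3)   # prior + two unit-precision experts
  one <- fuse_experts(list(std))
  expect_equal(exp(one$logvar), 1 / 2)

  # symmetric means cancel
  sym <- fuse_experts(list(gaussian_latent(c(2, -1), c(0.3, 0.1)),
                           gaussian_latent(c(-2, 1), c(0.3, 0.1))))
  expect_equal(sym$mu, c(0, 0))

  # general closed form on random posteriors
  set.seed(8)
  for (i in 1:20) {
    g1 <- gaussian_latent(rnorm(4), rnorm(4))
    g2 <- gaussian_latent(rnorm(4), rnorm(4))
    fused <- fuse_experts(list(g1, g2))
    prec <- 1 + exp(-g1$logvar) + exp(-g2$logvar)
    expect_equal(fused$mu, (g1$mu * exp(-g1$logvar) + g2$mu * exp(-g2$logvar)) / prec,
                 tolerance = 1e-12)
    expect_equal(fused$logvar, -log(prec), tolerance = 1e-12)
  }
  expect_error(fuse_experts(list()), "argument error")
})

test_that("reparameterization is the deterministic shift-and-scale map", {
  g <- gaussian_latent(c(1, 2), c(0, log(4)))
  expect_equal(reparameterize(g, c(0, 0)), c(1, 2))
  expect_equal(reparameterize(gaussian_latent(0, 0), 1), 1)
  expect_equal(reparameterize(g, c(1, 1)), c(2, 4))
  expect_error(reparameterize(g, c(1, 1, 1)), "shape error")

  # Monte-Carlo mean approaches mu at the parametric rate
  set.seed(9)
  draws <- replicate(1e5, reparameterize(gaussian_latent(0.5, log(0.25)), rnorm(1)))
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(1e5))
})

test_that("KL divergence matches its closed forms and rearrangement", {
  kl <- function(mu, logvar) sum(lignocomp:::.kl_terms(mu, logvar))
  expect_equal(kl(0, 0), 0)
  expect_equal(kl(1, 0), 0.5)
  expect_equal(kl(0, 1), (exp(1) - 2) / 2)
  set.seed(10)
  for (i in 1:50) {
    mu <- rnorm(6)
    lv <- rnorm(6)
    expect_lt(abs(kl(mu, lv) - 0.5 * sum(mu^2 + exp(lv) - 1 - lv)), 1e-12)
  }
})

test_that("decoders and the mixture head respect shapes and the simplex", {
  model <- build_mvae_moe(small_mcfg())
  z <- rnorm(8)
  expect_length(decode_modality(z, "TGA", model), 721L)
  expect_length(decode_modality(z, "FTIR", model), 3476L)
  expect_identical(decode_modality(z, "TGA", model), decode_modality(z, "TGA", model))

  out <- predict_composition(z, model)
  expect_lt(abs(sum(out$composition) - 1), 1e-9)
  expect_true(all(out$composition >= 0))
  expect_equal(sum(out$expert_weights), 1, tolerance = 1e-12)

  # a single expert receives all the gate mass
  solo <- build_mvae_moe(mvae_moe_config(latent_dim = 8L, encoder_hidden = 32L,
                                         n_experts = 1L, seed = 2))
  sout <- predict_composition(rnorm(8), solo)
  expect_identical(sout$expert_weights, 1)

  # the mixture is the gate-weighted convex combination of expert outputs
  mo <- lignocomp:::.moe_forward(model, matrix(z, 1L))
  manual <- 0
  for (e in seq_along(mo$expert_fwd)) {
    manual <- manual + mo$gate[, e] * mo$expert_fwd[[e]]$out
  }
  expect_equal(as.numeric(mo$pred), as.numeric(manual), tolerance = 1e-12)
  expect_equal(as.numeric(mo$pred), unname(out$composition), tolerance = 1e-12)
})

test_that("the composite loss decomposes additively and vanishes when perfect", {
  lb <- loss_breakdown(0, 0, 0, 0)
  expect_identical(lb$total, 0)
  lb <- loss_breakdown(0.12, 0.05, 0.01, 0.3)
  expect_identical(lb$total, 0.12 + 0.05 + 0.01 + 0.3)

  study <- simulate_study(params = noiseless_params(), seed = 2)
  triplets <- oracle_triplets(study, c(250, 320, 400))
  model <- build_mvae_moe(small_mcfg())
  l <- compute_losses(triplets, model, noise = "zero")
  expect_true(all(c(l$recon_tga, l$recon_ftir, l$pred) >= 0))
  expect_gte(l$kl, 0)
  expect_equal(l$total, l$recon_tga + l$recon_ftir + l$pred + l$kl)
  expect_error(compute_losses(list(), model), "argument error")
})

test_that("predictor training is seeded, monotone in loss and simplex at inference", {
  study <- simulate_study(params = noiseless_params(), seed = 2)
  triplets <- oracle_triplets(study, c(250, 280, 320, 360, 400))
  cfg <- train_config(epochs = 12L, seed = 3)
  m1 <- train_predictor(triplets, cfg, small_mcfg(7))
  m2 <- train_predictor(triplets, cfg, small_mcfg(7))
  expect_identical(m1$loss_history, m2$loss_history)
  expect_equal(nrow(m1$loss_history), 12L)
  expect_lt(m1$loss_history$total[12], m1$loss_history$total[1])
  expect_equal(m1$loss_history$total,
               with(m1$loss_history, recon_tga + recon_ftir + pred + kl))

  pr <- predict_gcms(m1, triplets[[2]]$tga, triplets[[2]]$ftir)
  expect_s3_class(pr, "composition_vector")
  expect_lt(abs(sum(pr$fractions) - 1), 1e-6)
  expect_identical(pr, predict_gcms(m1, triplets[[2]]$tga, triplets[[2]]$ftir))
  expect_error(train_predictor(triplets[1], cfg, small_mcfg()), "argument error")
  expect_error(predict_gcms(build_mvae_moe(small_mcfg()), triplets[[1]]$tga,
                            triplets[[1]]$ftir), "state error")
})
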