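test_that("generator architectures follow the per-modality layer stacks", {
  tga <- generator_trace(build_generator(generator_spec("TGA"), 1))
  expect_identical(tga$layer, c(
    "Conv1D(1, 16, kernel=3, stride=1, padding=1) + ReLU",
    "Conv1D(16, 32, kernel=3, stride=1, padding=1) + ReLU",
    "Flatten", "Linear(32, 1024) + ReLU", "Linear(1024, 721)"))

  ftir <- generator_trace(build_generator(generator_spec("FTIR"), 1))
  expect_identical(ftir$layer, c(
    "Conv1D(1, 16, kernel=3, stride=1, padding=1) + ReLU",
    "Conv1D(16, 32, kernel=3, stride=1, padding=1) + ReLU",
    "Conv1D(32, 64, kernel=3, stride=1, padding=1) + ReLU",
    "Flatten", "Linear(64, 1024) + ReLU", "Dropout(0.3)", "Linear(1024, 3476)"))

  gcms <- generator_trace(build_generator(generator_spec("GCMS"), 1))
  expect_identical(gcms$layer, c(
    "Conv1D(1, 64, kernel=3, stride=1, padding=1) + ReLU",
    "Conv1D(64, 64, kernel=3, stride=1, padding=1) + ReLU",
    "Conv1D(64, 64, kernel=3, stride=1, padding=1) + ReLU",
    "GlobalAveragePooling", "Linear(64, 128) + ReLU",
    "Linear(128, 10) + Softmax"))
})

test_that("weight initialization is a pure function of (spec, seed)", {
  a <- build_generator(generator_spec("TGA"), seed = 12)
  b <- build_generator(generator_spec("TGA"), seed = 12)
  c_ <- build_generator(generator_spec("TGA"), seed = 13)
  expect_identical(lignocomp:::nn_params(a$net), lignocomp:::nn_params(b$net))
  expect_false(identical(lignocomp:::nn_params(a$net), lignocomp:::nn_params(c_$net)))
})

test_that("condition encoding is the normalized HTL temperature", {
  expect_equal(as.numeric(encode_condition(250)), 0)
  expect_equal(as.numeric(encode_condition(400)), 1)
  expect_equal(as.numeric(encode_condition(325)), 0.5)
  expect_equal(dim(encode_condition(300, input_length = 4L)), c(1L, 4L))
  expect_error(encode_condition(500), "domain error")
})

test_that("the learning-rate schedule steps down by 10x after epoch 75", {
  expect_identical(lr_at_epoch(1), 0.001)
  expect_identical(lr_at_epoch(75), 0.001)
  expect_identical(lr_at_epoch(76), 1e-4)
  expect_identical(lr_at_epoch(100), 1e-4)
})

test_that("training reduces the loss and is reproducible", {
  study <- simulate_study(params = noiseless_params(), seed = 3)
  anchors <- oracle_triplets(study, c(250, 300, 350, 400))
  pairs <- lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                            target = t$gcms$fractions))
  cfg <- train_config(epochs = 30L, seed = 5)
  g1 <- train_generator(build_generator(generator_spec("GCMS"), 5), pairs, cfg)
  g2 <- train_generator(build_generator(generator_spec("GCMS"), 5), pairs, cfg)
  expect_length(g1$loss_history, 30L)
  expect_identical(g1$loss_history, g2$loss_history)
  expect_lt(g1$loss_history[30], g1$loss_history[1])

  bad <- lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                          target = t$gcms$fractions[1:5]))
  expect_error(train_generator(build_generator(generator_spec("GCMS"), 5), bad),
               "shape error")
  expect_error(train_generator(build_generator(generator_spec("GCMS"), 5), pairs[1]),
               "argument error")
})

test_that("generated outputs are deterministic, simplex-valued and smooth in T", {
  study <- simulate_study(params = noiseless_params(), seed = 3)
  anchors <- oracle_triplets(study, c(250, 300, 350, 400))
  pairs <- lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                            target = t$gcms$fractions))
  gen <- train_generator(build_generator(generator_spec("GCMS"), 5), pairs,
                         train_config(epochs = 30L, seed = 5))
  v1 <- generate_at_temperature(gen, 315)
  v2 <- generate_at_temperature(gen, 315)
  expect_identical(v1, v2)
  expect_lt(abs(sum(v1) - 1), 1e-6)
  expect_true(all(v1 >= 0))

  # conditional smoothness: small temperature steps move the output little
  temps <- seq(255, 395, by = 5)
  outs <- sapply(temps, function(t) generate_at_temperature(gen, t))
  step_norm <- sqrt(colSums((outs[, -1] - outs[, -ncol(outs)])^2))
  expect_lt(max(step_norm), 0.25)

  expect_error(generate_at_temperature(build_generator(generator_spec("GCMS"), 1), 300),
               "state error")
})

test_that("augment_dataset assembles valid triplets from the three generators", {
  study <- simulate_study(params = noiseless_params(), seed = 3)
  anchors <- oracle_triplets(study, c(250, 300, 350, 400))
  cfg <- train_config(epochs = 25L, seed = 2)
  models <- list(
    tga = train_generator(build_generator(generator_spec("TGA"), 2),
                          lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                                           target = t$tga$mass_pct / 100)), cfg),
    ftir = train_generator(build_generator(generator_spec("FTIR"), 2),
                           lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                                            target = t$ftir$values)), cfg),
    gcms = train_generator(build_generator(generator_spec("GCMS"), 2),
                           lapply(anchors, function(t) list(condition = t$htl_temperature_c,
                                                            target = t$gcms$fractions)), cfg))
  triplets <- augment_dataset(models)
  expect_length(triplets, 6L)
  for (t in triplets) expect_identical(validate_triplet(t), character(0))
  expect_identical(augment_dataset(models, numeric()), list())
  expect_error(augment_dataset(models[c("tga", "ftir")]), "state error")
})
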