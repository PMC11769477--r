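test_that("the residual backbone report reproduces the printed architecture figures", {
  m <- build_model(model_spec())
  rep <- m$layer_report
  expect_equal(m$flatten_len, 204800)
  expect_equal(rep$params[rep$name == "fc"], 204800 * 1024 + 1024) # 209,716,224
  expect_equal(rep$params[rep$name == "resnet50"], 23587712)
  expect_equal(rep$trainable[rep$name == "resnet50"], 23534592)
  expect_equal(rep$params[rep$name == "output"], 2050)
  expect_equal(m$backbone_out_shape, c(10L, 10L, 2048L))
  # totals are additive over the detailed per-layer report
  expect_equal(sum(m$backbone_report$params), 23587712)
  expect_equal(m$total_params, sum(rep$params))
})

test_that("architecture is reproducible across rebuilds and seeds; weights differ by seed", {
  spec <- model_spec(input_shape = c(64, 64, 3), backbone = "debug", fc_units = 32)
  m1 <- build_model(spec, seed = 1)
  m2 <- build_model(spec, seed = 1)
  m3 <- build_model(spec, seed = 2)
  expect_identical(m1$layer_report, m3$layer_report)
  expect_identical(m1$head$W[[1]], m2$head$W[[1]])
  expect_false(identical(m1$head$W[[1]], m3$head$W[[1]]))
  expect_error(build_model(model_spec(input_shape = c(100, 100, 3))), "stride-32")
  expect_error(build_model(model_spec(pretrained = TRUE)), "pretrained|weights")
})

test_that("FC feature extraction is a pure function with one 1024-wide row per image", {
  spec <- model_spec(input_shape = c(32, 32, 3), backbone = "debug")
  m <- build_model(spec, seed = 3)
  set.seed(8)
  tensor <- array(runif(7 * 32 * 32 * 3), c(7, 32, 32, 3))
  tensor[2, , , ] <- tensor[1, , , ] # duplicate image
  feats <- extract_fc_features(m, tensor)
  expect_equal(dim(feats), c(7, 1024))
  expect_equal(colnames(feats)[c(1, 1024)], c("f0001", "f1024"))
  expect_identical(feats[1, ], feats[2, ])
  expect_identical(feats, extract_fc_features(m, tensor))
  # zeroed dense weights + zero input -> features are exactly the (zero) bias
  m0 <- m
  m0$head$W[[1]][] <- 0
  zeros <- array(0, c(2, 32, 32, 3))
  expect_true(all(extract_fc_features(m0, zeros) == 0))
  # structural resnet50 model refuses inference
  big <- build_model(model_spec())
  expect_error(extract_fc_features(big, array(0, c(1, 320, 320, 3))), "structural|debug")
})

test_that("head training keeps an epoch-long trace and lr = 0 is a no-op", {
  gen <- synthetic_images(n_samples = 8, size = 32, seed = 2)
  tensor <- normalize_images(lapply(gen$images, convert_bit_depth), target_size = 32)
  m <- build_model(model_spec(input_shape = c(32, 32, 3), backbone = "debug",
                              fc_units = 16), seed = 1)
  tm <- train_model(m, tensor, gen$labels, training_config(epochs = 1), seed = 5)
  expect_equal(nrow(tm$trace), 1)
  frozen <- train_model(m, tensor, gen$labels,
                        training_config(learning_rate = 0, epochs = 3), seed = 5)
  expect_identical(frozen$head, m$head)
  expect_error(train_model(m, tensor, gen$labels, training_config(batch_size = 99)),
               "batch_size")
})

test_that("the head learns separable toy images within 50 epochs", {
  gen <- synthetic_images(n_samples = 40, size = 64, seed = 7)
  tensor <- normalize_images(lapply(gen$images, convert_bit_depth), target_size = 64)
  m <- build_model(model_spec(input_shape = c(64, 64, 3), backbone = "debug",
                              fc_units = 64), seed = 1)
  tm <- train_model(m, tensor, gen$labels,
                    training_config(learning_rate = 0.01, epochs = 50), seed = 3)
  expect_gte(tail(tm$trace$accuracy, 1), 0.9)
})

test_that("feature matrices round-trip through CSV", {
  set.seed(6)
  feats <- matrix(rnorm(12), 3, 4)
  labels <- c(0L, 1L, 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(feats, path, labels)
  back <- read_feature_csv(path)
  expect_equal(unname(back$features), unname(feats), tolerance = 1e-12)
  expect_identical(back$labels, labels)
  expect_equal(colnames(back$features), sprintf("f%04d", 1:4))
})
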