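test_that("network config enforces its constraints", {
  expect_error(keypoint_network_config(learning_rate = 0),
               class = "nf_config_error")
  expect_error(keypoint_network_config(dropout = 1), class = "nf_config_error")
  expect_error(keypoint_network_config(validation_split = 0),
               class = "nf_config_error")
  expect_error(keypoint_network_config(input_size = 100),
               class = "nf_config_error")
  expect_error(keypoint_network_config(backbone = "densenet"),
               class = "nf_config_error")
})

test_that("the extractor halves the spatial side four times (side/16)", {
  for (side in c(224L, 112L, 64L)) {
    cfg <- keypoint_network_config(input_size = side, width_scale = 1 / 32)
    net <- build_keypoint_network(cfg)
    s <- net$summary
    last_pool <- s[max(which(grepl("maxpool", s$layer))), ]
    expect_equal(last_pool$out_h, side / 16)
  }
})

test_that("a reduced-width network forward pass produces the summary shapes", {
  cfg <- keypoint_network_config(input_size = 64, channels = 1,
                                 width_scale = 1 / 16, dropout = 0)
  net <- build_keypoint_network(cfg)
  x <- array(rnorm(64 * 64), c(64, 64, 1))
  fw <- nasoform:::nn_forward(net$layers, x)
  expect_length(fw$out, 2 * cfg$n_landmarks)
  expect_true(all(fw$out >= 0 & fw$out <= 1))   # sigmoid-bounded coordinates
  # intermediate feature map matches the summary arithmetic
  s <- net$summary
  expect_equal(s$out_h[max(which(grepl("maxpool", s$layer)))], 4)
})

test_that("weight initialization is seed-deterministic", {
  cfg <- keypoint_network_config(width_scale = 1 / 32, seed = 9)
  n1 <- build_keypoint_network(cfg)
  n2 <- build_keypoint_network(cfg)
  expect_identical(n1$layers, n2$layers)
})

test_that("training overfits a single repeated image to ~0 landmark error", {
  subj <- tiny_population(2, seed = 6)
  ds <- render_landmark_dataset(subj[1:2, ], "basilar",
                                render_config(image_size = 64, channels = 1,
                                              noise_sd = 0), seed = 3)
  # duplicate the tiny set so train/val splits are populated
  ds$images <- ds$images[c(1, 1, 1, 1, 2)]
  ds$landmark_sets <- ds$landmark_sets[c(1, 1, 1, 1, 2)]
  cfg <- keypoint_network_config(view = "basilar", input_size = 64,
                                 channels = 1, width_scale = 1 / 16,
                                 dropout = 0, epochs = 150, batch_size = 4,
                                 learning_rate = 0.01, seed = 10)
  fit <- train_keypoint_model(ds, cfg)
  expect_equal(nrow(fit$history), 150)
  expect_true(all(is.finite(fit$history$train_loss)))
  # training MAE on the overfit image < 2 px
  model <- fit$model
  x <- normalize_image(ds$images[[1]] * 255, model$sigma)
  out <- nasoform:::nn_forward(model$layers, x)$out * 63
  tgt <- nasoform:::.nf_targets(ds$landmark_sets[[1]], cfg$codes, 64) * 63
  expect_lt(mean(abs(out - tgt)), 2)
})

test_that("training is reproducible for a fixed seed", {
  subj <- tiny_population(6, seed = 8)
  ds <- render_landmark_dataset(subj, "basilar",
                                render_config(image_size = 64, channels = 1),
                                seed = 4)
  cfg <- keypoint_network_config(view = "basilar", input_size = 64,
                                 channels = 1, width_scale = 1 / 32,
                                 dropout = 0.1, epochs = 2, batch_size = 3,
                                 seed = 77)
  f1 <- train_keypoint_model(ds, cfg)
  f2 <- train_keypoint_model(ds, cfg)
  expect_identical(f1$history, f2$history)
})

test_that("prediction maps through the resize transform back into the original frame", {
  subj <- tiny_population(3, seed = 12)
  ds <- render_landmark_dataset(subj, "basilar",
                                render_config(image_size = 64, channels = 1,
                                              noise_sd = 0), seed = 5)
  ds$images <- ds$images[c(1, 1, 1, 2)]
  ds$landmark_sets <- ds$landmark_sets[c(1, 1, 1, 2)]
  cfg <- keypoint_network_config(view = "basilar", input_size = 64,
                                 channels = 1, width_scale = 1 / 16,
                                 dropout = 0, epochs = 120, batch_size = 4,
                                 learning_rate = 0.01, seed = 13)
  fit <- train_keypoint_model(ds, cfg)
  # native-size prediction close to ground truth on the overfit image
  ls <- predict_landmarks(fit$model, ds$images[[1]], subject_id = "p")
  truth <- ds$landmark_sets[[1]]$points[cfg$codes, ]
  expect_lt(mean(abs(ls$points - truth)), 2.5)
  # all predictions inside the image bounds
  expect_length(validate_landmark_set(ls, image_shape = c(64, 64)), 0)
  # an upscaled copy of the image round-trips into the original frame:
  # predictions on the 96x96 upscale, mapped back, stay close
  big <- nasoform:::cpp_resize_bilinear(nasoform:::.nf_as_cube(ds$images[[1]]),
                                        96, 96)
  ls_big <- predict_landmarks(fit$model, big, subject_id = "p2")
  expect_lt(mean(abs(ls_big$points / (96 / 64) - truth)), 4)
  # wrong channel count is an input error
  bad <- array(0.5, c(64, 64, 3))
  expect_error(predict_landmarks(fit$model, bad), class = "nf_input_error")
})
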