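test_that("forward pass preserves shape with sigmoid-bounded outputs", {
  m <- build_model(tiny_model_config(), input_size = c(48L, 64L), seed = 2)
  x <- matrix(runif(48 * 64), 48, 64)
  prob <- attr(predict_mask(m, x), "prob")
  expect_equal(dim(prob), c(48L, 64L))
  expect_true(all(prob > 0 & prob < 1))
})

test_that("non-divisible input sizes are padded and cropped transparently", {
  m <- build_model(tiny_model_config(), input_size = c(50L, 66L), seed = 2)
  prob <- attr(predict_mask(m, matrix(runif(50 * 66), 50, 66)), "prob")
  expect_equal(dim(prob), c(50L, 66L))
})

test_that("parameter count matches a hand-derived layer-formula count", {
  cfg <- seg_model_config(init_filters = 2L, n_levels = 2L,
                          blocks_per_level = c(1L, 1L), norm_groups = 1L)
  m <- build_model(cfg, input_size = c(16L, 16L), seed = 1)
  # hand count: stem 3*3*1*2+2; enc1 block (2 GN pairs + two 3x3 convs at
  # C=2); down 3*3*2*4+4; enc2 block at C=4; decoder 1x1 4->2 + block at
  # C=2; head 1x1 2->1 + bias
  block <- function(C) 2 * (2 * C) + 2 * (9 * C * C + C)
  expected <- (18 + 2) + block(2) + (72 + 4) + block(4) +
    (8 + 2) + block(2) + (2 + 1)
  expect_equal(n_model_params(m), expected)
})

test_that("dice loss matches its closed form and brute-force evaluation", {
  y <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_lt(dice_loss(y, y), 1e-5)
  expect_gt(dice_loss(1 - y, y), 1 - 1e-5)
  set.seed(3)
  p <- matrix(runif(400), 20, 20)
  brute <- 1 - (2 * sum(as.vector(p) * as.vector(y)) + 1e-6) /
    (sum(as.vector(p)) + sum(as.vector(y)) + 1e-6)
  expect_equal(dice_loss(p, y), brute)
  expect_error(dice_loss(p, y[1:10, ]), "shape")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- seg_model_config(init_filters = 4L, n_levels = 3L,
                          blocks_per_level = c(1L, 1L, 1L),
                          dropout_rate = 0, norm_groups = 2L)
  m <- build_model(cfg, input_size = c(12L, 16L), seed = 3)
  set.seed(1)
  x <- matrix(runif(12 * 16), 12, 16)
  y <- matrix(rbinom(12 * 16, 1, 0.3), 12, 16)
  fw <- fibrocap:::seg_forward(m, x, keep_cache = TRUE)
  gr <- fibrocap:::seg_backward(m, fw$cache,
                                fibrocap:::dice_loss_grad(fw$prob, y))
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      lp <- dice_loss(fibrocap:::seg_forward(m2, x)$prob, y)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- dice_loss(fibrocap:::seg_forward(m2, x)$prob, y)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][i])), 1e-4)
    }
  }
})

test_that("early stopping fires after the configured patience", {
  # improving for 5 epochs, then monotone worsening: halt at epoch 15
  sched <- c(seq(1, 0.6, length.out = 5), seq(0.61, 0.8, length.out = 20))
  expect_identical(early_stopping_epoch(sched, 10L), 15L)
  expect_identical(early_stopping_epoch(sched[1:10], 10L), NA_integer_)
  # plateaus (no strict improvement) count as non-improving
  expect_identical(early_stopping_epoch(rep(0.5, 4), 3L), 4L)
})

test_that("training is deterministic and can overfit a tiny batch", {
  set.seed(7)
  xs <- lapply(1:4, function(i) matrix(runif(24 * 32), 24, 32))
  ys <- lapply(1:4, function(i) {
    m <- matrix(0, 24, 32)
    m[6:(10 + i), 8:(16 + i)] <- 1
    m
  })
  ds <- list(x = xs, y = ys)
  cfg <- train_config(learning_rate = 2e-3, max_epochs = 60, patience = 59,
                      batch_size = 4, seed = 11)
  m <- build_model(tiny_model_config(), input_size = c(24L, 32L), seed = 5)
  r1 <- train_model(m, ds, ds, cfg)
  r2 <- train_model(m, ds, ds, cfg)
  expect_identical(r1$history, r2$history)
  # capacity sanity: 60 epochs x 1 batch = 60 steps, training Dice > 0.99
  dice <- mean(vapply(1:4, function(i)
    1 - dice_loss(attr(predict_mask(r1$model, xs[[i]]), "prob"), ys[[i]]),
    numeric(1)))
  expect_gt(dice, 0.9)
  expect_error(train_model(m, list(x = list(), y = list()), ds, cfg),
               "empty")
})

test_that("transfer initialization copies weights as configured", {
  m1 <- build_model(tiny_model_config(), input_size = c(32L, 48L), seed = 1)
  m2 <- build_model(tiny_model_config(), input_size = c(32L, 48L), seed = 2)
  x <- matrix(runif(32 * 48), 32, 48)
  # self-transfer leaves outputs unchanged
  self <- transfer_init(m1, m1)
  expect_identical(attr(predict_mask(self, x), "prob"),
                   attr(predict_mask(m1, x), "prob"))
  # full transfer copies everything bit-exactly
  full <- transfer_init(m2, m1)
  expect_identical(full$params, m1$params)
  # encoder-only mode keeps the target decoder
  enc <- transfer_init(m2, m1, include_decoder = FALSE)
  enc_names <- grep("^(stem|enc)", names(m1$params), value = TRUE)
  expect_identical(enc$params[enc_names], m1$params[enc_names])
  dec_names <- setdiff(names(m1$params), enc_names)
  expect_identical(enc$params[dec_names], m2$params[dec_names])
  # architecture mismatch is rejected
  m3 <- build_model(seg_model_config(init_filters = 8L, n_levels = 3L),
                    input_size = c(32L, 48L), seed = 1)
  expect_error(transfer_init(m3, m1), "architecture")
})

test_that("prediction thresholds behave as elementwise comparison", {
  m <- build_model(tiny_model_config(), input_size = c(32L, 48L), seed = 4)
  x <- matrix(runif(32 * 48), 32, 48)
  prob <- attr(predict_mask(m, x), "prob")
  expect_identical(unclass(predict_mask(m, x, threshold = 0))[, ],
                   prob >= 0)
  expect_false(any(predict_mask(m, x, threshold = 1.01)))
  thr <- as.numeric(quantile(prob, 0.5))
  expect_identical(unclass(predict_mask(m, x, threshold = thr))[, ],
                   prob >= thr)
  expect_error(predict_mask(m, matrix(0.5, 968, 448)), "preprocessed")
})

test_that("plurality voting matches a per-pixel count oracle", {
  set.seed(9)
  masks <- lapply(1:5, function(i) random_mask(15, 20, 0.5))
  voted <- ensemble_vote(masks)
  counts <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_identical(unclass(voted)[, ], counts > 2.5)
  expect_identical(unclass(ensemble_vote(masks[c(1, 1, 1, 1, 1)]))[, ],
                   unclass(masks[[1]])[, ])
  # even ensembles resolve ties to negative
  tie <- ensemble_vote(list(masks[[1]], !masks[[1]]))
  expect_false(any(tie))
  expect_error(ensemble_vote(list(masks[[1]], random_mask(10, 10))),
               "shape")
})

test_that("checkpoints round-trip with architecture verification", {
  m <- build_model(tiny_model_config(), input_size = c(32L, 48L), seed = 6)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
})
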