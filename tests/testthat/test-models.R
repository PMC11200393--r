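test_that("autoencoder stages reproduce the intended shapes", {
  cae <- build_cae(0)
  shapes <- cae_stage_shapes(cae)
  expect_equal(shapes$shape,
               c("64x64x16", "32x32x32", "16x16x64", "8x8x128", "4x4x128",
                 "2048", "2048", "4x4x128", "8x8x128", "16x16x64",
                 "32x32x32", "64x64x16", "128x128x1"))
})

test_that("encoding is deterministic, 2048-long, and shape-checked", {
  cae <- build_cae(1)
  withr::local_seed(2)
  img <- matrix(runif(128 * 128), 128)
  z1 <- encode(cae, img)
  expect_length(z1, 2048L)
  expect_identical(z1, encode(cae, img))
  expect_error(encode(cae, matrix(0, 64, 64)), "128x128")
  # zeroed weights propagate nullity through the ReLU stages
  cae0 <- cae
  cae0$params <- purrr::map(cae0$params, ~ .x * 0)
  expect_equal(encode(cae0, matrix(0, 128, 128)), numeric(2048))
})

test_that("fused training step matches the layer-by-layer reference path", {
  cae <- build_cae(3)
  withr::local_seed(3)
  x <- lungsound:::image_array(lapply(1:4, function(i) matrix(runif(128 * 128), 128)))
  fwd <- lungsound:::cae_forward(cae, x)
  ref_loss <- mean((fwd$xhat - x)^2)
  ref_grads <- lungsound:::cae_backward(cae, x, fwd)
  step <- lungsound:::.cae_step(cae$params, x)
  expect_equal(step$loss, ref_loss, tolerance = 1e-6)
  for (nm in names(cae$params)) {
    a <- as.numeric(ref_grads[[nm]]); b <- as.numeric(step$grads[[nm]])
    expect_lt(max(abs(a - b)) / max(1e-12, max(abs(a))), 1e-4)
  }
})

test_that("training reduces the reconstruction error reproducibly", {
  withr::local_seed(4)
  imgs <- lapply(1:12, function(i) {
    to_image(outer(seq_len(32), seq_len(40), function(a, b)
      exp(-((a - 8 - (i %% 3) * 6)^2) / 20) + 0.05 * runif(1)))
  })
  cae <- build_cae(2)
  psnr0 <- mean(sapply(seq_along(imgs), function(i)
    psnr(imgs[[i]], reconstruct(cae, imgs[[i]])[, , 1, 1])))
  fit <- train_cae(cae, imgs, train_config(epochs = 6, seed = 1, batch_size = 4))
  expect_lt(fit$history$loss[6], fit$history$loss[1])
  psnr1 <- mean(sapply(seq_along(imgs), function(i)
    psnr(imgs[[i]], reconstruct(fit, imgs[[i]])[, , 1, 1])))
  expect_gt(psnr1, psnr0)
  fit2 <- train_cae(build_cae(2), imgs, train_config(epochs = 6, seed = 1,
                                                     batch_size = 4))
  expect_identical(fit$history$loss, fit2$history$loss)
  expect_identical(fit$params$enc1_w, fit2$params$enc1_w)
})

test_that("psnr follows its closed form with a capped perfect score", {
  a <- matrix(0.5, 8, 8)
  expect_equal(psnr(a, a), 120)
  b <- a + 0.1                                     # MSE 0.01 -> 20 dB
  expect_equal(psnr(a, b), 20, tolerance = 1e-9)
  c2 <- a + 0.001                                  # MSE 1e-6 -> 60 dB
  expect_equal(psnr(a, c2), 60, tolerance = 1e-9)
  expect_error(psnr(a, matrix(0.5, 4, 4)), "shapes")
})

test_that("fusion concatenates and reshapes row-major into 8x512", {
  z <- fuse(numeric(2048), numeric(2048))
  expect_equal(dim(z), c(8L, 512L))
  expect_true(all(z == 0))
  cwt <- as.numeric(0:2047); mel <- as.numeric(2048:4095)
  s <- fuse(cwt, mel)
  expect_equal(s[1, ], as.numeric(0:511))
  expect_equal(s[5, ], as.numeric(2048:2559))
  expect_equal(as.numeric(t(s)), c(cwt, mel))
  expect_error(fuse(numeric(2048), numeric(100)), "2048")
  expect_equal(dim(latent_sequence(numeric(2048))), c(4L, 512L))
})

test_that("the classifier reproduces the printed parameter counts", {
  counts <- count_parameters(build_classifier(512, 2))
  expect_equal(counts$parameters[counts$layer == "lstm"], 147712L)
  expect_equal(counts$parameters[counts$layer == "dense"], 130L)
  expect_equal(counts$parameters[counts$layer == "total"], 147842L)
  # the identity behind the count
  expect_equal(4 * ((512 + 64) * 64 + 64) + (64 * 2 + 2), 147842)
})

test_that("predictions are probability rows and stateless across samples", {
  m <- build_classifier(16, 3, hidden = 8, seed = 1)
  m$classes <- c("a", "b", "c")
  withr::local_seed(5)
  seqs <- lapply(1:6, function(i) matrix(rnorm(4 * 16), 4, 16))
  pr <- predict(m, seqs)
  probs <- as.matrix(pr[, m$classes])
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-6)
  dup <- predict(m, seqs[c(1, 1)])
  expect_equal(dup[1, ], dup[2, ])
  expect_error(predict(m, matrix(0, 4, 7)), "feature width")
})

test_that("LSTM gradients match finite differences", {
  m <- build_classifier(12, 3, hidden = 6, seed = 2)
  withr::local_seed(6)
  seqs <- lapply(1:5, function(i) matrix(rnorm(4 * 12), 4, 12))
  y <- matrix(0, 5, 3); y[cbind(1:5, c(1, 2, 3, 1, 2))] <- 1
  xt <- lungsound:::seq_batch(seqs)
  fwd <- lungsound:::lstm_forward(m, xt)
  g <- lungsound:::lstm_backward(m, xt, fwd, y)
  loss_at <- function(p) {
    m2 <- m; m2$params <- p
    f <- lungsound:::lstm_forward(m2, xt)
    -mean(log(rowSums(f$probs * y)))
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (k in 1:3) {
      i <- sample(length(m$params[[nm]]), 1)
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("the classifier fits separable latent sequences reproducibly", {
  withr::local_seed(7)
  n <- 40
  labs <- rep(c("up", "down"), each = n / 2)
  seqs <- lapply(seq_len(n), function(i) {
    base <- if (labs[i] == "up") seq(0, 1, length.out = 8) else seq(1, 0, length.out = 8)
    outer(base, rep(1, 16)) + matrix(rnorm(8 * 16, sd = 0.1), 8, 16)
  })
  m <- build_classifier(16, 2, hidden = 8, seed = 3)
  fit <- train_classifier(m, seqs, labs, train_config(epochs = 50, seed = 4,
                                                      batch_size = 8))
  expect_gte(tail(fit$history$accuracy, 1), 0.95)
  fit2 <- train_classifier(build_classifier(16, 2, hidden = 8, seed = 3),
                           seqs, labs,
                           train_config(epochs = 50, seed = 4, batch_size = 8))
  expect_identical(tail(fit$history$loss, 1), tail(fit2$history$loss, 1))
  expect_error(train_classifier(m, seqs, rep("up", n)), "single class")
})
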