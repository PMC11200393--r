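#' Training configuration
#'
#' Shared by the autoencoders and the classifier: Adam optimiser
#' (beta1 = 0.9, beta2 = 0.999) with a default learning rate of 0.001, the
#' setting found to score best at 200 epochs; desk-scale runs use far fewer
#' epochs.
#'
#' @param learning_rate Positive step size.
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 200L,
                         batch_size = 32L, seed = 0L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  list(learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

CAE_ENC <- list(c(1L, 16L), c(16L, 32L), c(32L, 64L), c(64L, 128L), c(128L, 128L))
CAE_DEC <- list(c(128L, 128L), c(128L, 64L), c(64L, 32L), c(32L, 16L), c(16L, 1L))

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a convolutional autoencoder
#'
#' Encoder: five 3x3 stride-2 convolutions (ReLU) taking a 128x128x1 image
#' through 64x64x16, 32x32x32, 16x16x64, 8x8x128 and 4x4x128, flattened to a
#' 2048-dimensional latent vector. Decoder: dense 2048 -> 2048, reshape to
#' 4x4x128, then five 3x3 stride-2 transposed convolutions (ReLU, sigmoid on
#' the output) back to 128x128x1.
#'
#' @param seed Integer seed for the Glorot-uniform initialisation.
#' @return A `lung_cae` object (list of weight arrays).
#' @export
build_cae <- function(seed = 0L) {
  withr::with_seed(seed, {
    p <- list()
    for (l in seq_along(CAE_ENC)) {
      cin <- CAE_ENC[[l]][1]; cout <- CAE_ENC[[l]][2]
      p[[paste0("enc", l, "_w")]] <- glorot(9 * cin, cout, 9 * cin, 9 * cout)
      p[[paste0("enc", l, "_b")]] <- numeric(cout)
    }
    p$dense_w <- glorot(2048, 2048, 2048, 2048)
    p$dense_b <- numeric(2048)
    for (l in seq_along(CAE_DEC)) {
      cin <- CAE_DEC[[l]][1]; cout <- CAE_DEC[[l]][2]
      p[[paste0("dec", l, "_w")]] <- glorot(cin, 9 * cout, 9 * cin, 9 * cout)
      p[[paste0("dec", l, "_b")]] <- numeric(cout)
    }
    structure(list(params = p, trained = FALSE, seed = as.integer(seed)),
              class = "lung_cae")
  })
}

# Stack a list of images (or a single matrix) into a (H, W, 1, N) array.
image_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  if (is.matrix(images)) images <- list(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  arr <- array(0, c(h, w, 1L, length(images)))
  for (i in seq_along(images)) arr[, , 1L, i] <- images[[i]]
  arr
}

relu_ <- function(x) { x[x < 0] <- 0; x }

# Full forward pass with cached activations for backprop.
cae_forward <- function(cae, x) {
  p <- cae$params
  n <- dim(x)[4]
  acts <- list(x)
  a <- x
  for (l in seq_along(CAE_ENC)) {
    a <- .conv_fwd(a, p[[paste0("enc", l, "_w")]], p[[paste0("enc", l, "_b")]],
                   TRUE)
    acts[[l + 1]] <- a
  }
  latent <- a; dim(latent) <- c(2048L, n)
  d <- relu_(p$dense_w %*% latent + p$dense_b)
  d_cube <- d; dim(d_cube) <- c(4L, 4L, 128L, n)
  dec_acts <- list(d_cube)
  a <- d_cube
  for (l in seq_len(4)) {
    a <- .convt_fwd(a, p[[paste0("dec", l, "_w")]], p[[paste0("dec", l, "_b")]],
                    TRUE)
    dec_acts[[l + 1]] <- a
  }
  z_out <- .convt_fwd(a, p$dec5_w, p$dec5_b)
  xhat <- 1 / (1 + exp(-z_out))
  list(xhat = xhat, latent = latent, enc_acts = acts, dec_acts = dec_acts)
}

cae_backward <- function(cae, x, fwd) {
  p <- cae$params
  n <- dim(x)[4]
  g <- list()
  d_out <- 2 * (fwd$xhat - x) / length(x)          # d(mean sq err)/d xhat
  dz <- d_out * fwd$xhat * (1 - fwd$xhat)          # sigmoid output stage
  bw <- .convt_bwd(fwd$dec_acts[[5]], p$dec5_w, dz)
  g$dec5_w <- bw$dw; g$dec5_b <- as.numeric(bw$db)
  da <- bw$dx
  for (l in 4:1) {
    bw <- .convt_bwd(fwd$dec_acts[[l]], p[[paste0("dec", l, "_w")]], da,
                     fwd$dec_acts[[l + 1]])
    g[[paste0("dec", l, "_w")]] <- bw$dw; g[[paste0("dec", l, "_b")]] <- as.numeric(bw$db)
    da <- bw$dx
  }
  dd <- da; dim(dd) <- c(2048L, n)
  d_flat <- fwd$dec_acts[[1]]; dim(d_flat) <- c(2048L, n)
  dd <- dd * (d_flat > 0)
  g$dense_w <- tcrossprod(dd, fwd$latent)
  g$dense_b <- rowSums(dd)
  da <- crossprod(p$dense_w, dd)
  dim(da) <- c(4L, 4L, 128L, n)
  for (l in 5:1) {
    bw <- .conv_bwd(fwd$enc_acts[[l]], p[[paste0("enc", l, "_w")]], da,
                    fwd$enc_acts[[l + 1]])
    g[[paste0("enc", l, "_w")]] <- bw$dw; g[[paste0("enc", l, "_b")]] <- as.numeric(bw$db)
    da <- bw$dx
  }
  g
}

adam_init <- function(params) {
  # moment buffers are freshly allocated so the compiled update may mutate
  # them in place across steps
  list(m = purrr::map(params, ~ .x * 0), v = purrr::map(params, ~ .x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  params <- .adam_update(params, grads[names(params)], state$m, state$v,
                         state$t, lr, beta1, beta2, eps)
  list(params = params, state = state)
}

#' Shapes of every autoencoder stage for a given input
#'
#' Runs a forward pass and reports the output shape of each encoder and
#' decoder stage; useful for conformance checks against the intended
#' architecture.
#'
#' @param cae A `lung_cae`.
#' @param image A 128x128 matrix (defaults to zeros).
#' @return Tibble with `stage` and `shape` (character, `"HxWxC"` or a length).
#' @export
cae_stage_shapes <- function(cae, image = matrix(0, 128, 128)) {
  fwd <- cae_forward(cae, image_array(image))
  fmt <- function(a) paste(dim(a)[1:3], collapse = "x")
  shapes <- c(purrr::map_chr(fwd$enc_acts[-1], fmt),
              as.character(nrow(fwd$latent)),
              "2048",
              purrr::map_chr(fwd$dec_acts, fmt)[-1],
              fmt(fwd$xhat))
  # decoder reshape stage
  shapes <- append(shapes, fmt(fwd$dec_acts[[1]]), after = 7L)
  tibble::tibble(
    stage = c(paste0("conv", 1:5), "flatten", "dense", "reshape",
              paste0("convT", 1:5)),
    shape = shapes)
}

#' Train a convolutional autoencoder
#'
#' Minimises the mean squared reconstruction error with Adam on shuffled
#' minibatches; fully seeded so identical configurations reproduce identical
#' weights.
#'
#' @param cae A `lung_cae` from [build_cae()].
#' @param images List of 128x128 matrices in \[0, 1\] (or an (H,W,1,N) array).
#' @param config A [train_config()].
#' @param verbose Print the per-epoch loss?
#' @return The trained `lung_cae`, with a `history` tibble (`epoch`, `loss`).
#' @export
train_cae <- function(cae, images, config = train_config(epochs = 30L),
                      verbose = FALSE) {
  x_all <- image_array(images)
  n <- dim(x_all)[4]
  stopifnot(n >= 1)
  state <- adam_init(cae$params)
  history <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        step <- .cae_step(cae$params, xb)
        loss <- step$loss
        if (!is.finite(loss))
          stop("non-finite reconstruction loss at epoch ", ep,
               " (learning rate too high?)")
        upd <- adam_step(cae$params, step$grads, state, config$learning_rate)
        cae$params <- upd$params; state <- upd$state
        losses <- c(losses, loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %3d  mse %.5f", ep, history[ep]))
    }
  })
  cae$trained <- TRUE
  cae$history <- tibble::tibble(epoch = seq_len(config$epochs), loss = history)
  cae
}

#' Encode images into latent feature vectors
#'
#' Deterministic encoder forward pass; each 128x128 image maps to the
#' 2048-dimensional bottleneck.
#'
#' @param cae A `lung_cae`.
#' @param images A matrix, list of matrices, or (H,W,1,N) array.
#' @return A 2048 x N matrix (a plain 2048-vector for a single image).
#' @export
encode <- function(cae, images) {
  x <- image_array(images)
  if (dim(x)[1] != 128 || dim(x)[2] != 128)
    stop("encoder expects 128x128 single-channel images, got ",
         dim(x)[1], "x", dim(x)[2])
  a <- .cae_encode(cae$params, x)
  if (ncol(a) == 1L) as.numeric(a) else a
}

#' Reconstruct images through the autoencoder
#'
#' @param cae A `lung_cae`.
#' @param images A matrix, list of matrices, or (H,W,1,N) array.
#' @return Array (128, 128, 1, N) of reconstructions in \[0, 1\].
#' @export
reconstruct <- function(cae, images) {
  cae_forward(cae, image_array(images))$xhat
}

#' Peak signal-to-noise ratio between two images in \[0, 1\]
#'
#' `10 * log10(1 / MSE)`; a perfect reconstruction (MSE = 0) is reported as
#' the capped sentinel value `cap`.
#'
#' @param original,reconstructed Equal-shaped numeric arrays in \[0, 1\].
#' @param cap Sentinel dB value for an exact match.
#' @return PSNR in decibels.
#' @export
psnr <- function(original, reconstructed, cap = 120) {
  if (!identical(dim(original), dim(reconstructed)) ||
      length(original) != length(reconstructed))
    stop("psnr: image shapes differ")
  mse <- mean((as.numeric(original) - as.numeric(reconstructed))^2)
  if (mse == 0) cap else min(10 * log10(1 / mse), cap)
}

#' Fuse the two branch latents into the hybrid feature sequence
#'
#' Concatenates `[cwt || mel]` into a 4096-vector and reshapes it row-major
#' into an 8-timestep x 512-feature sequence, the unique width for which the
#' 64-unit LSTM's printed parameter count holds. Flattening the result
#' row-wise reproduces the concatenation exactly.
#'
#' @param cwt,mel Length-2048 latent vectors.
#' @return An 8 x 512 matrix.
#' @export
fuse <- function(cwt, mel) {
  if (length(cwt) != 2048 || length(mel) != 2048)
    stop("fuse expects two length-2048 latent vectors")
  matrix(c(as.numeric(cwt), as.numeric(mel)), nrow = 8L, ncol = 512L, byrow = TRUE)
}

#' Reshape a single-branch latent into an LSTM input sequence
#'
#' Ablation helper: one 2048-vector becomes a 4 x 512 row-major sequence.
#'
#' @param latent Length-2048 vector.
#' @return A 4 x 512 matrix.
#' @export
latent_sequence <- function(latent) {
  if (length(latent) != 2048) stop("expected a length-2048 latent vector")
  matrix(as.numeric(latent), nrow = 4L, ncol = 512L, byrow = TRUE)
}

#' @export
print.lung_cae <- function(x, ...) {
  n_par <- sum(purrr::map_int(x$params, length))
  cat("<lung_cae> 128x128x1 -> 2048 latent, ", format(n_par, big.mark = ","),
      " parameters, ", if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}
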