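#' Build the LSTM sequence classifier
#'
#' A single LSTM layer (64 hidden units; input, forget, cell and output
#' gates with sigmoid/tanh activations) reads the latent feature sequence;
#' the final hidden state feeds a dense softmax over the task classes. For
#' the fused 512-feature input and 2 classes the architecture totals exactly
#' 147,842 trainable parameters (147,712 LSTM + 130 dense).
#'
#' @param input_dim Features per timestep (512 for the fused sequence).
#' @param n_classes Number of output classes (>= 2).
#' @param hidden Hidden units (default 64).
#' @param seed Integer seed for the Glorot-uniform initialisation.
#' @return A `lung_lstm` object.
#' @export
build_classifier <- function(input_dim = 512L, n_classes = 2L, hidden = 64L,
                             seed = 0L) {
  stopifnot(n_classes >= 2, input_dim >= 1, hidden >= 1)
  withr::with_seed(seed, {
    p <- list(
      # gate blocks ordered [i | f | c | o], one fused matrix per source
      Wx = glorot(input_dim, 4L * hidden, input_dim, hidden),
      Wh = glorot(hidden, 4L * hidden, hidden, hidden),
      b  = numeric(4L * hidden),
      Wd = glorot(hidden, n_classes, hidden, n_classes),
      bd = numeric(n_classes)
    )
    # forget-gate bias 1: standard initialisation easing gradient flow
    p$b[hidden + seq_len(hidden)] <- 1
    structure(list(params = p, input_dim = as.integer(input_dim),
                   n_classes = as.integer(n_classes), hidden = as.integer(hidden),
                   classes = NULL, trained = FALSE, seed = as.integer(seed)),
              class = "lung_lstm")
  })
}

#' Trainable parameter counts of a classifier
#'
#' @param model A `lung_lstm`.
#' @return Tibble with per-layer (`lstm`, `dense`) and `total` counts.
#' @export
count_parameters <- function(model) {
  p <- model$params
  lstm <- length(p$Wx) + length(p$Wh) + length(p$b)
  dense <- length(p$Wd) + length(p$bd)
  tibble::tibble(layer = c("lstm", "dense", "total"),
                 parameters = c(lstm, dense, lstm + dense))
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

# Stack a list of T x D sequence matrices into an (N, T, D)-indexed list of
# per-timestep N x D matrices (the layout the batched recurrence consumes).
seq_batch <- function(sequences) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  T_len <- nrow(sequences[[1]])
  lapply(seq_len(T_len), function(t)
    do.call(rbind, lapply(sequences, function(s) s[t, ])))
}

lstm_forward <- function(model, xt_list) {
  p <- model$params
  H <- model$hidden
  n <- nrow(xt_list[[1]])
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", length(xt_list))
  for (t in seq_along(xt_list)) {
    z <- xt_list[[t]] %*% p$Wx + h %*% p$Wh + matrix(p$b, n, 4 * H, byrow = TRUE)
    i_g <- sigmoid_(z[, 1:H, drop = FALSE])
    f_g <- sigmoid_(z[, H + 1:H, drop = FALSE])
    g_g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o_g <- sigmoid_(z[, 3 * H + 1:H, drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    h_new <- o_g * tanh(c_new)
    cache[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = cc, c = c_new, h_prev = h)
    cc <- c_new; h <- h_new
  }
  logits <- h %*% p$Wd + matrix(p$bd, n, length(p$bd), byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, h_final = h, cache = cache)
}

lstm_backward <- function(model, xt_list, fwd, y_onehot) {
  p <- model$params
  H <- model$hidden
  n <- nrow(y_onehot)
  dlogits <- (fwd$probs - y_onehot) / n
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0,
            Wd = t(fwd$h_final) %*% dlogits, bd = colSums(dlogits))
  dh <- dlogits %*% t(p$Wd)
  dc <- matrix(0, n, H)
  for (t in rev(seq_along(xt_list))) {
    cch <- fwd$cache[[t]]
    tc <- tanh(cch$c)
    do <- dh * tc * cch$o * (1 - cch$o)
    dc <- dc + dh * cch$o * (1 - tc^2)
    di <- dc * cch$g * cch$i * (1 - cch$i)
    df <- dc * cch$c_prev * cch$f * (1 - cch$f)
    dg <- dc * cch$i * (1 - cch$g^2)
    dz <- cbind(di, df, dg, do)
    g$Wx <- g$Wx + t(xt_list[[t]]) %*% dz
    g$Wh <- g$Wh + t(cch$h_prev) %*% dz
    g$b <- g$b + colSums(dz)
    dh <- dz %*% t(p$Wh)
    dc <- dc * cch$f
  }
  g
}

#' Train the LSTM classifier
#'
#' Categorical cross-entropy with the Adam optimiser on shuffled
#' minibatches; seeded and reproducible.
#'
#' @param model A `lung_lstm` from [build_classifier()].
#' @param sequences List of T x `input_dim` matrices (e.g. from [fuse()]).
#' @param labels Character/factor labels, one per sequence; at least two
#'   distinct classes must be present.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return The trained `lung_lstm` with a `history` tibble
#'   (`epoch`, `loss`, `accuracy`).
#' @export
train_classifier <- function(model, sequences, labels,
                             config = train_config(epochs = 50L),
                             verbose = FALSE) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training labels contain a single class")
  if (length(classes) != model$n_classes)
    stop("model built for ", model$n_classes, " classes but labels have ",
         length(classes))
  y_idx <- match(labels, classes)
  n <- length(sequences)
  y_onehot_all <- matrix(0, n, length(classes))
  y_onehot_all[cbind(seq_len(n), y_idx)] <- 1

  state <- adam_init(model$params)
  hist_loss <- hist_acc <- numeric(config$epochs)
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xt <- seq_batch(sequences[idx])
        yb <- y_onehot_all[idx, , drop = FALSE]
        fwd <- lstm_forward(model, xt)
        loss <- -mean(log(rowSums(fwd$probs * yb) + 1e-12))
        if (!is.finite(loss)) stop("non-finite classifier loss at epoch ", ep)
        grads <- lstm_backward(model, xt, fwd, yb)
        upd <- adam_step(model$params, grads, state, config$learning_rate)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(fwd$probs) == max.col(yb))
      }
      hist_loss[ep] <- ep_loss / n
      hist_acc[ep] <- ep_hit / n
      if (verbose) message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                                   ep, hist_loss[ep], hist_acc[ep]))
    }
  })
  model$classes <- classes
  model$trained <- TRUE
  model$history <- tibble::tibble(epoch = seq_len(config$epochs),
                                  loss = hist_loss, accuracy = hist_acc)
  model
}

#' Class probabilities for latent feature sequences
#'
#' @param object A `lung_lstm`.
#' @param sequences A T x `input_dim` matrix or list of them.
#' @param ... Unused.
#' @return Tibble with one row per sequence: `.pred_class` plus one
#'   probability column per class (rows sum to 1).
#' @export
predict.lung_lstm <- function(object, sequences, ...) {
  if (is.matrix(sequences)) sequences <- list(sequences)
  bad <- which(vapply(sequences, ncol, 1L) != object$input_dim)
  if (length(bad))
    stop("sequence feature width does not match the model input (",
         object$input_dim, ")")
  fwd <- lstm_forward(object, seq_batch(sequences))
  classes <- object$classes %||% paste0("class", seq_len(object$n_classes))
  probs <- fwd$probs
  colnames(probs) <- classes
  out <- tibble::as_tibble(as.data.frame(probs, check.names = FALSE))
  tibble::add_column(out, .pred_class = classes[max.col(probs, "first")],
                     .before = 1)
}

#' @export
print.lung_lstm <- function(x, ...) {
  cp <- count_parameters(x)
  cat("<lung_lstm> ", x$input_dim, "-feature steps -> ", x$hidden,
      " units -> ", x$n_classes, " classes (",
      format(cp$parameters[3], big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  invisible(x)
}
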