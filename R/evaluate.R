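#' Define a classification task over a cycle dataset
#'
#' The task menu mirrors the study design: six binary problems (`"n-ab"`
#' groups every adventitious label into `Ab`; `"c-w"`, `"b-c"`, `"b-w"`,
#' `"c-n"`, `"w-n"` keep two cycle labels), two three-class problems
#' (`"b-c-w"`, `"c-n-w"`), the four-class N/C/W/B problem (`"four"`), and
#' the eight-class disease problem (`"eight"`, which uses the per-patient
#' diagnosis instead of the cycle label).
#'
#' @param name One of the task names above.
#' @return A `task_definition` list: `name`, `label_source`,
#'   `included_labels`, `grouping`.
#' @export
task_definition <- function(name = c("four", "n-ab", "c-w", "b-c", "b-w",
                                     "c-n", "w-n", "b-c-w", "c-n-w", "eight")) {
  name <- match.arg(name)
  pair <- function(...) {
    labs <- toupper(c(...))
    list(label_source = "cycle_label", included_labels = labs, grouping = NULL)
  }
  def <- switch(name,
    "n-ab"  = list(label_source = "cycle_label", included_labels = CYCLE_LEVELS,
                   grouping = c(N = "N", C = "Ab", W = "Ab", B = "Ab")),
    "c-w"   = pair("c", "w"),
    "b-c"   = pair("b", "c"),
    "b-w"   = pair("b", "w"),
    "c-n"   = pair("c", "n"),
    "w-n"   = pair("w", "n"),
    "b-c-w" = pair("b", "c", "w"),
    "c-n-w" = pair("c", "n", "w"),
    "four"  = pair("n", "c", "w", "b"),
    "eight" = list(label_source = "disease_label",
                   included_labels = DISEASE_LEVELS, grouping = NULL))
  structure(c(list(name = name), def), class = "task_definition")
}

#' Restrict a dataset to a task and derive its labels
#'
#' Drops cycles outside the task's label set, applies any grouping (e.g.
#' `{C, W, B} -> Ab`), and stores the result in a `task_label` column.
#'
#' @param cycles A `lung_cycles` tibble.
#' @param task A [task_definition()] or task name.
#' @return The filtered tibble with `task_label` added.
#' @export
apply_task <- function(cycles, task = task_definition("four")) {
  if (is.character(task)) task <- task_definition(task)
  labs <- cycles[[task$label_source]]
  keep <- !is.na(labs) & labs %in% task$included_labels
  out <- cycles[keep, , drop = FALSE]
  lab <- out[[task$label_source]]
  if (!is.null(task$grouping)) lab <- unname(task$grouping[lab])
  out$task_label <- lab
  if (length(unique(lab)) < 2)
    stop("task '", task$name, "' yields fewer than two classes on this dataset")
  as_lung_cycles(out)
}

#' Stratified train/test split
#'
#' Splits per class so that each class contributes `round(train_fraction *
#' n_c)` training samples (within one); disjoint and exhaustive, seeded.
#'
#' @param cycles A tibble with the stratification column.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @param stratify_on Column name holding the class label.
#' @return List with `train` and `test` tibbles.
#' @export
split_dataset <- function(cycles, train_fraction = 0.8, seed = 0L,
                          stratify_on = "task_label") {
  labs <- cycles[[stratify_on]]
  counts <- table(labs)
  tiny <- names(counts)[counts < 2]
  if (length(tiny))
    stop("class(es) with fewer than 2 samples cannot be split: ",
         paste(tiny, collapse = ", "))
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(labs == cl)
      n_train <- min(max(round(train_fraction * length(idx)), 1L),
                     length(idx) - 1L)
      sample(idx, n_train)
    }))
  })
  list(train = as_lung_cycles(cycles[sort(train_idx), , drop = FALSE]),
       test = as_lung_cycles(cycles[-sort(train_idx), , drop = FALSE]))
}

#' Confusion matrix
#'
#' @param true,predicted Equal-length label vectors.
#' @param class_order Optional class ordering; defaults to the sorted union.
#' @return A `lung_confusion` integer matrix, rows = true, cols = predicted.
#' @export
confusion <- function(true, predicted, class_order = NULL) {
  if (length(true) == 0) stop("cannot build a confusion matrix from no samples")
  if (length(true) != length(predicted))
    stop("true and predicted label vectors differ in length")
  true <- as.character(true); predicted <- as.character(predicted)
  if (is.null(class_order)) class_order <- sort(unique(c(true, predicted)))
  unknown <- setdiff(unique(c(true, predicted)), class_order)
  if (length(unknown))
    stop("label(s) outside class_order: ", paste(unknown, collapse = ", "))
  f <- factor(true, class_order)
  g <- factor(predicted, class_order)
  m <- table(true = f, predicted = g)
  structure(unclass(as.matrix(m)), class = "lung_confusion")
}

# Per-class one-vs-rest counts.
ovr_counts <- function(cm) {
  total <- sum(cm)
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- total - tp - fn - fp
  tibble::tibble(class = rownames(cm), tp = tp, tn = tn, fp = fp, fn = fn)
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Per-class one-vs-rest metrics of a confusion matrix
#'
#' @param x A `lung_confusion`.
#' @param ... Unused.
#' @return Tibble with `class`, counts and `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
tidy.lung_confusion <- function(x, ...) {
  d <- ovr_counts(x)
  d$accuracy <- (d$tp + d$tn) / (d$tp + d$tn + d$fp + d$fn)
  d$precision <- safe_div(d$tp, d$tp + d$fp)
  d$sensitivity <- safe_div(d$tp, d$tp + d$fn)
  d$specificity <- safe_div(d$tn, d$tn + d$fp)
  d$f1 <- safe_div(2 * d$precision * d$sensitivity, d$precision + d$sensitivity)
  d
}

#' Averaged classification metrics
#'
#' One-vs-rest accuracy, precision, sensitivity (recall), specificity and F1.
#' `macro` averages the per-class values unweighted; `micro` pools the
#' one-vs-rest counts first (for which precision = recall = overall
#' accuracy). F1 combines precision and recall from the same averaging mode,
#' with the 0/0 -> 0 convention.
#'
#' @param cm A `lung_confusion`.
#' @param averaging `"macro"` or `"micro"`.
#' @return One-row tibble: `averaging`, `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`, `n`.
#' @export
metrics <- function(cm, averaging = c("macro", "micro")) {
  averaging <- match.arg(averaging)
  if (averaging == "macro") {
    d <- tidy.lung_confusion(cm)
    out <- tibble::tibble(averaging = "macro",
                          accuracy = mean(d$accuracy),
                          precision = mean(d$precision),
                          sensitivity = mean(d$sensitivity),
                          specificity = mean(d$specificity))
  } else {
    d <- ovr_counts(cm)
    p <- safe_div(sum(d$tp), sum(d$tp) + sum(d$fp))
    r <- safe_div(sum(d$tp), sum(d$tp) + sum(d$fn))
    out <- tibble::tibble(averaging = "micro",
                          accuracy = sum(diag(cm)) / sum(cm),
                          precision = p,
                          sensitivity = r,
                          specificity = safe_div(sum(d$tn), sum(d$tn) + sum(d$fp)))
  }
  out$f1 <- safe_div(2 * out$precision * out$sensitivity,
                     out$precision + out$sensitivity)
  out$n <- sum(cm)
  out
}

#' Overall multiclass accuracy (fraction of correctly labelled samples)
#' @param cm A `lung_confusion`.
#' @return `trace / total`.
#' @export
overall_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' @export
print.lung_confusion <- function(x, ...) {
  cat("<lung_confusion> (rows = true, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("overall accuracy: %.3f\n", overall_accuracy(x)))
  invisible(x)
}

#' Plot a confusion matrix as a heat map
#' @param object A `lung_confusion`.
#' @param ... Unused.
#' @return A ggplot tile plot with counts annotated.
#' @export
autoplot.lung_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Confusion matrix", x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

derive_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2147483647L

# Shared feature pipeline: transform, train per-branch CAEs on the training
# images only (two-phase: CAEs are frozen before classifier training), and
# encode both partitions.
pipeline_encode <- function(train, test, branches, cae_epochs, seed,
                            pad = pad_config(), verbose = FALSE) {
  tr <- preprocess_cycles(train, pad)
  te <- preprocess_cycles(test, pad)
  branch_arg <- if (length(branches) == 2) "both" else branches
  img_tr <- transform_cycles(tr, branch = branch_arg)
  img_te <- transform_cycles(te, branch = branch_arg)
  out <- list(caes = list(), train = list(), test = list())
  for (b in branches) {
    cae <- build_cae(seed = derive_seed(seed, match(b, c("mel", "cwt"))))
    cae <- train_cae(cae, img_tr[[b]],
                     train_config(epochs = cae_epochs,
                                  seed = derive_seed(seed, 10L)),
                     verbose = verbose)
    out$caes[[b]] <- cae
    lat_tr <- encode(cae, img_tr[[b]])
    lat_te <- encode(cae, img_te[[b]])
    # standardise latent features with training-set statistics: the raw
    # ReLU latents are large and non-negative, which saturates LSTM gates
    mu <- rowMeans(lat_tr)
    sg <- apply(lat_tr, 1, sd)
    sg[sg < 1e-8] <- 1
    out$train[[b]] <- (lat_tr - mu) / sg
    out$test[[b]] <- (lat_te - mu) / sg
    out$scaling[[b]] <- list(mean = mu, sd = sg)
  }
  out
}

feature_sequences <- function(enc, partition, features) {
  lat <- enc[[partition]]
  if (identical(features, "fused")) {
    lapply(seq_len(ncol(lat$cwt)), function(i) fuse(lat$cwt[, i], lat$mel[, i]))
  } else {
    m <- lat[[features]]
    lapply(seq_len(ncol(m)), function(i) latent_sequence(m[, i]))
  }
}

#' Run the full classification pipeline on a cycle dataset
#'
#' Orchestrates: task restriction, stratified 80/20 split, optional
#' training-set augmentation, resample/pad preprocessing, parallel mel/CWT
#' scalogram transformation, per-branch autoencoder training (training
#' images only, then frozen), latent encoding and fusion, LSTM training, and
#' test-set evaluation. Every stage is seeded from `seed`.
#'
#' @param cycles A `lung_cycles` tibble.
#' @param task A [task_definition()] or task name.
#' @param features `"fused"` (hybrid pool), `"cwt"` or `"mel"` (ablations).
#' @param seed Master integer seed.
#' @param cae_epochs,lstm_epochs Training lengths for the two phases.
#' @param train_fraction Training share of the split.
#' @param augment Optional named multiplicity vector passed to
#'   [augment_dataset()] on the training portion only (prevents leakage).
#' @param pad A [pad_config()].
#' @param verbose Print training progress?
#' @return A `lung_experiment`: metrics (macro and micro), confusion matrix,
#'   fitted models, histories and a config echo.
#' @export
run_experiment <- function(cycles, task = "four",
                           features = c("fused", "cwt", "mel"),
                           seed = 7L, cae_epochs = 30L, lstm_epochs = 50L,
                           train_fraction = 0.8, augment = NULL,
                           pad = pad_config(), verbose = FALSE) {
  features <- match.arg(features)
  if (is.character(task)) task <- task_definition(task)
  ds <- apply_task(cycles, task)
  split <- split_dataset(ds, train_fraction, seed = derive_seed(seed, 1L))
  train <- split$train
  if (!is.null(augment))
    train <- augment_dataset(train, augment_params(seed = derive_seed(seed, 2L)),
                             multiplicity = augment)
  branches <- if (features == "fused") c("cwt", "mel") else features
  enc <- pipeline_encode(train, split$test, branches, cae_epochs,
                         seed, pad, verbose)
  fit <- fit_and_score(enc, features, train$task_label, split$test$task_label,
                       lstm_epochs, seed, verbose)
  structure(list(
    task = task$name, features = features,
    metrics = dplyr::bind_rows(metrics(fit$cm, "macro"), metrics(fit$cm, "micro")),
    confusion = fit$cm,
    classifier = fit$model, caes = enc$caes,
    n_train = nrow(train), n_test = nrow(split$test),
    config = list(seed = seed, cae_epochs = cae_epochs,
                  lstm_epochs = lstm_epochs, train_fraction = train_fraction,
                  augment = augment, pad = pad)),
    class = "lung_experiment")
}

fit_and_score <- function(enc, features, train_labels, test_labels,
                          lstm_epochs, seed, verbose = FALSE) {
  seq_tr <- feature_sequences(enc, "train", features)
  seq_te <- feature_sequences(enc, "test", features)
  classes <- sort(unique(as.character(train_labels)))
  model <- build_classifier(input_dim = 512L, n_classes = length(classes),
                            seed = derive_seed(seed, 20L))
  model <- train_classifier(model, seq_tr, train_labels,
                            train_config(epochs = lstm_epochs,
                                         seed = derive_seed(seed, 21L)),
                            verbose = verbose)
  pred <- predict(model, seq_te)
  cm <- confusion(test_labels, pred$.pred_class, class_order = classes)
  list(model = model, cm = cm)
}

#' Fused-versus-single-branch ablation on one dataset
#'
#' Runs the pipeline once (shared split, transforms and autoencoders), then
#' trains one classifier per feature set (`cwt`, `mel`, `fused`) so the
#' comparison isolates the feature pool.
#'
#' @inheritParams run_experiment
#' @param detail Also return the fitted autoencoders, the split and the
#'   per-feature confusion matrices (as attributes `caes`, `split`,
#'   `confusions`)?
#' @return Tibble with one row per feature set: macro metrics plus
#'   `overall_accuracy`.
#' @export
run_ablation <- function(cycles, task = "four", seed = 7L, cae_epochs = 30L,
                         lstm_epochs = 50L, train_fraction = 0.8,
                         pad = pad_config(), verbose = FALSE, detail = FALSE) {
  if (is.character(task)) task <- task_definition(task)
  ds <- apply_task(cycles, task)
  split <- split_dataset(ds, train_fraction, seed = derive_seed(seed, 1L))
  enc <- pipeline_encode(split$train, split$test, c("cwt", "mel"),
                         cae_epochs, seed, pad, verbose)
  cms <- list()
  out <- purrr::map_dfr(c("cwt", "mel", "fused"), function(fm) {
    fit <- fit_and_score(enc, fm, split$train$task_label,
                         split$test$task_label, lstm_epochs, seed, verbose)
    cms[[fm]] <<- fit$cm
    dplyr::bind_cols(tibble::tibble(features = fm),
                     metrics(fit$cm, "macro"),
                     tibble::tibble(overall_accuracy = overall_accuracy(fit$cm)))
  })
  if (detail) {
    attr(out, "caes") <- enc$caes
    attr(out, "split") <- split
    attr(out, "confusions") <- cms
  }
  out
}

#' @export
print.lung_experiment <- function(x, ...) {
  cat("<lung_experiment> task '", x$task, "', features '", x$features,
      "' (", x$n_train, " train / ", x$n_test, " test)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.lung_experiment <- function(x, ...) x$metrics

#' @export
glance.lung_experiment <- function(x, ...) {
  tibble::tibble(task = x$task, features = x$features,
                 n_train = x$n_train, n_test = x$n_test,
                 accuracy = overall_accuracy(x$confusion),
                 macro_f1 = x$metrics$f1[x$metrics$averaging == "macro"])
}

#' @export
tidy.lung_lstm <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history; train it first")
  x$history
}

#' @export
glance.lung_lstm <- function(x, ...) {
  cp <- count_parameters(x)
  tibble::tibble(n_parameters = cp$parameters[cp$layer == "total"],
                 hidden = x$hidden, n_classes = x$n_classes,
                 trained = x$trained,
                 final_loss = if (is.null(x$history)) NA_real_
                              else x$history$loss[nrow(x$history)])
}

#' @export
tidy.lung_cae <- function(x, ...) {
  if (is.null(x$history)) stop("autoencoder has no training history")
  x$history
}

#' @export
glance.lung_cae <- function(x, ...) {
  tibble::tibble(n_parameters = sum(purrr::map_int(x$params, length)),
                 latent_dim = 2048L, trained = x$trained,
                 final_loss = if (is.null(x$history)) NA_real_
                              else x$history$loss[nrow(x$history)])
}

#' Plot a training history
#' @param object A trained `lung_cae` or `lung_lstm`.
#' @param ... Unused.
#' @return A ggplot line chart of loss (and accuracy when present) by epoch.
#' @export
autoplot.lung_lstm <- function(object, ...) plot_history(tidy(object))

#' @rdname autoplot.lung_lstm
#' @export
autoplot.lung_cae <- function(object, ...) plot_history(tidy(object))

plot_history <- function(h) {
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}
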