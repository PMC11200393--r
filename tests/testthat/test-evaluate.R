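toy_cycles <- function(labels, diseases = NULL) {
  n <- length(labels)
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    recording_id = sprintf("p%03d_r1", seq_len(n)),
    cycle_index = 1L,
    start_time = 0, end_time = 1,
    crackles = as.integer(labels %in% c("C", "B")),
    wheezes = as.integer(labels %in% c("W", "B")),
    cycle_label = labels,
    disease_label = diseases %||% NA_character_,
    sample_rate = 4000, augmented = FALSE,
    waveform = replicate(n, numeric(10), simplify = FALSE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tasks restrict labels and apply the N-vs-abnormal grouping", {
  labs <- c(rep("N", 10), rep("C", 6), rep("W", 3), rep("B", 2))
  cyc <- toy_cycles(labs)
  nab <- apply_task(cyc, "n-ab")
  expect_equal(sum(nab$task_label == "N"), 10)
  expect_equal(sum(nab$task_label == "Ab"), 11)
  cw <- apply_task(cyc, "c-w")
  expect_equal(sort(unique(cw$task_label)), c("C", "W"))
  expect_equal(nrow(cw), 9)
  four <- apply_task(cyc, "four")
  expect_equal(nrow(four), 21)
  dis <- sample(c("Healthy", "COPD", "Asthma"), 21, replace = TRUE)
  eight <- apply_task(toy_cycles(labs, dis), "eight")
  expect_equal(eight$task_label, dis)
  expect_error(apply_task(toy_cycles(rep("N", 5)), "four"), "fewer than two")
})

test_that("the stratified 80/20 split is exact per class and seeded", {
  labs <- rep(c("N", "C", "W", "B"), each = 25)
  cyc <- apply_task(toy_cycles(labs), "four")
  sp <- split_dataset(cyc, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(unname(table(sp$train$task_label)), rep(20L, 4), ignore_attr = TRUE)
  sp2 <- split_dataset(cyc, 0.8, seed = 1)
  expect_identical(sp$train$patient_id, sp2$train$patient_id)
  # imbalanced: per-class test fraction within one sample of 0.2
  withr::local_seed(2)
  labs2 <- sample(c("N", "C", "W"), 200, TRUE, prob = c(0.7, 0.2, 0.1))
  cyc2 <- apply_task(toy_cycles(labs2), "four")
  sp3 <- split_dataset(cyc2, 0.8, seed = 3)
  for (cl in unique(labs2)) {
    n_cl <- sum(labs2 == cl)
    expect_lte(abs(sum(sp3$test$task_label == cl) - 0.2 * n_cl), 1)
  }
  bad <- toy_cycles(c("N", "N", "W"))
  bad$task_label <- bad$cycle_label
  expect_error(split_dataset(bad, 0.8, 1), "W")
})

test_that("confusion matrices count true-by-predicted pairs", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(true = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 3L)
  perfect <- confusion(c("x", "y", "z"), c("x", "y", "z"))
  expect_true(all(unclass(perfect) == diag(3)))
  expect_error(confusion(character(), character()), "no samples")
  expect_error(confusion("A", "Q", class_order = c("A", "B")), "outside")
  expect_error(confusion(c("A", "B"), "A"), "length")
})

test_that("metrics follow the one-vs-rest definitions", {
  # TP = TN = FP = FN = 1 for the positive class
  cm <- confusion(c("pos", "pos", "neg", "neg"), c("pos", "neg", "pos", "neg"))
  d <- tidy(cm)
  pos <- d[d$class == "pos", ]
  expect_equal(pos$accuracy, 0.5)
  expect_equal(pos$precision, 0.5)
  expect_equal(pos$sensitivity, 0.5)
  expect_equal(pos$specificity, 0.5)
  expect_equal(pos$f1, 0.5)
  perfect <- confusion(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  mm <- metrics(perfect, "macro")
  expect_equal(unlist(mm[, c("accuracy", "precision", "sensitivity",
                             "specificity", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
})

test_that("micro averaging collapses to overall accuracy", {
  withr::local_seed(8)
  truth <- sample(c("a", "b", "c"), 60, TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("a", "b", "c", "a"), 60, TRUE))
  cm <- confusion(truth, pred, class_order = c("a", "b", "c"))
  mi <- metrics(cm, "micro")
  expect_equal(mi$precision, mi$sensitivity)
  expect_equal(mi$precision, overall_accuracy(cm))
  expect_equal(mi$accuracy, sum(diag(cm)) / sum(cm))
})

test_that("binary sensitivity of one class equals specificity of the other", {
  withr::local_seed(9)
  truth <- sample(c("N", "Ab"), 80, TRUE)
  pred <- ifelse(runif(80) < 0.8, truth, sample(c("N", "Ab"), 80, TRUE))
  d <- tidy(confusion(truth, pred, class_order = c("Ab", "N")))
  expect_equal(d$sensitivity[d$class == "Ab"], d$specificity[d$class == "N"])
  expect_equal(d$sensitivity[d$class == "N"], d$specificity[d$class == "Ab"])
})

test_that("F1 is zero when precision and recall are both zero", {
  cm <- confusion(c("a", "a", "b"), c("b", "b", "a"), class_order = c("a", "b"))
  d <- tidy(cm)
  expect_equal(d$f1, c(0, 0))
  expect_equal(metrics(cm, "macro")$f1, 0)
})

test_that("a reduced experiment runs end to end with tidy accessors", {
  cyc <- synth_cycles(8, tiny_config(seed = 12L), labels = c("N", "W"))
  exp1 <- run_experiment(cyc, task = "w-n", features = "mel", seed = 5,
                         cae_epochs = 2, lstm_epochs = 4)
  expect_s3_class(exp1, "lung_experiment")
  expect_equal(sum(unclass(exp1$confusion)), exp1$n_test)
  expect_equal(nrow(exp1$metrics), 2)
  expect_true(all(unlist(exp1$metrics[, 2:6]) >= 0 &
                  unlist(exp1$metrics[, 2:6]) <= 1))
  g <- glance(exp1)
  expect_equal(g$task, "w-n")
  expect_equal(g$n_train + g$n_test, 16)
  expect_s3_class(tidy(exp1$classifier), "tbl_df")
  expect_s3_class(autoplot(exp1$confusion), "ggplot")
  expect_s3_class(autoplot(exp1$caes$mel), "ggplot")
})
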