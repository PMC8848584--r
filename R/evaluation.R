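#' Confusion matrix
#'
#' `k x k` count table with rows = true class and columns = predicted
#' class: `counts[i, j]` is the number of sequences of true class `i - 1`
#' predicted as class `j - 1`.
#'
#' @param y_true,y_pred equal-length integer label vectors in `0:(k-1)`.
#' @param k number of classes (default 4).
#' @param class_names optional row/column names.
#' @return object of class `confusion_matrix` (an integer matrix).
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), k = 2)
#' @export
confusion_matrix <- function(y_true, y_pred, k = 4L, class_names = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  if (any(y_true < 0 | y_true > k - 1L) || any(y_pred < 0 | y_pred > k - 1L)) {
    stop(sprintf("labels must lie in 0..%d", k - 1L), call. = FALSE)
  }
  cm <- matrix(0L, k, k)
  for (t in seq_along(y_true)) {
    cm[y_true[t] + 1L, y_pred[t] + 1L] <- cm[y_true[t] + 1L, y_pred[t] + 1L] + 1L
  }
  if (!is.null(class_names)) {
    dimnames(cm) <- list(true = class_names, predicted = class_names)
  }
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' The proportion of correctly classified sequences,
#' `100 * sum(diag(cm)) / sum(cm)`, as a percentage.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @return percentage in \[0, 100\].
#' @examples
#' cm <- confusion_matrix(c(0, 1, 1), c(0, 1, 0), k = 2)
#' overall_accuracy(cm)  # 66.67
#' @export
overall_accuracy <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("cm must be a square matrix", call. = FALSE)
  }
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm)) / tot
}

#' Four-way feature-ablation experiment
#'
#' For each seed: pre-trains the stacked sparse auto-encoder once on the
#' training matrix, then fine-tunes and evaluates the four fusion
#' configurations — code-only, code + dispersion, code + ApEn, and code +
#' both — on the held-out test set. Reports a confusion matrix and
#' overall accuracy per configuration and seed, plus mean and SD over
#' seeds.
#'
#' @param dataset an `isi_dataset`.
#' @param config `sae_config`.
#' @param seeds integer vector of seeds (one pre-training per seed).
#' @return object of class `ablation_report`: list with `runs` (nested
#'   per seed and configuration: `cm`, `accuracy`), `summary`
#'   (data.frame of accuracies), `mean_accuracy` and `sd_accuracy`
#'   (named by configuration), `seeds`, `config`.
#' @export
run_ablation <- function(dataset, config = sae_config(), seeds = 0:4) {
  configs <- list(code_only = c(FALSE, FALSE),
                  with_cov = c(TRUE, FALSE),
                  with_apen = c(FALSE, TRUE),
                  with_both = c(TRUE, TRUE))
  runs <- list()
  rows <- list()
  for (sd_i in seeds) {
    stack <- stack_pretrain(dataset$train, config, seed = sd_i)
    per_cfg <- list()
    for (cn in names(configs)) {
      fl <- configs[[cn]]
      clf <- train_rhythm_classifier(dataset, config,
                                     include_cov = fl[1], include_apen = fl[2],
                                     seed = sd_i, stack = stack)
      pred <- predict(clf, dataset$test)
      cm <- confusion_matrix(dataset$test_labels, pred, k = 4L,
                             class_names = dataset$class_names)
      acc <- overall_accuracy(cm)
      per_cfg[[cn]] <- list(cm = cm, accuracy = acc)
      rows[[length(rows) + 1L]] <- data.frame(seed = sd_i, configuration = cn,
                                              accuracy = acc)
    }
    runs[[as.character(sd_i)]] <- per_cfg
  }
  summary <- do.call(rbind, rows)
  mean_acc <- tapply(summary$accuracy, summary$configuration, mean)[names(configs)]
  sd_acc <- tapply(summary$accuracy, summary$configuration, stats::sd)[names(configs)]
  structure(list(runs = runs, summary = summary,
                 mean_accuracy = mean_acc, sd_accuracy = sd_acc,
                 seeds = seeds, config = config),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("ablation_report over %d seed(s):\n", length(x$seeds)))
  for (cn in names(x$mean_accuracy)) {
    cat(sprintf("  %-10s mean accuracy %6.2f%%  (sd %.2f)\n",
                cn, x$mean_accuracy[[cn]],
                ifelse(is.na(x$sd_accuracy[[cn]]), 0, x$sd_accuracy[[cn]])))
  }
  invisible(x)
}

#' Write an ablation report to JSON and a text table
#'
#' @param report an `ablation_report`.
#' @param dir output directory (created if missing).
#' @return `dir` invisibly.
#' @export
write_ablation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- list(seeds = report$seeds,
              mean_accuracy = as.list(report$mean_accuracy),
              sd_accuracy = as.list(report$sd_accuracy),
              runs = lapply(report$runs, function(per_cfg) {
                lapply(per_cfg, function(r) {
                  list(confusion = unclass(r$cm), accuracy = r$accuracy)
                })
              }),
              config = unclass(report$config))
  jsonlite::write_json(obj, file.path(dir, "ablation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "ablation.txt"))
  invisible(dir)
}
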