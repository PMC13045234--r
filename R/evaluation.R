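# Evaluation: leave-one-subject-out cross-validation, the fixed
# train/validation protocol split, confusion matrices and accuracies.

#' Leave-one-subject-out split plan
#'
#' All recordings of `held_out_subject` form the test set; the
#' remaining recordings are shuffled deterministically and split into
#' training and validation sets (validation fraction 0.2 by default,
#' matching the 80/20 protocol).
#'
#' @param manifest Corpus manifest (see [generate_corpus()]).
#' @param held_out_subject Subject id to hold out.
#' @param seed Split seed.
#' @param val_fraction Fraction of the non-held-out recordings used for
#'   validation.
#' @return A `split_plan`: list of `train_ids`, `val_ids`, `test_ids`
#'   (recording ids), plus the arguments.
#' @export
make_split <- function(manifest, held_out_subject, seed = 1L,
                       val_fraction = 0.2) {
  validate_manifest(manifest)
  subjects <- sort(unique(manifest$subject_id))
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects; found ",
         length(subjects))
  if (!held_out_subject %in% subjects)
    stop("unknown subject: ", held_out_subject)
  test_ids <- manifest$recording_id[manifest$subject_id == held_out_subject]
  rest <- manifest$recording_id[manifest$subject_id != held_out_subject]
  ord <- with_seed(seed, sample(rest))
  n_val <- round(val_fraction * length(rest))
  val_ids <- sort(ord[seq_len(n_val)])
  train_ids <- sort(ord[-seq_len(n_val)])
  structure(list(held_out_subject = held_out_subject,
                 train_ids = train_ids, val_ids = val_ids,
                 test_ids = sort(test_ids),
                 val_fraction = val_fraction, split_seed = as.integer(seed)),
            class = "split_plan")
}

#' Confusion matrix with fixed class order
#'
#' @param truth,pred Vectors of labels (coerced to character).
#' @param levels Class order.
#' @return `length(levels)` square matrix; rows = truth, columns =
#'   predicted; row sums equal the per-class truth counts.
#' @export
confusion_matrix <- function(truth, pred, levels) {
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  if (anyNA(truth) || anyNA(pred))
    stop("labels outside the declared class set")
  table(truth = truth, predicted = pred)
}

#' Evaluate a trained model on one test set
#'
#' @param model A trained `throat_model`.
#' @param test_set List with `x`, `y_emotion`, `y_text` (as in
#'   [train_model()]).
#' @return A `fold_report`: confusion matrices over the fixed class
#'   orders, accuracies, and per-class precision; classes absent from
#'   the test set are reported as NA, not zero.
#' @export
evaluate_fold <- function(model, test_set) {
  pred <- predict_model(model, test_set$x)
  y_em <- EMOTIONS[as_label_index(test_set$y_emotion, EMOTIONS, "emotion") + 1L]
  y_tx <- as_label_index(test_set$y_text, as.character(0:4), "text")
  cm_em <- confusion_matrix(y_em, pred$emotion, EMOTIONS)
  cm_tx <- confusion_matrix(y_tx, pred$sentence_id, as.character(0:4))
  prec <- function(cm) {
    tp <- diag(cm)
    predicted <- colSums(cm)
    truth <- rowSums(cm)
    p <- ifelse(predicted > 0, tp / predicted, NA_real_)
    p[truth == 0] <- NA_real_   # class absent from the test set
    p
  }
  structure(list(
    emotion_confusion = cm_em,
    text_confusion = cm_tx,
    emotion_accuracy = sum(diag(cm_em)) / sum(cm_em),
    text_accuracy = sum(diag(cm_tx)) / sum(cm_tx),
    emotion_precision = prec(cm_em),
    text_precision = prec(cm_tx),
    n_test = length(y_em)),
    class = "fold_report")
}

subset_set <- function(features, manifest, ids) {
  rows <- match(ids, manifest$recording_id)
  list(x = features[ids],
       y_emotion = manifest$emotion[rows],
       y_text = manifest$sentence_id[rows])
}

#' Leave-one-subject-out cross-validation
#'
#' Runs one fold per subject: train on the remaining subjects (with an
#' 80/20 train/validation split), test on the held-out subject, and
#' aggregate accuracies as unweighted mean +/- SD across folds.
#'
#' @param features Named list of 40 x 128 feature matrices (names =
#'   recording ids), e.g. from [extract_features()] over a corpus.
#' @param manifest The corpus manifest.
#' @param config A [recognizer_config()].
#' @param seed Seed driving splits, initialization and training.
#' @param subjects Optional subset of subjects to use as folds.
#' @param verbose Print per-fold progress.
#' @return An `evaluation_report`: per-fold `fold_report`s plus
#'   aggregate mean/SD accuracies.
#' @export
run_loso <- function(features, manifest, config = recognizer_config(),
                     seed = 1L, subjects = NULL, verbose = FALSE) {
  validate_manifest(manifest)
  all_subjects <- sort(unique(manifest$subject_id))
  if (length(all_subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  if (is.null(subjects)) subjects <- all_subjects
  folds <- list()
  for (s in subjects) {
    plan <- make_split(manifest, s, seed = seed + s)
    model <- build_model(config, seed = seed + s)
    model <- train_model(model,
                         subset_set(features, manifest, plan$train_ids),
                         subset_set(features, manifest, plan$val_ids),
                         seed = seed + s, verbose = verbose)
    rep <- evaluate_fold(model, subset_set(features, manifest, plan$test_ids))
    rep$held_out_subject <- s
    rep$split <- plan
    rep$best_epoch <- model$best_epoch
    if (verbose)
      message(sprintf("fold subject %d: emotion %.3f text %.3f",
                      s, rep$emotion_accuracy, rep$text_accuracy))
    folds[[as.character(s)]] <- rep
  }
  em_acc <- vapply(folds, `[[`, numeric(1), "emotion_accuracy")
  tx_acc <- vapply(folds, `[[`, numeric(1), "text_accuracy")
  structure(list(folds = folds,
                 emotion_accuracy_mean = mean(em_acc),
                 emotion_accuracy_sd = if (length(em_acc) > 1) stats::sd(em_acc) else 0,
                 text_accuracy_mean = mean(tx_acc),
                 text_accuracy_sd = if (length(tx_acc) > 1) stats::sd(tx_acc) else 0,
                 seed = as.integer(seed)),
            class = "evaluation_report")
}

#' Serialize an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param path Output path; `.json` for machine-readable, `.md` for a
#'   rendered Markdown summary.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (grepl("\\.json$", path)) {
    out <- list(
      emotion_accuracy_mean = report$emotion_accuracy_mean,
      emotion_accuracy_sd = report$emotion_accuracy_sd,
      text_accuracy_mean = report$text_accuracy_mean,
      text_accuracy_sd = report$text_accuracy_sd,
      folds = lapply(report$folds, function(f) list(
        held_out_subject = f$held_out_subject,
        emotion_accuracy = f$emotion_accuracy,
        text_accuracy = f$text_accuracy,
        emotion_confusion = unclass(f$emotion_confusion),
        text_confusion = unclass(f$text_confusion))))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c("# Leave-one-subject-out evaluation", "",
               sprintf("- Emotion accuracy: %.4f +/- %.4f",
                       report$emotion_accuracy_mean,
                       report$emotion_accuracy_sd),
               sprintf("- Text accuracy: %.4f +/- %.4f",
                       report$text_accuracy_mean, report$text_accuracy_sd),
               "")
    for (f in report$folds) {
      lines <- c(lines,
                 sprintf("## Fold: held-out subject %d", f$held_out_subject),
                 sprintf("emotion %.4f, text %.4f", f$emotion_accuracy,
                         f$text_accuracy), "",
                 "### Emotion confusion", "```",
                 utils::capture.output(print(f$emotion_confusion)), "```",
                 "### Text confusion", "```",
                 utils::capture.output(print(f$text_confusion)), "```", "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}
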