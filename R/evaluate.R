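#' @name evaluate
#' @title Classification metrics
NULL

#' ROC AUC by the rank statistic
#'
#' Area under the ROC curve computed from the Mann-Whitney rank statistic
#' with average ranks, so tied scores receive half credit (constant scores
#' give AUC 0.5).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param positive Logical vector: `TRUE` for positive truth.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) if truth has a single
#'   class.
#' @export
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: truth contains a single class")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points over all score thresholds (ties merged)
roc_points <- function(scores, positive) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(s) {
    c(fpr = sum(scores >= s & !positive) / max(sum(!positive), 1L),
      tpr = sum(scores >= s & positive) / max(sum(positive), 1L))
  }, c(fpr = 0, tpr = 0)))
  rbind(data.frame(fpr = 0, tpr = 0), as.data.frame(pts),
        data.frame(fpr = 1, tpr = 1))
}

#' Evaluate predictions at patch or slide level
#'
#' At patch level each prediction row is scored against its true label.
#' At slide level patches are first aggregated per slide by majority vote
#' ([aggregate_slide_majority()]) with the slide's score taken as the mean
#' patch probability of the positive class.
#'
#' @param records [predict_graphs()] output.
#' @param truth Optional data.frame (`id`, `label`) keyed by patch or
#'   slide id; defaults to the `label` column carried in `records`.
#' @param level `"patch"` or `"slide"`.
#' @param positive_class Class treated as positive for ROC/AUC; defaults
#'   to the last probability column (the second class of a binary head).
#' @return List with `level`, `accuracy`, `confusion` (rows = truth),
#'   `auc`, `roc` (data.frame fpr/tpr), `n`.
#' @export
evaluate <- function(records, truth = NULL, level = c("patch", "slide"),
                     positive_class = NULL) {
  level <- match.arg(level)
  classes <- sub("^prob_", "", grep("^prob_", names(records), value = TRUE))
  if (is.null(positive_class)) positive_class <- classes[length(classes)]
  pcol <- paste0("prob_", positive_class)

  if (level == "patch") {
    truth_lab <- if (is.null(truth)) records$label else {
      truth$label[match(records$patch_id, truth$id)]
    }
    pred_lab <- records$predicted
    score <- records[[pcol]]
  } else {
    slides <- split(records, records$slide_id)
    pred_lab <- vapply(slides, aggregate_slide_majority, character(1),
                       classes = classes)
    score <- vapply(slides, function(df) mean(df[[pcol]]), numeric(1))
    truth_lab <- if (is.null(truth)) {
      vapply(slides, function(df) df$label[1L], character(1))
    } else {
      truth$label[match(names(slides), truth$id)]
    }
  }
  if (anyNA(truth_lab)) stop("missing truth label(s)")
  conf <- table(truth = factor(truth_lab, levels = classes),
                predicted = factor(pred_lab, levels = classes))
  list(level = level,
       accuracy = mean(pred_lab == truth_lab),
       confusion = conf,
       auc = rank_auc(score, truth_lab == positive_class),
       roc = roc_points(score, truth_lab == positive_class),
       n = length(truth_lab))
}

#' Build graphs for a whole dataset
#'
#' Convenience pipeline: fits the global feature scaler on the pooled
#' *training* nuclei only, builds a k-nearest-neighbour graph per patch,
#' applies the task's patch filter, and returns graphs grouped by split.
#'
#' @param dataset A [generate_dataset()] result, or a list with `manifest`
#'   and `tables`.
#' @param scheme The `cell_type_scheme` of the tables.
#' @param k Neighbour count.
#' @param counted_labels,min_count Optional patch filter (see
#'   [filter_patch()]); patches failing it are dropped.
#' @return List with `train`, `val`, `test` (lists of `cell_graph`s) and
#'   `scaler`.
#' @export
prepare_graphs <- function(dataset, scheme, k = 8, counted_labels = NULL,
                           min_count = 0) {
  man <- dataset$manifest
  keep <- rep(TRUE, nrow(man))
  if (!is.null(counted_labels)) {
    keep <- vapply(man$patch_id, function(pid) {
      filter_patch(dataset$tables[[pid]], counted_labels, min_count,
                   scheme = scheme)
    }, logical(1))
  }
  man <- man[keep, , drop = FALSE]
  train_tabs <- lapply(man$patch_id[man$split == "train"],
                       function(pid) as.data.frame(dataset$tables[[pid]]))
  if (length(train_tabs) == 0L) stop("no training patches after filtering")
  scaler <- fit_scaler(do.call(rbind, train_tabs))
  graphs <- lapply(seq_len(nrow(man)), function(i) {
    pid <- man$patch_id[i]
    build_graph(dataset$tables[[pid]], scheme = scheme, scaler = scaler,
                k = k,
                meta = list(patch_id = pid, slide_id = man$slide_id[i],
                            patient_id = man$patient_id[i],
                            label = man$label[i]))
  })
  out <- split(graphs, man$split)
  list(train = out[["train"]], val = out[["val"]], test = out[["test"]],
       scaler = scaler)
}
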