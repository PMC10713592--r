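#' @name train_eval
#' @title Training and prediction
#' @description
#' Networks are trained by minimizing graph-level cross-entropy with
#' either SGD with momentum (classification and risk tasks) or AdaDelta
#' (response task), selecting the epoch with the highest validation
#' accuracy (earliest epoch on ties).  Train/validation/test splits must
#' be slide-disjoint; this is asserted, never assumed.
NULL

#' Optimizer specification
#'
#' @param method `"sgd"` (with momentum) or `"adadelta"`.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param scaling_factor Multiplier on the AdaDelta update (the task
#'   presets use 2); decay `rho` and `epsilon` stay at conventional
#'   defaults.
#' @param rho,epsilon AdaDelta accumulator decay and stabilizer.
#' @param epochs Number of epochs, >= 1.
#' @param batch_size Graphs per gradient step.
#' @param seed Seed controlling shuffling, dropout and per-epoch
#'   resampling.
#' @return An `optimizer_spec`.
#' @export
optimizer_spec <- function(method = c("sgd", "adadelta"),
                           learning_rate = 1e-4, momentum = 0.9,
                           scaling_factor = 2, rho = 0.95, epsilon = 1e-6,
                           epochs = 50L, batch_size = 32L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(learning_rate > 0, momentum >= 0, scaling_factor > 0,
            epochs >= 1L, batch_size >= 1L)
  structure(list(method = method, learning_rate = learning_rate,
                 momentum = momentum, scaling_factor = scaling_factor,
                 rho = rho, epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "optimizer_spec")
}

# zero-filled structure matching a model's trainable parameters
zero_like_params <- function(model) {
  lapply(model$layers, function(l) {
    lapply(stats::setNames(layer_param_names, layer_param_names),
           function(nm) l[[nm]] * 0)
  })
}

add_grads <- function(acc, g) {
  for (i in seq_along(acc)) {
    for (nm in layer_param_names) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]]
  }
  acc
}

scale_grads <- function(g, s) {
  for (i in seq_along(g)) {
    for (nm in layer_param_names) g[[i]][[nm]] <- g[[i]][[nm]] * s
  }
  g
}

apply_update <- function(model, opt, state, grads) {
  for (i in seq_along(model$layers)) {
    for (nm in layer_param_names) {
      g <- grads[[i]][[nm]]
      if (opt$method == "sgd") {
        v <- opt$momentum * state$v[[i]][[nm]] - opt$learning_rate * g
        state$v[[i]][[nm]] <- v
        model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] + v
      } else {
        eg <- opt$rho * state$eg[[i]][[nm]] + (1 - opt$rho) * g^2
        dx <- -sqrt(state$ed[[i]][[nm]] + opt$epsilon) /
          sqrt(eg + opt$epsilon) * g * opt$scaling_factor
        state$eg[[i]][[nm]] <- eg
        state$ed[[i]][[nm]] <- opt$rho * state$ed[[i]][[nm]] +
          (1 - opt$rho) * dx^2
        model$layers[[i]][[nm]] <- model$layers[[i]][[nm]] + dx
      }
    }
  }
  list(model = model, state = state)
}

graph_labels <- function(graphs, classes) {
  labs <- vapply(graphs, function(g) as.character(g$meta$label), character(1))
  idx <- match(labs, classes)
  if (anyNA(idx)) {
    stop("graph label(s) not among model classes: ",
         paste(unique(labs[is.na(idx)]), collapse = ", "))
  }
  idx
}

assert_slide_disjoint <- function(...) {
  sets <- lapply(list(...), function(gs) {
    unique(vapply(gs, function(g) as.character(g$meta$slide_id), character(1)))
  })
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0) {
        stop("data leakage: the same slide_id appears in two splits (",
             paste(intersect(sets[[i]], sets[[j]]), collapse = ", "), ")")
      }
    }
  }
  invisible(TRUE)
}

#' Train a cell graph network
#'
#' Minimizes cross-entropy over the training graphs, evaluates accuracy on
#' the validation graphs after every epoch, and returns the checkpoint with
#' the highest validation accuracy (earliest epoch on ties).  Runs are
#' deterministic given `opt$seed`.
#'
#' @param model A `cellgraph_net`.
#' @param train_graphs,val_graphs Lists of labelled `cell_graph`s; their
#'   slide ids must be disjoint.
#' @param opt An [optimizer_spec()].
#' @param resample_per_epoch If `TRUE`, each epoch trains on one patch
#'   drawn (seeded) from each patient's pool instead of the full list —
#'   the regime used when patients contribute many patches but should
#'   weigh equally.
#' @return A `train_result`: list with `model` (best checkpoint),
#'   `best_epoch`, `history` (epoch, train_loss, val_accuracy) and
#'   `final_model`.
#' @export
train <- function(model, train_graphs, val_graphs, opt,
                  resample_per_epoch = FALSE) {
  stopifnot(inherits(opt, "optimizer_spec"),
            length(train_graphs) >= 1L, length(val_graphs) >= 1L)
  assert_slide_disjoint(train_graphs, val_graphs)
  classes <- model$config$classes
  train_y <- graph_labels(train_graphs, classes)
  val_y <- graph_labels(val_graphs, classes)
  patients <- vapply(train_graphs, function(g) as.character(g$meta$patient_id),
                     character(1))
  pools <- split(seq_along(train_graphs), patients)

  state <- list(v = zero_like_params(model), eg = zero_like_params(model),
                ed = zero_like_params(model))
  best <- list(acc = -Inf, epoch = NA_integer_, model = model)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_accuracy = numeric())
  set.seed(opt$seed)
  for (epoch in seq_len(opt$epochs)) {
    idx_pool <- if (resample_per_epoch) {
      vapply(pools, function(p) if (length(p) == 1L) p else sample(p, 1L),
             integer(1))
    } else {
      seq_along(train_graphs)
    }
    ord <- idx_pool[sample.int(length(idx_pool))]
    batches <- split(ord, ceiling(seq_along(ord) / opt$batch_size))
    losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      ids <- batches[[b]]
      acc <- zero_like_params(model)
      bl <- 0
      for (gi in ids) {
        r <- graph_loss_grads(model, train_graphs[[gi]], train_y[gi],
                              training = TRUE)
        if (!is.finite(r$loss)) {
          stop(sprintf("non-finite loss at epoch %d, graph %d", epoch, gi))
        }
        acc <- add_grads(acc, r$layer_grads)
        bl <- bl + r$loss
      }
      acc <- scale_grads(acc, 1 / length(ids))
      losses[b] <- bl / length(ids)
      upd <- apply_update(model, opt, state, acc)
      model <- upd$model; state <- upd$state
    }
    val_pred <- vapply(val_graphs, function(g) {
      which.max(forward(model, g)$probabilities)
    }, integer(1))
    val_acc <- mean(val_pred == val_y)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_accuracy = val_acc))
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch, model = model)
    }
  }
  structure(list(model = best$model, best_epoch = best$epoch,
                 history = history, final_model = model),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs; best val accuracy %.3f at epoch %d\n",
              nrow(x$history), max(x$history$val_accuracy), x$best_epoch))
  invisible(x)
}

#' Predict class probabilities for graphs
#'
#' Dropout is off; the predicted class is the argmax of the graph
#' probabilities (ties resolve to the lower class index).
#'
#' @param model A `cellgraph_net` (e.g. the best checkpoint from
#'   [train()]).
#' @param graphs List of `cell_graph`s.
#' @return Data frame with `patch_id`, `slide_id`, `patient_id`, `label`
#'   (the graph's own label, `NA` if unlabelled), one `prob_<class>`
#'   column per class, and `predicted`.
#' @export
predict_graphs <- function(model, graphs) {
  classes <- model$config$classes
  rows <- lapply(graphs, function(g) {
    p <- forward(model, g)$probabilities
    out <- data.frame(
      patch_id = as.character(g$meta$patch_id),
      slide_id = as.character(g$meta$slide_id),
      patient_id = as.character(g$meta$patient_id),
      label = as.character(g$meta$label),
      stringsAsFactors = FALSE
    )
    for (i in seq_along(classes)) out[[paste0("prob_", classes[i])]] <- p[i]
    out$predicted <- classes[which.max(p)]
    out
  })
  do.call(rbind, rows)
}

#' Slide label by majority vote
#'
#' The slide's label is the class with the most patch votes.  A tied vote
#' goes to the tied class with the higher mean predicted probability;
#' residual ties go to the lower class index.
#'
#' @param records Prediction rows ([predict_graphs()] output) for one
#'   slide.
#' @param classes Class names in logit order; defaults to those found in
#'   the probability columns.
#' @return A single class label.
#' @export
aggregate_slide_majority <- function(records, classes = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (is.null(classes)) {
    classes <- sub("^prob_", "",
                   grep("^prob_", names(records), value = TRUE))
  }
  votes <- vapply(classes, function(cl) sum(records$predicted == cl),
                  numeric(1))
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    meanp <- vapply(classes[top], function(cl) {
      mean(records[[paste0("prob_", cl)]])
    }, numeric(1))
    top <- top[which(meanp == max(meanp))]
  }
  classes[top[1L]]
}

#' Patient-level score by averaging patch scores
#'
#' Averages the predicted probability of the positive class (the "risk
#' score" or "benefitting score") over all of a patient's records.
#'
#' @param records Prediction rows for one patient.
#' @param positive_class Class whose probability is the score.
#' @return The mean score (scalar).
#' @export
aggregate_patient_mean <- function(records, positive_class) {
  stopifnot(nrow(records) >= 1L)
  col <- paste0("prob_", positive_class)
  if (!col %in% names(records)) stop("no probability column for class ",
                                     positive_class)
  mean(records[[col]])
}

#' Dichotomize patient scores
#'
#' Splits scores into positive/negative groups: `score > cutoff` is
#' positive, `score <= cutoff` negative.  `mode = "fixed"` uses the given
#' cutoff (e.g. 0.5 for risk stratification); `mode = "median"` sets the
#' cutoff to the sample median of the provided scores (so with all scores
#' equal, everyone is negative).
#'
#' @param scores Numeric patient-level scores (optionally named).
#' @param mode `"fixed"` or `"median"`.
#' @param cutoff Cutoff in (0, 1) for fixed mode.
#' @return Character vector (`"positive"`/`"negative"`) with the cutoff in
#'   attribute `"cutoff"`.
#' @export
dichotomize <- function(scores, mode = c("fixed", "median"), cutoff = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(scores) >= 1L)
  if (mode == "median") {
    cutoff <- stats::median(scores)
  } else {
    stopifnot(cutoff > 0, cutoff < 1)
  }
  out <- ifelse(scores > cutoff, "positive", "negative")
  names(out) <- names(scores)
  attr(out, "cutoff") <- cutoff
  out
}
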