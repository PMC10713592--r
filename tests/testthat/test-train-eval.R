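# small slide-disjoint labelled graph sets used across training tests
make_split_graphs <- function(n_train = 12, n_val = 6, seed0 = 100,
                              labels = c("A", "B")) {
  mk <- function(i, split) {
    g <- random_graph(seed0 + i, n_nuclei = 14,
                      label = labels[(i %% 2) + 1])
    g$meta$slide_id <- paste0(split, "_s", i)
    g$meta$patient_id <- paste0(split, "_pt", i)
    g$meta$patch_id <- paste0(split, "_p", i)
    g
  }
  list(train = lapply(seq_len(n_train), mk, split = "tr"),
       val = lapply(seq_len(n_val), mk, split = "va"))
}

test_that("training is deterministic under a fixed seed", {
  gs <- make_split_graphs()
  opt <- optimizer_spec("sgd", learning_rate = 1e-3, epochs = 3,
                        batch_size = 4, seed = 7)
  m <- new_cellgraph_net(config_histology(classes = c("A", "B")), seed = 2)
  r1 <- train(m, gs$train, gs$val, opt)
  r2 <- train(m, gs$train, gs$val, opt)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$layers, r2$model$layers)
})

test_that("the selected checkpoint is the earliest validation maximum", {
  gs <- make_split_graphs()
  opt <- optimizer_spec("sgd", learning_rate = 1e-3, epochs = 5,
                        batch_size = 4, seed = 3)
  m <- new_cellgraph_net(config_histology(classes = c("A", "B")), seed = 2)
  r <- train(m, gs$train, gs$val, opt)
  expect_equal(r$best_epoch,
               which.max(r$history$val_accuracy))  # which.max = earliest max
})

test_that("adadelta training runs and changes the parameters", {
  gs <- make_split_graphs(n_train = 8, n_val = 4)
  opt <- optimizer_spec("adadelta", scaling_factor = 2, epochs = 2,
                        batch_size = 4, seed = 1)
  m <- new_cellgraph_net(config_response(classes = c("A", "B")), seed = 2)
  r <- train(m, gs$train, gs$val, opt)
  expect_false(identical(r$final_model$layers[[1]]$theta,
                         m$layers[[1]]$theta))
  expect_equal(nrow(r$history), 2)
})

test_that("shared slide ids across splits are rejected as leakage", {
  gs <- make_split_graphs(n_train = 4, n_val = 2)
  gs$val[[1]]$meta$slide_id <- gs$train[[1]]$meta$slide_id
  opt <- optimizer_spec("sgd", epochs = 1, seed = 1)
  m <- new_cellgraph_net(config_histology(classes = c("A", "B")), seed = 1)
  expect_error(train(m, gs$train, gs$val, opt), "leakage")
})

test_that("per-epoch resampling draws one patch per patient and stays
           deterministic", {
  gs <- make_split_graphs(n_train = 12, n_val = 4)
  # pool patches under 3 patients
  for (i in seq_along(gs$train)) {
    gs$train[[i]]$meta$patient_id <- paste0("pt", (i %% 3) + 1)
  }
  opt <- optimizer_spec("sgd", learning_rate = 1e-3, epochs = 3,
                        batch_size = 3, seed = 11)
  m <- new_cellgraph_net(config_histology(classes = c("A", "B")), seed = 2)
  r1 <- train(m, gs$train, gs$val, opt, resample_per_epoch = TRUE)
  r2 <- train(m, gs$train, gs$val, opt, resample_per_epoch = TRUE)
  expect_identical(r1$history, r2$history)
})

test_that("prediction is deterministic with argmax ties to the lower class", {
  g <- random_graph(201, n_nuclei = 12)
  m <- random_model(config_histology(classes = c("A", "B")), 5)
  p1 <- predict_graphs(m, list(g))
  p2 <- predict_graphs(m, list(g))
  expect_identical(p1, p2)
  expect_equal(p1$prob_A + p1$prob_B, 1, tolerance = 1e-9)
  # a zeroed model emits logits (0,0): tie resolves to the first class
  m0 <- zero_messages(m)
  for (i in seq_along(m0$layers)) m0$layers[[i]]$theta[] <- 0
  expect_identical(predict_graphs(m0, list(g))$predicted, "A")
})

test_that("slide-union prediction matches global pooling over components", {
  cfg <- config_response(classes = c("NB", "B"), dropout = 0)
  m <- random_model(cfg, 8)
  graphs <- lapply(301:303, random_graph, n_nuclei = 10)
  u <- merge_slide_graphs(graphs)
  pu <- forward(m, u)$graph_logits
  per <- vapply(graphs, function(g) forward(m, g)$graph_logits,
                numeric(2))
  ns <- vapply(graphs, `[[`, numeric(1), "n")
  expect_equal(pu, as.numeric(per %*% ns / sum(ns)), tolerance = 1e-12)
})

test_that("slide majority voting applies the stated tie rules", {
  rec <- data.frame(predicted = c("A", "A", "B"),
                    prob_A = c(0.9, 0.8, 0.4), prob_B = c(0.1, 0.2, 0.6))
  expect_equal(aggregate_slide_majority(rec, c("A", "B")), "A")
  tie <- data.frame(predicted = c("A", "B"),
                    prob_A = c(0.9, 0.5), prob_B = c(0.1, 0.5))
  expect_equal(aggregate_slide_majority(tie, c("A", "B")), "A")  # mean prob
  allb <- data.frame(predicted = c("B", "B"),
                     prob_A = c(0.2, 0.3), prob_B = c(0.8, 0.7))
  expect_equal(aggregate_slide_majority(allb, c("A", "B")), "B")
  # residual tie (equal votes and equal mean probability): lower index
  even <- data.frame(predicted = c("A", "B"),
                     prob_A = c(0.5, 0.5), prob_B = c(0.5, 0.5))
  expect_equal(aggregate_slide_majority(even, c("A", "B")), "A")
})

test_that("patient scores average the positive-class probability", {
  rec <- data.frame(prob_high = c(0.2, 0.4))
  expect_equal(aggregate_patient_mean(rec, "high"), 0.3)
  expect_equal(aggregate_patient_mean(rec[1, , drop = FALSE], "high"), 0.2)
  rec100 <- data.frame(prob_high = rep(0.8, 100))
  expect_equal(aggregate_patient_mean(rec100, "high"), 0.8)
})

test_that("dichotomization puts the boundary in the negative group", {
  g <- dichotomize(c(0.6, 0.5, 0.4), "fixed", cutoff = 0.5)
  expect_equal(as.character(g), c("positive", "negative", "negative"))
  g2 <- dichotomize(c(0.1, 0.2, 0.8, 0.9), "median")
  expect_equal(attr(g2, "cutoff"), 0.5)
  expect_equal(sum(g2 == "positive"), 2)
  g3 <- dichotomize(rep(0.7, 5), "median")
  expect_true(all(g3 == "negative"))  # every score <= its own median
})

test_that("the rank AUC handles separation, ties and the 4-point example", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  expect_equal(rank_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(rank_auc(c(0.9, 0.8, 0.3, 0.2),
                        c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_warning(a <- rank_auc(c(0.1, 0.9), c(TRUE, TRUE)), "single class")
  expect_true(is.na(a))
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  set.seed(4)
  for (i in 1:5) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(40, mean = y), 1)  # rounding forces ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rank_auc(s, y == 1), ref, tolerance = 1e-12)
  }
})

test_that("evaluate reports accuracy, confusion and ROC at both levels", {
  rec <- data.frame(
    patch_id = paste0("p", 1:6),
    slide_id = rep(c("s1", "s2"), each = 3),
    patient_id = rep(c("q1", "q2"), each = 3),
    label = rep(c("A", "B"), each = 3),
    prob_A = c(0.9, 0.8, 0.4, 0.3, 0.2, 0.6),
    prob_B = c(0.1, 0.2, 0.6, 0.7, 0.8, 0.4),
    predicted = c("A", "A", "B", "B", "B", "A"),
    stringsAsFactors = FALSE)
  ev <- evaluate(rec, level = "patch", positive_class = "B")
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(as.vector(ev$confusion), c(2, 1, 1, 2))
  expect_equal(ev$auc, rank_auc(rec$prob_B, rec$label == "B"))
  expect_true(all(diff(ev$roc$fpr) >= 0))
  evs <- evaluate(rec, level = "slide", positive_class = "B")
  expect_equal(evs$accuracy, 1)  # both slides majority-vote correctly
  expect_equal(evs$n, 2)
})

test_that("prepare_graphs fits the scaler on training nuclei only and
           filters patches", {
  specs <- list(A = synthetic_spec(lung_scheme(), "A", n_nuclei = 30,
                                   min_separation = 5,
                                   type_mixture = lung_mixture()),
                B = synthetic_spec(lung_scheme(), "B", n_nuclei = 30,
                                   min_separation = 5,
                                   type_mixture = lung_mixture()))
  ds <- generate_dataset(specs, n_patients = 6, slides_per_patient = 1,
                         patches_per_slide = 3,
                         split_fractions = c(2 / 3, 1 / 6, 1 / 6), seed = 4)
  gr <- prepare_graphs(ds, lung_scheme(), k = 8,
                       counted_labels = "tumor", min_count = 5)
  expect_gt(length(gr$train), 0)
  # scaler reproduces from the train-split tables alone
  man <- ds$manifest
  keep <- vapply(man$patch_id, function(p) {
    filter_patch(ds$tables[[p]], "tumor", 5, scheme = lung_scheme())
  }, logical(1))
  tr_ids <- man$patch_id[keep & man$split == "train"]
  pooled <- do.call(rbind, lapply(ds$tables[tr_ids], as.data.frame))
  expect_equal(gr$scaler$means, fit_scaler(pooled)$means)
  # graphs carry their manifest metadata
  expect_true(all(vapply(gr$val, function(g) g$meta$label,
                         character(1)) %in% c("A", "B")))
})
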