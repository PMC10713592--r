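test_that("FiLM modulation is affine in the two edge features", {
  id <- list(gamma_w = c(0, 0), gamma_a = c(0, 0), gamma_b = c(1, 1),
             beta_w = c(0, 0), beta_a = c(0, 0), beta_b = c(0, 0))
  expect_equal(film_modulate(c(1, 2), 0.3, 0.7, id), c(1, 2))
  two <- id; two$gamma_b <- c(2, 2); two$beta_b <- c(1, 1)
  expect_equal(film_modulate(c(1, 2), 0.3, 0.7, two), c(3, 5))
  # gamma = 1*w + 0*a + 0 evaluated at w = 0.5 halves the modulator
  half <- id; half$gamma_w <- c(1, 1); half$gamma_b <- c(0, 0)
  expect_equal(film_modulate(c(4, 4), 0.5, 0.9, half), c(2, 2))
})

test_that("with zero embeddings the layer reduces to relu of the self map", {
  g <- random_graph(11, n_nuclei = 15)
  set.seed(1)
  layer <- new_csigc_layer_params(11, 11, 36, dropout = 0)
  layer$EM[] <- 0
  layer$gamma_b[] <- 1
  layer$theta <- diag(11)
  out <- csigc_forward(layer, g$X, g, final = FALSE)
  expect_equal(out, pmax(g$X, 0))
})

test_that("the scalar layer averages neighbour messages and adds the self term", {
  # nodes hold X = (0, 2, 4); node 1 points at nodes 2 and 3; theta = 0 and
  # unit modulators make its pre-activation the plain message mean, 3
  g <- structure(list(
    n = 3L, X = matrix(c(0, 2, 4), 3, 1),
    node_types = c(0L, 0L, 0L),
    edges = cbind(src = c(1L, 1L, 2L, 3L), dst = c(2L, 3L, 1L, 1L)),
    edge_type = c(0L, 0L, 0L, 0L),
    parallelism = rep(0.5, 4), closeness = rep(0.1, 4),
    scheme = cell_type_scheme("one", "a"),
    meta = list()), class = "cell_graph")
  set.seed(1)
  layer <- new_csigc_layer_params(1, 1, 1, dropout = 0)
  layer$EM[] <- 1
  layer$gamma_w[] <- 0; layer$gamma_a[] <- 0; layer$gamma_b[] <- 1
  layer$beta_w[] <- 0; layer$beta_a[] <- 0; layer$beta_b[] <- 0
  layer$theta[] <- 0
  out <- csigc_forward(layer, g$X, g, final = TRUE)
  expect_equal(out[1, 1], 3)       # mean of neighbour values 2 and 4
  expect_equal(out[2, 1], 0)       # message from node 1 carries X = 0
  # literal self-source variant: messages carry the source node's features
  out_self <- csigc_forward(layer, g$X, g, message_source = "self",
                            final = TRUE)
  expect_equal(out_self[1, 1], 0)  # both out-edges carry X_1 = 0
  expect_equal(out_self[2, 1], 2)
})

test_that("self message and averaged neighbour messages add per channel", {
  # engineered two-channel case: me_self = (1,1), messages (0,2) and (2,0)
  g <- structure(list(
    n = 3L, X = matrix(c(1, 2, 2), 3, 1),
    node_types = c(0L, 0L, 1L),
    edges = cbind(src = c(1L, 1L, 2L, 3L), dst = c(2L, 3L, 1L, 1L)),
    edge_type = c(0L, 1L, 0L, 0L),
    parallelism = rep(1, 4), closeness = rep(1, 4),
    scheme = cell_type_scheme("two", c("a", "b")),
    meta = list()), class = "cell_graph")
  set.seed(1)
  layer <- new_csigc_layer_params(1, 2, 4, dropout = 0)
  layer$EM[] <- 0
  layer$EM[1, ] <- c(0, 1)   # edge type 0: message (0, X_m)
  layer$EM[2, ] <- c(1, 0)   # edge type 1: message (X_m, 0)
  layer$gamma_w[] <- 0; layer$gamma_a[] <- 0; layer$gamma_b[] <- 1
  layer$beta_w[] <- 0; layer$beta_a[] <- 0; layer$beta_b[] <- 0
  layer$theta[] <- c(1, 1)
  out <- csigc_forward(layer, g$X, g, final = TRUE)
  expect_equal(out[1, ], c(2, 2))  # (1,1) + mean{(0,2),(2,0)}
})

test_that("subgroup mean pooling averages masked rows per channel", {
  m <- rbind(c(1, 0), c(3, 2), c(5, 4))
  expect_equal(subgroup_mean_pool(m, c(TRUE, TRUE, FALSE)), c(2, 1))
  expect_equal(subgroup_mean_pool(m, rep(TRUE, 3)), colMeans(m))
  expect_error(subgroup_mean_pool(m, rep(FALSE, 3)), "empty")
})

test_that("forward pools node logits and applies softmax", {
  # a single-layer identity-style model over controlled 2-feature inputs:
  # both nodes pooled, engineered node logits (2,0) and (0,2)
  scheme <- cell_type_scheme("pair", c("a", "b"), pooled_labels = c("a", "b"))
  cfg <- task_config(scheme, widths = 2L, classes = c("c1", "c2"),
                     pooling = "subgroup", dropout = 0, n_features = 2)
  model <- zero_messages(new_cellgraph_net(cfg, seed = 1))
  model$layers[[1]]$theta <- diag(2)
  g <- controlled_graph(rbind(c(2, 0), c(0, 2)), scheme = scheme)
  fwd <- forward(model, g)
  expect_equal(fwd$node_logits, rbind(c(2, 0), c(0, 2)))
  expect_equal(fwd$graph_logits, c(1, 1))
  expect_equal(fwd$probabilities, c(0.5, 0.5))

  # a single pooled node with logits (1, 0): softmax closed form
  cfg1 <- task_config(scheme, widths = 2L, classes = c("c1", "c2"),
                      pooling = "subgroup", pooled_labels = "a",
                      dropout = 0, n_features = 2)
  model1 <- zero_messages(new_cellgraph_net(cfg1, seed = 1))
  model1$layers[[1]]$theta <- diag(2)
  g1 <- controlled_graph(rbind(c(1, 0), c(9, 9)), scheme = scheme,
                         node_types = c(0L, 1L))
  fwd1 <- forward(model1, g1)
  expect_equal(fwd1$probabilities, c(0.7311, 0.2689), tolerance = 1e-4)
})

test_that("graph logits equal the pooled node-logit mean bitwise", {
  for (seed in 1:5) {
    g <- random_graph(seed, n_nuclei = 20)
    m <- random_model(config_histology(classes = c("A", "B")), seed)
    fwd <- forward(m, g)
    expect_identical(fwd$graph_logits,
                     subgroup_mean_pool(fwd$node_logits, fwd$pooled_mask))
  }
})

test_that("node permutation permutes node logits and fixes graph outputs", {
  g <- random_graph(21, n_nuclei = 18)
  m <- random_model(config_histology(classes = c("A", "B")), 4)
  fwd <- forward(m, g)
  set.seed(5)
  perm <- sample(g$n)
  inv <- order(perm)
  gp <- g
  gp$X <- g$X[perm, , drop = FALSE]
  gp$node_types <- g$node_types[perm]
  gp$edges <- cbind(src = inv[g$edges[, 1]], dst = inv[g$edges[, 2]])
  fwdp <- forward(m, gp)
  expect_equal(fwdp$node_logits, fwd$node_logits[perm, ], tolerance = 1e-12)
  expect_equal(fwdp$probabilities, fwd$probabilities, tolerance = 1e-9)
})

test_that("the default classification network is in the reported size regime", {
  m <- new_cellgraph_net(config_histology(classes = c("ADC", "SCC")),
                         seed = 1)
  expect_gte(n_params(m), 5e3)
  expect_lte(n_params(m), 2e4)
})

test_that("checkpoints round-trip exactly", {
  spec <- synthetic_spec(lung_scheme(), "A", n_nuclei = 15,
                         min_separation = 4)
  tab <- generate_patch(spec, 2)
  m <- random_model(config_histology(classes = c("A", "B")), 7)
  m$scaler <- fit_scaler(tab)
  f <- tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  for (i in seq_along(m$layers)) {
    for (nm in c("EM", "theta", "gamma_w", "gamma_a", "gamma_b",
                 "beta_w", "beta_a", "beta_b")) {
      expect_identical(unname(m2$layers[[i]][[nm]]),
                       unname(m$layers[[i]][[nm]]))
    }
  }
  expect_equal(m2$scaler$means, m$scaler$means)
  g <- random_graph(30, n_nuclei = 14)
  expect_identical(forward(m2, g)$probabilities,
                   forward(m, g)$probabilities)
})

test_that("forward on a slide union with global pooling is the node-count
           weighted mean over components", {
  cfg <- config_response(classes = c("NB", "B"), dropout = 0)
  m <- random_model(cfg, 3)
  g1 <- random_graph(41, n_nuclei = 12)
  g2 <- random_graph(42, n_nuclei = 20)
  u <- merge_slide_graphs(list(g1, g2))
  fu <- forward(m, u)
  f1 <- forward(m, g1); f2 <- forward(m, g2)
  expect_equal(fu$graph_logits,
               (g1$n * f1$graph_logits + g2$n * f2$graph_logits) /
                 (g1$n + g2$n),
               tolerance = 1e-12)
})

test_that("scheme and width mismatches are configuration errors", {
  g <- random_graph(1, n_nuclei = 10)
  m_oral <- new_cellgraph_net(config_risk(), seed = 1)
  expect_error(forward(m_oral, g), "scheme")
  cfg <- task_config(lung_scheme(), widths = 2L, classes = c("A", "B"),
                     n_features = 5)
  expect_error(forward(new_cellgraph_net(cfg, seed = 1), g), "features")
})
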